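# brute-force oracle: the classical balanced partition computed directly
# with stats::aov Error() strata
aov_oracle <- function(data, dv, within, subject = "subject") {
  for (w in within) data[[w]] <- factor(data[[w]])
  data[[subject]] <- factor(data[[subject]])
  rhs <- paste(within, collapse = "*")
  form <- stats::as.formula(paste(dv, "~", rhs, "+ Error(", subject,
                                  "/(", rhs, "))"))
  fit <- summary(stats::aov(form, data = data))
  out <- list()
  for (stratum in fit) {
    tab <- stratum[[1]]
    for (i in seq_len(nrow(tab))) {
      nm <- trimws(rownames(tab)[i])
      if (nm != "Residuals")
        out[[nm]] <- list(ss = tab[i, "Sum Sq"], df = tab[i, "Df"],
                          F = tab[i, "F value"], p = tab[i, "Pr(>F)"],
                          ss_err = tab["Residuals", "Sum Sq"])
    }
  }
  out
}

toy_data <- function(seed, n_subj = 4, k = c(3, 2)) {
  asrtlab:::with_seed(seed, {
    d <- expand.grid(subject = seq_len(n_subj),
                     A = letters[seq_len(k[1])], B = seq_len(k[2]))
    d$value <- rnorm(nrow(d)) + 0.6 * as.numeric(factor(d$A)) +
      0.3 * d$B + rep(rnorm(n_subj), length.out = nrow(d))
    d
  })
}

test_that("sums of squares and F match the aov oracle on toy tables", {
  for (seed in c(1, 2, 3)) {
    d <- toy_data(seed)
    mine <- rm_anova(d, "value", c("A", "B"))
    oracle <- aov_oracle(d, "value", c("A", "B"))
    for (eff in c("A", "B", "A:B")) {
      row <- mine[mine$effect == eff, ]
      expect_equal(row$ss_effect, oracle[[eff]]$ss, tolerance = 1e-10)
      expect_equal(row$ss_error, oracle[[eff]]$ss_err, tolerance = 1e-10)
      expect_equal(row$F, oracle[[eff]]$F, tolerance = 1e-10)
      expect_equal(row$p, oracle[[eff]]$p, tolerance = 1e-10)
    }
  }
})

test_that("three-factor designs match the aov oracle", {
  d <- asrtlab:::with_seed(5, {
    g <- expand.grid(subject = 1:5, A = c("s", "r"), B = c("p", "q", "r"),
                     C = 1:2)
    g$value <- rnorm(nrow(g))
    g
  })
  mine <- rm_anova(d, "value", c("A", "B", "C"))
  oracle <- aov_oracle(d, "value", c("A", "B", "C"))
  for (eff in c("A", "B", "C", "A:B", "A:C", "B:C", "A:B:C")) {
    row <- mine[mine$effect == eff, ]
    expect_equal(row$F, oracle[[eff]]$F, tolerance = 1e-10)
    expect_equal(row$df1, oracle[[eff]]$df)
  }
})

test_that("a two-level factor gives F = t-squared and epsilon = 1", {
  d <- asrtlab:::with_seed(8, data.frame(
    subject = rep(1:10, 2), A = rep(c("x", "y"), each = 10),
    value = rnorm(20)))
  res <- rm_anova(d, "value", "A")
  tt <- paired_t(d$value[d$A == "x"], d$value[d$A == "y"])
  expect_equal(res$F, tt$t^2, tolerance = 1e-12)
  expect_equal(res$epsilon, 1)
  expect_equal(res$p, tt$p, tolerance = 1e-12)
})

test_that("epsilon estimator: k = 2, compound symmetry, and lower bound", {
  expect_equal(gg_epsilon(matrix(c(2, 0.3, 0.3, 1), 2)), 1)

  cs <- diag(5) * 3 + matrix(0.8, 5, 5)
  expect_equal(gg_epsilon(cs), 1)

  u <- c(2, -1, 0.5, -1.5)
  expect_equal(gg_epsilon(u %o% u), 1 / 3)

  expect_error(gg_epsilon(matrix(1, 2, 3)), "square")
  # epsilon always within [1/(k-1), 1] for random PSD matrices
  for (s in 1:20) {
    S <- asrtlab:::with_seed(s, {
      X <- matrix(rnorm(40), 10, 4); crossprod(X) / 10
    })
    e <- gg_epsilon(S)
    expect_gte(e, 1 / 3); expect_lte(e, 1)
  }
})

test_that("GG correction never lowers the p-value", {
  for (s in 1:10) {
    d <- toy_data(s, n_subj = 6, k = c(4, 3))
    res <- rm_anova(d, "value", c("A", "B"))
    expect_true(all(res$p_gg >= res$p - 1e-12))
    expect_true(all(res$epsilon >= 1 / (res$df1) & res$epsilon <= 1))
  }
})

test_that("LSD pairwise equals direct paired t-tests", {
  d <- toy_data(4, n_subj = 6, k = c(3, 1))
  d <- d[d$B == 1, ]
  lsd <- lsd_pairwise(d, "value", "A")
  for (i in seq_len(nrow(lsd))) {
    a <- d$value[d$A == lsd$level_a[i]]
    b <- d$value[d$A == lsd$level_b[i]]
    ref <- t.test(a, b, paired = TRUE)
    expect_equal(lsd$p[i], ref$p.value, tolerance = 1e-12)
    expect_equal(lsd$mean_diff[i], unname(ref$estimate), tolerance = 1e-12)
  }
  # antisymmetry
  d2 <- d; d2$A <- factor(d$A, levels = rev(sort(unique(d$A))))
  lsd2 <- lsd_pairwise(d2, "value", "A")
  ab <- lsd$mean_diff[lsd$level_a == "a" & lsd$level_b == "b"]
  ba <- lsd2$mean_diff[lsd2$level_a == "b" & lsd2$level_b == "a"]
  expect_equal(ab, -ba)
  # identical columns: no difference, p = 1
  dd <- data.frame(subject = rep(1:5, 2), A = rep(c("u", "v"), each = 5),
                   value = rep(rnorm(5), 2))
  same <- lsd_pairwise(dd, "value", "A")
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p, 1)
})

test_that("t-tests match hand computation and the paired identity", {
  tt <- one_sample_t(c(1, 2, 3), 0)
  expect_equal(tt$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(tt$df, 2L)
  ref <- t.test(c(1, 2, 3), mu = 0)
  expect_equal(tt$p, ref$p.value, tolerance = 1e-12)
})

test_that("all-equal values at mu0 give t = 0 via the definitional limit", {
  # zero variance is undefined; values equal to mu0 with any jitter -> t ~ 0
  expect_error(one_sample_t(rep(2, 5), 2), "zero variance")
  expect_error(paired_t(1:4, 1:4), "zero variance")
  for (s in 1:10) {
    ab <- asrtlab:::with_seed(s, list(a = rnorm(8), b = rnorm(8)))
    p1 <- paired_t(ab$a, ab$b)
    p2 <- one_sample_t(ab$a - ab$b, 0)
    expect_equal(p1$t, p2$t)
    expect_equal(p1$p, p2$p)
  }
})

test_that("degenerate inputs raise structural errors", {
  d <- toy_data(1)
  expect_error(rm_anova(d[-1, ], "value", c("A", "B")), "missing cell")
  dc <- d; dc$value <- 1
  expect_error(rm_anova(dc, "value", c("A", "B")), "undefined")
  expect_error(rm_anova(d, "value", character(0)), "within factors")
  dn <- d; dn$value[3] <- NA
  expect_error(rm_anova(dn, "value", c("A", "B")), "missing value")
})

test_that("null data reject at the nominal alpha", {
  # 400 null tables, one-way with 4 levels, alpha = .05; the uncorrected
  # test is exact under sphericity, the GG-corrected one at most as liberal
  ps <- vapply(1:400, function(s) {
    d <- asrtlab:::with_seed(1e6 + s, data.frame(
      subject = rep(1:12, 4), A = rep(letters[1:4], each = 12),
      value = rnorm(48)))
    r <- rm_anova(d, "value", "A")
    c(r$p, r$p_gg)
  }, numeric(2))
  ci <- 3 * sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(mean(ps[1, ] < 0.05) - 0.05), ci)
  expect_lte(mean(ps[2, ] < 0.05), mean(ps[1, ] < 0.05))
})
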