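# Within-subject factorial ANOVA with Greenhouse-Geisser correction,
# partial eta-squared, LSD pairwise follow-ups, and t-tests.
#
# The sums-of-squares partition is the classical balanced repeated-measures
# decomposition: for every effect A (a subset of the within factors), the
# effect array is obtained by inclusion-exclusion over marginal means and
# SS_A = m_A * sum(effect^2), with m_A the number of observations per
# level combination; the error term for A is its interaction with Subject.
# The Greenhouse-Geisser epsilon is the classical sample estimator computed
# from the covariance of the subjects' cell scores projected onto an
# orthonormal contrast basis of the effect.

# ---- helpers ---------------------------------------------------------------

# expand an effect array defined on dims `over` (subset of 1..nd) to the
# full dim vector `dims`
expand_effect <- function(eff, over, dims) {
  if (length(over) == 0L) return(array(eff, dim = dims))
  perm <- c(over, setdiff(seq_along(dims), over))
  full <- array(eff, dim = c(dims[over], dims[setdiff(seq_along(dims), over)]))
  aperm(full, order(perm))
}

all_subsets <- function(x) {
  out <- list()
  for (k in seq_along(x)) out <- c(out, utils::combn(x, k, simplify = FALSE))
  out
}

effect_array <- function(arr, A) {
  # inclusion-exclusion of marginal means; A indexes dims of arr
  dims <- dim(arr)
  res <- apply(arr, A, mean)
  proper <- if (length(A) > 1L)
    all_subsets(A)[-length(all_subsets(A))] else list()
  # subtract every proper-subset effect plus the grand mean
  res <- array(res, dim = dims[A])
  res <- res - mean(arr)
  for (B in proper) {
    effB <- effect_array(arr, B)
    res <- res - expand_effect(effB, match(B, A), dims[A])
  }
  res
}

orthonormal_contrasts <- function(k) {
  m <- stats::contr.helmert(k)
  sweep(m, 2L, sqrt(colSums(m^2)), "/")
}

# ---- Greenhouse-Geisser ----------------------------------------------------

#' Greenhouse-Geisser epsilon from a cell covariance matrix
#'
#' Classical sample estimator: with `Sc` the double-centered covariance of
#' the k cell scores, epsilon = tr(Sc)^2 / ((k - 1) * sum(Sc^2)), clipped
#' to [1/(k - 1), 1]. Equals 1 under compound symmetry (sphericity) and
#' attains the lower bound for maximally non-spherical (rank-one centered)
#' covariance.
#'
#' @param S symmetric k x k covariance matrix of the cell scores.
#' @return epsilon in `[1/(k - 1), 1]`.
#' @export
gg_epsilon <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop("`S` must be a square covariance matrix", call. = FALSE)
  k <- nrow(S)
  if (k < 2L) stop("epsilon needs at least 2 cells", call. = FALSE)
  C <- diag(k) - 1 / k
  Sc <- C %*% S %*% C
  denom <- (k - 1) * sum(Sc^2)
  eps <- if (denom <= 0) 1 else sum(diag(Sc))^2 / denom
  min(1, max(1 / (k - 1), eps))
}

# epsilon for one effect: project subject x cell scores of the effect onto
# the Kronecker orthonormal contrast basis
effect_epsilon <- function(arr, A, subj_dim) {
  dims <- dim(arr)
  k <- prod(dims[A])
  if (k < 3L) return(1)                      # single contrast: eps = 1
  cellmeans <- apply(arr, c(A, subj_dim), mean)   # dims[A] x n
  Y <- t(array(cellmeans, dim = c(k, dims[subj_dim])))  # n x cells
  # first factor varies fastest in the flattened cells
  Ms <- lapply(dims[A], orthonormal_contrasts)
  M <- Reduce(kronecker, rev(Ms))
  E <- t(M) %*% stats::cov(Y) %*% M
  d <- ncol(M)
  denom <- d * sum(E^2)
  eps <- if (denom <= 0) 1 else sum(diag(E))^2 / denom
  min(1, max(1 / d, eps))
}

# ---- repeated-measures ANOVA ----------------------------------------------

#' Repeated-measures (within-subject) factorial ANOVA
#'
#' Full within-subject sums-of-squares partition for one to three within
#' factors on a complete balanced table (one value per subject x cell).
#' Each effect is tested against its interaction with Subject. Reports
#' uncorrected degrees of freedom, the Greenhouse-Geisser epsilon, the
#' corrected p (applied when the effect has more than one numerator df and
#' its epsilon falls below 1), and partial eta-squared
#' SS_effect / (SS_effect + SS_error).
#'
#' @param data long `data.frame` with one row per subject x cell.
#' @param dv name of the value column.
#' @param within character vector of within-factor column names (1-3).
#' @param subject name of the subject column.
#' @return `data.frame` of class `rm_anova` with one row per effect:
#'   `effect, df1, df2, F, epsilon, p, p_gg, eta_p2` (and `ss_effect`,
#'   `ss_error`).
#' @examples
#' d <- expand.grid(subject = 1:8, type = c("a", "b", "c"), epoch = 1:2)
#' d$value <- rnorm(nrow(d)) + as.numeric(d$type == "a")
#' rm_anova(d, "value", c("type", "epoch"))
#' @export
rm_anova <- function(data, dv, within, subject = "subject") {
  if (length(within) < 1L || length(within) > 3L)
    stop("1 to 3 within factors supported", call. = FALSE)
  cols <- c(within, subject, dv)
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyNA(data[[dv]])) {
    bad <- data[is.na(data[[dv]]), c(subject, within)]
    stop("missing value(s) at: ",
         paste(apply(bad, 1L, paste, collapse = "/"), collapse = ", "),
         call. = FALSE)
  }

  f <- lapply(data[within], function(x) factor(x))
  subj <- factor(data[[subject]])
  idx <- c(f, list(subj))
  counts <- tapply(data[[dv]], idx, length)
  if (anyNA(counts)) {
    where <- which(is.na(counts), arr.ind = TRUE)
    cell <- apply(where, 1L, function(r)
      paste(mapply(function(d, i) dimnames(counts)[[d]][i],
                   seq_along(r), r), collapse = "/"))
    stop("incomplete design; missing cell(s) [",
         paste(c(within, subject), collapse = "/"), "]: ",
         paste(utils::head(cell, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(counts != 1L))
    stop("exactly one observation per subject x cell required", call. = FALSE)
  tab <- tapply(data[[dv]], idx, mean)

  dims <- dim(tab)
  nd <- length(dims)
  subj_dim <- nd
  n <- dims[subj_dim]
  if (n < 2L) stop("at least 2 subjects required", call. = FALSE)
  N <- length(tab)

  factor_dims <- seq_len(nd - 1L)
  effects <- all_subsets(factor_dims)

  rows <- lapply(effects, function(A) {
    effA <- effect_array(tab, A)
    ssA <- (N / prod(dims[A])) * sum(effA^2)
    dfA <- prod(dims[A] - 1L)
    AE <- c(A, subj_dim)
    effE <- effect_array(tab, AE)
    ssE <- (N / prod(dims[AE])) * sum(effE^2)
    dfE <- dfA * (n - 1L)
    if (ssE <= 1e-12 * max(1, ssA))
      stop("zero error variance for effect '",
           paste(within[A], collapse = ":"),
           "': F is undefined (constant data?)", call. = FALSE)
    Fval <- (ssA / dfA) / (ssE / dfE)
    eps <- effect_epsilon(tab, A, subj_dim)
    p <- stats::pf(Fval, dfA, dfE, lower.tail = FALSE)
    # sphericity correction only ever makes the test more conservative:
    # for F < 1 the df-shrunken p could drop below the uncorrected one
    p_gg <- if (dfA > 1L && eps < 1 - 1e-9)
      max(p, stats::pf(Fval, eps * dfA, eps * dfE, lower.tail = FALSE))
    else p
    data.frame(effect = paste(within[A], collapse = ":"),
               df1 = dfA, df2 = dfE, F = Fval, epsilon = eps,
               p = p, p_gg = p_gg,
               eta_p2 = ssA / (ssA + ssE),
               ss_effect = ssA, ss_error = ssE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (Greenhouse-Geisser corrected)\n")
  df <- as.data.frame(x)
  df$F <- round(df$F, 2); df$epsilon <- round(df$epsilon, 3)
  df$p <- signif(df$p, 3); df$p_gg <- signif(df$p_gg, 3)
  df$eta_p2 <- round(df$eta_p2, 3)
  print(df[c("effect", "df1", "df2", "F", "epsilon", "p", "p_gg", "eta_p2")],
        row.names = FALSE)
  invisible(x)
}

# ---- t-tests and LSD -------------------------------------------------------

#' One-sample and paired t-tests
#'
#' Standard t statistics with two-sided p-values; `paired_t(a, b)` is
#' identical to `one_sample_t(a - b, 0)`.
#'
#' @param values numeric vector.
#' @param mu0 null mean.
#' @return list of class `t_test_result`: `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("zero variance: t is undefined", call. = FALSE)
  tval <- (mean(values) - mu0) / (s / sqrt(n))
  structure(list(t = tval, df = n - 1L,
                 p = 2 * stats::pt(abs(tval), n - 1L, lower.tail = FALSE),
                 mean_diff = mean(values) - mu0, n = n),
            class = "t_test_result")
}

#' @rdname one_sample_t
#' @param a,b paired numeric vectors of equal length.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b))
    stop("paired vectors must have equal length", call. = FALSE)
  one_sample_t(a - b, 0)
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g, mean difference = %.4g\n",
              x$df, x$t, x$p, x$mean_diff))
  invisible(x)
}

#' LSD (least significant difference) pairwise comparisons
#'
#' Uncorrected pairwise paired t-tests between the levels of one within
#' factor, the conventional follow-up to a significant repeated-measures
#' effect. `pooled_error = TRUE` instead tests each difference against the
#' ANOVA's pooled factor-by-subject error term.
#'
#' @param data long `data.frame` as for [rm_anova()].
#' @param dv value column name.
#' @param within single factor column name.
#' @param subject subject column name.
#' @param pooled_error use the pooled error variant.
#' @return `data.frame` of class `lsd_pairwise`: `level_a, level_b,
#'   mean_diff, t, df, p`.
#' @export
lsd_pairwise <- function(data, dv, within, subject = "subject",
                         pooled_error = FALSE) {
  if (length(within) != 1L)
    stop("LSD follow-ups compare the levels of one factor", call. = FALSE)
  f <- factor(data[[within]])
  subj <- factor(data[[subject]])
  tab <- tapply(data[[dv]], list(subj, f), mean)
  if (anyNA(tab)) stop("incomplete design", call. = FALSE)
  lev <- colnames(tab)
  n <- nrow(tab)
  pooled <- NULL
  if (pooled_error) {
    centered <- tab - rowMeans(tab) -
      matrix(colMeans(tab), n, ncol(tab), byrow = TRUE) + mean(tab)
    ms_err <- sum(centered^2) / ((n - 1L) * (ncol(tab) - 1L))
    pooled <- list(ms = ms_err, df = (n - 1L) * (ncol(tab) - 1L))
  }
  pairs <- utils::combn(seq_along(lev), 2L)
  rows <- apply(pairs, 2L, function(pr) {
    d <- tab[, pr[1L]] - tab[, pr[2L]]
    if (pooled_error) {
      se <- sqrt(2 * pooled$ms / n)
      tval <- mean(d) / se
      df <- pooled$df
    } else if (all(d == d[1L]) && d[1L] == 0) {
      tval <- 0; df <- n - 1L   # identical levels: no difference to test
    } else {
      tt <- one_sample_t(d, 0)
      tval <- tt$t; df <- tt$df
    }
    data.frame(level_a = lev[pr[1L]], level_b = lev[pr[2L]],
               mean_diff = mean(d), t = tval, df = df,
               p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("lsd_pairwise", "data.frame")
  out
}
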