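#' Bland-Altman agreement analysis
#'
#' Computes the bias (mean of grader1 - grader2), the 95% limits of
#' agreement (bias +/- 1.96 SD of the differences; the 1.96 multiplier is
#' fixed, not t-based), individual confidence intervals on each limit, and
#' the percentage of units falling inside the limits. The CI half-width on
#' each limit is `t(1 - (1-conf)/2, n-1) * SD * sqrt(1/n + z^2 / (2(n-1)))`
#' with z = 1.96.
#'
#' @param grader1,grader2 matched numeric vectors (dB, counts, or um).
#' @param conf confidence level for the limit-of-agreement intervals.
#' @return A list of class `bland_altman`: `n`, `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `loa_lower_ci`, `loa_upper_ci` (each a
#'   length-2 vector), `pct_within_loa`, `differences`, `means`.
#' @examples
#' ba <- bland_altman(c(10, 12, 14), c(11, 12, 13))
#' ba$bias
#' @export
bland_altman <- function(grader1, grader2, conf = 0.95) {
  check_paired(grader1, grader2)
  d <- grader1 - grader2
  n <- length(d)
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  z <- 1.96
  loa <- bias + c(-1, 1) * z * sd_diff
  if (n >= 3L) {
    half <- stats::qt(1 - (1 - conf) / 2, n - 1L) * sd_diff *
      sqrt(1 / n + z^2 / (2 * (n - 1L)))
    loa_lower_ci <- loa[1L] + c(-1, 1) * half
    loa_upper_ci <- loa[2L] + c(-1, 1) * half
  } else {
    loa_lower_ci <- loa_upper_ci <- c(NA_real_, NA_real_)
  }
  structure(
    list(n = n, bias = bias, sd_diff = sd_diff,
         loa_lower = loa[1L], loa_upper = loa[2L],
         loa_lower_ci = loa_lower_ci, loa_upper_ci = loa_upper_ci,
         pct_within_loa = 100 * mean(d >= loa[1L] & d <= loa[2L]),
         conf = conf, differences = d, means = (grader1 + grader2) / 2),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 4, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.*g, LOA [%.*g, %.*g]\n",
              x$n, digits, x$bias, digits, x$loa_lower, digits, x$loa_upper))
  if (!anyNA(x$loa_lower_ci))
    cat(sprintf("  %d%% CI lower LOA [%.*g, %.*g], upper LOA [%.*g, %.*g]\n",
                round(100 * x$conf),
                digits, x$loa_lower_ci[1L], digits, x$loa_lower_ci[2L],
                digits, x$loa_upper_ci[1L], digits, x$loa_upper_ci[2L]))
  cat(sprintf("  %.1f%% of units within the limits\n", x$pct_within_loa))
  invisible(x)
}

check_paired <- function(x, y, min_n = 2L) {
  if (length(x) != length(y))
    stop("grader vectors must have equal length", call. = FALSE)
  if (length(x) < min_n)
    stop(sprintf("at least %d paired measurements are required", min_n),
         call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("paired measurements must be finite", call. = FALSE)
  invisible(TRUE)
}

# two-way (units x raters) mean squares for the 2-rater design
two_way_mean_squares <- function(grader1, grader2) {
  n <- length(grader1)
  k <- 2L
  m <- cbind(grader1, grader2)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  msr <- k * sum((row_means - grand)^2) / (n - 1L)
  msc <- n * sum((col_means - grand)^2) / (k - 1L)
  resid <- sweep(sweep(m, 1L, row_means), 2L, col_means) + grand
  mse <- sum(resid^2) / ((n - 1L) * (k - 1L))
  list(msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Intraclass correlation coefficient for inter-grader agreement
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' (ICC(A,1) in the McGraw-Wong taxonomy), computed from the two-way
#' units-by-raters ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with k = 2 raters.
#'
#' @param grader1,grader2 matched numeric vectors over n >= 3 units.
#' @return Scalar ICC in \[-1, 1\]; `NA` with a warning when the total
#'   variance is zero (ICC undefined).
#' @export
icc_agreement <- function(grader1, grader2) {
  check_paired(grader1, grader2, min_n = 3L)
  ms <- two_way_mean_squares(grader1, grader2)
  denom <- ms$msr + (ms$k - 1L) * ms$mse + ms$k / ms$n * (ms$msc - ms$mse)
  if (denom == 0) {
    warning("ICC undefined: zero total variance", call. = FALSE)
    return(NA_real_)
  }
  (ms$msr - ms$mse) / denom
}

#' Coefficient of repeatability (smallest real difference)
#'
#' Primary convention: `CoR = 1.96 * sqrt(2) * s_w`, where `s_w^2` is the
#' within-unit (between-grader) error variance — the residual mean square of
#' the two-way ANOVA used by [icc_agreement()]. The literature also uses
#' `1.96 * SD` of the paired differences; both are returned so the
#' convention in use is always explicit.
#'
#' @param grader1,grader2 matched numeric vectors over n >= 3 units.
#' @return List with `cor_anova` (primary), `cor_sd_diff`, and `s_w`.
#' @export
coefficient_of_repeatability <- function(grader1, grader2) {
  check_paired(grader1, grader2, min_n = 3L)
  ms <- two_way_mean_squares(grader1, grader2)
  s_w <- sqrt(ms$mse)
  list(cor_anova = 1.96 * sqrt(2) * s_w,
       cor_sd_diff = 1.96 * stats::sd(grader1 - grader2),
       s_w = s_w)
}

#' Bland-Altman limits of agreement under repeated measures
#'
#' For clustered paired data (e.g., 68 stimuli per eye), the grader
#' differences `d_ij` are modeled as `mu + a_i + e_ij` with a random cluster
#' intercept. The cluster and residual variances are estimated by the
#' one-way ANOVA method of moments (negative moment estimates truncated at
#' zero; for the balanced design this coincides with REML in expectation),
#' and the limits of agreement are `mu +/- 1.96 * sqrt(sigma2_a + sigma2_e)`.
#'
#' With a single observation per cluster the components are not separable
#' and the plain [bland_altman()] result is returned; a single cluster falls
#' back to [bland_altman()] with a warning.
#'
#' @param grader1,grader2 matched numeric vectors.
#' @param cluster cluster (eye) identifier for each observation.
#' @param conf confidence level passed through for the unclustered fallback.
#' @return A list of class `bland_altman_repeated`: `n`, `n_clusters`,
#'   `bias`, `sigma2_cluster`, `sigma2_resid`, `sd_total`, `loa_lower`,
#'   `loa_upper`, `pct_within_loa`; or a `bland_altman` object in the
#'   fallback cases.
#' @export
bland_altman_repeated <- function(grader1, grader2, cluster, conf = 0.95) {
  check_paired(grader1, grader2)
  if (length(cluster) != length(grader1))
    stop("'cluster' must match the measurement vectors in length",
         call. = FALSE)
  cluster <- factor(cluster)
  if (nlevels(cluster) == 1L) {
    warning("single cluster: falling back to plain Bland-Altman",
            call. = FALSE)
    return(bland_altman(grader1, grader2, conf = conf))
  }
  d <- grader1 - grader2
  sizes <- as.integer(table(cluster))
  if (max(sizes) == 1L)
    return(bland_altman(grader1, grader2, conf = conf))
  N <- length(d)
  kk <- nlevels(cluster)
  cl_means <- tapply(d, cluster, mean)
  grand <- mean(d)
  ssb <- sum(sizes * (cl_means - grand)^2)
  ssw <- sum((d - cl_means[cluster])^2)
  msb <- ssb / (kk - 1L)
  msw <- ssw / (N - kk)
  m0 <- (N - sum(sizes^2) / N) / (kk - 1L)  # = m for balanced clusters
  sigma2_e <- msw
  sigma2_a <- max((msb - msw) / m0, 0)
  sd_total <- sqrt(sigma2_a + sigma2_e)
  loa <- grand + c(-1, 1) * 1.96 * sd_total
  structure(
    list(n = N, n_clusters = kk, bias = grand,
         sigma2_cluster = sigma2_a, sigma2_resid = sigma2_e,
         sd_total = sd_total,
         loa_lower = loa[1L], loa_upper = loa[2L],
         pct_within_loa = 100 * mean(d >= loa[1L] & d <= loa[2L]),
         differences = d),
    class = "bland_altman_repeated")
}

#' @export
print.bland_altman_repeated <- function(x, digits = 4, ...) {
  cat(sprintf("repeated-measures Bland-Altman (%d obs in %d clusters)\n",
              x$n, x$n_clusters))
  cat(sprintf("  bias %.*g, LOA [%.*g, %.*g] (sigma_cluster %.*g, sigma_resid %.*g)\n",
              digits, x$bias, digits, x$loa_lower, digits, x$loa_upper,
              digits, sqrt(x$sigma2_cluster), digits, sqrt(x$sigma2_resid)))
  invisible(x)
}

#' Full inter-grader repeatability report for one paired measure
#'
#' Bundles the agreement battery for a matched pair of grader measurements:
#' Bland-Altman bias and limits of agreement with individual CIs, the
#' two-way random-effects absolute-agreement single-measurement ICC, and the
#' coefficient of repeatability in both conventions. When `cluster` is
#' supplied the repeated-measures Bland-Altman variant is included as well.
#'
#' @param grader1,grader2 matched numeric vectors.
#' @param cluster optional cluster (eye) ids for repeated-measures data.
#' @param units unit label carried into the printout (e.g., `"dB"`).
#' @param conf confidence level for limit-of-agreement intervals.
#' @return A list of class `repeatability_report` with components
#'   `bland_altman`, `icc`, `icc_form`, `cor` (both conventions), `n`,
#'   `units`, and optionally `bland_altman_repeated`.
#' @export
repeatability_report <- function(grader1, grader2, cluster = NULL,
                                 units = "", conf = 0.95) {
  check_paired(grader1, grader2, min_n = 3L)
  out <- list(
    n = length(grader1),
    units = units,
    bland_altman = bland_altman(grader1, grader2, conf = conf),
    icc = suppressWarnings(icc_agreement(grader1, grader2)),
    icc_form = "two-way random effects, absolute agreement, single measurement (ICC(A,1))",
    cor = coefficient_of_repeatability(grader1, grader2))
  if (!is.null(cluster))
    out$bland_altman_repeated <-
      bland_altman_repeated(grader1, grader2, cluster, conf = conf)
  structure(out, class = "repeatability_report")
}

#' @export
print.repeatability_report <- function(x, digits = 4, ...) {
  cat(sprintf("repeatability report (n = %d%s)\n", x$n,
              if (nzchar(x$units)) paste0(", units: ", x$units) else ""))
  print(x$bland_altman, digits = digits)
  cat(sprintf("  ICC [%s]: %.*g\n", x$icc_form, digits, x$icc))
  cat(sprintf("  CoR (ANOVA, 1.96*sqrt(2)*s_w): %.*g; CoR (1.96*SD of differences): %.*g\n",
              digits, x$cor$cor_anova, digits, x$cor$cor_sd_diff))
  if (!is.null(x$bland_altman_repeated))
    print(x$bland_altman_repeated, digits = digits)
  invisible(x)
}
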