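#' Per-pair superior-inferior thickness differences for one eye
#'
#' For every inferior-hemisphere cell, the signed asymmetry is the cell's
#' thickness minus that of its corresponding superior cell (same column,
#' row 9 - r). The sign convention is fixed: positive means the inferior
#' cell is thicker.
#'
#' @param eye An `eye_record` containing a grid for `layer`.
#' @param layer One of [layer_ids()].
#' @return A data.frame with 32 rows and columns `inf_row`, `inf_col`,
#'   `sup_row`, `sup_col`, `diff_um` (inferior minus superior, microns),
#'   in row-major order over the inferior hemisphere.
#' @export
cell_pair_differences <- function(eye, layer) {
  assert_layer(layer)
  if (!inherits(eye, "eye_record")) {
    stop("eye must be an eye_record", call. = FALSE)
  }
  if (is.null(eye$grids[[layer]])) {
    stop("eye ", eye$subject_id, " has no grid for layer ", layer,
         call. = FALSE)
  }
  v <- eye$grids[[layer]]$values
  p <- cell_pairs()
  p$diff_um <- v[cbind(p$inf_row, p$inf_col)] - v[cbind(p$sup_row, p$sup_col)]
  p
}

# eyes x 32 matrix of pair differences for a layer, pair order = cell_pairs()
pair_difference_matrix <- function(cohort, layer) {
  assert_layer(layer)
  p <- cell_pairs()
  t(vapply(cohort$eyes, function(e) {
    if (is.null(e$grids[[layer]])) {
      stop("eye ", e$subject_id, " has no grid for layer ", layer,
           call. = FALSE)
    }
    v <- e$grids[[layer]]$values
    v[cbind(p$inf_row, p$inf_col)] - v[cbind(p$sup_row, p$sup_col)]
  }, numeric(32L)))
}

#' Hemisphere-level thickness summary over a cohort
#'
#' The superior hemisphere is summarised as the pool of the 32 superior
#' cells of every eye, and likewise for the inferior hemisphere. The pooled
#' mean equals the mean of the per-eye hemisphere means (equal weights); the
#' pooled SD is taken over all eyes x 32 cell values, so it reflects spatial
#' as well as between-subject variation.
#'
#' @param cohort A `ppa_cohort`; every eye must contain `layer`.
#' @param layer One of [layer_ids()].
#' @return A data.frame with two rows (inferior, superior) and columns
#'   `layer`, `hemisphere`, `pooled_mean`, `pooled_sd`, `n_eyes`. The
#'   per-eye hemisphere means are attached as attribute `per_eye_means`
#'   (a `n_eyes` x 2 matrix with columns inferior/superior), and the paired
#'   t-test comparing per-eye hemisphere means as attribute `paired_test`.
#' @export
hemisphere_summary <- function(cohort, layer) {
  if (!inherits(cohort, "ppa_cohort") || !length(cohort$eyes)) {
    stop("cohort must be a non-empty ppa_cohort", call. = FALSE)
  }
  assert_layer(layer)
  vals <- lapply(cohort$eyes, function(e) {
    if (is.null(e$grids[[layer]])) {
      stop("eye ", e$subject_id, " has no grid for layer ", layer,
           call. = FALSE)
    }
    v <- e$grids[[layer]]$values
    list(inf = v[1:4, , drop = FALSE], sup = v[5:8, , drop = FALSE])
  })
  inf_all <- unlist(lapply(vals, function(x) as.vector(x$inf)))
  sup_all <- unlist(lapply(vals, function(x) as.vector(x$sup)))
  per_eye <- cbind(inferior = vapply(vals, function(x) mean(x$inf), 1),
                   superior = vapply(vals, function(x) mean(x$sup), 1))
  n <- length(cohort$eyes)
  out <- data.frame(
    layer = layer,
    hemisphere = c("inferior", "superior"),
    pooled_mean = c(mean(inf_all), mean(sup_all)),
    pooled_sd = c(if (length(inf_all) > 1L) stats::sd(inf_all) else 0,
                  if (length(sup_all) > 1L) stats::sd(sup_all) else 0),
    n_eyes = n)
  attr(out, "per_eye_means") <- per_eye
  if (n >= 2L) {
    attr(out, "paired_test") <- tryCatch(
      paired_t_test(per_eye[, "inferior"] - per_eye[, "superior"]),
      error = function(e) NULL)
  }
  out
}

#' Paired Student's t-test on precomputed differences
#'
#' Given the within-eye differences d_i, computes t = dbar / (s_d / sqrt(n))
#' with the sample SD (n - 1 denominator) and a two-sided p-value from the t
#' distribution with n - 1 degrees of freedom.
#'
#' Degenerate inputs: when every difference equals zero the statistic is
#' defined as t = 0 with p = 1 (no evidence of asymmetry); a constant
#' non-zero difference has s_d = 0 and is rejected as degenerate.
#'
#' @param differences Numeric vector of paired differences, length >= 2.
#' @return A list of class `paired_t` with fields `n`, `mean_diff`,
#'   `sd_diff`, `t_statistic`, `degrees_of_freedom`, `p_value`.
#' @export
paired_t_test <- function(differences) {
  d <- as.numeric(differences)
  if (length(d) < 2L || any(!is.finite(d))) {
    stop("paired t-test requires at least 2 finite differences",
         call. = FALSE)
  }
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) {
      t_stat <- 0
      p <- 1
    } else {
      stop("degenerate input: constant non-zero differences (sd = 0, mean != 0)",
           call. = FALSE)
    }
  } else {
    t_stat <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  structure(list(n = n, mean_diff = m, sd_diff = s, t_statistic = t_stat,
                 degrees_of_freedom = n - 1L, p_value = p),
            class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  cat(sprintf(
    "Paired t-test: n = %d, mean diff = %.3f, SD = %.3f, t(%d) = %.3f, p = %.4g\n",
    x$n, x$mean_diff, x$sd_diff, x$degrees_of_freedom, x$t_statistic,
    x$p_value))
  invisible(x)
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of the values against a normal distribution with the
#' sample's own mean and SD (plug-in parameters, no small-sample
#' correction). With estimated parameters the test is anticonservative; it
#' is used as an advisory screen only and never switches the pipeline to
#' nonparametric tests.
#'
#' @param values Numeric vector, length >= 5, non-constant.
#' @return List with `statistic` (D) and `p_value`.
#' @export
ks_normality <- function(values) {
  x <- as.numeric(values)
  if (length(x) < 5L || any(!is.finite(x))) {
    stop("normality screen requires at least 5 finite values", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("normality screen is undefined for constant values", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' 2.5th and 97.5th percentile range
#'
#' Central 95% reference range computed by linear interpolation between
#' order statistics at rank 1 + q (n - 1) (the default quantile definition,
#' type 7). Bounds are reported inclusively: a value equal to either
#' percentile is inside the range.
#'
#' @param values Numeric vector, length >= 2.
#' @return Named numeric vector `c(p2_5 = ..., p97_5 = ...)`.
#' @export
percentile_range <- function(values) {
  x <- as.numeric(values)
  if (length(x) < 2L || any(!is.finite(x))) {
    stop("percentile range requires at least 2 finite values", call. = FALSE)
  }
  q <- stats::quantile(x, probs = c(0.025, 0.975), type = 7, names = FALSE)
  c(p2_5 = q[1L], p97_5 = q[2L])
}

#' Per-pair asymmetry summary over a cohort
#'
#' For each of the 32 corresponding cell pairs of a layer, aggregates the
#' per-eye differences (inferior minus superior) across the cohort: mean,
#' SD, paired t-test, and the 2.5th/97.5th percentile reference range.
#'
#' @param cohort A `ppa_cohort`; every eye must contain `layer`.
#' @param layer One of [layer_ids()].
#' @param alpha Two-sided significance level (default 0.05).
#' @param adjust Multiple-comparison adjustment across the 32 pairs:
#'   `"none"` (default, each pair tested at `alpha`), `"holm"`, or `"bh"`
#'   (Benjamini-Hochberg).
#' @return A data.frame with 32 rows and columns `layer`, `inf_row`,
#'   `inf_col`, `sup_row`, `sup_col`, `n`, `mean_diff_um`, `sd_diff_um`,
#'   `t`, `df`, `p`, `p2_5_um`, `p97_5_um`, `significant`.
#' @export
pairwise_summary_table <- function(cohort, layer, alpha = 0.05,
                                   adjust = c("none", "holm", "bh")) {
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  d <- pair_difference_matrix(cohort, layer)
  if (nrow(d) < 2L) {
    stop("pairwise summaries require a cohort of at least 2 eyes",
         call. = FALSE)
  }
  p <- cell_pairs()
  tests <- apply(d, 2L, paired_t_test)
  ranges <- apply(d, 2L, percentile_range)
  pvals <- vapply(tests, function(x) x$p_value, 1)
  padj <- switch(adjust,
                 none = pvals,
                 holm = stats::p.adjust(pvals, "holm"),
                 bh = stats::p.adjust(pvals, "BH"))
  out <- data.frame(
    layer = layer,
    inf_row = p$inf_row, inf_col = p$inf_col,
    sup_row = p$sup_row, sup_col = p$sup_col,
    n = nrow(d),
    mean_diff_um = vapply(tests, function(x) x$mean_diff, 1),
    sd_diff_um = vapply(tests, function(x) x$sd_diff, 1),
    t = vapply(tests, function(x) x$t_statistic, 1),
    df = vapply(tests, function(x) x$degrees_of_freedom, 1L),
    p = pvals,
    p2_5_um = ranges["p2_5", ],
    p97_5_um = ranges["p97_5", ],
    significant = padj < alpha)
  rownames(out) <- NULL
  out
}
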