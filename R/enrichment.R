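#' Motif fold enrichment with a one-sided exact test
#'
#' Fold enrichment of a feature (e.g. a transcription-factor motif) in a
#' foreground peak set relative to a background set:
#' `fold = (k_fg / n_fg) / (k_bg / n_bg)`. Significance is a one-sided
#' exact (hypergeometric / Fisher) test of enrichment on the 2x2 table with
#' fixed margins, `P(X >= k_fg)`. The 95% confidence interval on the ratio
#' uses the standard log-ratio normal approximation with variance
#' `1/k_fg - 1/n_fg + 1/k_bg - 1/n_bg`.
#'
#' @param k_fg Motif-positive foreground peaks.
#' @param n_fg Foreground total, > 0.
#' @param k_bg Motif-positive background peaks.
#' @param n_bg Background total, > 0.
#' @param conf_level Confidence level for the ratio interval.
#' @return A list of class `enrichment`: `fold` (`Inf` with `finite = FALSE`
#'   when `k_bg = 0`), `p`, `ci` (length-2), the input counts and the two
#'   fractions.
#' @examples
#' fold_enrichment(100, 1000, 100, 10000)$fold   # 10
#' fold_enrichment(260, 1000, 1500, 10000)$fold  # 1.733 -> "1.7-fold"
#' @export
fold_enrichment <- function(k_fg, n_fg, k_bg, n_bg, conf_level = 0.95) {
  if (n_fg <= 0 || n_bg <= 0) stop("totals must be > 0", call. = FALSE)
  if (k_fg < 0 || k_fg > n_fg || k_bg < 0 || k_bg > n_bg) {
    stop("need 0 <= k <= n in both sets", call. = FALSE)
  }
  p_fg <- k_fg / n_fg
  p_bg <- k_bg / n_bg
  finite <- k_bg > 0
  fold <- if (finite) p_fg / p_bg else Inf
  # one-sided Fisher exact = upper hypergeometric tail at fixed margins
  p <- stats::phyper(k_fg - 1, k_fg + k_bg, n_fg + n_bg - k_fg - k_bg, n_fg,
                     lower.tail = FALSE)
  ci <- c(NA_real_, NA_real_)
  if (finite && k_fg > 0) {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    se <- sqrt(1 / k_fg - 1 / n_fg + 1 / k_bg - 1 / n_bg)
    ci <- fold * exp(c(-z, z) * se)
  }
  structure(list(fold = fold, p = p, ci = ci, finite = finite,
                 k_fg = k_fg, n_fg = n_fg, k_bg = k_bg, n_bg = n_bg,
                 frac_fg = p_fg, frac_bg = p_bg),
            class = "enrichment")
}

#' @export
print.enrichment <- function(x, ...) {
  cat(sprintf("%.1f-fold enrichment (%.1f%% vs %.1f%%), one-sided exact p = %.3g\n",
              x$fold, 100 * x$frac_fg, 100 * x$frac_bg, x$p))
  if (all(is.finite(x$ci))) {
    cat(sprintf("  95%% CI on fold: [%.2f, %.2f]\n", x$ci[1], x$ci[2]))
  }
  invisible(x)
}

#' Per-motif enrichment table with BH correction
#'
#' Applies [fold_enrichment()] to every motif column shared by a foreground
#' and a background peak set, and adds Benjamini–Hochberg adjusted
#' p-values across motifs.
#'
#' @param foreground,background Peak data frames as produced by
#'   [generate_peak_universe()] or [read_peaks()]: BED-style columns
#'   followed by logical motif columns.
#' @param motifs Motif column names; by default all logical columns present
#'   in both sets.
#' @return A data frame with columns `motif`, `k_fg`, `n_fg`, `k_bg`,
#'   `n_bg`, `fold`, `p`, `fdr`.
#' @export
enrich_motifs <- function(foreground, background, motifs = NULL) {
  if (is.null(motifs)) {
    is_flag <- function(d) names(d)[vapply(d, is.logical, logical(1))]
    motifs <- intersect(is_flag(foreground), is_flag(background))
  }
  if (length(motifs) == 0) stop("no shared motif columns found", call. = FALSE)
  rows <- lapply(motifs, function(m) {
    e <- fold_enrichment(sum(foreground[[m]]), nrow(foreground),
                         sum(background[[m]]), nrow(background))
    data.frame(motif = m, k_fg = e$k_fg, n_fg = e$n_fg, k_bg = e$k_bg,
               n_bg = e$n_bg, fold = e$fold, p = e$p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Hypergeometric set-overlap test
#'
#' Tests whether two gene (or peak) sets drawn from a common universe
#' overlap more than chance: the upper hypergeometric tail
#' `P(overlap >= n_overlap)`, together with the expected overlap
#' `n_a * n_b / n_universe` and the Jaccard index.
#'
#' @param n_a,n_b Set sizes.
#' @param n_overlap Observed intersection size; at most `min(n_a, n_b)`.
#' @param n_universe Universe size; at least `max(n_a, n_b)`.
#' @return A list of class `overlap_test`: `p`, `expected_overlap`,
#'   `jaccard`, plus the inputs.
#' @examples
#' set_overlap_test(n_a = 5, n_b = 5, n_overlap = 2, n_universe = 20)
#' @export
set_overlap_test <- function(n_a, n_b, n_overlap, n_universe) {
  if (n_a < 0 || n_b < 0 || n_overlap < 0 || n_universe <= 0 ||
      n_a > n_universe || n_b > n_universe || n_overlap > min(n_a, n_b)) {
    stop("inconsistent overlap counts", call. = FALSE)
  }
  p <- stats::phyper(n_overlap - 1, n_a, n_universe - n_a, n_b,
                     lower.tail = FALSE)
  union <- n_a + n_b - n_overlap
  structure(list(p = p,
                 expected_overlap = n_a * n_b / n_universe,
                 jaccard = if (union > 0) n_overlap / union else 0,
                 n_a = n_a, n_b = n_b, n_overlap = n_overlap,
                 n_universe = n_universe),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("Overlap %d of sets %d & %d (universe %d)\n",
              x$n_overlap, x$n_a, x$n_b, x$n_universe))
  cat(sprintf("  expected %.2f, Jaccard %.4f, hypergeometric p = %.4g\n",
              x$expected_overlap, x$jaccard, x$p))
  invisible(x)
}
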