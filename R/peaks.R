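#' Parameters for a synthetic motif-annotated peak universe
#'
#' @param n_foreground,n_background Peak counts in the two sets, > 0.
#' @param motif_prob_foreground,motif_prob_background Named numeric vectors
#'   of per-motif occurrence probabilities (same names in both), each in
#'   \[0, 1\].
#' @param interval_length Peak width in bp.
#' @return An object of class `peak_universe_params`.
#' @export
peak_universe_params <- function(n_foreground, n_background,
                                 motif_prob_foreground,
                                 motif_prob_background,
                                 interval_length = 500) {
  if (n_foreground <= 0 || n_background <= 0) {
    stop("peak counts must be > 0", call. = FALSE)
  }
  if (is.null(names(motif_prob_foreground)) ||
      !identical(sort(names(motif_prob_foreground)),
                 sort(names(motif_prob_background)))) {
    stop("motif probability vectors must share the same names", call. = FALSE)
  }
  probs <- c(motif_prob_foreground, motif_prob_background)
  if (any(probs < 0 | probs > 1)) {
    stop("motif probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (interval_length <= 0) stop("`interval_length` must be > 0", call. = FALSE)
  structure(list(n_foreground = n_foreground, n_background = n_background,
                 motif_prob_foreground = motif_prob_foreground,
                 motif_prob_background = motif_prob_background,
                 interval_length = interval_length),
            class = "peak_universe_params")
}

make_peak_set <- function(n, probs, width, prefix) {
  chrom <- paste0("chr", sample.int(19, n, replace = TRUE))
  start <- floor(stats::runif(n, 0, 1.5e8))
  df <- data.frame(chrom = chrom, start = as.integer(start),
                   end = as.integer(start + width),
                   name = paste0(prefix, "_", seq_len(n)),
                   score = 0L, strand = ".")
  for (m in names(probs)) df[[m]] <- stats::runif(n) < probs[[m]]
  df
}

#' Generate foreground and background peak sets with planted motifs
#'
#' Emulates the input of a motif fold-enrichment analysis: two BED-style
#' interval sets (0-based, half-open) with one boolean column per motif,
#' motif presence drawn independently per peak at the planted
#' probabilities. Deterministic per seed.
#'
#' @param params A [peak_universe_params()].
#' @param seed Integer seed.
#' @return A list of class `peak_universe` with data frames `foreground`
#'   and `background` (columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, then one logical column per motif).
#' @examples
#' pu <- generate_peak_universe(peak_universe_params(
#'   1000, 10000, c(CTCF = 0.10), c(CTCF = 0.01)), seed = 1)
#' mean(pu$foreground$CTCF) / mean(pu$background$CTCF)  # ~10
#' @export
generate_peak_universe <- function(params, seed) {
  stopifnot(inherits(params, "peak_universe_params"))
  set.seed(seed)
  out <- list(
    foreground = make_peak_set(params$n_foreground,
                               params$motif_prob_foreground,
                               params$interval_length, "fg"),
    background = make_peak_set(params$n_background,
                               params$motif_prob_background,
                               params$interval_length, "bg"))
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  class(out) <- "peak_universe"
  out
}
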