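# Independent oracles used across the suite.

# Brute-force upper-tail probability P(X >= k_fg) of a 2x2 table with all
# margins fixed, by explicit summation over the admissible tables.
# Deliberately written from the counting definition (lchoose), independent
# of phyper/fisher.test.
hyper_tail_oracle <- function(k_fg, n_fg, k_bg, n_bg) {
  K <- k_fg + k_bg
  N <- n_fg + n_bg
  ks <- seq.int(max(k_fg, max(0L, K - n_bg)), min(K, n_fg))
  if (length(ks) == 0 || ks[1] > min(K, n_fg)) return(0)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n_fg - ks) - lchoose(N, n_fg)))
}

# Phase durations matching the fitted control and cKO conditions
control_phases <- function() phase_durations(t_g1 = 61.3, t_s = 13.5, t_g2 = 1.8)
cko_phases <- function() phase_durations(t_g1 = 159.3, t_s = 16.7, t_g2 = 3)

# Ordinary (unweighted) least squares on (t, li) as an independent check of
# the line recovery on noise-free data.
ols_line_oracle <- function(t, li) {
  cf <- solve(cbind(1, t) |> crossprod(cbind(1, t)),
              crossprod(cbind(1, t), li))
  c(y0 = cf[1], m = cf[2])
}
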