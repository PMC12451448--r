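# Shared fixtures for the test suite: a desk-scale configuration and a
# goodness-of-fit helper for comparing sampled communities to a multinomial.

tiny_config <- function(...) {
  defaults <- list(N_H = 10, N_M = 10, n_MH = 200, n_ME = 2000,
                   T_H = 20, burn_in = 5, T_M = 1, X = 0.5,
                   scenario = "1B", seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(holosim_config, args)
}

# Pearson chi-square GOF of pooled category counts, over `n_draws`
# invocations of `draw_fun()` (each returning a community vector), against
# multinomial sampling with probabilities `p`.
gof_pvalue <- function(draw_fun, p, n_draws = 1e4) {
  totals <- Reduce(`+`, lapply(seq_len(n_draws), function(i) draw_fun()))
  suppressWarnings(stats::chisq.test(totals, p = p)$p.value)
}
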