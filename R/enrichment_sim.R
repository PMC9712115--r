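# Minimal passage model of counterselection enrichment. Not a mechanistic
# phage-population model: one passage takes an edited fraction f to
# f' = f / (f + (1 - f) * escape_prob), i.e. every edited virion infects
# productively while a wildtype virion evades Cas13a with probability
# escape_prob, with equal amplification of survivors. It exists to
# sanity-check penetrance expectations (an edit at 0.1% rises to ~99% in a
# single passage when escape is ~1e-5), not to fit data.

#' Simulate counterselection enrichment over passages
#'
#' @param f0 Initial edited fraction in \[0, 1\].
#' @param escape_prob Probability that a wildtype virion infects
#'   productively under counterselection, in \[0, 1\].
#' @param n_passages Number of enrichment passages.
#' @param mode `"expectation"` (deterministic recursion), `"stochastic"`
#'   (binomial sampling at `pop_size` virions per passage) or `"both"`.
#' @param pop_size Virion population size per passage for stochastic mode.
#' @param seed Optional RNG seed for stochastic mode.
#' @return Data frame with `passage` (0 = input), `f_expected` and, in
#'   stochastic modes, `f_sampled`.
#' @export
#' @examples
#' simulate_enrichment(1e-3, 1e-5, 1)
simulate_enrichment <- function(f0, escape_prob, n_passages = 1L,
                                mode = c("expectation", "stochastic", "both"),
                                pop_size = 1e6, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(f0 >= 0, f0 <= 1, escape_prob >= 0, escape_prob <= 1,
            n_passages >= 1, pop_size >= 1)
  if (f0 == 0 && escape_prob == 0) {
    stop("no phage survives counterselection: edited fraction and escape ",
         "probability are both zero", call. = FALSE)
  }
  step <- function(f) {
    denom <- f + (1 - f) * escape_prob
    if (denom == 0) f else f / denom
  }
  f_exp <- numeric(n_passages + 1L); f_exp[1] <- f0
  for (p in seq_len(n_passages)) f_exp[p + 1L] <- step(f_exp[p])
  out <- data.frame(passage = 0:n_passages, f_expected = f_exp)
  if (mode %in% c("stochastic", "both")) {
    run <- function() {
      fs <- numeric(n_passages + 1L); fs[1] <- f0
      for (p in seq_len(n_passages)) {
        edited <- stats::rbinom(1L, pop_size, fs[p])
        wt_escaped <- stats::rbinom(1L, pop_size - edited, escape_prob)
        fs[p + 1L] <- if (edited + wt_escaped == 0L) 0
                      else edited / (edited + wt_escaped)
      }
      fs
    }
    out$f_sampled <- if (is.null(seed)) run() else with_seed(seed, run())
  }
  out
}

#' Write an enrichment trajectory as TSV
#'
#' @param trajectory Result of [simulate_enrichment()].
#' @param path Output path.
#' @export
write_enrichment_trajectory <- function(trajectory, path) {
  utils::write.table(trajectory, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
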