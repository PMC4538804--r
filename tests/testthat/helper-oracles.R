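# Independent oracles used across the suite.

# Brute-force two-sided Fisher p-value: enumerate every table with the
# observed margins, compute point probabilities from the closed-form
# factorial expression, and sum those no more probable than the observed
# table. Deliberately independent of the package implementation (which
# uses lchoose): probabilities here come from stats::dhyper.
oracle_fisher_two_sided <- function(a, b, c, d, rel_tol = 1e-7) {
  m <- a + b
  n <- c + d
  k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- probs[xs == a]
  min(1, sum(probs[probs <= p_obs * (1 + rel_tol)]))
}

# Exact central binomial acceptance interval for an observed count.
binom_accept <- function(n, p, level = 0.99) {
  alpha <- (1 - level) / 2
  c(stats::qbinom(alpha, n, p), stats::qbinom(1 - alpha, n, p))
}

# Build the standard single-locus simulation used by recovery tests.
toy_amplicon <- function(n_cpgs = 2, n_non_cpg = 2, name = "toy") {
  units <- c(rep("AACTTT", n_non_cpg), rep("AACGTT", n_cpgs))
  amplicon(name, paste(units, collapse = ""))
}

run_pipeline <- function(sim, amplicons, bulk, min_conversion = 0.95) {
  res <- call_methylation(sim$reads, amplicons)
  list(called = res,
       summary = summarize_epimutations(res$calls, res$qc, bulk,
                                        min_conversion = min_conversion))
}
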