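# Independent brute-force oracles. Each re-derives its statistic in the most
# literal way possible (full enumeration, explicit combinatorics) so that the
# package's optimized implementations are checked against a separate route.

# Conditional NB exact test by full enumeration over every split of K.
oracle_nb_p <- function(k_T0, k_T1, sf_T0, sf_T1, alpha) {
  KA <- sum(k_T0); KB <- sum(k_T1); K <- KA + KB
  if (K == 0) return(1)
  q <- (sum(k_T0 / sf_T0) + sum(k_T1 / sf_T1)) /
    (length(k_T0) + length(k_T1))
  dens <- function(x, s, s2) {
    mu <- q * s
    extra <- alpha * q^2 * s2
    if (extra <= 0) dpois(x, mu)
    else dnbinom(x, mu = mu, size = mu^2 / extra)
  }
  probs <- numeric(K + 1)
  for (a in 0:K) {
    probs[a + 1] <- dens(a, sum(sf_T0), sum(sf_T0^2)) *
      dens(K - a, sum(sf_T1), sum(sf_T1^2))
  }
  pobs <- probs[KA + 1]
  sum(probs[probs <= pobs * (1 + 1e-7)]) / sum(probs)
}

# Two-sided Fisher p by enumerating every table with the observed margins,
# probabilities from binomial coefficients (not dhyper).
oracle_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(m[, 2]) == 0) return(1)
  as <- max(0, c1 - r2):min(c1, r1)
  probs <- choose(r1, as) * choose(r2, c1 - as) / choose(n, c1)
  pobs <- choose(r1, m[1, 1]) * choose(r2, c1 - m[1, 1]) / choose(n, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Second-best gene ranks by literal sorting of a hairpin results table.
oracle_second_best <- function(results) {
  ord <- order(results$log2fc, results$p_value, results$hairpin_id)
  ranked <- results[ord, ]
  ranked$hrank <- seq_len(nrow(ranked))
  sapply(split(ranked$hrank, ranked$gene_symbol), function(r) {
    if (length(r) < 2) nrow(results) + 1L else sort(r)[2]
  })
}

# Small deterministic count fixture: 2 lines x (T0, T1) x 2 replicates.
make_tiny_table <- function(counts = NULL, n_hairpins = 4) {
  samples <- expand.grid(replicate = 1:2, timepoint = c("T0", "T1"),
                         cell_line = c("A", "B"), stringsAsFactors = FALSE)
  samples$sample_id <- with(samples, paste(cell_line, timepoint, replicate,
                                           sep = "_"))
  attr(samples, "out.attrs") <- NULL
  if (is.null(counts)) {
    set.seed(99)
    counts <- matrix(rpois(n_hairpins * nrow(samples), 200),
                     n_hairpins, nrow(samples))
  }
  rownames(counts) <- paste0("h", seq_len(nrow(counts)))
  colnames(counts) <- samples$sample_id
  count_table(counts, samples)
}
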