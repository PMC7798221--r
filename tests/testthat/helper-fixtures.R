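# Shared fixtures: every fixture is built in code.

# the 4-compound / 3-feature worked set whose relation matrices are known
# by hand: CORM [[3,2,1],[2,2,0],[1,0,2]]
worked_set <- function() {
  fpset(rbind(c(1, 1, 0), c(1, 1, 0), c(1, 0, 1), c(0, 0, 1)),
        fingerprint_spec("custom", length = 3))
}

rand_fpset <- function(n, d, p = 0.4) {
  fpset(matrix(as.integer(stats::runif(n * d) < p), n, d),
        fingerprint_spec("custom", length = d))
}

# independent oracle for CORM: explicit loop over compounds x feature pairs
naive_corm <- function(bits) {
  d <- ncol(bits)
  m <- matrix(0, d, d)
  for (o in seq_len(nrow(bits)))
    for (i in seq_len(d))
      for (j in seq_len(d))
        m[i, j] <- m[i, j] + bits[o, i] * bits[o, j]
  m
}

# independent AUC oracle: all ES x HS pairs, ties count 0.5
brute_auc <- function(es, hs) {
  tot <- 0
  for (e in es) for (h in hs)
    tot <- tot + if (e > h) 1 else if (e == h) 0.5 else 0
  tot / (length(es) * length(hs))
}

# coherent/scrambled classification scenario used by the end-to-end
# property: disjoint planted pairs over D features, marginal p, enrichment e
coherent_design <- function(n, seed, d = 64L, p = 0.3, e = 3, n_pairs = 24L) {
  pp <- data.frame(i = 2L * seq_len(n_pairs) - 2L,
                   j = 2L * seq_len(n_pairs) - 1L, e = e)
  synthetic_design(d, p, pp, n_compounds = n, seed = seed)
}
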