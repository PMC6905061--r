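# Shared fixture builders: everything is generated in code, no data files.

# Handcrafted two-locus table used throughout the marker tests.
tiny_table <- function() {
  ssr_table(
    c("g1", "g2", "g3"),
    list(L1 = list(c(161, 165), 161, 165),
         L2 = list(198, c(198, 202), NULL)))
}

# Random complete binary marker matrix (all columns polymorphic).
random_markers <- function(n, m, seed) {
  set.seed(seed)
  repeat {
    Z <- matrix(rbinom(n * m, 1, runif(m, 0.2, 0.8)[rep(seq_len(m),
                                                        each = n)]),
                n, m)
    if (all(colSums(Z) > 0 & colSums(Z) < n)) break
  }
  dimnames(Z) <- list(sprintf("g%02d", seq_len(n)),
                      sprintf("L%02d_%d", seq_len(m), 100 + seq_len(m)))
  marker_matrix(Z)
}

# Identity relationship set over given ids (no genomic information),
# for models where every covariance is an identity.
identity_rel <- function(ids) {
  n <- length(ids)
  I <- diag(n); dimnames(I) <- list(ids, ids)
  structure(list(ids = ids, genotyped = ids,
                 genotyped_idx = seq_len(n),
                 A = I, A22 = I, G = I, Gstar = I, Hinv = I, H = I,
                 weight = 1),
            class = "relationship_set")
}

# Reduced-scale simulated study (fast enough for unit tests).
small_study <- function(seed, ...) {
  args <- list(n_genotypes = 24, n_genotyped = 20, n_loci = 8,
               n_cuttings = 3, n_reps = 2, blocks_per_rep = 4,
               missing_marker_rate = 0.05, seed = seed)
  args[names(list(...))] <- list(...)
  simulate_study(do.call(sim_config, args))
}

fast_opts <- function(tol = 1e-6) reml_opts(method = "ai", tol = tol)
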