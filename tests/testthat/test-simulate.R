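test_that("simulate_genotypes is reproducible and shaped as configured", {
  cfg <- sim_config(n_genotypes = 30, n_genotyped = 25, n_loci = 10,
                    missing_marker_rate = 0.1, seed = 5)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  expect_length(g1$genotypes, 30)
  expect_length(g1$calls, 10)
  # expanded marker count equals a recount of distinct (locus, allele)
  # pairs in the unmasked table, and sits in the configured band
  comp <- attr(g1, "complete")
  mm <- expand_alleles(comp)
  n_pairs <- sum(vapply(comp$calls, function(l)
    length(unique(unlist(l))), integer(1)))
  expect_equal(ncol(mm$Z), n_pairs)
  expect_gte(ncol(mm$Z), 10 * 2)
  expect_lte(ncol(mm$Z), 10 * 9)
  expect_error(simulate_genotypes(
    sim_config(alleles_per_locus = c(1, 1), seed = 1)), "alleles")
})

test_that("missing-call injection hits the configured rate", {
  cfg0 <- sim_config(n_genotypes = 50, n_genotyped = 45, n_loci = 12,
                     missing_marker_rate = 0, seed = 9)
  g0 <- simulate_genotypes(cfg0)
  expect_true(all(vapply(g0$calls, function(l)
    !any(vapply(l, is.null, logical(1))), logical(1))))
  cfg <- sim_config(n_genotypes = 200, n_genotyped = 200, n_loci = 20,
                    missing_marker_rate = 0.2, seed = 9)
  g <- simulate_genotypes(cfg)
  miss <- mean(vapply(g$calls, function(l)
    mean(vapply(l, is.null, logical(1))), numeric(1)))
  expect_gt(miss, 0.16); expect_lt(miss, 0.24)   # binomial band
})

test_that("simulate_study is deterministic and decomposes exactly", {
  s1 <- small_study(33)
  s2 <- small_study(33)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth, s2$truth)
  dec <- s1$truth$per_trait$TRAIT$decomposition
  expect_equal(rowSums(dec), s1$phenotypes$TRAIT, tolerance = 1e-12)
})

test_that("all-zero components collapse phenotypes onto fixed means", {
  s <- small_study(3, sigma2 = c(a = 0, g = 0, b = 0, i = 0, r = 0,
                                 p = 0, residual = 0))
  m <- s$truth$per_trait$TRAIT$m
  expect_equal(s$phenotypes$TRAIT,
               unname(m[s$phenotypes$Cut.Rep]), tolerance = 1e-12)
})

test_that("true additive variance tracks the relationship diagonal", {
  # sigma2_a = 1, everything else 0: across replicates the empirical
  # variance of the true additive values approaches mean(diag(H)) ~ 1
  vars <- vapply(1:12, function(s) {
    st <- small_study(100 + s, n_genotypes = 40, n_genotyped = 34,
                      sigma2 = c(a = 1, g = 0, b = 0, i = 0, r = 0,
                                 p = 0, residual = 0))
    var(st$truth$per_trait$TRAIT$a)
  }, numeric(1))
  expect_gt(mean(vars), 0.7); expect_lt(mean(vars), 1.3)
})

test_that("inject_qtl shifts carriers by beta", {
  s <- small_study(8, sigma2 = c(a = 0, g = 0, b = 0, i = 0, r = 0,
                                 p = 0, residual = 0))
  s0 <- inject_qtl(s, s$truth$presence$markers[1], beta = 0)
  expect_equal(s0$phenotypes, s$phenotypes)
  beta <- 2.5
  mk <- s$truth$presence$markers[3]
  s2 <- inject_qtl(s, mk, beta)
  carrier <- s$truth$presence$Z[s$phenotypes$Gen, mk] == 1
  diffs <- s2$phenotypes$TRAIT - s$phenotypes$TRAIT
  expect_equal(unname(diffs[carrier]),
               rep(beta, sum(carrier)), tolerance = 1e-12)
  expect_equal(unname(diffs[!carrier]),
               rep(0, sum(!carrier)), tolerance = 1e-12)
  expect_error(inject_qtl(s, "no_such_1", 1), "unknown marker")
})

test_that("inject_missingness masks reproducibly and at rate", {
  s <- small_study(12, missing_marker_rate = 0)
  expect_identical(inject_missingness(s, 0, 0, seed = 1), s)
  m1 <- inject_missingness(s, 0.2, 0.1, seed = 77)
  m2 <- inject_missingness(s, 0.2, 0.1, seed = 77)
  expect_identical(m1$genotype_table, m2$genotype_table)
  expect_identical(m1$phenotypes, m2$phenotypes)
  expect_null(m1$markers)          # caches cleared after marker masking
  miss <- mean(vapply(m1$genotype_table$calls, function(l)
    mean(vapply(l, is.null, logical(1))), numeric(1)))
  expect_gt(miss, 0.1); expect_lt(miss, 0.3)
  expect_gt(mean(is.na(m1$phenotypes$TRAIT)), 0.03)
  expect_lt(mean(is.na(m1$phenotypes$TRAIT)), 0.2)
})

test_that("simulated tables round-trip through the file dialects", {
  s <- small_study(21, missing_marker_rate = 0.1)
  fg <- tempfile(fileext = ".csv"); fp <- tempfile(fileext = ".csv")
  write_ssr_table(s$genotype_table, fg)
  write_phenotypes(s$phenotypes, fp)
  tab <- read_marker_table(fg)
  ph <- read_phenotypes(fp)
  expect_equal(expand_alleles(tab)$Z, expand_alleles(s$genotype_table)$Z)
  expect_equal(ph$TRAIT, s$phenotypes$TRAIT, tolerance = 1e-9)
  expect_equal(ph$Gen, s$phenotypes$Gen)
})
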