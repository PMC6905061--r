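test_that("build_design enumerates levels and drops missing records", {
  rel <- identity_rel(c("g1", "g2"))
  ph <- expand.grid(Gen = c("g1", "g2"), Cut = 1:2, Rep = 1,
                    stringsAsFactors = FALSE)
  ph$y <- rnorm(4)
  spec <- mm_spec("y", fixed = "cut_rep", random = list(
    list(label = "g", unit = "genotype", cov = "identity"),
    list(label = "i", unit = "geno_cut", cov = "identity"),
    list(label = "p", unit = "plot", cov = "identity")))
  des <- build_design(ph, spec, rel)
  expect_equal(ncol(des$X), 2)            # intercept + 1 cut.rep contrast
  expect_equal(des$terms$g$q, 2)
  expect_equal(des$terms$i$q, 4)
  expect_equal(des$terms$p$q, 2)
  # every incidence row maps the record to exactly one level
  for (tm in des$terms)
    expect_equal(unname(Matrix::rowSums(tm$Z)), rep(1, des$n))
  ph$y[2] <- NA
  expect_message(des2 <- build_design(ph, spec, rel), "dropping 1")
  expect_equal(des2$n, 3)
  ph$Gen[1] <- "stranger"
  expect_error(build_design(ph, spec, rel), "stranger")
})

test_that("study-shaped layout yields ten fixed-effect columns", {
  st <- small_study(1, n_genotypes = 12, n_genotyped = 10,
                    n_cuttings = 5, n_reps = 2)
  des <- build_design(st$phenotypes, spec_full_ssgblup("TRAIT"),
                      st$relationships)
  expect_equal(ncol(des$X), 10)           # 5 cuttings x 2 reps
})

test_that("balanced one-way REML matches the ANOVA closed form", {
  q <- 12; nrep <- 5
  set.seed(31)
  g <- rnorm(q, 0, sqrt(2))
  y <- rep(g, each = nrep) + rnorm(q * nrep, 0, 1)
  # Rep constant so the fixed part is the intercept alone and the
  # classical one-way ANOVA identities apply
  ph <- data.frame(Gen = rep(sprintf("g%02d", 1:q), each = nrep),
                   Cut = 1, Rep = 1, y = y)
  spec <- mm_spec("y", fixed = "cut_rep", random = list(
    list(label = "g", unit = "genotype", cov = "identity")))
  rel <- identity_rel(sprintf("g%02d", 1:q))
  fit <- fit_reml(build_design(ph, spec, rel), rel, fast_opts(1e-10))
  means <- tapply(y, ph$Gen, mean)
  msb <- nrep * var(means)
  mse <- sum((y - means[ph$Gen])^2) / (q * (nrep - 1))
  expect_equal(fit$sigma2[["residual"]], mse, tolerance = 1e-6)
  expect_equal(fit$sigma2[["g"]], (msb - mse) / nrep, tolerance = 1e-6)
})

test_that("restricted log-likelihood matches the direct-V oracle", {
  st <- small_study(7)
  des <- build_design(st$phenotypes, spec_full_ssgblup("TRAIT"),
                      st$relationships)
  fit <- fit_reml(des, st$relationships, fast_opts())
  V <- ssrgblup:::.model_V(des, st$relationships, fit$sigma2)
  X <- des$X; y <- des$y
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi) %*% X
  b <- solve(XtViX, crossprod(X, Vi) %*% y)
  r <- y - X %*% b
  ll <- -0.5 * ((length(y) - ncol(X)) * log(2 * pi) +
                as.numeric(determinant(V)$modulus) +
                as.numeric(determinant(XtViX)$modulus) +
                drop(crossprod(r, Vi %*% r)))
  expect_equal(fit$logLik, ll, tolerance = 1e-6)
})

test_that("EM iterations never decrease the restricted log-likelihood", {
  st <- small_study(3, n_genotypes = 15, n_genotyped = 12)
  des <- build_design(st$phenotypes, spec_full_ssgblup("TRAIT"),
                      st$relationships)
  # monotonicity holds whether or not EM reaches the tolerance within
  # the iteration cap (the non-convergence error carries the trajectory)
  traj <- tryCatch(
    fit_reml(des, st$relationships,
             reml_opts(method = "em", tol = 1e-6, max_iter = 150))$trajectory,
    error = function(e) as.data.frame(e$trajectory))
  expect_gt(nrow(traj), 10)
  expect_true(all(diff(traj$logLik) > -1e-8))
})

test_that("a truly-zero component converges to the boundary", {
  s2 <- c(a = 1, g = 0, b = 0.25, i = 0.4, r = 0, p = 0.2, residual = 1)
  st <- small_study(11, sigma2 = s2)
  des <- build_design(st$phenotypes, spec_full_ssgblup("TRAIT"),
                      st$relationships)
  fit <- fit_reml(des, st$relationships, fast_opts())
  vy <- var(des$y)
  expect_lt(fit$sigma2[["g"]], 0.05 * vy)
  expect_lt(fit$sigma2[["r"]], 0.05 * vy)
})

test_that("PEV of every level is bounded by its term's variance", {
  st <- small_study(13)
  des <- build_design(st$phenotypes, spec_full_ssgblup("TRAIT"),
                      st$relationships)
  fit <- fit_reml(des, st$relationships, fast_opts())
  for (tm in c("g", "r", "p", "b")) {     # identity-covariance terms
    if (!tm %in% names(fit$u) || fit$sigma2[[tm]] <= 0) next
    expect_true(all(fit$pev[[tm]] <= fit$sigma2[[tm]] + 1e-8),
                label = paste("PEV bound for", tm))
  }
})

test_that("identity genotype covariance merges with the residual genetic
           term: split and merged fits have one likelihood", {
  st <- small_study(17)
  rel_I <- identity_rel(st$relationships$ids)
  spec <- spec_full_ssgblup("TRAIT", gi = "identity")
  full_I <- fit_reml(build_design(st$phenotypes, spec, rel_I), rel_I,
                     fast_opts(1e-8))
  merged <- fit_reml(build_design(st$phenotypes, drop_term(spec, "a"),
                                  rel_I), rel_I, fast_opts(1e-8))
  expect_equal(full_I$logLik, merged$logLik, tolerance = 1e-4)
  # and the split components sum to the merged genotype variance
  expect_equal(full_I$sigma2[["a"]] + full_I$sigma2[["g"]],
               merged$sigma2[["g"]], tolerance = 0.05)
})

test_that("lrt computes the chi-square(1) comparison", {
  fake <- function(ll, terms, n = 100)
    structure(list(logLik = ll,
                   u = setNames(vector("list", length(terms)), terms),
                   n = n), class = "blup_fit")
  r <- lrt(fake(-100, c("a", "g")), fake(-100, "g"))
  expect_equal(r$statistic, 0)
  expect_false(r$significant)
  r2 <- lrt(fake(-100, c("a", "g")), fake(-102, "g"))
  expect_equal(r2$statistic, 4)
  expect_true(r2$significant)              # 4 > 3.84
  expect_equal(r2$p.value, pchisq(4, 1, lower.tail = FALSE))
  # reduced likelihood above full within tolerance clamps at zero
  expect_equal(lrt(fake(-100, c("a", "g")), fake(-99.999, "g"))$statistic,
               0)
  expect_error(lrt(fake(-1, c("a", "g", "b")), fake(-2, "g")),
               "exactly one")
})

test_that("accuracy transforms PEV as sqrt(1 - PEV/sigma2)", {
  fit <- structure(list(
    sigma2 = c(a = 1, residual = 1),
    u = list(a = c(l1 = 0.5, l2 = -0.1, l3 = 0.2)),
    pev = list(a = c(l1 = 0, l2 = 1, l3 = 0.36))), class = "blup_fit")
  acc <- accuracy(fit, "a")
  expect_equal(unname(acc$per_level), c(1, 0, 0.8))
  expect_equal(acc$summary, mean(c(1, 0, 0.8)))
  fit$sigma2[["a"]] <- 0
  expect_warning(acc0 <- accuracy(fit, "a"), "undefined")
  expect_true(is.na(acc0$summary))
})

test_that("extract_blups returns one ordered row per level", {
  st <- small_study(19)
  des <- build_design(st$phenotypes, spec_full_ssgblup("TRAIT"),
                      st$relationships)
  fit <- fit_reml(des, st$relationships, fast_opts())
  tab <- extract_blups(fit, "a")
  expect_equal(nrow(tab), st$config$n_genotypes)
  expect_equal(tab$level, st$relationships$ids)
  tab_g <- extract_blups(fit, "g")
  expect_false(isTRUE(all.equal(tab$estimate, tab_g$estimate)))
  expect_error(extract_blups(fit, "zz"), "unknown term")
})

test_that("the full study-scale model fits within budget", {
  # default generator world: 100 genotypes (90 genotyped), 5 cuttings,
  # 2 reps -- the one full-scale fit of the suite
  st <- simulate_study(sim_config(seed = 77))
  des <- build_design(st$phenotypes, spec_full_ssgblup("TRAIT"),
                      st$relationships)
  expect_equal(des$n, 1000)
  expect_equal(ncol(des$X), 10)
  fit <- fit_reml(des, st$relationships, fast_opts())
  expect_true(fit$converged)
  expect_true(all(fit$sigma2 >= 0))
  acc <- accuracy(fit, "a")
  expect_gt(acc$summary, 0.4); expect_lte(acc$summary, 1)
  # ungenotyped individuals still receive predictions through H
  ungen <- setdiff(st$relationships$ids, st$markers$genotypes)
  expect_true(all(ungen %in% names(fit$u$a)))
  expect_gt(cor(st$truth$per_trait$TRAIT$a[names(fit$u$a)], fit$u$a),
            0.5)
})

test_that("BLUP-truth correlation increases with heritability", {
  cors <- vapply(c(0.1, 1, 6), function(s2a) {
    st <- small_study(23, sigma2 = c(a = s2a, g = 0.1, b = 0.1, i = 0.2,
                                     r = 0.1, p = 0.1, residual = 1))
    des <- build_design(st$phenotypes, spec_full_ssgblup("TRAIT"),
                        st$relationships)
    fit <- fit_reml(des, st$relationships, fast_opts(1e-4))
    truth_a <- st$truth$per_trait$TRAIT$a[st$relationships$ids]
    cor(truth_a, fit$u$a)
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})
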