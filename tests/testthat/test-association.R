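# Small association worlds: genotypes with one record per rep and a
# genomic relationship built from the markers themselves.
null_world <- function(n_gen, m, seed, n_rep = 2) {
  mm <- random_markers(n_gen, m, seed)
  set.seed(seed + 1000)
  ph <- expand.grid(Gen = mm$genotypes, Rep = 1:n_rep,
                    stringsAsFactors = FALSE)
  ph$Cut <- 1
  ph$y <- rnorm(nrow(ph)) + 0.3 * (ph$Rep == 2)
  list(markers = mm, ph = ph, rel = relationship_set(mm))
}

test_that("scan statistics agree with an independent GLS computation", {
  w <- null_world(30, 40, 1)
  res <- gwas_scan(w$ph, w$markers, w$rel, "y")
  # recompute effect, se and p from scratch at the same components
  s2 <- res$null_fit$sigma2
  n <- nrow(w$ph)
  Zg <- outer(w$ph$Gen, w$markers$genotypes, "==") * 1
  V <- s2[["residual"]] * diag(n) +
    s2[["a"]] * Zg %*% w$rel$H %*% t(Zg) +
    s2[["g"]] * tcrossprod(Zg)
  X <- model.matrix(~ factor(Rep), w$ph)
  Vi <- solve(V)
  P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X, t(X) %*% Vi)
  gi <- match(w$ph$Gen, w$markers$genotypes)
  for (j in c(1, 7, 23)) {
    x <- w$markers$Z[gi, j]
    eff <- drop(x %*% P %*% w$ph$y) / drop(x %*% P %*% x)
    se <- sqrt(1 / drop(x %*% P %*% x))
    expect_equal(res$table$effect[j], eff, tolerance = 1e-8)
    expect_equal(res$table$se[j], se, tolerance = 1e-8)
    expect_equal(res$table$p[j],
                 pchisq((eff / se)^2, 1, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("with zero genetic variance the scan reduces to least squares", {
  w <- null_world(40, 30, 2)
  res <- gwas_scan(w$ph, w$markers, w$rel, "y",
                   sigma2 = c(a = 0, g = 0, residual = 1))
  gi <- match(w$ph$Gen, w$markers$genotypes)
  X <- model.matrix(~ factor(Rep), w$ph)
  Mx <- diag(nrow(w$ph)) - X %*% solve(crossprod(X), t(X))
  for (j in seq_len(30)) {
    x <- w$markers$Z[gi, j]
    # OLS partial coefficient from lm is the exact oracle
    bj <- unname(coef(lm(w$ph$y ~ factor(w$ph$Rep) + x))["x"])
    expect_equal(res$table$effect[j], bj, tolerance = 1e-8)
    # with unit residual variance the Wald statistic is b^2 x'Mx
    expect_equal(res$table$wald[j],
                 bj^2 * drop(crossprod(x, Mx %*% x)), tolerance = 1e-8)
  }
})

test_that("null p-values are approximately uniform (QQ slope ~ 1)", {
  w <- null_world(60, 200, 3)
  res <- gwas_scan(w$ph, w$markers, w$rel, "y")
  p <- res$table$p[!is.na(res$table$p)]
  expect_gt(length(p), 190)
  expect_gt(mean(p), 0.4); expect_lt(mean(p), 0.6)
  obs <- sort(-log10(p)); exp_q <- sort(-log10((seq_along(p) - 0.5) /
                                               length(p)))
  slope <- coef(lm(obs ~ 0 + exp_q))[[1]]
  expect_gt(slope, 0.8); expect_lt(slope, 1.2)
  # and essentially nothing passes the FDR rule under the null
  expect_lte(sum(res$table$significant), 1)
})

test_that("a strong injected effect attains the scan minimum p", {
  w <- null_world(40, 50, 4)
  gi <- match(w$ph$Gen, w$markers$genotypes)
  y2 <- w$ph$y + 3 * w$markers$Z[gi, 17]
  ph <- w$ph; ph$y <- y2
  res <- gwas_scan(ph, w$markers, w$rel, "y")
  expect_equal(which.min(res$table$p), 17L)
  expect_true(res$table$significant[17])
})

test_that("scan output is invariant to marker column order", {
  w <- null_world(25, 20, 5)
  res1 <- gwas_scan(w$ph, w$markers, w$rel, "y")
  set.seed(9); perm <- sample(20)
  mm2 <- marker_matrix(w$markers$Z[, perm])
  res2 <- gwas_scan(w$ph, mm2, w$rel, "y")
  expect_equal(res2$table$p, res1$table$p[perm], tolerance = 1e-10)
  expect_equal(res2$threshold, res1$threshold)
})

test_that("constant markers are flagged as missing, not tested", {
  w <- null_world(20, 10, 6)
  Z <- w$markers$Z
  Z[, 4] <- 1
  res <- gwas_scan(w$ph, marker_matrix(Z), w$rel, "y")
  expect_true(is.na(res$table$p[4]))
  expect_false(res$table$significant[4])
  expect_equal(sum(is.na(res$table$p)), 1)
})

test_that("fdr_threshold implements screened Benjamini-Hochberg", {
  # hand-worked: only 0.001 <= 1 * 0.02 / 3
  expect_equal(fdr_threshold(c(0.001, 0.2, 0.9), q = 0.02),
               -log10(0.001))
  # all p = 1: threshold sits above every observed -log10(p)
  thr <- fdr_threshold(rep(1, 10))
  expect_gt(thr, 0)
  expect_true(all(-log10(rep(1, 10)) < thr))
  # screening: a p-value above alpha can never be declared
  expect_equal(fdr_threshold(c(0.06, 0.5), q = 0.9, alpha = 0.05),
               max(-log10(c(0.06, 0.5))) + 1)
  expect_error(fdr_threshold(numeric(0)), "empty")
})

test_that("adding a smaller p never lowers the BH discovery count", {
  count_disc <- function(p) {
    thr <- fdr_threshold(p, q = 0.1, alpha = 0.5)
    sum(-log10(p) >= thr)
  }
  set.seed(11)
  for (i in 1:20) {
    p <- runif(30)
    extra <- runif(1) * min(p)
    expect_gte(count_disc(c(p, extra)), count_disc(p))
  }
})

test_that("qq_manhattan_data lays out the plot tables", {
  w <- null_world(20, 15, 7)
  res <- gwas_scan(w$ph, w$markers, w$rel, "y")
  pd <- qq_manhattan_data(res)
  n <- sum(!is.na(res$table$p))
  expect_equal(pd$qq$expected, -log10((seq_len(n) - 0.5) / n))
  expect_true(all(pd$manhattan$threshold == res$threshold))
  expect_equal(nrow(pd$manhattan), 15)
  # all p equal -> observed flat
  res$table$p[] <- 0.25
  res$table$neglog10p[] <- -log10(0.25)
  pd2 <- qq_manhattan_data(res)
  expect_equal(var(pd2$qq$observed), 0)
})
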