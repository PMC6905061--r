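## Named RNG streams: every stage draws from its own seed derived from
## the single configuration seed, so stages can be regenerated
## independently and runs are byte-identical for a fixed configuration.
.stream_seed <- function(seed, name) {
  v <- utf8ToInt(name)
  h <- sum(v * seq_along(v)) %% 100003
  as.integer((as.numeric(seed) * 7919 + h * 10007) %% 2147483629)
}

.with_stream <- function(seed, name, expr) {
  set.seed(.stream_seed(seed, name))
  expr
}

#' Simulation configuration for a study-shaped data set
#'
#' The defaults mirror the trial this package is designed around: 100
#' clonal genotypes of which 90 are genotyped, 18 multiallelic SSR loci,
#' 5 harvests (cuttings) x 2 replications laid out in 10 incomplete
#' blocks of 10 plots per replication, and phenotypes generated under
#' the full evaluation model
#' \eqn{y = Xm + Za + Zg + Wb + Ti + Tr + Qp + \epsilon}.
#'
#' @param n_genotypes,n_genotyped totals; the last
#'   \code{n_genotypes - n_genotyped} individuals are left ungenotyped.
#' @param n_loci number of SSR loci.
#' @param alleles_per_locus integer range (min, max) of distinct alleles
#'   per locus; must reach at least 2.
#' @param n_cuttings,n_reps,blocks_per_rep trial layout.
#' @param sigma2 named true variance components for terms
#'   \code{a, g, b, i, r, p} and \code{residual}.
#' @param grand_mean,fixed_sd mean and spread of the fixed
#'   cutting-replication means.
#' @param traits trait names to simulate (independent draws, shared
#'   components).
#' @param qtl optional causal allele: \code{list(marker =, beta =,
#'   trait =)} (trait defaults to the first).
#' @param missing_marker_rate per genotype-locus probability of a
#'   missing call.
#' @param missing_phenotype_rate per record probability of a missing
#'   trait value.
#' @param weight relationship blending weight.
#' @param seed mandatory integer master seed.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_genotypes = 100, n_genotyped = 90, n_loci = 18,
                       alleles_per_locus = c(4, 8), n_cuttings = 5,
                       n_reps = 2, blocks_per_rep = 10,
                       sigma2 = c(a = 1, g = 0.5, b = 0.25, i = 0.5,
                                  r = 0.25, p = 0.25, residual = 1),
                       grand_mean = 10, fixed_sd = 2, traits = "TRAIT",
                       qtl = NULL, missing_marker_rate = 0.05,
                       missing_phenotype_rate = 0, weight = 0.95,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(n_genotyped <= n_genotypes, all(sigma2 >= 0),
            missing_marker_rate >= 0, missing_marker_rate < 1,
            missing_phenotype_rate >= 0, missing_phenotype_rate < 1)
  need <- c("a", "g", "b", "i", "r", "p", "residual")
  if (!all(need %in% names(sigma2)))
    stop("sigma2 must name components: ", paste(need, collapse = ", "))
  if (max(alleles_per_locus) < 2) stop("alleles_per_locus must reach 2")
  if (!is.null(qtl) && is.null(qtl$trait)) qtl$trait <- traits[1L]
  structure(list(n_genotypes = n_genotypes, n_genotyped = n_genotyped,
                 n_loci = n_loci, alleles_per_locus = alleles_per_locus,
                 n_cuttings = n_cuttings, n_reps = n_reps,
                 blocks_per_rep = blocks_per_rep, sigma2 = sigma2[need],
                 grand_mean = grand_mean, fixed_sd = fixed_sd,
                 traits = traits, qtl = qtl,
                 missing_marker_rate = missing_marker_rate,
                 missing_phenotype_rate = missing_phenotype_rate,
                 weight = weight, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate multiallelic SSR genotypes
#'
#' Per locus, an allele count is drawn from the configured range, allele
#' sizes and frequencies (flat Dirichlet) are drawn, and each genotype's
#' presence set is formed from four draws with replacement (a
#' tetraploid-like call, guaranteeing at least one allele per called
#' locus).  Missing calls are injected at the configured rate.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return An \code{\link{ssr_table}} covering all genotypes (masked
#'   calls at the missing rate); the unmasked table is attached as
#'   attribute \code{"complete"}.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- sprintf("G%03d", seq_len(cfg$n_genotypes))
  loci <- sprintf("M%02d", seq_len(cfg$n_loci))
  complete <- .with_stream(cfg$seed, "genotypes", {
    calls <- lapply(loci, function(locus) {
      n_all <- sample(seq(cfg$alleles_per_locus[1],
                          cfg$alleles_per_locus[2]), 1L)
      sizes <- sort(sample(seq(100L, 300L, by = 2L), n_all))
      freq <- stats::rgamma(n_all, 1)
      freq <- freq / sum(freq)
      lapply(seq_along(ids), function(g)
        sort(unique(sample(sizes, 4L, replace = TRUE, prob = freq))))
    })
    names(calls) <- loci
    ssr_table(ids, calls)
  })
  masked <- complete
  if (cfg$missing_marker_rate > 0) {
    masked <- .with_stream(cfg$seed, "marker_mask", {
      calls <- complete$calls
      for (locus in loci) {
        hit <- stats::runif(length(ids)) < cfg$missing_marker_rate
        calls[[locus]][hit] <- list(NULL)
      }
      ssr_table(ids, calls)
    })
  }
  attr(masked, "complete") <- complete
  masked
}

#' Simulate a complete study with recorded ground truth
#'
#' Simulates genotypes, builds the single-step relationship set from the
#' genotyped subset (QC + imputation with the package defaults), draws
#' every random effect of the full evaluation model at the configured
#' true components — additive values jointly over genotyped and
#' ungenotyped individuals via the H matrix — assembles phenotypes, and
#' records the exact per-record effect decomposition.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return Object of class \code{sim_study}: \code{genotype_table}
#'   (masked calls, genotyped individuals only), \code{phenotypes}
#'   (long-format records: Cut, Gen, Rep, Block, Cut.Rep, one column per
#'   trait), \code{markers} (post-QC imputed matrix),
#'   \code{relationships}, and \code{truth} (true effects per trait,
#'   components, QTL, complete presence matrix, per-record
#'   decomposition).
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  gt <- simulate_genotypes(cfg)
  complete <- attr(gt, "complete")
  ids <- gt$genotypes
  genotyped <- ids[seq_len(cfg$n_genotyped)]

  released <- .subset_ssr(gt, genotyped)
  mm <- impute_missing(qc_filter(expand_alleles(released))$markers)
  rel <- relationship_set(mm, individuals = ids, weight = cfg$weight)
  Zfull <- expand_alleles(complete)      # complete truth, no missing
  L <- t(chol(rel$H))                    # rel$ids order

  nc <- cfg$n_cuttings; nr <- cfg$n_reps
  layout <- .with_stream(cfg$seed, "layout", {
    bs <- ceiling(cfg$n_genotypes / cfg$blocks_per_rep)
    lapply(seq_len(nr), function(r) {
      perm <- sample(ids)
      stats::setNames(((match(ids, perm) - 1L) %/% bs) + 1L, ids)
    })
  })

  recs <- expand.grid(Gen = ids, Rep = seq_len(nr), Cut = seq_len(nc),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  recs <- recs[, c("Cut", "Gen", "Rep")]
  recs$Block <- vapply(seq_len(nrow(recs)), function(k)
    sprintf("C%d.R%d.B%02d", recs$Cut[k], recs$Rep[k],
            layout[[recs$Rep[k]]][[recs$Gen[k]]]), character(1))
  recs$Cut.Rep <- paste(recs$Cut, recs$Rep, sep = ".")
  cut_rep_levels <- sort(unique(recs$Cut.Rep))
  block_levels <- sort(unique(recs$Block))
  plot_levels <- sort(unique(paste(recs$Gen, recs$Rep, sep = ":")))
  s2 <- cfg$sigma2

  truth <- list(components = s2, qtl = cfg$qtl,
                presence = Zfull, per_trait = list())
  for (tr in cfg$traits) {
    eff <- .with_stream(cfg$seed, paste0("effects_", tr), {
      a_rel <- sqrt(s2[["a"]]) * as.numeric(L %*% stats::rnorm(length(ids)))
      names(a_rel) <- rel$ids
      a <- a_rel[ids]
      if (!is.null(cfg$qtl) && identical(cfg$qtl$trait, tr)) {
        j <- match(cfg$qtl$marker, Zfull$markers)
        if (is.na(j)) stop("unknown QTL marker '", cfg$qtl$marker, "'")
        a <- a + cfg$qtl$beta * Zfull$Z[ids, j]
      }
      g <- stats::setNames(stats::rnorm(length(ids), 0, sqrt(s2[["g"]])), ids)
      b <- stats::setNames(stats::rnorm(length(block_levels), 0,
                                        sqrt(s2[["b"]])), block_levels)
      i_eff <- unlist(lapply(seq_len(nc), function(cc) {
        v <- sqrt(s2[["i"]]) * as.numeric(L %*% stats::rnorm(length(ids)))
        stats::setNames(v, paste(cc, rel$ids, sep = ":"))
      }))
      r_eff <- stats::setNames(
        stats::rnorm(nc * length(ids), 0, sqrt(s2[["r"]])),
        as.vector(outer(ids, seq_len(nc), function(g, cc)
          paste(cc, g, sep = ":"))))
      p_eff <- stats::setNames(stats::rnorm(length(plot_levels), 0,
                                            sqrt(s2[["p"]])), plot_levels)
      m <- stats::setNames(cfg$grand_mean +
                             stats::rnorm(length(cut_rep_levels), 0,
                                          cfg$fixed_sd), cut_rep_levels)
      e <- stats::rnorm(nrow(recs), 0, sqrt(s2[["residual"]]))
      list(a = a, g = g, b = b, i = i_eff, r = r_eff, p = p_eff,
           m = m, e = e)
    })
    dec <- data.frame(
      m = eff$m[recs$Cut.Rep],
      a = eff$a[recs$Gen],
      g = eff$g[recs$Gen],
      b = eff$b[recs$Block],
      i = eff$i[paste(recs$Cut, recs$Gen, sep = ":")],
      r = eff$r[paste(recs$Cut, recs$Gen, sep = ":")],
      p = eff$p[paste(recs$Gen, recs$Rep, sep = ":")],
      e = eff$e)
    recs[[tr]] <- rowSums(dec)
    if (cfg$missing_phenotype_rate > 0) {
      recs[[tr]] <- .with_stream(cfg$seed, paste0("pheno_mask_", tr), {
        v <- recs[[tr]]
        v[stats::runif(length(v)) < cfg$missing_phenotype_rate] <- NA_real_
        v
      })
    }
    truth$per_trait[[tr]] <- c(eff, list(decomposition = dec))
  }
  rownames(recs) <- NULL
  structure(list(genotype_table = released, genotype_table_all = gt,
                 phenotypes = recs, markers = mm, relationships = rel,
                 truth = truth, config = cfg),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Simulated study:", x$config$n_genotypes, "genotypes (",
      x$config$n_genotyped, "genotyped ),", x$config$n_cuttings,
      "cuttings x", x$config$n_reps, "reps;",
      ncol(x$markers$Z), "post-QC markers\n")
  invisible(x)
}

.subset_ssr <- function(tab, keep_ids) {
  idx <- match(keep_ids, tab$genotypes)
  ssr_table(keep_ids,
            lapply(tab$calls, function(locus) locus[idx]))
}

#' Add a causal allele to a simulated study
#'
#' Adds \code{beta} times the (complete, truth-level) presence indicator
#' of the marker to the additive values of carriers, and propagates the
#' shift into the phenotype records and the recorded decomposition.
#'
#' @param study a \code{sim_study} from \code{\link{simulate_study}}.
#' @param marker marker label (\code{locus_allele}) in the truth
#'   presence matrix.
#' @param beta effect size in trait units.
#' @param trait trait to affect (defaults to the first).
#' @return The modified \code{sim_study}.
#' @export
inject_qtl <- function(study, marker, beta, trait = NULL) {
  stopifnot(inherits(study, "sim_study"))
  if (is.null(trait)) trait <- study$config$traits[1L]
  Zfull <- study$truth$presence
  j <- match(marker, Zfull$markers)
  if (is.na(j)) stop("unknown marker '", marker, "'")
  carrier <- Zfull$Z[, j]
  tt <- study$truth$per_trait[[trait]]
  tt$a <- tt$a + beta * carrier[names(tt$a)]
  add <- beta * carrier[study$phenotypes$Gen]
  keep <- !is.na(study$phenotypes[[trait]])
  study$phenotypes[[trait]][keep] <-
    study$phenotypes[[trait]][keep] + add[keep]
  tt$decomposition$a <- tt$decomposition$a + add
  study$truth$per_trait[[trait]] <- tt
  study$truth$qtl <- c(study$truth$qtl,
                       list(list(marker = marker, beta = beta,
                                 trait = trait)))
  study
}

#' Mask marker calls and phenotype records at random
#'
#' Masks locus calls of the released genotype table and trait values of
#' the phenotype table uniformly at random, reproducibly from the given
#' seed.  The cached post-QC markers and relationship set are cleared,
#' since they describe the pre-masking data; re-derive them through the
#' QC/imputation pipeline.
#'
#' @param study a \code{sim_study} from \code{\link{simulate_study}}.
#' @param marker_rate,phenotype_rate masking probabilities in [0, 1).
#' @param seed integer seed for the masks.
#' @return The masked \code{sim_study}.
#' @export
inject_missingness <- function(study, marker_rate = 0, phenotype_rate = 0,
                               seed) {
  stopifnot(inherits(study, "sim_study"),
            marker_rate >= 0, marker_rate < 1,
            phenotype_rate >= 0, phenotype_rate < 1)
  if (marker_rate == 0 && phenotype_rate == 0) return(study)
  tab <- study$genotype_table
  if (marker_rate > 0) {
    tab <- .with_stream(seed, "inject_marker_mask", {
      calls <- tab$calls
      for (locus in names(calls)) {
        hit <- stats::runif(length(tab$genotypes)) < marker_rate
        calls[[locus]][hit] <- list(NULL)
      }
      ssr_table(tab$genotypes, calls)
    })
    study$genotype_table <- tab
    study$markers <- NULL
    study$relationships <- NULL
  }
  if (phenotype_rate > 0) {
    study$phenotypes <- .with_stream(seed, "inject_pheno_mask", {
      ph <- study$phenotypes
      for (tr in study$config$traits) {
        hit <- stats::runif(nrow(ph)) < phenotype_rate
        ph[[tr]][hit] <- NA_real_
      }
      ph
    })
  }
  study
}
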