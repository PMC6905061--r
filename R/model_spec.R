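#' Low-level mixed-model specification
#'
#' Describes one response trait, the fixed term, and an ordered list of
#' random terms.  Each random term names the unit its incidence matrix
#' maps to and the covariance kind used for its levels:
#' \describe{
#'   \item{identity}{independent levels, \eqn{I \sigma^2}.}
#'   \item{genomic}{levels are the individuals of a
#'     \code{\link{relationship_set}} with covariance H (single-step) —
#'     the mixed-model equations use \code{Hinv} directly.}
#'   \item{interaction_genomic}{genotype-by-cutting levels with
#'     covariance \code{kron(I_cuttings, H)}: interaction effects
#'     correlated across genotypes via the relationship, independent
#'     across cuttings.}
#' }
#'
#' @param trait response column name in the phenotype table.
#' @param fixed fixed-effect kind: \code{"cut_rep"} (measurement x
#'   replication combination) or \code{"rep"} (replication only, used in
#'   per-cutting association fits).
#' @param random list of random-term descriptors, each
#'   \code{list(label =, unit =, cov =)} with unit one of
#'   \code{"genotype"}, \code{"block"}, \code{"geno_cut"}, \code{"plot"}.
#' @return Object of class \code{mm_spec}.
#' @export
mm_spec <- function(trait, fixed = "cut_rep", random) {
  stopifnot(fixed %in% c("cut_rep", "rep"))
  labs <- vapply(random, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("duplicate random-term labels")
  for (tm in random) {
    stopifnot(tm$unit %in% c("genotype", "block", "geno_cut", "plot"),
              tm$cov %in% c("identity", "genomic", "interaction_genomic"))
  }
  structure(list(trait = trait, fixed = fixed, random = random),
            class = "mm_spec")
}

#' Full single-step GBLUP model specification
#'
#' The multi-harvest evaluation model
#' \deqn{y = Xm + Za + Zg + Wb + Ti + Tr + Qp + \epsilon}
#' with additive effects \code{a} structured by the single-step
#' relationship (H), residual genetic effects \code{g} independent,
#' block effects \code{b}, genotype-by-cutting interaction \code{i}
#' (relationship-structured by default), residual interaction \code{r},
#' and permanent-environment (plot) effects \code{p}.
#'
#' @param trait response column name.
#' @param gi covariance for the interaction term: \code{"relationship"}
#'   (default, matches the genotype term) or \code{"identity"}.
#' @param block include the block term (dropped automatically with a
#'   warning when the data carry no Block column).
#' @return An \code{mm_spec}.
#' @export
spec_full_ssgblup <- function(trait, gi = c("relationship", "identity"),
                              block = TRUE) {
  gi <- match.arg(gi)
  gicov <- if (gi == "relationship") "interaction_genomic" else "identity"
  rn <- list(
    list(label = "a", unit = "genotype", cov = "genomic"),
    list(label = "g", unit = "genotype", cov = "identity"),
    list(label = "b", unit = "block", cov = "identity"),
    list(label = "i", unit = "geno_cut", cov = gicov),
    list(label = "r", unit = "geno_cut", cov = "identity"),
    list(label = "p", unit = "plot", cov = "identity"))
  if (!block) rn <- rn[vapply(rn, function(t) t$label != "b", logical(1))]
  mm_spec(trait, "cut_rep", rn)
}

#' Simple repeatability plus genotype-by-cutting model specification
#'
#' The no-relationship counterpart of \code{\link{spec_full_ssgblup}}:
#' \deqn{y = Xm + Zg + Wb + Ti + Qp + \epsilon}
#' with every random covariance an identity.
#'
#' @inheritParams spec_full_ssgblup
#' @return An \code{mm_spec}.
#' @export
spec_repeatability <- function(trait, block = TRUE) {
  rn <- list(
    list(label = "g", unit = "genotype", cov = "identity"),
    list(label = "b", unit = "block", cov = "identity"),
    list(label = "i", unit = "geno_cut", cov = "identity"),
    list(label = "p", unit = "plot", cov = "identity"))
  if (!block) rn <- rn[vapply(rn, function(t) t$label != "b", logical(1))]
  mm_spec(trait, "cut_rep", rn)
}

#' Per-cutting association-model specification (without the marker term)
#'
#' \deqn{y = Xm + Za + Zg + Wb + \epsilon} for a single cutting; the
#' marker enters later as a fixed covariate (\code{\link{gwas_scan}}).
#'
#' @inheritParams spec_full_ssgblup
#' @return An \code{mm_spec}.
#' @export
spec_association <- function(trait, block = TRUE) {
  rn <- list(
    list(label = "a", unit = "genotype", cov = "genomic"),
    list(label = "g", unit = "genotype", cov = "identity"),
    list(label = "b", unit = "block", cov = "identity"))
  if (!block) rn <- rn[vapply(rn, function(t) t$label != "b", logical(1))]
  mm_spec(trait, "rep", rn)
}

#' Drop one random term from a specification
#'
#' Used to form the reduced models of likelihood-ratio tests.
#'
#' @param spec an \code{mm_spec}.
#' @param label random-term label to remove.
#' @return The reduced \code{mm_spec}.
#' @export
drop_term <- function(spec, label) {
  labs <- vapply(spec$random, `[[`, character(1), "label")
  if (!label %in% labs) stop("no random term labelled '", label, "'")
  spec$random <- spec$random[labs != label]
  spec
}
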