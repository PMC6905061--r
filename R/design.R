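#' Build design matrices for a mixed-model specification
#'
#' Turns a long-format phenotype table (one row per genotype x cutting x
#' replication) into the response vector and incidence matrices of a
#' model specification.  Records with a missing trait value are dropped
#' with a message.  Level orderings are deterministic: genotype levels
#' follow the \code{relationship_set} ordering (ungenotyped block first),
#' genotype-by-cutting levels are cutting-major over that same genotype
#' ordering (so the interaction covariance is
#' \code{kron(I_cuttings, H)}), and factor levels read from the data are
#' sorted.
#'
#' @param phenotypes data frame with columns \code{Gen}, \code{Cut},
#'   \code{Rep}, optionally \code{Block}, and the trait column named in
#'   the spec.
#' @param spec an \code{\link{mm_spec}}.
#' @param relationships a \code{\link{relationship_set}} whose individual
#'   set covers every genotype present in the phenotypes.
#' @return Object of class \code{mm_design}: \code{y}, dense \code{X}
#'   (full-rank, first level of each fixed factor as reference), and a
#'   list \code{terms} of random-term descriptors carrying sparse
#'   incidence matrices \code{Z}, level labels and covariance kinds.
#' @export
build_design <- function(phenotypes, spec, relationships) {
  stopifnot(inherits(spec, "mm_spec"),
            inherits(relationships, "relationship_set"))
  need <- c("Gen", "Cut", "Rep", spec$trait)
  miss <- setdiff(need, names(phenotypes))
  if (length(miss)) stop("phenotype table lacks column(s): ",
                         paste(miss, collapse = ", "))
  ph <- phenotypes
  ph$Gen <- as.character(ph$Gen)
  drop <- is.na(ph[[spec$trait]])
  if (any(drop)) {
    message("dropping ", sum(drop), " record(s) with missing ", spec$trait)
    ph <- ph[!drop, , drop = FALSE]
  }
  if (!nrow(ph)) stop("no records left after dropping missing responses")
  unknown <- setdiff(unique(ph$Gen), relationships$ids)
  if (length(unknown))
    stop("genotype(s) absent from the relationship set: ",
         paste(unknown, collapse = ", "))

  y <- as.numeric(ph[[spec$trait]])
  n <- length(y)
  cuts <- sort(unique(ph$Cut))

  ## fixed part: reference-level (full-rank) coding
  fixed_fac <- if (spec$fixed == "cut_rep") {
    factor(paste(ph$Cut, ph$Rep, sep = "."),
           levels = sort(unique(paste(ph$Cut, ph$Rep, sep = "."))))
  } else {
    factor(ph$Rep, levels = sort(unique(ph$Rep)))
  }
  X <- if (nlevels(fixed_fac) > 1L) {
    stats::model.matrix(~fac, data.frame(fac = fixed_fac))
  } else {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  colnames(X) <- sub("^fac", spec$fixed, colnames(X))

  incidence <- function(fac) {
    Matrix::sparseMatrix(i = seq_len(n), j = as.integer(fac),
                         x = 1, dims = c(n, nlevels(fac)),
                         dimnames = list(NULL, levels(fac)))
  }

  random <- spec$random
  has_block <- "Block" %in% names(ph)
  terms <- list()
  for (tm in random) {
    lev <- switch(tm$unit,
      genotype = relationships$ids,
      block = if (has_block) sort(unique(as.character(ph$Block))) else NULL,
      geno_cut = as.vector(outer(relationships$ids, cuts,
                                 function(g, cc) paste(cc, g, sep = ":"))),
      plot = sort(unique(paste(ph$Gen, ph$Rep, sep = ":"))))
    if (is.null(lev)) {
      warning("no Block column in the phenotype table; dropping random ",
              "term '", tm$label, "'")
      next
    }
    fac <- switch(tm$unit,
      genotype = factor(ph$Gen, levels = lev),
      block = factor(as.character(ph$Block), levels = lev),
      geno_cut = factor(paste(ph$Cut, ph$Gen, sep = ":"), levels = lev),
      plot = factor(paste(ph$Gen, ph$Rep, sep = ":"), levels = lev))
    tm$levels <- lev
    tm$Z <- incidence(fac)
    tm$q <- length(lev)
    tm$n_cuttings <- length(cuts)
    terms[[tm$label]] <- tm
  }
  structure(list(y = y, X = X, terms = terms, trait = spec$trait,
                 n = n, records = ph, cuttings = cuts, spec = spec),
            class = "mm_design")
}

#' @export
print.mm_design <- function(x, ...) {
  cat("Mixed-model design for trait", x$trait, ":", x$n, "records,",
      ncol(x$X), "fixed columns\n")
  for (tm in x$terms)
    cat("  random ", tm$label, ": ", tm$q, " levels (", tm$cov, ")\n",
        sep = "")
  invisible(x)
}

## Resolve the precision (and covariance) matrix of one random term
## against a relationship set.  Returns dense Kinv, K and log|K|.
.term_covariance <- function(term, relationships) {
  q <- term$q
  if (term$cov == "identity")
    return(list(Kinv = NULL, K = NULL, logdetK = 0))   # NULL = identity
  if (term$cov == "genomic") {
    Kinv <- relationships$Hinv
    K <- relationships$H
  } else {                                             # interaction_genomic
    nc <- term$n_cuttings
    Kinv <- kronecker(diag(nc), relationships$Hinv)
    K <- kronecker(diag(nc), relationships$H)
  }
  if (nrow(Kinv) != q)
    stop("covariance dimension ", nrow(Kinv), " does not match the ", q,
         " levels of term '", term$label, "'")
  ld <- -2 * sum(log(diag(chol(Kinv))))                # log|K| = -log|Kinv|
  list(Kinv = Kinv, K = K, logdetK = ld)
}
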