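#' Genomic relationship matrix from centered binary markers
#'
#' \deqn{G = Z^* Z^{*\prime} / \sum_i p_i (1 - p_i)}
#' with \eqn{Z^* = Z - P}, where P repeats the presence frequency
#' \eqn{p_i} down column i.  When p is computed from Z itself the trace
#' of G equals the number of genotypes and all row sums are zero.
#'
#' @param x complete \code{\link{marker_matrix}} (post-imputation).
#' @param p frequencies used for centering and the denominator; defaults
#'   to those of \code{x}.
#' @return Symmetric positive semidefinite matrix, one row per genotype.
#' @export
build_G <- function(x, p = NULL) {
  Zs <- centered_markers(x, p)
  if (is.null(p)) p <- if (!is.null(x$p)) x$p else colMeans(x$Z)
  denom <- sum(p * (1 - p))
  if (denom <= 0)
    stop("all markers monomorphic: sum p(1-p) is zero, G undefined")
  G <- tcrossprod(Zs) / denom
  dimnames(G) <- list(x$genotypes, x$genotypes)
  (G + t(G)) / 2
}

#' Blend a genomic relationship matrix with its pedigree counterpart
#'
#' \code{Gstar = weight * G + (1 - weight) * A22}.  With \code{A22 = I}
#' the smallest eigenvalue of the result is at least \code{1 - weight},
#' so the blend is invertible; the default weight 0.95 is the customary
#' regularization used before inverting G.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationship among the genotyped individuals
#'   (identity when no pedigree exists).
#' @param weight blending weight in (0, 1].
#' @return The blended matrix G*.
#' @export
blend_G <- function(G, A22 = diag(nrow(G)), weight = 0.95) {
  stopifnot(weight > 0, weight <= 1)
  if (!all(dim(G) == dim(A22)))
    stop("G and A22 dimensions differ: ", nrow(G), " vs ", nrow(A22))
  Gs <- weight * G + (1 - weight) * A22
  dimnames(Gs) <- dimnames(G)
  Gs
}

#' Assemble a single-step relationship set
#'
#' Orders individuals with the ungenotyped block first and the genotyped
#' block second, builds G from the markers, blends it, and stores the
#' pieces needed by the mixed-model machinery (including \code{Hinv}).
#'
#' @param markers complete \code{\link{marker_matrix}} for the genotyped
#'   individuals.
#' @param individuals character vector of all individual ids (genotyped
#'   and not).  Defaults to the marker genotypes (everyone genotyped).
#' @param A pedigree relationship matrix for all individuals; identity by
#'   default (no pedigree information).
#' @param weight blending weight passed to \code{\link{blend_G}}.
#' @return An object of class \code{relationship_set} with fields
#'   \code{ids}, \code{genotyped} (ids), \code{A}, \code{A22}, \code{G},
#'   \code{Gstar}, \code{Hinv} and \code{H}.
#' @export
relationship_set <- function(markers, individuals = NULL, A = NULL,
                             weight = 0.95) {
  stopifnot(inherits(markers, "marker_matrix"))
  gen <- markers$genotypes
  if (is.null(individuals)) individuals <- gen
  if (!all(gen %in% individuals))
    stop("genotyped ids missing from the individual set: ",
         paste(setdiff(gen, individuals), collapse = ", "))
  ids <- c(setdiff(individuals, gen), gen)     # ungenotyped block first
  n <- length(ids)
  if (is.null(A)) {
    A <- diag(n)
    dimnames(A) <- list(ids, ids)
  } else {
    A <- A[ids, ids, drop = FALSE]
  }
  gidx <- match(gen, ids)
  A22 <- A[gidx, gidx, drop = FALSE]
  G <- build_G(markers)
  Gstar <- blend_G(G, A22, weight)
  Hinv <- build_Hinv(A, Gstar, gidx)
  H <- chol2inv(chol(Hinv))
  dimnames(H) <- dimnames(Hinv)
  structure(list(ids = ids, genotyped = gen, genotyped_idx = gidx,
                 A = A, A22 = A22, G = G, Gstar = Gstar,
                 Hinv = Hinv, H = H, weight = weight),
            class = "relationship_set")
}

#' @export
print.relationship_set <- function(x, ...) {
  cat("Relationship set:", length(x$ids), "individuals (",
      length(x$genotyped), "genotyped )\n")
  cat("  blending weight:", x$weight,
      "| mean diag(G):", format(mean(diag(x$G)), digits = 4), "\n")
  invisible(x)
}

#' Single-step inverse relationship matrix
#'
#' \deqn{H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G^{*-1} -
#' A_{22}^{-1} \end{bmatrix}}
#' The correction is added in the genotyped block only; ungenotyped
#' individuals are covered through the pedigree part.  When every
#' individual is genotyped and A = I this reduces to \code{solve(Gstar)}.
#'
#' @param A pedigree relationship matrix over all individuals (invertible).
#' @param Gstar blended, invertible genomic relationship matrix for the
#'   genotyped individuals.
#' @param genotyped_idx integer indices of the genotyped individuals
#'   within the rows of A.
#' @return Symmetric matrix of the same dimension as A.
#' @export
build_Hinv <- function(A, Gstar, genotyped_idx) {
  n <- nrow(A)
  genotyped_idx <- as.integer(genotyped_idx)
  stopifnot(length(genotyped_idx) == nrow(Gstar),
            all(genotyped_idx >= 1L), all(genotyped_idx <= n))
  Ainv <- tryCatch(chol2inv(chol(A)),
                   error = function(e) stop("A is not invertible: ",
                                            conditionMessage(e)))
  Hinv <- Ainv
  if (length(genotyped_idx)) {
    A22 <- A[genotyped_idx, genotyped_idx, drop = FALSE]
    Gstar_inv <- tryCatch(chol2inv(chol(Gstar)),
                          error = function(e)
                            stop("Gstar is singular; blend G with A22 ",
                                 "(see blend_G) before inverting: ",
                                 conditionMessage(e)))
    A22inv <- chol2inv(chol(A22))
    Hinv[genotyped_idx, genotyped_idx] <-
      Hinv[genotyped_idx, genotyped_idx] + Gstar_inv - A22inv
  }
  Hinv <- (Hinv + t(Hinv)) / 2
  dimnames(Hinv) <- dimnames(A)
  Hinv
}

#' Dump a relationship matrix as dense CSV with id header row/column
#'
#' @param M square matrix with dimnames.
#' @param path output file.
#' @export
write_matrix_csv <- function(M, path) {
  df <- data.frame(id = rownames(M), M, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
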