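#' Pairwise linkage disequilibrium between two binary markers
#'
#' Treats each genotype's presence/absence pair as one two-locus
#' observation and applies the classical squared-correlation measure
#' \deqn{r^2 = \frac{[p(AB) - p(A)p(B)]^2}
#'                  {p(A)p(B)[1 - p(A)][1 - p(B)]}}
#' where \eqn{p(A)}, \eqn{p(B)} are marginal presence frequencies and
#' \eqn{p(AB)} the joint presence frequency.  On 0/1 vectors this equals
#' the squared Pearson correlation.  Monomorphic input yields \code{NA}.
#'
#' @param a,b complete binary vectors of equal length.
#' @return List with \code{pA}, \code{pB}, \code{pAB}, \code{r2}.
#' @export
ld_r2 <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  if (anyNA(a) || anyNA(b)) stop("LD requires complete (imputed) markers")
  pA <- mean(a); pB <- mean(b); pAB <- mean(a * b)
  denom <- pA * pB * (1 - pA) * (1 - pB)
  r2 <- if (denom <= 0) NA_real_ else (pAB - pA * pB)^2 / denom
  list(pA = pA, pB = pB, pAB = pAB, r2 = r2)
}

#' Linkage-disequilibrium profile of one focal marker
#'
#' r-squared of the focal marker against every other marker of a
#' complete (post-QC, post-imputation) matrix, sorted descending with
#' NAs (monomorphic partners) last.
#'
#' @param markers complete \code{\link{marker_matrix}}.
#' @param focal focal marker label (e.g. \code{"M28_161"}).
#' @return Object of class \code{ld_result}: data frame \code{pairs}
#'   with columns markerA, markerB, pA, pB, pAB, r2; plus \code{focal}.
#' @export
ld_profile <- function(markers, focal) {
  stopifnot(inherits(markers, "marker_matrix"))
  if (anyNA(markers$Z)) stop("impute markers before LD profiling")
  j <- match(focal, markers$markers)
  if (is.na(j)) stop("unknown focal marker '", focal, "'")
  a <- markers$Z[, j]
  if (stats::var(a) == 0) stop("focal marker '", focal, "' is monomorphic")
  others <- setdiff(seq_len(ncol(markers$Z)), j)
  rows <- lapply(others, function(k) {
    ld <- ld_r2(a, markers$Z[, k])
    data.frame(markerA = focal, markerB = markers$markers[k],
               pA = ld$pA, pB = ld$pB, pAB = ld$pAB, r2 = ld$r2,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  pairs <- pairs[order(-pairs$r2, pairs$markerB, na.last = TRUE), ]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, focal = focal), class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat("LD profile for", x$focal, "against", nrow(x$pairs), "markers\n")
  print(utils::head(x$pairs, 5))
  invisible(x)
}
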