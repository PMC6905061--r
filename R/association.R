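## Record-level phenotypic covariance V at the fitted components:
## V = s2e I + sum_k s2k Z_k K_k Z_k'
.model_V <- function(design, relationships, sigma2) {
  n <- design$n
  V <- diag(sigma2[["residual"]], n)
  for (tm in design$terms) {
    s2 <- sigma2[[tm$label]]
    if (s2 <= 0) next
    cv <- .term_covariance(tm, relationships)
    Zd <- as.matrix(tm$Z)
    V <- V + s2 * (if (is.null(cv$K)) tcrossprod(Zd)
                   else Zd %*% cv$K %*% t(Zd))
  }
  (V + t(V)) / 2
}

#' Single-marker association scan for one cutting
#'
#' Fits the no-marker null model \eqn{y = Xm + Za + Zg + Wb + \epsilon}
#' once by REML for the cutting, then tests every marker as a single
#' fixed covariate by generalised least squares at the estimated
#' components (the usual two-step mixed-model scan).  The Wald statistic
#' \eqn{(\hat u / se)^2} is referred to a chi-square with one degree of
#' freedom.
#'
#' @param phenotypes records of one cutting (columns Gen, Cut, Rep,
#'   optionally Block, and the trait); only genotyped individuals may
#'   appear.
#' @param markers complete post-QC \code{\link{marker_matrix}} covering
#'   those genotypes.
#' @param relationships \code{\link{relationship_set}} over the
#'   genotyped individuals.
#' @param trait response column name.
#' @param q,alpha FDR rate and screening level for
#'   \code{\link{fdr_threshold}}.
#' @param opts REML options for the null fit.
#' @param sigma2 optional named variance components (term labels plus
#'   \code{"residual"}) to use instead of estimating them — e.g. to
#'   share one null fit across scans, or to study the scan at known
#'   components.
#' @param reestimate re-estimate the variance components for every
#'   marker (slow; for cross-checking the two-step approximation).
#' @return Object of class \code{gwas_result}: per-marker table
#'   (effect, se, wald, p, neglog10p, significant), the threshold on the
#'   \eqn{-\log_{10} p} scale, the null fit, cutting id and trait.
#' @export
gwas_scan <- function(phenotypes, markers, relationships, trait,
                      q = 0.02, alpha = 0.05,
                      opts = reml_opts(method = "ai", tol = 1e-6),
                      sigma2 = NULL, reestimate = FALSE) {
  stopifnot(inherits(markers, "marker_matrix"))
  if (anyNA(markers$Z)) stop("markers must be imputed before scanning")
  cuts <- unique(phenotypes$Cut)
  if (length(cuts) != 1L)
    stop("gwas_scan expects records of a single cutting; got ",
         length(cuts))
  spec <- spec_association(trait,
                           block = "Block" %in% names(phenotypes))
  design <- build_design(phenotypes, spec, relationships)
  ph <- design$records
  not_gt <- setdiff(unique(ph$Gen), markers$genotypes)
  if (length(not_gt))
    stop("ungenotyped individual(s) in the association records: ",
         paste(not_gt, collapse = ", "))
  null_fit <- if (is.null(sigma2)) fit_reml(design, relationships, opts)
              else list(sigma2 = sigma2)
  V <- .model_V(design, relationships, null_fit$sigma2)
  Vi <- chol2inv(chol(V))
  X <- design$X
  XtVi <- crossprod(X, Vi)
  Pmat <- Vi - t(XtVi) %*% solve(XtVi %*% X, XtVi)
  y <- design$y
  Py <- Pmat %*% y

  gi <- match(ph$Gen, markers$genotypes)
  m <- ncol(markers$Z)
  eff <- se <- wald <- pv <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    x <- markers$Z[gi, j]
    if (stats::var(x) < .Machine$double.eps) next    # constant in subset
    if (reestimate) {
      d2 <- design
      d2$X <- cbind(design$X, marker = x)
      f2 <- fit_reml(d2, relationships, opts)
      bidx <- ncol(d2$X)
      V2 <- .model_V(d2, relationships, f2$sigma2)
      Vi2 <- chol2inv(chol(V2))
      XtViX <- crossprod(d2$X, Vi2) %*% d2$X
      covb <- solve(XtViX)
      eff[j] <- f2$beta[bidx]
      se[j] <- sqrt(covb[bidx, bidx])
    } else {
      xPx <- drop(crossprod(x, Pmat %*% x))
      eff[j] <- drop(crossprod(x, Py)) / xPx
      se[j] <- sqrt(1 / xPx)
    }
    wald[j] <- (eff[j] / se[j])^2
    pv[j] <- stats::pchisq(wald[j], df = 1, lower.tail = FALSE)
  }
  thr <- fdr_threshold(pv[!is.na(pv)], q = q, alpha = alpha)
  tab <- data.frame(marker = markers$markers, effect = eff, se = se,
                    wald = wald, p = pv, neglog10p = -log10(pv),
                    stringsAsFactors = FALSE)
  tab$significant <- !is.na(tab$p) & tab$neglog10p >= thr
  structure(list(table = tab, threshold = thr, cutting = cuts,
                 trait = trait, null_fit = null_fit, q = q, alpha = alpha),
            class = "gwas_result")
}

#' @export
print.gwas_result <- function(x, ...) {
  cat("Association scan: trait ", x$trait, ", cutting ", x$cutting, ", ",
      nrow(x$table), " markers\n", sep = "")
  sig <- x$table$marker[x$table$significant]
  cat("  FDR threshold (-log10 p): ", format(x$threshold, digits = 4),
      "; significant: ",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n",
      sep = "")
  invisible(x)
}

#' FDR threshold on the -log10(p) scale
#'
#' Benjamini–Hochberg step-up at rate \code{q}, restricted to the
#' screened set \code{p < alpha}: the threshold is \eqn{-\log_{10}} of
#' the largest order statistic \eqn{p_{(k)}} with
#' \eqn{p_{(k)} \le k q / m} (m = number of tests) that also passes the
#' screen.  When nothing qualifies the threshold is placed above the
#' largest observed \eqn{-\log_{10} p}, so no marker is declared.
#'
#' @param pvalues vector of p-values (NAs ignored).
#' @param q FDR rate (default 0.02).
#' @param alpha screening level (default 0.05).
#' @return Scalar threshold on the \eqn{-\log_{10} p} scale.
#' @export
fdr_threshold <- function(pvalues, q = 0.02, alpha = 0.05) {
  stopifnot(q > 0, q < 1, alpha > 0, alpha < 1)
  pvalues <- pvalues[!is.na(pvalues)]
  if (!length(pvalues)) stop("empty p-value vector")
  m <- length(pvalues)
  ps <- sort(pvalues)
  ok <- which(ps <= seq_len(m) * q / m & ps < alpha)
  if (length(ok)) -log10(ps[max(ok)]) else max(-log10(ps)) + 1
}

#' Plot-ready Manhattan and QQ tables
#'
#' @param result a \code{gwas_result} from \code{\link{gwas_scan}}.
#' @return List with \code{manhattan} (marker index, marker,
#'   \eqn{-\log_{10} p}, threshold) and \code{qq} (expected vs observed
#'   \eqn{-\log_{10} p}, sorted), NAs dropped.
#' @export
qq_manhattan_data <- function(result) {
  stopifnot(inherits(result, "gwas_result"))
  tab <- result$table
  man <- data.frame(index = seq_len(nrow(tab)), marker = tab$marker,
                    neglog10p = tab$neglog10p,
                    threshold = result$threshold,
                    stringsAsFactors = FALSE)
  obs <- sort(tab$neglog10p[!is.na(tab$neglog10p)], decreasing = TRUE)
  nq <- length(obs)
  qq <- data.frame(expected = -log10((seq_len(nq) - 0.5) / nq),
                   observed = obs)
  list(manhattan = man, qq = qq)
}
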