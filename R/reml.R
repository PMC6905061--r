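#' REML fitting options
#'
#' @param method \code{"em"} — expectation-maximisation updates of the
#'   variance components (slow but monotone in the restricted
#'   likelihood), or \code{"ai"} — average-information acceleration
#'   after a short EM warm-up, falling back to an EM step whenever the
#'   AI step leaves the parameter space or decreases the likelihood.
#' @param tol convergence tolerance: maximum relative change of any
#'   variance component between successive iterations.
#' @param max_iter iteration cap; exceeding it raises an error carrying
#'   the iteration trajectory.
#' @param init optional named vector of starting values (term labels
#'   plus \code{"residual"}).
#' @param ll_tol secondary stopping rule: when the relative change of
#'   the restricted log-likelihood stays below this for three
#'   consecutive iterations the fit is declared converged even if some
#'   components still drift (this happens on flat likelihood ridges,
#'   e.g. when two random terms are aliased).
#' @param warmup EM iterations before the first AI step.
#' @param pin_after a component held at the zero boundary for this many
#'   consecutive iterations is fixed there and reported as pinned.
#' @return List of options for \code{\link{fit_reml}}.
#' @export
reml_opts <- function(method = c("em", "ai"), tol = 1e-8, max_iter = 500L,
                      init = NULL, ll_tol = 1e-10, warmup = 3L,
                      pin_after = 5L) {
  list(method = match.arg(method), tol = tol, max_iter = as.integer(max_iter),
       init = init, ll_tol = ll_tol, warmup = as.integer(warmup),
       pin_after = as.integer(pin_after))
}

## Evaluate the mixed-model equations at one set of components.
## Returns solutions, the inverse coefficient matrix, the restricted
## log-likelihood and the per-term traces needed by EM and AI updates.
.mme_eval <- function(pre, sigma2, s2e) {
  p <- pre$p; qtot <- pre$qtot; n <- pre$n
  M <- pre$M0                      # [X'X X'W; W'X W'W], dense copy
  for (k in seq_along(pre$terms)) {
    idx <- pre$terms[[k]]$idx + p
    lam <- s2e / sigma2[k]
    if (is.null(pre$terms[[k]]$Kinv)) {
      dg <- cbind(idx, idx)
      M[dg] <- M[dg] + lam
    } else {
      M[idx, idx] <- M[idx, idx] + lam * pre$terms[[k]]$Kinv
    }
  }
  ch <- tryCatch(chol(M), error = function(e)
    stop("singular mixed-model coefficient matrix: ", conditionMessage(e)))
  sol <- backsolve(ch, forwardsolve(t(ch), pre$rhs))
  Minv <- chol2inv(ch)
  yPy <- (pre$yty - sum(sol * pre$rhs)) / s2e
  logdetM <- 2 * sum(log(diag(ch)))
  ll <- -0.5 * ((n - p) * log(2 * pi) + (n - p - qtot) * log(s2e) +
                sum(vapply(seq_along(pre$terms), function(k)
                  pre$terms[[k]]$q * log(sigma2[k]) +
                  pre$terms[[k]]$logdetK, numeric(1))) +
                logdetM + yPy)
  trKC <- uKu <- numeric(length(pre$terms))
  for (k in seq_along(pre$terms)) {
    idx <- pre$terms[[k]]$idx + p
    uk <- sol[idx]
    Minv_kk <- Minv[idx, idx, drop = FALSE]
    if (is.null(pre$terms[[k]]$Kinv)) {
      trKC[k] <- sum(diag(Minv_kk))
      uKu[k] <- sum(uk * uk)
    } else {
      trKC[k] <- sum(pre$terms[[k]]$Kinv * Minv_kk)
      uKu[k] <- drop(crossprod(uk, pre$terms[[k]]$Kinv %*% uk))
    }
  }
  list(sol = sol, Minv = Minv, ch = ch, yPy = yPy, logLik = ll,
       trKC = trKC, uKu = uKu)
}

## P f  =  (f - X b_f - W u_f) / s2e  via the factored MME
.apply_P <- function(pre, ch, f, s2e) {
  rhs <- c(crossprod(pre$X, f), as.numeric(Matrix::crossprod(pre$W, f)))
  sol <- backsolve(ch, forwardsolve(t(ch), rhs))
  fit <- pre$X %*% sol[seq_len(pre$p)] +
    as.numeric(pre$W %*% sol[-seq_len(pre$p)])
  (f - as.numeric(fit)) / s2e
}

#' Fit a linear mixed model by REML
#'
#' Estimates all variance components of an \code{\link{mm_spec}} design
#' by restricted maximum likelihood, then solves Henderson's mixed-model
#' equations at the estimates for BLUEs (fixed effects) and BLUPs
#' (random effects) with prediction error variances (PEV) taken from the
#' diagonal of the inverse coefficient matrix.
#'
#' @param design an \code{mm_design} from \code{\link{build_design}}.
#' @param relationships the \code{\link{relationship_set}} resolving any
#'   genomic covariance structures (may be \code{NULL} when every term is
#'   identity-structured).
#' @param opts options from \code{\link{reml_opts}}.
#' @return Object of class \code{blup_fit}: \code{sigma2} (named
#'   components including \code{residual}), \code{beta}, \code{u} and
#'   \code{pev} lists per term, restricted \code{logLik},
#'   \code{trajectory} (per-iteration components and log-likelihood),
#'   \code{converged}, \code{iterations}, \code{pinned}.
#' @export
fit_reml <- function(design, relationships = NULL, opts = reml_opts()) {
  stopifnot(inherits(design, "mm_design"))
  y <- design$y; X <- design$X; n <- design$n; p <- ncol(X)
  terms <- design$terms
  if (!length(terms)) stop("model has no random terms")
  nt <- length(terms)

  ## precompute fixed pieces
  W <- do.call(cbind, lapply(terms, `[[`, "Z"))
  qtot <- ncol(W)
  off <- 0L
  tinfo <- vector("list", nt)
  for (k in seq_len(nt)) {
    cv <- .term_covariance(terms[[k]], relationships)
    tinfo[[k]] <- list(label = terms[[k]]$label, q = terms[[k]]$q,
                       idx = off + seq_len(terms[[k]]$q),
                       Kinv = cv$Kinv, K = cv$K, logdetK = cv$logdetK,
                       Z = terms[[k]]$Z, levels = terms[[k]]$levels)
    off <- off + terms[[k]]$q
  }
  WtW <- as.matrix(Matrix::crossprod(W))
  XtW <- as.matrix(Matrix::crossprod(X, W))
  M0 <- rbind(cbind(crossprod(X), XtW), cbind(t(XtW), WtW))
  pre <- list(X = X, W = W, M0 = M0,
              rhs = c(crossprod(X, y), as.numeric(Matrix::crossprod(W, y))),
              yty = sum(y * y), n = n, p = p, qtot = qtot, terms = tinfo)

  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  floor_val <- 1e-8 * vy
  sigma2 <- rep(vy / (nt + 1), nt)
  s2e <- vy / (nt + 1)
  labs <- vapply(tinfo, `[[`, character(1), "label")
  if (!is.null(opts$init)) {
    ini <- opts$init
    for (k in seq_len(nt)) if (labs[k] %in% names(ini)) sigma2[k] <- ini[[labs[k]]]
    if ("residual" %in% names(ini)) s2e <- ini[["residual"]]
  }

  pin_count <- integer(nt)
  pinned <- logical(nt)
  traj <- matrix(NA_real_, opts$max_iter, nt + 2L,
                 dimnames = list(NULL, c(labs, "residual", "logLik")))
  converged <- FALSE
  st <- NULL
  iter <- 0L
  ll_prev <- -Inf
  ll_still_count <- 0L
  while (iter < opts$max_iter) {
    iter <- iter + 1L
    st <- .mme_eval(pre, sigma2, s2e)
    traj[iter, ] <- c(sigma2, s2e, st$logLik)

    ## EM candidate (monotone)
    em_sig <- vapply(seq_len(nt), function(k)
      (st$uKu[k] + s2e * st$trKC[k]) / tinfo[[k]]$q, numeric(1))
    em_e <- (pre$yty - sum(st$sol * pre$rhs)) / (n - p)
    new_sig <- em_sig; new_e <- em_e

    use_ai <- opts$method == "ai" && iter > opts$warmup
    if (use_ai) {
      free <- which(!pinned)               # pinned terms stay at the floor
      Py <- .apply_P(pre, st$ch, y, s2e)   # equals R^-1 * residuals
      fs <- vector("list", length(free) + 1L)
      for (a in seq_along(free)) {
        k <- free[a]
        tk <- as.numeric(Matrix::crossprod(tinfo[[k]]$Z, Py))
        if (!is.null(tinfo[[k]]$K)) tk <- as.numeric(tinfo[[k]]$K %*% tk)
        fs[[a]] <- as.numeric(tinfo[[k]]$Z %*% tk)
      }
      nf <- length(free) + 1L
      fs[[nf]] <- Py
      Pf <- lapply(fs, function(f) .apply_P(pre, st$ch, f, s2e))
      AI <- matrix(0, nf, nf)
      for (a in seq_len(nf)) for (b in a:nf)
        AI[a, b] <- AI[b, a] <- 0.5 * sum(fs[[a]] * Pf[[b]])
      trfree <- vapply(seq_len(nt), function(k)
        tinfo[[k]]$q - (s2e / sigma2[k]) * st$trKC[k], numeric(1))
      trPV <- trfree[free] / sigma2[free]
      trP <- (n - p - sum(trfree)) / s2e
      score <- c(-0.5 * (trPV - vapply(seq_along(free), function(a)
                   sum(Py * fs[[a]]), numeric(1))),
                 -0.5 * (trP - sum(Py * Py)))
      step <- tryCatch(solve(AI, score), error = function(e) NULL)
      if (!is.null(step)) {
        ## full step, clamped at the boundary; halve on likelihood
        ## decrease, fall back to EM when no fraction helps
        frac <- 1
        for (half in 1:5) {
          cand_sig <- sigma2
          cand_sig[free] <- pmax(sigma2[free] +
                                   frac * step[seq_along(free)], floor_val)
          cand_e <- max(s2e + frac * step[nf], floor_val)
          st_c <- tryCatch(.mme_eval(pre, cand_sig, cand_e),
                           error = function(e) NULL)
          if (!is.null(st_c) && st_c$logLik >= st$logLik - 1e-10) {
            new_sig <- cand_sig; new_e <- cand_e
            break
          }
          frac <- frac / 2
        }
      }
    }

    ## zero-boundary projection and pinning
    at_floor <- new_sig < floor_val
    new_sig[at_floor] <- floor_val
    pin_count <- ifelse(at_floor, pin_count + 1L, 0L)
    pinned <- pinned | pin_count >= opts$pin_after
    new_sig[pinned] <- floor_val
    if (new_e < floor_val) new_e <- floor_val

    free <- c(!pinned, TRUE)
    delta <- max(abs(c(new_sig, new_e)[free] - c(sigma2, s2e)[free]) /
                 pmax(c(sigma2, s2e)[free], 1e-4 * vy))
    sigma2 <- new_sig; s2e <- new_e
    ll_still <- abs(st$logLik - ll_prev) <
      opts$ll_tol * (1 + abs(st$logLik))
    ll_still_count <- if (ll_still) ll_still_count + 1L else 0L
    ll_prev <- st$logLik
    if (delta < opts$tol ||
        (iter > opts$warmup && ll_still_count >= 3L)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    cond <- simpleError(paste0("REML did not converge in ", opts$max_iter,
                               " iterations (last max relative change above ",
                               "tolerance ", opts$tol, ")"))
    cond$trajectory <- traj[seq_len(iter), , drop = FALSE]
    stop(cond)
  }
  st <- .mme_eval(pre, sigma2, s2e)

  beta <- st$sol[seq_len(p)]
  names(beta) <- colnames(X)
  u <- pev <- list()
  for (k in seq_len(nt)) {
    idx <- tinfo[[k]]$idx + p
    uk <- st$sol[idx]
    names(uk) <- tinfo[[k]]$levels
    u[[labs[k]]] <- uk
    pv <- s2e * diag(st$Minv[idx, idx, drop = FALSE])
    names(pv) <- tinfo[[k]]$levels
    pev[[labs[k]]] <- pv
  }
  sig <- c(sigma2, s2e)
  sig[c(pinned, FALSE)] <- 0           # pinned components reported as zero
  names(sig) <- c(labs, "residual")
  structure(list(sigma2 = sig, beta = beta, u = u, pev = pev,
                 logLik = st$logLik, n = n, p_fixed = p,
                 trajectory = as.data.frame(traj[seq_len(iter), ,
                                                 drop = FALSE]),
                 converged = converged, iterations = iter,
                 pinned = stats::setNames(pinned, labs),
                 trait = design$trait, method = opts$method),
            class = "blup_fit")
}

#' @export
print.blup_fit <- function(x, ...) {
  cat("REML fit (", x$method, ") for trait ", x$trait, ": logL = ",
      format(x$logLik, digits = 8), ", ", x$iterations, " iterations\n",
      sep = "")
  print(round(x$sigma2, 6))
  invisible(x)
}

#' Likelihood-ratio test for one random term
#'
#' \code{2 * (logL_full - logL_reduced)} referred to a chi-square with
#' one degree of freedom; the statistic is clamped at zero when the
#' reduced fit's likelihood exceeds the full fit's within numerical
#' noise.  Significance is declared when the statistic exceeds the 5\%
#' critical value (3.84).
#'
#' @param full,reduced \code{blup_fit}s whose specifications differ by
#'   exactly one random term (same records).
#' @param alpha significance level.
#' @return Object of class \code{lrt_result}: term, statistic, df,
#'   p.value, significant.
#' @export
lrt <- function(full, reduced, alpha = 0.05) {
  tf <- names(full$u); tr <- names(reduced$u)
  extra <- setdiff(tf, tr)
  if (length(extra) != 1L || length(setdiff(tr, tf)) != 0L ||
      full$n != reduced$n)
    stop("reduced model must equal the full model minus exactly one ",
         "random term, on the same records")
  stat <- max(0, 2 * (full$logLik - reduced$logLik))
  pv <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  crit <- stats::qchisq(1 - alpha, df = 1)
  structure(list(term = extra, statistic = stat, df = 1L, p.value = pv,
                 critical = crit, significant = stat > crit),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat("LRT for term '", x$term, "': LR = ", format(x$statistic, digits = 5),
      ", p = ", format(x$p.value, digits = 4),
      if (x$significant) " (significant at 5%)" else "", "\n", sep = "")
  invisible(x)
}

#' PEV-based accuracy of a random term
#'
#' Per-level accuracy \eqn{r = \sqrt{1 - PEV / \hat\sigma^2}}, clamped
#' to [0, 1], and its mean (or median) over levels.
#'
#' @param fit a \code{blup_fit}.
#' @param term random-term label (e.g. \code{"a"} or \code{"g"}).
#' @param summary \code{"mean"} (default) or \code{"median"}.
#' @return List with \code{per_level} (named vector) and \code{summary}.
#' @export
accuracy <- function(fit, term, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  if (!term %in% names(fit$u)) stop("unknown term '", term, "'")
  s2 <- fit$sigma2[[term]]
  if (s2 <= 0) {
    warning("variance of term '", term, "' is zero; accuracy undefined")
    r <- rep(NA_real_, length(fit$pev[[term]]))
    names(r) <- names(fit$pev[[term]])
    return(list(per_level = r, summary = NA_real_))
  }
  r <- sqrt(pmax(0, pmin(1, 1 - fit$pev[[term]] / s2)))
  list(per_level = r,
       summary = if (summary == "mean") mean(r) else stats::median(r))
}

#' Extract BLUPs of one random term as a table
#'
#' @param fit a \code{blup_fit}.
#' @param term random-term label.
#' @return Data frame with columns level, estimate, pev, accuracy, in
#'   the term's deterministic level order.
#' @export
extract_blups <- function(fit, term) {
  if (!term %in% names(fit$u)) stop("unknown term '", term, "'")
  s2 <- fit$sigma2[[term]]
  acc <- if (s2 > 0) sqrt(pmax(0, pmin(1, 1 - fit$pev[[term]] / s2)))
         else rep(NA_real_, length(fit$u[[term]]))
  data.frame(level = names(fit$u[[term]]),
             estimate = unname(fit$u[[term]]),
             pev = unname(fit$pev[[term]]),
             accuracy = unname(acc),
             stringsAsFactors = FALSE)
}
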