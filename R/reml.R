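#' REML variance components for a multi-kernel mixed model
#'
#' Fits y = 1 mu + sum_k u_k + e with Var(u_k) = sigma2_k K_k and
#' Var(e) = sigma2_e I by restricted maximum likelihood, using
#' average-information updates with step-halving and EM fallback so the
#' restricted log-likelihood is non-decreasing across iterations. Components
#' are constrained non-negative (projected to the boundary).
#'
#' @param y numeric response vector.
#' @param kernels named list of n x n positive semi-definite covariance
#'   kernels (Z G Z' for each random term).
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter maximum iterations.
#' @return Object of class `gblup_reml`: `sigma2` (named vector including
#'   `"error"`), `loglik` (trace, one entry per accepted iteration),
#'   `converged`, `boundary`, `iterations`, plus `y` and the fitted `V` and
#'   its Cholesky factor for prediction.
#' @export
fit_gblup <- function(y, kernels, tol = 1e-8, max_iter = 200) {
  n <- length(y)
  stopifnot(n >= 2, is.list(kernels), length(kernels) >= 1,
            all(vapply(kernels, function(k) all(dim(k) == n), logical(1))))
  if (is.null(names(kernels)) || any(names(kernels) == ""))
    names(kernels) <- paste0("k", seq_along(kernels))
  klist <- c(kernels, list(error = diag(n)))
  nk <- length(klist)
  vy <- var(y)
  if (vy < 1e-14) {  # degenerate: constant response, all components at zero
    fit <- make_fit(y, klist, sigma2 = setNames(c(rep(0, nk - 1), 1e-8),
                                                names(klist)),
                    loglik = NA_real_, converged = TRUE, boundary = TRUE,
                    iterations = 0L)
    return(fit)
  }
  theta <- setNames(rep(vy / nk, nk), names(klist))
  floor_e <- 1e-8 * vy
  st <- reml_state(y, klist, theta)
  ll_trace <- st$ll
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    upd <- reml_direction(st, klist, theta)
    step <- upd$ai_step
    accepted <- FALSE
    for (h in 0:20) {  # AI step with halving
      cand <- theta + step / 2^h
      cand <- pmax(cand, 0)
      cand["error"] <- max(cand["error"], floor_e)
      st_new <- try(reml_state(y, klist, cand, full = FALSE), silent = TRUE)
      if (!inherits(st_new, "try-error") && st_new$ll >= st$ll - 1e-10) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) {  # EM fallback (monotone)
      cand <- pmax(theta + upd$em_step, 0)
      cand["error"] <- max(cand["error"], floor_e)
      st_new <- try(reml_state(y, klist, cand, full = FALSE), silent = TRUE)
      if (inherits(st_new, "try-error") || st_new$ll < st$ll - 1e-6) break
    }
    delta <- st_new$ll - st$ll
    theta <- cand
    st <- reml_state(y, klist, cand)  # full state for the next score
    ll_trace <- c(ll_trace, st$ll)
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  make_fit(y, klist, sigma2 = theta, loglik = ll_trace,
           converged = converged, boundary = any(theta[-nk] <= 0),
           iterations = it)
}

# V, its Cholesky factor, P-related quantities and the restricted
# log-likelihood at a parameter value; `full = FALSE` (line-search trials)
# computes the log-likelihood from triangular solves only, skipping the
# O(n^3) explicit inverse needed for the score
reml_state <- function(y, klist, theta, full = TRUE) {
  n <- length(y)
  v <- matrix(0, n, n)
  for (k in seq_along(klist)) v <- v + theta[k] * klist[[k]]
  ch <- chol(v)
  if (!full) {
    solve_v <- function(b) backsolve(ch, backsolve(ch, b, transpose = TRUE))
    viy <- solve_v(y)
    vix <- solve_v(rep(1, n))
    xtvix <- sum(vix)
    py <- viy - vix * (sum(vix * y) / xtvix)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + log(xtvix) + sum(y * py))
    return(list(v = v, chol = ch, p = NULL, py = py, ll = ll))
  }
  vi <- chol2inv(ch)
  x <- rep(1, n)
  vix <- vi %*% x
  xtvix <- sum(x * vix)
  p <- vi - tcrossprod(vix) / xtvix
  py <- drop(p %*% y)
  ll <- -0.5 * (2 * sum(log(diag(ch))) + log(xtvix) + sum(y * py))
  list(v = v, chol = ch, p = p, py = py, ll = ll)
}

# AI and EM proposal directions at the current state
reml_direction <- function(st, klist, theta) {
  nk <- length(klist)
  n <- length(st$py)
  score <- numeric(nk)
  tvec <- vector("list", nk)
  for (k in seq_len(nk)) {
    kpy <- drop(klist[[k]] %*% st$py)
    tvec[[k]] <- kpy
    score[k] <- -0.5 * (sum(st$p * klist[[k]]) - sum(st$py * kpy))
  }
  ai <- matrix(0, nk, nk)
  pt <- lapply(tvec, function(t) drop(st$p %*% t))
  for (k in seq_len(nk))
    for (l in k:nk)
      ai[k, l] <- ai[l, k] <- 0.5 * sum(tvec[[k]] * pt[[l]])
  ai_step <- tryCatch(solve(ai + diag(1e-10, nk), score),
                      error = function(e) score * 0)
  # EM-REML expressed as an additive step: sigma^4/n * (y'PKPy - tr(PK))
  em_step <- theta^2 * (2 * score) / n
  list(ai_step = ai_step, em_step = em_step)
}

make_fit <- function(y, klist, sigma2, loglik, converged, boundary,
                     iterations) {
  st <- tryCatch(reml_state(y, klist, sigma2), error = function(e) NULL)
  structure(list(sigma2 = sigma2, loglik = loglik, converged = converged,
                 boundary = boundary, iterations = iterations, y = y,
                 n = length(y),
                 v = if (is.null(st)) NULL else st$v,
                 chol = if (is.null(st)) NULL else st$chol),
            class = "gblup_reml")
}

#' @export
print.gblup_reml <- function(x, ...) {
  cat("REML variance components (n =", x$n, "):\n")
  print(round(x$sigma2, 6))
  cat(sprintf("converged: %s after %d iterations%s\n", x$converged,
              x$iterations, if (x$boundary) " (boundary solution)" else ""))
  invisible(x)
}

# V^{-1} (y - mu-hat) with mu-hat the GLS mean, reused by all predictors;
# identical to the u-component of the mixed-model-equation solution
viy_centred <- function(fit) {
  solve_v <- function(b) backsolve(fit$chol,
                                   backsolve(fit$chol, b, transpose = TRUE))
  vix <- solve_v(rep(1, fit$n))
  mu <- sum(vix * fit$y) / sum(vix)
  solve_v(fit$y - mu)
}

#' REML for the testcross (half-sib) model
#'
#' Model y_TC = 1 mu + u + e with u ~ N(0, sigma2_TC G_TS) over the training
#' candidates of one parent population.
#'
#' @param y testcross phenotypes of the training candidates.
#' @param g_ts genomic relationship matrix among the training candidates.
#' @param min_n guard on the training-set size per population.
#' @param ... passed to [fit_gblup].
#' @return A `gblup_reml` fit with components `tc` and `error`.
#' @export
reml_tc <- function(y, g_ts, min_n = 30, ...) {
  if (length(y) < min_n)
    stop("testcross training set too small: ", length(y), " < ", min_n)
  stopifnot(all(dim(g_ts) == length(y)))
  fit_gblup(y, list(tc = g_ts), ...)
}

#' GBLUP of testcross performance for all candidates
#'
#' u_hat = sigma2_TC * G_cand,TS * V^{-1} (y - ybar); one value per
#' candidate, including training-set parents themselves.
#'
#' @param fit a `gblup_reml` from [reml_tc].
#' @param g_cand_ts relationship block between candidates (rows) and training
#'   candidates (columns).
#' @export
predict_tc <- function(fit, g_cand_ts) {
  stopifnot(inherits(fit, "gblup_reml"), ncol(g_cand_ts) == fit$n)
  drop(pred_scale(fit, "tc") * g_cand_ts %*% viy_centred(fit))
}

# Multiplier of G V^{-1}(y - mu) for a component. At a boundary estimate of
# zero the BLUP vector is identically zero, which would make downstream
# selection arbitrary; the ranking of the GBLUPs as sigma2 -> 0+ is still
# well defined (proportional to G V^{-1}(y - mu)), so a vanishingly small
# positive multiplier is used to retain it.
pred_scale <- function(fit, comp) {
  s2 <- fit$sigma2[[comp]]
  if (s2 > 0) s2 else 1e-8 * max(var(fit$y), 1e-12)
}

#' REML for the single-cross (full-sib factorial) model
#'
#' Model y_SC = 1 mu + g_F + g_M [+ s] + e for paired inter-population
#' hybrids whose parents each appear exactly once, so the design matrices are
#' identities and the GCA kernels are the parent relationship matrices; the
#' SCA kernel is the training-set block of the Kronecker structure,
#' G_F * G_M elementwise. SCA is off by default (GBLUPs for GCA are
#' computed disregarding SCA), but can be switched on.
#'
#' @param y single-cross phenotypes (one hybrid per record).
#' @param g_f,g_m relationship matrices among the female and male parents of
#'   the hybrids, in record order.
#' @param include_sca fit the SCA component.
#' @param min_n guard on the training-set size.
#' @param ... passed to [fit_gblup].
#' @return A `gblup_reml` fit with components `gca_f`, `gca_m`
#'   (optionally `sca`) and `error`.
#' @export
reml_sc <- function(y, g_f, g_m, include_sca = FALSE, min_n = 60, ...) {
  if (length(y) < min_n)
    stop("single-cross training set too small: ", length(y), " < ", min_n)
  stopifnot(all(dim(g_f) == length(y)), all(dim(g_m) == length(y)))
  kernels <- list(gca_f = g_f, gca_m = g_m)
  if (include_sca) kernels$sca <- g_f * g_m
  fit_gblup(y, kernels, ...)
}

#' GBLUP of GCA for all candidates of one population
#'
#' g_hat = sigma2_gca * G_cand,TSparents * V^{-1} (y - ybar), with V
#' assembled from the fitted components (including the SCA block only if it
#' was fitted).
#'
#' @param fit a `gblup_reml` from [reml_sc].
#' @param g_cand_parents relationship block between the candidates of one
#'   population (rows) and the training-set parents of that population
#'   (columns, record order).
#' @param which `"gca_f"` or `"gca_m"`.
#' @export
predict_gca <- function(fit, g_cand_parents, which = c("gca_f", "gca_m")) {
  which <- match.arg(which)
  stopifnot(inherits(fit, "gblup_reml"), ncol(g_cand_parents) == fit$n)
  drop(pred_scale(fit, which) * g_cand_parents %*% viy_centred(fit))
}
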