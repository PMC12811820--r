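# Epsilon support vector regression with a radial basis function kernel,
# solved as the dual quadratic program with quadprog. Dimensions here are
# tiny (tens of samples), so a dense QP is the appropriate solver. Inputs
# and response are standardised internally, mirroring the conventions of
# the classic libsvm-based R interface.

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Fit an epsilon-SVR with RBF kernel
#'
#' Solves the dual QP
#' \deqn{\min_{\alpha,\alpha^*} \tfrac12 (\alpha-\alpha^*)^T K (\alpha-\alpha^*)
#'   - y^T(\alpha-\alpha^*) + \epsilon \mathbf{1}^T(\alpha+\alpha^*)}
#' subject to \eqn{\sum(\alpha-\alpha^*) = 0} and box constraints at `cost`.
#' There is no sample-weighting mechanism.
#'
#' @param X numeric matrix, samples x sites (standardised internally).
#' @param y numeric response (standardised internally).
#' @param cost box constraint C.
#' @param gamma RBF kernel width.
#' @param epsilon insensitivity tube half-width on the standardised response
#'   (default 0.1).
#' @return an `svr_model`.
#' @export
svr_fit <- function(X, y, cost = 1, gamma = NULL, epsilon = 0.1) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n == length(y), n >= 2, cost > 0)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  xc <- colMeans(X)
  xs <- apply(X, 2, sd); xs[xs == 0] <- 1
  Xs <- sweep(sweep(X, 2, xc), 2, xs, "/")
  yc <- mean(y); ys <- sd(y); if (ys == 0) ys <- 1
  ysc <- (y - yc) / ys

  K <- rbf_kernel(Xs, Xs, gamma)
  Dmat <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-8, 2 * n)
  dvec <- c(ysc - epsilon, -ysc - epsilon)
  # equality sum(alpha - alpha*) = 0, then 0 <= x <= C
  Amat <- cbind(c(rep(1, n), rep(-1, n)), diag(2 * n), -diag(2 * n))
  bvec <- c(0, rep(0, 2 * n), rep(-cost, 2 * n))
  sol <- quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = 1)
  a <- sol$solution[1:n]; as <- sol$solution[(n + 1):(2 * n)]
  beta <- a - as
  f0 <- as.vector(K %*% beta)
  # intercept from KKT conditions at free support vectors
  tol <- 1e-6 * cost
  free_lo <- which(a > tol & a < cost - tol)    # y - eps - f0
  free_hi <- which(as > tol & as < cost - tol)  # y + eps - f0
  bs <- c(ysc[free_lo] - epsilon - f0[free_lo],
          ysc[free_hi] + epsilon - f0[free_hi])
  b <- if (length(bs)) mean(bs) else {
    up <- c(ysc[a < cost - tol] - epsilon - f0[a < cost - tol],
            ysc[as > tol] + epsilon - f0[as > tol])
    lo <- c(ysc[a > tol] - epsilon - f0[a > tol],
            ysc[as < cost - tol] + epsilon - f0[as < cost - tol])
    (max(lo, -Inf) + min(up, Inf)) / 2
  }
  structure(list(beta = beta, b = b, Xs = Xs, xc = xc, xs = xs,
                 yc = yc, ys = ys, gamma = gamma, cost = cost,
                 epsilon = epsilon), class = "svr_model")
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Zs <- sweep(sweep(newdata, 2, object$xc), 2, object$xs, "/")
  K <- rbf_kernel(Zs, object$Xs, object$gamma)
  as.vector(K %*% object$beta + object$b) * object$ys + object$yc
}

#' Tune SVR cost and gamma by cross-validated grid search
#'
#' The published-scale grid steps every 0.1 in log10 over cost 1e-4..1e5 and
#' gamma 1e-5..1e4; `step` coarsens this for desk-scale runs. Ten-fold
#' cross-validated MSE picks the optimum.
#'
#' @inheritParams svr_fit
#' @param cost_range,gamma_range log10 bounds of the two grids.
#' @param step log10 grid spacing (published value 0.1; desk-scale runs use 1).
#' @param nfolds cross-validation folds.
#' @param seed RNG seed for the fold assignment.
#' @return list with `cost`, `gamma`, and the CV-MSE grid.
#' @export
svr_tune <- function(X, y, cost_range = c(-4, 5), gamma_range = c(-5, 4),
                     step = 0.1, nfolds = 10, epsilon = 0.1, seed = 1L) {
  n <- nrow(X)
  nfolds <- min(nfolds, n)
  if (nfolds < 2) stop("need at least 2 folds / samples for SVR tuning")
  costs <- 10^seq(cost_range[1], cost_range[2], by = step)
  gammas <- 10^seq(gamma_range[1], gamma_range[2], by = step)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- sample(rep_len(seq_len(nfolds), n))
  cv <- matrix(NA_real_, length(costs), length(gammas))
  for (i in seq_along(costs)) for (j in seq_along(gammas)) {
    err <- 0
    ok <- TRUE
    for (f in seq_len(nfolds)) {
      tr <- fold != f
      fit <- tryCatch(
        svr_fit(X[tr, , drop = FALSE], y[tr], cost = costs[i],
                gamma = gammas[j], epsilon = epsilon),
        error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      p <- predict(fit, X[!tr, , drop = FALSE])
      err <- err + sum((p - y[!tr])^2)
    }
    cv[i, j] <- if (ok) err / n else Inf
  }
  k <- which(cv == min(cv), arr.ind = TRUE)[1, ]
  list(cost = costs[k[1]], gamma = gammas[k[2]], cv_mse = cv,
       costs = costs, gammas = gammas)
}

# save/restore the global RNG state so tuners can use an explicit seed
# without disturbing the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
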