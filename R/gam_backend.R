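# Generalised additive model backend (mgcv): one penalised thin plate
# regression spline per CpG site, basis dimension k starting at 3 and
# escalated until the fitter converges.

#' Fit a GAM age model
#'
#' Builds `y ~ s(site1, bs = "tp", k = k) + ...` with mgcv. If the fit does
#' not converge (or errors), `k` is incremented by one and the fit retried,
#' up to `k_max`. Observation weights are supported.
#'
#' @param X numeric matrix, samples x sites. The number of coefficients
#'   grows with both sites and `k`; with more coefficients than samples the
#'   fit fails, so GAMs are practical only after site selection.
#' @param y numeric response.
#' @param weights optional observation weights.
#' @param k initial basis dimension per site (default 3).
#' @param k_max escalation cap.
#' @return a `gam_model`.
#' @export
gam_fit <- function(X, y, weights = NULL, k = 3, k_max = 10) {
  X <- as.matrix(X)
  df <- as.data.frame(X)
  vars <- make.names(colnames(X), unique = TRUE)
  colnames(df) <- vars
  df$.y <- y
  last_err <- NULL
  for (kk in k:k_max) {
    fml <- stats::as.formula(paste(
      ".y ~", paste(sprintf('s(%s, bs = "tp", k = %d)', vars, kk),
                    collapse = " + ")))
    fit <- tryCatch({
      f <- mgcv::gam(fml, data = df, weights = weights, method = "GCV.Cp")
      if (!f$converged) stop("mgcv did not converge at k = ", kk)
      f
    }, error = function(e) { last_err <<- e; NULL })
    if (!is.null(fit))
      return(structure(list(fit = fit, k = kk, vars = vars,
                            orig_names = colnames(X)),
                       class = "gam_model"))
  }
  stop("GAM failed to converge for k in ", k, "..", k_max, ": ",
       conditionMessage(last_err))
}

#' @export
predict.gam_model <- function(object, newdata, ...) {
  nd <- as.data.frame(as.matrix(newdata))
  colnames(nd) <- object$vars[match(colnames(newdata), object$orig_names)]
  as.vector(predict(object$fit, newdata = nd))
}
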