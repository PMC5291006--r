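#' Hyperbola model for lacunarity curves
#'
#' `L(b) = beta * b^(-alpha) + gamma`: the three-parameter decaying family
#' matching the asymptotic power-law lacunarity of self-similar fractals.
#' `alpha` relates to the fractal dimension of the set, `beta` scales the
#' lacunarity amplitude (the biomarker), `gamma` is the large-b asymptote.
#'
#' @param b box size(s), >= 1
#' @param alpha,beta,gamma model parameters
#' @return model value(s), same length as `b`
#' @export
hyperbolaModel <- function(b, alpha, beta, gamma) {
  beta * b^(-alpha) + gamma
}

#' Fit the hyperbola model to a lacunarity curve by least squares
#'
#' Minimizes the sum of squared residuals over `(alpha, beta, gamma)` with
#' Levenberg-Marquardt, bounds `alpha, gamma >= 0`, `beta` free. The start
#' is deterministic so repeated fits are bit-identical: `gamma0 = min(lambda)`,
#' then `(log(beta0), -alpha0)` from an ordinary linear regression of
#' `log(lambda - gamma0 + 1e-9)` on `log(b)`.
#'
#' @param curve a [LacunarityCurve-class], or a data.frame with columns
#'   `b` and `lambda`; at least 4 points
#' @param maxIterations optimizer iteration cap (default 500)
#' @param ftol relative residual-change convergence tolerance (default 1e-10)
#' @return a [HyperbolaFit-class]; `converged(fit)` is FALSE when the
#'   optimizer stopped on the iteration cap
#' @examples
#' b <- 3:16
#' lam <- hyperbolaModel(b, 0.4, 2, 1)
#' coef(fitHyperbola(data.frame(b = b, lambda = lam)))
#' @export
fitHyperbola <- function(curve, maxIterations = 500L, ftol = 1e-10) {
  if (is(curve, "LacunarityCurve")) {
    b <- as.numeric(boxSizes(curve))
    lam <- lambdaValues(curve)
  } else {
    b <- as.numeric(curve$b)
    lam <- as.numeric(curve$lambda)
  }
  if (length(b) < 4L)
    stop("need at least 4 curve points to fit 3 parameters", call. = FALSE)
  if (!all(is.finite(lam)) || !all(is.finite(b)))
    stop("curve contains non-finite values", call. = FALSE)

  g0 <- min(lam)
  y <- log(pmax(lam - g0, 0) + 1e-9)
  lin <- stats::lm.fit(cbind(1, log(b)), y)
  a0 <- max(0, -unname(lin$coefficients[2]))
  b0 <- exp(unname(lin$coefficients[1]))
  start <- c(alpha = a0, beta = b0, gamma = g0)

  residFun <- function(p) p[2] * b^(-p[1]) + p[3] - lam
  fit <- minpack.lm::nls.lm(
    par = start, fn = residFun,
    lower = c(0, -Inf, 0), upper = c(Inf, Inf, Inf),
    control = minpack.lm::nls.lm.control(
      ftol = ftol, ptol = 1e-12, maxiter = as.integer(maxIterations)))
  p <- fit$par
  new("HyperbolaFit",
      alpha = unname(p[1]), beta = unname(p[2]), gamma = unname(p[3]),
      residualNorm = fit$deviance,
      converged = fit$info %in% 1:4,
      nPoints = length(b), b = b, lambda = lam,
      fitted = hyperbolaModel(b, p[1], p[2], p[3]),
      initial = start)
}
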