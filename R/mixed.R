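# Random-intercept linear mixed models fit by restricted maximum
# likelihood, with marginal-R2 variance partitioning. The model is
# y = X beta + Z u + e with u ~ iid N(0, sigma2_u) per grouping level and
# e ~ N(0, sigma2_e). The REML criterion is profiled: for a given variance
# ratio lambda = sigma2_u / sigma2_e, beta is the GLS estimate and sigma2_e
# its profiled residual variance, leaving a one-dimensional optimization
# over log(lambda).

.reml_eval <- function(loglam, y, X, Zi, n, p) {
  lam <- exp(loglam)
  V <- diag(n)
  for (rows in Zi) V[rows, rows] <- V[rows, rows] + lam
  cv <- chol(V)
  logdetV <- 2 * sum(log(diag(cv)))
  Xi <- backsolve(cv, X, transpose = TRUE)
  yi <- backsolve(cv, y, transpose = TRUE)
  XtX <- crossprod(Xi)
  beta <- solve(XtX, crossprod(Xi, yi))
  resid <- yi - Xi %*% beta
  rss <- sum(resid^2)
  sigma2_e <- rss / (n - p)
  crit <- -0.5 * ((n - p) * log(sigma2_e) + logdetV +
                  determinant(XtX, logarithm = TRUE)$modulus[1] + (n - p))
  list(crit = as.numeric(crit), beta = drop(beta), sigma2_e = sigma2_e,
       lambda = lam)
}

#' Fit a random-intercept mixed model by REML
#'
#' @param y Response vector.
#' @param X Fixed-effect design matrix (including intercept); must be full
#'   rank.
#' @param groups Grouping labels (>= 2 levels), one per observation.
#' @return Object of class `mixed_fit`: `beta` (fixed effects), `sigma2_u`,
#'   `sigma2_e`, `reml` (criterion at the optimum), `boundary` (TRUE when
#'   the fit collapsed to sigma2_u = 0), plus `X` and `fitted_fixed`.
#' @export
fit_random_intercept <- function(y, X, groups) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) stop("input error: fixed design is rank deficient")
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) stop("need >= 2 groups")
  Zi <- split(seq_len(n), groups)
  f <- function(ll) .reml_eval(ll, y, X, Zi, n, p)$crit
  opt <- stats::optimize(f, interval = c(-30, 15), maximum = TRUE,
                         tol = 1e-10)
  # the profile can be monotone decreasing: check the sigma2_u = 0 boundary
  at_zero <- .reml_eval(-Inf + 0, y, X, list(), n, p)  # V = I
  best <- .reml_eval(opt$maximum, y, X, Zi, n, p)
  boundary <- FALSE
  if (at_zero$crit >= best$crit - 1e-10 || opt$maximum <= -29) {
    best <- at_zero
    best$lambda <- 0
    boundary <- TRUE
  }
  structure(list(beta = best$beta,
                 sigma2_u = best$lambda * best$sigma2_e,
                 sigma2_e = best$sigma2_e,
                 reml = max(best$crit, at_zero$crit),
                 boundary = boundary,
                 X = X, groups = groups,
                 fitted_fixed = drop(X %*% best$beta)),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("<mixed_fit: sigma2_u = %.4g, sigma2_e = %.4g%s>\n",
              x$sigma2_u, x$sigma2_e,
              if (x$boundary) " (boundary: sigma2_u = 0)" else ""))
  print(x$beta)
  invisible(x)
}

#' Marginal R-squared of the fixed effects
#'
#' `R2m = var(X beta) / (var(X beta) + sigma2_u + sigma2_e)`: the fraction
#' of total outcome variance attributed to the fixed effects. Zero for an
#' intercept-only fixed part.
#'
#' @param fit A [fit_random_intercept()] result.
#' @return R2m in `[0, 1]`.
#' @export
marginal_r2 <- function(fit) {
  vf <- stats::var(fit$fitted_fixed)
  if (!is.finite(vf)) vf <- 0
  vf / (vf + fit$sigma2_u + fit$sigma2_e)
}

#' Share of explained variance per fixed factor
#'
#' `share(factor) = (R2m_full - R2m_without_factor) / R2m_full * 100`,
#' floored at 0. Shares need not sum to 100 (factors may be correlated).
#'
#' @param full_fit Full-model [fit_random_intercept()].
#' @param reduced_fits Named list of fits, each dropping one factor.
#' @return Named numeric vector of percentage shares.
#' @export
factor_share <- function(full_fit, reduced_fits) {
  r2f <- marginal_r2(full_fit)
  if (r2f <= 0) stop("undefined: full-model R2m is zero")
  vapply(reduced_fits, function(rf) {
    max(0, (r2f - marginal_r2(rf)) / r2f * 100)
  }, 0)
}

#' Mixed-model variance partitioning over a set of covariates
#'
#' Fits the full model and all drop-one reduced models for one response,
#' returning estimates, variance components, R2m and per-covariate shares.
#'
#' @param y Response vector.
#' @param covariates data.frame of fixed covariates (factors or numeric).
#' @param groups Grouping labels for the random intercept.
#' @return List with `fit`, `r2m`, `shares`.
#' @export
variance_partition <- function(y, covariates, groups) {
  covariates <- as.data.frame(covariates)
  mk <- function(df) {
    if (!ncol(df)) return(matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)")))
    stats::model.matrix(~., data = df)
  }
  full <- fit_random_intercept(y, mk(covariates), groups)
  reduced <- lapply(stats::setNames(names(covariates), names(covariates)),
                    function(v) fit_random_intercept(
                      y, mk(covariates[, setdiff(names(covariates), v), drop = FALSE]),
                      groups))
  list(fit = full, r2m = marginal_r2(full),
       shares = factor_share(full, reduced))
}
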