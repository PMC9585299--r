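# Negative binomial GLM layer: MASS::glm.nb behind a uniform ModelFit
# surface, AICc, and Cragg-Uhler pseudo-R².

#' Small-sample corrected Akaike information criterion
#'
#' \eqn{AICc = -2\ln L + 2k + 2k(k+1)/(n-k-1)}; requires `k < n - 1`.
#'
#' @param logLik maximised log-likelihood.
#' @param k number of estimated parameters (coefficients plus dispersion,
#'   plus the random-intercept SD for mixed models).
#' @param n number of observations.
#' @return Scalar AICc.
#' @export
aicc <- function(logLik, k, n) {
  if (k >= n - 1) stopf("AICc needs k < n - 1 (k = %d, n = %d)", k, n)
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a negative binomial GLM (log link)
#'
#' Joint maximum-likelihood estimation of the coefficients and the dispersion
#' theta, via [MASS::glm.nb()]. The log-likelihood uses the gamma-function
#' (lgamma) form, so real-valued responses such as Hill numbers are accepted;
#' a note is recorded when the response is non-integer. On equidispersed data
#' theta diverges towards the Poisson limit; it is then capped at 1e8 and
#' flagged.
#'
#' @param y non-negative response vector.
#' @param X data frame or matrix of predictors (no intercept column; the
#'   intercept is always included), or `NULL` for an intercept-only model.
#' @param standardize z-standardise predictors before fitting (default
#'   `FALSE`); when `TRUE` coefficients are reported on both scales.
#' @return A `ModelFit` list: `coefficients` (matrix with estimate, SE, z, p),
#'   `theta`, `logLik`, `n`, `k` (betas + 1 for theta), `aicc`, `converged`,
#'   `formula`, `notes`, `model` (the underlying fit), and
#'   `coefficients_raw` when `standardize = TRUE`.
#' @export
fit_nb_glm <- function(y, X = NULL, standardize = FALSE) {
  if (any(!is.finite(y)) || any(y < 0)) stopf("`y` must be finite and >= 0")
  notes <- character(0)
  if (any(y != round(y))) {
    notes <- c(notes, "non-integer response: likelihood uses the continuous gamma-function extension")
  }
  dat <- data.frame(.y = y)
  scales <- NULL
  if (!is.null(X)) {
    X <- as.data.frame(X)
    if (nrow(X) != length(y)) stopf("nrow(X) != length(y)")
    if (standardize) {
      scales <- lapply(X, function(v) c(center = mean(v), sd = stats::sd(v)))
      X <- as.data.frame(lapply(X, function(v) as.numeric(scale(v))))
    }
    dat <- cbind(dat, X)
  }
  rhs <- if (is.null(X) || ncol(X) == 0L) "1" else
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")
  fml <- stats::as.formula(paste(".y ~", rhs))
  fit <- withCallingHandlers(
    tryCatch(MASS::glm.nb(fml, data = dat), error = function(e) e),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error")) {
    stopf("negative binomial GLM failed: %s", conditionMessage(fit))
  }
  theta <- fit$theta
  if (theta > 1e8) {
    theta <- 1e8
    notes <- c(notes, "theta capped at 1e8 (Poisson limit)")
  }
  sm <- summary(fit)
  co <- sm$coefficients
  k <- nrow(co) + 1L
  ll <- as.numeric(stats::logLik(fit))
  n <- length(y)
  converged <- isTRUE(fit$converged) &&
    !any(grepl("iteration limit", notes, fixed = TRUE))
  out <- list(kind = "nb_glm", coefficients = co, theta = theta,
              sigma_alpha = NA_real_, logLik = ll, n = n, k = k,
              aicc = aicc(ll, k, n),
              converged = converged, formula = paste(".y ~", rhs),
              notes = notes, model = fit,
              fixed_lp = as.numeric(stats::predict(fit, type = "link")))
  if (standardize && !is.null(scales)) {
    out$scales <- scales
    out$coefficients_raw <- unstandardize_coefs(co[, 1], scales)
  }
  class(out) <- "ModelFit"
  out
}

# Maps coefficients fitted on z-scored predictors back to the raw scale.
unstandardize_coefs <- function(beta, scales) {
  raw <- beta
  for (nm in names(scales)) {
    key <- sprintf("`%s`", nm)
    idx <- match(key, names(beta), nomatch = match(nm, names(beta)))
    if (is.na(idx)) next
    raw[idx] <- beta[idx] / scales[[nm]]["sd"]
    raw["(Intercept)"] <- raw["(Intercept)"] -
      beta[idx] * scales[[nm]]["center"] / scales[[nm]]["sd"]
  }
  raw
}

#' @export
print.ModelFit <- function(x, ...) {
  cat(sprintf("%s fit: %s\n", x$kind, x$formula))
  cat(sprintf("  n = %d, k = %d, logLik = %.4f, AICc = %.4f\n",
              x$n, x$k, x$logLik, x$aicc))
  cat(sprintf("  theta = %.4g%s\n", x$theta,
              if (!is.na(x$sigma_alpha))
                sprintf(", sigma_alpha = %.4g", x$sigma_alpha) else ""))
  stats::printCoefmat(x$coefficients, ...)
  invisible(x)
}

#' Cragg–Uhler (Nagelkerke) pseudo-R²
#'
#' \deqn{pR^2 = \frac{1 - (L_0/L_1)^{2/n}}{1 - L_0^{2/n}}}
#' computed from the maximised likelihoods of a fitted model and the
#' corresponding intercept-only null model; clamped to `[0, 1]` when sampling
#' noise puts \eqn{L_1} marginally below \eqn{L_0}.
#'
#' @param fit `ModelFit` of the model of interest.
#' @param null_fit `ModelFit` of the intercept-only model on the same response.
#' @return Scalar in `[0, 1]`.
#' @export
cragg_uhler_r2 <- function(fit, null_fit) {
  if (fit$n != null_fit$n) stopf("fits have different n (%d vs %d)", fit$n, null_fit$n)
  n <- fit$n
  num <- 1 - exp((2 / n) * (null_fit$logLik - fit$logLik))
  den <- 1 - exp((2 / n) * null_fit$logLik)
  val <- num / den
  min(1, max(0, val))
}
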