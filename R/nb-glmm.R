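# Negative binomial GLMM with a single Gaussian random intercept (log link).
# The marginal likelihood integrates the group intercept with adaptive
# Gauss-Hermite quadrature: for each group the integrand is shifted to its
# mode (inner Newton iterations; the integrand is log-concave) and scaled by
# the curvature there, so a modest number of nodes is accurate. One node
# recovers the Laplace approximation.

# Continuous-extension NB log density (lgamma form), vectorised over y, mu.
nb_logdens <- function(y, mu, theta) {
  lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
    theta * log(theta) + y * log(mu) - (y + theta) * log(mu + theta)
}

# Marginal log-likelihood of one group as a function of (eta, theta, sigma).
# eta is the fixed-effect linear predictor for the group's observations.
group_loglik_agq <- function(y, eta, theta, sigma, gh) {
  if (sigma < 1e-8) return(sum(nb_logdens(y, exp(eta), theta)))
  f <- function(b) sum(nb_logdens(y, exp(eta + b), theta)) -
    0.5 * (b / sigma)^2 - log(sigma) - 0.5 * log(2 * pi)
  # Newton mode search; f is strictly concave in b.
  b <- 0
  for (it in 1:50) {
    mu <- exp(eta + b)
    g <- sum(y - (y + theta) * mu / (mu + theta)) - b / sigma^2
    h <- -sum((y + theta) * theta * mu / (mu + theta)^2) - 1 / sigma^2
    step <- -g / h
    if (!is.finite(step)) break
    # dampen wild first steps far from the mode
    if (abs(step) > 5) step <- sign(step) * 5
    b <- b + step
    if (abs(step) < 1e-10) break
  }
  mu <- exp(eta + b)
  h <- sum((y + theta) * theta * mu / (mu + theta)^2) + 1 / sigma^2
  s <- 1 / sqrt(h)
  lvals <- log(gh$w) + gh$x^2 +
    vapply(gh$x, function(z) f(b + sqrt(2) * s * z), numeric(1))
  0.5 * log(2) + log(s) + logsumexp(lvals)
}

#' Fit a negative binomial GLMM with a region random intercept
#'
#' Maximises the marginal likelihood of a log-link negative binomial model
#' with one Gaussian random intercept per group, integrating the intercept by
#' adaptive Gauss–Hermite quadrature (default 15 nodes; 1 node gives the
#' Laplace approximation). Fixed-effect coefficients, the NB dispersion
#' theta, and the random-intercept SD sigma_alpha are estimated jointly by
#' L-BFGS-B on (beta, log theta, sigma).
#'
#' @param y non-negative response vector (real values accepted; the
#'   likelihood uses the gamma-function form).
#' @param X data frame or matrix of fixed-effect predictors (intercept always
#'   added), or `NULL` for the random-intercept-only model.
#' @param group factor (or vector coercible to one) of group memberships;
#'   at least 2 groups for a random intercept. With a single group the model
#'   reduces to the GLM with `sigma_alpha` fixed at 0.
#' @param nodes number of Gauss–Hermite nodes (default 15).
#' @param standardize z-standardise predictors before fitting.
#' @return A `ModelFit` list as in [fit_nb_glm()], plus `sigma_alpha`,
#'   `boundary` (TRUE when sigma_alpha hit the zero boundary), `ranef`
#'   (posterior-mode group intercepts), `fixed_lp` (fixed-effect linear
#'   predictor), and `nodes`. `k` counts betas + theta + sigma_alpha.
#' @export
fit_nb_glmm <- function(y, X = NULL, group, nodes = 15L, standardize = FALSE) {
  if (any(!is.finite(y)) || any(y < 0)) stopf("`y` must be finite and >= 0")
  group <- factor(group)
  if (length(group) != length(y)) stopf("`group` must match length(y)")
  if (!is_count(nodes)) stopf("`nodes` must be a positive integer")
  if (nlevels(group) < 2L) {
    fit <- fit_nb_glm(y, X, standardize = standardize)
    fit$kind <- "nb_glmm"
    fit$sigma_alpha <- 0
    fit$boundary <- TRUE
    fit$notes <- c(fit$notes, "single group: sigma_alpha fixed at 0 (GLM fit)")
    return(fit)
  }
  notes <- character(0)
  if (any(y != round(y))) {
    notes <- c(notes, "non-integer response: likelihood uses the continuous gamma-function extension")
  }
  scales <- NULL
  if (!is.null(X)) {
    X <- as.data.frame(X)
    if (standardize) {
      scales <- lapply(X, function(v) c(center = mean(v), sd = stats::sd(v)))
      X <- as.data.frame(lapply(X, function(v) as.numeric(scale(v))))
    }
    M <- cbind(`(Intercept)` = 1, as.matrix(X))
  } else {
    M <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  }
  p <- ncol(M)
  gh <- if (nodes == 1L) list(x = 0, w = sqrt(pi)) else
    pracma::gaussHermite(as.integer(nodes))
  idx <- split(seq_along(y), group)

  nll <- function(par) {
    beta <- par[1:p]
    theta <- exp(par[p + 1])
    sigma <- par[p + 2]
    eta <- drop(M %*% beta)
    ll <- sum(vapply(idx, function(i) {
      group_loglik_agq(y[i], eta[i], theta, sigma, gh)
    }, numeric(1)))
    if (!is.finite(ll)) 1e10 else -ll
  }

  start_glm <- suppressWarnings(fit_nb_glm(y, X))
  beta0 <- start_glm$coefficients[, 1]
  # crude starting sigma from group deviations of log means
  gm <- tapply(log(pmax(y, 0.5)), group, mean)
  sig0 <- max(0.05, stats::sd(gm - mean(gm)))
  par0 <- c(beta0, log(start_glm$theta), sig0)
  opt <- stats::optim(par0, nll, method = "L-BFGS-B",
                      lower = c(rep(-Inf, p + 1), 0),
                      control = list(maxit = 500), hessian = TRUE)
  beta <- opt$par[1:p]
  theta <- exp(opt$par[p + 1])
  sigma <- opt$par[p + 2]
  ll <- -opt$value
  converged <- opt$convergence == 0
  if (!converged) notes <- c(notes, sprintf("optim convergence code %d", opt$convergence))
  boundary <- sigma < 1e-4
  if (boundary) {
    sigma <- max(sigma, 0)
    notes <- c(notes, "sigma_alpha at the zero boundary")
  }
  # Wald SEs for beta from the observed information of the joint fit
  se <- rep(NA_real_, p)
  vc <- try(solve(opt$hessian), silent = TRUE)
  if (!inherits(vc, "try-error")) {
    dv <- diag(vc)[1:p]
    se[dv > 0] <- sqrt(dv[dv > 0])
  }
  zval <- beta / se
  co <- cbind(Estimate = beta, `Std. Error` = se, `z value` = zval,
              `Pr(>|z|)` = 2 * stats::pnorm(-abs(zval)))
  rownames(co) <- colnames(M)
  k <- p + 2L
  n <- length(y)
  eta <- drop(M %*% beta)
  # posterior modes of the group intercepts at the estimates
  ranef <- vapply(idx, function(i) {
    if (sigma < 1e-8) return(0)
    b <- 0
    for (it in 1:50) {
      mu <- exp(eta[i] + b)
      g <- sum(y[i] - (y[i] + theta) * mu / (mu + theta)) - b / sigma^2
      h <- -sum((y[i] + theta) * theta * mu / (mu + theta)^2) - 1 / sigma^2
      b <- b - g / h
      if (abs(g / h) < 1e-10) break
    }
    b
  }, numeric(1))
  out <- list(kind = "nb_glmm", coefficients = co, theta = theta,
              sigma_alpha = sigma, logLik = ll, n = n, k = k,
              aicc = aicc(ll, k, n), converged = converged,
              boundary = boundary,
              formula = sprintf(".y ~ %s + (1 | group)",
                                if (p == 1) "1" else
                                  paste(colnames(M)[-1], collapse = " + ")),
              notes = notes, ranef = ranef, fixed_lp = eta, nodes = nodes)
  if (standardize && !is.null(scales)) {
    out$scales <- scales
    out$coefficients_raw <- unstandardize_coefs(co[, 1], scales)
  }
  class(out) <- "ModelFit"
  out
}

#' Nakagawa marginal and conditional R² for a NB GLMM
#'
#' On the latent (log-link) scale, with \eqn{\sigma_f^2} the variance of the
#' fixed-effect linear predictor across observations, \eqn{\sigma_\alpha^2}
#' the random-intercept variance, and \eqn{\sigma_d^2} the observation-level
#' (distribution-specific) variance,
#' \deqn{R^2_m = \sigma_f^2 / (\sigma_f^2 + \sigma_\alpha^2 + \sigma_d^2),
#'   \quad R^2_c = (\sigma_f^2 + \sigma_\alpha^2) / (\cdot).}
#' For the NB log link \eqn{\sigma_d^2} uses the lognormal approximation
#' \eqn{\ln(1 + 1/\bar\mu + 1/\theta)} with
#' \eqn{\bar\mu = \exp(\beta_0 + \sigma_\alpha^2/2)}; the trigamma variant
#' \eqn{\psi_1(1/(1/\bar\mu + 1/\theta))} is available.
#'
#' @param fit converged `ModelFit` from [fit_nb_glmm()].
#' @param obs_var `"lognormal"` (default) or `"trigamma"`.
#' @return List with `Rm2` and `Rc2` (`0 <= Rm2 <= Rc2 <= 1`).
#' @export
nakagawa_r2 <- function(fit, obs_var = c("lognormal", "trigamma")) {
  obs_var <- match.arg(obs_var)
  if (!inherits(fit, "ModelFit") || fit$kind != "nb_glmm") {
    stopf("`fit` must be a nb_glmm ModelFit")
  }
  if (!isTRUE(fit$converged)) stopf("fit did not converge; R2 undefined")
  lp <- fit$fixed_lp %||% rep(fit$coefficients[1, 1], fit$n)
  var_f <- if (length(unique(lp)) == 1L) 0 else stats::var(lp)
  var_a <- fit$sigma_alpha^2
  beta0 <- fit$coefficients["(Intercept)", 1]
  mu_bar <- exp(beta0 + var_a / 2)
  var_d <- switch(obs_var,
    lognormal = log(1 + 1 / mu_bar + 1 / fit$theta),
    trigamma = trigamma(1 / (1 / mu_bar + 1 / fit$theta)))
  tot <- var_f + var_a + var_d
  list(Rm2 = var_f / tot, Rc2 = (var_f + var_a) / tot)
}
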