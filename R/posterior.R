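# Joint inference over the generating distribution's mean and precision.
#
# The observer sees noisy horizontal dot measurements X (per-dot sensory
# noise sigma_dot added to the displayed dots) and infers the generating
# mean mu_cloud while marginalising over the unknown generating precision
# tau_cloud.  Under the centred normal-gamma prior the joint posterior is
# a normal-gamma kernel whose kappa_p and beta_p depend on tau_cloud, so
# no analytic Student-t marginal exists; the marginal over mu_cloud is
# instead a finite mixture of Gaussians over a grid of spread values,
# which this file exploits both for the user-facing density objects and
# for the vectorised fast paths used in simulation and fitting.

#' Normal-gamma prior over the generating mean and precision
#'
#' Constants default to the study's moment-matched values: the marginal
#' mean and variance of the prior match the true stimulus statistics of
#' the experiment.  `kappa0` acts as a number of pseudo-observations,
#' `alpha0` as degrees of freedom and `beta0` as a prior pooled-variance
#' scale.
#'
#' @param mu0,kappa0,alpha0,beta0 prior constants; `kappa0`, `alpha0`,
#'   `beta0` must be positive.
#' @export
normal_gamma_prior <- function(mu0 = 0, kappa0 = 0.68, alpha0 = 3.84,
                               beta0 = 13.48) {
  stopifnot(kappa0 > 0, alpha0 > 0, beta0 > 0)
  structure(list(mu0 = mu0, kappa0 = kappa0, alpha0 = alpha0, beta0 = beta0),
            class = "ng_prior")
}

#' Grids for numerical marginalisation
#'
#' The mu grid covers the stimulus range (+/- 4 deg offsets, spreads up to
#' 2.5 deg) with wide margins; the spread grid spans the precisions the
#' marginalisation integrates over, uniform in sigma_cloud.
#'
#' @param mu_lim,mu_step support and step of the mu_cloud grid (deg).
#' @param sigma_lim,n_sigma support and resolution of the sigma_cloud grid.
#' @export
posterior_grids <- function(mu_lim = c(-20, 20), mu_step = 0.02,
                            sigma_lim = c(0.5, 5), n_sigma = 201L) {
  list(mu = seq(mu_lim[1], mu_lim[2], by = mu_step),
       sigma = seq(sigma_lim[1], sigma_lim[2], length.out = n_sigma))
}

#' Combined per-dot precision
#'
#' Generating spread and sensory noise add in variance, giving the
#' effective per-dot precision `1 / (sigma_cloud^2 + sigma_dot^2)`.
#'
#' @param sigma_cloud,sigma_dot SDs in degrees; at least one must be
#'   positive.
#' @export
combined_precision <- function(sigma_cloud, sigma_dot) {
  v <- sigma_cloud^2 + sigma_dot^2
  if (any(v == 0)) stop("combined precision is infinite when both ",
                        "sigma_cloud and sigma_dot are zero")
  1 / v
}

#' Sample mean and maximum-likelihood variance of measured dots
#'
#' @param x numeric vector of (noisy) horizontal dot measurements.
#' @return list with `x_bar` and `s2` (divide-by-N variance).
#' @export
dot_summaries <- function(x) {
  if (length(x) < 1) stop("dot_summaries() needs at least one measurement")
  xb <- mean(x)
  list(x_bar = xb, s2 = mean((x - xb)^2))
}

#' Conditional normal-gamma posterior parameters at one precision value
#'
#' The conjugate update for the joint posterior over (mu_cloud, tau_cloud)
#' evaluated at a given tau_cloud.  kappa_p and beta_p retain a tau_cloud
#' dependence (and beta_p a log(tau_cloud/tau_dot + 1) term) because the
#' per-dot likelihood precision mixes the generating and sensory variances.
#'
#' @param x_bar,s2 measurement summaries (see [dot_summaries()]).
#' @param n_dots number of measured dots.
#' @param sigma_dot sensory noise SD (deg).
#' @param tau_cloud generating precision value(s), `> 0`; vectorised.
#' @param prior an [normal_gamma_prior()].
#' @return list of vectors `mu_p`, `kappa_p`, `alpha_p`, `beta_p`.
#' @export
conditional_posterior_params <- function(x_bar, s2, n_dots, sigma_dot,
                                         tau_cloud,
                                         prior = normal_gamma_prior()) {
  stopifnot(all(tau_cloud > 0))
  n <- n_dots
  tau_dot <- 1 / sigma_dot^2     # Inf allowed for the noiseless limit
  tcomb <- 1 / (1 / tau_cloud + sigma_dot^2)
  denom <- prior$kappa0 * tau_cloud + n * tcomb
  mu_p <- (prior$kappa0 * tau_cloud * prior$mu0 + n * tcomb * x_bar) / denom
  kappa_p <- denom / tau_cloud
  alpha_p <- rep(prior$alpha0 + n / 2, length(tau_cloud))
  beta_p <- prior$beta0 + n / (2 * tau_cloud) *
    (prior$kappa0 * tau_cloud * tcomb * (x_bar - prior$mu0)^2 / denom +
       tcomb * s2 + log(tau_cloud / tau_dot + 1))
  if (any(beta_p <= 0)) stop("nonpositive beta_p at a grid point")
  list(mu_p = mu_p, kappa_p = kappa_p, alpha_p = alpha_p, beta_p = beta_p)
}

#' Marginal posterior over the generating mean
#'
#' Marginalises the joint posterior over the generating precision on a
#' grid uniform in sigma_cloud.  Two independent computational routes are
#' provided: `"conditional"` goes through the conditional normal-gamma
#' parameters (evaluating the posterior kernel per precision value), and
#' `"grid2d"` normalises likelihood x prior directly on the 2-D
#' (mu, sigma) grid.  The two must agree to tight tolerance; `"grid2d"`
#' serves as the independent oracle in the test suite.
#'
#' Under the flat variant the prior is uniform over the (mean, spread)
#' grid, so the marginal is the normalised likelihood; under the centred
#' variant it is the normal-gamma posterior.
#'
#' @param x noisy dot measurements.
#' @param sigma_dot sensory noise SD (deg).
#' @param prior_variant `"centred"` or `"flat"`.
#' @param prior an [normal_gamma_prior()] (centred variant only).
#' @param grids see [posterior_grids()].
#' @param method computational route, see Details.
#' @return a `marginal_posterior`: list with `mu_grid`, `density`
#'   (normalised to integrate to 1), `prior_variant`, measurement
#'   summaries, and for the centred conditional route the per-precision
#'   conditional parameters.
#' @export
marginal_posterior <- function(x, sigma_dot,
                               prior_variant = c("centred", "flat"),
                               prior = normal_gamma_prior(),
                               grids = posterior_grids(),
                               method = c("conditional", "grid2d")) {
  prior_variant <- match.arg(prior_variant)
  method <- match.arg(method)
  ds <- dot_summaries(x)
  n <- length(x)
  mu <- grids$mu
  sig <- grids$sigma
  tau <- 1 / sig^2
  tcomb <- combined_precision(sig, sigma_dot)
  cond <- NULL

  if (method == "conditional") {
    if (prior_variant == "centred") {
      cond <- conditional_posterior_params(ds$x_bar, ds$s2, n, sigma_dot,
                                           tau, prior)
      # decompose the joint as w(tau) * N(mu | mu_p, (kappa_p tau)^-1):
      # the marginal weight carries sqrt(kappa0/kappa_p) because the
      # conditional Gaussian is normalised with the posterior precision
      # while likelihood x prior carries the prior's sqrt(kappa0 tau);
      # log(2/sigma^3) is the tau(sigma) Jacobian of the sigma grid
      lw <- 0.5 * log(prior$kappa0 / cond$kappa_p) +
        (cond$alpha_p - 1) * log(tau) - cond$beta_p * tau +
        log(2 / sig^3)
      lw <- lw - max(lw)
      # mixture of conditional Gaussians N(mu_p, (kappa_p tau)^-1)
      prec <- cond$kappa_p * tau
      logd <- outer(mu, cond$mu_p, "-")
      logd <- -0.5 * sweep(logd^2, 2, prec, "*") +
        rep(lw, each = length(mu))
    } else {
      # flat prior: marginal over mu of the likelihood at each sigma
      lw <- (n / 2) * log(tcomb) - 0.5 * log(n * tcomb) -
        0.5 * n * tcomb * ds$s2
      lw <- lw - max(lw)
      prec <- n * tcomb
      logd <- -0.5 * sweep(outer(mu, rep(ds$x_bar, length(sig)), "-")^2,
                           2, prec, "*") + rep(lw, each = length(mu))
    }
    dens <- as.vector(exp(logd - max(logd)) %*% sqrt(prec / (2 * pi)))
  } else {
    # independent oracle: likelihood (x prior) evaluated on the 2-D grid
    loglik <- matrix(0, length(mu), length(sig))
    for (j in seq_along(sig)) {
      loglik[, j] <- (n / 2) * log(tcomb[j]) -
        0.5 * tcomb[j] * (n * ds$s2 + n * (ds$x_bar - mu)^2)
    }
    if (prior_variant == "centred") {
      logpr <- matrix(0, length(mu), length(sig))
      for (j in seq_along(sig)) {
        logpr[, j] <- dnorm(mu, prior$mu0,
                            1 / sqrt(prior$kappa0 * tau[j]), log = TRUE) +
          dgamma(tau[j], prior$alpha0, rate = prior$beta0, log = TRUE) +
          log(2 / sig[j]^3)
      }
      loglik <- loglik + logpr
    }
    dens <- rowSums(exp(loglik - max(loglik)))
  }

  z <- trapz(mu, dens)
  if (!is.finite(z) || z <= 0) stop("marginal posterior failed to normalise")
  dens <- dens / z
  if (max(dens[c(1, length(dens))]) > 1e-4 * max(dens)) {
    stop("mu grid too narrow: non-negligible density at the grid edge ",
         "(x_bar = ", signif(ds$x_bar, 4), "); widen posterior_grids()")
  }
  structure(list(mu_grid = mu, density = dens,
                 prior_variant = prior_variant, method = method,
                 x_bar = ds$x_bar, s2 = ds$s2, n_dots = n,
                 sigma_dot = sigma_dot, sigma_grid = sig,
                 conditional_params = cond, prior = prior),
            class = "marginal_posterior")
}

#' @export
print.marginal_posterior <- function(x, ...) {
  pe <- point_estimates(x)
  cat("Marginal posterior over mu_cloud (", x$prior_variant,
      " prior, ", x$method, " route)\n", sep = "")
  cat("  n_dots =", x$n_dots, " x_bar =", signif(x$x_bar, 4),
      " s2 =", signif(x$s2, 4), "\n")
  cat("  mode =", signif(pe$mu_hat, 4), " sd =", signif(pe$sigma_hat, 4),
      "\n")
  invisible(x)
}

#' Category evidence from a marginal posterior
#'
#' Probability that the generating mean lies right of the Type 1 criterion
#' `k1` (the evidence for category "right"); the evidence for "left" is its
#' complement.
#'
#' @param post a [marginal_posterior()].
#' @param k1 Type 1 criterion (deg).
#' @return `p(C = R | X, k1)`.
#' @export
category_evidence <- function(post, k1 = 0) {
  mu <- post$mu_grid
  d <- post$density
  if (k1 <= mu[1]) return(1)
  if (k1 >= mu[length(mu)]) return(0)
  i <- findInterval(k1, mu)
  # partial trapezoid in the cell containing k1
  t_ <- (k1 - mu[i]) / (mu[i + 1] - mu[i])
  dk <- d[i] + t_ * (d[i + 1] - d[i])
  part <- (dk + d[i + 1]) * (mu[i + 1] - k1) / 2
  if (i + 1 <= length(mu) - 1) {
    part <- part + trapz(mu[(i + 1):length(mu)], d[(i + 1):length(mu)])
  }
  min(max(part, 0), 1)
}

#' Point estimates of a marginal posterior
#'
#' The mode (grid argmax refined by local quadratic interpolation; ties
#' broken to the leftmost maximum, fully flat densities return the grid
#' midpoint with a warning) and the posterior SD (square root of the
#' second central moment under trapezoid integration).
#'
#' @param post a [marginal_posterior()].
#' @return list with `mu_hat` and `sigma_hat`.
#' @export
point_estimates <- function(post) {
  mu <- post$mu_grid
  d <- post$density
  imax <- which(d == max(d))
  if (length(imax) == length(d)) {
    warning("degenerate flat density; returning the grid midpoint")
    i <- (length(d) + 1) %/% 2
  } else {
    i <- imax[1]
  }
  if (i > 1 && i < length(d)) {
    # quadratic through the three points around the grid maximum
    y1 <- d[i - 1]; y2 <- d[i]; y3 <- d[i + 1]
    denom <- y1 - 2 * y2 + y3
    off <- if (denom < 0) 0.5 * (y1 - y3) / denom else 0
    off <- min(max(off, -0.5), 0.5)
    mu_hat <- mu[i] + off * (mu[2] - mu[1])
  } else {
    mu_hat <- mu[i]
  }
  m1 <- trapz(mu, mu * d)
  m2 <- trapz(mu, (mu - m1)^2 * d)
  list(mu_hat = mu_hat, sigma_hat = sqrt(max(m2, 0)))
}
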