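# Fast vectorised access to the marginal posterior.
#
# For fixed (n_dots, sigma_dot, prior variant) the marginal posterior over
# mu_cloud is a Gaussian mixture across the sigma_cloud grid whose
# component means are linear in x_bar and whose log-weights are
# quadratic in x_bar and linear in s2.  Precomputing the component
# coefficients lets every posterior summary (category evidence, mode,
# spread) be evaluated for hundreds of thousands of measurement draws by
# plain matrix arithmetic.  Equivalence with the marginal_posterior()
# density objects is asserted in the test suite.

# Component coefficients of the marginal-posterior mixture.
ng_mixture <- function(n_dots, sigma_dot, prior_variant,
                       prior = normal_gamma_prior(),
                       sigma_grid = posterior_grids()$sigma) {
  n <- n_dots
  sig <- sigma_grid
  tau <- 1 / sig^2
  tcomb <- combined_precision(sig, sigma_dot)
  if (prior_variant == "centred") {
    P <- prior$kappa0 * tau + n * tcomb
    cc <- n * tcomb / P
    sd_c <- 1 / sqrt(P)
    q <- 0.5 * n * tcomb * prior$kappa0 * tau / P
    h <- 0.5 * n * tcomb
    lw0 <- (n / 2) * log(tcomb) + 0.5 * log(prior$kappa0 * tau) -
      0.5 * log(P) + (prior$alpha0 - 1) * log(tau) - prior$beta0 * tau +
      log(2 / sig^3)
  } else {
    cc <- rep(1, length(sig))
    sd_c <- 1 / sqrt(n * tcomb)
    q <- rep(0, length(sig))
    h <- 0.5 * n * tcomb
    lw0 <- (n / 2) * log(tcomb) - 0.5 * log(n * tcomb)
  }
  list(n_dots = n, sigma_dot = sigma_dot, prior_variant = prior_variant,
       mu0 = if (prior_variant == "centred") prior$mu0 else 0,
       c = cc, sd = sd_c, lw0 = lw0 - max(lw0), q = q, h = h)
}

# Normalised mixture weights (n_draws x n_components) and component means.
mixture_weights <- function(mix, x_bar, s2) {
  lw <- -outer((x_bar - mix$mu0)^2, mix$q) - outer(s2, mix$h)
  lw <- sweep(lw, 2, mix$lw0, "+")
  lw <- lw - lw[cbind(seq_len(nrow(lw)), max.col(lw, ties.method = "first"))]
  w <- exp(lw)
  w / rowSums(w)
}

mixture_means <- function(mix, x_bar) {
  mix$mu0 + outer(x_bar - mix$mu0, mix$c)
}

# p(C = R | X, k1) = P(mu_cloud > k1 | X) for each draw; k1 may be a
# scalar or one criterion per draw.
mixture_pright <- function(mix, x_bar, s2, k1, w = NULL) {
  if (is.null(w)) w <- mixture_weights(mix, x_bar, s2)
  m <- mixture_means(mix, x_bar)
  z <- sweep(m - k1, 2, mix$sd, "/")
  rowSums(w * pnorm(z))
}

# Posterior mean and SD per draw.
mixture_moments <- function(mix, x_bar, s2, w = NULL) {
  if (is.null(w)) w <- mixture_weights(mix, x_bar, s2)
  m <- mixture_means(mix, x_bar)
  mean_ <- rowSums(w * m)
  ex2 <- rowSums(w * sweep(m^2, 2, mix$sd^2, "+"))
  list(mean = mean_, sd = sqrt(pmax(ex2 - mean_^2, 0)))
}

# Posterior mode per draw: mean-shift fixed point started at the posterior
# mean (the mixtures are unimodal in practice; agreement with the
# grid-argmax route is tested).  Flat-prior mixtures are symmetric about
# x_bar, so the mode is x_bar exactly.
mixture_mode <- function(mix, x_bar, s2, w = NULL, tol = 1e-7,
                         max_iter = 60L) {
  if (mix$prior_variant == "flat") return(x_bar)
  if (is.null(w)) w <- mixture_weights(mix, x_bar, s2)
  m <- mixture_means(mix, x_bar)
  inv_v <- 1 / mix$sd^2
  mode_ <- rowSums(w * m)
  for (it in seq_len(max_iter)) {
    z <- sweep(mode_ - m, 2, mix$sd, "/")
    r <- w * sweep(exp(-0.5 * z^2), 2, mix$sd, "/")
    num <- rowSums(sweep(r * m, 2, inv_v, "*"))
    den <- rowSums(sweep(r, 2, inv_v, "*"))
    new_mode <- num / den
    delta <- max(abs(new_mode - mode_))
    mode_ <- new_mode
    if (delta < tol) break
  }
  mode_
}

# All Type 2 evidence ingredients for a batch of measurement draws, in one
# pass: p(C=R|X,k1), posterior mode and SD.
mixture_summaries <- function(mix, x_bar, s2, k1) {
  w <- mixture_weights(mix, x_bar, s2)
  p_right <- mixture_pright(mix, x_bar, s2, k1, w = w)
  mode_ <- mixture_mode(mix, x_bar, s2, w = w)
  mom <- mixture_moments(mix, x_bar, s2, w = w)
  list(p_right = p_right, mu_hat = mode_, sigma_hat = mom$sd)
}

# Critical centroid-measurement boundary for the Type 1 decision:
# x_crit(s_emp) such that p(C=R|X,k1) = 0.5 at x_bar = x_crit.  The
# category evidence is monotone increasing in x_bar (tested property), so
# the decision reduces to x_bar > x_crit(s_emp), which makes grid fitting
# of the Type 1 stage cheap.  Flat variant: x_crit = k1 for every s_emp.
type1_boundary <- function(mix, k1, s_grid = seq(0, 9, by = 0.25),
                           iters = 50L) {
  if (mix$prior_variant == "flat") {
    return(list(s = s_grid, x = rep(k1, length(s_grid))))
  }
  s2 <- s_grid^2
  lo <- rep(min(mix$mu0, k1) - 30, length(s_grid))
  hi <- rep(max(mix$mu0, k1) + 30, length(s_grid))
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    p <- mixture_pright(mix, mid, s2, k1)
    up <- p < 0.5
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  list(s = s_grid, x = (lo + hi) / 2)
}

# Decision given measurement summaries: TRUE = "right".
type1_decide <- function(mix, x_bar, s2, k1, boundary = NULL) {
  if (mix$prior_variant == "flat") return(x_bar > k1)
  if (!is.null(boundary)) {
    xc <- approx(boundary$s, boundary$x, xout = pmin(sqrt(s2),
                 max(boundary$s)), rule = 2)$y
    return(x_bar > xc)
  }
  mixture_pright(mix, x_bar, s2, k1) > 0.5
}

# Bilinear lookup tables of the centred-variant posterior summaries over
# (x_bar, s_emp), so that per-draw evidence inside the fitting loops costs
# an interpolation rather than a mixture evaluation.  The signed log odds
# of "right" is tabled instead of the raw probability because it is
# near-linear in x_bar and therefore interpolates accurately.
summary_tables <- function(mix, k1,
                           xbar_grid = seq(-14, 14, by = 0.2),
                           s_grid = seq(0, 9, by = 0.25)) {
  nx <- length(xbar_grid); ns <- length(s_grid)
  g <- expand.grid(x = xbar_grid, s = s_grid)
  sm <- mixture_summaries(mix, g$x, g$s^2, k1)
  p <- clip01(sm$p_right)
  list(xg = xbar_grid, sg = s_grid,
       lodds = matrix(qlogis(p), nx, ns),
       mode = matrix(sm$mu_hat, nx, ns),
       sd = matrix(sm$sigma_hat, nx, ns))
}

table_summaries <- function(tab, x_bar, s_emp) {
  list(p_right = plogis(bilinear(tab$xg, tab$sg, tab$lodds, x_bar, s_emp)),
       mu_hat = bilinear(tab$xg, tab$sg, tab$mode, x_bar, s_emp),
       sigma_hat = bilinear(tab$xg, tab$sg, tab$sd, x_bar, s_emp))
}
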