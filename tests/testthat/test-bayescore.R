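# Joint inference over the generating mean and precision.

test_that("combined precision adds variances", {
  expect_equal(combined_precision(2, 0), 0.25)
  expect_equal(combined_precision(1.5, 1), 1 / 3.25)
  expect_error(combined_precision(0, 0), "infinite")
  # precision can never exceed either source alone
  for (sc in c(0.5, 1.5, 3)) {
    for (sd_ in c(0.2, 1, 2)) {
      expect_lte(combined_precision(sc, sd_), min(1 / sc^2, 1 / sd_^2))
    }
  }
})

test_that("dot summaries use the maximum-likelihood variance", {
  expect_equal(dot_summaries(c(-1, 3)), list(x_bar = 1, s2 = 4))
  expect_equal(dot_summaries(rep(2, 5)), list(x_bar = 2, s2 = 0))
  expect_equal(dot_summaries(c(0, 1, 2)), list(x_bar = 1, s2 = 2 / 3))
  expect_error(dot_summaries(numeric(0)), "at least one")
})

test_that("conditional posterior parameters follow the conjugate update", {
  # alpha_p depends on N only
  cp <- conditional_posterior_params(0, 1, 5, 1, c(0.1, 0.5, 2))
  expect_equal(cp$alpha_p, rep(3.84 + 2.5, 3))

  # data-dominated limit: no sensory noise, vanishing prior weight
  weak <- normal_gamma_prior(kappa0 = 1e-10)
  cp <- conditional_posterior_params(1.7, 0.5, 2, 1e-9, 0.25, weak)
  expect_equal(cp$mu_p, 1.7, tolerance = 1e-8)

  # full quadruple for X = [-1, 3], sigma_dot = 1, tau_cloud = 0.25,
  # default prior; expected values from direct evaluation of the update
  # equations (kappa0 tau = 0.17, N tau_comb = 0.4)
  cp <- conditional_posterior_params(1, 4, 2, 1, 0.25)
  expect_equal(cp$mu_p, 0.4 / 0.57)
  expect_equal(cp$kappa_p, 0.57 / 0.25)
  expect_equal(cp$alpha_p, 4.84)
  expect_equal(cp$beta_p, 13.48 + 4 * (0.17 * 0.2 / 0.57 + 0.8 + log(1.25)))
})

test_that("conditional-parameter route matches the 2-D grid oracle", {
  cases <- list(list(x = c(-1, 3), sd = 1),
                list(x = c(3, 5), sd = 1),
                list(x = c(-2.5, 0.5, 1, 4, 2), sd = 0.7),
                list(x = c(0.2, -0.2), sd = 2))
  for (cs in cases) {
    for (v in c("centred", "flat")) {
      a <- marginal_posterior(cs$x, cs$sd, v, method = "conditional")
      b <- marginal_posterior(cs$x, cs$sd, v, method = "grid2d")
      expect_lt(max(abs(a$density - b$density)), 1e-4)
    }
  }
})

test_that("flat-prior posterior peaks at the centroid, centred prior
           shrinks towards zero", {
  fp <- marginal_posterior(c(-2, 2), 1, "flat")
  expect_equal(point_estimates(fp)$mu_hat, 0, tolerance = 1e-8)
  expect_equal(category_evidence(fp, 0), 0.5, tolerance = 1e-6)

  fp2 <- marginal_posterior(c(0.3, 1.9, 2.6), 1, "flat")
  expect_equal(point_estimates(fp2)$mu_hat, 1.6, tolerance = 1e-6)

  cp <- marginal_posterior(c(3, 5), 1, "centred")
  mh <- point_estimates(cp)$mu_hat
  expect_gt(mh, 0)
  expect_lt(mh, 4)
})

test_that("category evidence behaves as a tail probability", {
  post <- marginal_posterior(c(1, 2.5), 1, "centred")
  for (k1 in c(-1, 0, 0.7, 2)) {
    pr <- category_evidence(post, k1)
    expect_gte(pr, 0); expect_lte(pr, 1)
  }
  # monotone decreasing in the criterion, and evidence splits to 1
  ks <- seq(-2, 4, by = 0.5)
  ps <- vapply(ks, category_evidence, numeric(1), post = post)
  expect_true(all(diff(ps) <= 0))
  expect_equal(category_evidence(post, -20), 1, tolerance = 1e-6)
})

test_that("point estimates recover the moments of a known density", {
  mu <- posterior_grids()$mu
  d <- dnorm(mu, 1, 2)
  post <- structure(list(mu_grid = mu, density = d / cfchoice:::trapz(mu, d)),
                    class = "marginal_posterior")
  pe <- point_estimates(post)
  expect_equal(pe$mu_hat, 1, tolerance = 1e-6)
  expect_equal(pe$sigma_hat, 2, tolerance = 1e-3)
})

test_that("posterior spread is smaller for five dots than two at equal
           summaries", {
  for (v in c("flat", "centred")) {
    m2 <- cfchoice:::ng_mixture(2, 1, v)
    m5 <- cfchoice:::ng_mixture(5, 1, v)
    s2 <- cfchoice:::mixture_moments(m2, 2, 2.5)$sd
    s5 <- cfchoice:::mixture_moments(m5, 2, 2.5)$sd
    expect_lt(s5, s2)
  }
})

test_that("fast mixture path agrees with the density objects", {
  cases <- list(list(x = c(-1, 3), sd = 1),
                list(x = c(1.5, -0.5, 2, 4, 0), sd = 0.8))
  for (cs in cases) {
    ds <- dot_summaries(cs$x)
    for (v in c("centred", "flat")) {
      post <- marginal_posterior(cs$x, cs$sd, v)
      pe <- point_estimates(post)
      mix <- cfchoice:::ng_mixture(length(cs$x), cs$sd, v)
      sm <- cfchoice:::mixture_summaries(mix, ds$x_bar, ds$s2, 0.3)
      expect_equal(sm$p_right, category_evidence(post, 0.3),
                   tolerance = 1e-3)
      expect_equal(sm$mu_hat, pe$mu_hat, tolerance = 1e-3)
      expect_equal(sm$sigma_hat, pe$sigma_hat, tolerance = 5e-3)
    }
  }
})

test_that("category evidence and posterior mode are monotone in the
           measured centroid", {
  rm_ <- random_measurements(50, seed = 31)
  xs <- seq(-8, 8, by = 0.25)
  for (v in c("centred", "flat")) {
    mix <- cfchoice:::ng_mixture(2, 1, v)
    for (i in 1:8) {
      s2 <- rm_$s2[i]
      pr <- cfchoice:::mixture_pright(mix, xs, rep(s2, length(xs)), 0.2)
      expect_true(all(diff(pr) > 0))
      md <- cfchoice:::mixture_mode(mix, xs, rep(s2, length(xs)))
      expect_true(all(diff(md) > 0))
    }
  }
})

test_that("mode side and probability side of the criterion concur at an
           unbiased criterion", {
  rm_ <- random_measurements(2000, seed = 77)
  for (v in c("centred", "flat")) {
    for (n in c(2L, 5L)) {
      idx <- rm_$n_dots == n
      mix <- cfchoice:::ng_mixture(n, 1, v)
      sm <- cfchoice:::mixture_summaries(mix, rm_$x_bar[idx],
                                         rm_$s2[idx], 0)
      expect_true(all((sm$mu_hat > 0) == (sm$p_right > 0.5)))
    }
  }
})

test_that("a too-narrow grid is reported, not silently truncated", {
  expect_error(marginal_posterior(c(11, 13), 1, "flat",
                                  grids = posterior_grids(c(-12, 12))),
               "grid too narrow")
})
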