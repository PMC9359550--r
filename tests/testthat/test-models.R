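# The twelve confidence models: registry, evidence, choice probabilities.

test_that("the registry enumerates exactly the twelve legal models", {
  reg <- cfc_models()
  expect_equal(nrow(reg), 12L)
  expect_setequal(reg$id, c(
    "ideal",
    "basic_probability:flat", "basic_probability:centred",
    "probability_difference:flat", "probability_difference:centred",
    "log_probability_ratio:flat", "log_probability_ratio:centred",
    "unscaled_distance:flat", "unscaled_distance:centred",
    "scaled_distance:flat", "scaled_distance:centred",
    "heuristic"))
  expect_equal(reg$n_type2_params[reg$id == "ideal"], 0L)
  expect_equal(reg$n_type2_params[reg$id == "heuristic"], 4L)
  expect_true(all(reg$n_type2_params[!reg$id %in% c("ideal", "heuristic")]
                  == 2L))
})

test_that("illegal model specifications are rejected", {
  expect_error(model_spec("ideal", "flat"), "centred prior only")
  expect_error(model_spec("posterior_entropy"), "unknown confidence metric")
  # parameter/model mismatches
  t1 <- type1_params(1)
  expect_error(simulate_observer(build_schedule(tiny_design(), 1),
                                 "scaled_distance:flat", t1,
                                 type2_params(nu = 5, sigma_conf = 1),
                                 config = smoke_cfg),
               "beta-noise concentration")
  expect_error(simulate_observer(build_schedule(tiny_design(), 1),
                                 "scaled_distance:flat", t1,
                                 type2_params(k2 = 0),
                                 config = smoke_cfg),
               "requires Type 2 parameter")
})

test_that("Type 1 choice probability follows the lapse-mixed decision
           rule", {
  t1_lapse <- type1_params(1, 0, lapse = 0.5)
  expect_equal(type1_choice_prob(c(2, -1, 0.5), t1_lapse, n_sim = 50), 0.5)

  # noiseless limit tracks the centroid sign
  t1_clean <- type1_params(1e-6, 0, 0)
  expect_equal(type1_choice_prob(c(2.5, 3.5), t1_clean, "flat",
                                 n_sim = 50), 1)
  expect_equal(type1_choice_prob(c(-4, -2), t1_clean, "centred",
                                 n_sim = 50), 0)

  # symmetric prior, unbiased criterion: flat and centred variants give
  # the same choice probabilities (same measurement draws via the seed)
  t1 <- type1_params(1, 0, 0)
  for (dots in list(c(1.5, -0.5), c(-2, 0.3, 1, 2, 0))) {
    pf <- type1_choice_prob(dots, t1, "flat", n_sim = 400, seed = 5)
    pc <- type1_choice_prob(dots, t1, "centred", n_sim = 400, seed = 5)
    expect_equal(pf, pc)
  }
})

test_that("confidence evidence matches each model's definition", {
  t1 <- type1_params(1, 0.1, 0)
  x1 <- c(-0.5, 2.5); x2 <- c(1, 3, 2, 4, 0.5)

  ev <- confidence_evidence(model_spec("ideal"), x1, x2, 1, 1, t1,
                            type2_params())
  p1 <- cfchoice:::mixture_summaries(cfchoice:::ng_mixture(2, 1, "centred"),
                                     1, dot_summaries(x1)$s2, 0.1)$p_right
  expect_equal(ev$w1, p1)  # identity: w is the probability-correct
  expect_gte(ev$w2, 0.5)   # consistent response carries the max side

  # reported-side probability drops below 0.5 on a lapse trial
  ev_l <- confidence_evidence(model_spec("ideal"), x1, x2, -1, 1, t1,
                              type2_params(), lapsed1 = TRUE)
  expect_equal(ev_l$w1, 1 - ev$w1)

  # heuristic cue differences, including the inverse-spread sign
  # convention (interval with smaller measured spread gains evidence)
  evh <- confidence_evidence(model_spec("heuristic"), x1, x2, 1, 1, t1,
                             type2_params(beta1 = 1, beta2 = 1,
                                          sigma_conf = 1))
  ds1 <- dot_summaries(x1); ds2 <- dot_summaries(x2)
  expect_equal(evh$d_pos, abs(ds2$x_bar - 0.1) - abs(ds1$x_bar - 0.1))
  expect_equal(evh$d_n, 3)
  expect_equal(evh$d_invsig, 1 / sqrt(ds2$s2) - 1 / sqrt(ds1$s2))

  # with flat prior the heuristic position cue equals the point-estimate
  # distance difference of the unscaled-distance model
  mixf2 <- cfchoice:::ng_mixture(2, 1, "flat")
  mixf5 <- cfchoice:::ng_mixture(5, 1, "flat")
  mu1 <- cfchoice:::mixture_mode(mixf2, ds1$x_bar, ds1$s2)
  mu2 <- cfchoice:::mixture_mode(mixf5, ds2$x_bar, ds2$s2)
  expect_equal(evh$d_pos, abs(mu2 - 0.1) - abs(mu1 - 0.1))
})

test_that("pair-choice probabilities have their analytic forms and
           limits", {
  m_pd <- model_spec("probability_difference:flat")
  t2 <- type2_params(sigma_conf = 0.2, k2 = 0.05)
  args <- list(p1 = 0.7, p2 = 0.9)
  expect_equal(confidence_choice_prob(m_pd, args, t2),
               pnorm((0.9 - 0.7 + 0.05) / 0.2))

  # lapse rate 1/2 forces indifference in every model
  for (id in cfc_models()$id) {
    m <- model_spec(id)
    t2i <- switch(m$metric, ideal = type2_params(),
                  basic_probability = type2_params(nu = 10, k2 = 0.3),
                  heuristic = type2_params(beta1 = 1, beta2 = 0.5,
                                           sigma_conf = 1, k2 = 0.2),
                  type2_params(sigma_conf = 0.5, k2 = 0.3))
    argsi <- list(p1 = 0.7, p2 = 0.95, d1 = 0.5, d2 = 2, delta = 0.8)
    expect_equal(confidence_choice_prob(m, argsi, t2i, lapse = 0.5), 0.5)
  }

  # vanishing confidence noise: hard indicator of the evidence ordering
  m_sc <- model_spec("scaled_distance:flat")
  for (sc in c(1, 0.1, 0.01)) {
    t2s <- type2_params(sigma_conf = sc, k2 = 0)
    p <- confidence_choice_prob(m_sc, list(d1 = 1, d2 = 1.6), t2s)
    expect_gte(p, 0.5)
  }
  expect_equal(confidence_choice_prob(
    m_sc, list(d1 = 1, d2 = 1.6), type2_params(sigma_conf = 0, k2 = 0)), 1)
  expect_equal(confidence_choice_prob(
    m_sc, list(d1 = -1.6, d2 = 1), type2_params(sigma_conf = 0, k2 = 0)), 0)
  expect_equal(confidence_choice_prob(
    m_sc, list(d1 = 1, d2 = -1), type2_params(sigma_conf = 0, k2 = 0)), 0.5)
})

test_that("folded-Gaussian and beta pair-choice quadratures match a
           Monte-Carlo oracle", {
  withr::with_seed(42, {
    nmc <- 200000
    for (cs in list(list(d1 = 0.8, d2 = 1.4, k2 = 0.2, sc = 0.7),
                    list(d1 = -0.3, d2 = 2.5, k2 = -0.4, sc = 1.5))) {
      w1 <- abs(cs$d1 + rnorm(nmc, 0, cs$sc))
      w2 <- abs(cs$d2 + rnorm(nmc, 0, cs$sc))
      mc <- mean(w2 + cs$k2 > w1)
      qd <- cfchoice:::p_choice_folded(cs$d1, cs$d2, cs$k2, cs$sc,
                                       cfchoice:::gauss_hermite(15))
      expect_equal(qd, mc, tolerance = 0.01)
    }
    for (cs in list(list(p1 = 0.8, p2 = 0.95, nu = 15, k2 = 0.1),
                    list(p1 = 0.99, p2 = 0.97, nu = 40, k2 = -0.05))) {
      w1 <- rbeta(nmc, cs$nu * cs$p1, cs$nu * (1 - cs$p1))
      w2 <- rbeta(nmc, cs$nu * cs$p2, cs$nu * (1 - cs$p2))
      mc <- mean(w2 + cs$k2 > w1)
      qd <- cfchoice:::p_choice_beta(cs$p1, cs$p2, cs$nu, cs$k2,
                                     n_quad = 16)
      expect_equal(qd, mc, tolerance = 0.015)
    }
  })
})

test_that("basic-probability choice probabilities converge monotonically
           to the ideal comparison as nu grows", {
  p1 <- 0.82; p2 <- 0.9
  ideal_p <- cfchoice:::p_choice_ideal(p1, p2)   # = 1
  ps <- vapply(c(10, 100, 1000), function(nu) {
    cfchoice:::p_choice_beta(p1, p2, nu, 0, n_quad = 24)
  }, numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_equal(ps[3], ideal_p, tolerance = 0.02)
  # symmetric evidence stays indifferent at any concentration
  expect_equal(cfchoice:::p_choice_beta(0.9, 0.9, 17, 0), 0.5,
               tolerance = 1e-6)
})

test_that("the confidence layer never alters Type 1 behaviour", {
  sch <- build_schedule(tiny_design(reps = 2L), seed = 21)
  t1 <- type1_params(1, 0.05, lapse = 0.03)
  t2s <- list(
    ideal = type2_params(),
    `basic_probability:centred` = type2_params(nu = 10, k2 = 0.2),
    `probability_difference:centred` = type2_params(sigma_conf = 0.1),
    `log_probability_ratio:centred` = type2_params(sigma_conf = 1),
    `unscaled_distance:centred` = type2_params(sigma_conf = 1),
    `scaled_distance:centred` = type2_params(sigma_conf = 1))
  rs <- lapply(names(t2s), function(id) {
    simulate_observer(sch, id, t1, t2s[[id]], seed = 77,
                      config = smoke_cfg)$trials$r
  })
  for (i in 2:length(rs)) expect_identical(rs[[i]], rs[[1]])

  # reproducibility: same seed, same everything
  a <- simulate_observer(sch, "scaled_distance:flat", t1,
                         type2_params(sigma_conf = 1), seed = 5,
                         config = smoke_cfg)
  b <- simulate_observer(sch, "scaled_distance:flat", t1,
                         type2_params(sigma_conf = 1), seed = 5,
                         config = smoke_cfg)
  expect_identical(a$trials, b$trials)
  expect_identical(a$pairs, b$pairs)
})

test_that("scaled and unscaled distance metrics dissociate on matched
           distances with unequal posterior spread", {
  # equal |mu_hat - k1|, sigma_hat differs: unscaled is indifferent,
  # scaled prefers the lower-spread interval
  d <- 1.5; s1 <- 1.8; s2 <- 0.9
  t2 <- type2_params(sigma_conf = 0.5, k2 = 0)
  p_un <- confidence_choice_prob(model_spec("unscaled_distance:flat"),
                                 list(d1 = d, d2 = d), t2)
  p_sc <- confidence_choice_prob(model_spec("scaled_distance:flat"),
                                 list(d1 = d / s1, d2 = d / s2), t2)
  expect_equal(p_un, 0.5, tolerance = 1e-4)
  expect_gt(p_sc, 0.6)
})

test_that("lapse-rate 1/2 yields chance Type 1 accuracy in simulation", {
  sch <- build_schedule(tiny_design(reps = 4L), seed = 31)
  resp <- simulate_observer(sch, "ideal", type1_params(1, 0, 0.5),
                            seed = 9, config = smoke_cfg)
  ok <- sch$mu_cloud != 0
  acc <- mean(resp$trials$r[ok] == sch$true_side[ok])
  expect_equal(acc, 0.5, tolerance = 0.07)
})
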