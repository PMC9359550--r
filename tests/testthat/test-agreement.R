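# N-pass confidence agreement.

fake_pairs <- function(choices_by_pass, pass_id = 1L) {
  # choices_by_pass: list of per-session choice vectors (same pairs)
  np <- length(choices_by_pass[[1]])
  trials <- do.call(rbind, lapply(seq_along(choices_by_pass), function(s) {
    data.frame(session = s, pass_id = pass_id,
               trial = seq_len(2 * np),
               pair = rep(seq_len(np), each = 2),
               interval = rep(1:2, np), r = 1L, lapsed = FALSE)
  }))
  pairs <- do.call(rbind, lapply(seq_along(choices_by_pass), function(s) {
    data.frame(session = s, pass_id = pass_id, pair = seq_len(np),
               conf_choice = choices_by_pass[[s]])
  }))
  structure(list(trials = trials, pairs = pairs), class = "cfc_responses")
}

test_that("agreement counts the most-selected choice per pair", {
  # 4 of 5 passes agree -> 80%
  r5 <- observed_agreement(fake_pairs(list(1L, 1L, 1L, 1L, 2L)))
  expect_equal(r5$agreement, 0.8)
  expect_equal(r5$count, 4L)

  r3 <- observed_agreement(fake_pairs(list(1L, 2L, 1L)))
  expect_equal(r3$agreement, 2 / 3)

  rall <- observed_agreement(fake_pairs(list(2L, 2L, 2L)))
  expect_equal(rall$agreement, 1)

  # even pass counts can tie; recorded as 0.5 and flagged
  r4 <- observed_agreement(fake_pairs(list(1L, 2L, 1L, 2L)))
  expect_equal(r4$agreement, 0.5)
  expect_true(r4$tie)

  # bounds hold on a batch of random response sets
  withr::with_seed(11, {
    ch <- lapply(1:5, function(s) sample(1:2, 20, replace = TRUE))
    rec <- observed_agreement(fake_pairs(ch))
    expect_true(all(rec$agreement >= ceiling(5 / 2) / 5))
    expect_true(all(rec$agreement <= 1))
    expect_true(all(rec$n_interval2 + pmax(rec$count, 5 - rec$count) <= 10))
  })
})

test_that("agreement requires repeated, complete passes", {
  single <- fake_pairs(list(c(1L, 2L)))
  expect_error(observed_agreement(single), "at least 2 sessions")
  broken <- fake_pairs(list(c(1L, 2L), c(1L, 1L)))
  broken$pairs <- broken$pairs[-1, ]
  expect_error(observed_agreement(broken), "mismatched schedules")
})

test_that("predicted agreement ranks the ideal observer highest and
           collapses to the coin-flip limit under huge noise", {
  sch <- build_schedule(experiment_design(reps_per_condition = 2L,
                                          n_sessions = 3L,
                                          pass_pattern = rep(1L, 3)),
                        seed = 5)
  t1 <- type1_params(1, 0, 0.01)
  p_ideal <- predicted_agreement(sch, "ideal", t1, n_sims = 8, seed = 2,
                                 config = smoke_cfg)
  p_noisy <- predicted_agreement(sch, "scaled_distance:flat", t1,
                                 type2_params(sigma_conf = 1.5, k2 = 0),
                                 n_sims = 8, seed = 2, config = smoke_cfg)
  expect_gt(p_ideal$prop_highest, p_noisy$prop_highest)

  # sigma_conf -> infinity: agreement counts approach the binomial(n, 1/2)
  # maximum-count distribution (n = 3: P(max = 3) = 1/4)
  p_coin <- predicted_agreement(sch, "unscaled_distance:flat", t1,
                                type2_params(sigma_conf = 1000, k2 = 0),
                                n_sims = 12, seed = 3, config = smoke_cfg)
  expect_equal(p_coin$prop_highest, 0.25, tolerance = 0.05)
  expect_equal(unname(p_coin$mean_prop["2"]), 0.75, tolerance = 0.05)

  # agreement decreases monotonically with confidence noise
  ph <- vapply(c(0.3, 1, 3), function(sc) {
    predicted_agreement(sch, "scaled_distance:flat", t1,
                        type2_params(sigma_conf = sc, k2 = 0),
                        n_sims = 6, seed = 4,
                        config = smoke_cfg)$prop_highest
  }, numeric(1))
  expect_true(all(diff(ph) < 0))
})

test_that("the observed-vs-predicted comparison is centred when the
           model is true and detects injected cross-pass correlation", {
  sch <- build_schedule(experiment_design(reps_per_condition = 2L,
                                          n_sessions = 3L,
                                          pass_pattern = rep(1L, 3)),
                        seed = 15)
  t1 <- type1_params(1, 0, 0.01)
  t2 <- type2_params(sigma_conf = 1, k2 = 0)
  pred <- predicted_agreement(sch, "unscaled_distance:flat", t1, t2,
                              n_sims = 15, seed = 6, config = smoke_cfg)
  obs_null <- vapply(1:6, function(i) {
    r <- simulate_observer(sch, "unscaled_distance:flat", t1, t2,
                           seed = 100 + i, config = smoke_cfg)
    cfchoice:::agreement_distribution(observed_agreement(r))$prop_highest
  }, numeric(1))
  cmp0 <- agreement_comparison(obs_null, rep(pred$prop_highest, 6))
  expect_lt(abs(mean(cmp0$delta)), 0.1)

  t2_rho <- type2_params(sigma_conf = 1, k2 = 0, rho = 0.8)
  obs_rho <- vapply(1:6, function(i) {
    r <- simulate_observer(sch, "unscaled_distance:flat", t1, t2_rho,
                           seed = 100 + i, config = smoke_cfg)
    cfchoice:::agreement_distribution(observed_agreement(r))$prop_highest
  }, numeric(1))
  cmp1 <- agreement_comparison(obs_rho, rep(pred$prop_highest, 6))
  expect_gt(mean(cmp1$delta), 0)

  # identical observed and predicted: null centre, p ~ 1
  same <- agreement_comparison(rep(0.6, 5), rep(0.6, 5))
  expect_equal(same$p_value, 1)
  expect_error(agreement_comparison(0.5, 0.5), "at least 2")
})
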