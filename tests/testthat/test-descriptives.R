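# Manipulation checks, nested logistic regression, choice heat-maps.

test_that("a random responder scores at chance on every accuracy
           measure", {
  sch <- build_schedule(tiny_design(reps = 4L), seed = 41)
  resp <- simulate_observer(sch, "ideal", type1_params(1, 0, 0.5),
                            seed = 2, config = smoke_cfg)
  mc <- manipulation_checks(sch, resp)
  for (m in c("accuracy_all", "accuracy_chosen", "accuracy_declined")) {
    expect_equal(mc[[m]], 0.5, tolerance = 0.09)
  }
})

test_that("confidence selects the more accurate interval and centroid
           scoring removes external noise", {
  sch <- build_schedule(tiny_design(reps = 6L), seed = 43)
  resp <- simulate_observer(sch, "ideal", type1_params(1, 0, 0.01),
                            seed = 3, config = smoke_cfg)
  mc <- manipulation_checks(sch, resp)
  expect_gt(mc$accuracy_chosen, mc$accuracy_declined)
  expect_gt(mc$accuracy_all_centroid, mc$accuracy_all)
  # exclusion rule: mu_cloud = 0 trials leave the accuracy denominator
  # but stay in the confidence pairs
  expect_equal(mc$n_trials, sum(sch$mu_cloud != 0))
  expect_equal(mc$n_pairs, nrow(resp$pairs))

  grp <- group_manipulation_checks(list(mc, mc))
  expect_equal(grp$mean[grp$measure == "accuracy_all"], mc$accuracy_all)
  expect_equal(grp$sem, rep(0, 6))
})

test_that("nested logistic regression identifies the cue structure of the
           generator", {
  sch <- build_schedule(experiment_design(reps_per_condition = 20L,
                                          n_sessions = 1L,
                                          pass_pattern = 1L), seed = 47)
  t1 <- type1_params(1, 0, 0.01)
  # strong quantity and quality use: the full tier must win
  rh <- simulate_observer(sch, "heuristic", t1,
                          type2_params(beta1 = 1, beta2 = 0.8,
                                       sigma_conf = 0.6, k2 = 0),
                          seed = 5, config = smoke_cfg)
  nl_full <- nested_logistic(sch, rh)
  expect_equal(nl_full$winner, "full")
  expect_gt(nl_full$coef$full["d_n"], 0)

  # coefficient signs probed on a design without near-degenerate 2-dot
  # spreads (1/sigma_emp outliers otherwise dilute the z-scored quality
  # cue)
  sch5 <- build_schedule(experiment_design(dot_counts = c(4L, 8L),
                                           reps_per_condition = 10L,
                                           n_sessions = 1L,
                                           pass_pattern = 1L), seed = 53)
  rh5 <- simulate_observer(sch5, "heuristic", t1,
                           type2_params(beta1 = 1, beta2 = 0.8,
                                        sigma_conf = 0.6, k2 = 0),
                           seed = 9, config = smoke_cfg)
  nl5 <- nested_logistic(sch5, rh5)
  expect_gt(nl5$coef$full["d_n"], 0)
  expect_gt(nl5$coef$full["d_inv"], 0)

  # position-only generator: the basic tier sits within ~2 AICc of the
  # best (the penalty dominates the unused predictors)
  ru <- simulate_observer(sch, "unscaled_distance:flat", t1,
                          type2_params(sigma_conf = 0.8, k2 = 0),
                          seed = 6, config = smoke_cfg)
  nl_basic <- nested_logistic(sch, ru)
  expect_lt(nl_basic$tiers$rel_aicc[nl_basic$tiers$tier == "basic"], 2.5)

  # likelihood is monotone in the predictor set (tier nesting)
  tab <- nl_full$tiers
  expect_lte(tab$nll[tab$tier == "full"],
             min(tab$nll[tab$tier != "full"]) + 1e-8)

  # unbiased generator: indifference at the origin (intercept near 0,
  # so the contour passes close to it)
  expect_lt(abs(nl_full$coef$full["(Intercept)"]), 0.3)
})

test_that("perfect separation triggers the ridge fallback rather than
           diverging", {
  sch <- build_schedule(tiny_design(reps = 2L), seed = 49)
  resp <- simulate_observer(sch, "heuristic", type1_params(1),
                            type2_params(beta1 = 0, beta2 = 0,
                                         sigma_conf = 0.5, k2 = 0),
                            seed = 7, config = smoke_cfg)
  # deterministic rule on one predictor: separable
  pp <- cfchoice:::pair_predictors(sch, resp)
  resp$pairs$conf_choice <- ifelse(pp$d_dist > 0, 2L, 1L)
  nl <- nested_logistic(sch, resp)
  expect_true(nl$penalized)
  expect_true(all(is.finite(unlist(nl$coef))))
})

test_that("choice heat-maps are anti-symmetric under interval relabelling
           and centred at indifference", {
  sch <- build_schedule(tiny_design(reps = 20L), seed = 51)
  resp <- simulate_observer(sch, "heuristic", type1_params(1, 0, 0.01),
                            type2_params(beta1 = 0.7, beta2 = 0.4,
                                         sigma_conf = 1, k2 = 0),
                            seed = 8, config = smoke_cfg)
  hm <- choice_heatmap(sch, resp, limit = 3, n_bins = 5L)
  expect_true(all(hm$equal_n >= 0 & hm$equal_n <= 1, na.rm = TRUE))

  # relabelling the intervals maps each bin (i, j) to (-i, -j) with 1 - p
  flipped <- resp
  flipped$pairs$conf_choice <- 3L - resp$pairs$conf_choice
  sch_f <- sch
  i1 <- sch$interval == 1L
  sch_f$interval[i1] <- 2L
  sch_f$interval[!i1] <- 1L
  hf <- choice_heatmap(sch_f, flipped, limit = 3, n_bins = 5L)
  rot <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))]
  same <- !is.na(hm$equal_n) & !is.na(rot(hf$equal_n))
  expect_equal(hm$equal_n[same], (1 - rot(hf$equal_n))[same])

  # equal stimuli, unbiased observer: the central bin is near 0.5 and the
  # choice rate increases along the position axis
  centre <- (length(hm$centers) + 1) / 2
  colmeans <- rowMeans(hm$equal_n, na.rm = TRUE)  # over d_dist bins
  expect_gt(cor(seq_along(colmeans), colmeans), 0.8)
  expect_equal(hm$equal_n[centre, centre], 0.5, tolerance = 0.25)

  # unequal-N panel: interval 2 always has more dots after the flip
  expect_true(all(!is.na(hm$more_dots_i2) |
                    hm$more_dots_i2_count == 0))
})
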