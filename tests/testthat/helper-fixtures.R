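# Shared fixtures: small designs and cached simulated datasets so the
# costlier objects are built once per test run.

tiny_design <- function(reps = 2L, sessions = 1L,
                        pass = rep(1L, sessions)) {
  experiment_design(reps_per_condition = reps, n_sessions = sessions,
                    pass_pattern = pass)
}

smoke_cfg <- run_config("smoke")

# single-session dataset simulated from a Scaled-Distance observer,
# reused across fitting tests
fixture_env <- new.env()
scaled_fixture <- function() {
  if (is.null(fixture_env$scaled)) {
    sch <- build_schedule(tiny_design(reps = 4L), seed = 101)
    t1 <- type1_params(sigma_dot = 1, k1 = 0, lapse = 0.02)
    t2 <- type2_params(sigma_conf = 1.2, k2 = 0.13)
    resp <- simulate_observer(sch, "scaled_distance:flat", t1, t2,
                              seed = 102, config = smoke_cfg)
    fixture_env$scaled <- list(sch = sch, t1 = t1, t2 = t2, resp = resp)
  }
  fixture_env$scaled
}

# random measurement summaries spanning the stimulus range
random_measurements <- function(n, seed = 1) {
  withr::with_seed(seed, {
    nd <- sample(c(2L, 5L), n, replace = TRUE)
    mu <- sample(c(-4, -2, -1, 0, 1, 2, 4), n, replace = TRUE)
    sig <- sample(c(1.5, 2, 2.5), n, replace = TRUE)
    x_bar <- rnorm(n, mu, sqrt((sig^2 + 1) / nd))
    s2 <- (sig^2 + 1) * rchisq(n, nd - 1) / nd
    list(n_dots = nd, x_bar = x_bar, s2 = pmax(s2, 1e-6))
  })
}
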