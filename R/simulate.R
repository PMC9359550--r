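# Simulated observers: full response sets for a schedule under any of the
# twelve confidence models.

# Draw noisy measurement summaries (x_bar, s2) for a set of trials;
# trials grouped by dot count for vectorisation.
draw_measurements <- function(dot_x_list, n_dots, sigma_dot) {
  nd <- length(dot_x_list)
  x_bar <- numeric(nd)
  s2 <- numeric(nd)
  for (n in unique(n_dots)) {
    idx <- which(n_dots == n)
    D <- matrix(unlist(dot_x_list[idx]), length(idx), n, byrow = TRUE)
    X <- D + matrix(rnorm(length(idx) * n, 0, sigma_dot), length(idx), n)
    xb <- rowMeans(X)
    x_bar[idx] <- xb
    s2[idx] <- rowMeans((X - xb)^2)
  }
  list(x_bar = x_bar, s2 = s2)
}

# Posterior summaries for heterogeneous trials, via per-N mixtures and
# (optionally) lookup tables for the centred variant.
posterior_summary_engine <- function(n_dots_levels, sigma_dot, prior_variant,
                                     k1, config,
                                     prior = normal_gamma_prior()) {
  sg <- config_sigma_grid(config)
  mixes <- lapply(n_dots_levels, function(n) {
    ng_mixture(n, sigma_dot, prior_variant, prior, sg)
  })
  names(mixes) <- as.character(n_dots_levels)
  tabs <- NULL
  if (config$use_tables && prior_variant == "centred") {
    tabs <- lapply(mixes, summary_tables, k1 = k1)
  }
  function(n_dots, x_bar, s2) {
    out <- list(p_right = numeric(length(x_bar)),
                mu_hat = numeric(length(x_bar)),
                sigma_hat = numeric(length(x_bar)))
    for (n in unique(n_dots)) {
      idx <- which(n_dots == n)
      sm <- if (!is.null(tabs)) {
        table_summaries(tabs[[as.character(n)]], x_bar[idx], sqrt(s2[idx]))
      } else {
        mixture_summaries(mixes[[as.character(n)]], x_bar[idx], s2[idx], k1)
      }
      out$p_right[idx] <- sm$p_right
      out$mu_hat[idx] <- sm$mu_hat
      out$sigma_hat[idx] <- sm$sigma_hat
    }
    out
  }
}

# z-score helper used by the Heuristic metric: standardise each cue
# difference across all pairs of the dataset.
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  (x - mean(x)) / s
}

#' Simulate a full observer dataset under one confidence model
#'
#' Runs the complete decision process on every trial of a schedule:
#' fresh sensory noise per pass (stimulus repeats share dots, never
#' measurements), Type 1 decisions with lapses, and the model's
#' confidence forced-choice for every pair with fresh confidence noise.
#' Deterministic given `(schedule, model, parameters, seed)`.
#'
#' `t2$rho > 0` (Gaussian-noise models only) correlates the confidence
#' noise across sessions that share a `pass_id`, an injection experiment
#' used to demonstrate that the agreement analysis detects super-model
#' consistency; the models themselves assume independent noise.
#'
#' @param schedule a [build_schedule()] result.
#' @param model a [model_spec()] (or model id string).
#' @param t1,t2 parameter objects.
#' @param seed master seed for sensory and confidence noise.
#' @param config a [run_config()].
#' @param prior inference prior (centred variants).
#' @return `cfc_responses`: list with `trials` (per-trial Type 1 data:
#'   session, pass_id, trial, pair, interval, r in {-1, +1}, lapsed),
#'   `pairs` (session, pass_id, pair, conf_choice in {1, 2}) and
#'   provenance fields.
#' @export
simulate_observer <- function(schedule, model, t1, t2 = type2_params(),
                              seed = 1L, config = run_config("desk"),
                              prior = normal_gamma_prior()) {
  if (is.character(model)) model <- model_spec(model)
  check_type2(model, t2)
  if (t2$rho > 0 && model$metric %in% c("ideal", "basic_probability")) {
    stop("cross-pass noise correlation is defined for the Gaussian ",
         "confidence-noise models only")
  }
  sch <- as.data.frame(schedule)
  nt <- nrow(sch)

  engine <- posterior_summary_engine(sort(unique(sch$n_dots)), t1$sigma_dot,
                                     model$prior_variant, t1$k1, config,
                                     prior)

  meas <- with_seed(derive_seed(seed, "sensory"),
                    draw_measurements(sch$dot_x, sch$n_dots, t1$sigma_dot))
  sm <- engine(sch$n_dots, meas$x_bar, meas$s2)

  # Type 1: report the more probable category, flipped on lapse trials
  intent <- ifelse(sm$p_right > 0.5, 1L, -1L)
  und <- sm$p_right == 0.5
  lapsed <- with_seed(derive_seed(seed, "t1lapse"), {
    if (any(und)) intent[und] <- sample(c(-1L, 1L), sum(und), replace = TRUE)
    runif(nt) < t1$lapse
  })
  r <- ifelse(lapsed, -intent, intent)

  # pair bookkeeping: interval-1 and interval-2 rows in pair order
  key <- paste(sch$session, sch$pair)
  i1 <- which(sch$interval == 1L)
  i2 <- which(sch$interval == 2L)
  i2 <- i2[match(key[i1], key[i2])]
  np <- length(i1)

  p_rep <- ifelse(r > 0, sm$p_right, 1 - sm$p_right)

  # shared-noise key for the rho injection: position within the repeated
  # stimulus set identifies the "same" pair across passes
  pair_key <- paste(sch$pass_id[i1], sch$pair[i1])
  trial_key <- paste(sch$pass_id, sch$trial)
  mix_noise <- function(fresh, shared_by_key, keys, rho) {
    if (rho == 0) return(fresh)
    sqrt(rho) * shared_by_key[keys] + sqrt(1 - rho) * fresh
  }

  conf2 <- with_seed(derive_seed(seed, "confidence"), {
    rho <- t2$rho
    switch(
      model$metric,
      ideal = {
        w1 <- p_rep[i1]; w2 <- p_rep[i2]
        ties <- w1 == w2
        ch <- w2 > w1
        ch[ties] <- runif(sum(ties)) < 0.5
        ch
      },
      basic_probability = {
        p1 <- clip01(p_rep[i1]); p2 <- clip01(p_rep[i2])
        w1 <- rbeta(np, t2$nu * p1, t2$nu * (1 - p1))
        w2 <- rbeta(np, t2$nu * p2, t2$nu * (1 - p2))
        if (t2$late_sd > 0) {
          w1 <- w1 + rnorm(np, 0, t2$late_sd)
          w2 <- w2 + rnorm(np, 0, t2$late_sd)
        }
        w2 + t2$k2 > w1
      },
      probability_difference = {
        sh <- structure(rnorm(np, 0, t2$sigma_conf), names = pair_key)
        eps <- mix_noise(rnorm(np, 0, t2$sigma_conf), sh, pair_key, rho)
        p_rep[i2] - p_rep[i1] + eps + t2$k2 > 0
      },
      log_probability_ratio = {
        sh <- structure(rnorm(nt, 0, t2$sigma_conf), names = trial_key)
        eps <- mix_noise(rnorm(nt, 0, t2$sigma_conf), sh, trial_key, rho)
        w <- abs(qlogis(clip01(p_rep)) + eps)
        w[i2] + t2$k2 > w[i1]
      },
      unscaled_distance = {
        sh <- structure(rnorm(nt, 0, t2$sigma_conf), names = trial_key)
        eps <- mix_noise(rnorm(nt, 0, t2$sigma_conf), sh, trial_key, rho)
        w <- abs(sm$mu_hat - t1$k1 + eps)
        w[i2] + t2$k2 > w[i1]
      },
      scaled_distance = {
        sh <- structure(rnorm(nt, 0, t2$sigma_conf), names = trial_key)
        eps <- mix_noise(rnorm(nt, 0, t2$sigma_conf), sh, trial_key, rho)
        w <- abs((sm$mu_hat - t1$k1) / sm$sigma_hat + eps)
        w[i2] + t2$k2 > w[i1]
      },
      heuristic = {
        s_emp <- pmax(sqrt(meas$s2), 0.01)
        d_pos <- abs(meas$x_bar[i2] - t1$k1) - abs(meas$x_bar[i1] - t1$k1)
        d_n <- sch$n_dots[i2] - sch$n_dots[i1]
        d_inv <- 1 / s_emp[i2] - 1 / s_emp[i1]
        w_det <- zscore(d_pos) + t2$beta1 * zscore(d_n) +
          t2$beta2 * zscore(d_inv)
        sh <- structure(rnorm(np, 0, t2$sigma_conf), names = pair_key)
        eps <- mix_noise(rnorm(np, 0, t2$sigma_conf), sh, pair_key, rho)
        w_det + eps + t2$k2 > 0
      })
  })

  conf_lapse <- with_seed(derive_seed(seed, "t2lapse"),
                          runif(np) < t1$lapse)
  conf2 <- xor(conf2, conf_lapse)

  trials <- data.frame(session = sch$session, pass_id = sch$pass_id,
                       trial = sch$trial, pair = sch$pair,
                       interval = sch$interval, r = r, lapsed = lapsed)
  pairs <- data.frame(session = sch$session[i1], pass_id = sch$pass_id[i1],
                      pair = sch$pair[i1],
                      conf_choice = ifelse(conf2, 2L, 1L))
  structure(list(trials = trials, pairs = pairs, model = model$id,
                 t1 = t1, t2 = t2, seed = as.integer(seed)),
            class = "cfc_responses")
}

#' @export
print.cfc_responses <- function(x, ...) {
  cat("cfc_responses:", nrow(x$trials), "Type 1 responses,",
      nrow(x$pairs), "confidence choices")
  if (!is.null(x$model)) cat("  (simulated from ", x$model, ")", sep = "")
  cat("\n")
  invisible(x)
}
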