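# Two-step maximum-likelihood fitting.
#
# Step 1: the Type 1 parameters (sigma_dot, k1, lambda) by brute-force
# grid search, with choice probabilities estimated from simulated
# measurement draws (common random numbers across the grid).
# Step 2: each confidence model's Type 2 parameters by bounded
# derivative-free optimisation of a simulated likelihood in which only
# measurements consistent with the observed Type 1 response enter
# (rejection-sampled "measurement bank"), with Type 1 parameters held
# fixed.  Models are compared by AICc.

#' Corrected Akaike information criterion
#'
#' `aicc = 2 nll + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param nll negative log-likelihood at the maximum.
#' @param k number of free parameters.
#' @param n number of fitted responses; must exceed `k + 1`.
#' @export
aicc <- function(nll, k, n) {
  if (n <= k + 1) stop("AICc undefined for n <= k + 1 (n = ", n,
                       ", k = ", k, ")")
  2 * nll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Decision boundaries in x_bar as a function of measured spread, for a
# whole vector of candidate criteria at once and either Type 1 metric
# (probability: p(C=R|X,k1) = 0.5; mode: posterior mode = k1).  Both
# decision variables are increasing in x_bar (tested property), so
# bisection applies; all (s, k1) combinations are bisected in one
# vectorised sweep.
type1_boundary_multi <- function(mix, k1_vec, metric = "probability",
                                 s_grid = seq(0, 9, by = 0.5),
                                 iters = 40L) {
  ns <- length(s_grid); nk <- length(k1_vec)
  if (mix$prior_variant == "flat") {
    return(list(s = s_grid, k1 = k1_vec,
                x = matrix(rep(k1_vec, each = ns), ns, nk)))
  }
  s2 <- rep(s_grid^2, nk)
  kk <- rep(k1_vec, each = ns)
  lo <- pmin(mix$mu0, kk) - 30
  hi <- pmax(mix$mu0, kk) + 30
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    v <- if (metric == "probability") {
      mixture_pright(mix, mid, s2, kk) - 0.5
    } else {
      mixture_mode(mix, mid, s2) - kk
    }
    up <- v < 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  list(s = s_grid, k1 = k1_vec, x = matrix((lo + hi) / 2, ns, nk))
}

decide_by_boundary <- function(boundary, x_bar, s2) {
  xc <- approx(boundary$s, boundary$x,
               xout = pmin(sqrt(s2), max(boundary$s)), rule = 2)$y
  x_bar > xc
}

#' Fit the Type 1 stage by brute-force grid search
#'
#' Fits all four Type 1 observer variants — flat/centred prior crossed
#' with the probability (`p(C=R|X,k1) > 0.5`) and posterior-mode
#' (`mu_hat > k1`) decision metrics — by maximising the Bernoulli
#' likelihood of the observed left/right responses over the parameter
#' grid, with per-trial response probabilities estimated from `n_sim_t1`
#' simulated measurement draws and mixed with the lapse rate.  The same
#' measurement draws are reused across all grid points and variants
#' (common random numbers).  The probability and mode metrics give
#' identical decisions for these posteriors, so their fits coincide; both
#' are computed and returned for verification.
#'
#' @param schedule a [build_schedule()] result.
#' @param responses a `cfc_responses` (or any list with `$trials$r`).
#' @param config a [run_config()]; `config$t1_grid` defines the grid.
#' @param seed RNG seed for the measurement draws.
#' @param prior inference prior for the centred variants.
#' @return list of class `cfc_t1fits` with one `cfc_fit` per variant
#'   (named `flat.probability`, `flat.mode`, `centred.probability`,
#'   `centred.mode`).
#' @export
fit_type1 <- function(schedule, responses, config = run_config("desk"),
                      seed = 1L, prior = normal_gamma_prior(),
                      variants = c("flat", "centred"),
                      metrics = c("probability", "mode")) {
  sch <- as.data.frame(schedule)
  r_obs <- responses$trials$r
  stopifnot(length(r_obs) == nrow(sch))
  grid <- config$t1_grid
  nt <- nrow(sch)
  ns <- config$n_sim_t1
  sg <- config_sigma_grid(config)
  n_levels <- sort(unique(sch$n_dots))
  right <- r_obs > 0

  results <- list()
  for (variant in variants) {
    best <- list()
    for (metric in metrics) {
      best[[metric]] <- list(nll = Inf)
    }
    for (isd in seq_along(grid$sigma_dot)) {
      sd_dot <- grid$sigma_dot[isd]
      # same seed for every grid point: the underlying standard-normal
      # noise is shared (common random numbers), scaled by sigma_dot
      meas <- with_seed(derive_seed(seed, "t1draws"),
                        draw_measurements(rep(sch$dot_x, ns),
                                          rep(sch$n_dots, ns), sd_dot))
      n_rep <- rep(sch$n_dots, ns)
      idx_n <- lapply(n_levels, function(n) which(n_rep == n))
      names(idx_n) <- as.character(n_levels)
      for (metric in metrics) {
        if (variant == "flat") {
          # flat prior: the decision is x_bar > k1 for both metrics
          dec_by_k1 <- lapply(grid$k1, function(k1) meas$x_bar > k1)
        } else {
          dec_by_k1 <- rep(list(logical(nt * ns)), length(grid$k1))
          for (n in n_levels) {
            mix <- ng_mixture(n, sd_dot, variant, prior, sg)
            bd <- type1_boundary_multi(mix, grid$k1, metric)
            idx <- idx_n[[as.character(n)]]
            se <- pmin(sqrt(meas$s2[idx]), max(bd$s))
            for (ik in seq_along(grid$k1)) {
              xc <- approx(bd$s, bd$x[, ik], xout = se, rule = 2)$y
              dec_by_k1[[ik]][idx] <- meas$x_bar[idx] > xc
            }
          }
        }
        for (ik in seq_along(grid$k1)) {
          p_trial <- rowMeans(matrix(dec_by_k1[[ik]], nt, ns))
          for (lam in grid$lambda) {
            p <- clip01(lam + (1 - 2 * lam) * p_trial)
            nll <- -sum(log(ifelse(right, p, 1 - p)))
            if (nll < best[[metric]]$nll) {
              best[[metric]] <- list(nll = nll, sigma_dot = sd_dot,
                                     k1 = grid$k1[ik], lambda = lam)
            }
          }
        }
      }
    }
    for (metric in metrics) {
      b <- best[[metric]]
      edge <- c(sigma_dot = b$sigma_dot %in% range(grid$sigma_dot),
                k1 = b$k1 %in% range(grid$k1) && length(grid$k1) > 1,
                lambda = b$lambda == max(grid$lambda))
      if (any(edge)) {
        warning("Type 1 optimum on the grid boundary (",
                paste(names(edge)[edge], collapse = ", "),
                ") for the ", variant, "/", metric,
                " variant; consider extending t1_grid", call. = FALSE)
      }
      results[[paste(variant, metric, sep = ".")]] <- structure(
        list(model = paste0("type1:", variant, ":", metric),
             variant = variant, metric = metric,
             params = list(sigma_dot = b$sigma_dot, k1 = b$k1,
                           lambda = b$lambda),
             nll = b$nll, k = 3L, n = nt, aicc = aicc(b$nll, 3L, nt)),
        class = "cfc_fit")
    }
  }
  class(results) <- "cfc_t1fits"
  results
}

#' @export
print.cfc_fit <- function(x, ...) {
  cat("cfc_fit:", x$model, "\n")
  if (length(x$params)) {
    cat("  params:", paste(names(x$params), signif(unlist(x$params), 4),
                           sep = " = ", collapse = ", "), "\n")
  }
  cat("  nll =", signif(x$nll, 6), " k =", x$k, " n =", x$n,
      " AICc =", signif(x$aicc, 6), "\n")
  invisible(x)
}

#' @export
print.cfc_t1fits <- function(x, ...) {
  for (f in x) print(f)
  invisible(x)
}

# Convenience: pull Type 1 parameters for a given prior variant out of a
# cfc_t1fits (probability metric; the mode metric matches in practice).
t1_for_variant <- function(t1_fits, variant) {
  f <- t1_fits[[paste(variant, "probability", sep = ".")]]
  if (is.null(f)) f <- t1_fits[[paste(variant, "mode", sep = ".")]]
  type1_params(f$params$sigma_dot, f$params$k1, f$params$lambda)
}

#' Build the response-conditioned measurement bank
#'
#' For every trial, rejection-samples measurement summaries whose Type 1
#' decision (under the fitted parameters, lapse-free branch) reproduces
#' the observed response, retaining `bank_floor` samples per trial.
#' Trials whose response cannot be reproduced within the sampling cap
#' (e.g. lapses on easy stimuli) are flagged; their slots are filled with
#' unconditioned draws and the Type 2 likelihood routes them through the
#' lapse-aware branch.  Trials that reach the floor only partially are
#' completed by resampling their accepted draws.
#'
#' @param schedule,responses the dataset.
#' @param t1 fitted [type1_params()].
#' @param prior_variant `"flat"` or `"centred"`.
#' @param config a [run_config()].
#' @param seed RNG seed.
#' @param prior inference prior.
#' @return `cfc_bank`: list with matrices `x_bar`, `s2`
#'   (trials x bank_floor), `acc_rate`, `flagged`, and the generating
#'   settings.
#' @export
build_measurement_bank <- function(schedule, responses, t1, prior_variant,
                                   config = run_config("desk"), seed = 1L,
                                   prior = normal_gamma_prior()) {
  sch <- as.data.frame(schedule)
  r_obs <- responses$trials$r
  nt <- nrow(sch)
  floor_n <- config$bank_floor
  sg <- config_sigma_grid(config)
  n_levels <- sort(unique(sch$n_dots))
  mixes <- lapply(n_levels, ng_mixture, sigma_dot = t1$sigma_dot,
                  prior_variant = prior_variant, prior = prior,
                  sigma_grid = sg)
  names(mixes) <- as.character(n_levels)
  bounds <- lapply(mixes, type1_boundary, k1 = t1$k1)

  xb_bank <- matrix(NA_real_, nt, floor_n)
  s2_bank <- matrix(NA_real_, nt, floor_n)
  filled <- integer(nt)
  drawn <- integer(nt)

  with_seed(derive_seed(seed, "bank"), {
    todo <- seq_len(nt)
    for (round in seq_len(config$bank_max_rounds)) {
      if (!length(todo)) break
      meas <- draw_measurements(rep(sch$dot_x[todo], floor_n),
                                rep(sch$n_dots[todo], floor_n),
                                t1$sigma_dot)
      n_rep <- rep(sch$n_dots[todo], floor_n)
      dec <- logical(length(todo) * floor_n)
      for (n in n_levels) {
        idx <- which(n_rep == n)
        dec[idx] <- decide_by_boundary(bounds[[as.character(n)]],
                                       meas$x_bar[idx], meas$s2[idx])
      }
      ok <- matrix(dec, length(todo), floor_n) ==
        matrix(r_obs[todo] > 0, length(todo), floor_n)
      xb_m <- matrix(meas$x_bar, length(todo), floor_n)
      s2_m <- matrix(meas$s2, length(todo), floor_n)
      drawn[todo] <- drawn[todo] + floor_n
      for (ii in seq_along(todo)) {
        tr <- todo[ii]
        acc <- which(ok[ii, ])
        if (!length(acc)) next
        take <- acc[seq_len(min(length(acc), floor_n - filled[tr]))]
        sel <- filled[tr] + seq_along(take)
        xb_bank[tr, sel] <- xb_m[ii, take]
        s2_bank[tr, sel] <- s2_m[ii, take]
        filled[tr] <- filled[tr] + length(take)
      }
      todo <- which(filled < floor_n)
    }
    flagged <- filled == 0L
    partial <- which(filled > 0L & filled < floor_n)
    for (tr in partial) {
      sel <- (filled[tr] + 1L):floor_n
      res <- sample(seq_len(filled[tr]), length(sel), replace = TRUE)
      xb_bank[tr, sel] <- xb_bank[tr, res]
      s2_bank[tr, sel] <- s2_bank[tr, res]
    }
    if (any(flagged)) {
      meas <- draw_measurements(rep(sch$dot_x[flagged], floor_n),
                                rep(sch$n_dots[flagged], floor_n),
                                t1$sigma_dot)
      xb_bank[flagged, ] <- matrix(meas$x_bar, sum(flagged), floor_n)
      s2_bank[flagged, ] <- matrix(meas$s2, sum(flagged), floor_n)
    }
    structure(list(x_bar = xb_bank, s2 = s2_bank,
                   acc_rate = filled / pmax(drawn, 1L), flagged = flagged,
                   t1 = t1, prior_variant = prior_variant,
                   floor = floor_n),
              class = "cfc_bank")
  })
}

#' @export
print.cfc_bank <- function(x, ...) {
  cat("cfc_bank:", nrow(x$x_bar), "trials x", x$floor, "retained draws (",
      x$prior_variant, "prior )\n")
  cat("  flagged (response-inconsistent) trials:", sum(x$flagged), "\n")
  cat("  median acceptance rate:", signif(median(x$acc_rate), 3), "\n")
  invisible(x)
}

# Parameter box (fitting scale) per metric; nu and sigma_conf live on
# log10 scale.
type2_bounds <- function(metric) {
  free <- type2_free_params(metric)
  lo <- c(nu = -3, sigma_conf = -3, k2 = -5, beta1 = -10, beta2 = -10)
  hi <- c(nu = 3, sigma_conf = 3, k2 = 5, beta1 = 10, beta2 = 10)
  list(names = free, lo = lo[free], hi = hi[free])
}

par_to_type2 <- function(metric, par, late_sd = 0) {
  p <- as.list(par)
  names(p) <- type2_free_params(metric)
  if (!is.null(p$nu)) p$nu <- 10^p$nu
  if (!is.null(p$sigma_conf)) p$sigma_conf <- 10^p$sigma_conf
  do.call(type2_params, c(p, list(late_sd = late_sd)))
}

# Precompute all per-draw evidence ingredients a Type 2 likelihood needs.
type2_precompute <- function(model, schedule, responses, t1, bank, config,
                             prior = normal_gamma_prior()) {
  sch <- as.data.frame(schedule)
  nb <- min(config$nb_eval, bank$floor)
  xb <- bank$x_bar[, seq_len(nb), drop = FALSE]
  s2 <- bank$s2[, seq_len(nb), drop = FALSE]
  nt <- nrow(sch)
  engine <- posterior_summary_engine(sort(unique(sch$n_dots)),
                                     t1$sigma_dot, model$prior_variant,
                                     t1$k1, config, prior)
  n_rep <- rep(sch$n_dots, nb)
  sm <- engine(n_rep, as.vector(xb), as.vector(s2))
  r_rep <- rep(responses$trials$r, nb)
  p_rep <- ifelse(r_rep > 0, sm$p_right, 1 - sm$p_right)

  key <- paste(sch$session, sch$pair)
  i1 <- which(sch$interval == 1L)
  i2 <- which(sch$interval == 2L)
  i2 <- i2[match(key[i1], key[i2])]
  np <- length(i1)
  idx1 <- as.vector(outer(i1, (seq_len(nb) - 1L) * nt, "+"))
  idx2 <- as.vector(outer(i2, (seq_len(nb) - 1L) * nt, "+"))

  out <- list(np = np, nb = nb, y2 = responses$pairs$conf_choice == 2L,
              lambda = t1$lapse)
  if (model$metric %in% c("ideal", "probability_difference")) {
    out$p1 <- p_rep[idx1]; out$p2 <- p_rep[idx2]
  } else if (model$metric == "basic_probability") {
    out$p1 <- p_rep[idx1]; out$p2 <- p_rep[idx2]
    # beta-noise likelihoods are evaluated through per-draw quantile
    # ladders computed exactly at each probed nu (cached); midpoint
    # levels carry the w2 average, the extra tail levels only anchor the
    # piecewise-linear CDF of w1
    L <- max(config$n_quad, 12L)
    u_mid <- (seq_len(L) - 0.5) / L
    out$u_all <- sort(unique(c(1e-4, 1e-3, 1e-2, u_mid,
                               1 - 1e-2, 1 - 1e-3, 1 - 1e-4)))
    out$u_interior <- match(u_mid, out$u_all)
    out$pc <- pmin(pmax(p_rep, 1e-6), 1 - 1e-6)
    out$idx1 <- idx1
    out$idx2 <- idx2
    out$ladder_cache <- new.env(parent = emptyenv())
  } else if (model$metric == "log_probability_ratio") {
    lpr <- qlogis(clip01(p_rep))
    out$d1 <- lpr[idx1]; out$d2 <- lpr[idx2]
  } else if (model$metric == "unscaled_distance") {
    d <- sm$mu_hat - t1$k1
    out$d1 <- d[idx1]; out$d2 <- d[idx2]
  } else if (model$metric == "scaled_distance") {
    d <- (sm$mu_hat - t1$k1) / sm$sigma_hat
    out$d1 <- d[idx1]; out$d2 <- d[idx2]
  } else if (model$metric == "heuristic") {
    pos <- abs(as.vector(xb) - t1$k1)
    invs <- 1 / pmax(sqrt(as.vector(s2)), 0.01)
    ndot <- n_rep
    out$z_pos <- zscore(pos[idx2] - pos[idx1])
    out$z_n <- zscore(ndot[idx2] - ndot[idx1])
    out$z_inv <- zscore(invs[idx2] - invs[idx1])
  }
  out
}

# Negative log-likelihood of the confidence choices for one model.
type2_nll <- function(model, pre, t2, config) {
  p <- switch(model$metric,
    ideal = p_choice_ideal(pre$p1, pre$p2),
    basic_probability = {
      key <- sprintf("nu%.8g", t2$nu)
      qn <- pre$ladder_cache[[key]]
      if (is.null(qn)) {
        a <- t2$nu * pre$pc; b <- t2$nu * (1 - pre$pc)
        qn <- vapply(pre$u_all, function(u) {
          suppressWarnings(qbeta(u, a, b))
        }, numeric(length(pre$pc)))
        pre$ladder_cache[[key]] <- qn
      }
      .beta_pair_prob_tab(qn[pre$idx1, , drop = FALSE],
                          qn[pre$idx2, , drop = FALSE],
                          pre$u_all, pre$u_interior, t2$k2)
    },
    probability_difference = p_choice_gaussian_diff(pre$p2 - pre$p1, t2$k2,
                                                    t2$sigma_conf),
    log_probability_ratio = ,
    unscaled_distance = ,
    scaled_distance = p_choice_folded(pre$d1, pre$d2, t2$k2, t2$sigma_conf,
                                      gauss_hermite(config$gh_nodes)),
    heuristic = p_choice_gaussian_diff(
      pre$z_pos + t2$beta1 * pre$z_n + t2$beta2 * pre$z_inv,
      t2$k2, t2$sigma_conf))
  p_pair <- rowMeans(matrix(p, pre$np, pre$nb))
  p_resp <- clip01(pre$lambda + (1 - 2 * pre$lambda) * p_pair)
  -sum(log(ifelse(pre$y2, p_resp, 1 - p_resp)))
}

#' Fit one confidence model's Type 2 parameters
#'
#' Maximises the Bernoulli likelihood of the interval choices under the
#' model's analytic pair-choice probabilities, averaged over the
#' response-conditioned measurement bank, holding the Type 1 parameters
#' fixed.  The simulated likelihood is deterministic (frozen bank,
#' quadrature noise integrals), so a bounded derivative-free simplex
#' search with Latin-hypercube multistarts is used.  The Ideal model has
#' no free parameters and is evaluated once.
#'
#' @param model a [model_spec()] or model id.
#' @param schedule,responses the dataset.
#' @param t1 fitted [type1_params()] for the model's prior variant.
#' @param bank matching [build_measurement_bank()].
#' @param config a [run_config()].
#' @param seed seed for the multistart points.
#' @param prior inference prior.
#' @return a `cfc_fit` with fields `model`, `params`, `nll`, `k`, `n`,
#'   `aicc`.
#' @export
fit_type2 <- function(model, schedule, responses, t1, bank,
                      config = run_config("desk"), seed = 1L,
                      prior = normal_gamma_prior()) {
  if (is.character(model)) model <- model_spec(model)
  if (bank$prior_variant != model$prior_variant) {
    stop("bank was built for the ", bank$prior_variant,
         " prior variant but model '", model$id, "' uses ",
         model$prior_variant)
  }
  pre <- type2_precompute(model, schedule, responses, t1, bank, config,
                          prior)
  np <- pre$np
  bounds <- type2_bounds(model$metric)
  k <- length(bounds$names)

  if (k == 0L) {
    nll <- type2_nll(model, pre, type2_params(), config)
    return(structure(list(model = model$id, params = list(), nll = nll,
                          k = 0L, n = np, aicc = aicc(nll, 0L, np),
                          t1 = t1),
                     class = "cfc_fit"))
  }

  if (model$metric == "basic_probability") {
    # the beta-noise likelihood rebuilds its quantile ladders whenever nu
    # changes, so nu is profiled on a log grid (exact ladders per knot,
    # cached) with Brent's method on the interval bias inside each knot,
    # then refined by a quadratic step through the three best knots --
    # bounded and derivative-free like the simplex path
    lognu_grid <- c(-3, -1, seq(0, 3, by = 0.5))
    # the k2 likelihood can be sharply peaked on the probability scale,
    # so each knot scans a k2 grid; only the winning knot gets polished
    ks <- sort(c(seq(-0.75, 0.75, by = 0.15), -5, -2.5, -1.5, 1.5,
                 2.5, 5))
    nll_at <- function(lognu, k2) {
      type2_nll(model, pre, type2_params(nu = 10^lognu, k2 = k2), config)
    }
    prof <- function(lognu) {
      vals <- vapply(ks, nll_at, numeric(1), lognu = lognu)
      j <- which.min(vals)
      list(nll = vals[j], k2 = ks[j], j = j)
    }
    polish <- function(lognu, j0) {
      lo <- ks[max(j0 - 1, 1)]
      hi <- ks[min(j0 + 1, length(ks))]
      op <- optimize(nll_at, c(lo, hi), lognu = lognu, tol = 1e-3)
      list(nll = op$objective, k2 = op$minimum)
    }
    fits <- lapply(lognu_grid, prof)
    nlls <- vapply(fits, `[[`, numeric(1), "nll")
    j <- which.min(nlls)
    best_lognu <- lognu_grid[j]
    best_fit <- polish(best_lognu, fits[[j]]$j)
    if (best_fit$nll > nlls[j]) best_fit <- fits[[j]]
    if (j > 1 && j < length(lognu_grid)) {
      # quadratic step through the three best knots, then re-polish
      den <- nlls[j - 1] - 2 * nlls[j] + nlls[j + 1]
      if (den > 0) {
        step <- 0.5 * (nlls[j - 1] - nlls[j + 1]) / den *
          (lognu_grid[j + 1] - lognu_grid[j])
        cand <- min(max(best_lognu + step, -3), 3)
        pc <- prof(cand)
        pc2 <- polish(cand, pc$j)
        if (pc2$nll > pc$nll) pc2 <- pc
        if (pc2$nll < best_fit$nll) {
          best_lognu <- cand
          best_fit <- pc2
        }
      }
    }
    est <- list(nu = 10^best_lognu, k2 = best_fit$k2)
    return(structure(list(model = model$id, params = est,
                          nll = best_fit$nll, k = k, n = np,
                          aicc = aicc(best_fit$nll, k, np), t1 = t1,
                          convergence = 0L, n_starts = length(lognu_grid)),
                     class = "cfc_fit"))
  }

  obj <- function(u) {
    par <- bounds$lo + (bounds$hi - bounds$lo) * plogis(u)
    t2 <- par_to_type2(model$metric, par)
    v <- type2_nll(model, pre, t2, config)
    if (!is.finite(v)) 1e10 else v
  }

  starts <- with_seed(derive_seed(seed, "t2start", model$id), {
    s <- lhs::randomLHS(config$n_multistart, k)
    s[1, ] <- 0.5  # always include the box centre
    qlogis(0.05 + 0.9 * s)
  })
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- optim(starts[i, ], obj, method = "Nelder-Mead",
                 control = list(maxit = config$optim_maxit,
                                reltol = 1e-5))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  par <- bounds$lo + (bounds$hi - bounds$lo) * plogis(best$par)
  t2_hat <- par_to_type2(model$metric, par)
  est <- t2_hat[bounds$names]
  structure(list(model = model$id, params = est, nll = best$value, k = k,
                 n = np, aicc = aicc(best$value, k, np), t1 = t1,
                 convergence = best$convergence,
                 n_starts = nrow(starts)),
            class = "cfc_fit")
}

#' Fit all twelve confidence models to one dataset
#'
#' Convenience wrapper: fits the Type 1 stage (both prior variants),
#' builds one measurement bank per variant, and fits every model in the
#' registry.
#'
#' @param schedule,responses the dataset.
#' @param config a [run_config()].
#' @param seed master seed.
#' @param models character vector of model ids (default: all twelve).
#' @param t1_fits optionally, a precomputed [fit_type1()] result.
#' @return list with `t1_fits`, `fits` (named list of `cfc_fit`) and
#'   `comparison` (see [compare_fits()]).
#' @export
fit_all_models <- function(schedule, responses, config = run_config("desk"),
                           seed = 1L, models = cfc_models()$id,
                           t1_fits = NULL) {
  if (is.null(t1_fits)) {
    t1_fits <- fit_type1(schedule, responses, config, seed)
  }
  variants <- unique(vapply(models, function(id) model_spec(id)$prior_variant,
                            character(1)))
  banks <- list()
  t1s <- list()
  for (v in variants) {
    t1s[[v]] <- t1_for_variant(t1_fits, v)
    banks[[v]] <- build_measurement_bank(schedule, responses, t1s[[v]], v,
                                         config, seed)
  }
  fits <- list()
  for (id in models) {
    m <- model_spec(id)
    fits[[id]] <- fit_type2(m, schedule, responses,
                            t1s[[m$prior_variant]],
                            banks[[m$prior_variant]], config, seed)
  }
  list(t1_fits = t1_fits, fits = fits, comparison = compare_fits(fits))
}

#' Compare fitted models by AICc
#'
#' @param fits list of `cfc_fit` objects for one observer.
#' @return data frame with one row per model: `model`, `nll`, `k`, `n`,
#'   `aicc` and `rel_aicc` (difference from the observer's best model,
#'   minimum exactly 0), ordered by `aicc`.
#' @export
compare_fits <- function(fits) {
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    nll = vapply(fits, `[[`, numeric(1), "nll"),
    k = vapply(fits, `[[`, integer(1), "k"),
    n = vapply(fits, `[[`, numeric(1), "n"),
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    row.names = NULL)
  tab$rel_aicc <- tab$aicc - min(tab$aicc)
  tab[order(tab$aicc), ]
}

#' Group-level model comparison
#'
#' @param comparisons list of per-observer [compare_fits()] tables.
#' @return data frame per model: mean relative AICc across observers and
#'   the number of observers best fit (`rel_aicc == 0`); best-fit counts
#'   sum to the number of observers.
#' @export
group_comparison <- function(comparisons) {
  all_models <- sort(unique(unlist(lapply(comparisons, `[[`, "model"))))
  mean_rel <- vapply(all_models, function(m) {
    mean(vapply(comparisons, function(cmp) cmp$rel_aicc[cmp$model == m],
                numeric(1)))
  }, numeric(1))
  n_best <- vapply(all_models, function(m) {
    sum(vapply(comparisons, function(cmp) cmp$model[which.min(cmp$aicc)] == m,
               logical(1)))
  }, integer(1))
  out <- data.frame(model = all_models, mean_rel_aicc = mean_rel,
                    n_best = n_best, row.names = NULL)
  out[order(out$mean_rel_aicc), ]
}
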