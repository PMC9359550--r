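# The four Type 1 decision models and the twelve Type 2 confidence models.
#
# All twelve confidence models share the same Type 1 front end (noisy dot
# measurements, posterior inference, criterion k1, lapse rate) and differ
# only in the confidence decision variable compared across the two
# intervals of a pair:
#
#   Probability metrics      ideal, basic_probability (early beta noise),
#                            probability_difference (late Gaussian noise),
#                            log_probability_ratio
#   Evidence-Strength (DFC)  unscaled_distance, scaled_distance
#   Heuristic                weighted stimulus cues (position, dot count,
#                            inverse spread)
#
# Prior variants (flat/centred) double every base model except the Ideal
# observer (centred only, by definition) and the Heuristic model (no
# posterior involved), giving twelve models.

#' Enumerate the twelve confidence models
#'
#' @return data frame with columns `id`, `metric`, `prior_variant` and
#'   `n_type2_params` (free Type 2 parameters: Ideal 0, probability and
#'   distance models 2, Heuristic 4).
#' @export
cfc_models <- function() {
  base <- data.frame(
    metric = c("ideal", rep(c("basic_probability", "probability_difference",
                              "log_probability_ratio", "unscaled_distance",
                              "scaled_distance"), each = 2), "heuristic"),
    prior_variant = c("centred", rep(c("flat", "centred"), 5), "flat"),
    stringsAsFactors = FALSE)
  base$prior_variant[base$metric == "heuristic"] <- NA
  base$id <- ifelse(is.na(base$prior_variant), base$metric,
                    ifelse(base$metric == "ideal", "ideal",
                           paste0(base$metric, ":", base$prior_variant)))
  base$n_type2_params <- c(0L, rep(2L, 10), 4L)
  base[c("id", "metric", "prior_variant", "n_type2_params")]
}

#' Specify one confidence model
#'
#' @param metric one of `"ideal"`, `"basic_probability"`,
#'   `"probability_difference"`, `"log_probability_ratio"`,
#'   `"unscaled_distance"`, `"scaled_distance"`, `"heuristic"`, or a full
#'   id such as `"scaled_distance:flat"`.
#' @param prior_variant `"flat"` or `"centred"`; ignored for the
#'   Heuristic model, must be `"centred"` (or omitted) for the Ideal
#'   observer.
#' @return object of class `cfc_model`.
#' @export
model_spec <- function(metric, prior_variant = NULL) {
  if (grepl(":", metric, fixed = TRUE)) {
    parts <- strsplit(metric, ":", fixed = TRUE)[[1]]
    metric <- parts[1]
    prior_variant <- parts[2]
  }
  metrics <- unique(cfc_models()$metric)
  if (!metric %in% metrics) {
    stop("unknown confidence metric '", metric, "'; see cfc_models()")
  }
  if (metric == "ideal") {
    if (!is.null(prior_variant) && prior_variant != "centred") {
      stop("the Ideal confidence observer is defined with the centred ",
           "prior only")
    }
    prior_variant <- "centred"
  } else if (metric == "heuristic") {
    # the heuristic metric reads stimulus cues, not the posterior; its
    # Type 1 stage uses the flat-prior (normalised likelihood) observer
    prior_variant <- "flat"
  } else {
    if (is.null(prior_variant)) {
      stop("prior_variant (flat/centred) required for metric '", metric, "'")
    }
    prior_variant <- match.arg(prior_variant, c("flat", "centred"))
  }
  id <- if (metric %in% c("ideal", "heuristic")) metric else
    paste0(metric, ":", prior_variant)
  structure(list(id = id, metric = metric, prior_variant = prior_variant),
            class = "cfc_model")
}

#' @export
print.cfc_model <- function(x, ...) {
  cat("cfc_model:", x$id, "\n")
  invisible(x)
}

#' Type 1 (perceptual stage) parameters
#'
#' @param sigma_dot per-dot sensory noise SD (deg), `> 0`.
#' @param k1 perceptual decision criterion (deg).
#' @param lapse lapse rate, in `[0, 0.5]`.
#' @export
type1_params <- function(sigma_dot, k1 = 0, lapse = 0) {
  stopifnot(sigma_dot > 0, lapse >= 0, lapse <= 0.5)
  structure(list(sigma_dot = sigma_dot, k1 = k1, lapse = lapse),
            class = "cfc_type1")
}

#' Type 2 (confidence stage) parameters
#'
#' Only the parameters a model actually uses may be supplied: `nu`
#' (beta-noise concentration, Basic-Probability only), `sigma_conf`
#' (additive Gaussian confidence noise, all other noisy models), `k2`
#' (confidence interval bias), `beta1`/`beta2` (Heuristic weights on the
#' dot-count and inverse-spread differences).  `late_sd` adds Gaussian
#' noise after the beta draw in the Basic-Probability model (used for the
#' 1%-late-noise agreement variant) and `rho` injects cross-pass
#' correlation into the confidence noise (agreement experiments only;
#' the models themselves assume independent noise across passes).
#'
#' @param nu,sigma_conf,k2,beta1,beta2,late_sd,rho see Description.
#' @export
type2_params <- function(nu = NULL, sigma_conf = NULL, k2 = 0,
                         beta1 = NULL, beta2 = NULL, late_sd = 0, rho = 0) {
  if (!is.null(nu)) stopifnot(nu > 0)
  if (!is.null(sigma_conf)) stopifnot(sigma_conf >= 0)
  stopifnot(rho >= 0, rho <= 1, late_sd >= 0)
  structure(list(nu = nu, sigma_conf = sigma_conf, k2 = k2,
                 beta1 = beta1, beta2 = beta2, late_sd = late_sd, rho = rho),
            class = "cfc_type2")
}

# Free Type 2 parameter names per metric (fitting order).
type2_free_params <- function(metric) {
  switch(metric,
         ideal = character(0),
         basic_probability = c("nu", "k2"),
         probability_difference = c("sigma_conf", "k2"),
         log_probability_ratio = c("sigma_conf", "k2"),
         unscaled_distance = c("sigma_conf", "k2"),
         scaled_distance = c("sigma_conf", "k2"),
         heuristic = c("beta1", "beta2", "sigma_conf", "k2"),
         stop("unknown metric '", metric, "'"))
}

check_type2 <- function(model, t2) {
  need <- type2_free_params(model$metric)
  for (p in need) {
    if (is.null(t2[[p]])) {
      stop("model '", model$id, "' requires Type 2 parameter '", p, "'")
    }
  }
  if (model$metric != "basic_probability" && !is.null(t2$nu)) {
    stop("'nu' is the beta-noise concentration of the Basic-Probability ",
         "model; it has no meaning for '", model$id, "'")
  }
  invisible(TRUE)
}

#' Type 1 choice probability for one stimulus
#'
#' Monte-Carlo estimate of the probability of responding "right": noisy
#' measurements of the displayed dots are simulated, the category decision
#' applied (`p(C = R | X, k1) > p(C = L | X, k1)`), and the result mixed
#' with the lapse rate (`p = lambda + (1 - 2 lambda) p_decide`).
#'
#' @param dot_x displayed horizontal dot positions (deg).
#' @param t1 a [type1_params()].
#' @param prior_variant `"flat"` or `"centred"`.
#' @param n_sim number of measurement draws.
#' @param seed RNG seed.
#' @param prior,sigma_grid inference settings.
#' @return probability of a "right" response.
#' @export
type1_choice_prob <- function(dot_x, t1, prior_variant = "centred",
                              n_sim = 1000L, seed = 1L,
                              prior = normal_gamma_prior(),
                              sigma_grid = posterior_grids()$sigma) {
  n <- length(dot_x)
  mix <- ng_mixture(n, t1$sigma_dot, prior_variant, prior, sigma_grid)
  dec <- with_seed(seed, {
    X <- matrix(dot_x, n_sim, n, byrow = TRUE) +
      matrix(rnorm(n_sim * n, 0, t1$sigma_dot), n_sim, n)
    xb <- rowMeans(X)
    s2 <- rowMeans((X - xb)^2)
    type1_decide(mix, xb, s2, t1$k1)
  })
  t1$lapse + (1 - 2 * t1$lapse) * mean(dec)
}

# ---- analytic pair-choice probabilities (before lapse mixing) ----------

# Late-Gaussian difference rule: p(w + k2 > 0), w = delta + eps.
p_choice_gaussian_diff <- function(delta, k2, sigma_conf) {
  if (sigma_conf == 0) {
    return((delta + k2 > 0) + 0.5 * (delta + k2 == 0))
  }
  pnorm((delta + k2) / sigma_conf)
}

# Folded-Gaussian rule: p(|d2 + e2| + k2 > |d1 + e1|), e ~ N(0, s^2).
# Gauss-Hermite over the interval-1 variable.
p_choice_folded <- function(d1, d2, k2, sigma_conf,
                            gh = gauss_hermite(15L)) {
  if (sigma_conf == 0) {
    lhs <- abs(d2) + k2
    return((lhs > abs(d1)) + 0.5 * (lhs == abs(d1)))
  }
  n <- max(length(d1), length(d2))
  .folded_pair_prob(rep_len(as.numeric(d1), n), rep_len(as.numeric(d2), n),
                    k2, sigma_conf, gh$x, gh$w)
}

# reference implementation in plain R, kept for cross-checking the
# compiled kernel
p_choice_folded_r <- function(d1, d2, k2, sigma_conf,
                              gh = gauss_hermite(15L)) {
  if (sigma_conf == 0) return(p_choice_folded(d1, d2, k2, sigma_conf))
  p <- 0
  for (m in seq_along(gh$x)) {
    # t <= 0 collapses to survival 1 automatically via pmax
    t_ <- pmax(abs(d1 + sqrt(2) * sigma_conf * gh$x[m]) - k2, 0)
    surv <- 1 - (pnorm((t_ - d2) / sigma_conf) -
                   pnorm((-t_ - d2) / sigma_conf))
    p <- p + gh$w[m] * surv
  }
  p
}

# Beta-noise rule of the Basic-Probability model:
# p(w2 + k2 > w1), w_i ~ Beta(nu p_i, nu (1 - p_i)); evaluated on a fixed
# quantile grid of w2 (deterministic, suitable for derivative-free
# optimisation).  late_sd > 0 adds Gaussian noise after the beta draw, in
# which case the comparison is done by Gauss-Hermite over the late noise
# of the difference.
p_choice_beta <- function(p1, p2, nu, k2, n_quad = 16L, late_sd = 0) {
  p1 <- clip01(p1); p2 <- clip01(p2)
  u <- (seq_len(n_quad) - 0.5) / n_quad
  a1 <- nu * p1; b1 <- nu * (1 - p1)
  a2 <- nu * p2; b2 <- nu * (1 - p2)
  if (late_sd == 0) {
    n <- max(length(p1), length(p2))
    return(.beta_pair_prob(rep_len(as.numeric(p1), n),
                           rep_len(as.numeric(p2), n), nu, k2, u))
  }
  p <- 0
  # with late noise: w_i = beta_i + eps_i; difference noise SD late_sd*sqrt(2)
  for (l in seq_len(n_quad)) {
    q2 <- suppressWarnings(qbeta(u[l], a2, b2))
    for (l1 in seq_len(n_quad)) {
      q1 <- suppressWarnings(qbeta(u[l1], a1, b1))
      p <- p + pnorm((q2 - q1 + k2) / (late_sd * sqrt(2)))
    }
  }
  p / n_quad^2
}

# Ideal rule: noiseless comparison of probability-correct.
p_choice_ideal <- function(p1, p2) {
  (p2 > p1) + 0.5 * (p2 == p1)
}

#' Confidence evidence for one stimulus pair
#'
#' Computes the model's confidence decision variable(s) from the noisy
#' measurements of the two intervals, conditioned on the realised Type 1
#' responses.  Evidence-noise draws use the supplied seed.  For the
#' interval-wise models the result holds `w1`/`w2`; for the difference
#' models (`probability_difference`, `heuristic`) a single `w`.
#'
#' For the Heuristic model the three cue differences are returned
#' unstandardised (`z = FALSE` equivalent): z-scoring is defined across
#' all pairs of a dataset, so it lives in [simulate_observer()] and the
#' fitting routines, not here.
#'
#' @param model a [model_spec()].
#' @param x1,x2 noisy measurement vectors for intervals 1 and 2.
#' @param r1,r2 realised Type 1 responses (+1 right, -1 left).
#' @param t1,t2 parameter objects.
#' @param lapsed1,lapsed2 whether the Type 1 response was a lapse (the
#'   observer is aware of lapses: probability evidence uses the reported,
#'   i.e. unintended, side).
#' @param seed RNG seed for the evidence noise.
#' @param prior,sigma_grid inference settings.
#' @export
confidence_evidence <- function(model, x1, x2, r1, r2, t1, t2,
                                lapsed1 = FALSE, lapsed2 = FALSE,
                                seed = 1L, prior = normal_gamma_prior(),
                                sigma_grid = posterior_grids()$sigma) {
  check_type2(model, t2)
  ev <- function(x) {
    mix <- ng_mixture(length(x), t1$sigma_dot, model$prior_variant, prior,
                      sigma_grid)
    ds <- dot_summaries(x)
    mixture_summaries(mix, ds$x_bar, ds$s2, t1$k1)
  }
  s1 <- ev(x1); s2_ <- ev(x2)
  # probability that the *reported* side is correct (min side on lapses)
  p_rep <- function(sm, r) if (r > 0) sm$p_right else 1 - sm$p_right
  p1 <- p_rep(s1, r1); p2 <- p_rep(s2_, r2)
  with_seed(seed, switch(
    model$metric,
    ideal = list(w1 = p1, w2 = p2),
    basic_probability = list(
      w1 = rbeta(1, t2$nu * clip01(p1), t2$nu * (1 - clip01(p1))) +
        rnorm(1, 0, t2$late_sd),
      w2 = rbeta(1, t2$nu * clip01(p2), t2$nu * (1 - clip01(p2))) +
        rnorm(1, 0, t2$late_sd)),
    probability_difference = list(
      w = p2 - p1 + rnorm(1, 0, t2$sigma_conf)),
    log_probability_ratio = list(
      w1 = abs(qlogis(clip01(p1)) + rnorm(1, 0, t2$sigma_conf)),
      w2 = abs(qlogis(clip01(p2)) + rnorm(1, 0, t2$sigma_conf))),
    unscaled_distance = list(
      w1 = abs(s1$mu_hat - t1$k1 + rnorm(1, 0, t2$sigma_conf)),
      w2 = abs(s2_$mu_hat - t1$k1 + rnorm(1, 0, t2$sigma_conf))),
    scaled_distance = list(
      w1 = abs((s1$mu_hat - t1$k1) / s1$sigma_hat +
                 rnorm(1, 0, t2$sigma_conf)),
      w2 = abs((s2_$mu_hat - t1$k1) / s2_$sigma_hat +
                 rnorm(1, 0, t2$sigma_conf))),
    heuristic = {
      ds1 <- dot_summaries(x1); ds2 <- dot_summaries(x2)
      list(d_pos = abs(ds2$x_bar - t1$k1) - abs(ds1$x_bar - t1$k1),
           d_n = length(x2) - length(x1),
           # defined as interval 2 minus interval 1 so that the interval
           # with the SMALLER measured spread gains evidence when beta2 > 0
           # (reconciling the printed minus sign with the fitted positive
           # coefficients)
           d_invsig = 1 / pmax(sqrt(ds2$s2), 0.01) -
             1 / pmax(sqrt(ds1$s2), 0.01))
    }))
}

#' Probability of choosing Interval 2 as more confident
#'
#' Analytic (or quadrature) pair-choice probability for fixed
#' deterministic evidence inputs, mixed with the Type 2 lapse per the
#' forced-choice decision rule `p = lambda + (1 - 2 lambda) p(rule)`.
#' Vectorised over pairs.
#'
#' @param model a [model_spec()].
#' @param args list of deterministic evidence inputs: `p1`,`p2` for the
#'   probability metrics, `d1`,`d2` (signed distances or log odds) for the
#'   folded-noise metrics, `delta` for the difference metrics (already
#'   weighted and z-scored for the Heuristic model).
#' @param t2 a [type2_params()].
#' @param lapse Type 2 lapse rate (fixed from the Type 1 fit).
#' @param gh_nodes,n_quad quadrature resolution.
#' @export
confidence_choice_prob <- function(model, args, t2, lapse = 0,
                                   gh_nodes = 15L, n_quad = 16L) {
  check_type2(model, t2)
  p <- switch(model$metric,
    ideal = p_choice_ideal(args$p1, args$p2),
    basic_probability = p_choice_beta(args$p1, args$p2, t2$nu, t2$k2,
                                      n_quad = n_quad,
                                      late_sd = t2$late_sd),
    probability_difference = p_choice_gaussian_diff(args$p2 - args$p1,
                                                    t2$k2, t2$sigma_conf),
    log_probability_ratio = p_choice_folded(args$d1, args$d2, t2$k2,
                                            t2$sigma_conf,
                                            gauss_hermite(gh_nodes)),
    unscaled_distance = p_choice_folded(args$d1, args$d2, t2$k2,
                                        t2$sigma_conf,
                                        gauss_hermite(gh_nodes)),
    scaled_distance = p_choice_folded(args$d1, args$d2, t2$k2,
                                      t2$sigma_conf,
                                      gauss_hermite(gh_nodes)),
    heuristic = p_choice_gaussian_diff(args$delta, t2$k2, t2$sigma_conf))
  lapse + (1 - 2 * lapse) * p
}
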