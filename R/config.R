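# Scale presets binding the numerical settings of the pipeline.

#' Pipeline configuration
#'
#' Bundles the numerical settings of the simulation and fitting stages.
#' Three presets trade accuracy for runtime: `"full"` reproduces the
#' study-scale analysis (fine grids, 1000 measurement draws per trial,
#' 200-sample measurement banks — hours of compute for a full model
#' recovery), `"desk"` is a reduced-resolution setting for interactive
#' work, and `"smoke"` is a minimal setting for integration tests.
#' Individual fields can be overridden via `...`.
#'
#' @param preset `"desk"`, `"smoke"` or `"full"`.
#' @param ... named overrides of individual fields.
#' @return list of class `cfc_config`; fields: `n_sigma` (spread-grid
#'   resolution of the marginalisation), `n_sim_t1` (measurement draws per
#'   trial for Type 1 choice probabilities), `bank_floor` (retained
#'   conditional measurements per trial), `bank_max_rounds` (rejection
#'   sampling cap, in multiples of `bank_floor`), `nb_eval` (bank columns
#'   entering each Type 2 likelihood evaluation), `gh_nodes`/`n_quad`
#'   (quadrature resolution of the analytic pair-choice probabilities),
#'   `n_multistart`/`optim_maxit` (derivative-free optimiser effort),
#'   `t1_grid` (brute-force grid for the Type 1 fit), `use_tables`
#'   (interpolate centred-prior posterior summaries from lookup tables),
#'   `agree_sims` (simulated datasets per agreement prediction).
#' @export
run_config <- function(preset = c("desk", "smoke", "full"), ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    full = list(
      n_sigma = 201L, n_sim_t1 = 1000L,
      bank_floor = 200L, bank_max_rounds = 40L, nb_eval = 50L,
      gh_nodes = 21L, n_quad = 24L,
      n_multistart = 10L, optim_maxit = 400L,
      t1_grid = list(sigma_dot = seq(0.2, 3, by = 0.05),
                     k1 = seq(-1.5, 1.5, by = 0.05),
                     lambda = seq(0, 0.1, by = 0.005)),
      use_tables = TRUE, agree_sims = 100L),
    desk = list(
      n_sigma = 61L, n_sim_t1 = 100L,
      bank_floor = 50L, bank_max_rounds = 40L, nb_eval = 20L,
      gh_nodes = 11L, n_quad = 12L,
      n_multistart = 3L, optim_maxit = 200L,
      t1_grid = list(sigma_dot = seq(0.5, 2, by = 0.1),
                     k1 = seq(-0.6, 0.6, by = 0.1),
                     lambda = seq(0, 0.08, by = 0.02)),
      use_tables = TRUE, agree_sims = 50L),
    smoke = list(
      n_sigma = 31L, n_sim_t1 = 50L,
      bank_floor = 24L, bank_max_rounds = 30L, nb_eval = 12L,
      gh_nodes = 9L, n_quad = 8L,
      n_multistart = 2L, optim_maxit = 150L,
      t1_grid = list(sigma_dot = seq(0.6, 1.6, by = 0.2),
                     k1 = seq(-0.3, 0.3, by = 0.15),
                     lambda = c(0, 0.02, 0.05)),
      use_tables = TRUE, agree_sims = 20L))
  cfg$preset <- preset
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  class(cfg) <- "cfc_config"
  cfg
}

config_sigma_grid <- function(config) {
  posterior_grids(n_sigma = config$n_sigma)$sigma
}
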