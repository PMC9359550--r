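# N-pass confidence agreement: how consistently the same confidence
# choice is made when the exact same stimulus sequence is shown again.
# Sensory and confidence noise are fresh on every pass, so even a
# deterministic-parameter model agrees with itself on fewer than 100% of
# pairs; human observers exceeded their best-fitting model's prediction,
# which is the effect this module measures.

#' Observed confidence agreement across repeated passes
#'
#' For every confidence pair of a repeated stimulus set, counts the
#' choices across all sessions sharing the same `pass_id` and computes
#' the agreement as the proportion of the most-selected choice (e.g. 4
#' "Interval 1" responses out of 5 passes is 80% agreement).  For an even
#' number of passes a split vote gives agreement 0.5 and is flagged as a
#' tie.
#'
#' @param responses a `cfc_responses` whose schedule repeated stimulus
#'   sets across sessions (at least one `pass_id` must cover two or more
#'   sessions).
#' @return data frame of class `cfc_agreement`: `pass_id`, `pair`,
#'   `n_passes`, `n_interval2`, `count` (most-selected count),
#'   `agreement`, `tie`.
#' @export
observed_agreement <- function(responses) {
  pr <- responses$pairs
  n_sess <- tapply(pr$session, pr$pass_id, function(s) length(unique(s)))
  keep <- names(n_sess)[n_sess >= 2]
  if (!length(keep)) {
    stop("confidence agreement needs at least 2 sessions sharing a ",
         "pass_id (identical stimulus sets)")
  }
  pr <- pr[pr$pass_id %in% as.integer(keep), ]
  key <- interaction(pr$pass_id, pr$pair, drop = TRUE)
  n2 <- tapply(pr$conf_choice == 2L, key, sum)
  n <- tapply(pr$conf_choice, key, length)
  pid <- tapply(pr$pass_id, key, `[`, 1)
  pair <- tapply(pr$pair, key, `[`, 1)
  exp_n <- n_sess[as.character(pid)]
  if (any(n != exp_n)) {
    stop("mismatched schedules across passes: some pairs are missing ",
         "responses in some sessions")
  }
  count <- pmax(n2, n - n2)
  out <- data.frame(pass_id = as.integer(pid), pair = as.integer(pair),
                    n_passes = as.integer(n), n_interval2 = as.integer(n2),
                    count = as.integer(count), agreement = count / n,
                    tie = n %% 2 == 0 & n2 == n - n2,
                    row.names = NULL)
  class(out) <- c("cfc_agreement", "data.frame")
  out
}

# Distribution over most-selected counts and the proportion of pairs at
# the maximum possible count.
agreement_distribution <- function(records) {
  n <- max(records$n_passes)
  counts <- seq(ceiling(n / 2), n)
  tab <- vapply(counts, function(k) mean(records$count == k), numeric(1))
  names(tab) <- counts
  list(n_passes = n, counts = counts, prop = tab,
       prop_highest = mean(records$count == n))
}

#' Model-predicted confidence agreement
#'
#' Repeats the full N-pass simulation `n_sims` times with fresh sensory
#' and confidence noise per pass, and aggregates the distribution of
#' per-pair agreement counts, giving the model's predicted agreement with
#' +/- 2 SD bands.
#'
#' @param schedule schedule with repeated sessions (the N-pass design).
#' @param model model id or [model_spec()].
#' @param t1,t2 (typically best-fitting) parameters.
#' @param n_sims number of simulated datasets.
#' @param seed master seed.
#' @param config a [run_config()].
#' @return `cfc_agreement_pred`: list with `counts`, `mean_prop`,
#'   `sd_prop`, `band_lo`/`band_hi` (+/- 2 SD), `prop_highest`
#'   (mean and sd across simulations), `n_sims`.
#' @export
predicted_agreement <- function(schedule, model, t1, t2 = type2_params(),
                                n_sims = 100L, seed = 1L,
                                config = run_config("desk")) {
  if (is.character(model)) model <- model_spec(model)
  props <- NULL
  ph <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    resp <- simulate_observer(schedule, model, t1, t2,
                              seed = derive_seed(seed, "agreesim", s),
                              config = config)
    dist <- agreement_distribution(observed_agreement(resp))
    if (is.null(props)) {
      props <- matrix(NA_real_, n_sims, length(dist$counts))
      colnames(props) <- dist$counts
    }
    props[s, ] <- dist$prop
    ph[s] <- dist$prop_highest
  }
  mean_prop <- colMeans(props)
  sd_prop <- apply(props, 2, sd)
  structure(list(model = model$id,
                 counts = as.integer(colnames(props)),
                 mean_prop = mean_prop, sd_prop = sd_prop,
                 band_lo = mean_prop - 2 * sd_prop,
                 band_hi = mean_prop + 2 * sd_prop,
                 prop_highest = mean(ph), prop_highest_sd = sd(ph),
                 n_sims = n_sims),
            class = "cfc_agreement_pred")
}

#' @export
print.cfc_agreement_pred <- function(x, ...) {
  cat("Predicted confidence agreement (", x$model, ", ", x$n_sims,
      " simulations)\n", sep = "")
  tab <- rbind(mean = x$mean_prop, `-2SD` = x$band_lo, `+2SD` = x$band_hi)
  colnames(tab) <- paste0(x$counts, "/", max(x$counts))
  print(round(tab, 3))
  cat("prop at highest count:", signif(x$prop_highest, 4), "+/-",
      signif(x$prop_highest_sd, 4), "(SD)\n")
  invisible(x)
}

#' Observed-versus-predicted agreement comparison
#'
#' Per observer, the difference between the observed and the
#' model-predicted proportion of pairs at the highest possible agreement
#' count, with a two-sided Wilcoxon signed-rank test of the deltas
#' against zero.  Positive deltas mean observers are more consistent
#' than their model predicts.
#'
#' @param observed numeric vector: per-observer observed proportion at
#'   the highest agreement count.
#' @param predicted numeric vector: matching model predictions (e.g.
#'   `prop_highest` of [predicted_agreement()]).
#' @return list with `delta`, `statistic`, `p_value`, `n`.
#' @export
agreement_comparison <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must be per-observer vectors of equal ",
         "length")
  }
  if (length(observed) < 2) {
    stop("agreement comparison needs at least 2 observers")
  }
  if (length(observed) < 5) {
    warning("signed-rank test with fewer than 5 observers has little ",
            "power", call. = FALSE)
  }
  delta <- observed - predicted
  wt <- if (all(delta == 0)) {
    list(statistic = NA_real_, p.value = 1)
  } else {
    suppressWarnings(wilcox.test(delta, mu = 0, exact = TRUE))
  }
  list(delta = delta, statistic = unname(wt$statistic),
       p_value = wt$p.value, n = length(delta))
}
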