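# Experiment design, trial schedules and dot-cloud stimuli.

#' Define the dot-cloud discrimination experiment design
#'
#' The default design reproduces the study conditions: seven horizontal
#' offsets of the generating mean, three generating spreads, two dot
#' counts, 20 presentations of each of the 42 unique conditions per
#' session, and five sessions.  `pass_pattern` gives one label per session;
#' sessions sharing a label are exact stimulus repeats (identical dots in
#' identical order), which is what enables the N-pass confidence-agreement
#' analysis.  The default is the 5-pass case (all sessions identical).
#'
#' @param mean_offsets horizontal offsets of the generating mean (deg).
#' @param spreads generating-distribution SDs (deg), all `> 0`.
#' @param dot_counts numbers of dots per stimulus, all `>= 1`.
#' @param reps_per_condition presentations of each unique condition per
#'   session.
#' @param n_sessions number of sessions.
#' @param pass_pattern integer vector of length `n_sessions`; equal values
#'   mark exact stimulus repeats.
#' @param blob_sd rendering SD of each dot blob (deg); metadata only, never
#'   used by inference.
#' @return an object of class `cfc_design`.
#' @export
experiment_design <- function(mean_offsets = c(-4, -2, -1, 0, 1, 2, 4),
                              spreads = c(1.5, 2, 2.5),
                              dot_counts = c(2L, 5L),
                              reps_per_condition = 20L,
                              n_sessions = 5L,
                              pass_pattern = rep(1L, n_sessions),
                              blob_sd = 0.1) {
  stopifnot(all(spreads > 0), all(dot_counts >= 1),
            reps_per_condition >= 1, n_sessions >= 1,
            length(pass_pattern) == n_sessions)
  n_cond <- length(mean_offsets) * length(spreads) * length(dot_counts)
  n_trials <- n_cond * reps_per_condition
  if (n_trials %% 2L != 0L) {
    stop("trials per session (", n_trials, ") must be even so every trial ",
         "belongs to a confidence pair")
  }
  structure(list(mean_offsets = mean_offsets, spreads = spreads,
                 dot_counts = as.integer(dot_counts),
                 reps_per_condition = as.integer(reps_per_condition),
                 n_sessions = as.integer(n_sessions),
                 pass_pattern = as.integer(pass_pattern),
                 blob_sd = blob_sd),
            class = "cfc_design")
}

#' @export
print.cfc_design <- function(x, ...) {
  n_cond <- length(x$mean_offsets) * length(x$spreads) * length(x$dot_counts)
  cat("Confidence forced-choice design\n")
  cat("  offsets (deg):", paste(x$mean_offsets, collapse = ", "), "\n")
  cat("  spreads (deg):", paste(x$spreads, collapse = ", "), "\n")
  cat("  dots per cloud:", paste(x$dot_counts, collapse = ", "), "\n")
  cat("  unique conditions:", n_cond, "\n")
  cat("  trials per session:", n_cond * x$reps_per_condition,
      " (", n_cond * x$reps_per_condition / 2, "pairs )\n")
  cat("  sessions:", x$n_sessions, " pass pattern:",
      paste(x$pass_pattern, collapse = " "), "\n")
  invisible(x)
}

#' Sample one dot-cloud stimulus
#'
#' Dots are i.i.d. draws from a 2D circular symmetric Gaussian centred at
#' `(mu_cloud, 0)` with SD `sigma_cloud` on both axes.  The centroid and the
#' empirical spread summarise the horizontal coordinates; the vertical
#' coordinate is carried for fidelity but ignored by all inference.
#'
#' @param mu_cloud generating mean offset (deg).
#' @param sigma_cloud generating SD (deg), `> 0` (0 allowed as a degenerate
#'   limit for testing).
#' @param n_dots number of dots.
#' @param unbiased_sd if `TRUE` use the n-1 divisor for `sigma_emp`;
#'   the default is the maximum-likelihood (divide-by-n) convention used
#'   throughout the models.
#' @return list with `dot_x`, `dot_y`, `centroid`, `sigma_emp`.
#' @export
sample_dot_cloud <- function(mu_cloud, sigma_cloud, n_dots,
                             unbiased_sd = FALSE) {
  stopifnot(sigma_cloud >= 0, n_dots >= 1)
  x <- mu_cloud + rnorm(n_dots, 0, sigma_cloud)
  y <- rnorm(n_dots, 0, sigma_cloud)
  div <- if (unbiased_sd) max(n_dots - 1L, 1L) else n_dots
  cen <- mean(x)
  list(dot_x = x, dot_y = y, centroid = cen,
       sigma_emp = sqrt(sum((x - cen)^2) / div))
}

#' Build the full trial schedule for an experiment
#'
#' Per session, each unique (offset, spread, dot count) condition appears
#' exactly `reps_per_condition` times, shuffled at the level of individual
#' trials (interleaved design); consecutive trials (1,2), (3,4), ... form
#' the confidence pairs.  Sessions that share a `pass_pattern` label are
#' generated from the same stimulus stream and are therefore bit-identical
#' repeats, including the sampled dot positions.  Stimuli with
#' `mu_cloud == 0` favour neither category; their true side is assigned
#' uniformly at random at generation time and recorded.
#'
#' @param design a `cfc_design`.
#' @param seed master seed; per-pass stimulus streams are derived from it.
#' @return a `cfc_schedule`: a data frame with one row per trial and
#'   columns session, pass_id, trial, pair, interval, mu_cloud, sigma_cloud,
#'   n_dots, true_side, centroid, sigma_emp and list columns dot_x, dot_y.
#' @export
build_schedule <- function(design, seed = 1L) {
  stopifnot(inherits(design, "cfc_design"))
  conds <- expand.grid(mu_cloud = design$mean_offsets,
                       sigma_cloud = design$spreads,
                       n_dots = design$dot_counts,
                       KEEP.OUT.ATTRS = FALSE)
  n_per_session <- nrow(conds) * design$reps_per_condition

  # one stimulus realisation per distinct pass label
  pass_stims <- list()
  for (p in unique(design$pass_pattern)) {
    pass_stims[[as.character(p)]] <- with_seed(
      derive_seed(seed, "stimuli", p),
      local({
        idx <- rep(seq_len(nrow(conds)), design$reps_per_condition)
        idx <- sample(idx)
        df <- conds[idx, , drop = FALSE]
        rownames(df) <- NULL
        clouds <- lapply(seq_len(n_per_session), function(i) {
          sample_dot_cloud(df$mu_cloud[i], df$sigma_cloud[i], df$n_dots[i])
        })
        df$true_side <- ifelse(df$mu_cloud > 0, 1L,
                               ifelse(df$mu_cloud < 0, -1L,
                                      sample(c(-1L, 1L), n_per_session,
                                             replace = TRUE)))
        df$dot_x <- I(lapply(clouds, `[[`, "dot_x"))
        df$dot_y <- I(lapply(clouds, `[[`, "dot_y"))
        df$centroid <- vapply(clouds, `[[`, numeric(1), "centroid")
        df$sigma_emp <- vapply(clouds, `[[`, numeric(1), "sigma_emp")
        df
      }))
  }

  out <- vector("list", design$n_sessions)
  for (s in seq_len(design$n_sessions)) {
    p <- design$pass_pattern[s]
    df <- pass_stims[[as.character(p)]]
    df <- cbind(session = s, pass_id = p,
                trial = seq_len(n_per_session),
                pair = rep(seq_len(n_per_session / 2L), each = 2L),
                interval = rep(1:2, n_per_session / 2L),
                df)
    out[[s]] <- df
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "design") <- design
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("cfc_schedule", "data.frame")
  out
}

#' @export
print.cfc_schedule <- function(x, ...) {
  d <- attr(x, "design")
  cat("cfc_schedule:", nrow(x), "trials,", max(x$pair) * d$n_sessions,
      "pairs total,", d$n_sessions, "session(s)\n")
  print.data.frame(utils::head(as.data.frame(x)[
    c("session", "pass_id", "trial", "pair", "interval", "mu_cloud",
      "sigma_cloud", "n_dots", "centroid", "sigma_emp")]), ...)
  invisible(x)
}
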