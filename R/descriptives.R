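# Manipulation checks and the preliminary nested logistic regression:
# model-free evidence that the quantity (dot count) and quality (dot
# spread) manipulations affected confidence.

# Pair-level predictors from the *displayed* dots (empirical centroid and
# spread, not the generating parameters): difference in distance from the
# screen centre, in inverse dot spread, and in dot count, all as
# interval 2 minus interval 1.
pair_predictors <- function(schedule, responses) {
  sch <- as.data.frame(schedule)
  key <- paste(sch$session, sch$pair)
  i1 <- which(sch$interval == 1L)
  i2 <- which(sch$interval == 2L)
  i2 <- i2[match(key[i1], key[i2])]
  dist <- abs(sch$centroid)
  inv <- 1 / pmax(sch$sigma_emp, 0.01)
  data.frame(session = sch$session[i1], pair = sch$pair[i1],
             d_dist = dist[i2] - dist[i1],
             d_inv = inv[i2] - inv[i1],
             d_n = sch$n_dots[i2] - sch$n_dots[i1],
             i1 = i1, i2 = i2,
             y2 = responses$pairs$conf_choice == 2L)
}

#' Accuracy manipulation checks
#'
#' Type 1 accuracy overall and split by the confidence choice (chosen
#' versus declined interval of each pair), scored both against the
#' generating mean (`mu_cloud = 0` trials excluded) and against the
#' displayed dot centroid (removing external noise from the score).  A
#' positive chosen-minus-declined difference is the model-free signature
#' of metacognitive sensitivity.
#'
#' @param schedule,responses one observer's dataset.
#' @return named list of proportions: `accuracy_all`, `accuracy_chosen`,
#'   `accuracy_declined` and centroid-scored counterparts, plus trial
#'   counts.
#' @export
manipulation_checks <- function(schedule, responses) {
  sch <- as.data.frame(schedule)
  pp <- pair_predictors(schedule, responses)
  if (!nrow(pp)) stop("no confidence pairs in this dataset")
  r <- responses$trials$r
  ok_gen <- sch$mu_cloud != 0
  correct_gen <- r == sch$true_side
  correct_cen <- r * sch$centroid > 0
  chosen_idx <- ifelse(pp$y2, pp$i2, pp$i1)
  declined_idx <- ifelse(pp$y2, pp$i1, pp$i2)
  acc <- function(correct, idx) mean(correct[idx][ok_gen[idx]])
  list(accuracy_all = mean(correct_gen[ok_gen]),
       accuracy_chosen = acc(correct_gen, chosen_idx),
       accuracy_declined = acc(correct_gen, declined_idx),
       accuracy_all_centroid = mean(correct_cen[ok_gen]),
       accuracy_chosen_centroid = acc(correct_cen, chosen_idx),
       accuracy_declined_centroid = acc(correct_cen, declined_idx),
       n_trials = sum(ok_gen), n_pairs = nrow(pp))
}

#' Group summary of manipulation checks
#'
#' @param checks list of per-observer [manipulation_checks()] results.
#' @return data frame with per-measure group mean and SEM.
#' @export
group_manipulation_checks <- function(checks) {
  meas <- c("accuracy_all", "accuracy_chosen", "accuracy_declined",
            "accuracy_all_centroid", "accuracy_chosen_centroid",
            "accuracy_declined_centroid")
  vals <- vapply(meas, function(m) {
    v <- vapply(checks, function(ch) as.numeric(ch[[m]]), numeric(1))
    c(mean(v), sd(v) / sqrt(length(v)))
  }, numeric(2))
  data.frame(measure = meas, mean = vals[1, ], sem = vals[2, ],
             row.names = NULL)
}

# Logistic negative log-likelihood with optional ridge penalty.
logit_nll <- function(beta, X, y, ridge = 0) {
  eta <- drop(X %*% beta)
  p <- clip01(plogis(eta))
  -sum(ifelse(y, log(p), log(1 - p))) + ridge * sum(beta[-1]^2)
}

#' Nested logistic regression of the confidence choices
#'
#' Fits four nested logistic models of the interval-2 choice: `basic`
#' (position difference only), `basic+quantity` (adds the dot-count
#' difference), `basic+quality` (adds the inverse-spread difference) and
#' `full` (all three predictors), and ranks them by AICc.  Predictors
#' derive from the displayed dots.  Perfect separation (diverging
#' coefficients) triggers a ridge-penalised refit and is flagged.
#'
#' @param schedule,responses one observer's dataset.
#' @return `cfc_nested_logit`: list with `tiers` (tier, k, nll, aicc,
#'   rel_aicc), `coef` per tier, `winner`, `penalized` flag and
#'   `contour(d_dist, d_n = 0)`, the confidence-indifference locus giving
#'   the inverse-spread difference at which p(choose Interval 2) = 0.5.
#' @export
nested_logistic <- function(schedule, responses) {
  pp <- pair_predictors(schedule, responses)
  tiers <- list(basic = c("d_dist"),
                `basic+quantity` = c("d_dist", "d_n"),
                `basic+quality` = c("d_dist", "d_inv"),
                full = c("d_dist", "d_n", "d_inv"))
  fits <- list()
  penalized <- FALSE
  for (tn in names(tiers)) {
    fml <- reformulate(tiers[[tn]], response = "y2")
    fit <- suppressWarnings(glm(fml, family = binomial(), data = pp))
    cf <- coef(fit)
    if (!fit$converged || any(abs(cf) > 15)) {
      # separation guard: small ridge via direct optimisation
      X <- model.matrix(fml, pp)
      opt <- optim(rep(0, ncol(X)), logit_nll, X = X, y = pp$y2,
                   ridge = 1e-3, method = "BFGS")
      cf <- setNames(opt$par, colnames(X))
      nll <- logit_nll(cf, X, pp$y2, ridge = 0)
      penalized <- TRUE
    } else {
      nll <- -as.numeric(logLik(fit))
    }
    fits[[tn]] <- list(coef = cf, nll = nll, k = length(cf))
  }
  tab <- data.frame(
    tier = names(fits),
    k = vapply(fits, function(f) as.numeric(f$k), numeric(1)),
    nll = vapply(fits, `[[`, numeric(1), "nll"),
    row.names = NULL)
  tab$aicc <- mapply(aicc, tab$nll, tab$k, nrow(pp))
  tab$rel_aicc <- tab$aicc - min(tab$aicc)
  full_cf <- fits$full$coef
  contour <- function(d_dist, d_n = 0) {
    -(full_cf["(Intercept)"] + full_cf["d_dist"] * d_dist +
        full_cf["d_n"] * d_n) / full_cf["d_inv"]
  }
  structure(list(tiers = tab[order(tab$aicc), ],
                 coef = lapply(fits, `[[`, "coef"),
                 winner = tab$tier[which.min(tab$aicc)],
                 penalized = penalized, contour = contour,
                 n_pairs = nrow(pp)),
            class = "cfc_nested_logit")
}

#' @export
print.cfc_nested_logit <- function(x, ...) {
  cat("Nested logistic regression of confidence choices (",
      x$n_pairs, " pairs)\n", sep = "")
  print(x$tiers, row.names = FALSE)
  cat("winner:", x$winner,
      if (x$penalized) " (ridge-penalised: separation detected)", "\n")
  invisible(x)
}

#' Binned confidence-choice heat-map
#'
#' Mean proportion of "Interval 2 more confident" choices binned over the
#' pairwise differences in distance-from-centre and inverse dot spread
#' (displayed dots), within `+/- limit` degrees.  Pairs with equal dot
#' counts form one panel; unequal-count pairs form a second panel with
#' stimulus and choice flipped where needed so that Interval 2 is always
#' the interval with more dots.  Empty bins are `NA`.
#'
#' @param schedule,responses the dataset.
#' @param limit bin range (deg).
#' @param n_bins number of bins per axis.
#' @return `cfc_heatmap`: list with matrices `equal_n` and `more_dots_i2`
#'   (rows: d_dist bins, columns: d_inv bins), bin `centers`, `breaks`
#'   and per-bin counts.
#' @export
choice_heatmap <- function(schedule, responses, limit = 3, n_bins = 13L) {
  pp <- pair_predictors(schedule, responses)
  breaks <- seq(-limit, limit, length.out = n_bins + 1L)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  binmat <- function(dd, di, y) {
    bx <- findInterval(dd, breaks, rightmost.closed = TRUE)
    by <- findInterval(di, breaks, rightmost.closed = TRUE)
    ok <- bx >= 1 & bx <= n_bins & by >= 1 & by <= n_bins
    m <- matrix(NA_real_, n_bins, n_bins)
    cnt <- matrix(0L, n_bins, n_bins)
    sums <- tapply(y[ok], list(factor(bx[ok], 1:n_bins),
                               factor(by[ok], 1:n_bins)), sum)
    ns <- tapply(rep(1L, sum(ok)), list(factor(bx[ok], 1:n_bins),
                                        factor(by[ok], 1:n_bins)), sum)
    filled <- !is.na(ns)
    m[filled] <- sums[filled] / ns[filled]
    cnt[filled] <- ns[filled]
    list(p = m, n = cnt)
  }
  eq <- pp$d_n == 0
  flip <- pp$d_n < 0   # recode so interval 2 has more dots
  dd <- ifelse(flip, -pp$d_dist, pp$d_dist)
  di <- ifelse(flip, -pp$d_inv, pp$d_inv)
  yy <- ifelse(flip, !pp$y2, pp$y2)
  eqm <- binmat(pp$d_dist[eq], pp$d_inv[eq], pp$y2[eq])
  nem <- binmat(dd[!eq], di[!eq], yy[!eq])
  structure(list(equal_n = eqm$p, equal_n_count = eqm$n,
                 more_dots_i2 = nem$p, more_dots_i2_count = nem$n,
                 centers = centers, breaks = breaks),
            class = "cfc_heatmap")
}

#' Plot a confidence-choice heat-map
#'
#' @param x a [choice_heatmap()] result.
#' @param panel `"equal_n"` or `"more_dots_i2"`.
#' @param contour optionally, the `contour` function of a
#'   [nested_logistic()] fit, drawn as the confidence-indifference line.
#' @param ... passed to [graphics::image()].
#' @export
plot.cfc_heatmap <- function(x, panel = c("equal_n", "more_dots_i2"),
                             contour = NULL, ...) {
  panel <- match.arg(panel)
  z <- x[[panel]]
  graphics::image(x$centers, x$centers, z,
                  col = grDevices::hcl.colors(25, "RdBu", rev = TRUE),
                  zlim = c(0, 1),
                  xlab = "d distance from centre (deg, I2 - I1)",
                  ylab = "d inverse spread (1/deg, I2 - I1)",
                  main = paste("p(choose Interval 2):", panel), ...)
  if (!is.null(contour)) {
    xs <- seq(min(x$centers), max(x$centers), length.out = 101)
    graphics::lines(xs, contour(xs), col = "goldenrod", lwd = 2)
  }
  invisible(x)
}
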