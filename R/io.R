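# File interfaces: trial tables as CSV (dot coordinates serialised as a
# semicolon-delimited subfield), fits and configs as JSON.  Readers and
# writers are exact inverses on their own output.

serialise_dots <- function(lst) {
  vapply(lst, function(v) paste(formatC(v, format = "g", digits = 15),
                                collapse = ";"), character(1))
}

parse_dots <- function(s) {
  lapply(strsplit(s, ";", fixed = TRUE), as.numeric)
}

#' Write a trial table (schedule plus optional responses) to CSV
#'
#' One row per trial with columns observer, session, pass_id, trial,
#' pair, interval, mu_cloud, sigma_cloud, n_dots, dot_x, dot_y, centroid,
#' sigma_emp, true_side, r, conf_choice.  Dot coordinates are
#' semicolon-delimited within their cell (the dialect used throughout the
#' package).  `conf_choice` is recorded on the interval-1 row of each
#' pair and `NA` on the interval-2 row; without responses both response
#' columns are `NA`.
#'
#' @param schedule a `cfc_schedule`.
#' @param path output file.
#' @param responses optional matching `cfc_responses`.
#' @param observer observer label.
#' @export
write_trials <- function(schedule, path, responses = NULL,
                         observer = "obs1") {
  sch <- as.data.frame(schedule)
  out <- data.frame(observer = observer, session = sch$session,
                    pass_id = sch$pass_id, trial = sch$trial,
                    pair = sch$pair, interval = sch$interval,
                    mu_cloud = sch$mu_cloud, sigma_cloud = sch$sigma_cloud,
                    n_dots = sch$n_dots,
                    dot_x = serialise_dots(sch$dot_x),
                    dot_y = serialise_dots(sch$dot_y),
                    centroid = sch$centroid, sigma_emp = sch$sigma_emp,
                    true_side = sch$true_side,
                    r = NA_integer_, conf_choice = NA_integer_)
  if (!is.null(responses)) {
    out$r <- responses$trials$r
    i1 <- out$interval == 1L
    key <- paste(out$session[i1], out$pair[i1])
    pkey <- paste(responses$pairs$session, responses$pairs$pair)
    out$conf_choice[i1] <- responses$pairs$conf_choice[match(key, pkey)]
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial table written by [write_trials()]
#'
#' @param path CSV file.
#' @return list with `schedule` (a `cfc_schedule` data frame) and
#'   `responses` (a `cfc_responses`, or `NULL` if the file holds no
#'   responses).
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("session", "pass_id", "trial", "pair", "interval", "mu_cloud",
            "sigma_cloud", "n_dots", "dot_x", "dot_y", "centroid",
            "sigma_emp", "true_side")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trial table lacks required columns: ",
         paste(miss, collapse = ", "))
  }
  sch <- df[c("session", "pass_id", "trial", "pair", "interval",
              "mu_cloud", "sigma_cloud", "n_dots")]
  sch$true_side <- df$true_side
  sch$dot_x <- I(parse_dots(df$dot_x))
  sch$dot_y <- I(parse_dots(df$dot_y))
  sch$centroid <- df$centroid
  sch$sigma_emp <- df$sigma_emp
  class(sch) <- c("cfc_schedule", "data.frame")
  responses <- NULL
  if ("r" %in% names(df) && !all(is.na(df$r))) {
    i1 <- sch$interval == 1L
    responses <- structure(
      list(trials = data.frame(session = sch$session,
                               pass_id = sch$pass_id, trial = sch$trial,
                               pair = sch$pair, interval = sch$interval,
                               r = as.integer(df$r),
                               lapsed = NA),
           pairs = data.frame(session = sch$session[i1],
                              pass_id = sch$pass_id[i1],
                              pair = sch$pair[i1],
                              conf_choice = as.integer(df$conf_choice[i1])),
           model = NULL, t1 = NULL, t2 = NULL, seed = NA_integer_),
      class = "cfc_responses")
  }
  list(schedule = sch, responses = responses)
}

#' Write/read a fit result as JSON
#'
#' @param fit a `cfc_fit`.
#' @param path JSON file.
#' @export
write_fit <- function(fit, path) {
  obj <- list(model = fit$model, params = fit$params, nll = fit$nll,
              k = fit$k, n = fit$n, aicc = fit$aicc)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$k <- as.integer(obj$k)
  obj$params <- as.list(obj$params)
  class(obj) <- "cfc_fit"
  obj
}

# Canonicalise (sort names recursively) so the hash ignores key order.
canonicalise <- function(x) {
  if (is.list(x) && !is.null(names(x))) {
    x <- x[order(names(x))]
    lapply(x, canonicalise)
  } else if (is.list(x)) {
    lapply(x, canonicalise)
  } else x
}

#' Stable hash of a configuration
#'
#' Invariant under key reordering; used to stamp output provenance.
#'
#' @param config any nested list of scalars/vectors.
#' @return hex string.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(canonicalise(unclass(config)), auto_unbox = TRUE,
                        digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write/read a run configuration as JSON
#'
#' @param config a [run_config()] list.
#' @param path JSON file.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$t1_grid <- as.list(cfg$t1_grid)
  class(cfg) <- "cfc_config"
  cfg
}

#' Validate an external deposit-style trial table
#'
#' Checks that a data frame (or CSV file) provides the columns this
#' package's ingest expects, without reading any remote resource.  A
#' small synthetic example of the layout ships in
#' `inst/extdata/osf_layout_synthetic.csv`.
#'
#' @param x data frame or path to a CSV file.
#' @return invisibly `TRUE`; errors listing any missing columns.
#' @export
validate_osf_layout <- function(x) {
  if (is.character(x)) x <- utils::read.csv(x, nrows = 5)
  need <- c("observer", "session", "trial", "pair", "interval",
            "mu_cloud", "sigma_cloud", "n_dots", "dot_x", "dot_y",
            "r", "conf_choice")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("external trial table is missing columns: ",
         paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
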