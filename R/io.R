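TRIAL_SCHEMA <- c("subject_id", "experiment", "trial_index", "n_informative",
                  "window_mask", "stake_cents", "arrangement", "choice",
                  "outcome", "payoff_cents")

#' Read and write trial-record CSV files
#'
#' The on-disk format is a UTF-8 comma-delimited file with the fixed header
#' `subject_id, experiment, trial_index, n_informative, window_mask,
#' stake_cents, arrangement, choice, outcome, payoff_cents`; `window_mask`
#' is a five-character string of 0/1 (leftmost window first), `choice` is
#' literally `ACCEPT` or `REJECT`, `outcome` is `WIN`, `LOSS` or `NONE`.
#' `read_trials()` validates the schema and reports offending row numbers;
#' `write_trials()` drops any extra columns (e.g. the simulated face
#' strings) so that a write-then-read round trip is lossless over the
#' schema columns.
#'
#' @param data Trial records, e.g. from [simulate_cohort()].
#' @param path File path.
#' @return `read_trials()` returns the validated data.frame;
#'   `write_trials()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_trials(simulate_cohort(2, seed = 5), f)
#' nrow(read_trials(f))
#' @export
write_trials <- function(data, path) {
  miss <- setdiff(TRIAL_SCHEMA, names(data))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- data[TRIAL_SCHEMA]
  out$arrangement[is.na(out$arrangement)] <- "NA"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(window_mask = "character"),
                       fileEncoding = "UTF-8")
  miss <- setdiff(TRIAL_SCHEMA, names(d))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  d$arrangement[d$arrangement == "NA"] <- NA_character_
  bad_row <- function(cond, what) {
    if (any(cond)) {
      stop(sprintf("%s at row(s) %s", what,
                   paste(utils::head(which(cond), 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad_row(!grepl("^[01]{5}$", d$window_mask), "malformed window_mask")
  bad_row(mask_popcount(d$window_mask) != d$n_informative,
          "window_mask inconsistent with n_informative")
  bad_row(!d$choice %in% c("ACCEPT", "REJECT"), "invalid choice")
  bad_row(!d$outcome %in% c("WIN", "LOSS", "NONE"), "invalid outcome")
  bad_row(!d$stake_cents %in% STAKES, "invalid stake_cents")
  bad_row(d$choice == "REJECT" & d$payoff_cents != 0,
          "nonzero payoff on rejected trial")
  d
}

#' Export the information-value table
#'
#' Writes the full four-model table of Information Values (24 value cells)
#' as a tidy CSV with columns `model_id`, `n_informative`, `value`, rounded
#' to `digits` decimals.
#'
#' @param path Output CSV path.
#' @param digits Decimal places for the value column (default 3, the
#'   conventional display precision).
#' @return Invisibly, the exported data.frame.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_info_value_table(f)
#' read.csv(f)[7:12, ]
#' @export
write_info_value_table <- function(path, digits = 3) {
  tab <- info_value_table(digits = digits)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(tab)
}

#' Read a run configuration file
#'
#' Reads simulation/analysis settings (cohort size, generative model id,
#' effect sizes, intercept distribution, seed, ...) from a YAML or JSON
#' file, filling unspecified fields with the package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("the 'jsonlite' package is required for JSON configs",
           call. = FALSE)
    }
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  defaults <- list(experiment = 1L, n_subjects = NULL,
                   model = "early_resolution", beta_info = 1.2,
                   beta_stake = -0.02, mu = 0.4, sigma = 0.8, seed = NULL,
                   nAGQ = 1L, n_boot = 1000L)
  utils::modifyList(defaults, cfg)
}
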