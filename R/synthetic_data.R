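#' @importFrom stats rnorm rbinom plogis qchisq pchisq pbinom quantile
#'   logLik vcov coef simulate residuals fitted predict p.adjust
#'   binomial as.formula setNames aggregate
NULL

STAKES <- c(10L, 20L, 30L, 40L, 50L)
N_TRIALS <- 180L

mask_string <- function(positions) {
  m <- rep("0", 5)
  m[positions] <- "1"
  paste(m, collapse = "")
}

# all C(5, i) masks with i informative windows, as "01011"-style strings
all_masks <- function(i) {
  i <- check_i(i)
  if (i == 0L) return("00000")
  apply(utils::combn(5L, i), 2L, mask_string)
}

mask_popcount <- function(mask) {
  vapply(strsplit(mask, ""), function(ch) sum(ch == "1"), integer(1))
}

#' Build one subject's trial design
#'
#' Generates the 180-trial design of one of the three experiments:
#' \describe{
#'   \item{Experiment 1}{30 trials at each of the six levels of information
#'     availability (0--5 informative windows), all at a 50-cent stake.}
#'   \item{Experiment 2}{six trials in each cell of the 6 (information) x
#'     5 (stake 10--50 cents) factorial.}
#'   \item{Experiment 3}{crosses information availability with the relative
#'     timing of information: for 1--4 informative windows the informative
#'     windows form either a prefix (`EARLY`) or a suffix (`LATE`) of the
#'     five positions; 0 and 5 windows admit no timing manipulation. The ten
#'     resulting cells get 18 trials each, with the five stakes balanced
#'     exactly overall (36 trials per stake) and near-balanced within cells.}
#' }
#' Window masks for experiments 1 and 2 are drawn uniformly from all
#' \eqn{\binom{5}{i}} arrangements (for 2 and 3 informative windows that
#' pool has exactly 10 members). Trial order is randomly interleaved.
#'
#' @param experiment Integer 1, 2 or 3.
#' @param seed Optional integer seed for reproducible mask draws and trial
#'   order.
#' @return A data.frame with one row per trial: `experiment`, `trial_index`,
#'   `n_informative`, `window_mask` (five-character string of 0/1, leftmost
#'   window first), `stake_cents`, `arrangement` (`"EARLY"`, `"LATE"` or
#'   `NA`).
#' @examples
#' d <- build_design(1, seed = 1)
#' table(d$n_informative)
#' @export
build_design <- function(experiment, seed = NULL) {
  if (!experiment %in% 1:3) stop("experiment must be 1, 2 or 3", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cells <- switch(as.character(experiment),
    "1" = data.frame(i = rep(0:5, each = 30L), stake = 50L,
                     arrangement = NA_character_),
    "2" = {
      g <- expand.grid(i = 0:5, stake = STAKES)
      data.frame(i = rep(g$i, each = 6L), stake = rep(g$stake, each = 6L),
                 arrangement = NA_character_)
    },
    "3" = exp3_cells()
  )
  mask <- character(nrow(cells))
  for (r in seq_len(nrow(cells))) {
    mask[r] <- if (is.na(cells$arrangement[r])) {
      pool <- all_masks(cells$i[r])
      pool[sample.int(length(pool), 1L)]
    } else if (cells$arrangement[r] == "EARLY") {
      mask_string(seq_len(cells$i[r]))
    } else {
      mask_string((5L - cells$i[r] + 1L):5L)
    }
  }
  ord <- sample.int(nrow(cells))
  data.frame(
    experiment = as.integer(experiment),
    trial_index = seq_len(nrow(cells)),
    n_informative = cells$i[ord],
    window_mask = mask[ord],
    stake_cents = as.integer(cells$stake[ord]),
    arrangement = cells$arrangement[ord],
    stringsAsFactors = FALSE
  )
}

# 10 cells x 18 trials; stakes cycled so each appears 36 times overall
exp3_cells <- function() {
  cells <- rbind(
    data.frame(i = 0L, arrangement = NA_character_),
    expand.grid(i = 1:4, arrangement = c("EARLY", "LATE"),
                stringsAsFactors = FALSE),
    data.frame(i = 5L, arrangement = NA_character_)
  )
  out <- vector("list", nrow(cells))
  for (j in seq_len(nrow(cells))) {
    stakes <- c(rep(STAKES, 3L), STAKES[(3L * (j - 1L) + 0:2) %% 5L + 1L])
    out[[j]] <- data.frame(i = cells$i[j], stake = stakes,
                           arrangement = cells$arrangement[j],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate one lottery and its revealed sequence
#'
#' Draws the final five-face sequence as five independent fair coin flips,
#' so the outcome is a win with probability exactly 0.5 whatever the window
#' mask. Informative windows reveal the veridical face; non-informative
#' windows reveal an independent random face.
#'
#' @param window_mask Five-character string of 0/1 (1 = informative),
#'   leftmost window first.
#' @return A list with `lottery_faces` and `revealed_faces` (each a
#'   five-element character vector of `"WIN"`/`"LOSS"`) and `outcome`
#'   (`"WIN"` if at least three faces win, else `"LOSS"`).
#' @examples
#' set.seed(1)
#' simulate_lottery("11000")
#' @export
simulate_lottery <- function(window_mask) {
  mask <- check_mask(window_mask)
  faces <- sample(c(WIN, LOSS), 5L, replace = TRUE)
  revealed <- sample(c(WIN, LOSS), 5L, replace = TRUE)
  revealed[mask] <- faces[mask]
  list(lottery_faces = faces, revealed_faces = revealed,
       outcome = if (sum(faces == WIN) >= 3L) WIN else LOSS)
}

check_mask <- function(window_mask) {
  if (length(window_mask) != 1L || is.na(window_mask) ||
      !grepl("^[01]{5}$", window_mask)) {
    stop("window_mask must be a five-character string of 0/1", call. = FALSE)
  }
  strsplit(window_mask, "")[[1]] == "1"
}

#' Simulate choices for a block of trials
#'
#' Generative mirror of the fitted logistic mixed model: a gamble is
#' accepted with probability
#' \deqn{P(accept) = logit^{-1}(\alpha + \beta_{info} V(i) +
#'   \beta_{stake} (stake - 30)),}
#' where \eqn{V(i)} is the Information Value of the trial's number of
#' informative windows under the chosen model and the stake is centered at
#' 30 cents so that \eqn{\alpha} is the log-odds of gambling at the mean
#' stake. Each trial's lottery is simulated with [simulate_lottery()];
#' rejected trials have outcome `"NONE"`, zero payoff and no revealed
#' sequence.
#'
#' @param design Trial design as returned by [build_design()].
#' @param intercept Subject's log-odds of accepting at zero Information
#'   Value and the 30-cent stake.
#' @param beta_info Log-odds change per unit Information Value.
#' @param beta_stake Log-odds change per cent of stake.
#' @param model Information-value model id driving choice ([info_models()]).
#' @param subject_id Identifier stored in the output.
#' @return A data.frame of choice records: the design columns plus
#'   `subject_id`, `choice` (`"ACCEPT"`/`"REJECT"`), `outcome`
#'   (`"WIN"`/`"LOSS"`/`"NONE"`), `payoff_cents`, `lottery_faces` and
#'   `revealed_faces` (five-character strings of W/L, empty when rejected).
#' @examples
#' set.seed(1)
#' head(simulate_choices(build_design(1), intercept = 0.4, beta_info = 1.2))
#' @export
simulate_choices <- function(design, intercept, beta_info = 1.2,
                             beta_stake = -0.02,
                             model = "early_resolution",
                             subject_id = "s01") {
  model <- match.arg(model, info_models())
  n <- nrow(design)
  v <- info_value(model, design$n_informative)
  eta <- intercept + beta_info * v + beta_stake * (design$stake_cents - 30)
  accept <- rbinom(n, 1L, plogis(eta)) == 1L

  faces <- matrix(sample(c(WIN, LOSS), 5L * n, replace = TRUE), nrow = n)
  noise <- matrix(sample(c(WIN, LOSS), 5L * n, replace = TRUE), nrow = n)
  maskm <- t(vapply(design$window_mask, check_mask, logical(5)))
  revealed <- ifelse(maskm, faces, noise)
  won <- rowSums(faces == WIN) >= 3L

  out <- design
  out$subject_id <- subject_id
  out$choice <- ifelse(accept, "ACCEPT", "REJECT")
  out$outcome <- ifelse(!accept, "NONE", ifelse(won, WIN, LOSS))
  out$payoff_cents <- ifelse(!accept, 0L,
                             ifelse(won, out$stake_cents, -out$stake_cents))
  fstr <- function(m) apply(m, 1L, function(x) {
    paste(substr(x, 1L, 1L), collapse = "")
  })
  out$lottery_faces <- fstr(faces)
  out$revealed_faces <- ifelse(accept, fstr(revealed), "")
  out[c("subject_id", "experiment", "trial_index", "n_informative",
        "window_mask", "stake_cents", "arrangement", "choice", "outcome",
        "payoff_cents", "lottery_faces", "revealed_faces")]
}

#' Simulate a cohort of subjects
#'
#' Draws subject-specific gamble propensities (random intercepts) from
#' \eqn{N(\mu, \sigma^2)} on the log-odds scale and simulates each
#' subject's full 180-trial session with [simulate_choices()], with a fresh
#' trial order and fresh window masks per subject. Default cohort sizes are
#' the study's per-experiment samples (22, 29 and 20 subjects).
#'
#' @param n_subjects Number of subjects (default depends on `experiment`).
#' @param experiment Integer 1, 2 or 3, passed to [build_design()].
#' @param model,beta_info,beta_stake Generative choice model, see
#'   [simulate_choices()].
#' @param mu,sigma Mean and SD (log-odds) of the population of subject
#'   intercepts; `sigma = 0` gives a common intercept.
#' @param seed Optional integer seed; the full dataset is reproducible
#'   given the seed.
#' @return A data.frame of choice records for all subjects (rows =
#'   `n_subjects * 180`).
#' @examples
#' trials <- simulate_cohort(4, experiment = 1, seed = 7)
#' nrow(trials)
#' @export
simulate_cohort <- function(n_subjects = c(22L, 29L, 20L)[experiment],
                            experiment = 1,
                            model = "early_resolution",
                            beta_info = 1.2, beta_stake = -0.02,
                            mu = 0.4, sigma = 0.8, seed = NULL) {
  if (length(n_subjects) != 1L || is.na(n_subjects) || n_subjects < 1L) {
    stop("n_subjects must be a positive integer", call. = FALSE)
  }
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  intercepts <- rnorm(n_subjects, mu, sigma)
  ids <- sprintf("s%02d", seq_len(n_subjects))
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    out[[s]] <- simulate_choices(build_design(experiment),
                                 intercept = intercepts[s],
                                 beta_info = beta_info,
                                 beta_stake = beta_stake,
                                 model = model, subject_id = ids[s])
  }
  do.call(rbind, out)
}
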