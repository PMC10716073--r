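#' Information-value models for the five-window lottery task
#'
#' The task presents a five-window slot machine whose lottery wins when at
#' least three of the five faces are winning faces (a strict majority always
#' exists). Before choosing, the player is told which windows are
#' *informative*: those windows later reveal veridical faces from the final
#' sequence, while the remaining windows show independent random faces. The
#' revealed information is non-instrumental -- it cannot change the outcome.
#'
#' Four models assign each level of information availability
#' \eqn{i \in \{0,\dots,5\}} (the number of informative windows) a
#' dimensionless "Information Value":
#' \describe{
#'   \item{\code{baseline}}{zero everywhere; choice depends only on the
#'     subject's propensity to gamble.}
#'   \item{\code{linear}}{\eqn{i/5}, equal increments from 0 to 1.}
#'   \item{\code{entropy_reduction}}{the expected reduction in Shannon
#'     entropy of the win probability after observing the informative
#'     windows, averaged over all \eqn{2^i} equiprobable permutations of
#'     winning/losing faces (bits; prior entropy is 1 bit).}
#'   \item{\code{early_resolution}}{the probability that the informative
#'     windows alone fix the outcome before feedback, i.e. that the revealed
#'     permutation already contains at least three winning or three losing
#'     faces.}
#' }
#'
#' @return `info_models()` returns the four model identifiers as a character
#'   vector, in canonical order.
#' @examples
#' info_models()
#' info_value("entropy_reduction", 0:5)
#' @export
info_models <- function() {
  c("baseline", "linear", "entropy_reduction", "early_resolution")
}

WIN <- "WIN"
LOSS <- "LOSS"

check_i <- function(i) {
  if (length(i) == 0 || anyNA(i) || !is.numeric(i) ||
      any(i != as.integer(i)) || any(i < 0) || any(i > 5)) {
    stop("number of informative windows must be an integer in 0..5",
         call. = FALSE)
  }
  as.integer(i)
}

check_stimuli <- function(stimuli) {
  if (is.null(stimuli)) stimuli <- character(0)
  if (!all(stimuli %in% c(WIN, LOSS))) {
    stop("stimuli must be a vector of \"WIN\"/\"LOSS\" faces", call. = FALSE)
  }
  check_i(length(stimuli))
  stimuli
}

#' Minimum additional winning faces needed for a win majority
#'
#' Given the faces revealed by the informative windows, returns the smallest
#' number of winning faces among the \eqn{5 - i} unrevealed windows that
#' still yields a majority of winning faces overall, or `NA` when a win is
#' already impossible (three or more losing faces revealed).
#'
#' @param stimuli Character vector of revealed faces, each `"WIN"` or
#'   `"LOSS"`; its length is the number of informative windows \eqn{i}
#'   (0 to 5). Window positions are irrelevant: only the counts matter.
#' @return Integer in `0:(5 - i)`, or `NA_integer_` when no completion of
#'   the unrevealed windows can produce a win.
#' @examples
#' min_additional_wins(c("WIN", "LOSS"))        # 2 more wins needed
#' min_additional_wins(rep("WIN", 3))           # 0, majority secured
#' min_additional_wins(rep("LOSS", 3))          # NA, win impossible
#' @export
min_additional_wins <- function(stimuli) {
  stimuli <- check_stimuli(stimuli)
  wins <- sum(stimuli == WIN)
  losses <- length(stimuli) - wins
  if (losses >= 3L) return(NA_integer_)
  max(0L, 3L - wins)
}

#' Probability of a win majority given revealed faces
#'
#' Computes the binomial tail probability that the final five-face sequence
#' contains a majority of winning faces, given the faces already revealed by
#' the informative windows. With \eqn{w_{min}} the minimum number of
#' additional winning faces required (see [min_additional_wins()]) and
#' \eqn{r = 5 - i} unrevealed windows, each independently winning with
#' probability 0.5,
#' \deqn{P(win \mid i, w_{min}) = \sum_{k = w_{min}}^{r} \binom{r}{k} 0.5^r,}
#' and \eqn{P(win) = 0} when no \eqn{w_{min}} exists. The value equals the
#' fraction of the \eqn{2^{r}} completions of the unrevealed windows that
#' produce at least three winning faces overall.
#'
#' @inheritParams min_additional_wins
#' @return Probability in \[0, 1\].
#' @examples
#' win_probability(character(0))   # no information: the 50% prior
#' win_probability("WIN")          # 11 of the 16 completions win
#' @export
win_probability <- function(stimuli) {
  stimuli <- check_stimuli(stimuli)
  win_probability_counts(sum(stimuli == WIN), length(stimuli))
}

# count-based kernel: `wins` winning faces among `i` revealed windows
win_probability_counts <- function(wins, i) {
  if (wins >= 3L) return(1)
  if ((i - wins) >= 3L) return(0)
  r <- 5L - i
  w_min <- 3L - wins
  stats::pbinom(w_min - 1L, r, 0.5, lower.tail = FALSE)
}

#' Shannon entropy of a win probability
#'
#' Binary entropy in bits,
#' \eqn{H(p) = -[p \log_2 p + (1-p)\log_2(1-p)]}, with the convention
#' \eqn{H(0) = H(1) = 0}. Symmetric about, and maximal (1 bit) at,
#' \eqn{p = 0.5}.
#'
#' @param p Numeric vector of probabilities in \[0, 1\].
#' @return Entropy in bits, same length as `p`.
#' @examples
#' shannon_entropy(c(0, 0.5, 1))
#' @export
shannon_entropy <- function(p) {
  if (anyNA(p) || !is.numeric(p) || any(p < 0) || any(p > 1)) {
    stop("p must be a probability in [0, 1]", call. = FALSE)
  }
  term <- function(q) ifelse(q == 0, 0, q * log2(q))
  -(term(p) + term(1 - p))
}

#' Information value under each model
#'
#' `linear_value()`, `entropy_reduction_value()` and
#' `early_resolution_value()` evaluate one model's Information Value at a
#' number of informative windows; `info_value()` dispatches on the model
#' identifier ([info_models()]).
#'
#' `entropy_reduction_value(i)` enumerates all \eqn{2^i} equiprobable
#' permutations of winning/losing faces on the informative windows, computes
#' each permutation's information content
#' \eqn{I = H(P(win)_{prior}) - H(P(win)_{post})} with
#' \eqn{H(P(win)_{prior}) = 1} bit, and returns the mean of \eqn{I}
#' (aggregated over win counts with binomial weights, which is equivalent
#' because the win probability depends only on the counts).
#'
#' `early_resolution_value(i)` is the closed-form binomial probability that
#' the revealed permutation already fixes the outcome:
#' \deqn{P(early \mid i) = \sum_{k=3}^{i} \binom{i}{k} 0.5^{i-1}}
#' for \eqn{i \ge 3} and 0 otherwise (the factor \eqn{0.5^{i-1}} counts
#' permutations with at least three winning *or* three losing faces).
#'
#' @param i Integer vector, number of informative windows, each in 0..5.
#' @param model_id One of `"baseline"`, `"linear"`, `"entropy_reduction"`,
#'   `"early_resolution"`.
#' @return Numeric vector of Information Values in \[0, 1\] (bits for
#'   entropy reduction, a probability for early resolution).
#' @examples
#' entropy_reduction_value(0:5)
#' early_resolution_value(0:5)
#' info_value("linear", 3)
#' @export
info_value <- function(model_id, i) {
  model_id <- match.arg(model_id, info_models())
  switch(model_id,
    baseline = baseline_value(i),
    linear = linear_value(i),
    entropy_reduction = entropy_reduction_value(i),
    early_resolution = early_resolution_value(i)
  )
}

#' @rdname info_value
#' @export
baseline_value <- function(i) {
  i <- check_i(i)
  rep(0, length(i))
}

#' @rdname info_value
#' @export
linear_value <- function(i) {
  i <- check_i(i)
  i / 5
}

#' @rdname info_value
#' @export
entropy_reduction_value <- function(i) {
  i <- check_i(i)
  one <- function(ii) {
    if (ii == 0L) return(0)
    wins <- 0:ii
    weights <- choose(ii, wins) / 2^ii
    h_post <- vapply(wins, function(w) {
      shannon_entropy(win_probability_counts(w, ii))
    }, numeric(1))
    sum(weights * (1 - h_post))
  }
  vapply(i, one, numeric(1))
}

#' @rdname info_value
#' @export
early_resolution_value <- function(i) {
  i <- check_i(i)
  ifelse(i < 3L, 0, vapply(i, function(ii) {
    if (ii < 3L) 0 else sum(choose(ii, 3:ii)) * 0.5^(ii - 1L)
  }, numeric(1)))
}

#' Tabulate Information Values
#'
#' Builds the tidy table of Information Values for every level of
#' information availability (0--5 informative windows) under one or more
#' models. With the default `models`, the result is the full 4-model by
#' 6-level table; each model's value sequence is non-decreasing in the
#' number of informative windows and (except for the baseline) ends at 1.
#'
#' @param models Character vector of model identifiers; defaults to all
#'   four ([info_models()]).
#' @param digits Round values to this many decimals; `NULL` keeps full
#'   precision. The conventional display precision is 3 decimals.
#' @return A data.frame with columns `model_id`, `n_informative`, `value`.
#' @examples
#' info_value_table("early_resolution")
#' subset(info_value_table(digits = 3), n_informative == 3)
#' @export
info_value_table <- function(models = info_models(), digits = NULL) {
  models <- match.arg(models, info_models(), several.ok = TRUE)
  out <- do.call(rbind, lapply(models, function(m) {
    data.frame(model_id = m, n_informative = 0:5,
               value = info_value(m, 0:5), stringsAsFactors = FALSE)
  }))
  if (!is.null(digits)) out$value <- round(out$value, digits)
  rownames(out) <- NULL
  out
}
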