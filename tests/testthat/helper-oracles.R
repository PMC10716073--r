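# Brute-force enumeration oracles, independent of the package internals.
# Faces are coded 1 = winning, 0 = losing; a lottery wins on >= 3 winning
# faces among the 5 windows.

# all 0/1 vectors of length n, one per row (2^n rows; 1 row of length 0)
enum_bits <- function(n) {
  if (n == 0) return(matrix(integer(0), nrow = 1))
  as.matrix(expand.grid(rep(list(0:1), n)))
}

# P(win) given revealed faces at specific window positions: enumerate every
# completion of the unrevealed windows
oracle_win_prob <- function(faces, positions) {
  stopifnot(length(faces) == length(positions))
  free <- setdiff(1:5, positions)
  completions <- enum_bits(length(free))
  full <- matrix(NA_integer_, nrow(completions), 5)
  full[, positions] <- rep(faces, each = nrow(completions))
  full[, free] <- completions
  mean(rowSums(full) >= 3)
}

oracle_entropy <- function(p) {
  if (p == 0 || p == 1) return(0)
  -(p * log2(p) + (1 - p) * log2(1 - p))
}

# mean information content over all 2^i equiprobable revealed permutations,
# informative windows fixed at positions 1..i (position-independent)
oracle_entropy_reduction <- function(i) {
  perms <- enum_bits(i)
  mean(apply(perms, 1, function(s) {
    1 - oracle_entropy(oracle_win_prob(s, seq_len(i)))
  }))
}

# fraction of 2^i revealed permutations that already fix the outcome
oracle_early_resolution <- function(i) {
  perms <- enum_bits(i)
  mean(apply(perms, 1, function(s) sum(s) >= 3 || sum(1 - s) >= 3))
}

as_faces <- function(bits) c("LOSS", "WIN")[bits + 1]

# every window mask with i informative windows, as a 0/1 string
all_masks_for_test <- function(i) {
  if (i == 0) return("00000")
  apply(utils::combn(5, i), 2, function(pos) {
    m <- rep("0", 5)
    m[pos] <- "1"
    paste(m, collapse = "")
  })
}

# small simulated cohort reused across glmm tests
tiny_cohort <- function(n_subjects = 6, experiment = 1, seed = 42, ...) {
  simulate_cohort(n_subjects, experiment = experiment, seed = seed, ...)
}
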