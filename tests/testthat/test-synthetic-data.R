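popcount <- function(mask) {
  vapply(strsplit(mask, ""), function(ch) sum(ch == "1"), integer(1))
}

test_that("experiment designs are exactly balanced", {
  d1 <- build_design(1, seed = 1)
  expect_equal(nrow(d1), 180L)
  expect_equal(unname(table(d1$n_informative)), rep(30L, 6), ignore_attr = TRUE)
  expect_true(all(d1$stake_cents == 50L))
  expect_true(all(is.na(d1$arrangement)))

  d2 <- build_design(2, seed = 1)
  expect_equal(nrow(d2), 180L)
  cell <- table(d2$n_informative, d2$stake_cents)
  expect_true(all(cell == 6L))

  d3 <- build_design(3, seed = 1)
  expect_equal(nrow(d3), 180L)
  cell3 <- table(d3$n_informative, d3$arrangement, useNA = "ifany")
  expect_true(all(cell3[2:5, c("EARLY", "LATE")] == 18L))
  expect_equal(unname(cell3["0", 3]), 18L)
  expect_equal(unname(cell3["5", 3]), 18L)
  expect_equal(unname(table(d3$stake_cents)), rep(36L, 5), ignore_attr = TRUE)

  expect_error(build_design(4), "experiment")
})

test_that("window masks respect availability, pools and timing placement", {
  d1 <- build_design(1, seed = 8)
  expect_equal(popcount(d1$window_mask), d1$n_informative)
  # two informative windows: exactly the C(5,2) = 10 possible arrangements
  pool2 <- unique(d1$window_mask[d1$n_informative == 2])
  expect_true(length(pool2) <= 10)
  expect_true(all(popcount(pool2) == 2L))

  d3 <- build_design(3, seed = 8)
  early <- d3[!is.na(d3$arrangement) & d3$arrangement == "EARLY", ]
  late <- d3[!is.na(d3$arrangement) & d3$arrangement == "LATE", ]
  expect_equal(unique(early$window_mask[early$n_informative == 2]), "11000")
  expect_equal(unique(late$window_mask[late$n_informative == 2]), "00011")
  expect_equal(unique(early$window_mask[early$n_informative == 4]), "11110")
  expect_equal(unique(late$window_mask[late$n_informative == 4]), "01111")
})

test_that("designs and cohorts are reproducible under a seed", {
  expect_identical(build_design(2, seed = 99), build_design(2, seed = 99))
  expect_identical(simulate_cohort(3, experiment = 1, seed = 7),
                   simulate_cohort(3, experiment = 1, seed = 7))
})

test_that("lotteries follow the majority rule and reveal veridical faces", {
  set.seed(5)
  for (r in 1:50) {
    mask <- sample(all_masks_for_test(sample(0:5, 1)), 1)
    lot <- simulate_lottery(mask)
    wins <- sum(lot$lottery_faces == "WIN")
    expect_equal(lot$outcome, if (wins >= 3) "WIN" else "LOSS")
    informative <- strsplit(mask, "")[[1]] == "1"
    expect_equal(lot$revealed_faces[informative],
                 lot$lottery_faces[informative])
  }
  set.seed(6)
  full <- simulate_lottery("11111")
  expect_equal(full$revealed_faces, full$lottery_faces)
})

test_that("the win rate is 50% independent of the window mask", {
  # accept every gamble so each trial's outcome is observed
  n <- 100000L
  set.seed(31)
  design <- data.frame(
    experiment = 1L, trial_index = seq_len(n),
    n_informative = sample(0:5, n, replace = TRUE),
    stake_cents = 50L, arrangement = NA_character_
  )
  design$window_mask <- vapply(design$n_informative, function(i) {
    sample(all_masks_for_test(i), 1)
  }, character(1))
  rec <- simulate_choices(design, intercept = 50, beta_info = 0,
                          beta_stake = 0)
  expect_true(all(rec$choice == "ACCEPT"))
  won <- rec$outcome == "WIN"
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(won) - 0.5), 3 * se)
  # independence of mask: chi-square across information levels
  expect_gt(chisq.test(table(rec$n_informative, won))$p.value, 0.01)
  # veridicality on every accepted trial
  minf <- t(vapply(strsplit(rec$window_mask, ""), `==`, logical(5), "1"))
  lotm <- do.call(rbind, strsplit(rec$lottery_faces, ""))
  revm <- do.call(rbind, strsplit(rec$revealed_faces, ""))
  expect_true(all(lotm[minf] == revm[minf]))
})

test_that("choice probabilities follow the generative logistic model", {
  n <- 10000L
  design <- data.frame(
    experiment = 1L, trial_index = seq_len(n), n_informative = 5L,
    window_mask = "11111", stake_cents = 30L, arrangement = NA_character_
  )
  set.seed(21)
  flat <- simulate_choices(design, intercept = 0, beta_info = 0,
                           beta_stake = 0)
  expect_lt(abs(mean(flat$choice == "ACCEPT") - 0.5), 3 * sqrt(0.25 / n))
  set.seed(22)
  steep <- simulate_choices(design, intercept = 0, beta_info = 2,
                            beta_stake = 0, model = "early_resolution")
  p <- plogis(2)
  expect_lt(abs(mean(steep$choice == "ACCEPT") - p),
            4 * sqrt(p * (1 - p) / n))
  # rejected trials carry no outcome, payoff or revealed sequence
  rej <- flat[flat$choice == "REJECT", ]
  expect_true(all(rej$outcome == "NONE"))
  expect_true(all(rej$payoff_cents == 0L))
  expect_true(all(rej$revealed_faces == ""))
  acc <- flat[flat$choice == "ACCEPT", ]
  expect_true(all(acc$payoff_cents == ifelse(acc$outcome == "WIN", 30L, -30L)))
})

test_that("cohort size, defaults and degenerate sigma behave as specified", {
  tr <- simulate_cohort(22, experiment = 1, seed = 12)
  expect_equal(nrow(tr), 22L * 180L)
  expect_equal(length(unique(tr$subject_id)), 22L)
  expect_error(simulate_cohort(0, experiment = 1), "positive")
  expect_error(simulate_cohort(3, experiment = 1, sigma = -1), "non-negative")
  # sigma = 0: acceptance rates are exchangeable across subjects
  tr0 <- simulate_cohort(40, experiment = 1, sigma = 0, mu = 0,
                         beta_info = 0, seed = 13)
  rates <- tapply(tr0$choice == "ACCEPT", tr0$subject_id, mean)
  expect_gt(chisq.test(cbind(rates * 180, (1 - rates) * 180))$p.value, 0.01)
})
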