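make_session <- function(correct_pattern) {
  # one participant, trials interleaved in condition blocks of 4 so each
  # condition's k-th occurrence is at a known position
  cond <- rep(GNG_CONDITIONS_ <- c("G2W", "NG2W", "G2AL", "NG2AL"), times = 36)
  correct <- c(G2W = "go", NG2W = "nogo", G2AL = "go", NG2AL = "nogo")
  k <- ave(seq_along(cond), cond, FUN = seq_along)
  act <- ifelse(correct_pattern(k), correct[cond],
                ifelse(correct[cond] == "go", "nogo", "go"))
  win <- cond %in% c("G2W", "NG2W")
  tibble::tibble(
    participant_id = "p1", session = "baseline",
    trial_index = seq_along(cond),
    stimulus_id = match(cond, c("G2W", "NG2W", "G2AL", "NG2AL")),
    condition = cond, action = unname(act),
    outcome = as.integer(ifelse(win, act == correct[cond],
                                -(act != correct[cond]))),
    feedback_valid = TRUE)
}

test_that("the early ramp, late window and overall fractions follow the weighting rule", {
  all_right <- make_session(function(k) rep(TRUE, length(k)))
  for (ph in c("early", "late", "all"))
    expect_equal(unname(weighted_performance(all_right, ph)), rep(1, 4))
  all_wrong <- make_session(function(k) rep(FALSE, length(k)))
  for (ph in c("early", "late", "all"))
    expect_equal(unname(weighted_performance(all_wrong, ph)), rep(0, 4))

  # first 18 occurrences correct, last 18 incorrect
  half <- make_session(function(k) k <= 18)
  expect_equal(unname(weighted_performance(half, "early")), rep(1, 4))
  expect_equal(unname(weighted_performance(half, "late")), rep(0, 4))
  expect_equal(unname(weighted_performance(half, "all")), rep(0.5, 4))

  # fractions are invariant to reordering other conditions' trials
  s <- random_session(51)
  base <- weighted_performance(s, "early")
  other <- which(s$condition != "G2W")
  perm <- s
  perm[other, ] <- perm[rev(other), ]
  perm$trial_index <- s$trial_index
  expect_equal(weighted_performance(perm, "early")[["G2W"]], base[["G2W"]])

  # all-missing condition is flagged as undefined
  miss <- s
  miss$action[miss$condition == "NG2W"] <- "missing"
  expect_true(is.na(weighted_performance(miss, "all")[["NG2W"]]))
})

test_that("the descriptive Pavlovian-bias index is exact and antisymmetric", {
  expect_equal(pav_bias_index(c(G2W = 0.9, NG2W = 0.5, NG2AL = 0.8,
                                G2AL = 0.6)), 0.3)
  f <- c(G2W = 0.7, NG2W = 0.4, G2AL = 0.55, NG2AL = 0.85)
  equal <- c(G2W = 0.6, NG2W = 0.6, G2AL = 0.6, NG2AL = 0.6)
  expect_equal(pav_bias_index(equal), 0)
  # swapping congruent and incongruent labels within each valence flips sign
  swapped <- c(G2W = f[["NG2W"]], NG2W = f[["G2W"]],
               G2AL = f[["NG2AL"]], NG2AL = f[["G2AL"]])
  expect_equal(pav_bias_index(swapped), -pav_bias_index(f))
  expect_true(is.na(pav_bias_index(c(G2W = 0.5, NG2W = NA, G2AL = 0.5,
                                     NG2AL = 0.5))))
})

test_that("paired change tests detect planted shifts and are null on identical cohorts", {
  sim <- simulate_cohort(population_spec(n = 15, seed = 53))
  same <- condition_change_tests(sim$cohorts$baseline, sim$cohorts$baseline)
  expect_true(all(same$median_diff == 0))
  expect_true(all(same$p_corrected == 1))

  # plant a +0.05 accuracy shift in G2AL by flipping wrong answers to right
  spec <- population_spec(n = 300, seed = 54)
  sim2 <- simulate_cohort(spec)
  shifted <- sim2$cohorts$baseline
  withr::with_seed(55, {
    for (id in unique(shifted$participant_id)) {
      rows <- which(shifted$participant_id == id & shifted$condition == "G2AL" &
                      shifted$action == "nogo")
      nflip <- min(length(rows), round(0.05 * 36))
      if (nflip > 0) {
        fl <- sample(rows, nflip)
        shifted$action[fl] <- "go"
        shifted$outcome[fl] <- as.integer(ifelse(shifted$feedback_valid[fl], 0, -1))
      }
    }
  })
  cc <- condition_change_tests(sim2$cohorts$baseline, shifted)
  got <- cc$median_diff[cc$condition == "G2AL"]
  expect_lt(abs(got - 0.05), 0.02)
  expect_lt(cc$p_corrected[cc$condition == "G2AL"], 0.01)
})

test_that("cross-condition contrasts are near zero for chance-level performers", {
  spec <- population_spec(n = 40, mean = c(xi = qlogis(0.99)),
                          sd = c(xi = 0.01), seed = 56)
  sim <- simulate_cohort(spec)
  ct <- cross_condition_tests(sim$cohorts$baseline, "all")
  expect_true(all(abs(ct$median_diff) < 0.12))
  # and detect the congruency gap for Pavlovian agents in early trials
  spec2 <- population_spec(n = 60, mean = c(b_pav = log(1.2)), seed = 57)
  sim2 <- simulate_cohort(spec2)
  ct2 <- cross_condition_tests(sim2$cohorts$baseline, "early")
  gap <- ct2[ct2$condition_1 == "NG2W" & ct2$condition_2 == "G2AL", ]
  expect_lt(gap$median_diff, 0)  # G2AL starts better than NG2W
})

test_that("performance summaries attach the bias index per participant and phase", {
  sim <- simulate_cohort(population_spec(n = 4, seed = 58))
  ps <- performance_summary(sim$cohorts$baseline)
  expect_equal(nrow(ps), 4 * 3)
  expect_true(all(ps$G2W >= 0 & ps$G2W <= 1, na.rm = TRUE))
  one <- ps[ps$participant_id == ps$participant_id[1] & ps$phase == "all", ]
  expect_equal(one$pav_bias,
               ((one$G2W - one$NG2W) + (one$NG2AL - one$G2AL)) / 2)
})
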