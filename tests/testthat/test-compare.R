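test_that("prediction probability per trial is the geometric mean and monotone in evidence", {
  expect_equal(ppt(144 * log(0.5), 144), 0.5)
  expect_equal(ppt(0, 144), 1)
  expect_equal(round(ppt(-64.4, 144), 3), 0.639)
  il <- seq(-120, -40, by = 10)
  expect_true(all(diff(ppt(il, 144)) > 0))
  expect_error(ppt(5, 144))
})

test_that("iBIC comparison is exact on self and errors on mismatched cohorts", {
  sim <- simulate_cohort(population_spec(n = 10, seed = 41))
  fit <- fit_em(sim$cohorts$baseline, "valenced_learning", seed = 13,
                n_samples = 400, max_iter = 10)
  self <- compare_ibic(fit, fit)
  expect_equal(self$delta_ibic, 0)
  expect_true(all(self$delta_il == 0))
  expect_equal(self$wilcoxon_p, 1)

  other <- fit
  other$subjects <- other$subjects[-1, ]
  expect_error(compare_ibic(fit, other), "agent0001")
})

test_that("protected exceedance behaves at its symmetry, dominance and exchangeability limits", {
  set.seed(7)
  L <- cbind(m1 = rnorm(60, -70, 5), m2 = rnorm(60, -70, 5))
  L[, 2] <- L[, 1]  # identical evidence
  px <- protected_exceedance(L, seed = 2)
  expect_equal(px$protected_exceedance, c(0.5, 0.5), tolerance = 0.02)
  expect_equal(sum(px$exceedance), 1, tolerance = 1e-9)

  # one model better by 10 nats for every subject
  L2 <- cbind(good = rnorm(100, -60, 3), bad = NA)
  L2[, 2] <- L2[, 1] - 10
  px2 <- protected_exceedance(L2, seed = 3)
  expect_gt(px2$protected_exceedance[1], 0.99)

  # permuting model order permutes the output
  px2r <- protected_exceedance(L2[, 2:1], seed = 3)
  expect_equal(px2$protected_exceedance,
               rev(px2r$protected_exceedance), tolerance = 0.01)
  expect_error(protected_exceedance(L2[, 1, drop = FALSE]), "at least 2")
})

test_that("a model compared against itself by LOL gives exactly zero paired differences", {
  sim <- simulate_cohort(population_spec(n = 16, seed = 43))
  lc <- lol_config(training_n = 10, chains = 1, draws = 200, warmup = 150,
                   n_boot = 200, seed = 14)
  res <- lol_compare(sim$cohorts$baseline,
                     list(a = "valenced_learning", b = "valenced_learning"),
                     lc, fit_args = list(max_iter = 8, n_samples = 300))
  wide <- tidyr::pivot_wider(res$per_subject[, c("participant_id", "model", "lol")],
                             names_from = "model", values_from = "lol")
  expect_equal(wide$a, wide$b, tolerance = 0)
  expect_equal(res$comparisons$median_delta_ppt, 0)
  # and the run itself is reproducible
  res2 <- lol_compare(sim$cohorts$baseline,
                      list(a = "valenced_learning", b = "valenced_learning"),
                      lc, fit_args = list(max_iter = 8, n_samples = 300))
  expect_equal(res$per_subject$lol, res2$per_subject$lol, tolerance = 0)
})

test_that("LOL bookkeeping: Ppt signs agree, CIs contain the point estimate, split is deterministic", {
  sim <- simulate_cohort(population_spec(n = 24, seed = 45))
  lc <- lol_config(training_n = 14, chains = 2, draws = 300, warmup = 200,
                   n_boot = 500, seed = 15)
  res <- lol_compare(sim$cohorts$baseline,
                     list("valenced_learning", "valenced_sensitivity"), lc,
                     fit_args = list(max_iter = 10, n_samples = 400))
  expect_equal(sort(c(res$train_ids, res$test_ids)),
               sort(unique(sim$cohorts$baseline$participant_id)))
  expect_length(res$train_ids, 14)
  wide <- tidyr::pivot_wider(res$per_subject[, c("participant_id", "model", "lol")],
                             names_from = "model", values_from = "lol")
  d_lol <- wide$valenced_learning - wide$valenced_sensitivity
  d_ppt <- ppt(wide$valenced_learning, 2) - ppt(wide$valenced_sensitivity, 2)
  expect_true(all(sign(d_lol) == sign(d_ppt)))
  cmp <- res$comparisons
  expect_true(cmp$ci_lower <= cmp$median_delta_ppt + 1e-12)
  expect_true(cmp$ci_upper >= cmp$median_delta_ppt - 1e-12)
  expect_true(all(res$grand_mean_ppt$grand_mean_ppt > 0 &
                    res$grand_mean_ppt$grand_mean_ppt <= 1))
  expect_error(lol_compare(sim$cohorts$baseline, list("valenced_learning"),
                           lc), "at least 2")
  expect_error(lol_compare(sim$cohorts$baseline,
                           list("valenced_learning", "valenced_sensitivity"),
                           lol_config(training_n = 24)), "larger")
})

test_that("held-out likelihoods degrade against truth as more trials are left out", {
  # replication of the left-out-trial count study at 100 training / 50 test
  # agents: estimate the generative model's LOL from per-subject posteriors
  # and compare with the true LOL at the generative parameters
  sel <- model_selection_fixture()
  cohort <- sel$sim$cohorts$baseline
  model <- gng_model("valenced_learning")
  truth <- sel$sim$params
  ids <- unique(cohort$participant_id)
  split_ids <- withr::with_seed(16, sample(ids))
  train_ids <- split_ids[1:100]
  test_ids <- split_ids[101:150]
  prior <- fit_em(cohort[cohort$participant_id %in% train_ids, ],
                  model, seed = 17, max_iter = 60)$prior
  run_lots <- function(lots) {
    cfg <- lol_config(left_out_trials = lots, chains = 2, draws = 400,
                      warmup = 300, seed = 18)
    d <- vapply(seq_along(test_ids), function(i) {
      id <- test_ids[i]
      s <- cohort[cohort$participant_id == id, ]
      arr <- gngbias:::session_arrays(s)
      est <- gngbias:::sample_subject_posterior(
        arr, model, prior, lots, cfg, gngbias:::derive_seed(18, 79, i))$lol
      pars <- unlist(truth[truth$participant_id == id, model$params])
      est - sum(session_log_likelihood(s, pars, model)$trial_logp[lots])
    }, numeric(1))
    boots <- withr::with_seed(19, replicate(1000, mean(sample(d, replace = TRUE))))
    c(mean = mean(d), lo = quantile(boots, 0.025, names = FALSE),
      hi = quantile(boots, 0.975, names = FALSE))
  }
  few <- run_lots(c(48, 96))
  many <- run_lots(round(seq(9, 144, length.out = 16)))
  # two held-out trials: the interval covers the truth
  expect_true(few[["lo"]] <= 0 && few[["hi"]] >= 0)
  # sixteen held-out trials: the estimate departs detectably from truth
  expect_true(many[["hi"]] < 0 || many[["lo"]] > 0)
})
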