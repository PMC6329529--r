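test_that("single-trial value updates follow the Rescorla-Wagner rule", {
  st <- learner_state()
  p <- vl_params(rho = 2, lam_app = 0.1)
  trial <- list(stimulus_id = 1L, condition = "G2W", action = "go",
                outcome = 1L)
  st2 <- update_values(st, trial, p, "valenced_learning")
  expect_equal(unname(st2$Q["go", 1]), 0.1 * (2 * 1 - 0), tolerance = 1e-12)  # 0.2
  expect_equal(st2$V[1], 0.2, tolerance = 1e-12)
  # everything else carried forward
  expect_equal(unname(st2$Q["nogo", 1]), 0)
  expect_equal(st2$Q[, 2:4], st$Q[, 2:4])
  expect_equal(st2$V[2:4], st$V[2:4])

  # zero learning rate leaves the state unchanged
  p0 <- vl_params(lam_app = 1e-300, lam_av = 1e-300)
  p0["lam_app"] <- 0.0  # natural space allows 0 here; update is a no-op
  st3 <- update_values(st, trial, p0, "valenced_learning")
  expect_equal(st3$Q, st$Q)

  # missing action is a no-op
  st4 <- update_values(st2, list(stimulus_id = 1L, condition = "G2W",
                                 action = "missing", outcome = 0L),
                       p, "valenced_learning")
  expect_identical(st4, st2)

  # forgetting decays only non-realized Q entries, toward zero
  stf <- learner_state()
  stf$Q[] <- 1
  pf <- c(vl_params(), m = 0.9)
  st5 <- update_values(stf, trial, pf, "valenced_learning+forget")
  expect_equal(unname(st5$Q["nogo", 1]), 0.9)
  expect_equal(unname(st5$Q["go", 2]), 0.9)
  expect_equal(unname(st5$Q["go", 1]), 1 + 0.1 * (2 - 1))  # updated, not decayed
})

test_that("propensities add Go and Pavlovian bias to the Go action only", {
  st <- learner_state()
  st$Q["go", 2] <- 0.5
  st$Q["nogo", 2] <- -0.1
  st$V[2] <- -0.4
  q <- action_propensities(st, 2, vl_params(b_go = 0.2, b_pav = 0.3),
                           "valenced_learning")
  expect_equal(unname(q["q_go"]), 0.5 + 0.2 + 0.3 * (-0.4))  # 0.58
  expect_equal(unname(q["q_nogo"]), -0.1)                    # untouched
})

test_that("the lapse-mixed softmax matches closed forms and stays in bounds", {
  expect_equal(unname(choice_probability(c(0, 0), 0)), c(0.5, 0.5))
  expect_equal(unname(choice_probability(c(5, -3), 1)), c(0.5, 0.5))
  p <- choice_probability(c(1, 0), 0)
  expect_equal(unname(p["p_go"]), exp(1) / (exp(1) + 1), tolerance = 1e-6)
  expect_equal(round(unname(p["p_go"]), 4), 0.7311)
  p2 <- choice_probability(c(1, 0), 0.1)
  expect_equal(round(unname(p2["p_go"]), 4), 0.7080)
  # overflow safety and bounds
  for (xi in c(0, 0.2, 0.9)) {
    pr <- choice_probability(c(900, -900), xi)
    expect_equal(sum(pr), 1)
    expect_true(all(pr >= xi / 2 - 1e-12 & pr <= 1 - xi / 2 + 1e-12))
  }
})

test_that("session log-likelihood matches an independent reference implementation", {
  for (seed in 1:6) {
    model <- c("valenced_learning", "valenced_sensitivity",
               "sensitivity_ratio")[(seed %% 3) + 1]
    p <- switch(model,
      valenced_learning = vl_params(),
      valenced_sensitivity = c(rho_app = 2, rho_av = 3, lam = 0.15,
                               b_go = 0.3, b_pav = 0.5, xi = 0.05),
      sensitivity_ratio = c(rho_app = 2, kappa = 0.4, lam = 0.15,
                            b_go = 0.3, b_pav = 0.5, xi = 0.05))
    s <- random_session(seed, p, model, n_missing = seed)
    skip_idx <- if (seed > 3) c(48L, 96L) else integer()
    got <- session_log_likelihood(s, p, model, skip = skip_idx)
    ref <- ref_session_loglik(s, p, model, skip = skip_idx)
    expect_equal(got$total, ref$total, tolerance = 1e-10)
    expect_equal(got$trial_logp, ref$trial_logp, tolerance = 1e-10)
  }
  # forgetting variant against the reference too
  pf <- c(vl_params(), m = 0.92)
  s <- random_session(31, pf, "valenced_learning+forget")
  got <- session_log_likelihood(s, pf, "valenced_learning+forget")
  ref <- ref_session_loglik(s, pf, "valenced_learning+forget")
  expect_equal(got$total, ref$total, tolerance = 1e-10)
})

test_that("a hand-worked two-trial session matches to 1e-12", {
  s <- tibble::tibble(
    participant_id = "p1", session = "baseline", trial_index = 1:2,
    stimulus_id = c(1L, 1L), condition = c("G2W", "G2W"),
    action = c("go", "nogo"), outcome = c(1L, 0L),
    feedback_valid = c(TRUE, FALSE))
  rho <- 2; lam <- 0.1; b_go <- 0.2; b_pav <- 0.5; xi <- 0.1
  # trial 1: Q = V = 0, q_go = b_go, q_nogo = 0
  p1 <- (1 - xi) * exp(b_go) / (exp(b_go) + 1) + xi / 2
  # after trial 1: Q(go,1) = lam * rho, V(1) = lam * rho
  Qg <- lam * rho; V1 <- lam * rho
  q_go <- Qg + b_go + b_pav * V1
  p2go <- (1 - xi) * exp(q_go) / (exp(q_go) + 1) + xi / 2
  expected <- log(p1) + log(1 - p2go)
  got <- session_log_likelihood(
    s, vl_params(rho = rho, lam_app = lam, lam_av = 0.3, b_go = b_go,
                 b_pav = b_pav, xi = xi), "valenced_learning")
  expect_equal(got$total, expected, tolerance = 1e-12)
})

test_that("lapse-only sessions are at chance and skipping is additive", {
  p <- vl_params(xi = 1)
  s <- random_session(7, p)
  got <- session_log_likelihood(s, p, "valenced_learning")
  expect_equal(got$total, 144 * log(0.5), tolerance = 1e-9)

  p2 <- vl_params()
  s2 <- random_session(8, p2)
  full <- session_log_likelihood(s2, p2, "valenced_learning")
  part <- session_log_likelihood(s2, p2, "valenced_learning", skip = c(48, 96))
  expect_equal(part$total,
               full$total - full$trial_logp[48] - full$trial_logp[96],
               tolerance = 1e-10)
  # skipped trials still drive learning: later log-probabilities unchanged
  expect_equal(part$trial_logp, full$trial_logp, tolerance = 1e-12)
})

test_that("valenced-sensitivity and sensitivity-ratio are likelihood-identical per individual", {
  for (seed in c(3, 4)) {
    pv <- c(rho_app = 1.8, rho_av = 3.1, lam = 0.2, b_go = 0.4, b_pav = 0.3,
            xi = 0.06)
    pr <- c(rho_app = 1.8, kappa = log(3.1 / 1.8), lam = 0.2, b_go = 0.4,
            b_pav = 0.3, xi = 0.06)
    s <- random_session(seed, pv, "valenced_sensitivity")
    expect_equal(session_log_likelihood(s, pv, "valenced_sensitivity")$total,
                 session_log_likelihood(s, pr, "sensitivity_ratio")$total,
                 tolerance = 1e-10)
  }
})

test_that("parameter transforms are bijective with boundary guidance", {
  p <- vl_params()
  th <- transform_params(p, "valenced_learning", "to_transformed")
  back <- transform_params(th, "valenced_learning", "to_natural")
  expect_equal(back, p[names(back)], tolerance = 1e-10)
  expect_equal(unname(th["b_pav"]), log(0.5))
  expect_equal(unname(transform_params(vl_params(b_pav = 1),
                                       "valenced_learning",
                                       "to_transformed")["b_pav"]), 0)
  expect_error(transform_params(vl_params(lam_app = 1), "valenced_learning",
                                "to_transformed"), "machine epsilon")
  expect_error(transform_params(vl_params(b_pav = 0), "valenced_learning",
                                "to_transformed"), "machine epsilon")

  # log-normal median property: transformed-Gaussian prior mean mu for
  # b_pav corresponds to a natural-space median of exp(mu)
  mu <- -1.2
  draws <- exp(rnorm(20000, mu, 0.7))
  expect_lt(abs(median(draws) - exp(mu)) / exp(mu), 0.05)
})

test_that("the model registry exposes six variants with declared transforms", {
  expect_length(gng_models(), 6)
  m <- gng_model("valenced_learning+forget")
  expect_equal(m$n_params, 7)
  expect_equal(m$transform[m$params == "m"], "logit")
  expect_equal(gng_model("sensitivity_ratio")$transform[
    gng_model("sensitivity_ratio")$params == "kappa"], "identity")
  expect_error(gng_model("nonexistent"), "unknown model")
})
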