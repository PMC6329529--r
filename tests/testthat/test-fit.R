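test_that("the iBIC formula is exact", {
  # penalty alone: 6 subject-level parameters, means + variances, n_pt = 817
  expect_equal(2 * 6 * log(144 * 817), 140.11, tolerance = 0.001)

  fake <- list(subjects = tibble::tibble(il = -100), model = "valenced_learning",
               n_participants = 1, n_trials = 144)
  expect_equal(ibic(fake), 200 + 12 * log(144), tolerance = 1e-10)

  # monotone penalty: equal evidence, fewer parameters wins
  il <- rep(-70, 50)
  f6 <- list(il = il, model = "valenced_learning", n_participants = 50,
             n_trials = 144)
  f7 <- list(il = il, model = "valenced_learning+forget", n_participants = 50,
             n_trials = 144)
  expect_lt(ibic(f6), ibic(f7))
})

test_that("the integrated likelihood collapses to a point evaluation as the prior narrows", {
  p <- vl_params()
  s <- random_session(12, p)
  model <- gng_model("valenced_learning")
  th <- transform_params(p, model, "to_transformed")
  prior <- list(mean = th, sd = setNames(rep(1e-4, 6), model$params))
  r <- integrated_likelihood(s, prior, model, n_samples = 400, seed = 3)
  point <- session_log_likelihood(s, p, model)$total
  expect_lt(abs(r$il - point), 0.01)
})

test_that("the sampling estimate matches adaptive quadrature on a one-parameter problem", {
  # only b_go varies; all other prior masses are point-like
  p <- vl_params()
  s <- random_session(13, p)
  model <- gng_model("valenced_learning")
  th <- transform_params(p, model, "to_transformed")
  sdv <- setNames(c(1e-6, 1e-6, 1e-6, 0.8, 1e-6, 1e-6), model$params)
  prior <- list(mean = th, sd = sdv)
  r <- integrated_likelihood(s, prior, model, n_samples = 20000, seed = 4)
  integrand <- function(b) {
    vapply(b, function(bi) {
      pp <- p; pp["b_go"] <- bi
      exp(session_log_likelihood(s, pp, model)$total) *
        dnorm(bi, th[["b_go"]], 0.8)
    }, numeric(1))
  }
  quad <- log(integrate(integrand, th[["b_go"]] - 6 * 0.8,
                        th[["b_go"]] + 6 * 0.8, rel.tol = 1e-9)$value)
  expect_lt(abs(r$il - quad), 3 * r$se)
  expect_lt(abs(r$il - quad), 0.05)
})

test_that("the Monte-Carlo standard error shrinks like one over root n", {
  p <- vl_params()
  s <- random_session(14, p)
  model <- gng_model("valenced_learning")
  prior <- list(mean = transform_params(p, model, "to_transformed"),
                sd = setNames(rep(0.5, 6), model$params))
  ses <- vapply(c(1000, 4000, 16000), function(n) {
    integrated_likelihood(s, prior, model, n_samples = n, seed = 5)$se
  }, numeric(1))
  expect_equal(ses[1] / ses[2], 2, tolerance = 0.7)
  expect_equal(ses[2] / ses[3], 2, tolerance = 0.7)
  expect_true(all(diff(ses) < 0))
})

test_that("EM fits a small cohort deterministically and flags the trace", {
  sim <- simulate_cohort(population_spec(n = 14, seed = 31))
  fit <- fit_em(sim$cohorts$baseline, "valenced_learning", seed = 9,
                n_samples = 600, max_iter = 25)
  expect_s3_class(fit, "gng_fit")
  expect_equal(nrow(fit$subjects), 14)
  expect_true(all(fit$subjects$il <= 0))
  expect_equal(fit$ibic,
               -2 * sum(fit$subjects$il) + 12 * log(144 * 14),
               tolerance = 1e-8)
  # determinism
  fit2 <- fit_em(sim$cohorts$baseline, "valenced_learning", seed = 9,
                 n_samples = 600, max_iter = 25)
  expect_equal(fit$prior$mean, fit2$prior$mean, tolerance = 1e-12)
  expect_equal(fit$subjects$il, fit2$subjects$il, tolerance = 1e-12)
  # tidy/glance interface
  td <- tidy(fit)
  expect_true(all(c("participant_id", "b_pav", "il", "ppt") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_participants, 14)
  expect_error(fit_em(sim$cohorts$baseline[sim$cohorts$baseline$participant_id ==
                                             "agent0001", ],
                      "valenced_learning"), "at least 2")
})

test_that("a cohort of lapse-only agents is fitted to chance-level evidence", {
  spec <- population_spec(n = 10, mean = c(xi = qlogis(0.995)),
                          sd = list(rho = 0.1, lam_app = 0.1, lam_av = 0.1,
                                    b_go = 0.1, b_pav = 0.1, xi = 0.01),
                          seed = 33)
  sim <- simulate_cohort(spec)
  fit <- fit_em(sim$cohorts$baseline, "valenced_learning", seed = 10,
                n_samples = 600, max_iter = 30)
  # per-subject evidence within a few nats of pure chance
  expect_true(all(abs(fit$subjects$il - 144 * log(0.5)) < 6))
  # fitted lapse prior sits high, near the boundary region
  expect_gt(plogis(fit$prior$mean[["xi"]]), 0.6)
})

test_that("the Laplace-MAP E-step variant runs and carries its monotonicity diagnostic", {
  sim <- simulate_cohort(population_spec(n = 8, seed = 35))
  fit <- fit_em(sim$cohorts$baseline, "valenced_learning", seed = 11,
                n_samples = 400, max_iter = 8, estep = "map", n_restarts = 2)
  expect_s3_class(fit, "gng_fit")
  expect_true(all(c("iteration", "delta_mean", "objective") %in%
                    names(fit$trace)))
  expect_true(all(is.finite(fit$subjects$il)))
})

test_that("independently drawn parameters stay uncorrelated after fitting", {
  rec <- recovery_fixture()
  m <- rec$merged
  # generative parameters are independent by construction; the fitted
  # Pavlovian bias must not acquire a spurious correlation with the
  # learning rates
  expect_lt(abs(cor(m$t_b_pav_true, m$t_lam_app_true)), 0.12)
  expect_lt(abs(cor(m$t_b_pav_fit, m$t_lam_app_fit) -
                  cor(m$t_b_pav_true, m$t_lam_app_true)), 0.1)
  expect_lt(abs(cor(m$t_b_pav_fit, m$t_lam_av_fit) -
                  cor(m$t_b_pav_true, m$t_lam_av_true)), 0.1)
})

test_that("recovery is robust to misspecified Pavlovian-bias population families", {
  for (fam in c("gamma_natural", "normal_natural")) {
    spec <- population_spec(n = 100, family = fam, seed = 37)
    sim <- simulate_cohort(spec)
    fit <- fit_em(sim$cohorts$baseline, "valenced_learning", seed = 12,
                  n_samples = 1500, max_iter = 60)
    m <- dplyr::inner_join(sim$params, fit$subjects, by = "participant_id",
                           suffix = c("_true", "_fit"))
    r <- cor(m$b_pav_true, m$b_pav_fit, method = "spearman")
    expect_gt(r, 0.55)
  }
})
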