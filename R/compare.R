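#' Compare two hierarchical fits by iBIC
#'
#' @param fitA,fitB \code{gng_fit} objects for the same cohort and wave.
#' @return List with \code{delta_ibic} (\code{iBIC_B - iBIC_A}; positive
#'   favours A), per-subject \code{delta_il} (\code{iL_B - iL_A}) and a
#'   paired Wilcoxon signed-rank test on the per-subject integrated
#'   likelihoods.
#' @export
compare_ibic <- function(fitA, fitB) {
  a <- fitA$subjects; b <- fitB$subjects
  if (!setequal(a$participant_id, b$participant_id)) {
    d <- union(setdiff(a$participant_id, b$participant_id),
               setdiff(b$participant_id, a$participant_id))
    abort(paste("fits cover different participants:", paste(d, collapse = ", ")))
  }
  b <- b[match(a$participant_id, b$participant_id), ]
  d_il <- b$il - a$il
  wt <- if (all(d_il == 0)) list(statistic = NA_real_, p.value = 1)
        else suppressWarnings(wilcox.test(a$il, b$il, paired = TRUE, correct = TRUE))
  list(delta_ibic = fitB$ibic - fitA$ibic,
       delta_il = setNames(d_il, a$participant_id),
       wilcoxon_statistic = unname(wt$statistic),
       wilcoxon_p = wt$p.value)
}

#' Prediction probability per trial
#'
#' Converts a log-likelihood over \code{n} counted trials into the
#' geometric-mean per-trial prediction probability \eqn{Ppt =
#' \exp(iL/n)}.
#'
#' @param il Log-likelihood in nats (non-positive).
#' @param n_trials_counted Number of trials it covers.
#' @return Probability in (0, 1].
#' @examples
#' ppt(144 * log(0.5), 144)  # chance
#' @export
ppt <- function(il, n_trials_counted) {
  stopifnot(all(il <= 0), n_trials_counted > 0)
  exp(il / n_trials_counted)
}

#' Protected exceedance probabilities
#'
#' Random-effects Bayesian model selection over a matrix of per-subject
#' model log-evidences (integrated likelihoods): a variational Dirichlet
#' estimate of model frequencies, exceedance probabilities by Monte-Carlo,
#' and protection against the null of indistinguishable models via the
#' Bayesian omnibus risk, \eqn{PXP_k = (1 - BOR)\,XP_k + BOR/K}.
#'
#' @param il_matrix Numeric matrix, subjects x models (at least 2 models);
#'   column names label models.
#' @param n_draws Dirichlet draws for the exceedance Monte-Carlo.
#' @param seed Integer seed.
#' @return Tibble with per-model expected frequency, exceedance and
#'   protected exceedance probabilities (each set sums to 1), plus the BOR
#'   as an attribute.
#' @export
protected_exceedance <- function(il_matrix, n_draws = 1e5, seed = 1) {
  L <- as.matrix(il_matrix)
  K <- ncol(L)
  if (K < 2) abort("protected_exceedance needs at least 2 models")
  n <- nrow(L)
  alpha0 <- rep(1, K)
  alpha <- alpha0
  z <- matrix(1 / K, n, K)
  for (it in 1:200) {
    lg <- sweep(L, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    z <- exp(lg - apply(lg, 1, logsumexp))
    alpha_new <- alpha0 + colSums(z)
    if (max(abs(alpha_new - alpha)) < 1e-8) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  # exceedance by Dirichlet Monte-Carlo
  xp <- withr_seed(seed, {
    g <- matrix(rgamma(n_draws * K, shape = rep(alpha, each = n_draws)),
                nrow = n_draws)
    tabulate(max.col(g, ties.method = "random"), K) / n_draws
  })
  # Bayesian omnibus risk: H0 = equal frequencies
  f0 <- sum(apply(L, 1, logsumexp) - log(K))
  eln_r <- digamma(alpha) - digamma(sum(alpha))
  f1 <- sum(z * L) + sum(z %*% eln_r) +
    (lgamma(sum(alpha0)) - sum(lgamma(alpha0)) + sum((alpha0 - 1) * eln_r)) -
    sum(z * log(pmax(z, 1e-300))) -
    (lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * eln_r))
  bor <- 1 / (1 + exp(f1 - f0))
  pxp <- (1 - bor) * xp + bor / K
  out <- tibble::tibble(
    model = colnames(L) %||% paste0("model", seq_len(K)),
    expected_frequency = alpha / sum(alpha),
    exceedance = xp, protected_exceedance = pxp)
  attr(out, "bor") <- bor
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configure the left-out-likelihood procedure
#'
#' @param training_n Size of the group-training split used to fit the
#'   population prior (default 300).
#' @param left_out_trials 1-based session-global indices of the held-out
#'   trials (default the 48th and 96th).
#' @param chains,draws,warmup Per-subject random-walk Metropolis settings
#'   (defaults 4 chains x 2000 retained draws after 1000 warmup).
#' @param n_boot Bootstrap resamples for the CI of the median difference.
#' @param rhat_max Split-chain convergence threshold; subjects above it are
#'   flagged and excluded from the bootstrap CI.
#' @param seed Integer seed (controls the training split, the samplers and
#'   the bootstrap).  Chains for different models reuse the same per-subject
#'   seeds, so comparing a model with itself yields exactly zero paired
#'   differences.
#' @return A \code{gng_lol_config} list.
#' @export
lol_config <- function(training_n = 300, left_out_trials = c(48, 96),
                       chains = 4, draws = 2000, warmup = 1000,
                       n_boot = 10000, rhat_max = 1.1, seed = 1) {
  structure(list(training_n = training_n, left_out_trials = left_out_trials,
                 chains = chains, draws = draws, warmup = warmup,
                 n_boot = n_boot, rhat_max = rhat_max, seed = seed),
            class = "gng_lol_config")
}

#' Left-out-likelihood out-of-sample model comparison
#'
#' Splits the cohort into a group-training set and a test set by a
#' deterministic seeded shuffle; fits each model's population prior to the
#' training set by \code{\link{fit_em}}; then, for every test subject and
#' model, samples the individual posterior over transformed parameters given
#' the non-left-out trials only (the left-out trials' realized actions and
#' outcomes still drive value learning - "informed" handling - but
#' contribute no likelihood, so they never inform parameter estimation) and
#' averages the likelihood of the left-out actions over the posterior draws
#' to form the left-out likelihood (LOL).  Models are compared by paired
#' per-subject differences, with a bootstrap confidence interval for the
#' median difference in per-trial prediction probability.
#'
#' @param cohort A validated single-wave cohort larger than
#'   \code{config$training_n}.
#' @param models List (optionally named) of at least two model names or
#'   \code{\link{gng_model}} objects.  The first model is the reference.
#' @param config A \code{\link{lol_config}}.
#' @param fit_args Extra arguments passed to \code{\link{fit_em}} for the
#'   training fits.
#' @return A \code{gng_lol}: per-subject LOL per model, paired differences
#'   versus the reference model with \eqn{\Delta Ppt} and bootstrap CI of
#'   the median, grand mean Ppt over test subjects and left-out trials, and
#'   sampler diagnostics.
#' @export
lol_compare <- function(cohort, models, config = lol_config(),
                        fit_args = list()) {
  models <- lapply(models, as_gng_model)
  if (length(models) < 2) abort("lol_compare needs at least 2 models")
  mnames <- names(models) %||% rep("", length(models))
  empty <- !nzchar(mnames)
  mnames[empty] <- vapply(models[empty], function(m) m$name, character(1))
  mnames <- make.unique(mnames)
  ids <- unique(cohort$participant_id)
  if (length(ids) <= config$training_n)
    abort("cohort must be larger than the training split")
  shuffled <- withr_seed(derive_seed(config$seed, 71), sample(ids))
  train_ids <- shuffled[seq_len(config$training_n)]
  test_ids <- setdiff(shuffled, train_ids)
  training <- cohort[cohort$participant_id %in% train_ids, ]
  test_sessions <- split_sessions(cohort[cohort$participant_id %in% test_ids, ])

  lot <- as.integer(config$left_out_trials)
  n_lot <- length(lot)

  priors <- purrr::map(models, function(m) {
    # seed keyed by model identity, so identical models get identical fits
    fit <- do.call(fit_em, c(list(cohort = training, model = m,
                                  seed = derive_seed(config$seed, 73,
                                                     sum(utf8ToInt(m$name)))),
                             fit_args))
    fit$prior
  })
  names(priors) <- mnames

  rows <- list()
  for (i in seq_along(test_sessions)) {
    arr <- session_arrays(test_sessions[[i]])
    sid <- names(test_sessions)[i]
    sseed <- derive_seed(config$seed, 79, i)  # shared across models
    for (j in seq_along(models)) {
      s <- sample_subject_posterior(arr, models[[j]], priors[[j]], lot,
                                    config, sseed)
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant_id = sid, model = mnames[j], lol = s$lol,
        rhat = s$rhat, accept = s$accept,
        flagged = is.na(s$rhat) || s$rhat > config$rhat_max)
    }
  }
  per_subject <- dplyr::bind_rows(rows)

  wide <- tidyr::pivot_wider(per_subject[, c("participant_id", "model", "lol")],
                             names_from = "model", values_from = "lol")
  flagged_ids <- unique(per_subject$participant_id[per_subject$flagged])
  ref <- mnames[1]
  comp <- list()
  for (j in seq_along(mnames)[-1]) {
    alt <- mnames[j]
    d_lol <- wide[[ref]] - wide[[alt]]
    d_ppt <- ppt(wide[[ref]], n_lot) - ppt(wide[[alt]], n_lot)
    keep <- !(wide$participant_id %in% flagged_ids)
    ci <- withr_seed(derive_seed(config$seed, 83, j), {
      boots <- replicate(config$n_boot,
                         median(sample(d_ppt[keep], replace = TRUE)))
      quantile(boots, c(0.025, 0.975), names = FALSE)
    })
    comp[[alt]] <- tibble::tibble(
      reference = ref, model = alt,
      median_delta_lol = median(d_lol[keep]),
      median_delta_ppt = median(d_ppt[keep]),
      ci_lower = ci[1], ci_upper = ci[2],
      n_subjects = sum(keep), n_flagged = sum(!keep))
  }
  grand <- dplyr::summarise(
    dplyr::group_by(per_subject, .data$model),
    grand_mean_ppt = mean(ppt(.data$lol, n_lot)), .groups = "drop")

  structure(list(per_subject = per_subject,
                 comparisons = dplyr::bind_rows(comp),
                 grand_mean_ppt = grand,
                 train_ids = train_ids, test_ids = test_ids,
                 priors = priors, config = config),
            class = "gng_lol")
}

# Random-walk Metropolis on the transformed-parameter posterior of one
# subject, with the left-out trials' likelihood excluded from the target
# (informed handling) and the LOL accumulated over retained draws.
sample_subject_posterior <- function(arr, model, prior, lot, config, seed) {
  k <- model$n_params
  mu <- prior$mean[model$params]
  sdv <- prior$sd[model$params]
  lot_pos <- lot[lot <= length(arr$stim)]

  th2core <- make_theta_to_core(model)
  eval_theta <- function(th) {
    cp <- th2core(th)
    if (any(!is.finite(cp))) return(c(-Inf, -Inf))
    r <- cpp_session_loglik(arr$stim, arr$action, arr$valence, arr$outcome,
                            cp, model$forget, FALSE, lot_pos)
    lp <- r$total + sum(dnorm(th, mu, sdv, log = TRUE))
    lot_lp <- sum(r$trial_logp[lot_pos], na.rm = TRUE)
    c(lp, lot_lp)
  }

  n_keep <- config$draws
  n_iter <- config$warmup + n_keep
  kept_lot <- matrix(NA_real_, n_keep, config$chains)
  kept_lp <- matrix(NA_real_, n_keep, config$chains)
  acc_total <- 0

  withr_seed(seed, {
    for (ch in seq_len(config$chains)) {
      th <- mu + rnorm(k, 0, 0.3 * sdv)
      cur <- eval_theta(th)
      step <- 2.38 / sqrt(k) * sdv * 0.5
      acc_win <- 0
      for (it in seq_len(n_iter)) {
        prop <- th + rnorm(k, 0, step)
        cand <- eval_theta(prop)
        if (is.finite(cand[1]) && log(runif(1)) < cand[1] - cur[1]) {
          th <- prop; cur <- cand
          acc_win <- acc_win + 1
          if (it > config$warmup) acc_total <- acc_total + 1
        }
        if (it <= config$warmup && it %% 50 == 0) {
          rate <- acc_win / 50
          step <- step * exp(rate - 0.3)  # aim near 0.3 acceptance
          acc_win <- 0
        }
        if (it > config$warmup) {
          kept_lot[it - config$warmup, ch] <- cur[2]
          kept_lp[it - config$warmup, ch] <- cur[1]
        }
      }
    }
  })
  lol <- log_mean_exp(as.vector(kept_lot))
  list(lol = lol, rhat = split_rhat(kept_lp),
       accept = acc_total / (n_keep * config$chains))
}

# split-chain potential scale reduction on the log-posterior trace
split_rhat <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[seq(n - half + 1, n), , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' @export
print.gng_lol <- function(x, ...) {
  cat("<gng_lol>", length(x$test_ids), "test subjects, trials",
      paste(x$config$left_out_trials, collapse = ", "), "held out\n")
  print(x$comparisons)
  print(x$grand_mean_ppt)
  invisible(x)
}
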