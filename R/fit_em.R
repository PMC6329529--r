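#' Hierarchical type-2 maximum-likelihood fit by expectation-maximization
#'
#' Fits a model to a wave of data under independent Gaussian population
#' priors over transformed parameters.  The E-step finds each subject's
#' maximum a posteriori (MAP) transformed parameters by multi-start
#' quasi-Newton optimization of log-likelihood plus log-prior, with a
#' Laplace (inverse-Hessian) estimate of local curvature; the M-step updates
#' the prior mean to the mean of the MAP estimates and the prior variance to
#' their variance plus the mean inverse-Hessian diagonal (floored at
#' \code{var_floor}).  Iteration stops when the largest change in any
#' transformed prior mean falls below \code{tol}.  After convergence the
#' integrated likelihood of each subject's data under the fitted prior is
#' estimated by Monte-Carlo sampling, and the group-level iBIC
#' \deqn{iBIC = -2\sum_{pt} iL_{pt} + N_{par}\ln(n_{tr} n_{pt})}
#' is computed with \eqn{N_{par}} counting both the mean and the variance of
#' every subject-level parameter.
#'
#' @param cohort A validated cohort (single wave; waves are fitted
#'   independently).
#' @param model Model name or \code{\link{gng_model}}.
#' @param max_iter,tol EM stopping rule (defaults 200 iterations, 1e-3 on
#'   transformed means).
#' @param n_restarts Extra jittered starts per subject in the first E-step
#'   (later iterations warm-start from the previous MAP).
#' @param seed Integer seed controlling jitter and integrated-likelihood
#'   sampling.
#' @param n_samples Prior draws per subject for the integrated likelihood.
#' @param var_floor Lower bound on prior variances in transformed space.
#' @param init_mean,init_sd Optional named starting prior.
#' @param decay_v See \code{\link{update_values}}.
#' @param estep \code{"mc"} (default): the E-step computes each subject's
#'   posterior mean and second moment by importance sampling from the
#'   current prior with common random numbers, and the M-step matches the
#'   prior to those moments - unbiased for the skewed posteriors of
#'   log-space parameters.  \code{"map"}: the classical Laplace variant
#'   (M-step from MAP estimates plus inverse-Hessian curvature), which can
#'   drift upward for weakly identified log-space parameters; see the
#'   methods vignette.
#' @param verbose Print per-iteration progress.
#' @return A \code{gng_fit}: fitted prior, per-subject tibble (MAP
#'   transformed and natural parameters, curvature, integrated likelihood
#'   and its Monte-Carlo SE), iBIC, and the EM trace.  The sum of
#'   per-subject MAP log-posteriors is logged each iteration as a
#'   monotonicity diagnostic; decreases are flagged with a warning in the
#'   trace.
#' @export
fit_em <- function(cohort, model, max_iter = 200, tol = 1e-3, n_restarts = 4,
                   seed = 1, n_samples = 2000, var_floor = 1e-6,
                   init_mean = NULL, init_sd = NULL, decay_v = FALSE,
                   estep = c("mc", "map"), verbose = FALSE) {
  estep <- match.arg(estep)
  model <- as_gng_model(model)
  sessions <- split_sessions(cohort)
  if (length(sessions) < 2) abort("fit_em needs at least 2 participants")
  arrs <- lapply(sessions, session_arrays)
  ids <- names(sessions)
  n_sub <- length(arrs)
  k <- model$n_params

  mu <- default_prior_mean(model)
  if (!is.null(init_mean)) mu[names(init_mean)] <- unlist(init_mean)
  sig2 <- setNames(rep(4, k), model$params)
  if (!is.null(init_sd)) sig2[names(init_sd)] <- unlist(init_sd)^2

  theta <- matrix(rep(mu, each = n_sub), nrow = n_sub,
                  dimnames = list(ids, model$params))
  invh <- matrix(1, n_sub, k)
  lpost <- rep(NA_real_, n_sub)
  trace <- list()
  converged <- FALSE

  th2core <- make_theta_to_core(model)
  none <- integer()
  neg_logpost <- function(th, arr, mu, sig2) {
    cp <- th2core(th)
    if (any(!is.finite(cp))) return(1e10)
    ll <- cpp_session_loglik(arr$stim, arr$action, arr$valence, arr$outcome,
                             cp, model$forget, decay_v, none)$total
    -(ll + sum(dnorm(th, mu, sqrt(sig2), log = TRUE)))
  }

  map_estep <- function(starts_mat, mu, sig2, with_hessian = TRUE) {
    for (i in seq_len(n_sub)) {
      starts <- list(starts_mat[i, ])
      if (n_restarts > 1) {
        jit <- withr_seed(derive_seed(seed, 53, i), {
          lapply(seq_len(n_restarts - 1), function(j)
            mu + rnorm(k, 0, 0.5 * sqrt(sig2)))
        })
        starts <- c(starts, jit)
      }
      best <- NULL
      for (st in starts) {
        op <- tryCatch(
          optim(st, neg_logpost, arr = arrs[[i]], mu = mu, sig2 = sig2,
                method = "BFGS", control = list(maxit = 300)),
          error = function(e) NULL)
        if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
      }
      if (is.null(best))
        best <- list(par = starts_mat[i, ],
                     value = neg_logpost(starts_mat[i, ], arrs[[i]], mu, sig2))
      theta[i, ] <<- best$par
      lpost[i] <<- -best$value
      if (with_hessian) {
        H <- tryCatch(
          optimHess(best$par, neg_logpost, arr = arrs[[i]], mu = mu, sig2 = sig2),
          error = function(e) NULL)
        invh[i, ] <<- hessian_inv_diag(H, sig2)
      }
    }
  }

  il <- il_se <- ess <- rep(NA_real_, n_sub)
  pmean <- theta

  if (estep == "mc") {
    # per-subject fixed draws: the EM map stays deterministic given the seed,
    # while Monte-Carlo errors are independent across subjects and average
    # out in the M-step
    Zs <- lapply(seq_len(n_sub), function(i) {
      withr_seed(derive_seed(seed, 61, i), {
        matrix(rnorm(n_samples * k), nrow = n_samples)
      })
    })
    mc_pass <- function(mu, sig2) {
      E1 <- E2 <- matrix(0, n_sub, k)
      il_i <- se_i <- ess_i <- numeric(n_sub)
      sg <- sqrt(sig2)
      for (i in seq_len(n_sub)) {
        draws <- sweep(sweep(Zs[[i]], 2, sg, "*"), 2, mu, "+")
        colnames(draws) <- model$params
        core <- core_pars_mat(natural_from_transformed_mat(draws, model), model)
        a <- arrs[[i]]
        ll <- cpp_session_loglik_mat(a$stim, a$action, a$valence, a$outcome,
                                     core, model$forget, decay_v, integer())
        u <- exp(ll - max(ll))
        w <- u / sum(u)
        E1[i, ] <- colSums(w * draws)
        E2[i, ] <- colSums(w * draws^2)
        il_i[i] <- max(ll) + log(mean(u))
        se_i[i] <- sd(u) / (mean(u) * sqrt(n_samples))
        ess_i[i] <- 1 / sum(w^2)
      }
      list(E1 = E1, E2 = E2, il = il_i, se = se_i, ess = ess_i)
    }
    for (iter in seq_len(max_iter)) {
      e <- mc_pass(mu, sig2)
      mu_new <- setNames(colMeans(e$E1), model$params)
      sig2_new <- setNames(pmax(colMeans(e$E2) - mu_new^2, var_floor),
                           model$params)
      delta <- max(abs(mu_new - mu))
      trace[[iter]] <- tibble::tibble(iteration = iter, delta_mean = delta,
                                      objective = sum(e$il))
      if (verbose)
        message(sprintf("EM iter %d: sum iL %.2f, max |d mean| %.4g",
                        iter, sum(e$il), delta))
      mu <- mu_new
      sig2 <- sig2_new
      if (delta < tol) { converged <- TRUE; break }
    }
    e <- mc_pass(mu, sig2)   # moments and evidence under the final prior
    il <- e$il; il_se <- e$se; ess <- e$ess; pmean <- e$E1
    # MAP and Laplace curvature at the fitted prior, for reporting
    map_estep(e$E1, mu, sig2, with_hessian = TRUE)
  } else {
    for (iter in seq_len(max_iter)) {
      map_estep(theta, mu, sig2)
      mu_new <- colMeans(theta)
      sig2_new <- pmax(colMeans(theta^2) - mu_new^2 + colMeans(invh), var_floor)
      delta <- max(abs(mu_new - mu))
      trace[[iter]] <- tibble::tibble(iteration = iter, delta_mean = delta,
                                      objective = sum(lpost))
      if (verbose)
        message(sprintf("EM iter %d: sum log-post %.2f, max |d mean| %.4g",
                        iter, sum(lpost), delta))
      mu <- mu_new
      sig2 <- sig2_new
      if (delta < tol) { converged <- TRUE; break }
    }
    if (length(trace) > 1) {
      obj <- vapply(trace, function(t) t$objective, numeric(1))
      if (any(diff(obj) < -1e-6 * abs(obj[-1])))
        warning("EM monotonicity diagnostic: sum MAP log-posterior decreased in some iteration")
    }
    # integrated likelihoods under the final prior, fixed per-subject seeds
    for (i in seq_len(n_sub)) {
      r <- integrated_likelihood_arr(arrs[[i]], mu, sig2, model, n_samples,
                                     derive_seed(seed, 67, i), decay_v)
      il[i] <- r$il
      il_se[i] <- r$se
    }
  }
  trace <- dplyr::bind_rows(trace)

  nat <- natural_from_transformed_mat(theta, model)
  subjects <- dplyr::bind_cols(
    tibble::tibble(participant_id = ids),
    tibble::as_tibble(setNames(as.data.frame(theta),
                               paste0("t_", model$params))),
    tibble::as_tibble(as.data.frame(nat)),
    tibble::tibble(map_log_posterior = lpost, il = il, il_se = il_se,
                   ess = ess,
                   n_trials = vapply(arrs, function(a) sum(a$action != 0L),
                                     integer(1)))
  )
  fit <- structure(
    list(model = model, prior = list(mean = mu, sd = sqrt(sig2)),
         subjects = subjects, trace = trace, converged = converged,
         n_participants = n_sub,
         n_trials = length(arrs[[1]]$stim),
         posterior_mean = pmean,
         config = list(max_iter = max_iter, tol = tol,
                       n_restarts = n_restarts, seed = seed,
                       n_samples = n_samples, var_floor = var_floor,
                       decay_v = decay_v, estep = estep)),
    class = "gng_fit")
  fit$ibic <- ibic(fit)
  fit
}

default_prior_mean <- function(model) {
  # weakly informative generic starting point in transformed space
  defaults <- c(rho = 0, rho_app = 0, rho_av = 0, kappa = 0, lam = -1,
                lam_app = -1, lam_av = -1, b_go = 0, b_pav = -1, xi = -2,
                m = 1)
  setNames(defaults[model$params], model$params)
}

hessian_inv_diag <- function(H, sig2) {
  k <- length(sig2)
  if (is.null(H) || anyNA(H)) return(unname(sig2))
  d <- tryCatch({
    hi <- solve(H)
    diag(hi)
  }, error = function(e) 1 / pmax(diag(H), 1e-8))
  bad <- !is.finite(d) | d <= 0
  d[bad] <- sig2[bad]  # singular curvature: fall back to the prior scale
  pmin(unname(d), unname(sig2) * 10)
}

integrated_likelihood_arr <- function(arr, mu, sig2, model, n_samples, seed,
                                      decay_v = FALSE) {
  k <- length(mu)
  draws <- withr_seed(seed, {
    matrix(rnorm(n_samples * k, rep(mu, each = n_samples),
                 rep(sqrt(sig2), each = n_samples)), nrow = n_samples)
  })
  colnames(draws) <- model$params
  nat <- natural_from_transformed_mat(draws, model)
  ll <- cpp_session_loglik_mat(arr$stim, arr$action, arr$valence, arr$outcome,
                               core_pars_mat(nat, model), model$forget,
                               decay_v, integer())
  m <- max(ll)
  u <- exp(ll - m)
  il <- m + log(mean(u))
  se <- sd(u) / (mean(u) * sqrt(n_samples))  # delta method on log mean
  list(il = il, se = se)
}

#' Monte-Carlo integrated likelihood of one session
#'
#' Estimates \eqn{iL = \ln\int p(d|\theta, M)\,p(\theta|\Theta)\,d\theta} by
#' the log of the mean likelihood over draws from the population prior,
#' computed in log space, with a delta-method standard error.
#'
#' @param session A session tibble (one participant's trials in order).
#' @param prior List with named \code{mean} and \code{sd} vectors in
#'   transformed space (as in a \code{gng_fit}'s \code{prior}).
#' @param model Model name or \code{\link{gng_model}}.
#' @param n_samples Number of prior draws (at least 100).
#' @param seed Integer seed.
#' @param decay_v See \code{\link{update_values}}.
#' @return List with \code{il} (nats) and \code{se}.
#' @export
integrated_likelihood <- function(session, prior, model, n_samples = 2000,
                                  seed = 1, decay_v = FALSE) {
  if (n_samples < 100) abort("n_samples must be >= 100")
  model <- as_gng_model(model)
  mu <- prior$mean[model$params]
  sig2 <- prior$sd[model$params]^2
  r <- integrated_likelihood_arr(session_arrays(session), mu, sig2, model,
                                 n_samples, seed, decay_v)
  list(il = r$il, se = r$se)
}

#' Integrated Bayesian Information Criterion
#'
#' \eqn{iBIC = -2\sum_{pt} iL_{pt} + N_{par}\ln(n_{tr} n_{pt})} where
#' \eqn{N_{par}} is the number of population-level parameters (a mean and a
#' variance per subject-level parameter), \eqn{n_{tr}} the trials per
#' participant and \eqn{n_{pt}} the number of participants.
#'
#' @param fit A \code{gng_fit}, or a list with elements \code{subjects$il}
#'   (or \code{il}), \code{model}, \code{n_trials}, \code{n_participants}.
#' @return The iBIC (smaller is better).
#' @export
ibic <- function(fit) {
  il <- if (!is.null(fit$subjects)) fit$subjects$il else fit$il
  model <- as_gng_model(fit$model)
  n_pt <- if (!is.null(fit$n_participants)) fit$n_participants else length(il)
  n_tr <- if (!is.null(fit$n_trials)) fit$n_trials else 144
  -2 * sum(il) + 2 * model$n_params * log(n_tr * n_pt)
}

#' @export
print.gng_fit <- function(x, ...) {
  cat("<gng_fit>", x$model$name, "-", x$n_participants, "participants,",
      nrow(x$trace), "EM iterations",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  iBIC:", format(x$ibic, digits = 8), "  sum iL:",
      format(sum(x$subjects$il), digits = 8), "\n")
  cat("  prior mean (transformed):\n")
  print(round(x$prior$mean, 3))
  invisible(x)
}
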