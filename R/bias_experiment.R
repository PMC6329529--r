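#' Configure the informed-vs-agnostic hidden-trial audit
#'
#' The audit checks whether letting held-out ("hidden") trials' realized
#' actions and outcomes drive learning during estimation ("informed"
#' handling) biases out-of-sample prediction, compared with marginalizing
#' over all possible hidden action sequences ("agnostic" handling).  Toy
#' two-armed learners with deterministic returns are simulated for many
#' epochs; the first trials of each epoch are hidden; and per epoch the
#' hidden-trial predictive likelihood \eqn{p(h|v,M)} (flat prior over a
#' learning-rate grid) and grid-based maximum-likelihood learning-rate
#' estimates are computed under both handlings and over hidden trials alone.
#'
#' @param learner \code{"rw_softmax"} (Rescorla-Wagner with softmax
#'   temperature \code{tau}), \code{"eta_greedy"}, or
#'   \code{"observation_violating_eta_greedy"} (exploratory actions update
#'   values only on better-than-expected prediction errors).
#' @param eps_levels True learning rates to study (default 0.05, 0.15, 0.25).
#' @param tau Known softmax scaling parameter (not fitted; default 0.1).  It
#'   multiplies action values in the policy, the role the motivational
#'   exchange rate plays in the full task models.
#' @param eta Exploration rate of the greedy learners (default 0.1).
#' @param n_epochs Epochs per level (default 10000).
#' @param n_trials Trials per epoch (default 28).
#' @param n_hidden Number of initial hidden trials (default 8; must be less
#'   than \code{n_trials}).
#' @param returns Deterministic returns of the two actions (default 1 and 5).
#' @param eps_grid Learning-rate grid for ML estimation and the flat-prior
#'   marginal (default 101 points on [0.005, 0.505]).
#' @param seed Integer seed.
#' @return A \code{gng_bias_config} list.
#' @export
bias_experiment_config <- function(learner = c("rw_softmax", "eta_greedy",
                                               "observation_violating_eta_greedy"),
                                   eps_levels = c(0.05, 0.15, 0.25),
                                   tau = 0.1, eta = 0.1, n_epochs = 10000,
                                   n_trials = 28, n_hidden = 8,
                                   returns = c(1, 5),
                                   eps_grid = seq(0.005, 0.505, length.out = 101),
                                   seed = 1) {
  learner <- match.arg(learner)
  if (n_hidden >= n_trials) abort("n_hidden must be < n_trials")
  structure(list(learner = learner, eps_levels = eps_levels, tau = tau,
                 eta = eta, n_epochs = n_epochs, n_trials = n_trials,
                 n_hidden = n_hidden, returns = returns, eps_grid = eps_grid,
                 seed = seed),
            class = "gng_bias_config")
}

#' Run the informed-vs-agnostic hidden-trial audit
#'
#' @param config A \code{\link{bias_experiment_config}}.
#' @param keep_grid Keep the per-epoch grid log-likelihood matrices (memory
#'   scales with \code{n_epochs * length(eps_grid)}).
#' @return A \code{gng_bias_experiment} object with \code{epochs} (per-epoch
#'   tibble: ML learning-rate estimates under informed / agnostic / hidden
#'   handling and the Eq-style hidden-trial predictive log-likelihoods) and
#'   \code{summary} (per true learning rate: mean informed-minus-agnostic
#'   difference in hidden predictive log-likelihood with its SE and Wilcoxon
#'   signed-rank p; mean amount by which the informed ML estimate is closer
#'   in log units to the hidden-trial ML estimate than the agnostic one).
#' @examples
#' \donttest{
#' res <- run_bias_experiment(bias_experiment_config(n_epochs = 200))
#' res$summary
#' }
#' @export
run_bias_experiment <- function(config, keep_grid = FALSE) {
  stopifnot(inherits(config, "gng_bias_config"))
  lcode <- match(config$learner,
                 c("rw_softmax", "eta_greedy",
                   "observation_violating_eta_greedy")) - 1L
  epochs <- list()
  grids <- list()
  for (i in seq_along(config$eps_levels)) {
    eps <- config$eps_levels[i]
    raw <- withr_seed(derive_seed(config$seed, 41, i), {
      cpp_bias_experiment(config$n_epochs, config$n_trials, config$n_hidden,
                          eps, config$tau, config$eta, lcode,
                          config$returns, config$eps_grid, keep_grid)
    })
    epochs[[i]] <- tibble::tibble(
      eps_true = eps, epoch = seq_len(config$n_epochs),
      eps_ml_informed = raw$eps_ml_informed,
      eps_ml_agnostic = raw$eps_ml_agnostic,
      eps_ml_hidden = raw$eps_ml_hidden,
      log_ph_informed = raw$log_ph_informed,
      log_ph_agnostic = raw$log_ph_agnostic
    )
    if (keep_grid)
      grids[[as.character(eps)]] <- raw[c("ll_hidden", "ll_visible_informed",
                                          "ll_visible_agnostic")]
  }
  epochs <- dplyr::bind_rows(epochs)
  summary <- dplyr::summarise(
    dplyr::group_by(epochs, .data$eps_true),
    n_epochs = dplyr::n(),
    mean_dlogph = mean(.data$log_ph_informed - .data$log_ph_agnostic),
    se_dlogph = sd(.data$log_ph_informed - .data$log_ph_agnostic) /
      sqrt(dplyr::n()),
    wilcoxon_p_dlogph = tryCatch(
      wilcox.test(.data$log_ph_informed, .data$log_ph_agnostic,
                  paired = TRUE)$p.value,
      error = function(e) NA_real_),
    # how much closer (log units) the informed ML estimate sits to the
    # hidden-trial ML estimate than the agnostic one, on average
    informed_closer_log = mean(
      abs(log(.data$eps_ml_agnostic) - log(.data$eps_ml_hidden)) -
        abs(log(.data$eps_ml_informed) - log(.data$eps_ml_hidden))),
    wilcoxon_p_closer = tryCatch(
      wilcox.test(abs(log(.data$eps_ml_agnostic) - log(.data$eps_ml_hidden)),
                  abs(log(.data$eps_ml_informed) - log(.data$eps_ml_hidden)),
                  paired = TRUE)$p.value,
      error = function(e) NA_real_),
    grand_mean_ppt = mean(exp(.data$log_ph_informed / !!config$n_hidden)),
    .groups = "drop"
  )
  structure(list(epochs = epochs, summary = summary, config = config,
                 grids = if (keep_grid) grids else NULL),
            class = "gng_bias_experiment")
}

#' @export
print.gng_bias_experiment <- function(x, ...) {
  cat("<gng_bias_experiment>", x$config$learner, "-", x$config$n_epochs,
      "epochs x", x$config$n_trials, "trials\n")
  print(x$summary)
  invisible(x)
}

#' Flat-prior posterior over the learning-rate grid
#'
#' Normalized posterior \eqn{p(\varepsilon|v)} over the grid for one epoch,
#' under a flat prior; requires a result run with \code{keep_grid = TRUE}.
#'
#' @param x A \code{gng_bias_experiment} run with \code{keep_grid = TRUE}.
#' @param eps_true Which true-learning-rate level.
#' @param epoch Epoch number.
#' @param handling \code{"informed"} or \code{"agnostic"}.
#' @return Tibble with \code{eps} and \code{posterior} (sums to 1).
#' @export
bias_grid_posterior <- function(x, eps_true, epoch = 1,
                                handling = c("informed", "agnostic")) {
  handling <- match.arg(handling)
  g <- x$grids[[as.character(eps_true)]]
  if (is.null(g)) abort("run_bias_experiment() must be called with keep_grid = TRUE")
  ll <- if (handling == "informed") g$ll_visible_informed[epoch, ]
        else g$ll_visible_agnostic[epoch, ]
  tibble::tibble(eps = x$config$eps_grid,
                 posterior = exp(ll - logsumexp(ll)))
}
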