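#' Specify a synthetic agent population
#'
#' Agents are drawn from independent Gaussian distributions over the model's
#' transformed parameters (log / logit / identity space), matching the
#' population assumption of the hierarchical fit.  Two robustness families
#' replace the implied log-normal natural-space distribution of the
#' Pavlovian bias: \code{"gamma_natural"} draws natural \code{b_pav} from a
#' gamma and \code{"normal_natural"} from a normal with matching natural
#' moments (the normal admits a small tail of negative biases).
#'
#' Defaults are anchored to the baseline population of the large longitudinal
#' study that motivates the package: median Pavlovian bias 0.205, Go bias
#' 0.73, lapse rate 0.069; the remaining means and all spreads are typical
#' of hierarchical fits of this task family (see the methods vignette).
#'
#' @param model Model name or \code{\link{gng_model}} (default
#'   \code{"valenced_learning"}).
#' @param mean,sd Named numeric vectors of transformed-space population means
#'   and SDs; missing entries fall back to defaults.
#' @param n Number of agents per wave.
#' @param n_waves 1 or 2 measurement waves.
#' @param drift Named additive shift of transformed means applied at wave 2
#'   (default: none).
#' @param family Population family for \code{b_pav}; see Details.
#' @param bpav_natural_mean,bpav_natural_sd Natural-space moments used by the
#'   alternative families; default to the moments implied by the log-normal.
#' @param n_per_condition Trials per condition in simulated sessions.
#' @param feedback_validity Feedback validity of simulated sessions.
#' @param seed Master seed for sampling and simulation.
#' @return A \code{gng_population_spec} object.
#' @examples
#' spec <- population_spec(n = 10, seed = 1)
#' @export
population_spec <- function(model = "valenced_learning", mean = NULL, sd = NULL,
                            n = 100, n_waves = 1, drift = NULL,
                            family = c("gaussian_transformed", "gamma_natural",
                                       "normal_natural"),
                            bpav_natural_mean = NULL, bpav_natural_sd = NULL,
                            n_per_condition = 36, feedback_validity = 0.8,
                            seed = 1) {
  family <- match.arg(family)
  model <- as_gng_model(model)
  mu <- default_population_mean(model)
  sg <- default_population_sd(model)
  if (!is.null(mean)) mu[names(mean)] <- unlist(mean)
  if (!is.null(sd)) sg[names(sd)] <- unlist(sd)
  if (any(sg < 0)) abort("population SDs must be >= 0")
  dr <- setNames(numeric(model$n_params), model$params)
  if (!is.null(drift)) dr[names(drift)] <- unlist(drift)
  if (family != "gaussian_transformed") {
    lm <- mu[["b_pav"]]; ls <- sg[["b_pav"]]
    if (is.null(bpav_natural_mean))
      bpav_natural_mean <- exp(lm + ls^2 / 2)
    if (is.null(bpav_natural_sd))
      bpav_natural_sd <- sqrt((exp(ls^2) - 1) * exp(2 * lm + ls^2))
  }
  structure(
    list(model = model$name, mean = mu, sd = sg, n = n, n_waves = n_waves,
         drift = dr, family = family,
         bpav_natural_mean = bpav_natural_mean,
         bpav_natural_sd = bpav_natural_sd,
         n_per_condition = n_per_condition,
         feedback_validity = feedback_validity, seed = seed),
    class = "gng_population_spec"
  )
}

default_population_mean <- function(model) {
  defaults <- c(rho = log(5), rho_app = log(5), rho_av = log(5),
                kappa = 0, lam = qlogis(0.15), lam_app = qlogis(0.14),
                lam_av = qlogis(0.17), b_go = 0.73, b_pav = log(0.205),
                xi = qlogis(0.069), m = qlogis(0.9))
  setNames(defaults[model$params], model$params)
}

default_population_sd <- function(model) {
  defaults <- c(rho = 0.5, rho_app = 0.5, rho_av = 0.5, kappa = 0.4,
                lam = 1.0, lam_app = 1.0, lam_av = 1.0, b_go = 0.7,
                b_pav = 0.9, xi = 0.8, m = 0.7)
  setNames(defaults[model$params], model$params)
}

#' Sample agents from a population specification
#'
#' @param spec A \code{\link{population_spec}}.
#' @return Tibble with one row per agent and wave: \code{wave},
#'   \code{participant_id}, transformed parameters (prefix \code{t_}) and
#'   natural-space parameters.
#' @export
sample_population <- function(spec) {
  model <- gng_model(spec$model)
  out <- list()
  for (w in seq_len(spec$n_waves)) {
    mu <- spec$mean + if (w == 2) spec$drift else 0
    theta <- withr_seed(derive_seed(spec$seed, 11, w), {
      th <- matrix(rnorm(spec$n * model$n_params, rep(mu, each = spec$n),
                         rep(spec$sd, each = spec$n)),
                   nrow = spec$n)
      if (spec$family != "gaussian_transformed") {
        nm <- spec$bpav_natural_mean; ns <- spec$bpav_natural_sd
        j <- match("b_pav", model$params)
        bp <- if (spec$family == "gamma_natural") {
          if (ns == 0) rep(nm, spec$n)
          else rgamma(spec$n, shape = (nm / ns)^2, rate = nm / ns^2)
        } else rnorm(spec$n, nm, ns)
        th[, j] <- bp  # stored natural-side below
      }
      th
    })
    colnames(theta) <- model$params
    nat <- natural_from_transformed_mat(theta, model)
    if (spec$family != "gaussian_transformed") {
      # b_pav column held natural values directly for the alternative families
      nat[, "b_pav"] <- theta[, "b_pav"]
      tb <- rep(NA_real_, nrow(nat))
      pos <- nat[, "b_pav"] > 0
      tb[pos] <- log(nat[pos, "b_pav"])
      theta[, "b_pav"] <- tb
    }
    tt <- tibble::as_tibble(theta)
    names(tt) <- paste0("t_", names(tt))
    out[[w]] <- dplyr::bind_cols(
      tibble::tibble(wave = w,
                     participant_id = sprintf("agent%04d", seq_len(spec$n))),
      tt, tibble::as_tibble(nat))
  }
  dplyr::bind_rows(out)
}

#' Simulate one session of the Go-NoGo task
#'
#' Runs an agent through a schedule: propensities, a lapse-mixed softmax
#' action draw, outcome delivery according to the condition and the
#' pre-drawn feedback validity, and the value update.
#'
#' @param params Named natural-space parameter vector.
#' @param model Model name or \code{\link{gng_model}}.
#' @param schedule A \code{\link{gng_schedule}} tibble.
#' @param seed Integer seed; the session is deterministic given seed and
#'   inputs.
#' @param participant_id,session Identifiers written into the result.
#' @param decay_v See \code{\link{update_values}}.
#' @return A session tibble in the canonical long format.
#' @export
simulate_session <- function(params, model, schedule, seed,
                             participant_id = "sim01", session = "baseline",
                             decay_v = FALSE) {
  model <- as_gng_model(model)
  cp <- core_pars(params, model)
  res <- withr_seed(seed, {
    cpp_simulate_session(as.integer(schedule$stimulus_id),
                         unname(GNG_VALENCE[schedule$condition]),
                         as.integer(schedule$correct_action == "go"),
                         as.integer(schedule$validity_draw),
                         cp, model$forget, decay_v)
  })
  tibble::tibble(
    participant_id = participant_id,
    session = session,
    trial_index = schedule$trial_index,
    stimulus_id = schedule$stimulus_id,
    condition = schedule$condition,
    action = c("go", "nogo")[res$action],
    outcome = as.integer(res$outcome),
    feedback_valid = schedule$validity_draw
  )
}

#' Simulate a full synthetic cohort
#'
#' Samples agents from the population specification and simulates one
#' session per agent and wave, each with its own fully randomized schedule.
#' Wave 1 is labelled \code{"baseline"} and wave 2 \code{"long_followup"}.
#'
#' @param spec A \code{\link{population_spec}}.
#' @return A \code{gng_simulation}: list with \code{cohorts} (named list of
#'   cohort tibbles per wave) and \code{params} (generative parameters with
#'   ground truth for recovery studies).
#' @export
simulate_cohort <- function(spec) {
  model <- gng_model(spec$model)
  params <- sample_population(spec)
  labels <- c("baseline", "long_followup")
  cohorts <- list()
  for (w in seq_len(spec$n_waves)) {
    pw <- params[params$wave == w, ]
    sessions <- purrr::map(seq_len(nrow(pw)), function(i) {
      sched <- gng_schedule(derive_seed(spec$seed, 23, w, i),
                            spec$n_per_condition, spec$feedback_validity)
      simulate_session(unlist(pw[i, model$params]), model, sched,
                       seed = derive_seed(spec$seed, 31, w, i),
                       participant_id = pw$participant_id[i],
                       session = labels[w])
    })
    cohorts[[labels[w]]] <- dplyr::bind_rows(sessions)
  }
  structure(list(cohorts = cohorts, params = params, spec = spec),
            class = "gng_simulation")
}

#' @export
print.gng_simulation <- function(x, ...) {
  cat("<gng_simulation>", x$spec$model, "-", x$spec$n, "agents x",
      x$spec$n_waves, "wave(s)\n")
  invisible(x)
}

#' Write or read a population specification as YAML
#'
#' @param spec A \code{\link{population_spec}}.
#' @param path File path.
#' @return \code{read_population_spec()} returns the spec; the writer
#'   returns \code{path} invisibly.
#' @export
write_population_spec <- function(spec, path) {
  x <- unclass(spec)
  x$mean <- as.list(x$mean); x$sd <- as.list(x$sd); x$drift <- as.list(x$drift)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_population_spec
#' @export
read_population_spec <- function(path) {
  x <- yaml::read_yaml(path)
  population_spec(model = x$model, mean = unlist(x$mean), sd = unlist(x$sd),
                  n = x$n, n_waves = x$n_waves, drift = unlist(x$drift),
                  family = x$family,
                  bpav_natural_mean = x$bpav_natural_mean,
                  bpav_natural_sd = x$bpav_natural_sd,
                  n_per_condition = x$n_per_condition,
                  feedback_validity = x$feedback_validity, seed = x$seed)
}
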