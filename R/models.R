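#' Model registry for the orthogonalized Go-NoGo task
#'
#' Six reinforcement-learning model variants describe behaviour in the task.
#' All share the Rescorla-Wagner action-value update
#' \deqn{Q_{t+1}(a_t,s_t) = Q_t(a_t,s_t) + \lambda_v(\rho_v r_t - Q_t(a_t,s_t))}
#' and an identical update for the stimulus (state) value \eqn{V_t(s_t)},
#' together with Go-biased action propensities
#' \deqn{q_t(a,s) = Q_t(a,s) + b_{go}[a=Go] + b_{pav}[a=Go]\,V_t(s)}
#' and a lapse-mixed softmax policy
#' \deqn{p(a|s) = (1-\xi)\,\mathrm{softmax}(q) + \xi/2.}
#' The variants differ in which of \eqn{\lambda} (learning rate) and
#' \eqn{\rho} (motivational exchange rate, i.e. outcome sensitivity) are
#' valenced, and in whether unexperienced state-action values decay toward
#' zero ("forgetting", retention fraction \code{m} per trial).
#'
#' \itemize{
#'   \item \code{valenced_learning}: \eqn{\rho, \lambda_{app}, \lambda_{av},
#'     b_{go}, b_{pav}, \xi}
#'   \item \code{valenced_sensitivity}: \eqn{\rho_{app}, \rho_{av}, \lambda,
#'     b_{go}, b_{pav}, \xi}
#'   \item \code{sensitivity_ratio}: \eqn{\rho_{app}, \kappa = \ln\rho_{av} -
#'     \ln\rho_{app}, \lambda, b_{go}, b_{pav}, \xi}; per individual this is a
#'     reparameterization of \code{valenced_sensitivity} and yields identical
#'     session likelihoods, but the population prior is placed on
#'     \eqn{\kappa} instead of \eqn{\ln\rho_{av}}.
#'   \item each of the above with suffix \code{"+forget"}: adds \code{m}.
#' }
#'
#' Parameters are fitted in a transformed space in which the population prior
#' is Gaussian: positive parameters (\eqn{\rho}'s, \eqn{b_{pav}}) in log
#' space, unit-interval parameters (\eqn{\lambda}'s, \eqn{\xi}, \code{m}) in
#' logit space, and \eqn{b_{go}} and \eqn{\kappa} untransformed.
#'
#' @param name Model name, e.g. \code{"valenced_learning"} or
#'   \code{"valenced_sensitivity+forget"}.
#' @return \code{gng_model()} returns a \code{gng_model} object (list with
#'   \code{name}, \code{params}, \code{transform}, \code{n_params});
#'   \code{gng_models()} returns the names of all registered variants.
#' @examples
#' gng_models()
#' gng_model("valenced_learning")
#' @export
gng_model <- function(name) {
  base <- sub("\\+forget$", "", name)
  forget <- grepl("\\+forget$", name)
  pars <- switch(base,
    valenced_learning = c(rho = "log", lam_app = "logit", lam_av = "logit",
                          b_go = "identity", b_pav = "log", xi = "logit"),
    valenced_sensitivity = c(rho_app = "log", rho_av = "log", lam = "logit",
                             b_go = "identity", b_pav = "log", xi = "logit"),
    sensitivity_ratio = c(rho_app = "log", kappa = "identity", lam = "logit",
                          b_go = "identity", b_pav = "log", xi = "logit"),
    abort(paste0("unknown model: ", name))
  )
  if (forget) pars <- c(pars, m = "logit")
  structure(
    list(name = name, base = base, forget = forget,
         params = names(pars), transform = unname(pars),
         n_params = length(pars)),
    class = "gng_model"
  )
}

#' @rdname gng_model
#' @export
gng_models <- function() {
  base <- c("valenced_learning", "valenced_sensitivity", "sensitivity_ratio")
  c(base, paste0(base, "+forget"))
}

#' @export
print.gng_model <- function(x, ...) {
  cat("<gng_model>", x$name, "\n  parameters:",
      paste(x$params, paste0("(", x$transform, ")"), collapse = ", "), "\n")
  invisible(x)
}

as_gng_model <- function(model) {
  if (inherits(model, "gng_model")) model else gng_model(model)
}

# Map a named natural-space parameter vector onto the shared core layout
# [rho_app, rho_av, lam_app, lam_av, b_go, b_pav, xi, m_ret].
core_pars <- function(params, model) {
  model <- as_gng_model(model)
  p <- as.list(params)
  m <- if (model$forget) p$m else 1.0
  switch(model$base,
    valenced_learning =
      c(p$rho, p$rho, p$lam_app, p$lam_av, p$b_go, p$b_pav, p$xi, m),
    valenced_sensitivity =
      c(p$rho_app, p$rho_av, p$lam, p$lam, p$b_go, p$b_pav, p$xi, m),
    sensitivity_ratio =
      c(p$rho_app, p$rho_app * exp(p$kappa), p$lam, p$lam, p$b_go, p$b_pav,
        p$xi, m)
  )
}

core_pars_mat <- function(theta_nat, model) {
  model <- as_gng_model(model)
  x <- theta_nat
  m <- if (model$forget) x[, 7] else rep(1, nrow(x))
  switch(model$base,
    valenced_learning =
      cbind(x[, 1], x[, 1], x[, 2], x[, 3], x[, 4], x[, 5], x[, 6], m),
    valenced_sensitivity =
      cbind(x[, 1], x[, 2], x[, 3], x[, 3], x[, 4], x[, 5], x[, 6], m),
    sensitivity_ratio =
      cbind(x[, 1], x[, 1] * exp(x[, 2]), x[, 3], x[, 3], x[, 4], x[, 5],
            x[, 6], m)
  )
}

# Fast closure mapping an unnamed transformed-parameter vector straight to
# the core natural layout; used in optimization and sampling hot loops.
make_theta_to_core <- function(model) {
  model <- as_gng_model(model)
  tcode <- match(model$transform, c("log", "logit", "identity"))
  base <- model$base
  forget <- model$forget
  k <- model$n_params
  function(th) {
    nat <- numeric(k)
    for (i in seq_len(k)) {
      nat[i] <- if (tcode[i] == 1L) exp(th[i])
                else if (tcode[i] == 2L) plogis(th[i]) else th[i]
    }
    m <- if (forget) nat[7] else 1.0
    if (base == "valenced_learning")
      c(nat[1], nat[1], nat[2], nat[3], nat[4], nat[5], nat[6], m)
    else if (base == "valenced_sensitivity")
      c(nat[1], nat[2], nat[3], nat[3], nat[4], nat[5], nat[6], m)
    else
      c(nat[1], nat[1] * exp(nat[2]), nat[3], nat[3], nat[4], nat[5], nat[6], m)
  }
}

#' Transform model parameters between natural and fitting space
#'
#' Positive parameters are log-transformed, unit-interval parameters
#' logit-transformed, unbounded ones left as-is, making the transformed space
#' suitable for a Gaussian population prior.  The map is bijective; values on
#' a transform boundary (e.g. a learning rate of exactly 0 or 1 under the
#' logit) are rejected with advice to clip away from the boundary by machine
#' epsilon.
#'
#' @param params Named numeric vector (or single-row data frame) of parameter
#'   values, in the space named by \code{direction}'s source.
#' @param model A \code{\link{gng_model}} or model name.
#' @param direction \code{"to_transformed"} (natural to fitting space) or
#'   \code{"to_natural"}.
#' @return Named numeric vector in the target space.
#' @examples
#' th <- transform_params(c(rho = 2, lam_app = 0.1, lam_av = 0.2,
#'                          b_go = 0.3, b_pav = 1, xi = 0.05),
#'                        "valenced_learning", "to_transformed")
#' transform_params(th, "valenced_learning", "to_natural")
#' @export
transform_params <- function(params, model,
                             direction = c("to_transformed", "to_natural")) {
  direction <- match.arg(direction)
  model <- as_gng_model(model)
  if (is.data.frame(params)) params <- unlist(params[1, model$params])
  x <- params[model$params]
  if (anyNA(x)) abort("params must contain all model parameters")
  out <- numeric(model$n_params)
  for (i in seq_along(x)) {
    tr <- model$transform[i]
    v <- x[[i]]
    if (direction == "to_transformed") {
      if (tr == "log" && v <= 0)
        abort(sprintf("%s must be > 0 for the log transform; clip by machine epsilon if at the boundary", model$params[i]))
      if (tr == "logit" && (v <= 0 || v >= 1))
        abort(sprintf("%s must lie strictly in (0, 1) for the logit transform; clip by machine epsilon if at the boundary", model$params[i]))
      out[i] <- switch(tr, log = log(v), logit = qlogis(v), identity = v)
    } else {
      out[i] <- switch(tr, log = exp(v), logit = plogis(v), identity = v)
    }
  }
  setNames(out, model$params)
}

natural_from_transformed_mat <- function(theta, model) {
  model <- as_gng_model(model)
  out <- theta
  for (i in seq_len(ncol(theta))) {
    out[, i] <- switch(model$transform[i],
                       log = exp(theta[, i]),
                       logit = plogis(theta[, i]),
                       identity = theta[, i])
  }
  colnames(out) <- model$params
  out
}

#' Learner state and single-trial operations
#'
#' These small reference functions expose the per-trial building blocks of
#' the models: a learner state (a 4 stimuli x 2 actions \code{Q} matrix and a
#' 4-vector of state values \code{V}, both initialized at zero), the
#' value-update rule, the Go-biased action propensities, and the lapse-mixed
#' softmax choice rule.  Session-level likelihoods
#' (\code{\link{session_log_likelihood}}) run the same recursion in compiled
#' code; these R versions are the readable specification and are convenient
#' for single-trial inspection.
#'
#' @param state A learner state from \code{learner_state()}.
#' @param trial A one-row data frame (or list) with \code{stimulus_id},
#'   \code{condition}, \code{action} and \code{outcome}.
#' @param params Named natural-space parameter vector.
#' @param model A \code{\link{gng_model}} or name.
#' @param decay_v In forgetting models, whether unseen stimuli's \code{V}
#'   values also decay (default \code{FALSE}: only \code{Q} decays).
#' @return \code{learner_state()} and \code{update_values()} return a state;
#'   \code{action_propensities()} a named vector \code{c(q_go, q_nogo)};
#'   \code{choice_probability()} a named vector \code{c(p_go, p_nogo)}.
#' @export
learner_state <- function() {
  list(Q = matrix(0, nrow = 2, ncol = 4,
                  dimnames = list(c("go", "nogo"), NULL)),
       V = numeric(4))
}

#' @rdname learner_state
#' @export
update_values <- function(state, trial, params, model, decay_v = FALSE) {
  model <- as_gng_model(model)
  trial <- as.list(trial)
  if (identical(trial$action, "missing")) return(state)
  cp <- core_pars(params, model)
  s <- trial$stimulus_id
  a <- if (trial$action == "go") 1L else 2L
  win <- GNG_VALENCE[[trial$condition]] == 1L
  rho <- if (win) cp[1] else cp[2]
  lam <- if (win) cp[3] else cp[4]
  if (model$forget) {
    keep <- state$Q[a, s]
    state$Q <- state$Q * cp[8]
    state$Q[a, s] <- keep
    if (decay_v) {
      keepv <- state$V[s]
      state$V <- state$V * cp[8]
      state$V[s] <- keepv
    }
  }
  target <- rho * trial$outcome
  state$Q[a, s] <- state$Q[a, s] + lam * (target - state$Q[a, s])
  state$V[s] <- state$V[s] + lam * (target - state$V[s])
  state
}

#' @rdname learner_state
#' @param stimulus_id Stimulus index 1..4.
#' @export
action_propensities <- function(state, stimulus_id, params, model) {
  cp <- core_pars(params, model)
  c(q_go = unname(state$Q[1, stimulus_id] + cp[5] +
                    cp[6] * state$V[stimulus_id]),
    q_nogo = unname(state$Q[2, stimulus_id]))
}

#' @rdname learner_state
#' @param q Propensity pair as returned by \code{action_propensities()}.
#' @param xi Lapse rate in \code{[0, 1]}.
#' @export
choice_probability <- function(q, xi) {
  stopifnot(xi >= 0, xi <= 1)
  m <- max(q)
  e <- exp(q - m)
  p <- (1 - xi) * e / sum(e) + xi / 2
  setNames(p, c("p_go", "p_nogo"))
}

session_arrays <- function(session) {
  stopifnot(all(c("stimulus_id", "condition", "action", "outcome") %in%
                  names(session)))
  list(
    stim = as.integer(session$stimulus_id),
    action = ifelse(session$action == "go", 1L,
                    ifelse(session$action == "nogo", 2L, 0L)),
    valence = unname(GNG_VALENCE[session$condition]),
    outcome = as.numeric(session$outcome)
  )
}

#' Session log-likelihood of observed choices
#'
#' Runs the model's value recursion over a session in trial order, updating
#' on every non-missing trial, and accumulates the log-probability of each
#' observed action.  Trials listed in \code{skip} contribute no likelihood
#' but their realized actions and outcomes still drive learning ("informed"
#' handling of held-out trials); missing responses contribute neither
#' likelihood nor learning.
#'
#' @param session Data frame of one participant-session's trials, in trial
#'   order, with columns \code{stimulus_id}, \code{condition}, \code{action},
#'   \code{outcome}.
#' @param params Named natural-space parameter vector.
#' @param model A \code{\link{gng_model}} or name.
#' @param skip Integer vector of 1-based trial positions to exclude from the
#'   total (their per-trial log-probabilities are still returned).
#' @param decay_v See \code{\link{update_values}}.
#' @return List with \code{total} (log-likelihood over non-skipped,
#'   non-missing trials) and \code{trial_logp} (per-trial log-probabilities,
#'   \code{NA} for missing responses).
#' @export
session_log_likelihood <- function(session, params, model, skip = integer(),
                                   decay_v = FALSE) {
  model <- as_gng_model(model)
  arr <- session_arrays(session)
  cp <- core_pars(params, model)
  cpp_session_loglik(arr$stim, arr$action, arr$valence, arr$outcome, cp,
                     model$forget, decay_v, as.integer(skip))
}
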