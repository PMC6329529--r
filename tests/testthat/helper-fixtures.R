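# Independent reference implementation of the session log-likelihood,
# written as plain data-frame arithmetic with no shared code with the
# package's compiled recursion.  Serves as the oracle in likelihood tests.
ref_session_loglik <- function(session, params, model_name,
                               skip = integer(), decay_v = FALSE) {
  forget <- grepl("forget", model_name)
  base <- sub("\\+forget$", "", model_name)
  p <- as.list(params)
  get_rho <- function(win) {
    if (base == "valenced_learning") p$rho
    else if (base == "valenced_sensitivity") if (win) p$rho_app else p$rho_av
    else if (win) p$rho_app else p$rho_app * exp(p$kappa)
  }
  get_lam <- function(win) {
    if (base == "valenced_learning") if (win) p$lam_app else p$lam_av
    else p$lam
  }
  Q <- matrix(0, 2, 4)  # rows: go, nogo
  V <- rep(0, 4)
  total <- 0
  logp <- rep(NA_real_, nrow(session))
  for (t in seq_len(nrow(session))) {
    act <- session$action[t]
    if (act == "missing") next
    s <- session$stimulus_id[t]
    win <- session$condition[t] %in% c("G2W", "NG2W")
    qg <- Q[1, s] + p$b_go + p$b_pav * V[s]
    qn <- Q[2, s]
    pg <- (1 - p$xi) * exp(qg) / (exp(qg) + exp(qn)) + p$xi / 2
    lp <- if (act == "go") log(pg) else log(1 - pg)
    logp[t] <- lp
    if (!(t %in% skip)) total <- total + lp
    rho <- get_rho(win); lam <- get_lam(win)
    ai <- if (act == "go") 1 else 2
    if (forget) {
      keep <- Q[ai, s]
      Q <- Q * p$m
      Q[ai, s] <- keep
      if (decay_v) { kv <- V[s]; V <- V * p$m; V[s] <- kv }
    }
    Q[ai, s] <- Q[ai, s] + lam * (rho * session$outcome[t] - Q[ai, s])
    V[s] <- V[s] + lam * (rho * session$outcome[t] - V[s])
  }
  list(total = total, trial_logp = logp)
}

vl_params <- function(rho = 2, lam_app = 0.1, lam_av = 0.2, b_go = 0.3,
                      b_pav = 0.5, xi = 0.05) {
  c(rho = rho, lam_app = lam_app, lam_av = lam_av, b_go = b_go,
    b_pav = b_pav, xi = xi)
}

random_session <- function(seed, params = vl_params(), model = "valenced_learning",
                           n_missing = 0) {
  sched <- gng_schedule(seed)
  s <- simulate_session(params, model, sched, seed = seed + 1)
  if (n_missing > 0) {
    idx <- withr::with_seed(seed + 2, sample(nrow(s), n_missing))
    s$action[idx] <- "missing"
  }
  s
}

# Large fixtures shared between the acceptance suite and property tests;
# computed once per session on first use.
.fixtures <- new.env(parent = emptyenv())

recovery_fixture <- function() {
  if (is.null(.fixtures$rec)) {
    spec <- population_spec(n = 300, seed = 101)
    sim <- simulate_cohort(spec)
    fit <- fit_em(sim$cohorts$baseline, "valenced_learning", seed = 202)
    merged <- dplyr::inner_join(sim$params, fit$subjects,
                                by = "participant_id",
                                suffix = c("_true", "_fit"))
    .fixtures$rec <- list(spec = spec, sim = sim, fit = fit, merged = merged)
  }
  .fixtures$rec
}

model_selection_fixture <- function() {
  if (is.null(.fixtures$sel)) {
    spec <- population_spec(n = 150, seed = 303)
    sim <- simulate_cohort(spec)
    .fixtures$sel <- list(spec = spec, sim = sim)
  }
  .fixtures$sel
}
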