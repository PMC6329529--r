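#' Test-retest statistics for per-subject measures
#'
#' Joins two per-subject tables by \code{participant_id} and reports, per
#' measure, a correlation across waves (Pearson for approximately Gaussian
#' measures, Spearman for skewed ones - declared per measure via
#' \code{method}), a paired Wilcoxon test of change, and Bonferroni
#' correction over the number of measures tested.
#'
#' @param table1,table2 Data frames with \code{participant_id} plus numeric
#'   measure columns.
#' @param measures Character vector of measure columns (default: all shared
#'   numeric columns).
#' @param method Named character vector mapping measures to
#'   \code{"pearson"} or \code{"spearman"}; unnamed entries are resolved by
#'   the default rule (Spearman for natural-scale \code{b_pav}, learning
#'   rates and lapse rates; Pearson otherwise).
#' @return Tibble per measure: correlation type, estimate, p, paired
#'   Wilcoxon p, Bonferroni-corrected ps, median change and n.
#' @export
retest_statistics <- function(table1, table2, measures = NULL, method = NULL) {
  m <- dplyr::inner_join(tibble::as_tibble(table1), tibble::as_tibble(table2),
                         by = "participant_id", suffix = c("_1", "_2"))
  if (!nrow(m)) abort("no matched participants")
  if (nrow(m) < 10) abort("need at least 10 matched participants")
  if (is.null(measures)) {
    shared <- intersect(names(table1), names(table2))
    measures <- shared[shared != "participant_id" &
                         vapply(table1[shared], is.numeric, logical(1))]
  }
  n_meas <- length(measures)
  purrr::map_dfr(measures, function(v) {
    x <- m[[paste0(v, "_1")]]; y <- m[[paste0(v, "_2")]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    type <- unname(method[v])
    if (is.null(type) || is.na(type)) type <- default_cor_method(v)
    ct <- suppressWarnings(cor.test(x, y, method = type))
    d <- y - x
    wp <- if (all(d == 0)) 1
          else suppressWarnings(wilcox.test(x, y, paired = TRUE)$p.value)
    tibble::tibble(measure = v, method = type,
                   estimate = unname(ct$estimate), cor_p = ct$p.value,
                   cor_p_corrected = min(1, ct$p.value * n_meas),
                   median_change = median(d), change_p = wp,
                   change_p_corrected = min(1, wp * n_meas), n = length(x))
  })
}

default_cor_method <- function(v) {
  skewed <- c("b_pav", "lam", "lam_app", "lam_av", "xi", "m", "rho",
              "rho_app", "rho_av")
  if (v %in% skewed) "spearman" else "pearson"
}

#' Gaussianize a vector by rank transform
#'
#' Maps values through their empirical cumulative distribution (average
#' ranks over \code{n + 1} to avoid the unit boundary) and then through the
#' inverse Gaussian CDF with the input's mean and SD.  The map preserves
#' ranks exactly and is idempotent up to tolerance.
#'
#' @param values Finite numeric vector, length at least 10, non-constant.
#' @return Gaussianized vector of the same length.
#' @export
gaussianize <- function(values) {
  if (length(values) < 10) abort("gaussianize needs n >= 10")
  if (any(!is.finite(values))) abort("values must be finite")
  if (sd(values) == 0) abort("values are constant; cannot gaussianize")
  r <- rank(values, ties.method = "average")
  qnorm(r / (length(values) + 1), mean = mean(values), sd = sd(values))
}

#' Just-identified univariate latent change score model
#'
#' Models two-wave data as \eqn{x_2 = x_1 + \Delta} with latent change
#' \eqn{\Delta = \alpha + \beta x_1 + \zeta}, \eqn{\zeta \sim N(0,
#' \sigma^2_\zeta)}: the most complex bivariate-normal model identifiable
#' from two waves, whose implied moments equal the sample moments exactly.
#' The self-feedback coefficient \eqn{\beta} is the regression of change on
#' baseline; pure regression to the mean corresponds to \eqn{\beta = -1}.
#' Likelihood-ratio tests compare the just-identified model against (a) the
#' regression-to-mean-only model (\eqn{\beta} fixed at -1; df = 1) and (b) a
#' model with equal mean and variance across waves (df = 2).
#'
#' @param x1,x2 Matched (preferably Gaussianized) vectors, n >= 30.
#' @return A \code{gng_lcs}: change mean and variance, \code{beta}, residual
#'   variance, log-likelihood, BIC, and a tibble of nested-model tests
#'   (\code{chisq}, \code{df}, \code{p}, \code{bic}).
#' @export
fit_lcs <- function(x1, x2) {
  if (any(!is.finite(x1)) || any(!is.finite(x2))) abort("inputs must be finite")
  n <- length(x1)
  stopifnot(length(x2) == n, n >= 30)
  m1 <- mean(x1); m2 <- mean(x2)
  v1 <- mean((x1 - m1)^2); v2 <- mean((x2 - m2)^2)  # ML variances
  c12 <- mean((x1 - m1) * (x2 - m2))
  d <- x2 - x1
  beta <- (c12 - v1) / v1
  alpha <- mean(d) - beta * m1
  var_d <- mean((d - mean(d))^2)
  resid_var <- max(var_d - beta^2 * v1, 0)

  ll_full <- bvn_loglik(x1, x2, m1, m2, v1, v2, c12)

  # (a) beta = -1: x2 = alpha + zeta, independent of x1
  ll_rtm <- bvn_loglik(x1, x2, m1, m2, v1, v2, 0)
  # (b) equal mean and variance across waves
  fit_b <- optim(c(mu = (m1 + m2) / 2, ls = log((v1 + v2) / 2),
                   z = atanh(max(min(c12 / sqrt(v1 * v2), 0.99), -0.99))),
                 function(p) {
                   s2 <- exp(p[2]); r <- tanh(p[3])
                   -bvn_loglik(x1, x2, p[1], p[1], s2, s2, r * s2)
                 }, method = "BFGS")
  ll_eq <- -fit_b$value

  tests <- tibble::tibble(
    hypothesis = c("regression_to_mean_only", "equal_mean_variance"),
    chisq = c(2 * (ll_full - ll_rtm), 2 * (ll_full - ll_eq)),
    df = c(1L, 2L))
  tests$p <- stats::pchisq(tests$chisq, tests$df, lower.tail = FALSE)
  tests$bic <- c(-2 * ll_rtm + 4 * log(n), -2 * ll_eq + 3 * log(n))

  structure(list(
    n = n, change_mean = mean(d), change_var = var_d, beta = beta,
    alpha = alpha, resid_var = resid_var, loglik = ll_full,
    bic = -2 * ll_full + 5 * log(n), tests = tests,
    moments = c(mean1 = m1, mean2 = m2, var1 = v1, var2 = v2, cov = c12)),
    class = "gng_lcs")
}

bvn_loglik <- function(x1, x2, m1, m2, v1, v2, c12) {
  det <- v1 * v2 - c12^2
  if (!is.finite(det) || det <= 0 || v1 <= 0 || v2 <= 0) return(-Inf)
  z1 <- x1 - m1; z2 <- x2 - m2
  q <- (v2 * z1^2 - 2 * c12 * z1 * z2 + v1 * z2^2) / det
  sum(-log(2 * pi) - 0.5 * log(det) - 0.5 * q)
}

#' @export
print.gng_lcs <- function(x, ...) {
  cat("<gng_lcs> n =", x$n, "\n")
  cat(sprintf("  change mean %.4f, change var %.4f, beta %.4f, resid var %.4f\n",
              x$change_mean, x$change_var, x$beta, x$resid_var))
  print(x$tests)
  invisible(x)
}

#' Gaussian-mixture clustering of paired model-fit values
#'
#' Fits full-covariance Gaussian mixtures to the joint distribution of a
#' model-fit measure (per-subject integrated likelihoods) at two waves,
#' selects the number of components by BIC, and hard-assigns each subject to
#' its most probable component.
#'
#' @param il1,il2 Matched vectors (n >= 50) of per-subject fit values.
#' @param K_candidates Candidate component counts (default 1..6).
#' @param n_init Retained for interface compatibility; the deterministic
#'   model-based hierarchical initialization used by the backend makes
#'   restarts unnecessary.
#' @param seed Integer seed.
#' @return A \code{gng_clusters}: selected \code{K}, component means,
#'   covariances and weights, per-subject assignments, cluster sizes and the
#'   BIC (-2 loglik + k log n; smaller is better) per candidate K.
#' @export
cluster_fit_values <- function(il1, il2, K_candidates = 1:6, n_init = 20,
                               seed = 1) {
  stopifnot(length(il1) == length(il2))
  if (length(il1) < 50) abort("cluster_fit_values needs n >= 50")
  X <- cbind(wave1 = il1, wave2 = il2)
  fit <- withr_seed(seed, {
    Mclust(X, G = K_candidates, modelNames = "VVV", verbose = FALSE)
  })
  if (is.null(fit)) abort("mixture fit failed for all candidate K")
  bics <- -as.numeric(fit$BIC[, "VVV"])  # mclust maximizes 2ll - k log n
  structure(list(
    K = fit$G,
    weights = fit$parameters$pro,
    means = t(fit$parameters$mean),
    covariances = fit$parameters$variance$sigma,
    assignment = as.integer(fit$classification),
    sizes = as.integer(table(factor(fit$classification, seq_len(fit$G)))),
    bic = tibble::tibble(K = K_candidates, bic = bics),
    loglik = fit$loglik, n = nrow(X)),
    class = "gng_clusters")
}

#' @export
print.gng_clusters <- function(x, ...) {
  cat("<gng_clusters> K =", x$K, "- sizes:", paste(x$sizes, collapse = ", "),
      "\n")
  invisible(x)
}
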