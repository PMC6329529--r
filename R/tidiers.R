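#' Tidy a hierarchical fit
#'
#' @param x A \code{gng_fit}.
#' @param ... Unused.
#' @return One row per participant: MAP parameters in natural and
#'   transformed space, integrated likelihood and per-trial prediction
#'   probability.
#' @export
tidy.gng_fit <- function(x, ...) {
  dplyr::mutate(x$subjects, ppt = ppt(.data$il, .data$n_trials))
}

#' @rdname tidy.gng_fit
#' @export
glance.gng_fit <- function(x, ...) {
  tibble::tibble(model = x$model$name, n_participants = x$n_participants,
                 n_trials = x$n_trials, ibic = x$ibic,
                 sum_il = sum(x$subjects$il),
                 grand_mean_ppt = mean(ppt(x$subjects$il, x$subjects$n_trials)),
                 iterations = nrow(x$trace), converged = x$converged)
}

#' Tidy a left-out-likelihood comparison
#'
#' @param x A \code{gng_lol}.
#' @param ... Unused.
#' @return \code{tidy()}: the per-subject table; \code{glance()}: one row
#'   per comparison with the bootstrap CI and grand mean Ppt of the
#'   reference model.
#' @export
tidy.gng_lol <- function(x, ...) x$per_subject

#' @rdname tidy.gng_lol
#' @export
glance.gng_lol <- function(x, ...) {
  ref_ppt <- x$grand_mean_ppt$grand_mean_ppt[
    x$grand_mean_ppt$model == x$comparisons$reference[1]]
  dplyr::mutate(x$comparisons, reference_grand_mean_ppt = ref_ppt)
}

#' Tidy a latent change score fit
#'
#' @param x A \code{gng_lcs}.
#' @param ... Unused.
#' @return \code{tidy()}: the nested-model comparison table;
#'   \code{glance()}: one row with estimates and fit measures.
#' @export
tidy.gng_lcs <- function(x, ...) x$tests

#' @rdname tidy.gng_lcs
#' @export
glance.gng_lcs <- function(x, ...) {
  tibble::tibble(n = x$n, change_mean = x$change_mean,
                 change_var = x$change_var, beta = x$beta, alpha = x$alpha,
                 resid_var = x$resid_var, loglik = x$loglik, bic = x$bic,
                 p_vs_regression_to_mean = x$tests$p[1],
                 p_vs_equal_moments = x$tests$p[2])
}

#' Tidy a mixture clustering of fit values
#'
#' @param x A \code{gng_clusters}.
#' @param ... Unused.
#' @return \code{tidy()}: one row per component (weight, means, size);
#'   \code{glance()}: one row with K, log-likelihood and BIC.
#' @export
tidy.gng_clusters <- function(x, ...) {
  tibble::tibble(cluster = seq_len(x$K), weight = x$weights,
                 mean_wave1 = x$means[, 1], mean_wave2 = x$means[, 2],
                 size = x$sizes)
}

#' @rdname tidy.gng_clusters
#' @export
glance.gng_clusters <- function(x, ...) {
  tibble::tibble(K = x$K, n = x$n, loglik = x$loglik,
                 bic = x$bic$bic[match(x$K, x$bic$K)])
}

#' Tidy a parameter-recovery report
#'
#' @param x A \code{gng_recovery}.
#' @param ... Unused.
#' @return The per-parameter recovery table.
#' @export
tidy.gng_recovery <- function(x, ...) x$recovery

#' Tidy a bias-experiment result
#'
#' @param x A \code{gng_bias_experiment}.
#' @param ... Unused.
#' @return \code{tidy()}: the per-epoch table; \code{glance()}: the
#'   per-level summary.
#' @export
tidy.gng_bias_experiment <- function(x, ...) x$epochs

#' @rdname tidy.gng_bias_experiment
#' @export
glance.gng_bias_experiment <- function(x, ...) x$summary
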