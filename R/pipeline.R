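#' Run the full analysis pipeline from one configuration
#'
#' Executes the requested stages in dependency order - \code{simulate} (or
#' load cohorts from files), \code{fit} (one hierarchical fit per model and
#' wave), \code{describe}, \code{compare} (iBIC + protected exceedance when
#' at least two models are fitted), \code{lol}, and \code{longitudinal}
#' (retest statistics, latent change scores and fit clustering when two
#' waves exist) - writing every table as CSV with a JSON metadata sidecar,
#' and returns a manifest of artifacts with checksums.  Every stochastic
#' stage derives its seed deterministically from the master seed.
#'
#' @param config Either a YAML file path or a list with (optional) entries:
#'   \code{seed} (master seed), \code{simulate} (arguments to
#'   \code{\link{population_spec}}), \code{inputs} (named list of cohort CSV
#'   paths per wave, alternative to \code{simulate}), \code{models}
#'   (character vector, default \code{"valenced_learning"}), \code{fit}
#'   (extra arguments to \code{\link{fit_em}}), \code{stages} (subset of
#'   \code{c("simulate", "fit", "describe", "compare", "lol",
#'   "longitudinal")}), \code{lol} (arguments to \code{\link{lol_config}}).
#' @param out_dir Output directory (created if needed).
#' @return A manifest tibble (stage, status, artifact paths, md5 checksums,
#'   elapsed seconds).  On stage failure the manifest records the failure,
#'   downstream stages are skipped, and the manifest carries attribute
#'   \code{"failed" = TRUE}.
#' @export
run_pipeline <- function(config, out_dir = tempfile("gng_run")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1
  stages <- config$stages %||%
    c(if (!is.null(config$simulate)) "simulate", "fit", "describe",
      if (length(config$models %||% "valenced_learning") > 1) "compare",
      if (!is.null(config$lol)) "lol", "longitudinal")
  models <- config$models %||% "valenced_learning"

  manifest <- list()
  failed <- FALSE
  note <- function(stage, status, files = character(), secs = NA_real_) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, status = status,
      artifact = if (length(files)) files else NA_character_,
      md5 = if (length(files)) unname(tools::md5sum(files)) else NA_character_,
      seconds = secs)
  }
  run_stage <- function(stage, fn) {
    if (failed) { note(stage, "skipped"); return(invisible(NULL)) }
    t0 <- proc.time()[3]
    res <- tryCatch(fn(), error = function(e) e)
    secs <- round(proc.time()[3] - t0, 2)
    if (inherits(res, "error")) {
      failed <<- TRUE
      note(stage, paste("failed:", conditionMessage(res)), secs = secs)
      NULL
    } else {
      note(stage, "completed", res %||% character(), secs)
      res
    }
  }
  write_table <- function(df, name, meta = list()) {
    csv <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(df, csv)
    side <- file.path(out_dir, paste0(name, ".json"))
    jsonlite::write_json(c(list(table = name, rows = nrow(df),
                                created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                seed = seed), meta),
                         side, auto_unbox = TRUE)
    c(csv, side)
  }

  cohorts <- NULL
  sim <- NULL
  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      spec <- do.call(population_spec,
                      modifyList(config$simulate %||% list(),
                                 list(seed = derive_seed(seed, 101))))
      sim <<- simulate_cohort(spec)
      cohorts <<- sim$cohorts
      files <- character()
      for (w in names(cohorts))
        files <- c(files, write_cohort(cohorts[[w]],
                                       file.path(out_dir, paste0("cohort_", w, ".csv"))))
      files <- c(files, write_table(sim$params, "generative_parameters"))
      files
    })
  } else {
    run_stage("load", function() {
      if (is.null(config$inputs)) abort("config needs either simulate or inputs")
      cohorts <<- lapply(config$inputs, read_cohort)
      unlist(config$inputs)
    })
  }

  fits <- list()
  if ("fit" %in% stages) run_stage("fit", function() {
    files <- character()
    for (w in names(cohorts)) {
      for (mn in models) {
        fit <- do.call(fit_em, c(list(cohort = cohorts[[w]], model = mn,
                                      seed = derive_seed(seed, 103,
                                                         sum(utf8ToInt(paste(w, mn))))),
                                 config$fit %||% list()))
        fits[[w]][[mn]] <<- fit
        files <- c(files,
                   write_table(tidy(fit), paste0("fit_", w, "_", mn),
                               list(model = mn, wave = w,
                                    ibic = fit$ibic, converged = fit$converged)))
      }
    }
    files
  })

  if ("describe" %in% stages) run_stage("describe", function() {
    files <- character()
    for (w in names(cohorts)) {
      files <- c(files,
                 write_table(performance_summary(cohorts[[w]]),
                             paste0("performance_", w)),
                 write_table(cross_condition_tests(cohorts[[w]], "early"),
                             paste0("cross_condition_early_", w)))
    }
    if (length(cohorts) == 2)
      files <- c(files, write_table(
        condition_change_tests(cohorts[[1]], cohorts[[2]]), "condition_change"))
    files
  })

  if ("compare" %in% stages) run_stage("compare", function() {
    files <- character()
    for (w in names(fits)) {
      if (length(fits[[w]]) < 2) next
      f <- fits[[w]]
      cmp <- compare_ibic(f[[1]], f[[2]])
      L <- do.call(cbind, lapply(f, function(x) x$subjects$il))
      pxp <- protected_exceedance(L, seed = derive_seed(seed, 107))
      files <- c(files,
                 write_table(tibble::tibble(
                   wave = w, model_a = names(f)[1], model_b = names(f)[2],
                   delta_ibic = cmp$delta_ibic, wilcoxon_p = cmp$wilcoxon_p),
                   paste0("ibic_comparison_", w)),
                 write_table(pxp, paste0("exceedance_", w)))
    }
    files
  })

  if ("lol" %in% stages) run_stage("lol", function() {
    lc <- do.call(lol_config, modifyList(config$lol %||% list(),
                                         list(seed = derive_seed(seed, 109))))
    res <- lol_compare(cohorts[[1]], as.list(models), lc,
                       fit_args = config$fit %||% list())
    c(write_table(res$per_subject, "lol_per_subject"),
      write_table(res$comparisons, "lol_comparisons"))
  })

  if ("longitudinal" %in% stages && length(cohorts) == 2 &&
      length(fits) == 2) run_stage("longitudinal", function() {
    f1 <- fits[[1]][[1]]$subjects
    f2 <- fits[[2]][[1]]$subjects
    model <- gng_model(models[1])
    meas <- c(model$params, "il")
    rt <- retest_statistics(f1[, c("participant_id", meas)],
                            f2[, c("participant_id", meas)])
    files <- write_table(rt, "retest_statistics")
    m <- dplyr::inner_join(f1, f2, by = "participant_id", suffix = c("_1", "_2"))
    if (nrow(m) >= 50) {
      cl <- cluster_fit_values(m$il_1, m$il_2, seed = derive_seed(seed, 113))
      files <- c(files, write_table(
        tibble::tibble(participant_id = m$participant_id,
                       cluster = cl$assignment), "fit_clusters",
        list(K = cl$K, sizes = cl$sizes)))
    }
    if (nrow(m) >= 30) {
      lcs <- fit_lcs(gaussianize(m$t_b_pav_1), gaussianize(m$t_b_pav_2))
      files <- c(files, write_table(glance(lcs), "lcs_b_pav"))
    }
    files
  })

  manifest <- dplyr::bind_rows(manifest)
  mf <- file.path(out_dir, "manifest.csv")
  readr::write_csv(manifest, mf)
  attr(manifest, "failed") <- failed
  attr(manifest, "out_dir") <- out_dir
  attr(manifest, "fits") <- fits
  manifest
}

#' Parameter-recovery report
#'
#' Simulates a cohort from a population specification, refits it with the
#' hierarchical EM procedure, and tabulates per-parameter recovery of the
#' transformed per-agent parameters: correlation between generative and
#' recovered values with a bootstrap CI, bias and RMSE, plus recovery of the
#' population means.
#'
#' @param spec A \code{\link{population_spec}} (wave 1 is used).
#' @param model Model to refit with (default: the generative model).
#' @param fit_args Extra arguments to \code{\link{fit_em}}.
#' @param n_boot Bootstrap resamples for the correlation CI.
#' @param seed Integer seed.
#' @return A \code{gng_recovery}: per-parameter tibble (\code{cor},
#'   \code{cor_lower}, \code{cor_upper}, \code{bias}, \code{rmse},
#'   \code{true_pop_mean}, \code{recovered_pop_mean}), the fit, and the
#'   merged per-agent table.  Zero-variance parameters yield \code{NA}
#'   correlations.
#' @export
recovery_report <- function(spec, model = NULL, fit_args = list(),
                            n_boot = 1000, seed = 1) {
  sim <- simulate_cohort(spec)
  gen_model <- gng_model(spec$model)
  model <- if (is.null(model)) gen_model else as_gng_model(model)
  fit <- do.call(fit_em, c(list(cohort = sim$cohorts[[1]], model = model,
                                seed = derive_seed(seed, 127)),
                           fit_args))
  truth <- sim$params[sim$params$wave == 1, ]
  shared <- intersect(gen_model$params, model$params)
  m <- dplyr::inner_join(truth, fit$subjects, by = "participant_id",
                         suffix = c("_true", "_fit"))
  per_par <- purrr::map_dfr(shared, function(p) {
    x <- m[[paste0("t_", p, "_true")]]
    y <- m[[paste0("t_", p, "_fit")]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (sd(x) == 0 || sd(y) == 0) {
      r <- ci <- c(NA_real_, NA_real_)
      return(tibble::tibble(param = p, cor = NA_real_, cor_lower = NA_real_,
                            cor_upper = NA_real_, bias = mean(y - x),
                            rmse = sqrt(mean((y - x)^2)),
                            true_pop_mean = mean(x), recovered_pop_mean = fit$prior$mean[[p]]))
    }
    r <- cor(x, y)
    ci <- withr_seed(derive_seed(seed, 131, sum(utf8ToInt(p))), {
      quantile(replicate(n_boot, {
        i <- sample.int(length(x), replace = TRUE)
        cor(x[i], y[i])
      }), c(0.025, 0.975), names = FALSE)
    })
    tibble::tibble(param = p, cor = r, cor_lower = ci[1], cor_upper = ci[2],
                   bias = mean(y - x), rmse = sqrt(mean((y - x)^2)),
                   true_pop_mean = mean(x),
                   recovered_pop_mean = fit$prior$mean[[p]])
  })
  structure(list(recovery = per_par, fit = fit, merged = m, spec = spec),
            class = "gng_recovery")
}

#' @export
print.gng_recovery <- function(x, ...) {
  cat("<gng_recovery>", x$spec$model, "-", x$spec$n, "agents\n")
  print(x$recovery)
  invisible(x)
}
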