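#' Configuration for the end-to-end pipeline
#'
#' Bundles every setting of the simulate / fit / law / predict /
#' analyze pipeline. Defaults mirror the study design: kinetic
#' parameters trained at 20, 25 and 29 degrees C, the non-robust
#' fraction anchored at the stressful temperatures, and held-out
#' predictions at 23, 28 and 30 degrees C.
#'
#' @param temps_train temperatures (degrees C) used to fit the kinetic
#'   laws.
#' @param temps_delta temperatures at which `delta` is estimated
#'   (those where it is nonzero).
#' @param temps_test held-out prediction temperatures.
#' @param pp a [population_params()] object (generator truth).
#' @param law a [temperature_law()] used as the generating truth.
#' @param proto an [observation_protocol()].
#' @param n_starts optimization starts per fit.
#' @param n_rep_predict simulated animals per prediction.
#' @param n_resamples permutation resamples in the CoV analysis.
#' @param seed master integer seed; every stage derives its own seed
#'   from it.
#' @param out_dir output directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(temps_train = c(20, 25, 29),
                            temps_delta = c(28, 29),
                            temps_test = c(23, 28, 30),
                            pp = population_params(),
                            law = default_temperature_law(),
                            proto = observation_protocol(),
                            n_starts = 4, n_rep_predict = 200,
                            n_resamples = 1e4, seed = 20L,
                            out_dir = file.path(tempdir(), "wormrepro_run")) {
  temps <- c(temps_train, temps_delta, temps_test)
  if (any(temps < 20 | temps > 31))
    stop("all configured temperatures must lie in [20, 31] degrees C")
  structure(list(temps_train = temps_train, temps_delta = temps_delta,
                 temps_test = temps_test, pp = pp, law = law, proto = proto,
                 n_starts = n_starts, n_rep_predict = n_rep_predict,
                 n_resamples = n_resamples, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full simulate / fit / law / predict / analyze pipeline
#'
#' Executes the complete in-silico study design against synthetic
#' data: (1) simulate cohorts from the generating temperature law at
#' the training and `delta` temperatures; (2) infer the sperm-cache
#' hyper-parameters from the 20 degrees C broods; (3) fit the kinetic
#' parameters per temperature by maximum likelihood (`delta` only at
#' 28 degrees C and above); (4) fit the exponential temperature laws;
#' (5) predict egg-laying dynamics at the held-out temperatures from
#' the fitted laws; (6) run the brood-size analyses (mixture fit at
#' the hottest training temperature, CoV permutation test between the
#' two permissive temperatures). All tables, fit JSONs, the law
#' config, prediction CSVs and a manifest (config, seeds, versions,
#' file list) are written under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) stop("`config` must be a pipeline_config")
  out <- config$out_dir
  for (d in file.path(out, c("tables", "fits", "predictions", "analysis")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  temps_sim <- sort(unique(c(config$temps_train, config$temps_delta)))
  seeds <- config$seed + seq_along(temps_sim)
  names(seeds) <- as.character(temps_sim)

  tabs <- stage("simulate", {
    tt <- lapply(seq_along(temps_sim), function(i)
      simulate_cohort(config$pp, config$proto, temp_C = temps_sim[i],
                      law = config$law, seed = seeds[i]))
    names(tt) <- as.character(temps_sim)
    for (nm in names(tt))
      write_egg_table(tt[[nm]], file.path(out, "tables",
                                          sprintf("cohort_T%s.csv", nm)),
                      meta = list(seed = seeds[nm], temp_C = nm,
                                  generator = "wormrepro::simulate_cohort"))
    tt
  })

  pp_fit <- stage("sperm_inference", {
    ref <- as.character(min(temps_sim))
    sp <- infer_sperm_from_brood(suppressWarnings(brood_sizes(tabs[[ref]])))
    pp <- config$pp
    pp$mu_S <- sp$mu_S
    pp$sigma_S <- sp$sigma_S
    pp
  })

  fits <- stage("fit", {
    ff <- lapply(temps_sim, function(tc)
      fit_mle(tabs[[as.character(tc)]], temp_C = tc, pp = pp_fit,
              k_hat = config$law$k_hat, fit_delta = tc >= 28,
              n_starts = config$n_starts, seed = config$seed + 100L + tc))
    names(ff) <- as.character(temps_sim)
    for (nm in names(ff))
      jsonlite::write_json(ff[[nm]][c("estimates", "loglik", "temp_C",
                                      "k_hat", "convergence", "seed")],
                           file.path(out, "fits", sprintf("fit_T%s.json", nm)),
                           auto_unbox = TRUE, digits = NA)
    ff
  })

  law_hat <- stage("law", {
    lw <- suppressWarnings(fit_temperature_law(
      fits[as.character(sort(unique(config$temps_train)))],
      delta_fits = fits[as.character(sort(unique(config$temps_delta)))]))
    write_temperature_law(lw, file.path(out, "law.yaml"))
    lw
  })

  preds <- stage("predict", {
    pr <- lapply(config$temps_test, function(tc)
      suppressWarnings(
        predict_cohort(law_hat, pp_fit, temp_C = tc, proto = config$proto,
                       n_rep = config$n_rep_predict,
                       seed = config$seed + 200L + tc)))
    names(pr) <- as.character(config$temps_test)
    for (nm in names(pr))
      utils::write.csv(pr[[nm]],
                       file.path(out, "predictions",
                                 sprintf("pred_T%s.csv", nm)),
                       row.names = FALSE)
    pr
  })

  analysis <- stage("analyze", {
    hot <- as.character(max(temps_sim))
    cool <- as.character(sort(temps_sim)[1:2])
    broods_hot <- suppressWarnings(brood_sizes(tabs[[hot]]))
    broods_cool <- lapply(cool, function(nm)
      suppressWarnings(brood_sizes(tabs[[nm]])))
    mix <- fit_brood_mixture(broods_hot, family = "normal_normal",
                             n_boot = 199, seed = config$seed + 300L)
    pt <- permutation_test_cov(broods_cool[[1]], broods_cool[[2]],
                               n_resamples = config$n_resamples,
                               seed = config$seed + 301L)
    res <- list(mixture_temp_C = as.numeric(hot),
                mixture = mix[c("family", "weights", "components", "loglik",
                                "aic", "p_single_normal", "preferred")],
                cov_test_temps_C = as.numeric(cool),
                cov_test = pt[c("statistic", "p_value", "n_resamples")])
    jsonlite::write_json(res, file.path(out, "analysis", "broods.json"),
                         auto_unbox = TRUE, digits = NA)
    res
  })

  manifest <- list(
    package = "wormrepro",
    version = as.character(utils::packageVersion("wormrepro")),
    seed = config$seed, cohort_seeds = as.list(seeds),
    temps_train = config$temps_train, temps_delta = config$temps_delta,
    temps_test = config$temps_test,
    sperm_hyperparams = list(mu_S = pp_fit$mu_S, sigma_S = pp_fit$sigma_S),
    estimates = lapply(fits, `[[`, "estimates"),
    law = list(k_max = as.list(law_hat$k_max), k_d = as.list(law_hat$k_d),
               delta = as.list(law_hat$delta), k_hat = law_hat$k_hat),
    predicted_mean_brood = lapply(preds, function(p)
      mean(attr(p, "broods"))),
    analysis = analysis,
    files = sort(unique(c(list.files(out, recursive = TRUE),
                          "manifest.json"))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
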