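# End-to-end orchestration: simulate (or load) -> screen -> fit ->
# diagnose -> summarize -> recover, with every artifact written as a
# plain-text file and a manifest recording seeds and stage progress.

#' Run the full scale-mark analysis pipeline
#'
#' Sequences the whole analysis and writes its artifacts under `out_dir`:
#' the dataset (`dataset.csv`), the damage/regeneration percentage table
#' (`status_table.csv`, `status_summary.csv`), the locality screen and
#' length correlation (`screening.json`), species-level posterior draws in
#' long format (`draws.csv`), the diagnostics report
#' (`diagnostics.json`), effect and interaction summaries (`effects.csv`,
#' `surface.csv`), in synthetic mode a truth-recovery report
#' (`recovery.csv`) and the truth itself (`truth.yml`), and a
#' `manifest.json` with the seed, configuration and per-stage record
#' counts. Exactly one of `data` and `truth` must be given: a CSV path (or
#' data frame) of observed records, or a generative truth to simulate
#' from. Mixed-species inputs are split and fitted one model per species.
#'
#' The pipeline is a pure function of its configuration and seed: repeated
#' runs produce identical artifacts.
#'
#' @param out_dir Output directory (created if needed).
#' @param data CSV path or data frame of scale records (observed mode).
#' @param truth A [scale_truth()] (synthetic mode).
#' @param n_individuals Specimens to simulate (synthetic mode).
#' @param seed Integer seed for simulation, fitting, and posterior
#'   predictive checks.
#' @param per_scale Passed to [kw_locality_screen()].
#' @param ppc Compute posterior-predictive p-values in the diagnostics.
#' @param ... Model settings passed to [scale_model_config()].
#' @return Invisibly, a list with one element per species: `fit`,
#'   `diagnostics`, `effects`, `surface`, and (synthetic mode)
#'   `recovery`; plus `screening` and `manifest`.
#' @export
run_scale_pipeline <- function(out_dir, data = NULL, truth = NULL,
                               n_individuals = NULL, seed = 1,
                               per_scale = FALSE, ppc = TRUE, ...) {
  if (is.null(data) == is.null(truth)) {
    abort("Provide exactly one of `data` (observed) or `truth` (synthetic).",
          class = "scalemarks_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = as.integer(seed),
                   package_version = as.character(utils::packageVersion("scalemarks")),
                   mode = if (is.null(truth)) "observed" else "synthetic",
                   stages = list())
  stage <- function(name, value) {
    manifest$stages[[name]] <<- value
    write_manifest(manifest, out_dir)
  }
  on_failure <- function(name, err) {
    manifest$stages[[name]] <<- paste("FAILED:", conditionMessage(err))
    write_manifest(manifest, out_dir)
    abort(paste0("Pipeline stage '", name, "' failed: ",
                 conditionMessage(err)))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) on_failure(name, e))
  }

  sim <- NULL
  dataset <- run_stage("input", {
    if (!is.null(truth)) {
      sim <- simulate_scales(truth, seed = seed,
                             n_individuals = n_individuals %||%
                               truth$n_individuals)
      write_truth(truth, file.path(out_dir, "truth.yml"))
      sim$data
    } else if (is.character(data)) {
      read_scale_table(data)
    } else {
      validate_scales(data)
    }
  })
  write_scale_table(dataset, file.path(out_dir, "dataset.csv"))
  stage("input", list(n_scales = nrow(dataset),
                      n_specimens = dplyr::n_distinct(dataset$specimen_id)))

  screening <- run_stage("screen", {
    st <- status_table(dataset)
    readr::write_csv(st$cells, file.path(out_dir, "status_table.csv"))
    readr::write_csv(st$summary, file.path(out_dir, "status_summary.csv"))
    species_list <- split(dataset, dataset$species)
    kw <- lapply(species_list, function(d)
      tryCatch(unclass(kw_locality_screen(d, per_scale = per_scale)),
               error = function(e) list(error = conditionMessage(e))))
    corr <- lapply(species_list, length_correlation)
    out <- list(kruskal_wallis = kw, length_correlation = corr)
    write_json_file(out, file.path(out_dir, "screening.json"))
    list(status = st, tests = out)
  })
  readable <- run_stage("filter", filter_readable(dataset))
  stage("screen", list(n_readable = nrow(readable),
                       n_dropped = nrow(dataset) - nrow(readable)))

  results <- list(screening = screening)
  for (sp in unique(readable$species)) {
    d_sp <- dplyr::filter(readable, .data$species == sp)
    tag <- if (dplyr::n_distinct(readable$species) > 1) paste0("_", sp) else ""
    fit <- run_stage(paste0("fit", tag), {
      design <- build_design(d_sp)
      fit_model(design, config = scale_model_config(seed = seed, ...))
    })
    write_species_draws(fit, file.path(out_dir, paste0("draws", tag, ".csv")))
    stage(paste0("fit", tag),
          list(n_scales = nrow(d_sp), chains = fit$chains, draws = fit$draws,
               tune = fit$tune, retried = fit$retried))

    diag <- run_stage(paste0("diagnose", tag), diagnose(fit, ppc = ppc))
    write_json_file(
      list(converged = diag$converged, n_divergent = diag$n_divergent,
           max_rhat = max(diag$parameters$rhat),
           min_ess = min(diag$parameters$ess),
           ebfmi = diag$ebfmi, ppc_pvalues = as.list(diag$ppc_pvalues)),
      file.path(out_dir, paste0("diagnostics", tag, ".json")))
    stage(paste0("diagnose", tag), list(converged = diag$converged))

    res <- run_stage(paste0("summarize", tag), {
      eff <- effect_summary(fit)
      surf <- interaction_surface(fit)
      readr::write_csv(eff, file.path(out_dir, paste0("effects", tag, ".csv")))
      readr::write_csv(surf, file.path(out_dir, paste0("surface", tag, ".csv")))
      list(effects = eff, surface = surf)
    })
    rec <- NULL
    if (!is.null(sim) && sp == sim$truth$species) {
      rec <- run_stage(paste0("recover", tag), {
        r <- recovery_report(sim$truth, res$effects)
        readr::write_csv(r$table, file.path(out_dir, paste0("recovery", tag, ".csv")))
        r
      })
      stage(paste0("recover", tag),
            list(coverage_fraction = rec$coverage_fraction))
    }
    results[[sp]] <- list(fit = fit, diagnostics = diag,
                          effects = res$effects, surface = res$surface,
                          recovery = rec)
  }
  manifest$stages$done <- TRUE
  write_manifest(manifest, out_dir)
  results$manifest <- manifest
  invisible(results)
}

write_manifest <- function(manifest, out_dir) {
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
}

write_json_file <- function(x, path) {
  # jsonlite is available wherever tidyverse is; kept as a soft dependency
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                           null = "null")), path)
}

# Long-format species-level draws: parameter, chain, draw, value.
write_species_draws <- function(fit, path) {
  pars <- species_level_parameters(fit)
  long <- dplyr::bind_rows(lapply(pars, function(p) {
    m <- posterior_matrix(fit, p)
    tibble::tibble(parameter = p,
                   chain = rep(seq_len(nrow(m)), times = ncol(m)),
                   draw = rep(seq_len(ncol(m)), each = nrow(m)),
                   value = as.vector(m))
  }))
  readr::write_csv(long, path)
  invisible(path)
}
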