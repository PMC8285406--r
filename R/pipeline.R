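# End-to-end orchestration: count -> growth/viability -> TAS -> classify ->
# IC50 -> cluster, with provenance (config hash + derived per-stage seeds)
# and optional TSV outputs with stage-level resume.

#' Pipeline parameters
#'
#' Validated parameter set for [run_mano_pipeline()]; unknown arguments are
#' rejected by R's argument matching. The single root `seed` is fanned out
#' to per-stage seeds with [derive_seed()], so each stage is individually
#' reproducible.
#'
#' @param reference_day,target_day growth-assay reference and endpoint days.
#' @param alpha significance level for growth calls and classification.
#' @param chains,warmup,samples TAS MCMC settings.
#' @param n_draws posterior parameter sets for the TAS summary.
#' @param viability_reference `"negative_control"` or `"none"`, see
#'   [viability_from_counts()].
#' @param censored_policy `"impute"` or `"drop"`, see
#'   [transform_sensitivity()].
#' @param k_clusters clusters to cut the variant dendrogram into.
#' @param seed root seed.
#' @return a named list of class `mano_params`.
#' @export
mano_params <- function(reference_day = 3, target_day = 18, alpha = 0.05,
                        chains = 4, warmup = 1500, samples = 2000,
                        n_draws = 500,
                        viability_reference = c("negative_control", "none"),
                        censored_policy = c("impute", "drop"),
                        k_clusters = 4, seed = 1) {
  stopifnot(alpha > 0, alpha <= 1, n_draws >= 1)
  p <- list(reference_day = reference_day, target_day = target_day,
            alpha = alpha, chains = chains, warmup = warmup,
            samples = samples, n_draws = n_draws,
            viability_reference = match.arg(viability_reference),
            censored_policy = match.arg(censored_policy),
            k_clusters = k_clusters, seed = seed)
  structure(p, class = "mano_params",
            hash = fnv1a_hex(paste(names(p), unlist(p), collapse = ";")))
}

stage_path <- function(out_dir, name) file.path(out_dir, paste0(name, ".tsv"))

maybe_write <- function(tbl, out_dir, name, hash) {
  if (is.null(out_dir)) return(invisible(NULL))
  path <- stage_path(out_dir, name)
  readr::write_lines(sprintf("# manoscreen config=%s", hash), path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full MANO analysis pipeline
#'
#' Executes, in dependency order, every stage for which input data are
#' supplied: growth normalization and significance, TAS fitting and
#' summarization, oncogenicity classification, pooled-viability
#' dose-response fitting, and drug-sensitivity clustering. Each TSV output
#' carries the configuration hash; with `resume = TRUE` stages whose output
#' file already exists in `out_dir` are skipped and reloaded.
#'
#' @param growth_counts long count tibble for the growth screen (or `NULL`).
#' @param drug_counts long count tibble for the drug screen (or `NULL`).
#' @param assay_scores ordinal assay score tibble (or `NULL`).
#' @param params a [mano_params()] object.
#' @param out_dir optional directory for TSV outputs and the JSON run
#'   report.
#' @param resume reload finished stages from `out_dir` instead of
#'   recomputing.
#' @return list of stage results: `growth`, `growth_significance`,
#'   `tas_fit`, `tas`, `classification`, `viability`, `ic50_fits`,
#'   `clustering`, and `report` (config hash, seed, stage log).
#' @export
run_mano_pipeline <- function(growth_counts = NULL, drug_counts = NULL,
                              assay_scores = NULL, params = mano_params(),
                              out_dir = NULL, resume = FALSE) {
  stopifnot(inherits(params, "mano_params"))
  hash <- attr(params, "hash")
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  res <- list()
  log <- list()
  run_stage <- function(name, fun, writable = TRUE) {
    path <- if (!is.null(out_dir)) stage_path(out_dir, name) else NULL
    if (resume && writable && !is.null(path) && file.exists(path)) {
      log[[name]] <<- "resumed"
      return(readr::read_tsv(path, comment = "#", show_col_types = FALSE))
    }
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            parent = e)
    })
    log[[name]] <<- sprintf("ran in %.2fs", as.numeric(Sys.time() - t0, units = "secs"))
    if (writable && is.data.frame(out)) maybe_write(out, out_dir, name, hash)
    out
  }

  if (!is.null(growth_counts)) {
    res$growth <- run_stage("growth", function() {
      relative_proliferation(growth_counts, params$reference_day,
                             params$target_day)
    }, writable = FALSE)
    maybe_write(res$growth, out_dir, "growth", hash)
    res$growth_significance <- run_stage("growth_significance", function() {
      growth_significance(res$growth, "wild_type", params$alpha)
    })
  }

  if (!is.null(assay_scores)) {
    res$tas_fit <- run_stage("tas_fit", function() {
      fit_tas(assay_scores, chains = params$chains, warmup = params$warmup,
              samples = params$samples,
              seed = derive_seed(params$seed, "tas_fit"))
    }, writable = FALSE)
    res$tas <- run_stage("tas", function() {
      compute_tas(res$tas_fit, n_draws = params$n_draws,
                  seed = derive_seed(params$seed, "tas_draws"))
    })
  }

  if (!is.null(res$tas) && !is.null(res$growth_significance) &&
      !is.null(growth_counts)) {
    res$classification <- run_stage("classification", function() {
      info <- growth_counts |> distinct(.data$variant_id, .data$gene, .data$role)
      oncogenicity_evidence(res$tas, res$growth_significance, info) |>
        classify_variants(alpha = params$alpha)
    })
  }

  if (!is.null(drug_counts)) {
    res$viability <- run_stage("viability", function() {
      drug_relative_viability(drug_counts)
    })
    res$ic50_fits <- run_stage("ic50_fits", function() {
      viability_from_counts(res$viability, params$viability_reference) |>
        fit_dose_response()
    })
    res$clustering <- run_stage("clustering", function() {
      uncensored_drugs <- res$ic50_fits |>
        filter(.data$converged)
      z <- transform_sensitivity(uncensored_drugs,
                                 censored_policy = params$censored_policy)
      cluster_sensitivity(z, "variants",
                          k = min(params$k_clusters, nrow(z) - 1))
    }, writable = FALSE)
    if (!is.null(out_dir)) {
      maybe_write(res$clustering$merge_table, out_dir, "clustering_merges", hash)
      write_dendrogram_newick(res$clustering,
                              file.path(out_dir, "variants.nwk"))
    }
  }

  res$report <- list(config_hash = hash, seed = params$seed,
                     params = unclass(params), stages = log,
                     package_version = as.character(utils::packageVersion("manoscreen")))
  if (!is.null(out_dir)) {
    jsonlite::write_json(res$report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
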