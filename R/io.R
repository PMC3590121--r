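#' Read a branch-record CSV
#'
#' Reads and validates the long-format branch/tree harvest schema:
#' species_id, tree_id, branch_id, parent_id, diameter_cm, length_m,
#' wood_wet_kg, leaf_wet_kg. Validation failures raise typed conditions of
#' class `allom_validation_error` naming the offending row.
#'
#' @param path Path to a CSV file with a header.
#' @return A validated branch-record `data.frame`.
#' @export
read_branch_csv <- function(path) {
  if (!file.exists(path)) {
    allom_error(paste0("file not found: ", path), "allom_io_error")
  }
  rec <- read.csv(path, stringsAsFactors = FALSE)
  validate_branch_records(rec)
}

allom_error <- function(msg, class) {
  stop(structure(
    class = c(class, "allom_validation_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

validate_branch_records <- function(rec) {
  required <- c("species_id", "tree_id", "branch_id", "parent_id",
                "diameter_cm", "length_m", "wood_wet_kg", "leaf_wet_kg")
  missing_cols <- setdiff(required, names(rec))
  if (length(missing_cols)) {
    allom_error(paste0("missing column(s): ",
                       paste(missing_cols, collapse = ", ")),
                "allom_schema_error")
  }
  rec$parent_id[!is.na(rec$parent_id) & rec$parent_id == ""] <- NA
  key <- paste(rec$tree_id, rec$branch_id)
  if (anyDuplicated(key)) {
    row <- which(duplicated(key))[1L]
    allom_error(paste0("duplicate (tree_id, branch_id) at row ", row),
                "allom_schema_error")
  }
  bad_d <- which(!is.finite(rec$diameter_cm) | rec$diameter_cm <= 0)
  if (length(bad_d)) {
    allom_error(paste0("nonpositive diameter at row ", bad_d[1L]),
                "allom_value_error")
  }
  for (tid in unique(rec$tree_id)) {
    idx <- which(rec$tree_id == tid)
    p <- rec$parent_id[idx]
    orphan <- which(!is.na(p) & !(p %in% rec$branch_id[idx]))
    if (length(orphan)) {
      allom_error(paste0("parent_id '", p[orphan[1L]],
                         "' not found within tree '", tid, "' (row ",
                         idx[orphan[1L]], ")"),
                  "allom_topology_error")
    }
  }
  rec
}

#' Write a branch-record CSV
#'
#' @param records Branch-record `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_branch_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write posterior summaries, variance components and diagnostics
#'
#' Emits per-level exponent/intercept summary CSVs, a variance-component
#' table (one row per trait with tree-level and species-level exponent
#' variances and their 95% CIs), and a diagnostics JSON (R-hat per global
#' parameter, Heidelberger–Welch results, acceptance rates).
#'
#' @param fit An `allom_hb` fit.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_posterior_summary <- function(fit, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    exponents = file.path(out_dir, "exponent_summaries.csv"),
    intercepts = file.path(out_dir, "intercept_summaries.csv"),
    variance = file.path(out_dir, "variance_components.csv"),
    diagnostics = file.path(out_dir, "diagnostics.json")
  )
  s <- summary(fit)
  write.csv(s$exponents, paths["exponents"], row.names = FALSE)
  write.csv(s$intercepts, paths["intercepts"], row.names = FALSE)
  write.csv(s$variance_components, paths["variance"], row.names = FALSE)

  hw <- lapply(sprintf("B[%s]", TRAITS), function(nm) {
    chain <- fit$samples$chains[[1L]][, nm]
    if (length(chain) >= 100) heidelberger_welch(chain) else NULL
  })
  names(hw) <- sprintf("B[%s]", TRAITS)
  diag <- list(
    rhat = as.list(s$rhat),
    heidelberger = hw,
    acceptance = fit$samples$acceptance,
    runtime_s = fit$samples$runtime_s
  )
  jsonlite::write_json(diag, paths["diagnostics"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate/ingest, preprocessing, model fitting, convergence
#' diagnostics, posterior predictive checks and theoretical-model
#' comparison, writing every artifact plus a run manifest (config snapshot,
#' seeds, file checksums) to `out_dir`. If the R-hat convergence gate fails
#' on any global parameter, all outputs are still written and a warning of
#' class `allom_convergence_warning` is raised.
#'
#' @param config A list (or path to a YAML file) with optional entries:
#'   `input_csv` (path to branch records; if absent the study-design
#'   fixture is generated), `ratios` (named dry:wet vector; required with
#'   `input_csv`), `mode` (fixture generation mode), `sampler` (arguments
#'   for [allom_sampler_control()]), `model` (arguments for
#'   [allom_model_config()]), `n_replicates` (PPC replicates, default 500),
#'   `rhat_threshold` (default 1.1).
#' @param out_dir Output directory.
#' @param seed Integer seed controlling every stage.
#' @return A list with the fit, ppc, comparison and artifact paths,
#'   invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)

  sampler_args <- config$sampler %||% list()
  model_args <- config$model %||% list()
  control <- do.call(allom_sampler_control, sampler_args)
  model <- do.call(allom_model_config, model_args)

  ## stage 1: ingest or generate
  if (!is.null(config$input_csv)) {
    records <- read_branch_csv(config$input_csv)
    ratios <- unlist(config$ratios)
    if (is.null(ratios)) {
      allom_error("`ratios` required with `input_csv`", "allom_config_error")
    }
    truth <- NULL
  } else {
    fx <- study_fixture(seed = seed, mode = config$mode %||% "model-exact")
    records <- fx$records
    ratios <- setNames(fx$truth$config$dry_wet_ratios,
                       fx$truth$species_ids)
    truth <- fx$truth
  }
  data_csv <- file.path(out_dir, "branch_records.csv")
  write_branch_csv(records, data_csv)

  ## stage 2: preprocess
  obs <- allom_observations(records, ratios,
                            min_diameter = config$min_diameter %||% 2.0)
  obs_csv <- file.path(out_dir, "observations.csv")
  write.csv(as.data.frame(obs), obs_csv, row.names = FALSE)
  jsonlite::write_json(attr(obs, "report"),
                       file.path(out_dir, "preprocess_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  ## stage 3: fit
  fit <- allom_hb(obs, model = model, control = control, seed = seed)
  sum_paths <- write_posterior_summary(fit, out_dir)

  ## stage 4: posterior predictive checks
  pp <- allom_ppc(fit, n_replicates = config$n_replicates %||% 500,
                  seed = seed)
  write.csv(as.data.frame(pp), file.path(out_dir, "ppc.csv"),
            row.names = FALSE)

  ## stage 5: model comparison
  cmp <- compare_scaling_models(fit)
  write.csv(cmp$inclusion, file.path(out_dir, "ci_inclusion.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(percentages = cmp$percentages, best = cmp$best,
         contrasts = cmp$contrasts),
    file.path(out_dir, "comparison.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  ## manifest + convergence gate
  rh <- global_rhat(fit)
  threshold <- config$rhat_threshold %||% 1.1
  converged <- length(fit$samples$chains) < 2L || all(rh <= threshold)
  manifest <- list(
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    sampler = unclass(control),
    model = lapply(unclass(model), function(x) {
      if (is.matrix(x)) as.data.frame(x) else x
    }),
    converged = converged,
    rhat = if (all(is.na(rh))) NULL else as.list(rh),
    files = file_hashes(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!converged) {
    warning(structure(
      class = c("allom_convergence_warning", "warning", "condition"),
      list(message = paste0("convergence gate failed: max R-hat = ",
                            format(max(rh), digits = 4)),
           call = NULL)
    ))
  }
  invisible(list(fit = fit, ppc = pp, comparison = cmp,
                 converged = converged, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 checksums of the artifacts for the run manifest
file_hashes <- function(dir) {
  fs <- list.files(dir, full.names = TRUE)
  fs <- fs[!grepl("manifest\\.json$", fs)]
  h <- tools::md5sum(fs)
  as.list(setNames(as.character(h), basename(fs)))
}
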