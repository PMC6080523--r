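#' Pipeline configuration
#'
#' Resolved settings for an end-to-end run: either paths to existing inputs
#' (pedigree/genotype/phenotype/annotation files) or a simulation request.
#' Defaults mirror the analysis conventions of weighted single-step GWAS for
#' chip data: QC at call rate 0.95 / MAF 0.01 / HWE chi-square 600 / animal
#' missingness 0.05, three weighting iterations, 0.4 Mb windows, 1%
#' selection threshold.
#'
#' @param pedigree_path,genotype_prefix,phenotype_path,annotation_path input
#'   file locations (`genotype_prefix` as in [read_plink()]); all `NULL`
#'   when `simulate` is given.
#' @param simulate optional [sim_config()]; when present, inputs are
#'   generated instead of read.
#' @param traits trait names to analyse (matched against the record table's
#'   `trait` column).
#' @param thresholds a [qc_thresholds()].
#' @param n_iterations,span_bp,selection_threshold_pct,blend_alpha WssGWAS
#'   settings.
#' @param seed integer seed recorded with the run.
#' @param out_dir output directory (created if needed).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(pedigree_path = NULL, genotype_prefix = NULL,
                            phenotype_path = NULL, annotation_path = NULL,
                            simulate = NULL, traits = "sim_trait",
                            thresholds = qc_thresholds(),
                            n_iterations = 3L, span_bp = 400000,
                            selection_threshold_pct = 1.0,
                            blend_alpha = 0.05, seed = 1L,
                            out_dir = tempfile("wssgwas_run_")) {
  structure(list(
    pedigree_path = pedigree_path, genotype_prefix = genotype_prefix,
    phenotype_path = phenotype_path, annotation_path = annotation_path,
    simulate = simulate, traits = traits, thresholds = thresholds,
    n_iterations = as.integer(n_iterations), span_bp = span_bp,
    selection_threshold_pct = selection_threshold_pct,
    blend_alpha = blend_alpha, seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

# Internal: serialisable view of a config (for the run log / hash).
config_as_list <- function(config) {
  out <- unclass(config)
  out$thresholds <- unclass(out$thresholds)
  if (!is.null(out$simulate)) out$simulate <- unclass(out$simulate)
  out
}

#' Run the full WssGWAS pipeline
#'
#' simulate/load -> QC -> REML (unit weights) -> weighted single-step GWAS ->
#' window selection and region merging -> reports. Every stage's output is
#' written under `config$out_dir` together with the resolved configuration
#' and its hash; re-running with the same configuration reproduces identical
#' files. Any stage failure aborts with the stage name in the condition.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the per-trait fits, the QC report, the
#'   region tables, and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_wssgwas(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)),
                   "pipeline_stage_error", stage = name, parent = e)
    })
  }
  log_lines <- c(
    paste0("wssgwas pipeline run, package version ",
           as.character(utils::packageVersion("wssgwas"))),
    paste0("R version: ", R.version.string),
    paste0("seed: ", config$seed))

  cfg_path <- file.path(config$out_dir, "run_config.json")
  jsonlite::write_json(config_as_list(config), cfg_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  # hash the analysis-relevant settings only, so runs differing solely in
  # their output location share a hash
  hash_cfg <- config_as_list(config)
  hash_cfg$out_dir <- NULL
  hash_path <- tempfile(fileext = ".json")
  jsonlite::write_json(hash_cfg, hash_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  cfg_hash <- unname(tools::md5sum(hash_path))
  unlink(hash_path)
  log_lines <- c(log_lines, paste0("config hash: ", cfg_hash))

  inputs <- stage("load", {
    if (!is.null(config$simulate)) {
      ds <- simulate_dataset(config$simulate)
      list(ped = ds$ped, panel = ds$panel, records = ds$records,
           truth = ds$truth, annotation = NULL)
    } else {
      for (p in c(config$pedigree_path, config$phenotype_path)) {
        if (!file.exists(p)) {
          stop_wssgwas(paste0("input file not found: ", p), "io_missing_file")
        }
      }
      list(
        ped = read_pedigree_csv(config$pedigree_path),
        panel = read_plink(config$genotype_prefix),
        records = read_phenotypes_csv(config$phenotype_path),
        truth = NULL,
        annotation = if (!is.null(config$annotation_path))
          read_gene_annotation(config$annotation_path) else NULL
      )
    }
  })
  if (is.null(inputs$annotation) && !is.null(config$annotation_path)) {
    inputs$annotation <- stage("load", read_gene_annotation(config$annotation_path))
  }

  qc <- stage("qc", apply_qc(inputs$panel, config$thresholds))
  write_qc_report(qc$report, file.path(config$out_dir, "qc_report.tsv"))

  keep <- union(unique(inputs$records$animal), rownames(qc$panel$geno))
  ped <- stage("prune", prune_pedigree(inputs$ped, keep))

  fits <- list()
  all_windows <- list()
  for (tr in config$traits) {
    model <- stage("model", build_model(inputs$records, ped, trait_name = tr))
    vc <- stage("reml", estimate_reml(model))
    write_vc_report(vc, file.path(config$out_dir,
                                  paste0("variance_components_", tr, ".tsv")))
    fit <- stage("gwas", run_wssgwas(model, qc$panel, vc,
                                     n_iterations = config$n_iterations,
                                     blend_alpha = config$blend_alpha,
                                     span_bp = config$span_bp))
    Z <- center_gene_content(qc$panel)
    mt <- manhattan_table(fit, Z)
    for (it in unique(mt$iteration)) {
      write_manhattan_tsv(mt[mt$iteration == it, ],
                          file.path(config$out_dir,
                                    sprintf("manhattan_%s_iter%d.tsv", tr, it)))
    }
    fits[[tr]] <- fit
    all_windows[[tr]] <- tidy(fit)
  }

  windows <- dplyr::bind_rows(all_windows)
  selected <- stage("select", select_windows(windows, config$selection_threshold_pct))
  regions <- stage("select", overlap_windows(selected, config$span_bp))
  top3 <- stage("select", top_windows_with_flanks(windows, k = 3,
                                                  flank_bp = config$span_bp))
  if (!is.null(inputs$annotation) && nrow(regions)) {
    regions <- stage("annotate", genes_in_region(regions, inputs$annotation))
  }
  write_region_report(regions, file.path(config$out_dir, "regions.tsv"))
  readr::write_tsv(top3, file.path(config$out_dir, "top_windows.tsv"))

  log_lines <- c(log_lines,
                 paste0("traits: ", paste(config$traits, collapse = ", ")),
                 paste0("windows: ", nrow(windows), "; selected: ",
                        nrow(selected), "; regions: ", nrow(regions)))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(fits = fits, qc_report = qc$report, windows = windows,
                 selected = selected, regions = regions, top_windows = top3,
                 config_hash = cfg_hash, out_dir = config$out_dir,
                 truth = inputs$truth))
}
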