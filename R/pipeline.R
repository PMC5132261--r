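#' Pipeline configuration
#'
#' One structured configuration drives the whole workflow. Two modes exist:
#'
#' * counts mode -- `counts` (a wide dSpC matrix `data.frame` or TSV path)
#'   is classified directly;
#' * full mode -- either `simulate = simulation_config(...)` generates the
#'   inputs, or `fasta` + `psm_tables` point at files; the pipeline then
#'   runs database assembly, PSM filtering, quantification and
#'   classification end to end.
#'
#' @param counts Wide count `data.frame` or TSV path (counts mode).
#' @param fasta Target FASTA path (file mode).
#' @param psm_tables Character vector of PSM TSV paths (file mode).
#' @param simulate A [simulation_config()] (simulate mode).
#' @param thresholds A [filter_thresholds()].
#' @param design An [experiment_design()].
#' @param seed Seed recorded in the manifest and used for decoy generation
#'   in file mode.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, fasta = NULL, psm_tables = NULL,
                            simulate = NULL,
                            thresholds = filter_thresholds(),
                            design = experiment_design(), seed = 1L) {
  if (is.null(counts) && is.null(simulate) &&
      (is.null(fasta) || is.null(psm_tables)))
    stop("provide counts, a simulate block, or fasta + psm_tables")
  structure(list(counts = counts, fasta = fasta, psm_tables = psm_tables,
                 simulate = simulate, thresholds = thresholds,
                 design = design, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `counts`, `fasta`, `psm_tables`, `seed`, `thresholds`
#' (`min_delt_cn`, `min_xcorr` as a charge-to-value map,
#' `min_peptide_length`, `require_fully_tryptic`), `design` (`frac_runs` map
#' with `f210`/`f290`/`f350`, `bait_runs`, `control_runs`,
#' `fold_threshold`, `ip_rule`) and `simulate` (fields of
#' [simulation_config()]).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  th_args <- y$thresholds %||% list()
  if (!is.null(th_args$min_xcorr))
    th_args$min_xcorr <- unlist(th_args$min_xcorr)
  th <- do.call(filter_thresholds, th_args)
  de_args <- y$design %||% list()
  if (!is.null(de_args$frac_runs))
    de_args$frac_runs <- unlist(de_args$frac_runs)
  de <- do.call(experiment_design, de_args)
  sim <- if (is.null(y$simulate)) NULL else
    do.call(simulation_config, y$simulate)
  pipeline_config(counts = y$counts, fasta = y$fasta,
                  psm_tables = y$psm_tables, simulate = sim,
                  thresholds = th, design = de, seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the pipeline end to end
#'
#' Executes database assembly, PSM filtering, FDR estimation,
#' quantification and co-enrichment classification (per the config mode),
#' writing every intermediate table plus a machine-readable manifest
#' (`manifest.json`: package version, config hash, seed, per-stage row
#' counts) into `outdir`. Decoy and contaminant entries are excluded from
#' the candidate report (decoys serve FDR bookkeeping; contaminants are
#' reported but flagged). Outputs contain no timestamps, so re-running an
#' unchanged config is byte-identical.
#'
#' @param config A [pipeline_config()] or path to a YAML file.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the main tables (`report`, `counts`,
#'   `quant`, `fdr`, `manifest`).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "cospec",
                   version = as.character(utils::packageVersion("cospec")),
                   seed = config$seed, config_hash = config_hash(config),
                   stages = list())
  quant <- NULL; fdr <- NULL
  if (!is.null(config$counts)) {
    counts <- stage("coenrichment", {
      if (is.character(config$counts))
        utils::read.delim(config$counts, stringsAsFactors = FALSE)
      else config$counts
    })
  } else {
    if (!is.null(config$simulate)) {
      sim <- stage("synthetic_data", simulate_experiment(config$simulate))
      db <- sim$search_db
      psms <- sim$psms
      write_simulation(sim, file.path(outdir, "simulated"))
    } else {
      db <- stage("sequence_db", {
        targets <- read_fasta(config$fasta)
        build_search_db(targets, seed = config$seed)
      })
      psms <- stage("psm_filter",
                    do.call(rbind, lapply(config$psm_tables,
                                          read_psm_table)))
    }
    mapping <- stage("sequence_db",
                     map_peptides(unique(psms$peptide), db,
                                  method = "index"))
    manifest$stages$input_psms <- nrow(psms)
    filtered <- stage("psm_filter",
                      filter_psms(psms, mapping, config$thresholds))
    accepted <- filtered[filtered$accepted, , drop = FALSE]
    accepted <- stage("psm_filter", flag_decoys(accepted, mapping, db))
    fdr <- stage("psm_filter", estimate_fdr(accepted))
    write_psm_table(filtered, file.path(outdir, "psms_filtered.tsv"))
    manifest$stages$accepted_psms <- nrow(accepted)
    manifest$stages$fdr <- fdr$fdr
    proteins <- stage("psm_filter", accept_proteins(accepted, mapping))
    manifest$stages$accepted_proteins <- length(proteins)
    quant <- stage("spectral_quant",
                   quantify_runs(accepted, mapping, proteins, db))
    write_quant_report(quant, file.path(outdir, "quant.tsv"))
    manifest$stages$quantified_proteins <- length(unique(quant$accession))
    counts <- stage("spectral_quant", build_count_matrix(quant))
    counts <- counts[!counts$accession %in%
                       db$accession[db$category == "decoy"], , drop = FALSE]
  }
  report <- stage("coenrichment", make_report(counts, config$design))
  write_candidate_report(report, file.path(outdir, "candidates.tsv"))
  utils::write.table(counts, file.path(outdir, "count_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$candidates <- nrow(report)
  manifest$stages$combined_positive <- sum(report$combined_positive)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(report = report, counts = counts, quant = quant, fdr = fdr,
                 manifest = manifest))
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  # drop non-serializable closures; hash the declarative content only
  writeLines(utils::capture.output(utils::str(config, digits.d = 12)), f)
  unname(tools::md5sum(f))
}
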