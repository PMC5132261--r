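# small in-code fixtures shared across test files

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len, kr = 0.11) {
  probs <- rep((1 - kr) / 18, 20)
  names(probs) <- aa20
  probs[c("K", "R")] <- kr / 2
  paste(sample(aa20, len, replace = TRUE, prob = probs), collapse = "")
}

random_db <- function(n, len_range = c(30, 80), kr = 0.11,
                      prefix = "P") {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  data.frame(accession = sprintf("%s%03d", prefix, seq_len(n)),
             sequence = vapply(lens, random_protein, "", kr = kr),
             length = lens, category = "target", stringsAsFactors = FALSE)
}

# PSM row constructor with passing defaults
psm <- function(peptide, charge = 2L, xcorr = 3, delt_cn = 0.2,
                run_id = "R1", scan_id = NULL) {
  data.frame(run_id = run_id,
             scan_id = scan_id %||% paste0("s", sample.int(1e8, 1)),
             peptide = peptide, charge = charge, xcorr = xcorr,
             delt_cn = delt_cn, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

psm_table <- function(...) {
  out <- do.call(rbind, list(...))
  out$scan_id <- sprintf("s%04d", seq_len(nrow(out)))
  out
}

# mapping table constructor: one row per (peptide, accession, status)
map_row <- function(peptide, accession, status = "fully", start = 1L,
                    end = nchar(peptide)) {
  data.frame(peptide = peptide, accession = accession, start = start,
             end = end, status = status, stringsAsFactors = FALSE)
}

run_recovery <- function(seed, config = simulation_config(seed = seed)) {
  sim <- simulate_experiment(config)
  mapping <- map_peptides(unique(sim$psms$peptide), sim$search_db,
                          method = "index")
  filt <- filter_psms(sim$psms, mapping)
  acc <- filt[filt$accepted, , drop = FALSE]
  acc <- flag_decoys(acc, mapping, sim$search_db)
  prots <- accept_proteins(acc, mapping)
  quant <- quantify_runs(acc, mapping, prots, sim$search_db)
  counts <- build_count_matrix(quant)
  counts <- counts[!grepl("^DECOY_", counts$accession), , drop = FALSE]
  report <- make_report(counts, experiment_design())
  pos <- report$accession[report$combined_positive]
  list(sim = sim, accepted = acc, report = report,
       fdr = estimate_fdr(acc),
       true_fdr = mean(!acc$correct),
       tp = sum(sim$members %in% pos),
       fp = sum(!pos %in% sim$members))
}
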