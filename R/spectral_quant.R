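#' Per-peptide spectral counts and unique spectral counts for one run
#'
#' Counts accepted spectra per peptide within a run, restricted to peptides
#' mapping to at least one accepted protein, and sums the counts of peptides
#' unique to a single accepted protein into that protein's unique spectral
#' count (uSpC). Spectra whose peptides map only to non-accepted proteins
#' are excluded from counting (and hence from the conservation total).
#'
#' @param psms Accepted PSMs for one run (`peptide`, `run_id`, `scan_id`).
#' @param mapping Peptide-to-protein map from [map_peptides()].
#' @param accepted_proteins Character vector from [accept_proteins()].
#' @return A list: `peptide_counts` (named integer, spectra per peptide),
#'   `parents` (list of accepted-parent accessions per counted peptide),
#'   `u_spc` (named numeric over `accepted_proteins`).
#' @export
count_spectra <- function(psms, mapping, accepted_proteins) {
  u_spc <- stats::setNames(numeric(length(accepted_proteins)),
                           accepted_proteins)
  m <- unique(mapping[mapping$accession %in% accepted_proteins,
                      c("peptide", "accession"), drop = FALSE])
  pep <- toupper(psms$peptide)
  counted <- pep[pep %in% m$peptide]
  if (!length(counted))
    return(list(peptide_counts = integer(0), parents = list(), u_spc = u_spc))
  peptide_counts <- table(counted)
  peptide_counts <- stats::setNames(as.integer(peptide_counts),
                                    names(peptide_counts))
  parents <- split(m$accession, m$peptide)[names(peptide_counts)]
  uniq <- lengths(parents) == 1L
  if (any(uniq)) {
    per_prot <- tapply(peptide_counts[uniq],
                       unlist(parents[uniq], use.names = FALSE), sum)
    u_spc[names(per_prot)] <- per_prot
  }
  list(peptide_counts = peptide_counts, parents = parents, u_spc = u_spc)
}

#' Distribute shared spectral counts (dSpC)
#'
#' Apportions each shared peptide's spectra among its parent proteins in
#' proportion to their unique spectral counts:
#' `dSpC_k = uSpC_k + sum_j SpC_j * uSpC_k / sum_{i in parents(j)} uSpC_i`
#' over shared peptides `j`. When every sharer of a peptide has zero unique
#' counts, its spectra are split equally among the sharers, which preserves
#' the conservation of total counts.
#'
#' @param peptide_counts,parents,u_spc Components of a [count_spectra()]
#'   result.
#' @return Named numeric vector of dSpC over the same proteins as `u_spc`;
#'   its sum equals the total number of counted spectra.
#' @export
distribute_counts <- function(peptide_counts, parents, u_spc) {
  d_spc <- u_spc
  shared <- names(parents)[lengths(parents) > 1L]
  for (p in shared) {
    ac <- parents[[p]]
    w <- u_spc[ac]
    w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(ac), length(ac))
    d_spc[ac] <- d_spc[ac] + peptide_counts[[p]] * w
  }
  d_spc
}

#' Distributed normalized spectral abundance factors (dNSAF)
#'
#' `dNSAF_k = (dSpC_k / L_k) / sum_i (dSpC_i / L_i)`: distributed counts are
#' length-normalized and rescaled to sum to one within the run, giving a
#' relative abundance estimate.
#'
#' @param d_spc Named numeric vector of distributed spectral counts.
#' @param lengths Protein lengths `L` (residues), in the same order or named.
#' @return Named numeric vector summing to 1; proteins with zero counts
#'   get 0.
#' @export
compute_dnsaf <- function(d_spc, lengths) {
  if (!is.null(names(lengths)) && !is.null(names(d_spc)))
    lengths <- lengths[names(d_spc)]
  stopifnot(length(lengths) == length(d_spc))
  if (any(lengths <= 0) || anyNA(lengths)) stop("all protein lengths must be > 0")
  if (sum(d_spc) <= 0) stop("empty run: no counted spectra")
  saf <- d_spc / lengths
  saf / sum(saf)
}

#' Quantify one run
#'
#' Runs [count_spectra()], [distribute_counts()] and [compute_dnsaf()] for
#' the accepted PSMs of a single run.
#'
#' @param psms Accepted PSMs (any runs; rows are subset to `run_id`).
#' @param mapping Peptide-to-protein map.
#' @param accepted_proteins Accessions from [accept_proteins()].
#' @param db Protein database (for lengths).
#' @param run_id Run label to quantify.
#' @return `data.frame` with columns `accession`, `run_id`, `u_spc`,
#'   `d_spc`, `dnsaf`, one row per accepted protein (zero rows dropped).
#' @export
quantify_run <- function(psms, mapping, accepted_proteins, db, run_id) {
  rp <- psms[psms$run_id == run_id, , drop = FALSE]
  cs <- count_spectra(rp, mapping, accepted_proteins)
  d_spc <- distribute_counts(cs$peptide_counts, cs$parents, cs$u_spc)
  out <- data.frame(accession = names(d_spc), run_id = run_id,
                    u_spc = unname(cs$u_spc), d_spc = unname(d_spc),
                    dnsaf = 0, stringsAsFactors = FALSE)
  if (sum(d_spc) > 0) {
    lens <- stats::setNames(db$length, db$accession)
    out$dnsaf <- unname(compute_dnsaf(d_spc, lens))
  }
  out[out$d_spc > 0, , drop = FALSE]
}

#' Quantify several runs and assemble a condition count matrix
#'
#' Counting is strictly per run; the cross-condition matrix is assembled by
#' column binding (never by summing runs), since the co-enrichment
#' classifier needs per-fraction values.
#'
#' @param psms Accepted PSMs across runs.
#' @param mapping Peptide-to-protein map.
#' @param accepted_proteins Accessions from [accept_proteins()].
#' @param db Protein database.
#' @param run_ids Runs to quantify (default: all in `psms`).
#' @return Long `data.frame` of per-run [quantify_run()] results.
#' @export
quantify_runs <- function(psms, mapping, accepted_proteins, db,
                          run_ids = unique(psms$run_id)) {
  do.call(rbind, lapply(run_ids, function(r)
    quantify_run(psms, mapping, accepted_proteins, db, r)))
}

#' Wide condition count matrix
#'
#' @param quant Long quantification table from [quantify_runs()].
#' @param value Which quantity to spread: `"d_spc"`, `"u_spc"` or `"dnsaf"`.
#' @param run_ids Column order (default: order of appearance).
#' @return `data.frame` with `accession` plus one numeric column per run;
#'   absent cells are 0.
#' @export
build_count_matrix <- function(quant, value = c("d_spc", "u_spc", "dnsaf"),
                               run_ids = unique(quant$run_id)) {
  value <- match.arg(value)
  acc <- sort(unique(quant$accession))
  out <- data.frame(accession = acc, stringsAsFactors = FALSE)
  for (r in run_ids) {
    sub <- quant[quant$run_id == r, , drop = FALSE]
    out[[r]] <- sub[[value]][match(acc, sub$accession)]
    out[[r]][is.na(out[[r]])] <- 0
  }
  out
}

#' Write a quantification report
#'
#' Tab-delimited `accession run_id u_spc d_spc dnsaf`; `d_spc` is kept as a
#' real here, while Table-style wide exports round it to the nearest integer
#' for display.
#' @param quant Long quantification table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_report <- function(quant, path) {
  utils::write.table(quant, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
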