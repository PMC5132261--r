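#' Acceptance thresholds for peptide-spectrum matches
#'
#' The defaults are the DTASelect-era criteria used throughout this package:
#' DeltCn at least 0.08; minimum XCorr of 1.8 for singly-, 2.0 for doubly-
#' and 3.0 for triply-charged spectra; peptides fully tryptic and at least
#' 7 residues long. All thresholds are inclusive ("at least"/"minimum").
#'
#' @param min_delt_cn Minimum DeltCn (normalized gap to the second-best
#'   match), inclusive.
#' @param min_xcorr Named numeric vector mapping charge state to the minimum
#'   XCorr for that charge.
#' @param min_peptide_length Minimum peptide length in residues.
#' @param require_fully_tryptic If `TRUE`, a PSM is acceptable only when at
#'   least one of its peptide's parent occurrences is fully tryptic (a
#'   peptide can sit differently in different proteins).
#' @param extend_max_charge Policy for charges above the highest configured
#'   one: if `TRUE` (default) they inherit the highest configured threshold,
#'   a conservative extension; if `FALSE`, such charges are an error.
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_delt_cn = 0.08,
                              min_xcorr = c("1" = 1.8, "2" = 2.0, "3" = 3.0),
                              min_peptide_length = 7L,
                              require_fully_tryptic = TRUE,
                              extend_max_charge = TRUE) {
  stopifnot(min_delt_cn >= 0, all(min_xcorr >= 0), min_peptide_length >= 0,
            !is.null(names(min_xcorr)), !anyNA(as.integer(names(min_xcorr))))
  structure(list(min_delt_cn = min_delt_cn, min_xcorr = min_xcorr,
                 min_peptide_length = as.integer(min_peptide_length),
                 require_fully_tryptic = isTRUE(require_fully_tryptic),
                 extend_max_charge = isTRUE(extend_max_charge)),
            class = "filter_thresholds")
}

xcorr_threshold_for <- function(charge, th) {
  configured <- as.integer(names(th$min_xcorr))
  out <- th$min_xcorr[match(charge, configured)]
  high <- is.na(out) & charge > max(configured)
  if (th$extend_max_charge)
    out[high] <- th$min_xcorr[which.max(configured)]
  if (anyNA(out))
    stop("no XCorr threshold configured for charge ",
         paste(unique(charge[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Filter peptide-spectrum matches
#'
#' Applies the spectrum-level acceptance criteria to a PSM table. A PSM is
#' accepted iff its DeltCn and XCorr meet the (inclusive) thresholds for its
#' charge, its peptide is long enough, and -- when required -- at least one
#' parent occurrence of the peptide is fully tryptic. PSMs whose peptide is
#' absent from `mapping` are rejected with reason `"unmapped"`.
#'
#' @param psms `data.frame` with columns `run_id`, `scan_id`, `peptide`,
#'   `charge`, `xcorr`, `delt_cn` (extra columns are carried through).
#' @param mapping Peptide-to-protein map from [map_peptides()].
#' @param thresholds A [filter_thresholds()] object.
#' @return The input with two added columns: logical `accepted` and
#'   character `reason` (`""` for accepted rows; otherwise the first failing
#'   check among `unmapped`, `delt_cn`, `xcorr`, `length`, `tryptic`).
#' @export
filter_psms <- function(psms, mapping, thresholds = filter_thresholds()) {
  need <- c("run_id", "scan_id", "peptide", "charge", "xcorr", "delt_cn")
  miss <- setdiff(need, names(psms))
  if (length(miss)) stop("psms lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(paste(psms$run_id, psms$scan_id)))
    stop("duplicate (run_id, scan_id) in PSM table")
  n <- nrow(psms)
  if (n == 0L) {
    psms$accepted <- logical(); psms$reason <- character()
    return(psms)
  }
  pep <- toupper(psms$peptide)
  mapped <- pep %in% mapping$peptide
  fully_ok <- pep %in% mapping$peptide[mapping$status == "fully"]
  th_x <- xcorr_threshold_for(psms$charge, thresholds)
  reason <- character(n)
  fail <- function(cond, code) reason <<- ifelse(!nzchar(reason) & cond,
                                                 code, reason)
  fail(!mapped, "unmapped")
  fail(psms$delt_cn < thresholds$min_delt_cn, "delt_cn")
  fail(psms$xcorr < th_x, "xcorr")
  fail(nchar(pep) < thresholds$min_peptide_length, "length")
  if (thresholds$require_fully_tryptic) fail(!fully_ok, "tryptic")
  psms$accepted <- !nzchar(reason)
  psms$reason <- reason
  psms
}

#' Protein-level acceptance
#'
#' Pooling accepted PSMs across all runs, a protein is accepted iff it is
#' detected by at least 2 distinct peptide sequences, or by 1 peptide
#' supported by at least 2 independent spectra (distinct `(run_id, scan_id)`
#' pairs).
#'
#' @param accepted `data.frame` of accepted PSMs (rows of a [filter_psms()]
#'   result with `accepted == TRUE`, or any table with `run_id`, `scan_id`,
#'   `peptide`).
#' @param mapping Peptide-to-protein map from [map_peptides()].
#' @return Character vector of accepted accessions (sorted).
#' @export
accept_proteins <- function(accepted, mapping) {
  if (!nrow(accepted)) return(character())
  pep <- toupper(accepted$peptide)
  m <- unique(mapping[mapping$peptide %in% pep,
                      c("peptide", "accession"), drop = FALSE])
  spec <- unique(data.frame(peptide = pep,
                            key = paste(accepted$run_id, accepted$scan_id,
                                        sep = "\r"),
                            stringsAsFactors = FALSE))
  j <- merge(m, spec, by = "peptide")
  if (!nrow(j)) return(character())
  n_pep <- tapply(j$peptide, j$accession, function(x) length(unique(x)))
  n_spec <- tapply(j$key, j$accession, function(x) length(unique(x)))
  sort(names(n_pep)[n_pep >= 2L | n_spec >= 2L])
}

#' Label PSMs as target or decoy matches
#'
#' A PSM is a decoy match iff every parent of its peptide is a decoy entry;
#' a peptide mapping to both target and decoy proteins is labeled target
#' (the standard concatenated-search tie-break). Unmapped peptides get `NA`.
#'
#' @param psms PSM `data.frame`.
#' @param mapping Peptide-to-protein map.
#' @param db Protein database with `accession` and `category` columns.
#' @return `psms` with a logical `is_decoy` column.
#' @export
flag_decoys <- function(psms, mapping, db) {
  cat_by_acc <- db$category[match(mapping$accession, db$accession)]
  any_target <- tapply(cat_by_acc != "decoy", mapping$peptide, any)
  pep <- toupper(psms$peptide)
  hit <- match(pep, names(any_target))
  psms$is_decoy <- as.vector(!any_target[hit])
  psms$is_decoy[is.na(hit)] <- NA
  psms
}

#' Estimate the false discovery rate from decoy matches
#'
#' Classical concatenated-search estimate over accepted PSMs:
#' `FDR = D / max(T, 1)` where `D` and `T` are the numbers of accepted decoy
#' and target PSMs. The symmetric variant `2D / (T + D)` is also reported.
#'
#' @param accepted `data.frame` of accepted PSMs with an `is_decoy` column
#'   (see [flag_decoys()]).
#' @return A list: `fdr` (D/T), `fdr_symmetric` (2D/(T+D)), `n_target`,
#'   `n_decoy`, `per_run` (`data.frame` of the same quantities by run) and
#'   logical `empty` (`TRUE`, with a warning, when no PSMs were supplied).
#' @export
estimate_fdr <- function(accepted) {
  if (!nrow(accepted)) {
    warning("empty accepted PSM set; FDR reported as 0")
    return(list(fdr = 0, fdr_symmetric = 0, n_target = 0L, n_decoy = 0L,
                per_run = data.frame(run_id = character(), fdr = numeric()),
                empty = TRUE))
  }
  if (anyNA(accepted$is_decoy)) stop("is_decoy must be set on every PSM")
  tally <- function(d) {
    nd <- sum(d); nt <- sum(!d)
    c(fdr = nd / max(nt, 1), fdr_symmetric = 2 * nd / (nt + nd),
      n_target = nt, n_decoy = nd)
  }
  tot <- tally(accepted$is_decoy)
  per <- do.call(rbind, lapply(split(accepted$is_decoy, accepted$run_id),
                               tally))
  per_run <- data.frame(run_id = rownames(per), per, row.names = NULL,
                        stringsAsFactors = FALSE)
  list(fdr = unname(tot["fdr"]), fdr_symmetric = unname(tot["fdr_symmetric"]),
       n_target = unname(as.integer(tot["n_target"])),
       n_decoy = unname(as.integer(tot["n_decoy"])),
       per_run = per_run, empty = FALSE)
}

#' Read / write PSM tables
#'
#' Tab-delimited with header `run_id scan_id peptide charge xcorr delt_cn`;
#' the writer also emits `accepted` and `reason` when present.
#'
#' @param path File path.
#' @return `read_psm_table`: a PSM `data.frame`.
#' @export
read_psm_table <- function(path) {
  psms <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("run_id", "scan_id", "peptide", "charge", "xcorr", "delt_cn")
  miss <- setdiff(need, names(psms))
  if (length(miss)) stop("PSM table lacks column(s): ",
                         paste(miss, collapse = ", "))
  psms
}

#' @rdname read_psm_table
#' @param psms PSM `data.frame`.
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
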