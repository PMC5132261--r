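#' Experiment design for the dual-criteria classifier
#'
#' Names which run labels play which role: the three salt-step elution
#' fractions of the anion-exchange column (210, 290 and 350 mM NaCl), the
#' bait immunoprecipitation (IP) replicates and the matched control-IgG
#' replicates.
#'
#' @param frac_runs Named character vector with elements `f210`, `f290`,
#'   `f350` giving the run labels of the three fractions.
#' @param bait_runs Character vector of bait-IP run labels (2 replicates in
#'   the reference design).
#' @param control_runs Character vector of control-IgG run labels.
#' @param fold_threshold Fold-enrichment required of the 290 mM over the
#'   350 mM fraction (default 5).
#' @param ip_rule `"any"` (default): presence in at least one bait replicate
#'   counts as presence; `"all"`: required in every bait replicate.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(frac_runs = c(f210 = "F210", f290 = "F290",
                                            f350 = "F350"),
                              bait_runs = c("BAIT1", "BAIT2"),
                              control_runs = c("CTRL1", "CTRL2"),
                              fold_threshold = 5,
                              ip_rule = c("any", "all")) {
  ip_rule <- match.arg(ip_rule)
  stopifnot(all(c("f210", "f290", "f350") %in% names(frac_runs)),
            fold_threshold > 0)
  all_runs <- c(unname(frac_runs), bait_runs, control_runs)
  if (anyDuplicated(all_runs)) stop("design run labels must be disjoint")
  structure(list(frac_runs = frac_runs[c("f210", "f290", "f350")],
                 bait_runs = bait_runs, control_runs = control_runs,
                 fold_threshold = fold_threshold, ip_rule = ip_rule),
            class = "experiment_design")
}

#' Fractionation-positivity call
#'
#' A protein is fractionation-positive iff it is absent from the 210 mM
#' fraction, present in the 290 mM fraction, and its 290 mM count is at
#' least `fold_threshold` times its 350 mM count. "Absent" means a
#' distributed spectral count of exactly 0 after PSM filtering and protein
#' acceptance. A zero 350 mM count passes the fold criterion whenever the
#' 290 mM count is positive (the convention forced by calling a protein
#' detected only in the 290 mM fraction positive).
#'
#' @param c210,c290,c350 Nonnegative dSpC vectors for the three fractions.
#' @param fold_threshold Fold requirement (default 5).
#' @return `data.frame` with logical `positive` and character `reason`
#'   (`"frac-positive"` or comma-joined failure codes among
#'   `present-in-210`, `absent-in-290`, `fold-below-threshold`).
#' @export
classify_fractionation <- function(c210, c290, c350, fold_threshold = 5) {
  stopifnot(all(c210 >= 0), all(c290 >= 0), all(c350 >= 0))
  pos <- c210 == 0 & c290 > 0 & c290 >= fold_threshold * c350
  reason <- mapply(function(a, b, d, p) {
    if (p) return("frac-positive")
    r <- c(if (a > 0) "present-in-210",
           if (b == 0) "absent-in-290",
           if (b > 0 && b < fold_threshold * d) "fold-below-threshold")
    paste(r, collapse = ",")
  }, c210, c290, c350, pos)
  data.frame(positive = unname(pos), reason = unname(reason),
             stringsAsFactors = FALSE)
}

#' Immunoprecipitation-positivity call
#'
#' A protein is IP-positive iff it is present in the bait IP (in at least
#' one replicate under the default `"any"` rule) and absent from every
#' control-IgG replicate.
#'
#' @param bait Matrix (proteins x replicates) or vector of bait-IP dSpC.
#' @param control Matrix or vector of control-IgG dSpC.
#' @param rule `"any"` or `"all"` bait replicates required.
#' @return `data.frame` with logical `positive` and character `reason`.
#' @export
classify_ip <- function(bait, control, rule = c("any", "all")) {
  rule <- match.arg(rule)
  bait <- as.matrix(bait); control <- as.matrix(control)
  stopifnot(all(bait >= 0), all(control >= 0),
            nrow(bait) == nrow(control))
  in_bait <- if (rule == "any") rowSums(bait > 0) > 0 else
    rowSums(bait > 0) == ncol(bait)
  clean <- rowSums(control > 0) == 0
  pos <- in_bait & clean
  reason <- mapply(function(b, cl, p) {
    if (p) return("ip-positive")
    paste(c(if (!b) "absent-in-bait", if (!cl) "present-in-control"),
          collapse = ",")
  }, in_bait, clean, pos)
  data.frame(positive = unname(pos), reason = unname(reason),
             stringsAsFactors = FALSE)
}

#' Combine the two positivity calls
#'
#' @param frac [classify_fractionation()] result.
#' @param ip [classify_ip()] result (same row order).
#' @param accession Optional accession vector for the output.
#' @return `data.frame` with `accession` (if given), `frac_positive`,
#'   `ip_positive`, `combined_positive` (their conjunction) and the
#'   concatenated `reasons`.
#' @export
combine_calls <- function(frac, ip, accession = NULL) {
  stopifnot(nrow(frac) == nrow(ip))
  out <- data.frame(frac_positive = frac$positive, ip_positive = ip$positive,
                    combined_positive = frac$positive & ip$positive,
                    reasons = paste(frac$reason, ip$reason, sep = ";"),
                    stringsAsFactors = FALSE)
  if (!is.null(accession)) out <- cbind(accession = accession, out,
                                        stringsAsFactors = FALSE)
  out
}

#' Ranked candidate report
#'
#' Applies the dual-criteria classifier to a wide condition count matrix and
#' ranks the calls: combined positives first, then fractionation-only, then
#' IP-only, then the rest, each block sorted by descending 290 mM dSpC with
#' ties broken by accession.
#'
#' @param counts Wide `data.frame`: `accession` plus one dSpC column per
#'   design run label.
#' @param design An [experiment_design()].
#' @return `data.frame` with the count columns, the three positivity flags
#'   and `reasons`, ranked as above.
#' @export
make_report <- function(counts, design) {
  runs <- c(unname(design$frac_runs), design$bait_runs, design$control_runs)
  miss <- setdiff(runs, names(counts))
  if (length(miss)) stop("missing design column: ", paste(miss, collapse = ", "))
  if (!nrow(counts)) {
    out <- cbind(counts[, c("accession", runs), drop = FALSE],
                 frac_positive = logical(), ip_positive = logical(),
                 combined_positive = logical(), reasons = character())
    return(out)
  }
  frac <- classify_fractionation(counts[[design$frac_runs[["f210"]]]],
                                 counts[[design$frac_runs[["f290"]]]],
                                 counts[[design$frac_runs[["f350"]]]],
                                 design$fold_threshold)
  ip <- classify_ip(as.matrix(counts[, design$bait_runs, drop = FALSE]),
                    as.matrix(counts[, design$control_runs, drop = FALSE]),
                    design$ip_rule)
  calls <- combine_calls(frac, ip, accession = counts$accession)
  out <- cbind(counts[, c("accession", runs), drop = FALSE],
               calls[, c("frac_positive", "ip_positive", "combined_positive",
                         "reasons")])
  group <- with(out, ifelse(combined_positive, 0L,
                     ifelse(frac_positive, 1L,
                     ifelse(ip_positive, 2L, 3L))))
  f290 <- out[[design$frac_runs[["f290"]]]]
  out <- out[order(group, -f290, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a candidate report as tab-delimited text
#'
#' @param report [make_report()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Published distributed spectral counts of the reference co-enrichment table
#'
#' The packaged fixture reproduces, cell for cell, the distributed spectral
#' counts (dSpC) of the printed table of proteins co-enriched with Piccolo:
#' ten active-zone-related proteins across the three Q-column NaCl fractions
#' (210, 290, 350 mM), two Piccolo-antibody IP replicates and two
#' control-IgG replicates. Blank cells in the printed table are 0.
#'
#' @return Wide `data.frame` with columns `accession`, `F210`, `F290`,
#'   `F350`, `BAIT1`, `BAIT2`, `CTRL1`, `CTRL2`.
#' @export
table1_counts <- function() {
  path <- system.file("extdata", "table1_dspc.tsv", package = "cospec",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Design matching the packaged reference table
#' @return An [experiment_design()] whose run labels are the columns of
#'   [table1_counts()].
#' @export
table1_design <- function() {
  experiment_design(frac_runs = c(f210 = "F210", f290 = "F290",
                                  f350 = "F350"),
                    bait_runs = c("BAIT1", "BAIT2"),
                    control_runs = c("CTRL1", "CTRL2"))
}
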