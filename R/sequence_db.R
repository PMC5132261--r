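AA_20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded generators do not disturb the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Read a protein FASTA file
#'
#' Parses a (wrapped or unwrapped) amino-acid FASTA file into a protein
#' database table. Sequences are upper-cased and validated against the
#' 20-letter amino-acid alphabet; accessions are the first whitespace-
#' delimited token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @param category Category assigned to every record: one of `"target"`,
#'   `"decoy"`, `"contaminant"`.
#' @return A `data.frame` with columns `accession`, `sequence`, `length`
#'   (residue count) and `category`, one row per entry in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo", "MKAR", ">P2", "PEPTIDEK"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, category = c("target", "decoy", "contaminant")) {
  category <- match.arg(category)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  # validate structure with line numbers before handing off to Biostrings
  is_header <- startsWith(trimws(lines), ">")
  body <- which(keep & !is_header)
  if (length(body) && (!any(is_header) || body[1] < which(is_header)[1]))
    stop("malformed FASTA: sequence before first header at line ", body[1])
  bad <- body[grepl(sprintf("[^%s]", paste(AA_20, collapse = "")),
                    toupper(trimws(lines[body])))]
  if (length(bad))
    stop("illegal residue character in FASTA at line ", bad[1])
  empty_header <- which(is_header & !nzchar(sub("^>\\s*", "", trimws(lines))))
  if (length(empty_header))
    stop("malformed FASTA: empty header at line ", empty_header[1])
  if (!any(keep)) {
    return(data.frame(accession = character(), sequence = character(),
                      length = integer(), category = character(),
                      stringsAsFactors = FALSE))
  }
  aset <- Biostrings::readAAStringSet(path)
  acc <- vapply(strsplit(names(aset), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(acc))
    stop("duplicated accession in FASTA: ", acc[duplicated(acc)][1])
  seqs <- toupper(as.character(aset))
  if (any(!nzchar(seqs))) stop("empty sequence for accession ",
                               acc[!nzchar(seqs)][1])
  data.frame(accession = unname(acc), sequence = unname(seqs),
             length = unname(nchar(seqs)), category = category,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a protein database to FASTA
#'
#' @param db Protein database `data.frame` (see [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(db))) {
    writeLines(paste0(">", db$accession[i]), con)
    s <- db$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Build a randomized decoy database
#'
#' Creates exactly one decoy entry per target entry by uniformly permuting
#' the residues of the source sequence, so every decoy retains its source's
#' length and amino-acid composition -- the properties a target-decoy search
#' relies on for false-discovery-rate estimation.
#'
#' @param targets Protein database `data.frame` (targets and/or contaminants).
#' @param seed Integer seed; the decoy set is deterministic given the seed.
#' @param prefix Accession prefix marking decoy entries.
#' @return A `data.frame` of decoy records (`category = "decoy"`), one per
#'   input row, in input order.
#' @export
make_decoy_db <- function(targets, seed, prefix = "DECOY_") {
  stopifnot(nrow(targets) > 0)
  with_seed(seed, {
    shuffled <- vapply(targets$sequence, function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, "", USE.NAMES = FALSE)
    data.frame(accession = paste0(prefix, targets$accession),
               sequence = shuffled, length = nchar(shuffled),
               category = "decoy", stringsAsFactors = FALSE)
  })
}

#' Assemble a concatenated target-decoy search database
#'
#' @param targets Target protein `data.frame`.
#' @param contaminants Optional contaminant `data.frame` (category
#'   `"contaminant"`); contaminants participate in search and quantification
#'   but are flagged in reports.
#' @param seed Seed forwarded to [make_decoy_db()]; decoys are generated for
#'   targets and contaminants alike.
#' @param prefix Decoy accession prefix.
#' @return Combined `data.frame`: targets, contaminants, then decoys.
#' @export
build_search_db <- function(targets, contaminants = NULL, seed = 1L,
                            prefix = "DECOY_") {
  fwd <- rbind(targets, contaminants)
  if (anyDuplicated(fwd$accession))
    stop("duplicated accession across targets/contaminants")
  rbind(fwd, make_decoy_db(fwd, seed = seed, prefix = prefix))
}

cleavage_points <- function(sequence) {
  # positions i such that a trypsin-like cut falls between i and i+1:
  # after K or R, never before P
  hits <- gregexpr("[KR](?!P)", sequence, perl = TRUE)[[1]]
  hits <- hits[hits > 0]
  hits[hits < nchar(sequence)]
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P (Lys-C followed by
#' trypsin is modeled as this single trypsin-like rule, as both enzymes cut
#' after lysine). The protein's own termini count as valid tryptic termini.
#' No length filter is applied here; length-based acceptance is the PSM
#' filter's job.
#'
#' @param sequence Amino-acid string (one protein).
#' @param max_missed_cleavages Maximum number of internal (missed) cleavage
#'   sites allowed within a peptide.
#' @return `data.frame` with columns `peptide`, `start`, `end` (1-based,
#'   inclusive) and `missed` (internal cleavage sites spanned).
#' @examples
#' digest("MKAR")                 # MK, AR
#' digest("AKPR")                 # KP is not cleaved
#' @export
digest <- function(sequence, max_missed_cleavages = 0L) {
  stopifnot(max_missed_cleavages >= 0)
  sequence <- toupper(sequence)
  bounds <- c(0L, cleavage_points(sequence), nchar(sequence))
  n <- length(bounds) - 1L
  reps <- pmin(n, seq_len(n) + max_missed_cleavages) - seq_len(n) + 1L
  si <- rep.int(seq_len(n), reps)
  ei <- si + sequence(reps) - 1L
  start <- bounds[si] + 1L
  end <- bounds[ei + 1L]
  data.frame(peptide = substring(sequence, start, end),
             start = start, end = end, missed = ei - si,
             stringsAsFactors = FALSE)
}

#' Tryptic status of peptide occurrences
#'
#' For occurrences `[start, end]` within `sequence`, classifies each as
#' `"fully"`, `"half"` or `"non"` tryptic. A terminus is tryptic if it is a
#' protein terminus or sits at a valid cleavage point (after K/R, not
#' before P).
#' @noRd
tryptic_status <- function(sequence, start, end) {
  L <- nchar(sequence)
  prev <- substring(sequence, start - 1L, start - 1L)
  first <- substring(sequence, start, start)
  nterm_ok <- start == 1L | (prev %in% c("K", "R") & first != "P")
  last <- substring(sequence, end, end)
  nxt <- substring(sequence, end + 1L, end + 1L)
  cterm_ok <- end == L | (last %in% c("K", "R") & nxt != "P")
  c("non", "half", "fully")[nterm_ok + cterm_ok + 1L]
}

#' Map peptides onto a protein database
#'
#' Locates every occurrence of each peptide in the database and classifies
#' its tryptic status from the flanking residues. Two methods are available:
#'
#' * `"scan"` -- exact substring search of every peptide against every
#'   protein (the reference semantics: a parent is any protein containing
#'   the peptide, tryptic or not).
#' * `"index"` -- hash lookup against an in-silico digest of the database
#'   (all fully-tryptic occurrences with up to `index_max_missed` missed
#'   cleavages); peptides with no tryptic occurrence fall back to the
#'   substring scan. Much faster on large instances; only non-tryptic
#'   *additional* occurrences of tryptically-matched peptides are missed,
#'   which for realistic databases is a vanishing set.
#'
#' `"auto"` picks `"scan"` for small problems and `"index"` otherwise.
#'
#' @param peptides Character vector of peptide sequences.
#' @param db Protein database `data.frame`.
#' @param method One of `"auto"`, `"scan"`, `"index"`.
#' @param index_max_missed Missed-cleavage cap for the digest index.
#' @return `data.frame` with columns `peptide`, `accession`, `start`, `end`,
#'   `status` (one row per occurrence). Peptides matching nothing contribute
#'   no rows; they are listed in the `"unmapped"` attribute so the caller can
#'   decide their fate.
#' @export
map_peptides <- function(peptides, db, method = c("auto", "scan", "index"),
                         index_max_missed = 2L) {
  method <- match.arg(method)
  peptides <- unique(toupper(peptides))
  if (method == "auto") {
    method <- if (length(peptides) * sum(nchar(db$sequence)) <= 5e7)
      "scan" else "index"
  }
  empty <- data.frame(peptide = character(), accession = character(),
                      start = integer(), end = integer(),
                      status = character(), stringsAsFactors = FALSE)
  if (!length(peptides) || !nrow(db)) {
    attr(empty, "unmapped") <- peptides
    return(empty)
  }
  if (method == "index") {
    idx <- digest_index(db, index_max_missed)
    hit <- idx[idx$peptide %in% peptides, , drop = FALSE]
    rest <- setdiff(peptides, hit$peptide)
    out <- hit
    if (length(rest)) out <- rbind(hit, scan_peptides(rest, db))
  } else {
    out <- scan_peptides(peptides, db)
  }
  out <- out[order(match(out$peptide, peptides), out$accession, out$start), ]
  rownames(out) <- NULL
  attr(out, "unmapped") <- setdiff(peptides, out$peptide)
  out
}

# exhaustive substring search (Biostrings) with per-occurrence status
scan_peptides <- function(peptides, db) {
  subjects <- Biostrings::AAStringSet(db$sequence)
  rows <- vector("list", length(peptides))
  for (k in seq_along(peptides)) {
    p <- peptides[k]
    hits <- which(Biostrings::vcountPattern(p, subjects) > 0)
    if (!length(hits)) next
    occ <- lapply(hits, function(i) {
      m <- Biostrings::matchPattern(p, subjects[[i]])
      data.frame(peptide = p, accession = db$accession[i],
                 start = Biostrings::start(m), end = Biostrings::end(m),
                 stringsAsFactors = FALSE)
    })
    rows[[k]] <- do.call(rbind, occ)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(peptide = character(), accession = character(),
                      start = integer(), end = integer(),
                      status = character(), stringsAsFactors = FALSE))
  seqs <- db$sequence[match(out$accession, db$accession)]
  out$status <- tryptic_status(seqs, out$start, out$end)
  out
}

# long table of all tryptic peptide occurrences in the database
digest_index <- function(db, max_missed = 2L) {
  per <- lapply(seq_len(nrow(db)), function(i)
    digest(db$sequence[i], max_missed))
  nrows <- vapply(per, nrow, 0L)
  data.frame(peptide = unlist(lapply(per, `[[`, "peptide"), use.names = FALSE),
             accession = rep.int(db$accession, nrows),
             start = unlist(lapply(per, `[[`, "start"), use.names = FALSE),
             end = unlist(lapply(per, `[[`, "end"), use.names = FALSE),
             status = "fully", stringsAsFactors = FALSE)
}

#' Write a peptide-to-protein map as tab-delimited text
#'
#' Columns `peptide`, `accession`, `start`, `end`, `status` with 1-based
#' inclusive coordinates.
#' @param mapping Result of [map_peptides()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_map <- function(mapping, path) {
  utils::write.table(mapping, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
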