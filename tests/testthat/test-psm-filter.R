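tiny_map <- rbind(
  map_row("PEPTIDEK", "A"),
  map_row("ELVISLIVESK", "A"),
  map_row("SHORTK", "B"),
  map_row("NONTRYPTIC", "B", status = "non"),
  map_row("HALFWAYK", "B", status = "half")
)

test_that("spectrum thresholds are inclusive and rejections carry codes", {
  at_boundary <- psm("PEPTIDEK", charge = 2, xcorr = 2.0, delt_cn = 0.08)
  f <- filter_psms(at_boundary, tiny_map)
  expect_true(f$accepted)

  cases <- psm_table(
    psm("PEPTIDEK", charge = 2, xcorr = 1.999),          # just below
    psm("PEPTIDEK", delt_cn = 0.0799),
    psm("SHORTK"),                                       # 6 residues
    psm("NONTRYPTIC", charge = 3, xcorr = 3.5),
    psm("HALFWAYK"),
    psm("UNKNOWNPEPK")                                   # not in mapping
  )
  f <- filter_psms(cases, tiny_map)
  expect_false(any(f$accepted))
  expect_equal(f$reason, c("xcorr", "delt_cn", "length", "tryptic",
                           "tryptic", "unmapped"))

  # per-charge boundaries are the published 1.8 / 2.0 / 3.0
  per_charge <- psm_table(
    psm("PEPTIDEK", charge = 1, xcorr = 1.8),
    psm("PEPTIDEK", charge = 1, xcorr = 1.79),
    psm("PEPTIDEK", charge = 3, xcorr = 3.0),
    psm("PEPTIDEK", charge = 3, xcorr = 2.99)
  )
  expect_equal(filter_psms(per_charge, tiny_map)$accepted,
               c(TRUE, FALSE, TRUE, FALSE))
})

test_that("charges above the configured set inherit the top threshold", {
  high <- psm("PEPTIDEK", charge = 5, xcorr = 3.1)
  expect_true(filter_psms(high, tiny_map)$accepted)
  expect_false(filter_psms(psm("PEPTIDEK", charge = 5, xcorr = 2.9),
                           tiny_map)$accepted)
  th <- filter_thresholds(extend_max_charge = FALSE)
  expect_error(filter_psms(high, tiny_map, th), "charge 5")
})

test_that("filtering equals an independently coded predicate row by row", {
  set.seed(41)
  n <- 1000
  peps <- sample(tiny_map$peptide, n, replace = TRUE)
  psms <- data.frame(run_id = sample(c("R1", "R2"), n, TRUE),
                     scan_id = sprintf("s%04d", seq_len(n)),
                     peptide = peps,
                     charge = sample(1:4, n, TRUE),
                     xcorr = round(runif(n, 0, 5), 3),
                     delt_cn = round(runif(n, 0, 0.3), 3),
                     stringsAsFactors = FALSE)
  got <- filter_psms(psms, tiny_map)$accepted

  # oracle: direct re-evaluation of the four published conditions
  fully <- unique(tiny_map$peptide[tiny_map$status == "fully"])
  xmin <- c(1.8, 2.0, 3.0, 3.0)
  want <- logical(n)
  for (i in seq_len(n)) {
    want[i] <- psms$peptide[i] %in% tiny_map$peptide &&
      psms$delt_cn[i] >= 0.08 &&
      psms$xcorr[i] >= xmin[psms$charge[i]] &&
      nchar(psms$peptide[i]) >= 7 &&
      psms$peptide[i] %in% fully
  }
  expect_equal(got, want)
})

test_that("raising any threshold never enlarges the accepted set", {
  set.seed(42)
  n <- 400
  psms <- data.frame(run_id = "R1", scan_id = sprintf("s%04d", 1:n),
                     peptide = sample(tiny_map$peptide, n, TRUE),
                     charge = sample(1:3, n, TRUE),
                     xcorr = runif(n, 0, 5), delt_cn = runif(n, 0, 0.3),
                     stringsAsFactors = FALSE)
  base <- filter_psms(psms, tiny_map)
  key <- function(f) f$scan_id[f$accepted]
  for (rep in 1:10) {
    th <- filter_thresholds(
      min_delt_cn = 0.08 + runif(1, 0, 0.1),
      min_xcorr = c("1" = 1.8, "2" = 2.0, "3" = 3.0) + runif(3, 0, 1),
      min_peptide_length = sample(7:12, 1))
    expect_true(all(key(filter_psms(psms, tiny_map, th)) %in% key(base)))
  }
  # idempotence: refiltering the accepted set changes nothing
  acc <- base[base$accepted, setdiff(names(base), c("accepted", "reason"))]
  again <- filter_psms(acc, tiny_map)
  expect_true(all(again$accepted))
})

test_that("protein acceptance needs 2 peptides or 1 peptide with 2 spectra", {
  mapping <- rbind(map_row("AAAAAAK", "P1"), map_row("CCCCCCK", "P1"),
                   map_row("DDDDDDK", "P2"), map_row("EEEEEEK", "P3"))
  two_peps <- psm_table(psm("AAAAAAK"), psm("CCCCCCK"))
  expect_equal(accept_proteins(two_peps, mapping), "P1")

  one_pep_two_spec <- psm_table(psm("DDDDDDK", run_id = "R1"),
                                psm("DDDDDDK", run_id = "R2"))
  expect_equal(accept_proteins(one_pep_two_spec, mapping), "P2")

  singleton <- psm_table(psm("EEEEEEK"))
  expect_equal(accept_proteins(singleton, mapping), character())
})

test_that("acceptance equals a group-by count when peptides are unique", {
  set.seed(43)
  for (rep in 1:5) {
    n_prot <- sample(10:50, 1)
    prot <- sprintf("Q%02d", seq_len(n_prot))
    peps <- sprintf("PEP%03dK", 1:120)
    owner <- sample(prot, length(peps), replace = TRUE)
    mapping <- do.call(rbind, Map(map_row, peps, owner))
    n <- 150
    psms <- data.frame(run_id = sample(c("R1", "R2"), n, TRUE),
                       scan_id = sprintf("s%04d", 1:n),
                       peptide = sample(peps, n, TRUE),
                       charge = 2L, xcorr = 3, delt_cn = 0.2,
                       stringsAsFactors = FALSE)
    got <- accept_proteins(psms, mapping)
    # brute-force oracle
    want <- character()
    for (p in prot) {
      mine <- psms[psms$peptide %in% peps[owner == p], ]
      if (length(unique(mine$peptide)) >= 2 || nrow(mine) >= 2)
        want <- c(want, p)
    }
    expect_setequal(got, want)
  }
})

test_that("decoy labelling uses the target tie-break and FDR is D over T", {
  db <- data.frame(accession = c("A", "DECOY_A", "DECOY_B"),
                   sequence = c("X", "X", "X"), length = 1L,
                   category = c("target", "decoy", "decoy"),
                   stringsAsFactors = FALSE)
  mapping <- rbind(map_row("BOTHPEPK", "A"), map_row("BOTHPEPK", "DECOY_A"),
                   map_row("DECOYPEPK", "DECOY_B"))
  psms <- psm_table(psm("BOTHPEPK"), psm("DECOYPEPK"), psm("NOWHEREK"))
  lab <- flag_decoys(psms, mapping, db)
  expect_equal(lab$is_decoy, c(FALSE, TRUE, NA))

  acc <- data.frame(run_id = "R1", scan_id = sprintf("s%03d", 1:100),
                    is_decoy = rep(c(FALSE, TRUE), c(95, 5)))
  fdr <- estimate_fdr(acc)
  expect_equal(fdr$fdr, 5 / 95)
  expect_equal(fdr$fdr_symmetric, 10 / 100)
  expect_equal(fdr$n_decoy, 5L)

  none <- acc[!acc$is_decoy, ]
  expect_equal(estimate_fdr(none)$fdr, 0)
  expect_warning(empty <- estimate_fdr(acc[0, ]), "empty")
  expect_true(empty$empty)
  expect_equal(empty$fdr, 0)
})
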