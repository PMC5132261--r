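test_that("unique counts tally spectra of protein-unique peptides", {
  mapping <- rbind(map_row("AAAAAAK", "A"), map_row("SHAREDK", "A"),
                   map_row("SHAREDK", "B"), map_row("BBBBBBK", "B"))
  psms <- psm_table(psm("AAAAAAK"), psm("AAAAAAK"), psm("AAAAAAK"),
                    psm("SHAREDK"), psm("BBBBBBK"))
  cs <- count_spectra(psms, mapping, c("A", "B"))
  expect_equal(cs$u_spc, c(A = 3, B = 1))
  expect_equal(cs$peptide_counts[["SHAREDK"]], 1L)
  # a peptide mapping only to non-accepted proteins is not counted
  cs2 <- count_spectra(psms, mapping, "A")
  expect_equal(sum(cs2$peptide_counts), 4L)  # BBBBBBK dropped, SHAREDK kept
})

test_that("shared spectra are apportioned by unique evidence", {
  mapping <- rbind(map_row("UNIQA1K", "A"), map_row("UNIQB1K", "B"),
                   map_row("SHAREDK", "A"), map_row("SHAREDK", "B"))
  psms <- psm_table(psm("UNIQA1K"), psm("UNIQA1K"), psm("UNIQA1K"),
                    psm("UNIQB1K"),
                    psm("SHAREDK"), psm("SHAREDK"), psm("SHAREDK"),
                    psm("SHAREDK"))
  cs <- count_spectra(psms, mapping, c("A", "B"))
  d <- distribute_counts(cs$peptide_counts, cs$parents, cs$u_spc)
  expect_equal(d, c(A = 3 + 4 * 3 / 4, B = 1 + 4 * 1 / 4))

  # no sharing: dSpC equals uSpC
  solo <- count_spectra(psm_table(psm("UNIQA1K"), psm("UNIQB1K")),
                        mapping, c("A", "B"))
  expect_equal(distribute_counts(solo$peptide_counts, solo$parents,
                                 solo$u_spc), solo$u_spc)

  # all sharers at zero unique counts: equal split
  only_shared <- count_spectra(psm_table(psm("SHAREDK"), psm("SHAREDK")),
                               mapping, c("A", "B"))
  expect_equal(distribute_counts(only_shared$peptide_counts,
                                 only_shared$parents, only_shared$u_spc),
               c(A = 1, B = 1))
})

test_that("distribution conserves totals and matches a brute-force oracle", {
  set.seed(51)
  for (rep in 1:100) {
    n_prot <- sample(3:12, 1)
    prot <- sprintf("P%02d", seq_len(n_prot))
    n_pep <- sample(5:25, 1)
    parents <- lapply(seq_len(n_pep), function(i)
      sample(prot, sample(1:3, 1)))
    names(parents) <- sprintf("PEP%03dK", seq_len(n_pep))
    counts <- stats::setNames(sample(0:6, n_pep, TRUE), names(parents))
    counts <- counts[counts > 0]
    parents <- parents[names(counts)]
    u <- stats::setNames(numeric(n_prot), prot)
    uniq <- lengths(parents) == 1
    for (p in names(parents)[uniq])
      u[parents[[p]]] <- u[parents[[p]]] + counts[[p]]

    d <- distribute_counts(counts, parents, u)
    expect_equal(sum(d), sum(counts), tolerance = 1e-9)
    expect_true(all(d >= u - 1e-12))

    # oracle: per-spectrum allocation, written independently
    want <- u
    for (p in names(parents)) {
      sh <- parents[[p]]
      if (length(sh) < 2) next
      w <- if (sum(u[sh]) > 0) u[sh] / sum(u[sh])
           else rep(1 / length(sh), length(sh))
      for (s in seq_len(counts[[p]])) want[sh] <- want[sh] + w
    }
    expect_equal(d, want, tolerance = 1e-9)

    # scale equivariance: doubling counts doubles dSpC, preserves dNSAF
    d2 <- distribute_counts(counts * 2, parents, u * 2)
    expect_equal(d2, d * 2, tolerance = 1e-9)
    lens <- stats::setNames(sample(100:500, n_prot), prot)
    if (sum(d) > 0) {
      expect_equal(compute_dnsaf(d2, lens), compute_dnsaf(d, lens),
                   tolerance = 1e-9)
    }
  }
})

test_that("dNSAF normalizes to one and reduces to NSAF without sharing", {
  expect_equal(compute_dnsaf(c(A = 5), c(A = 100)), c(A = 1))
  expect_equal(compute_dnsaf(c(A = 4, B = 4), c(A = 200, B = 200)),
               c(A = 0.5, B = 0.5))
  set.seed(52)
  for (rep in 1:20) {
    d <- stats::setNames(c(rpois(8, 20), 0), sprintf("P%d", 1:9))
    lens <- stats::setNames(sample(100:900, 9), names(d))
    nsaf <- compute_dnsaf(d, lens)
    expect_equal(sum(nsaf), 1, tolerance = 1e-9)
    expect_equal(unname(nsaf), unname((d / lens) / sum(d / lens)))
    expect_equal(nsaf[["P9"]], 0)
  }
  expect_error(compute_dnsaf(c(A = 0), c(A = 10)), "empty run")
  expect_error(compute_dnsaf(c(A = 1), c(A = 0)), "lengths")
})

test_that("per-run quantification and the wide matrix agree with counts", {
  db <- data.frame(accession = c("A", "B"),
                   sequence = c(strrep("X", 100), strrep("X", 200)),
                   length = c(100L, 200L), category = "target",
                   stringsAsFactors = FALSE)
  mapping <- rbind(map_row("AAAAAAK", "A"), map_row("BBBBBBK", "B"))
  psms <- rbind(
    data.frame(run_id = "R1", scan_id = c("s1", "s2", "s3"),
               peptide = c("AAAAAAK", "AAAAAAK", "BBBBBBK"),
               charge = 2L, xcorr = 3, delt_cn = 0.2),
    data.frame(run_id = "R2", scan_id = "s1", peptide = "BBBBBBK",
               charge = 2L, xcorr = 3, delt_cn = 0.2))
  q <- quantify_runs(psms, mapping, c("A", "B"), db)
  m <- build_count_matrix(q)
  expect_equal(m$R1[m$accession == "A"], 2)
  expect_equal(m$R2[m$accession == "A"], 0)   # absent cell filled with 0
  expect_equal(m$R2[m$accession == "B"], 1)
  # dNSAF within run R1: (2/100) vs (1/200)
  qa <- q[q$run_id == "R1", ]
  expect_equal(qa$dnsaf[qa$accession == "A"], (2 / 100) / (2 / 100 + 1 / 200))
})
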