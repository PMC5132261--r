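mask_from <- function(idx, nr = 12, nc = 12) {
  m <- matrix(FALSE, nr, nc)
  m[idx] <- TRUE
  m
}

test_that("thresholding handles flat, two-level and degenerate images", {
  zeros <- matrix(0, 8, 8)
  expect_false(any(threshold_channel(zeros, "fixed", value = 1)))
  two <- matrix(0, 8, 8); two[3:4, 3:4] <- 100
  expect_equal(threshold_channel(two, "fixed", value = 100), two == 100)
  expect_equal(threshold_channel(two, "otsu"), two == 100)
  expect_equal(threshold_channel(two, "percentile", value = 90), two == 100)
  expect_error(threshold_channel(matrix(5, 8, 8), "otsu"),
               "degenerate histogram")
})

test_that("thresholded spot area matches the generator's punctum table", {
  sim <- simulate_image_set(n_images = 1, n_puncta = 40, seed = 12)
  img <- sim$images[[1]]$marker
  pars <- sim$params
  mask <- threshold_channel(img, "fixed",
                            value = pars$background + pars$spot_amplitude / 2)
  truth_area <- sum(sim$truth$area)   # analytic half-maximum disc areas
  expect_lt(abs(sum(mask) - truth_area) / truth_area, 0.2)
})

test_that("components are 8-connected and small ones are dropped", {
  # two diagonal pixels touch corner-to-corner: one component
  diag2 <- mask_from(c(1 + 0 * 12 + 0, 2 + 1 * 12))  # (1,1) and (2,2)
  ps <- find_puncta(diag2, min_area = 1)
  expect_equal(nrow(ps$puncta), 1L)
  expect_equal(ps$puncta$area, 2L)
  # min_area filter
  m <- mask_from(integer(), 12, 12)
  m[2:4, 2:4] <- TRUE       # area 9
  m[10, 10] <- TRUE         # area 1, dropped at min_area 4
  ps <- find_puncta(m, min_area = 4)
  expect_equal(nrow(ps$puncta), 1L)
  expect_equal(ps$puncta$area, 9L)
  expect_equal(ps$puncta$row, 3)
  expect_equal(ps$puncta$col, 3)
})

test_that("reference partition equals a per-pixel intersection oracle", {
  m <- matrix(FALSE, 12, 12)
  m[2:3, 2:3] <- TRUE    # punctum 1
  m[8:9, 8:10] <- TRUE   # punctum 2
  ref <- matrix(FALSE, 12, 12)
  ref[1:5, 1:5] <- TRUE  # covers punctum 1 fully, misses punctum 2
  ps <- apply_reference_mask(find_puncta(m, min_area = 1), ref)
  expect_equal(ps$puncta$ref_positive, c(TRUE, FALSE))

  expect_error(apply_reference_mask(find_puncta(m, 1),
                                    matrix(FALSE, 5, 5)),
               "dimension mismatch")

  set.seed(81)
  for (rep in 1:10) {
    mask <- matrix(runif(400) < 0.2, 20, 20)
    ref <- matrix(runif(400) < 0.3, 20, 20)
    ps <- apply_reference_mask(find_puncta(mask, min_area = 1), ref)
    lab <- ps$labels
    for (id in ps$puncta$id) {
      want <- sum(ref & lab == id) >= 1
      expect_equal(ps$puncta$ref_positive[ps$puncta$id == id], want)
    }
  }
})

test_that("third-channel scoring is exact on constructed masks", {
  m <- matrix(FALSE, 12, 12)
  m[2:3, 2:3] <- TRUE; m[8:9, 8:9] <- TRUE
  ref <- matrix(FALSE, 12, 12); ref[1:5, 1:5] <- TRUE
  ps <- apply_reference_mask(find_puncta(m, 1), ref)
  # third identical to marker support: both fractions are 1
  s <- score_third_channel(ps, m)
  expect_equal(c(s$frac_refpos, s$frac_refneg), c(1, 1))
  # empty third mask: both fractions are 0
  s0 <- score_third_channel(ps, matrix(FALSE, 12, 12))
  expect_equal(c(s0$frac_refpos, s0$frac_refneg), c(0, 0))
  # empty group reported as missing
  full_ref <- matrix(TRUE, 12, 12)
  ps2 <- apply_reference_mask(find_puncta(m, 1), full_ref)
  s2 <- score_third_channel(ps2, m)
  expect_equal(s2$n_refneg, 0L)
  expect_true(is.na(s2$frac_refneg))
  expect_equal(s2$frac_refpos, 1)
})

test_that("shrinking the third mask never raises a fraction", {
  set.seed(82)
  mask <- matrix(runif(900) < 0.15, 30, 30)
  ref <- matrix(runif(900) < 0.4, 30, 30)
  ps <- apply_reference_mask(find_puncta(mask, min_area = 1), ref)
  third <- matrix(runif(900) < 0.5, 30, 30)
  s_full <- score_third_channel(ps, third)
  for (rep in 1:5) {
    shrunk <- third & (matrix(runif(900), 30, 30) < 0.6)
    s <- score_third_channel(ps, shrunk)
    expect_lte(s$frac_refpos, s_full$frac_refpos)
    expect_lte(s$frac_refneg, s_full$frac_refneg)
    third <- shrunk
  }
})

test_that("planted colocalization fractions are recovered from images", {
  sim <- simulate_image_set(n_images = 6, n_puncta = 80, p_refpos = 0.75,
                            p_refneg = 0.40, seed = 13)
  res <- score_image_set(sim$images)
  tr <- sim$truth
  planted_pos <- mean(tr$in_third[tr$in_reference])
  planted_neg <- mean(tr$in_third[!tr$in_reference])
  expect_lt(abs(res$pooled$frac_refpos - planted_pos), 0.05)
  expect_lt(abs(res$pooled$frac_refneg - planted_neg), 0.05)
  expect_lt(res$pooled$p_value, 0.0005)
  # scoring is invariant to image order
  rev_res <- score_image_set(rev(sim$images))
  expect_equal(sort(rev_res$per_image$frac_refpos),
               sort(res$per_image$frac_refpos))
  expect_equal(rev_res$pooled$frac_refpos, res$pooled$frac_refpos)
})

test_that("TIFF stacks round-trip at 16-bit and max-project correctly", {
  img1 <- matrix(as.integer(round(seq(0, 65535, length.out = 64))), 8, 8)
  img2 <- matrix(32768L, 8, 8)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(list(img1, img2), path)
  back <- read_image_stack(path)
  expect_equal(back[[1]], img1)
  expect_equal(back[[2]], img2)
  expect_equal(max_project(back), pmax(img1, img2))
})
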