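#' Threshold a single-channel image
#'
#' @param image Numeric matrix of nonnegative intensities.
#' @param method `"percentile"` (mask = pixels above the given intensity
#'   percentile), `"otsu"` (between-class-variance threshold via
#'   `EBImage::otsu`) or `"fixed"` (mask = pixels at or above `value`).
#' @param value Percentile in `(0, 100)` for `"percentile"`; intensity for
#'   `"fixed"`; ignored for `"otsu"`.
#' @param max_intensity Intensity range upper bound used by `"otsu"`
#'   (default: 16-bit).
#' @return Logical matrix of the same dimensions.
#' @export
threshold_channel <- function(image, method = c("otsu", "percentile",
                                                "fixed"),
                              value = 99, max_intensity = 65535) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), all(image >= 0))
  if (method == "fixed") return(image >= value)
  if (diff(range(image)) == 0)
    stop("degenerate histogram: constant image cannot be auto-thresholded")
  if (method == "percentile") {
    stopifnot(value > 0, value < 100)
    return(image > stats::quantile(image, value / 100))
  }
  # normalize to the image's own range so sparse 16-bit histograms are
  # resolved by otsu's default binning
  lo <- min(image); hi <- max(image)
  th <- EBImage::otsu(EBImage::Image((image - lo) / (hi - lo)),
                      range = c(0, 1))
  image > lo + th * (hi - lo)
}

# 8-connected labeling of a binary mask (flood fill over frontiers)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask)
  neighbors <- function(idx) {
    r <- (idx - 1L) %% nr + 1L
    c <- (idx - 1L) %/% nr + 1L
    dr <- rep(c(-1L, 0L, 1L), 3L); dc <- rep(c(-1L, 0L, 1L), each = 3L)
    keep <- !(dr == 0L & dc == 0L)
    rr <- outer(r, dr[keep], "+"); cc <- outer(c, dc[keep], "+")
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    unique((cc[ok] - 1L) * nr + rr[ok])
  }
  cur <- 0L
  for (p in fg) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    frontier <- p
    while (length(frontier)) {
      lab[frontier] <- cur
      nb <- neighbors(frontier)
      frontier <- nb[mask[nb] & lab[nb] == 0L]
    }
  }
  lab
}

#' Detect puncta as connected components of a mask
#'
#' Components are 8-connected; components smaller than `min_area` pixels are
#' discarded (noise suppression).
#'
#' @param mask Logical matrix (see [threshold_channel()]).
#' @param min_area Minimum component area in pixels.
#' @return An object of class `punctum_set`: list with `labels` (integer
#'   matrix, 0 = background), `puncta` (`data.frame`: `id`, `area`, centroid
#'   `row`/`col`) and `pixels` (list of linear pixel indices per punctum).
#' @export
find_puncta <- function(mask, min_area = 4L) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  lab <- label_components(mask != 0)
  ids <- seq_len(max(lab, 0L))
  pix <- split(which(lab > 0L), lab[lab > 0L])
  keep <- lengths(pix) >= min_area
  pix <- pix[keep]
  relabel <- integer(length(ids)); relabel[as.integer(names(pix))] <-
    seq_along(pix)
  lab[lab > 0L] <- relabel[lab[lab > 0L]]
  nr <- nrow(mask)
  puncta <- data.frame(
    id = seq_along(pix),
    area = lengths(pix),
    row = vapply(pix, function(i) mean((i - 1L) %% nr + 1L), 0),
    col = vapply(pix, function(i) mean((i - 1L) %/% nr + 1L), 0))
  names(pix) <- NULL
  structure(list(labels = lab, puncta = puncta, pixels = pix),
            class = "punctum_set")
}

#' Partition puncta by overlap with a reference mask
#'
#' A punctum is reference-positive iff its overlap with the reference mask
#' meets the overlap rule: at least `min_overlap` shared pixels (default 1),
#' or -- when `min_fraction` is given -- at least that fraction of the
#' punctum's area.
#'
#' @param puncta A `punctum_set` from [find_puncta()].
#' @param reference_mask Logical matrix, same dimensions as the punctum
#'   mask.
#' @param min_overlap Minimum shared pixels.
#' @param min_fraction Optional minimum shared fraction of punctum area.
#' @return `puncta` with columns `overlap` and logical `ref_positive` added
#'   to `$puncta`.
#' @export
apply_reference_mask <- function(puncta, reference_mask, min_overlap = 1L,
                                 min_fraction = NULL) {
  if (!all(dim(puncta$labels) == dim(reference_mask)))
    stop("dimension mismatch between punctum labels and reference mask")
  ov <- vapply(puncta$pixels, function(i) sum(reference_mask[i]), 0)
  need <- rep(min_overlap, length(ov))
  if (!is.null(min_fraction))
    need <- pmax(need, min_fraction * puncta$puncta$area)
  puncta$puncta$overlap <- ov
  puncta$puncta$ref_positive <- ov >= need
  puncta
}

#' Score a partitioned punctum set against a third channel
#'
#' For the reference-positive and reference-negative groups separately,
#' computes the fraction of marker puncta overlapping the third-channel
#' mask (same overlap rule as [apply_reference_mask()]). A group with zero
#' puncta yields `NA` fractions.
#'
#' @param puncta A partitioned `punctum_set` (after
#'   [apply_reference_mask()]).
#' @param third_mask Logical matrix.
#' @param min_overlap,min_fraction Overlap rule for the third channel.
#' @return One-row `data.frame`: `n_refpos`, `n_refneg`, `frac_refpos`,
#'   `frac_refneg`.
#' @export
score_third_channel <- function(puncta, third_mask, min_overlap = 1L,
                                min_fraction = NULL) {
  if (!all(dim(puncta$labels) == dim(third_mask)))
    stop("dimension mismatch between punctum labels and third-channel mask")
  if (is.null(puncta$puncta$ref_positive))
    stop("puncta must first be partitioned with apply_reference_mask()")
  ov <- vapply(puncta$pixels, function(i) sum(third_mask[i]), 0)
  need <- rep(min_overlap, length(ov))
  if (!is.null(min_fraction))
    need <- pmax(need, min_fraction * puncta$puncta$area)
  hit <- ov >= need
  pos <- puncta$puncta$ref_positive
  frac <- function(sel) if (!sum(sel)) NA_real_ else mean(hit[sel])
  data.frame(n_refpos = sum(pos), n_refneg = sum(!pos),
             frac_refpos = frac(pos), frac_refneg = frac(!pos))
}

#' Object-based colocalization scoring across an image set
#'
#' For each image: thresholds the three channels, detects marker puncta,
#' partitions them by overlap with the reference mask, and scores each group
#' against the third channel. Image stacks are max-projected first. The
#' pooled summary weights images by punctum counts and compares the two
#' groups' per-image fractions with a paired two-sided t-test (the image is
#' the statistical unit); images where either group is empty are excluded
#' from the paired test.
#'
#' @param images List of images; each a list with single-channel matrices
#'   (or lists of matrices, i.e. stacks) named `marker`, `reference`,
#'   `third`.
#' @param threshold_method,threshold_value Passed to [threshold_channel()].
#' @param min_area Minimum punctum area (pixels).
#' @param min_overlap,min_fraction Overlap rule.
#' @return A list: `per_image` (`data.frame` of per-image counts and
#'   fractions), `pooled` (list with pooled `frac_refpos`, `frac_refneg`,
#'   `n_refpos`, `n_refneg`, `p_value`, `n_images_tested`).
#' @export
score_image_set <- function(images, threshold_method = "otsu",
                            threshold_value = 99, min_area = 4L,
                            min_overlap = 1L, min_fraction = NULL) {
  rows <- lapply(seq_along(images), function(i) {
    ch <- lapply(images[[i]][c("marker", "reference", "third")], max_project)
    masks <- lapply(ch, threshold_channel, method = threshold_method,
                    value = threshold_value)
    ps <- find_puncta(masks$marker, min_area = min_area)
    ps <- apply_reference_mask(ps, masks$reference, min_overlap,
                               min_fraction)
    cbind(image = i,
          score_third_channel(ps, masks$third, min_overlap, min_fraction))
  })
  per_image <- do.call(rbind, rows)
  ok <- stats::complete.cases(per_image[, c("frac_refpos", "frac_refneg")])
  p_value <- if (sum(ok) >= 2) {
    stats::t.test(per_image$frac_refpos[ok], per_image$frac_refneg[ok],
                  paired = TRUE)$p.value
  } else NA_real_
  pooled <- list(
    frac_refpos = with(per_image, sum(frac_refpos * n_refpos,
                                      na.rm = TRUE) / sum(n_refpos)),
    frac_refneg = with(per_image, sum(frac_refneg * n_refneg,
                                      na.rm = TRUE) / sum(n_refneg)),
    n_refpos = sum(per_image$n_refpos),
    n_refneg = sum(per_image$n_refneg),
    p_value = p_value, n_images_tested = sum(ok))
  list(per_image = per_image, pooled = pooled)
}

#' Maximum projection of an image stack
#'
#' @param x A matrix (returned unchanged) or list of matrices.
#' @return Single matrix of per-pixel maxima.
#' @export
max_project <- function(x) {
  if (is.matrix(x)) return(x)
  Reduce(pmax, x)
}

#' Read / write grayscale TIFF stacks
#'
#' 16-bit grayscale, one file per channel; multi-page files are returned as
#' lists of integer matrices.
#'
#' @param path File path.
#' @return `read_image_stack`: list of integer matrices (0..65535).
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  lapply(pages, function(p) matrix(as.integer(p), nrow(p), ncol(p)))
}

#' @rdname read_image_stack
#' @param stack Matrix or list of matrices with intensities in 0..65535.
#' @export
write_image_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- list(stack)
  tiff::writeTIFF(lapply(stack, function(m) m / 65535), path,
                  bits.per.sample = 16L)
  invisible(path)
}
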