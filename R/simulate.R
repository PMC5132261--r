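SIM_RUNS <- c("F210", "F290", "F350", "BAIT1", "BAIT2", "CTRL1", "CTRL2")

#' Configuration for the synthetic MudPIT experiment
#'
#' The defaults emulate the reference study design: three salt-elution
#' fractions plus two bait-IP and two control-IgG runs, with a small planted
#' bait complex whose abundance is concentrated in the 290 mM fraction and
#' the bait IPs (zero in the 210 mM fraction and in the controls, and at
#' least 8-fold lower in the 350 mM fraction), against a background of
#' condition-independent log-normal abundances.
#'
#' @param n_target_proteins Number of target proteins.
#' @param n_complex_members Planted bait-complex size.
#' @param protein_length_range Length range (residues), sampled uniformly.
#' @param background_abundance `c(meanlog, sdlog)` of the background
#'   log-normal.
#' @param member_abundance `c(meanlog, sdlog)` for complex members (shifted
#'   up: the purification enriches the bait complex).
#' @param fold_gap_range Range of the planted 290/350 mM fold gap (drawn
#'   uniformly, minimum 8 so the 5-fold criterion is satisfiable but not
#'   trivially).
#' @param run_depth Expected number of spectra per run (Poisson).
#' @param decoy_match_rate Fraction of spectra replaced by near-threshold
#'   decoy-peptide matches, in `[0, 1)`.
#' @param score_correct,score_incorrect Per-class score models: lists with
#'   `xcorr = c(mean, sd)` and `delt_cn = c(mean, sd)`; Gaussians truncated
#'   at 0 (DeltCn also capped at 1). Defaults put about 95% of correct PSMs
#'   above the charge-2 XCorr threshold and center incorrect PSMs at the
#'   acceptance boundary.
#' @param charge_probabilities Named probabilities per charge state.
#' @param kr_frequency Combined K+R residue frequency (0.11 gives realistic
#'   tryptic peptide lengths); the other 18 residues are uniform.
#' @param n_shared_segments,shared_segment_length Number and length of
#'   duplicated subsequences copied between background proteins so that
#'   shared-peptide distribution is actually exercised (complex members keep
#'   unique sequences).
#' @param max_missed_cleavages Missed cleavages allowed when building the
#'   peptide pools spectra are drawn from.
#' @param seed Integer seed; all generators are deterministic given it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_target_proteins = 200L,
                              n_complex_members = 5L,
                              protein_length_range = c(200L, 600L),
                              background_abundance = c(meanlog = 0, sdlog = 1),
                              member_abundance = c(meanlog = 1.5, sdlog = 0.5),
                              fold_gap_range = c(8, 20),
                              run_depth = 2000,
                              decoy_match_rate = 0.05,
                              score_correct = list(
                                xcorr = c(mean = 3.0, sd = 0.6),
                                delt_cn = c(mean = 0.25, sd = 0.08)),
                              score_incorrect = list(
                                xcorr = c(mean = 2.0, sd = 0.5),
                                delt_cn = c(mean = 0.08, sd = 0.05)),
                              charge_probabilities = c("1" = 0.1, "2" = 0.6,
                                                       "3" = 0.3),
                              kr_frequency = 0.11,
                              n_shared_segments = 10L,
                              shared_segment_length = 30L,
                              max_missed_cleavages = 0L,
                              seed = 1L) {
  stopifnot(n_complex_members <= n_target_proteins,
            run_depth > 0,
            decoy_match_rate >= 0, decoy_match_rate < 1,
            abs(sum(charge_probabilities) - 1) < 1e-8,
            fold_gap_range[1] >= 1)
  structure(as.list(environment()), class = "simulation_config")
}

sample_sequence <- function(len, kr_frequency) {
  probs <- rep((1 - kr_frequency) / 18, 20)
  names(probs) <- AA_20
  probs[c("K", "R")] <- kr_frequency / 2
  paste(sample(AA_20, len, replace = TRUE, prob = probs), collapse = "")
}

#' Simulate a proteome with a planted co-enriched complex
#'
#' Generates random protein sequences (uniform residues except a combined
#' K+R frequency of `kr_frequency`), copies a few segments between
#' background proteins to create shared peptides, picks the complex members,
#' and lays down the per-condition abundance matrix: members get abundance
#' `a` in the 290 mM fraction and both bait IPs, `a / fold_gap` in the
#' 350 mM fraction and exactly 0 in the 210 mM fraction and the controls;
#' background proteins get one log-normal abundance shared by every
#' condition.
#'
#' @param config A [simulation_config()].
#' @return A list of class `sim_proteome`: `db` (target protein
#'   `data.frame`), `abundance` (proteins x conditions matrix over
#'   `F210, F290, F350, BAIT1, BAIT2, CTRL1, CTRL2`), `members` (accessions
#'   of the planted complex), `fold_gaps`, `config`.
#' @export
simulate_proteome <- function(config) {
  with_seed(config$seed, {
    n <- config$n_target_proteins
    acc <- sprintf("SIM%04d", seq_len(n))
    lens <- sample(seq(config$protein_length_range[1],
                       config$protein_length_range[2]), n, replace = TRUE)
    seqs <- vapply(lens, sample_sequence, "",
                   kr_frequency = config$kr_frequency)
    members <- sort(sample(acc, config$n_complex_members))
    background <- setdiff(acc, members)
    # duplicated segments among background proteins only, so the planted
    # condition profile of members is not blurred by shared-peptide counts
    seg_len <- config$shared_segment_length
    if (config$n_shared_segments > 0 && length(background) >= 2) {
      for (s in seq_len(config$n_shared_segments)) {
        pair <- sample(match(background, acc), 2L)
        from <- pair[1]; to <- pair[2]
        if (lens[from] <= seg_len || lens[to] <= seg_len) next
        a <- sample(lens[from] - seg_len, 1L)
        b <- sample(lens[to] - seg_len, 1L)
        substr(seqs[to], b, b + seg_len - 1L) <-
          substr(seqs[from], a, a + seg_len - 1L)
      }
    }
    db <- data.frame(accession = acc, sequence = seqs, length = nchar(seqs),
                     category = "target", stringsAsFactors = FALSE)
    abundance <- matrix(0, n, length(SIM_RUNS),
                        dimnames = list(acc, SIM_RUNS))
    bg_a <- stats::rlnorm(length(background),
                          config$background_abundance[["meanlog"]],
                          config$background_abundance[["sdlog"]])
    abundance[background, ] <- bg_a
    mem_a <- stats::rlnorm(length(members),
                           config$member_abundance[["meanlog"]],
                           config$member_abundance[["sdlog"]])
    fold_gaps <- stats::runif(length(members), config$fold_gap_range[1],
                              config$fold_gap_range[2])
    abundance[members, "F210"] <- 0
    abundance[members, "F290"] <- mem_a
    abundance[members, "F350"] <- mem_a / fold_gaps
    abundance[members, c("BAIT1", "BAIT2")] <- mem_a
    abundance[members, c("CTRL1", "CTRL2")] <- 0
    structure(list(db = db, abundance = abundance, members = members,
                   fold_gaps = stats::setNames(fold_gaps, members),
                   config = config),
              class = "sim_proteome")
  })
}

# fully-tryptic peptide pool (length >= 7) per protein, as a long table
peptide_pool <- function(db, max_missed = 0L) {
  per <- lapply(seq_len(nrow(db)), function(i) {
    p <- digest(db$sequence[i], max_missed)$peptide
    p[nchar(p) >= 7L]
  })
  data.frame(accession = rep.int(db$accession, lengths(per)),
             peptide = unlist(per, use.names = FALSE),
             stringsAsFactors = FALSE)
}

rtrunc0 <- function(n, mean, sd, upper = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), 0), upper)
}

# analytic probability that a simulated spectrum survives the canonical
# spectrum-level thresholds (DeltCn >= 0.08; XCorr >= 1.8/2.0/3.0 by
# charge); peptide pools are already fully tryptic and >= 7 residues, so
# run_depth ("expected accepted spectra per run") maps to total sampled
# spectra as depth / p_accept
expected_acceptance_rate <- function(config,
                                     thresholds = filter_thresholds()) {
  xth <- xcorr_threshold_for(as.integer(names(config$charge_probabilities)),
                             thresholds)
  p_class <- function(m) {
    px <- sum(config$charge_probabilities *
                stats::pnorm(xth, m$xcorr[["mean"]], m$xcorr[["sd"]],
                             lower.tail = FALSE))
    pd <- stats::pnorm(thresholds$min_delt_cn, m$delt_cn[["mean"]],
                       m$delt_cn[["sd"]], lower.tail = FALSE)
    px * pd
  }
  (1 - config$decoy_match_rate) * p_class(config$score_correct) +
    config$decoy_match_rate * p_class(config$score_incorrect)
}

#' Simulate the PSM table of one MudPIT run
#'
#' Spectra are sampled multinomially over proteins with probability
#' proportional to abundance times peptide-pool size, then uniformly over
#' each protein's fully-tryptic peptide pool. Correct PSMs draw scores from
#' the "correct" model; a `decoy_match_rate` fraction of spectra is replaced
#' by decoy-peptide PSMs scored from the "incorrect" (near-threshold) model.
#'
#' @param proteome A [simulate_proteome()] result.
#' @param run_id One of the condition labels of the abundance matrix.
#' @param config Defaults to `proteome$config`.
#' @param decoy_db Decoy database to draw incorrect matches from; created
#'   from `proteome$db` on the fly when `NULL`.
#' @param pools,decoy_pool Optional precomputed peptide pools (long tables
#'   from internal digestion), to avoid re-digesting across runs.
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (so a seeded caller gets a deterministic sequence of runs).
#' @return `data.frame` with columns `run_id`, `scan_id`, `peptide`,
#'   `charge`, `xcorr`, `delt_cn`, plus ground-truth columns
#'   `true_accession` and `correct`. A condition with all-zero abundance
#'   yields an empty table.
#' @export
simulate_run <- function(proteome, run_id, config = proteome$config,
                         decoy_db = NULL, pools = NULL, decoy_pool = NULL,
                         seed = NULL) {
  force(config)
  run <- function() {
    ab <- proteome$abundance[, run_id]
    if (is.null(pools))
      pools <- peptide_pool(proteome$db, config$max_missed_cleavages)
    if (is.null(decoy_pool)) {
      if (is.null(decoy_db))
        decoy_db <- make_decoy_db(proteome$db, seed = config$seed + 7919L)
      decoy_pool <- peptide_pool(decoy_db, config$max_missed_cleavages)
    }
    empty <- data.frame(run_id = character(), scan_id = character(),
                        peptide = character(), charge = integer(),
                        xcorr = numeric(), delt_cn = numeric(),
                        true_accession = character(), correct = logical(),
                        stringsAsFactors = FALSE)
    if (all(ab == 0)) return(empty)
    # run_depth is the expected number of *accepted* spectra; sample enough
    # total spectra that the canonical filter keeps that many on average
    n <- stats::rpois(1L, config$run_depth / expected_acceptance_rate(config))
    if (n == 0L) return(empty)
    all_acc <- rownames(proteome$abundance)
    cnt <- table(factor(pools$accession, levels = all_acc))
    npep <- stats::setNames(as.integer(cnt), all_acc)
    w <- ab * npep
    prot_idx <- sample.int(length(w), n, replace = TRUE, prob = w)
    # uniform peptide within the chosen protein, via pool offsets
    pools_sorted <- pools[order(factor(pools$accession, levels = all_acc)), ,
                          drop = FALSE]
    offset <- stats::setNames(cumsum(npep) - npep, all_acc)
    acc <- all_acc[prot_idx]
    pick <- offset[acc] + floor(stats::runif(n) * npep[acc]) + 1L
    peptide <- pools_sorted$peptide[pick]
    correct <- stats::runif(n) >= config$decoy_match_rate
    n_bad <- sum(!correct)
    if (n_bad > 0) {
      bad_pick <- sample.int(nrow(decoy_pool), n_bad, replace = TRUE)
      peptide[!correct] <- decoy_pool$peptide[bad_pick]
      acc[!correct] <- decoy_pool$accession[bad_pick]
    }
    charge <- as.integer(sample(names(config$charge_probabilities), n,
                                replace = TRUE,
                                prob = config$charge_probabilities))
    xcorr <- numeric(n); delt_cn <- numeric(n)
    xcorr[correct] <- rtrunc0(sum(correct),
                              config$score_correct$xcorr[["mean"]],
                              config$score_correct$xcorr[["sd"]])
    delt_cn[correct] <- rtrunc0(sum(correct),
                                config$score_correct$delt_cn[["mean"]],
                                config$score_correct$delt_cn[["sd"]], 1)
    xcorr[!correct] <- rtrunc0(n_bad,
                               config$score_incorrect$xcorr[["mean"]],
                               config$score_incorrect$xcorr[["sd"]])
    delt_cn[!correct] <- rtrunc0(n_bad,
                                 config$score_incorrect$delt_cn[["mean"]],
                                 config$score_incorrect$delt_cn[["sd"]], 1)
    data.frame(run_id = run_id, scan_id = sprintf("s%06d", seq_len(n)),
               peptide = peptide, charge = charge,
               xcorr = round(xcorr, 4), delt_cn = round(delt_cn, 4),
               true_accession = unname(acc), correct = correct,
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate the full multi-condition experiment
#'
#' Generates the proteome, its decoy database and the PSM tables of all
#' seven runs (three fractions, two bait IPs, two control IPs), everything
#' deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list of class `sim_experiment`: `proteome`, `search_db`
#'   (targets + decoys), `psms` (row-bound PSM tables of all runs, with
#'   ground-truth columns), `members`, `config`.
#' @export
simulate_experiment <- function(config = simulation_config()) {
  proteome <- simulate_proteome(config)
  decoy_db <- make_decoy_db(proteome$db, seed = config$seed + 7919L)
  pools <- peptide_pool(proteome$db, config$max_missed_cleavages)
  decoy_pool <- peptide_pool(decoy_db, config$max_missed_cleavages)
  psms <- with_seed(config$seed + 104729L, {
    do.call(rbind, lapply(SIM_RUNS, function(r)
      simulate_run(proteome, r, config, decoy_db = decoy_db,
                   pools = pools, decoy_pool = decoy_pool)))
  })
  structure(list(proteome = proteome,
                 search_db = rbind(proteome$db, decoy_db),
                 psms = psms, members = proteome$members, config = config),
            class = "sim_experiment")
}

#' Simulate a three-channel punctum image set with planted colocalization
#'
#' Renders Gaussian-spot puncta for a marker channel, a reference channel
#' overlapping a configurable fraction of them, and a third channel
#' overlapping (Bernoulli, per punctum) a planted fraction of the
#' reference-positive and reference-negative marker puncta. Gaussian
#' background noise is added and intensities are clipped to the 16-bit
#' range.
#'
#' @param n_images Number of images.
#' @param n_puncta Marker puncta per image.
#' @param p_refpos Planted probability that a reference-positive marker
#'   punctum has a third-channel partner.
#' @param p_refneg Same for reference-negative marker puncta.
#' @param ref_fraction Probability that a marker punctum is also a reference
#'   punctum.
#' @param dim Image dimensions `c(rows, cols)` in pixels.
#' @param spot_sigma Gaussian spot standard deviation (pixels).
#' @param spot_amplitude Peak spot intensity above background.
#' @param background,noise_sd Background level and noise standard deviation.
#' @param min_distance Minimum center-to-center distance between puncta.
#' @param seed Integer seed.
#' @return A list of class `sim_images`: `images` (per image, a list with
#'   16-bit integer matrices `marker`, `reference`, `third`), `truth`
#'   (`data.frame`: `image`, `punctum`, `row`, `col`, `in_reference`,
#'   `in_third`, `area` -- the analytic spot area above the half-maximum
#'   isophote), `params`.
#' @export
simulate_image_set <- function(n_images = 10L, n_puncta = 100L,
                               p_refpos = 0.75, p_refneg = 0.40,
                               ref_fraction = 0.6, dim = c(256L, 256L),
                               spot_sigma = 1.5, spot_amplitude = 8000,
                               background = 500, noise_sd = 200,
                               min_distance = 8, seed = 1L) {
  stopifnot(p_refpos >= 0, p_refpos <= 1, p_refneg >= 0, p_refneg <= 1)
  with_seed(seed, {
    margin <- ceiling(4 * spot_sigma) + 1
    half_max_area <- pi * 2 * spot_sigma^2 * log(2)
    images <- vector("list", n_images)
    truth <- vector("list", n_images)
    for (im in seq_len(n_images)) {
      centers <- matrix(NA_real_, 0, 2)
      while (nrow(centers) < n_puncta) {
        cand <- c(stats::runif(1, margin, dim[1] - margin),
                  stats::runif(1, margin, dim[2] - margin))
        if (!nrow(centers) ||
            min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= min_distance)
          centers <- rbind(centers, cand)
      }
      in_ref <- stats::runif(n_puncta) < ref_fraction
      p <- ifelse(in_ref, p_refpos, p_refneg)
      in_third <- stats::runif(n_puncta) < p
      render <- function(on) {
        img <- matrix(background, dim[1], dim[2])
        r <- ceiling(4 * spot_sigma)
        g <- seq(-r, r)
        kern <- spot_amplitude *
          exp(-outer(g^2, g^2, "+") / (2 * spot_sigma^2))
        for (k in which(on)) {
          ro <- round(centers[k, 1]); co <- round(centers[k, 2])
          rows <- (ro - r):(ro + r); cols <- (co - r):(co + r)
          img[rows, cols] <- img[rows, cols] + kern
        }
        img <- img + matrix(stats::rnorm(prod(dim), 0, noise_sd),
                            dim[1], dim[2])
        matrix(as.integer(pmin(pmax(round(img), 0), 65535)), dim[1], dim[2])
      }
      images[[im]] <- list(marker = render(rep(TRUE, n_puncta)),
                           reference = render(in_ref),
                           third = render(in_third))
      truth[[im]] <- data.frame(image = im, punctum = seq_len(n_puncta),
                                row = round(centers[, 1]),
                                col = round(centers[, 2]),
                                in_reference = in_ref, in_third = in_third,
                                area = half_max_area)
    }
    structure(list(images = images, truth = do.call(rbind, truth),
                   params = list(n_images = n_images, n_puncta = n_puncta,
                                 p_refpos = p_refpos, p_refneg = p_refneg,
                                 ref_fraction = ref_fraction, dim = dim,
                                 spot_sigma = spot_sigma,
                                 spot_amplitude = spot_amplitude,
                                 background = background,
                                 noise_sd = noise_sd, seed = seed)),
              class = "sim_images")
  })
}

#' Write the tables of a simulated experiment to a directory
#'
#' Emits the target FASTA, the decoy FASTA, one PSM TSV per run, and a
#' ground-truth TSV (members and per-condition abundances).
#'
#' @param sim A [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$proteome$db, file.path(dir, "targets.fasta"))
  write_fasta(sim$search_db[sim$search_db$category == "decoy", ],
              file.path(dir, "decoys.fasta"))
  for (r in unique(sim$psms$run_id))
    write_psm_table(sim$psms[sim$psms$run_id == r, ],
                    file.path(dir, paste0("psms_", r, ".tsv")))
  truth <- data.frame(accession = rownames(sim$proteome$abundance),
                      is_member = rownames(sim$proteome$abundance) %in%
                        sim$members,
                      sim$proteome$abundance, stringsAsFactors = FALSE)
  utils::write.table(truth, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
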