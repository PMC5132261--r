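---
title: "Calling bait co-enriched proteins from MudPIT spectral counts"
author: "cospec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling bait co-enriched proteins from MudPIT spectral counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cospec)
```

## The problem

Shotgun proteomics of a biochemical enrichment — here, salt-step anion-exchange
fractions of a brain light-membrane preparation and a parallel
immunoprecipitation (IP) of the presynaptic active-zone scaffold Piccolo —
identifies hundreds of proteins per run, most of them abundant contaminants.
The question is which of them are genuinely co-enriched with the bait complex.
`cospec` implements the complete computational path from peptide-spectrum
matches (PSMs) to a ranked candidate table:

1. **sequence database handling** — concatenated target–decoy database
   construction and in-silico tryptic digestion;
2. **PSM filtering** — DTASelect-style spectrum- and protein-level acceptance
   with decoy-based false discovery rate (FDR) estimation;
3. **spectral quantification** — distributed spectral counts (dSpC) and
   distributed normalized spectral abundance factors (dNSAF);
4. **co-enrichment classification** — a dual-criteria decision rule that
   combines fractionation and IP evidence;
5. **a ground-truthed synthetic-data generator** used to benchmark all of the
   above;
6. **object-based puncta colocalization** scoring for the accompanying
   imaging assay.

The package does not score spectra: SEQUEST-style attributes (XCorr, DeltCn)
are inputs carried by each PSM.

## Decoy databases and digestion

`make_decoy_db()` creates exactly one decoy per database entry by uniformly
permuting its residues. A shuffle preserves length and amino-acid
composition — the two properties the downstream search statistics rely on —
and is deterministic given a seed. Decoy accessions carry the `DECOY_`
prefix; contaminants are ordinary searchable entries flagged by
`category = "contaminant"`.

`digest()` models Lys-C followed by trypsin as a single trypsin-like rule:
cleave after K or R, never before P. Both enzymes cut after lysine, and no
separate rule is needed downstream. Protein termini count as tryptic termini,
and no length filter is applied at digestion time — length is an acceptance
criterion, not a chemistry fact.

`map_peptides()` locates peptides in the database and classifies each
occurrence as fully, half or non tryptic from its flanking residues. Two
methods exist: an exact substring scan (`method = "scan"`, the reference
semantics — any protein containing the peptide is a parent) and a digest-index
fast path (`method = "index"`) that covers all tryptic occurrences up to a
missed-cleavage cap and falls back to the scan for unmatched peptides. On
random-sequence databases the difference is a vanishing set of chance
non-tryptic substring matches; `method = "auto"` picks the scan for small
problems. Matching is case-insensitive on the 20-letter alphabet and keeps
I and L distinct — collapsing them would lose information without gaining
anything for spectral counting.

## PSM filtering

`filter_thresholds()` encodes the acceptance criteria, all inclusive:

| parameter | default | meaning |
|---|---|---|
| `min_delt_cn` | 0.08 | minimum normalized score gap to the runner-up match |
| `min_xcorr` | 1.8 / 2.0 / 3.0 | minimum XCorr for charge 1+ / 2+ / 3+ |
| `min_peptide_length` | 7 | residues |
| `require_fully_tryptic` | `TRUE` | at least one fully tryptic parent occurrence |

Charges above the highest configured state inherit its threshold
(`extend_max_charge = TRUE`), a conservative convention; set it to `FALSE` to
make unexpected charges an error instead. A peptide that sits differently in
different proteins satisfies the tryptic requirement if *any* occurrence is
fully tryptic.

Protein-level acceptance pools all runs: a protein needs at least 2 distinct
accepted peptides, or 1 peptide observed in 2 independent spectra.

`estimate_fdr()` reports the classical concatenated-search estimate
`D / T` over accepted PSMs (decoy over target counts), with the symmetric
variant `2D / (T + D)` alongside and a per-run breakdown. PSMs whose peptide
maps to both a target and a decoy are counted as target — the standard
tie-break. The package exposes the estimate and makes no acceptance decision
from it.

## dSpC and dNSAF

Within one run, a peptide's spectral count is the number of accepted spectra
matching it. Counts of peptides unique to one accepted protein sum to that
protein's unique count uSpC. Shared peptides are then apportioned in
proportion to unique evidence:

$$\mathrm{dSpC}_k \;=\; \mathrm{uSpC}_k \;+\; \sum_{j \in \text{shared}}
\mathrm{SpC}_j \,\frac{\mathrm{uSpC}_k}{\sum_{i \in \mathrm{parents}(j)}
\mathrm{uSpC}_i}$$

and length-normalized into relative abundances:

$$\mathrm{dNSAF}_k \;=\;
\frac{\mathrm{dSpC}_k / L_k}{\sum_i \mathrm{dSpC}_i / L_i}.$$

Numerical choices: when every sharer of a peptide has zero unique counts the
spectra are split equally (the only choice that preserves the conservation
identity $\sum_k \mathrm{dSpC}_k = $ total counted spectra); spectra of
peptides mapping only to non-accepted proteins are excluded from counting and
from the conservation total; counting is strictly per run and cross-condition
matrices are assembled by column binding, never by summing runs. dSpC is kept
as a real number internally; printed tables round it for display. dNSAF
values cannot be re-derived from a published table alone — they depend on
every protein in the run — so they are treated as display values, not
re-computation targets.

## The dual-criteria classifier

`experiment_design()` names the run labels: three salt-elution fractions
(210, 290, 350 mM NaCl), bait-IP replicates and control-IgG replicates.
A protein is

* **fractionation-positive** iff its 210 mM dSpC is exactly 0, its 290 mM
  dSpC is positive, and the 290 mM dSpC is at least `fold_threshold`
  (default 5) times the 350 mM dSpC;
* **IP-positive** iff it appears in at least one bait replicate and in no
  control replicate;
* **combined-positive** iff both.

Three conventions deserve comment. "Absent" means zero distributed counts
*after* filtering and protein acceptance, matching how published tables are
blanked. A zero 350 mM count passes the fold test whenever the 290 mM count
is positive — a protein detected only in the 290 mM fraction is the
archetypal positive, including single-spectrum detections. And single-
replicate bait presence counts as presence (`ip_rule = "any"`); published
candidate tables treat proteins seen in only one IP replicate as present.
All three policies, the fold threshold and the replicate rule are
configuration, not constants. Whether the 5-fold rule is applied to spectra
or to distinct peptide sequences is ambiguous in prose descriptions of such
workflows; it is applied here to dSpC, the quantity candidate tables print,
and on the packaged reference table either reading yields the same three
positives.

`make_report()` ranks candidates: combined positives, then
fractionation-only, then IP-only, then the rest, each by descending 290 mM
dSpC with accession as the tie-break. The packaged fixture
(`table1_counts()`) carries the printed dSpC cells of the reference
co-enrichment table; running the classifier on it yields exactly the three
known positives:

```{r}
report <- make_report(table1_counts(), table1_design())
report[, c("accession", "F210", "F290", "F350", "combined_positive")]
```

## What the synthetic generator emulates

`simulation_config()` fixes the study conditions; its defaults were chosen
once, as follows, and the benchmark tests run against them unchanged.

* **Design**: seven runs — F210/F290/F350, two bait IPs, two control IPs.
* **Proteome**: 200 target proteins of 200–600 residues, uniform residues
  except a combined K+R frequency of 0.11 so tryptic peptides have realistic
  lengths; plus a same-size shuffled decoy database.
* **Planted complex**: 5 members whose abundance is `a` in F290 and both
  bait IPs, exactly 0 in F210 and the controls, and `a / fold_gap` in F350
  with `fold_gap` uniform on [8, 20] — the 5-fold criterion is satisfiable
  but not trivially. Member abundance is log-normal(meanlog 1.5, sdlog 0.5),
  one e-fold-and-a-half above the background's log-normal(0, 1): the
  purification enriching the bait complex is the premise of the experiment.
  This puts typical member counts at roughly 10–60 spectra per positive run,
  the range printed for real co-enriched proteins (1–35 in the fractionation
  arm).
* **Background**: condition-independent log-normal abundances — the
  contaminant behaviour the classifier must reject.
* **Shared peptides**: ten 30-residue segments copied between background
  proteins so the dSpC distribution step is actually exercised; members keep
  unique sequences so the planted condition profile is not blurred.
* **Spectra**: `run_depth` (default 2000) is the *expected number of
  accepted spectra per run*; the generator samples
  `run_depth / p_accept` spectra where `p_accept` is the analytic acceptance
  probability of the score models under the canonical thresholds. Spectra
  are multinomial over proteins with weight abundance × pool size, uniform
  over each protein's fully tryptic ≥7-residue peptides.
* **Scores**: correct PSMs draw XCorr from N(3.0, 0.6) — about 95% above the
  charge-2 threshold — and DeltCn from N(0.25, 0.08); a 5% fraction of
  spectra is replaced by decoy-peptide matches scored at the acceptance
  boundary (XCorr N(2.0, 0.5), DeltCn N(0.08, 0.05)). Gaussians are clipped
  at 0 (and DeltCn at 1); at these means the clipped mass is negligible.
  Charge states occur at 10/60/30%.

What the generator does *not* emulate: real retention/elution chemistry,
intensity-dependent identification bias, correlated contaminant structure
across runs, modified peptides, and the long tail of near-identical isoforms
in a real 86k-entry database. Passing benchmarks on these simulations shows
the decision rules and arithmetic are implemented correctly under the planted
model, not that the biological study would replicate.

Benchmarks computed by the test suite and the acceptance script at these
defaults (20 simulations, 100 planted members): pooled recall of planted
members, false positives per replicate, decoy-FDR calibration against
ground-truth labels, and the conservation/normalization identities on random
instances. Two boundary phenomena are worth knowing about, both properties
of the published decision rule rather than implementation artifacts: a
background protein with expected counts below ~1 per run can by chance show
the exact positive pattern (a singleton false positive), and a protein whose
only 210 mM spectrum comes from a shared peptide can have that evidence
apportioned entirely to a sharer with unique counts, zeroing its 210 mM dSpC.
At the default conditions the false-positive rate from both mechanisms
together stays well below one call per replicate on average, but individual
replicates can show two.

## Puncta colocalization

The imaging module reproduces an object-based cell-scoring procedure:
threshold each channel, detect marker puncta as 8-connected components
(minimum area 4 pixels by default, suppressing single-pixel noise), partition
them by overlap with the reference-channel mask, and score each group for
overlap with the third channel. Image stacks are max-projected first. The
default overlap rule is ≥1 shared pixel, with an optional fractional-overlap
parameter; thresholding methods are `otsu` (between-class variance on the
image's own intensity range), `percentile`, and `fixed`, since the original
commercial software's exact semantics are not documented. The statistical
unit is the image: the pooled summary reports count-weighted fractions and a
paired two-sided t-test across images comparing the reference-positive and
reference-negative groups, excluding images where either group is empty.
A degenerate (constant) image is an error for the automatic methods rather
than an arbitrary mask.

The companion generator `simulate_image_set()` plants Gaussian-spot puncta
(σ = 1.5 px, amplitude 8000 over a background of 500 with noise σ = 200 on a
16-bit scale, centers at least 8 px apart) and marks a planted fraction of
reference-positive and reference-negative marker puncta with third-channel
partners; its truth table records the analytic half-maximum disc area of each
spot. The reference fixture plants 75% / 40% over 10 images × 100 puncta —
fractions in the neighbourhood reported for the real assay (~75% vs <50%) —
and the benchmarks require recovery within three binomial standard errors
with the paired test rejecting at α = 5×10⁻⁴. Raw micrographs from the
original study are not available, so those printed percentages are
property-level targets on synthetic data, never re-computations.

## Pipeline and reproducibility

`run_pipeline()` executes the stages end to end from a single configuration
(R object or YAML), writing every intermediate table and a manifest with the
package version, a configuration hash, the seed and per-stage row counts.
Outputs contain no timestamps, so identical configurations produce
byte-identical bundles. Decoy entries never reach the candidate report; they
exist for FDR bookkeeping only. Any stage failure aborts with the failing
stage named. A thin command-line dispatcher over these functions ships in
`inst/scripts/cospec.R`.

Problem sizes used by the shipped benchmarks — 20 simulations at 200
proteins × 2000 accepted spectra × 7 runs, 100 random quantification
instances, 10 synthetic images — were chosen so the full suite exercises
every decision path at well-powered sample sizes while remaining quick to
run on a laptop.

## Known limitations

* The FDR calibration check is partially self-referential: in the simulator
  every planted incorrect match is a decoy match, so the decoy-based
  estimate and the ground-truth incorrect fraction differ only by the
  `D/T` versus `D/(T+D)` denominators. It validates the bookkeeping, not
  the biological adequacy of the decoy model.
* `map_peptides(method = "index")` will not report additional *non-tryptic*
  occurrences of a peptide that already has a tryptic parent; use
  `method = "scan"` when that distinction matters.
* The classifier is deterministic set logic, as published; it has no error
  model, so single-spectrum detections can flip calls. Probabilistic
  interactor scoring is out of scope by design.
* Quantification assumes protein length is a fair proxy for detectable
  peptide yield; strongly atypical K/R content breaks that proxy for
  individual proteins.
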