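---
title: "Measuring chromatin accessibility with methyltransferase footprinting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring chromatin accessibility with methyltransferase footprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement

A DNA methyltransferase expressed in (or added to) cells marks every
recognition site it can reach: Dam methylates the adenine of GATC, M.SssI
methylates the cytosine of CG. A site wrapped in a nucleosome or occluded by
a bound complex is protected; an exposed site is methylated. Reading the
methylation state of every site in every molecule therefore converts
chromatin accessibility into a sequence-level signal.

`chromflux` implements the quantitative read-out of this assay in two
dialects:

* **Short-read fragment counting.** Methylated GATC sites are cleaved by
  DpnI, the DNA is sonicated and sequenced paired-end, and each fragment end
  that coincides with a cut boundary is evidence that the site was
  methylated in that molecule. The per-site statistic is the *fraction cut*
  (`fcut`).
* **Long-read CpG calling.** Single molecules are read on a nanopore
  instrument and scored per CG site with a log-likelihood ratio
  (Nanopolish-style tables); per-site methylated frequencies take the place
  of fcut.

Two chromatin regimes give the two analysis modes:

* **Static chromatin (isolated nuclei).** Each site is accessible in a
  fixed fraction `p` of nuclei. Increasing enzyme concentration saturates:
  `f(c) = f_bg + (f_max - f_bg)(1 - exp(-c/c0))`. The plateau `f_max` is
  the *limit digest* and estimates the accessible fraction.
* **Dynamic chromatin (living cells).** Every site is eventually
  methylated; the *apparent first-order rate constant* `k` is the negative
  slope of `ln(u)` against time, where `u` is the median unmethylated
  fraction of a site group. Regional biology lives in the ratios of these
  rates: promoter NDRs and tRNA genes marginally faster than gene bodies,
  centromeres and silenced loci strongly protected.

# The fcut estimator

DpnI cuts bluntly between the A and T of a fully methylated GATC. With the
G at 0-based position `s`, a cut produces a left fragment whose last base is
the A (`s+1`) and a right fragment whose first base is the T (`s+2`).
Library preparation sometimes removes the terminal A or T, so ends one base
short are counted too:

```
fcut_right = (right ends on A + right ends on G) / coverage of G
fcut_left  = (left starts on T + left starts on C) / coverage of C
```

Because any fragment ending on the A or G necessarily covers the G (and
symmetrically for the left side), both ratios are bounded by [0, 1], and
the two-base acceptance window makes the estimate invariant to the
terminal-loss probability — a property the test suite checks against the
simulator at loss probabilities 0, 0.3 and 1.

Numerical and policy choices:

* Coordinates are 0-based half-open throughout; BED is ingested natively
  and GFF3 is shifted by −1 on start. Fragment coverage and end tracks are
  accumulated with a difference array and are exactly equal to per-fragment
  enumeration (tested against a brute-force oracle on random instances).
* **Neighbor policy.** Fragments shorter than ~200 bp are recovered
  inefficiently, so a neighboring site closer than 200 bp biases the facing
  side. Sites with close neighbors on *both* sides are excluded; with a
  close neighbor on one side the close side's value is overwritten by the
  far side's (`substituted_left`/`substituted_right`). Distances are
  measured between blunt-cut midpoints (`start+2` for GATC, `start+1` for
  CG); the distance anchor is our convention — motif starts would shift
  every gap by a constant and never change a 200-bp verdict by more than
  the anchor offset. A chromosome end closer than 200 bp is treated as a
  close-neighbor side.
* **Side combination.** Both per-side values are always emitted; the
  site-level `fcut` defaults to the mean of the usable sides, so either the
  per-side or the averaged convention can be reproduced downstream.
* **Coverage gate.** A side with coverage below 8 is too quantized to be
  useful and is flagged `low_coverage`, kept out of group medians.
* **Duplicates** are kept by default: cut-site pileups are the signal in
  this assay, not PCR artifacts; an optional `dedup` flag removes identical
  intervals.

# Kinetic and plateau fits

* `fit_rate` regresses `ln(u)` on time (minutes) by OLS; `k = -slope` with
  its OLS standard error. Points with `u < 0.05` are excluded — near
  complete methylation the log diverges and sampling noise dominates. The
  `t = 0` point is included by default and no background is subtracted
  (the raw `ln u` is what is plotted); a normalized variant
  (`u' = u/u(0)`) can be obtained by dividing the series beforehand.
* `rate_ratio` propagates uncertainty by the delta method:
  `se = (kA/kB) sqrt((seA/kA)^2 + (seB/kB)^2)`.
* `fit_plateau` fits the saturating exponential by bounded
  Levenberg–Marquardt least squares (`minpack.lm`), constraining
  `0 ≤ f_bg, f_max ≤ 1`. A series that decreases by more than 0.05, a
  non-converging fit, or an inverted fit (`f_bg > f_max`) falls back to the
  mean of the two highest-concentration values, and the method used is
  always recorded in the result.
* Group summaries use the median with type-7 (linearly interpolated)
  quartiles; the 25–75% band is what the accessor reports, and the full
  range can be recomputed from the per-site tables.
* Units are minutes and nM throughout.

# Dyad-aligned phasing profiles

Methylation is averaged at each signed offset from the +1 nucleosome dyad,
pooling all (site, gene) pairs — a site within the window of two genes
contributes to both. Pooling pairs (rather than averaging per gene first)
weights each site equally, matching profiles built from "sites in all
genes". Offsets are strand-corrected so positive always points into the
gene body.

* Offsets supported by fewer than 20 pairs are masked before smoothing by
  default (GATC is ~25-fold sparser than CG; the CG analyses in this
  package lower the mask to 5 because site density is high and gene counts
  are modest).
* Smoothing is a centered 21-bp boxcar whose window shrinks at the edges;
  undefined offsets are skipped, never zero-filled, so the smoothed curve
  stays within the range of its inputs.
* Companion nucleosome tracks are max-scaled to 0.1 so they fit under fcut
  curves on a 0–1 axis (area normalization would untie the track from the
  figure convention it mimics). `occupancy_track` convolves a dyad-density
  track with the 147-bp nucleosome footprint: occupancy, not the raw dyad
  spike train, is the quantity directly anti-correlated with accessibility,
  and the anti-phase score against occupancy is correspondingly much
  stronger (≈ −1 on simulated arrays, vs ≈ −0.5 against raw dyad density).
* **Array shift.** The shift between two conditions is the integer lag (±60
  bp) maximizing the Pearson correlation of the smoothed profiles over the
  genic array (offsets 0..+500): all phased peaks contribute, which is far
  more stable than tracking a single peak. Ties go to the smallest |lag|;
  a negative value means the second profile is shifted toward the promoter.
  A secondary +1-trough estimate (depth-weighted centroid of the
  methylation minimum) is also provided; with hard-edged footprints its
  flat-bottomed trough makes it noticeably less accurate than the
  cross-correlation estimate, which is why the latter is primary.
* **Disorder index.** Peak-to-trough amplitude in the +2..+4 nucleosome
  band divided by the +1-band amplitude: ≈1 for a well-phased array, →0 as
  downstream phasing dissolves while the +1 nucleosome persists — the
  spacing-enzyme-depletion phenotype.

# Long-read CpG aggregation

Nanopolish-style call tables are parsed with malformed rows counted and
skipped. Calls with |LLR| below 2.0 are *ambiguous* and excluded from
coverage (the threshold is configurable; 2.0 is the community default since
the source analyses do not publish a cutoff). Grouped calls (CG sites
within ~10 bp merged by the caller) are split by recovering CG offsets from
the sequence context, anchored at the record's start; every CG in the group
inherits the group call — assigning only the first CG would distort phasing
density. Records whose context disagrees with `num_motifs` are quarantined,
so split evidence exactly equals the sum of `num_motifs` over accepted
records. Calls are reported on the forward-strand C coordinate (CpG
symmetry). Sites with coverage below 10% of the median covered-site
coverage are flagged; frequencies map onto the common fcut table layout so
kinetics and phasing run unchanged on CG data.

# The synthetic-data generator

The simulator provides ground-truthed inputs for every stage. Its defaults
are the study conditions the analyses assume:

| Parameter | Default | Meaning |
|---|---|---|
| induction half-time | 80 min | exponential per-cell induction delays |
| `sigma_cell` | 0.5 | sdlog of the log-normal per-cell enzyme level |
| `c0` | 0.5 nM | concentration saturation scale (nuclei mode) |
| sonication mean length `L` | 350 bp | Poisson breakpoints at rate 1/L |
| recovery ramp | 100–300 bp | linear 0→1 retention (~50% at 200 bp) |
| terminal loss `q` | 0.3 | per-DpnI-end loss of the terminal A/T |
| class rate presets | NDR:ORF 1.3 (GATC) or 2.9 (CG), tRNA:ORF 1.2, ARS/TEL/Ty:ORF 1.0, CEN:ORF 1/14, silenced:ORF 1/20 | scenario presets, not constants |

Mechanics worth knowing:

* **Within-cell monotonicity** is enforced by construction: each (cell,
  site) draws a methylation *time* (or threshold concentration), so a site
  methylated at one design point stays methylated at later ones.
* **In vivo**, a cell's delay is Exponential(ln2 / half-time) and its rate
  multiplier log-normal (median 1); a site is methylated by time `t` with
  probability `f0 + (1-f0)(1 - exp(-k λ max(0, t-τ)))`. `f0` models
  pre-induction background and is per-class configurable (promoter NDRs
  higher), since its magnitude is not quantified anywhere.
* **Nuclei mode**: accessible with probability `p` per (cell, site);
  accessible sites methylate with probability `1 - exp(-c/c0)`;
  inaccessible sites never methylate.
* **DpnI digestion is complete** at methylated sites (excess enzyme);
  hemimethylation is not modeled. Terminal-base loss applies only at DpnI
  ends, never at sonication ends. Sonication breakpoints are an independent
  per-boundary Bernoulli(1/L) process, sampled exactly as a binomial count
  with uniform positions.
* **Positional accessibility**: nucleosome arrays are laid out per gene
  (+1 dyad plus multiples of the 165-bp repeat) with per-nucleosome
  Gaussian positional jitter; the per-site open probability is the exact
  product of non-coverage probabilities, so phased-chromatin scenarios have
  closed-form ground truth. Phased scenarios use jitter growing from 8 bp
  at the +1 to ~38 bp at the +5, the realistic pattern of yeast arrays.
* **Reproducibility**: every stochastic entry point requires an explicit
  seed, and draws are ordered cell by cell, so enlarging `n_cells` leaves
  the states of earlier cells unchanged under the same seed.

What the generator deliberately does **not** emulate: base-call or
alignment errors, mappability and GC bias, PCR duplication, replication
and cell-cycle structure, sequence preferences of nucleosome positioning,
and mechanistic distinctions between histone exchange, sliding and
conformational breathing — the in-vivo model is the *net* first-order
exposure rate, because population methylation curves cannot identify the
mechanism. Passing tests therefore show that the estimators recover the
parameters of this idealized assay, not that real libraries are free of
the biases above.

# A property the simulator exposed

Fragments that end at a cut site are systematically shorter than fragments
that span it, so length-dependent recovery (the 100–300 bp ramp) depletes
the fcut numerator more than its denominator. On the synthetic titration
this attenuates fitted plateaus by roughly a third at the default settings
(e.g. generating 0.70/0.30 → fitted ≈0.55/0.19), while with recovery
disabled the generating fractions are recovered to within sampling error
(see `analysis/02_nuclei_limit_digest.R`, which runs both). The
estimator-calibration checks are therefore run with the ramp disabled —
they test the end-counting correction, not library-preparation loss — and
the attenuation is documented here as an assay property that real
experiments calibrate against spike-ins or accept as a scale factor.

# Problem sizes

The shipped analyses and tests are deliberately small-scale: 10-kb genomes
with ≤1,000 fragments for the enumeration oracle; 200–2,000 cells per
simulation; 150-gene phased arrays with CG-density sites (~16,000 sites);
a 200-kb two-chromosome census (~700 GATC sites) for the workflow scripts.
These sizes give the quoted recovery tolerances (binomial standard errors
at 2,000 cells are ~0.01) while keeping every analysis in seconds to tens
of seconds.

# Known limitations

* Group-level calls copied to member CGs blur per-site frequencies where
  neighboring CGs genuinely differ within a molecule; this mirrors the
  upstream caller's behavior and is quantified in the tests only for
  homogeneous groups.
* The +1-trough shift estimate is biased toward zero for shifts comparable
  to its search band; use the cross-correlation estimate for inference.
* `fit_rate` on a population with broad per-cell enzyme variation measures
  an apparent rate whose ratio between groups equals the per-cell ratio
  only when induction is fast relative to methylation; the rate-recovery
  checks use instant induction for exactly this reason, and the
  induction-linearity diagnostic covers the slow-induction regime.
* Real MNase dyad tracks carry their own digestion biases; the simulated
  density track models positional jitter only.
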