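---
title: "Codon-resolution elongation dynamics with ribodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-resolution elongation dynamics with ribodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribodyn)
library(dplyr)
```

## The model

Ribosome profiling reads out where ribosomes sit on mRNAs: each footprint
is the ~17–34-nt fragment protected by a single 80S ribosome, and under
steady-state translation the density of footprints whose A-site falls on a
codon is proportional to the time the ribosome spends decoding it. ribodyn
treats every footprint as a transcript-relative record
`(transcript_id, five_prime_pos, length, count)` (0-based, half-open
coordinates) and derives three families of statistics from it:

* **Relative codon occupancy.** For 28–30-nt footprints the A-site
  nucleotide sits 15 nt downstream of the 5' end; its codon index is
  `floor((A - cds_start)/3)`, and the P- and E-sites are one and two codons
  upstream. After reads-per-million (RPM) normalisation, the relative
  occupancy of a codon identity is

  $$\rho_c = \frac{\overline{\mathrm{RPM}}_{\,\text{positions with codon } c}}
                  {\overline{\mathrm{RPM}}_{\,\text{all analyzed positions}}},$$

  so the occurrence-weighted mean of $\rho_c$ is exactly 1 and $\rho_c > 1$
  marks slow decoding. The first and last five codons of every CDS are
  excluded to avoid initiation/termination artifacts, so the analyzed
  window of an $L$-codon CDS is codons $[5, L-6]$ and stop codons never
  enter the statistics.

* **RUST-style metafootprint enrichment.** Coverage heterogeneity between
  transcripts can distort pooled means, so each transcript profile is also
  binarised at its own mean (strictly above-mean positions count as 1) and
  codon frequencies among above-mean positions are divided by the codon
  frequencies among all analyzed positions. This observed/expected ratio is
  robust to per-transcript depth and is used as a cross-check on $\rho_c$.

* **Per-transcript CV.** The coefficient of variation (sample s.d. over
  mean, $n-1$ denominator) of the per-codon A-site density summarises how
  heterogeneous elongation is along a transcript; both local slowdowns and
  local accelerations raise it. One value per transcript is reported, and
  violin/MWU comparisons are made at the transcript level. (Whether the
  per-codon or per-transcript unit is the better observation unit is
  genuinely open; the transcript keeps the values exchangeable across
  conditions with different depths.)

Between conditions, codon-level log2 fold changes of $\rho_c$ are compared
(replicate means, ratio on the natural scale), and individual codon
positions are tested for differential pausing with a two-sided
pooled-variance Student's t test on per-replicate values normalised as
position RPM over transcript-mean RPM. That normalisation removes
transcript-abundance differences between genotypes, isolating local
occupancy; it is the one genuinely open design choice in the testing path,
and positions with zero transcript mean are excluded rather than imputed.
p values are Benjamini-Hochberg adjusted **within each amino-acid family**
of the tested codons (e.g. Pro and Ala positions form separate families),
mirroring the family-wise volcano analyses this kind of study reports.

Disome (collided-ribosome) libraries carry 50–80-nt fragments protected by
two ribosomes. The literature does not fix how a disome fragment maps to
the stalled ribosome's codon, so ribodyn declares a convention: the **leading** (downstream, stalled) ribosome's A-site is
`five_prime_pos + length - 15`, the monosome offset applied from the 3'
end; the alternative trailing rule (`five_prime_pos + 15`) is available via
`offset_rule = "trailing"`. Collision peaks are likewise a declared rule
(none is standard): a codon is a candidate when its disome RPM is at least
`k_fold = 4` times the transcript median over non-zero codons and its raw
count is at least `min_count = 5`; candidates within `merge_gap = 1`
intervening codon merge, the summit is the densest codon, and the rule is
invariant to global library scaling. Peak sets from two conditions are
matched greedily by nearest summit within one codon, giving
common/condition-specific Venn counts, and intensity fold changes over the
union use a 0.5-RPM pseudocount so condition-specific peaks stay finite.

## Read-length calibration

Only read lengths that show 3-nt periodicity carry positional information.
ribodyn scores each length by the modal-frame fraction of CDS-internal 5'
ends (ties go to the lower frame index); lengths scoring at least 0.5 are
retained, the 20–22-nt class is dropped (open-A-site footprints, which
typically lack periodicity), and the result is intersected with the offset
table, by default 15 nt for 28–30-nt reads. The published score this
mirrors comes from dedicated ORF-calling tools; the modal-frame fraction is
transparent, monotone in periodicity, and keeps the same 0.5 decision
boundary. Out-of-frame reads are excluded from profiles by default because
their A-site codon identity is ill-defined; `keep_offframe = TRUE` assigns
them to the codon containing the A-site nucleotide for sensitivity
analyses. The RPM denominator is the library size after length filtering
(post-filter); passing `total_count` switches to pre-filter normalisation.

## What the synthetic generator emulates

`generate_transcriptome()` builds ATG-initiated CDSs of uniform random
sense codons (configurable weights; uniform by default so codon usage never
confounds occupancy estimates in tests), 30–400 codons, flanked by 60-nt
UTRs — long enough that a 15-nt offset never underflows and an 80-nt disome
fragment always fits. Transcript abundances are log-normal (sdlog 1),
roughly the dynamic range of a deeply sequenced tissue library, and are
normalised to sum to 1.

`simulate_monosome_footprints()` draws A-site positions multinomially with
probability proportional to abundance × codon dwell × site multiplier over
the analyzed window, lengths from a distribution putting 80% of mass on
28–30 nt, 5' ends 15 nt upstream of the A-site, and shifts a configurable
fraction (default 5%) of reads ±1 nt off frame. Replicates jitter both
library depth and per-position means log-normally (sigma = `dispersion`,
default 0.1), a simple overdispersion adequate for exercising a
t-test-based pipeline. `simulate_disome_footprints()` places the leading
ribosome's A-site on a planted collision site with probability `p_stall`
and uniformly otherwise, with 50–80-nt lengths.

The generator deliberately omits sequencing error, rRNA contamination, UMI
structure, nuclease sequence bias, codon-pair effects and 5'/3' ramps.
Passing tests therefore demonstrate that the estimators recover the
generative dwell/collision structure under realistic counting noise — not
that they are robust to every artifact of real libraries.

## Numerical and design choices

* Coverage gates are config-exposed; `relative_codon_occupancy()` defaults
  are permissive (so worked examples stay transparent) while the pipeline
  defaults gate at ≥ 20–100 analyzed codons per transcript. For real
  libraries, a mean raw count of about 1 per codon is a sensible floor.
* $\rho$ uses the pooled position-level estimator (all qualifying positions
  across transcripts enter one mean) rather than per-transcript averaging;
  it reads the RPM-averaging definition literally and weights positions by
  their information content.
* RUST binarisation uses strict `>`; ties at the mean count as 0, and
  zero-variance transcripts contribute nothing.
* Degenerate t tests: zero pooled variance with equal means gives p = 1;
  with unequal means p = 0, flagged `degenerate`.
* The Mann-Whitney U test enumerates the exact null over pooled average
  ranks when $n_x + n_y \le 12$ (ties handled exactly; two-sided p is twice
  the smaller tail, clipped at 1 — identical samples give p = 1), and
  otherwise uses the normal approximation with tie and 0.5 continuity
  corrections.
* Spearman p values use the t approximation; cross-site families (A, P, E)
  are Bonferroni-adjusted with family size 3.
* Every stochastic operation takes an explicit integer seed; there is no
  hidden global state, and reruns of a pipeline config are bit-identical
  for deterministic stages.

## Problem sizes used in the checks

The packaged checks run on simulated studies of 20–30 transcripts of
100–300 codons at 10^5–2×10^6 footprints per library — small enough to run
on a laptop in minutes, deep enough that per-position counts (~100–200)
put counting noise well below the planted effects. Dwell-heterogeneity
levels for the CV analysis use codon multipliers drawn log-normally with
sigma 0, 0.3 and 0.6: sigma 0.3 is about the spread of published
codon-level dwell estimates, 0.6 a clearly pathological regime. The planted
differential-pausing study mirrors a 4-vs-4 animal design with 40 stalled
Pro positions at twice the baseline dwell.

Two designs deserve a note. The sign-pattern check perturbs the
Pro/Ala/Lys/Asn codons (x1.5 and x0.8), but a Spearman correlation between
planted multipliers and recovered occupancy is only meaningful when the
multipliers vary across the codon table: with 49 of 61 multipliers tied at
1, rank-tie algebra caps the attainable correlation well below 1 however
accurate the estimator, so rank recovery is scored on full-spectrum
log-normal dwell profiles. Rank recovery also uses the largest simulated
transcript pool (100 transcripts): the pooled occupancy estimator carries a
depth-independent distortion from which codons the abundant transcripts
happen to contain, and that structural term only averages out with a
realistic number of transcripts — real libraries pool thousands. Likewise, the paired "opposite perturbation"
experiment applies a dwell profile and its exact inverse on *different*
transcriptomes: the changes such perturbations induce are
transcriptome-wide (as they are in real gain- versus loss-of-function
comparisons), and using distinct transcript pools prevents shared
sequence-context effects from leaking an artifactual anti-correlation into
the upstream-site (E) control comparison.

A worked two-condition analysis, end to end:

```{r demo, eval = FALSE}
out <- tempfile("ribodyn-demo-")
res <- run_pipeline(demo_config(seed = 1), out)
res$differential$fold_change |>
  filter(codon %in% codons_for(c("P", "K")))
glance(res$disome$match)
autoplot(res$differential$positions)
```

## Known limitations

* Offsets are table-driven (15 nt for 28–30-nt reads); no metagene-based
  offset learning. Lengths outside the offset table never contribute to
  occupancy.
* The disome position convention and the peak rule are declared package
  choices, both config-exposed; peak counts are not comparable across
  tools without aligning those choices.
* TE is reported descriptively (density ratios); no GLM-based differential
  TE testing, and no empirical-Bayes variance moderation in the position
  tests — with 4 replicates per group the pooled t is adequate but not
  optimal.
* Gene-level integration matches ids as exact strings (optional alias
  mapping only); no ortholog handling.
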