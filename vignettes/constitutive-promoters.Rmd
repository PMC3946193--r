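---
title: "Locating constitutive sigma-70 promoters: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating constitutive sigma-70 promoters: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conpromo)
```

# The problem

Most annotated bacterial promoters are *inducible*: they fire only when a
transcription factor assists the RNA polymerase. A *constitutive*
promoter, by contrast, is recognized by the sigma-70 (RpoD) holoenzyme
alone. Identifying the constitutive set requires two ingredients this
package models end to end: a genome-wide map of where the holoenzyme
binds naked DNA in vitro, and a sequence criterion for what the
holoenzyme considers a promoter.

# Peak calling on tiling-array binding signal

Holoenzyme-bound genomic fragments (200–300 bp) hybridized to a tiling
array of 60-mer probes at 105-bp spacing produce a Cy5/Cy3 ratio track.
Two criteria define a binding peak in `call_peaks()`:

* **relative height** — probe ratio at least `cutoff_frac` (default 2%)
  of the genome-wide maximum ratio; an absolute threshold would be
  meaningless for a single-experiment ratio scale;
* **multi-probe support** — at least `min_probes` (default 2)
  consecutive probes above threshold. A genuinely bound ~300-bp fragment
  must span two 105-bp-spaced probes, so isolated single-probe spikes
  are treated as noise.

Peak extent is `[first probe start, last probe start + probe length)`;
the summit is the max-ratio probe (first wins ties). Adjacent runs
separated by one sub-threshold probe are *not* merged — no merge rule is
defensible without a fragment-level model. Zero Cy3 intensities are
floored at `1e-6` times the median Cy3 so degenerate probes yield large
finite ratios rather than division blowups. A relative threshold has one
documented pathological case: on a perfectly flat track every probe
passes its own 2% cutoff and the genome becomes a single run; real and
simulated tracks are peaked, so this arises only in contrived input.

# Spacer orientation classes and promoter-count bounds

Intergenic spacers are classified purely by flanking-gene strands:
type **A** (`-`,`+`) between divergent genes, type **B** (`+`,`+`) or
(`-`,`-`) between codirectional genes, type **C** (`+`,`-`) between
convergent genes. Promoters live upstream of the genes they drive, so a
peak-bearing A spacer holds one *or two* promoters, a B spacer exactly
one, and a C spacer none:

```{r}
count_constitutive_bounds(n_a = 177, n_b = 315)
```

Peak-to-feature assignment uses the summit position only; overlap
fractions would require the unmodeled fragment distribution. Summits
falling in coordinate gaps (between overlapping genes) are assigned to
the nearest feature and flagged. Spacers whose flanking genes share an
operon identifier are flagged `internal`; operon structure is always an
*input* (a curated table), never inferred.

# The consensus scoring scan

A promoter candidate is a (−35 hexamer, spacer, −10 hexamer) triple.
Scoring is pure match counting: one point per base identical to
`TTGACA` (−35) or `TATAAT` (−10), no gaps, `N` never matches, plus a
spacer bonus of +3/+2/+1 for 17/16,18/15,19 bp. The maximum is
6 + 6 + 3 = 15:

```{r}
score_promoter_string("TTGACA-17-TATAAT")
```

`scan_sequence()` enumerates every (−35 start, spacer ∈ 15..19) pair on
both strands by sliding 1 bp and retains candidates with both boxes at
≥ 4/6 matches and box-score sum ≥ 8. The source description of this
threshold ("more than 4 out of 6 … total score, higher than 8") is
ambiguous between inclusive and strict readings and its genome-scale
counts cannot adjudicate; the package defaults to the inclusive reading,
which matches the aggregate "higher than 4/6 agreement" statistic, and
exposes `scoring_scheme(strict = TRUE)` for the strict one. The
"best-match score of 12" of the two boxes is the box-score *maximum*,
not a filter: no hit is discarded for scoring below 12.

Minus-strand hits are found by scanning the reverse complement and
reported at the mirrored forward coordinate, so scanning is involutive
under reverse complement — a property the test suite checks, along with
hit-for-hit agreement with a brute-force enumeration of all
(−35, spacer, −10) triples.

When scanning per spacer, regions are extended 20 bp into each flanking
gene so a −35 box abutting a gene start is not lost. Ties in
`best_hit()` break by spacer length closest to 17, then larger −10
match, then position — ordering the biology considers stronger first.

# Conservation statistics and logos

`conservation_crosstab()` bins −35 and −10 match counts into
{6, 5, 4, ≤3} and reports the full 4×4 table rather than guessing any
coarser grouping; the headline aggregate is the fraction with ≥ 4/6 in
*both* boxes. `position_information()` computes per-column base
frequencies and Shannon information `R(i) = 2 − H(i)` bits with uniform
background and no small-sample correction — at the alignment sizes in
play (hundreds of sequences) the correction is negligible.

Percentages round half away from zero, matching the printed style of
the field's tables. One number is deliberately *not* matched: 203/669
is 30.3%, reported here as 30% even though it is sometimes printed as
31%; exact arithmetic wins. The H-NS accounting itself doubles the
type-A contribution (`2 × 63 + 77 = 203`) because H-NS filaments spread
cooperatively across a spacer and silence both promoters of a divergent
pair.

# Kinetics of open-complex formation

The single-round mixed-transcription assay preincubates polymerase with
template for time *t*, then adds substrates plus heparin so that only
already-formed open complexes transcribe once. The natural observable of
the irreversible two-step open-complex model is the saturating
exponential

$$y(t) = A\,(1 - e^{-kt}),$$

the minimal model consistent with a "final level" (parameter I = A, the
binding level) and a "time required to reach the plateau". Parameter II
is the reciprocal of that time; "plateau" is operational, so the package
defines it as reaching a configurable `plateau_frac` (default 0.95) of
A, giving

$$\text{parameter II} = \frac{k}{\ln\frac{1}{1-\text{plateau\_frac}}}.$$

Band intensities are first divided by the transcript's U count
(`u_correct()`), since incorporation labeling makes raw intensity
proportional to labeled residues, not moles of RNA.

Fitting uses Levenberg–Marquardt least squares with `A0 = max(signal)`
and `k0` from the earliest half-rise. Two degenerate regimes are
flagged, never coerced: if the first sample already sits at
`plateau_frac` of the maximum, no finite rate is identifiable and the
fit returns status `"saturated"` with parameter II at its grid-resolved
ceiling `1/min(times)`; non-convergent or non-positive fits return
`"failed"` with `NA` estimates. Within a set of single-base variant
templates, activities are normalized so the most active template is 1.

```{r}
fit <- fit_single_round(simulate_time_course(100, 0.5))
coef(fit)
parameter_II(fit)
```

# What the synthetic generator does and does not emulate

The generator reproduces the *structure* of the study's data: i.i.d.
genomes at a chosen GC content; gene pairs realizing each spacer class;
promoter motifs planted with exact match counts (mismatch positions
uniform over the six, substitute base uniform over the three
non-consensus bases — tie-free by construction); probe signal at the
study's geometry (60-mer probes, 105-bp spacing) with a triangular peak
kernel of 150-bp half-width reflecting the 200–300-bp fragment length;
multiplicative lognormal noise (ratios are positive); AT-enriched
silencer intervals; and time courses on the assay's grid (0.5, 1, 2.5,
5, 7.5, 10, 15 min).

It does **not** emulate: selection-cycle enrichment bias, the genomic
correlation structure of real intergenic sequence (real spacers are
AT-rich and repeat-laden), cross-hybridization, dye effects, or
operon-level transcription units beyond an annotation attribute.
Passing recovery tests therefore demonstrates the *algorithms* are
correct against known truth, not that the study's genome-scale counts
(2,701 peaks, 543 spacers) would be reproduced — those depend on raw
arrays that are not available, and the package makes no attempt at
them.

Default study conditions used by the test suite: recovery tests plant
promoters at 4–6/6 agreement with spacers 15–19 bp on both strands;
peak-recovery tracks use 10 peaks on a 20-kb genome separated by more
than twice the kernel half-width; kinetic recovery uses 200 replicates
at 5% multiplicative noise on the assay grid. Scanner–oracle agreement
is checked on one hundred 2-kb random sequences.

# Numerical choices

* Coordinates 0-based half-open internally; 1-based closed only at GFF3
  boundaries; BED stays 0-based half-open.
* Percent and mean rounding: half away from zero (2 dp for means,
  integers for percentages).
* Peak summit ties: first (leftmost) max-ratio probe.
* Circular genomes: an above-threshold run crossing the origin is
  stitched into one peak when the track is flagged circular.
* `N` bases score zero at their position in either box — never an
  error, so draft genomes scan cleanly.

# Known limitations

* The scan is a match-count model, not a PWM or energy model; extended
  −10 (TG) and UP elements are out of scope by design.
* Between-array normalization, dye-swap correction and replicate
  merging are not implemented (single-experiment design).
* Operon prediction, transcription-start-site mapping and regulatory
  network construction are out of scope; operon structure must be
  supplied.
* Parameter II is derived from the fitted curve, not read off raw
  points; with ≤ 7 time points a raw-point reading would be dominated
  by the grid.
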