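---
title: "Chip-SIP quantitative analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chip-SIP quantitative analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipsip)
```

## The measurement and the statistic

Chip-SIP identifies which microbial taxa incorporated a stable-isotope label
by hybridizing a community's rRNA to a phylogenetic microarray and imaging
the probe spots with NanoSIMS. Each spot yields secondary-ion counts for the
two nitrogen isotopologues of the CN⁻ ion (¹²C¹⁴N⁻ and ¹²C¹⁵N⁻), from which
the spot's ¹⁵N/¹⁴N ratio follows directly as the count quotient. Under
Poisson counting statistics its standard error is

$$\mathrm{SE}(r) = r\,\sqrt{\tfrac{1}{N_{15}} + \tfrac{1}{N_{14}}}.$$

Ratios are expressed as permil (‰) enrichment relative to the array's own
background,

$$\delta = \left(\frac{r}{r_\mathrm{bg}} - 1\right) \times 1000,$$

where $r_\mathrm{bg}$ is estimated from spots hybridized with unlabeled
control oligonucleotides on the same array. We aggregate control spots with
an $N_{14}$-count-weighted mean, the efficient pooled estimate under Poisson
noise (`estimate_background()` offers a median alternative for arrays with
suspect controls). Division by the background — rather than subtraction of a
background delta — was adopted as the correction convention; the two agree
to first order at these enrichment levels. Spots with zero ¹⁴N counts have
no defined ratio; they are excluded and every exclusion is counted in the
run report, never silently dropped.

A single spot's enrichment conflates incorporation with hybridization
strength: a weak, partially nonspecific spot dilutes the labeled signal.
The per-OTU statistic therefore regresses spot enrichment on spot
fluorescence across the OTU's probe set (~25 probes spanning a range of
melting temperatures). The ordinary-least-squares slope of

$$\delta_i = \beta_0 + \beta_1 f_i + \varepsilon_i$$

is the *hybridization-corrected enrichment* (HCE, ‰ per kflu; fluorescence
is in kilo-units of scanner signal). An intercept is always fitted: the
background correction can leave a small offset, and forcing the line through
the origin would bias the slope. Spots are unweighted by default — the
spot-level Poisson SEs are nearly homogeneous within a probe set, and the
residual variance is dominated by probe-specific hybridization effects the
counting model does not see.

## Enrichment calls

An OTU is called enriched on an array when both parts of a dual criterion
hold: the slope minus two standard errors is positive, and the slope's
t-test ($t = \beta_1/\mathrm{SE}$, two-sided, $df = n-2$) is significant at
an adjusted $p < 0.05$ after Benjamini–Hochberg correction. The BH family is
all OTUs fitted on the same array, since each array is an independent
hybridization of an independent RNA sample; `call_enrichment(family =
"global")` pools all arrays instead. Two-sided p-values are used because the
directional requirement is already enforced by the 2·SE margin. An OTU is
enriched in a condition when at least two of its three replicate arrays are
individually enriched; with other replicate counts the threshold generalizes
to $\lceil 2n/3 \rceil$, and missing replicates reduce $n$ rather than
counting against the OTU.

Fits require at least `min_spots = 5` usable spots (three residual degrees
of freedom) and positive fluorescence variance; with 25 designed probes per
OTU this only removes OTUs that largely failed hybridization. Degenerate
cases — an exact line (SE 0), an all-zero response — are resolved
deterministically (p of 0 or 1 respectively) rather than left to floating
noise.

## Treatment contrasts (ANCOVA)

Whether light regime or lifestyle changes a taxon's incorporation is tested
per OTU with the model

$$\delta = \beta_0 + \beta_1 f + \beta_2 g + \beta_3 (f \times g) +
\varepsilon,$$

where $g$ codes the two contrasted conditions. The interaction coefficient
$\beta_3$ is exactly the difference between the two groups' HCE slopes (the
crossed effect), and its two-sided t-test is the call; main effects are
reported but never drive calls. Spots from all replicates of a condition are
pooled into one group — the replicate arrays are exchangeable draws of the
same condition under the generator's assumptions; a replicate covariate is a
straightforward extension we deliberately left out of the default to keep
the tested model identical across contrasts. Four contrasts are run (light
vs dark within each fraction; attached vs free-living within each light
regime), each BH-adjusted across OTUs within the contrast, and significant
OTUs are assigned the direction of the larger slope. `tabulate_contrasts()`
reshapes the calls into the conventional five-column summary (higher in
light/dark among attached, higher in light among free-living, higher in
free-living within light and within dark); that layout has no
"higher-in-dark free-living" column, and no combined rule across columns is
invented.

## Family contributions

A family's share of community incorporation multiplies its mean HCE by its
16S read fraction. The mean is taken over all (OTU, replicate) HCE values in
the family — value-level averaging, so OTUs measured in more replicates
carry proportionally more information; `averaging = "otu_means"` gives the
OTU-balanced alternative. Negative family means are clipped to zero before
weighting (net incorporation cannot be negative; negative slopes are noise
around zero), and percentages are normalized over the targeted families
within each condition. Read fractions come from the OTU read-count table
pooled across a condition's replicates.

## What the generator emulates — and what it does not

`generate_experiment()` inverts the analysis model so every stage is
testable against known truth: fixed per-probe lognormal affinities (sdlog
0.5) emulate the designed spread of probe melting temperatures; spot
fluorescence is the affinity-scaled mean (5 kflu) with residual lognormal
noise (sdlog 0.2); expected enrichment is linear in fluorescence with the
OTU's true slope; and ion counts are independent Poisson draws partitioning
a per-spot CN⁻ budget according to the implied ratio. The default budget of
2×10⁶ counts per spot gives per-spot permil SEs near 12‰ and per-array HCE
SEs near 0.8 ‰/kflu under the default design — magnitudes chosen as
realistic for NanoSIMS analyses of 17 µm array spots; published Chip-SIP
work does not state per-spot totals, so this parameter is deliberately
configurable and flagged as unconstrained. Control spots are generated at
exactly the background ratio. The companion read table is a multinomial
draw (20,000 reads per sample) from a geometric family rank-abundance
profile. The experimental layout defaults to the study design: two
treatments × two size fractions × three replicate arrays.

The generator deliberately omits several features of real Chip-SIP data:
electron-multiplier dead time and quasi-simultaneous-arrival effects,
spatial structure within and between spots (ROI stitching happens upstream),
probe-sequence-dependent cross-hybridization (affinity is random, not
sequence-driven), and any coupling between an OTU's read abundance and its
fluorescence. Passing tests therefore demonstrate that the statistical
pipeline is correct under its own assumptions — Poisson counting, lognormal
hybridization heterogeneity, linear enrichment–fluorescence relations — not
that those assumptions hold on any particular instrument run. The optional
¹³C channel is generated with a higher, noisier background and is never used
in calls, mirroring its lower signal-to-noise in practice.

The generator's defaults are the study conditions for the package's
acceptance checks (false-positive-rate calibration at 200 null OTUs,
CI coverage at 10⁷ counts/spot and slope 5 ‰/kflu, ANCOVA power at a
planted slope gap of 3 ‰/kflu ≈ 5× the analytic interaction SE) and are not
tuned per test.

## Probe design screening

Candidate probes are reverse complements of windows (default 20–25 nt, step
1) that are identical across the OTU's target sequences; any position where
the targets disagree excludes every window overlapping it. Candidates are
screened against a non-target database with two rules: fewer than 5 perfect
matches, and no more than 100 matches at a two-substitution budget — counting
*sequences*, not sites, and matching both strands with ungapped Hamming
distance (the phrasing "base-pair changes" describes substitutions, and
oligo hybridization screening conventionally ignores indels). Melting
temperatures use the Wallace rule, $T_m = 4(G{+}C) + 2(A{+}T)$; a
nearest-neighbor model would change the numbers but not the selection logic,
which only uses Tm spread. The final set of up to 25 probes is chosen
greedily so the selected target positions are spread evenly along the region
(each of $k$ evenly spaced anchors claims the nearest unused candidate),
with ties preferring Tm diversity and resolved deterministically by
(start, sequence).

## Numerical and reproducibility notes

All randomness flows from a single integer seed per generator call;
identical (design, effects, seed) triples give byte-identical output tables,
and `run_pipeline()` writes no timestamps, so reruns are file-identical.
Off-target matching filters out alignments that hang over a subject's ends
(the underlying string matcher would otherwise count out-of-bounds positions
as mismatches): a partial overhang is not a hybridization site. The test
suite and acceptance checks run at deliberately compact problem sizes — 20
null experiments of 200 OTUs for FDR calibration, 100 seeds for CI coverage,
500 OTUs for interaction-p uniformity, 200 random probe/database pairs for
the Hamming oracle — sizes at which the Monte-Carlo error of each check is
well below the margin it asserts.

## Known limitations

Spot-level heteroscedasticity (higher-enrichment spots have slightly larger
permil SEs) is ignored by the unweighted fit; at realistic count depths the
effect on coverage is far below Monte-Carlo resolution. The consensus rule
treats replicates as exchangeable and ignores effect sizes. The ANCOVA pools
replicates without a replicate effect, so array-to-array offsets inflate the
residual rather than being absorbed. Family contributions assume 16S read
fractions proxy cell abundance and that the arrays' targeted families span
the incorporating community; the normalization is over targeted families
only.
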