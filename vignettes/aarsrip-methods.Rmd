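---
title: "Methods: RIP-seq enrichment, fRIP mapping and anticodon-mimic scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RIP-seq enrichment, fRIP mapping and anticodon-mimic scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aarsrip)
```

## The enrichment statistic

A RIP-seq experiment yields four libraries: Input and Bound for the
strain carrying the tagged protein, and Input and Bound for an untagged
strain processed identically, which measures what the affinity beads
capture nonspecifically. After normalizing each library to reads per
million (RPM), the per-gene RIP efficiency is

$$e(g) = \frac{\mathrm{RPM}_{\mathrm{Bound}}(g)}{\mathrm{RPM}_{\mathrm{Input}}(g)},$$

and the background-corrected efficiency is

$$c(g) = e_{\mathrm{tagged}}(g) - e_{\mathrm{untagged}}(g).$$

Dividing by the Input removes abundance and transcript-length effects;
subtracting the untagged efficiency removes bead affinity. The
subtraction is only meaningful under the assumption that nonspecific
capture is the same in both strains — which holds when the strains differ
only by the tag — and this assumption is exactly what the simulator
encodes (below), so the pipeline's recovery tests exercise the statistic
under its own model.

Two filters precede the ratio: transcripts with Input RPM below 15 are
removed (at such depths — 10–18 million reads per library — that is
roughly 150–270 reads, below which the ratio is dominated by counting
noise), as are noncoding RNAs, which co-purify with beads promiscuously.
The boundary is exclusive: RPM exactly 15 is retained. "Coverage" is
interpreted as RPM, not raw reads, since the filter must be comparable
across libraries of different depth. Genes failing the filter in either
the tagged or the untagged experiment are excluded from correction
(`mode = "intersection"`), because a difference with an unmeasured term
is undefined; `mode = "zero"` (missing untagged efficiency treated as 0)
is provided for sensitivity analysis.

Ranking is descending in $c$, with ties broken by larger Bound RPM and
then lexicographic gene id. Ties are vanishingly rare in real data, but a
total order makes every downstream artifact byte-reproducible.

## Target calling

The target rule is the boxplot-whisker convention: a gene is called when
$c(g) > Q_3 + k\,\mathrm{IQR}$ with $k = 1.5$ by default. The
distribution of $c$ is approximately symmetric around 0 with heavy ratio
tails, and the whisker rule is the natural reading of an
"outliers beyond 1.5 IQR" criterion attached to a box plot. Because the
phrase "above the average" can also be read mean-centred, a
`center_rule = "mean"` variant is provided; overlap counts between
target sets are sensitive to both the centring and the quartile
estimator, so the estimator (linear interpolation between order
statistics, `quantile` type 7) is fixed and recorded in the output.
With all values equal, IQR is 0 and the strict inequality returns an
empty set rather than everything.

A gene that is an IQR outlier of the *untagged* experiment's uncorrected
efficiency distribution binds beads, not protein; `untagged_outliers()`
computes that list so callers can exclude it from called sets. Venn
regions over several target sets are exact membership patterns — every
gene in the union lands in exactly one region — and are cross-checked in
the tests against brute-force enumeration over all $2^n$ patterns.

## fRIP peak mapping

Mild RNase fragmentation (~200-nt fragments) before pull-down means only
the fragment carrying the binding site co-purifies. With a panel of 14
amplicons of ~150 bp spaced evenly along the ORF, the per-fragment
Bound/(fragmented-)Input ratio cancels per-amplicon RT-PCR efficiency,
provided all intensities come from the same unsaturated PCR cycle
(`select_common_cycle()` picks the largest such cycle). Fragments whose
input intensity falls below 10% of the median input amplify too poorly
to interpret; they are flagged and excluded from peak calling rather
than silently reported — a quantitative version of what is otherwise a
judgement call on a gel image.

The peak is the best unflagged ratio (ties to the smaller index).
Partial cleavage leaves longer fragments that still contain the site, so
amplicons immediately upstream of the peak show a decaying echo; the
smear report is the contiguous run of fragments directly upstream whose
ratio is strictly above the median of the non-peak unflagged fragments.
The median is a deliberately coarse threshold: the smear is descriptive,
the peak is the call.

## Folding and mimic scanning

Windows are folded by base-pair maximization (Nussinov dynamic
programming) over Watson–Crick pairs plus GU wobble, with a minimum
hairpin loop of 3 nt. For 15-nt windows the quantity that matters
downstream is the pairing pattern — which bases form the stem and which
sit in the loop — not folding free energy, and pair maximization makes
the whole core exactly testable: `enumerate_structures()` exhaustively
lists every valid structure of a short sequence, and the test suite and
acceptance script verify over thousands of random sequences that the
DP's pair count equals the enumerated maximum. Thermodynamic ensembles,
suboptimal structures and pseudoknots are out of scope. The traceback is
canonical — prefer "last base unpaired", otherwise the smallest partner —
so co-optimal structures resolve deterministically and dot-brackets are
reproducible across machines.

A mimic hit is an anticodon triplet lying entirely inside a hairpin loop
whose closing stem has at least `min_stem = 2` contiguous pairs. Hits at
consecutive window starts for the same triplet occurrence are merged,
keeping the longest stem. Coordinates are 1-based from the A of the
start codon, and DNA input is transcribed automatically.

Mutation classification refolds: `anticodon_lost` is decided from
sequence alone (any mutated base inside the triplet); otherwise the
mutant window is refolded, and the element is `stem_disrupted` when the
triplet is no longer loop-presented or when fewer than 50%
(`stem_retention`) of the wild-type closing-stem pairs survive *as part
of the mutant's contiguous closing stack*. The contiguity requirement
matters: breaking one middle pair of a 5-bp stem leaves four pairs
somewhere in the structure but only a 2-bp stack actually closing the
loop, and it is the stack that presents the loop to a protein. The 50%
threshold is a configurable interpretation of a qualitative prediction.
Synonymy of mutations is checked against the standard genetic code;
the test suite verifies all 576 single-substitution codon cases against
an independent full-sequence translation.

## What the simulators emulate — and what they do not

`simulate_ripseq()` draws latent transcript abundances log-normal
(sdlog 1.2 across genes — a realistic bulk-mRNA spread under which the
vast majority of ~5,000 genes clear the 15-RPM input floor, matching the
near-complete transcriptome coverage such experiments report), then four
libraries of 12 million reads (within the typical 10–18 M range) as
negative binomial counts: Input expectations proportional to abundance;
Bound expectations proportional to abundance × bead-capture rate ×
(planted fold, tagged strain only). The dispersion convention is the
RNA-seq standard $\mathrm{var} = \mu + \alpha\mu^2$ with $\alpha = 0.1$
by default and $\alpha = 0$ giving exact Poisson. A single replicate per
condition is generated by default, matching the single-experiment design
the pipeline targets; the enrichment statistic uses no replicate-based
inference, which is also why no p-values are produced anywhere.

The generator shares one latent abundance vector and one capture rate
between tagged and untagged strains — precisely the assumption that
justifies the subtraction. What it does *not* model: transcript-length
bias, positional coverage, cross-linking efficiency differences between
transcripts, batch effects between libraries, or correlated
bead-affinity structure (rRNA/ncRNA families). Passing recovery tests
therefore show the statistic is implemented correctly and behaves as
designed under its own assumptions — not that those assumptions hold in
any particular real dataset.

`simulate_frip()` gives the site fragment unit signal, leaks
`carryover^d` into the $d$-th fragment upstream for $d \le$
`max_leak_depth` (default 2: with ~200-nt fragments and ~117-nt amplicon
spacing, a site-containing fragment rarely spans more than two upstream
windows), adds a flat off-site baseline (0.02) and multiplies bound and
input by per-amplicon PCR efficiency and log-normal noise
(sdlog 0.1; 0 gives the deterministic fixture panel).
`simulate_cds_with_mimic()` embeds a designed C/G-armed hairpin with the
triplet as its loop in pairing-poor (A-rich, G/U-free) flanks, so the
planted element is provably the optimal fold of any window covering it
and round-trip recovery is exact.

## Problem sizes and determinism

All randomness flows through explicit seed arguments; the generators
save and restore the caller's RNG state. The shipped test and acceptance
runs use 2,000-gene tables over 100 seeds for recovery, 5 × 2,000 genes
for null calibration, 200 tiling panels for fRIP recovery, and 1,000
random sequences of 5–18 nt against the enumeration oracle — sizes at
which every distributional claim is stable to the third seed digit while
the whole suite completes in well under a minute.

## Known limitations

* The enrichment statistic is a ratio of ratios with no shrinkage; genes
  near the input floor have noisy $c$, which is why the floor is a hard
  filter rather than a weight.
* Overlap (Venn) counts are sensitive to the quartile estimator and
  centring rule; both are recorded in outputs, and published counts can
  only be expected to reproduce under the estimator that produced them.
* Pair maximization ignores stacking energetics; a thermodynamically
  marginal hairpin with many pairs can outrank a stable one with fewer.
  For 15-nt windows this rarely changes loop/stem assignment, but hits
  should be read as structural candidates, not stability predictions.
* The fRIP smear rule is descriptive and threshold-based; it reports
  which upstream fragments are elevated, not a cleavage-probability
  model.
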