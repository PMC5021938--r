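---
title: "Tiered androgen response element analysis: models and methods"
author: "tierscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered androgen response element analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tierscan)
```

## The biological problem

The androgen receptor (AR) binds DNA as a homodimer at androgen
response elements (AREs): a palindromic pair of `AGAACA` hexamers in
inverted-repeat orientation, separated by a 3-bp spacer —
`AGAACAnnnTGTTCT`. Genome-wide, perfect AREs are vanishingly rare;
almost all functional AR binding happens at degenerate copies, and at
isolated half sites the receptor depends on cooperating transcription
factors (KLF, FOX, SREBF, MYC families) bound at short, preferred
distances. `tierscan` implements the computational core of this style
of analysis: exact-p-value motif scanning, a discrete degeneracy
grading (tiers), genomic annotation, spacing analysis, and the
region-density and expression-response statistics used to interpret
site catalogs.

## Scoring model and exact p-values

A motif model of width $W$ stores per-position probabilities
$p_{i,b}$ ($b \in \{A,C,G,T\}$, rows summing to 1, entries floored at
$10^{-10}$ so log-odds stay finite) and a zero-order background $q_b$.
A window $x$ scores $S(x) = \sum_i \log_2 (p_{i,x_i}/q_{x_i})$ bits.

P-values require the full null distribution of $S$ when $x$ is drawn
i.i.d. from $q$. Following the standard dynamic-programming approach,
per-position scores are discretized to integers and the position-wise
score atoms (weighted by $q$) are convolved. Two numerical choices:

* **Common grid.** Per-column steps cannot be summed across positions,
  so a single step $\varepsilon = \max_i(\mathrm{range}_i)/1000$ is
  used — the widest column gets 1000 levels, and column scores are
  `round()`ed onto that grid. A granularity coarse enough to collapse
  all distinct scores of some column triggers a warning, not an error.
* **Consistency.** The scanner computes window scores by summing the
  *same* integer column scores, so a reported p-value is exactly the
  survival function at the window's atom. The DP distribution is
  verified against exhaustive enumeration of all $4^W$ windows for
  $W \le 8$ (total variation $< 10^{-9}$), and the ideal full-site
  model's best-match p-value equals $0.25^{12}$ analytically.

Both strands are scanned. The default background (`"auto"`) is the
strand-symmetrized composition of the scanned sequences, so one null
distribution serves both strands; explicit or uniform backgrounds are
config options, and asymmetric backgrounds get a separate minus-strand
DP. For self-reverse-complementary models (the full-site ARE) the minus
strand would duplicate every plus-strand hit, so only the plus strand
is reported. Windows containing non-ACGT letters (masked repeats) are
skipped, not scored.

## Tier classification

Tier assignment is by Hamming mismatch count against the canonical
consensus over the 12 informative positions (spacer ignored): $m$
mismatches $\to$ tier $m+1$ for $m \le 3$; tier 5 is an exact, isolated
hexamer. This is deliberately *not* a PSSM-score ranking — the tiers
are defined as "k bp off perfect", and a score rank would depend on
matrix values. PSSM scanning remains available as a cross-check: with
a uniform-penalty consensus matrix the two routes select identical
window sets.

Design choices where the definition leaves room:

* **Lowest-tier resolution.** Any base-pair overlap between a hexamer
  and an accepted tier 1–4 window absorbs the hexamer into the full
  site (the strictest reading of "lowest tier possible"). Overlapping
  full-site windows are resolved greedily in (tier, start) order —
  lower tier wins, ties go leftmost — so every genomic position
  contributes to at most one reported site.
* **Mismatch placement.** By default the up-to-3 mismatches may split
  across both hexamers; `mismatches_one_hexamer = TRUE` restricts them
  to a single hexamer (one perfect half), reflecting the observation
  that degenerate sites usually retain one intact half site.
* **Half sites are exact.** Degenerate hexamers are never tier 5;
  widening half-site degeneracy floods the genome without adding
  information.

Exhaustive enumeration of all $4^{12}$ informative cores gives
mismatch-class sizes $\binom{12}{m}3^m$ = 1 / 36 / 594 / 5940, and the
most degenerate full site (tier 4) still agrees with the consensus at
9 of the 15 window positions — the spacer carries no consensus letter
and never counts as agreement.

## Genomic annotation

Each site is represented by its midpoint and assigned exactly one
category by strand-aware priority
TSS > TTS > 5'UTR > 3'UTR > exon > intron > non-coding > intergenic.
Defaults (config keys): promoter window −1000/+100 bp around the TSS,
terminator window −100/+1000 bp around the TTS, both in transcript
orientation. A second, wider ±5000 bp end-flank does *not* define a
category; it only extends gene association for nearest-gene assignment,
which otherwise uses distance-to-TSS capped at 100 kb. Where two
definitions of the promoter window could be read from the source
material, the narrow window defines the category and the wide flank
defines association — both are exposed as parameters.

## Cooperation (spaced-motif) analysis

For each anchor ARE the best-scoring secondary-motif occurrence with an
edge-to-edge gap in $[0, 160)$ bp is located (gap 0 = adjacent;
overlapping matches are not counted; center-to-center gaps are a config
option). Each anchor contributes at most one count — one bin, one side
— preventing long flanks from inflating the histogram. Sides are
oriented by the anchor strand (downstream = 3'). Bins are 5 bp.

Each (side, bin) cell is tested with an upper-tail binomial test
against uniform placement over the bins of one side (success
probability $1/32$ at the defaults), Bonferroni-corrected over
bins × sides. This null is a package choice — the source analyses show
spacing peaks without specifying a null — and it is calibrated: with
uniformly placed gaps, ≥95% of seeded simulations produce no
significant bin at corrected $\alpha = 0.05$, and a bin holding 30% of
500 anchors is detected essentially always. The default secondary-hit
threshold is $p < 10^{-4}$.

## Density and hit-rate statistics

**Region density.** Sites are assigned to a merged region set by
midpoint containment; densities are hits/Mbp inside versus the covered
complement. The test is an exact two-sided binomial, conditional on the
total count, with success probability proportional to region length —
the source analysis reports a p-value without naming its test, so this
package states its own. A permutation cross-check (uniform midpoint
shuffling) gives equivalent answers on synthetic data.

**Tier hit rate.** A gene "has" tier $k$ if at least one tier-$k$ site
is associated with it; by default tiers count independently per gene
(a config flag restricts each gene to its best tier). The hit rate is
the fraction of tier-$k$ genes confirmed as differentially expressed
(either direction). The trend statistic is a Spearman rank correlation
of hit rate against tier index (exact p at $n = 5$ tiers), plus a
proportion trend test over the per-tier counts.

## The synthetic world

The generators state a fixed world; they are not tuned to tests:

* Background is zero-order with default composition 0.25 each —
  matching the null the p-values assume. Real genomes are not
  zero-order (GC-rich spacers, repeats, CpG structure), so a green test
  establishes correctness of the machinery, not genomic realism.
* Planted full sites are the consensus with exactly tier−1 informative
  positions mutated (spacer random); planting *verifies* that no
  overlapping window classifies to an equal or lower tier, re-drawing
  otherwise, so classifier recovery of planted truth is provable, with
  surplus detections only at the analytic background rate
  ($(L-14)\cdot 6571/4^{12}$ full sites and $2(L-5)/4^6$ half sites —
  single strand factors, because the palindromic Hamming classifier
  covers both strands in one pass).
* Half-site planting requires every overlapping 15-bp frame to carry
  ≥4 informative mismatches (the complementary half is "destroyed").
* Sites keep a ≥30 bp mutual gap and a 200 bp edge margin, so
  cooperation analysis always sees full ±160 bp context.
* Gene models are non-overlapping, multi-exon, both strands, ~90%
  coding with genuine UTRs; response tables mark ARE-bearing genes DE
  with a per-tier probability, direction uniform.

Everything is a pure function of (parameters, seed), and generators
restore the caller's RNG state.

## Conventions and limitations

* Coordinates are 1-based inclusive throughout the R API (the natural
  convention for R and GRanges); BED output is converted to 0-based
  half-open at the I/O boundary, and every output file carries a header
  comment naming its convention. BED score columns are
  $\min(1000, \mathrm{round}(-10\log_{10}p))$.
* Config files are JSON (flat keys, unknown keys rejected); YAML is not
  supported.
* Fixed 3-bp spacer only: variable-spacer or direct-repeat dihexamers
  are out of scope, as are first-order backgrounds, q-value/FDR across
  scan hits, de-novo motif discovery, peak calling, and copy-number
  calling (region sets are consumed as BED).
* Reference matrices deposited in motif databases are not reproduced;
  equivalent models are rebuilt from consensus strings or user site
  collections, with thresholds (e.g. $4.94\times10^{-5}$) exposed as
  configuration defaults rather than claimed as numerically identical.
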