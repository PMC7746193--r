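---
title: "waldscan: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{waldscan: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waldscan)
```

## The problem

Clinical variant databases only show the variants that produced a viable,
diagnosable patient. For a multidomain protein this creates a
survivorship bias: a domain in which most missense changes are
embryonic-lethal or otherwise never ascertained will look *depleted* of
variants, while a tolerant domain accumulates them and is then,
circularly, blamed for the disease. `waldscan` assembles four mutually
independent lines of evidence that do not rely on patient variants —
population-level variant rates, interspecies conservation, predicted
per-substitution pathogenicity, and codon-level mutational opportunity —
and asks which domain behaves like the part of Wald's aircraft that never
came back: the **Wald's domain**, characterised by a lower O/E variant
ratio, higher conservation, more disease-propensity hotspots and lower
dN/dS.

## Conservation model

Let column $j$ of the ortholog MSA map to reference residue $i$ (columns
where the reference is gapped map to nothing). With per-sequence weights
$w_k$ and weighted amino-acid frequencies $p_a$ in the column (gaps and
`X` excluded, weights renormalised), the score is

$$s_i = 1 - \frac{H_i}{\ln 20}, \qquad
  H_i = -\sum_a p_a \ln p_a .$$

Weights are Henikoff position-based: each column contributes
$1/(r\,s_a)$ to every sequence carrying residue $a$, with $r$ the number
of distinct residues in the column and $s_a$ the number of carriers;
weights are normalised to sum to one. This damps redundant taxon
sampling (e.g. an alignment that is half mammals) without requiring a
tree.

Scores are binned into **nine equal-width grades** spanning the observed
score range, grade 9 the most conserved; a constant profile gets the
middle grade 5. This is a deliberate, documented approximation to
ConSurf's empirical-Bayes evolutionary rates: it preserves the 1–9 grade
semantics that downstream tests consume, runs at desk scale, and needs
no phylogeny — but it is *not* ConSurf, and grade-for-grade concordance
with ConSurf output is not promised. Columns with more than
`max_gap_fraction` (default 0.5) gap/`X` cells are left ungraded and are
excluded from grade distributions and tests.

## Tolerance (dN/dS) model

For codon $i$, exhaustive enumeration of its nine single-nucleotide
substitutions gives the *possible* missense ($M_i$), synonymous ($S_i$)
and nonsense counts (they sum to 9 for every sense codon). Observed
counts $m_i$, $s_i$ are presence counts of distinct SNV records —
allele counts are ignored, because the analysis counts *variants*, not
alleles — and nonsense SNVs are excluded from both sides. With window
half-width $h$ (window $= 2h+1$, truncated at the protein ends) and
pseudocount $c$:

$$\mathrm{dN/dS}_i =
  \frac{(\sum_{|j-i|\le h} m_j + c) / (\sum_{|j-i|\le h} s_j + c)}
       {\sum_{|j-i|\le h} M_j / \sum_{|j-i|\le h} S_j}.$$

Defaults: window 21 codons, $c = 0.5$. The window width is a smoothing
choice in the spirit of sliding-window tolerance landscapes; whether the
published per-position values were windowed or raw is not stated by
their source, so both are exposed (`window = 1` gives raw values).

**Where the tests run.** Window smoothing induces strong serial
correlation between neighbouring positions, which the
Kolmogorov–Smirnov and Mann–Whitney tests do not survive (their
effective sample size collapses and type-I error explodes). The report
therefore computes the **inference** (KS, MWU between domains) on raw
per-codon values, and uses the smoothed landscape for the exported
per-position values and the per-domain mean dN/dS summaries (the mean is
essentially unaffected by smoothing). This was decided a priori on
statistical grounds and is verified by the type-I calibration criterion.

The pseudocount on both observed counts biases the ratio slightly upward
when synonymous coverage is thin (Jensen effect of $1/(s+c)$, ~3–5% at
the default simulation depth); the neutral-calibration test bounds the
net bias: the grand mean on neutral simulations must lie in
$[0.85, 1.15]$.

## Disease-propensity hotspots

A position's DPS is the arithmetic mean of its 19 substitution scores
(the reference amino acid is excluded). The **critical value** is a
percentile of the per-position means over the *whole protein* (default
95th, linear interpolation between order statistics; nearest-rank
offered), matching the single critical line of the published landscape
plots. A **hotspot** is a maximal run of consecutive positions whose
mean is *strictly greater* than the critical value, kept if the run has
at least `min_run` positions. `min_run` defaults to 3 — the smallest
hotspot reported in the motivating study spans three residues — and
"strictly above" follows its "over the critical value" reading; whether
a run of 2 should count is unstated there, so the choice is exposed as a
parameter.

## Domain comparison and verdict

* Grade distributions: Pearson homogeneity χ² on the 2 × 9 grade table,
  all-zero grade columns dropped, no continuity correction.
* Missense counts: goodness-of-fit χ², $\sum (O-E)^2/E$, df $=k-1$. The
  expectation model is selectable: `equal` (the default — it reproduces
  the published 11.449 on counts 193/132 exactly, so that is evidently
  the model used there), `length`-proportional, or `possible`-SNV
  proportional (the correct null when opportunity differs; used in the
  calibration tests).
* DPS distributions: two-sample KS, full and "> 50" subsets (whether the
  published D used all means or the subset is ambiguous, so both are
  reported).
* dN/dS: KS and Mann–Whitney. The MWU statistic follows the
  first-sample-greater pair-count convention
  $W = \#\{x_i > y_j\} + \tfrac12\#\{x_i = y_j\}$ with tie-corrected
  two-sided normal p, no continuity correction. Published W magnitudes
  from unstated software conventions are therefore only approximately
  comparable.
* All p-values are asymptotic, two-sided and unadjusted (the motivating
  analysis applies no multiplicity correction; the report lists raw
  p-values).

**Verdict.** Four criteria — lower O/E, higher mean grade, more hotspot
positions, lower mean dN/dS — one point each, exact ties half a point.
A domain winning ≥ 3 is the Wald's domain; a 2–2 split is
"inconclusive".

## Synthetic data: the stated world

The generator's defaults *are* the emulated setting, chosen once:

| parameter | default | why |
|---|---|---|
| protein length | 521 aa | PNKP-sized |
| domains | 146–337, 341–521 | published boundaries (192/181 residues) |
| taxa | 30, star phylogeny | desk-scale ortholog panel |
| divergences | 0.05–0.95, mean 0.5 | primate-to-fish-like spread |
| site rates | Gamma(1) × per-domain ρ (0.5 / 1.5) | standard rate heterogeneity; conserved vs fast domain |
| SNV inclusion π_s | 0.3 | gnomAD-like fraction of possible synonymous SNVs observed |
| missense retention f | 0.2 / 0.8 | strong vs weak purifying selection |
| nonsense retention | 0.1 | strongly selected |
| allele counts | 1 + Geometric(0.5) | heavy-tailed spectrum (downstream uses presence only) |
| score coupling | logistic, β₀ = −2, β₁ = 4, noise sd 8 | conserved sites score ≈ 88, fast sites ≈ 12, per-substitution scatter |
| planted stretches | 170–177, 217–219, 259–261, 377–379, boost 40 | mirror the published hotspot coordinates |

Randomness is a single seed with deterministic per-component sub-seeds,
so regenerating one component never perturbs another, and a bundle is
byte-identical across reruns.

What the generator does **not** emulate: indel evolution (gapless by
default; a gap-injection rate exists), codon usage bias, CpG/trinucleotide
mutation-rate structure, coalescent population structure, and tree
topology beyond a star. A green test therefore establishes that the
pipeline recovers planted domain asymmetries under idealised neutrality
and selection — not that it reproduces any specific published,
server-derived statistic (those inputs — ConSurf rates, SuSPect scores,
MetaDome landscapes, BLAST identities — are not public as data).

## Numerical choices and degenerate inputs

* Entropy in natural log, normalised by $\ln 20$; zero-residue columns
  and over-gapped columns are `NA` and excluded downstream.
* Percentiles by linear interpolation (quantile type 7).
* Windows truncate at protein ends (no padding).
* `M = 0` or `S = 0` in a window yields `NA` dN/dS, reported with a
  count, and such positions are omitted from domain samples.
* Multi-allelic sites are separate records, each counted once; variant
  rows whose reference allele mismatches the CDS are dropped with a
  logged count.
* A single terminal stop codon in the CDS is allowed and stripped;
  internal stops are an error.
* Exact ties in verdict criteria score half a point each (relevant in
  null simulations where both domains may have zero hotspot positions).

## Known limitations

* The conservation score is alignment-column entropy, not an
  evolutionary-rate model; it is blind to tree structure and saturation
  at deep divergences.
* The equal-expectation variant-count test ignores domain length and
  opportunity; it is the published convention, not the best null (use
  `gof_model = "possible"` for the opportunity-corrected test).
* Asymptotic p-values throughout; KS p-values are conservative under
  heavy ties (raw dN/dS values are discrete at low coverage).
* The FHA domain of the motivating protein has no published boundaries
  and is left to user annotation.
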