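# waldscan

Is a protein domain mutation-rich because it matters little — or does it
only *look* tolerant because the variants that would have told us
otherwise never made it into a patient database? `waldscan` asks this
survivorship-bias question for multidomain proteins. Named after Abraham
Wald's analysis of returning aircraft, it operationalises a **"Wald's
domain"** as the domain whose damage is mostly invisible: the one with

1. a **lower observed/expected (O/E) missense ratio** in population data,
2. a **higher degree of sequence conservation**,
3. **more disease-propensity hotspots**, and
4. **lower dN/dS** mutational tolerance.

The motivating case is the DNA-repair enzyme PNKP (521 aa; phosphatase
domain at residues 146–337, kinase domain at 341–521), where clinical
variants cluster in the kinase domain yet multiple lines of evidence mark
the phosphatase domain as the less tolerant one.

## What it computes

For a reference protein with a domain annotation, the package takes four
inputs — an ortholog protein MSA (FASTA), the in-frame coding sequence
(FASTA), a gnomAD-style SNV table (TSV: `cds_pos`, `ref_nt`, `alt_nt`,
`allele_count`, `hom_count`), and a saturation-mutagenesis score matrix
(TSV, 0–100 per substitution) — and produces:

- **Conservation profile** — Henikoff position-weighted Shannon-entropy
  score per residue, `s_i = 1 − H_i/ln 20`, binned into ConSurf-style
  grades 1–9 (9 = most conserved); per-domain grade distributions are
  compared with a homogeneity χ².
- **Tolerance landscape** — per-residue
  `dN/dS_i = ((m_i + c)/(s_i + c)) / (M_i/S_i)`, where `m, s` are
  observed missense/synonymous SNVs and `M, S` the *possible*
  missense/synonymous SNVs from exhaustive codon enumeration, summed over
  a sliding window (default 21 codons, pseudocount c = 0.5). Domains are
  compared with Kolmogorov–Smirnov and Mann–Whitney tests on the raw
  (window 1) values.
- **Disease-propensity hotspots** — per-position mean of the 19
  substitution scores (DPS); the critical value is the 95th percentile of
  the means; hotspots are maximal runs of ≥ 3 consecutive positions
  strictly above it.
- **Variant-rate test** — per-domain observed missense counts against
  equal, length-proportional or opportunity-proportional expectations
  (χ² goodness of fit), plus O/E ratios.
- **Verdict** — the four criteria above, 3-of-4 majority (ties score ½
  each), otherwise "inconclusive".

A synthetic-data generator (`synthetic_config()`, `generate_dataset()`)
produces complete input bundles with known ground truth — gamma site-rate
heterogeneity scaled per domain, a star phylogeny of orthologs, per-domain
purifying selection on missense SNVs, and score matrices coupled to
conservation with planted functional stretches — used throughout the test
suite for calibration and parameter recovery.

## Worked example

```r
library(waldscan)

cfg <- synthetic_config(seed = 42)   # PNKP-shaped two-domain protein
ds  <- simulate_dataset(cfg)
rep <- analyze_dataset(ds$aln, ds$cds, ds$variants, ds$smat, ds$annot,
                       "phosphatase", "kinase")
print(rep)
```

```
Domain comparison: phosphatase vs kinase 
  phosphatase    len 192  mean grade 6.755  mean dN/dS 0.275  O/E 0.0702  hotspot aa 3 
  kinase         len 181  mean grade 4.906  mean dN/dS 0.819  O/E 0.2536  hotspot aa 0 
  grade homogeneity chi2 = 65.045 (df 8, p = 4.73e-11)
  missense count GOF chi2 = 122.980 (df 1, p = 1.41e-28, model equal)
  DPS KS D = 0.351 (p = 2.25e-10); >cutoff D = 0.165 (p = 0.199)
  dN/dS KS D = 0.367 (p = 2.97e-10); MWU W = 7246.0 (p = 7.74e-15)
  Wald's domain: phosphatase (4.0 - 0.0)
```

The generator planted strong purifying selection (missense retention
0.2 vs 0.8) and slow evolution (rate multiplier 0.5 vs 1.5) in the
phosphatase-like domain; the report recovers all four signatures — lower
O/E (0.070 vs 0.254), higher mean conservation grade (6.8 vs 4.9), more
hotspot positions (3 vs 0) and lower mean dN/dS (0.27 vs 0.82) — and
names it the Wald's domain 4–0.

The same run from the shell:

```sh
Rscript inst/cli/waldscan.R simulate --seed 42 --out sim42
Rscript inst/cli/waldscan.R run \
    --msa sim42/msa.fasta --cds sim42/cds.fasta \
    --variants sim42/variants.tsv --scores sim42/scores.tsv \
    --domains sim42/domains.json --out out42
```

writes `profile.tsv`, `landscape.tsv`, `hotspots.tsv`, `report.json` and
`summary.txt` into `out42/` (byte-identical across reruns).

## Documentation

See the methods vignette (`vignettes/waldscan-methods.Rmd`) for the model,
its assumptions, every tunable parameter, and known limitations.
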