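---
title: "Methylome-domain profiling by in-silico McrBC digestion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylome-domain profiling by in-silico McrBC digestion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcrbcarray)
```

# The assay model

The package models a restriction-based methylome mapping assay. McrBC cleaves
DNA containing methylcytosine; its recognition element is a *half-site* — a
purine followed by a methylated cytosine (Pu-mC) — and cleavage requires two
half-sites separated by roughly 40–3000 bp. In a heavily methylated genome
half-sites are dense, nearly every consecutive pair is in the eligible
spacing window, and the DNA is digested to sub-kilobase fragments. A
megabase-scale hypomethylated domain contributes almost no half-sites and
survives as high-molecular-weight DNA. Gel recovery of the large resistant
fraction, two-channel hybridization against undigested genomic DNA, and a
per-probe fold change (resistant / total) therefore read out hypomethylation
as fold change > 1; the stringent calls used throughout are **> 2 for
hypomethylation and < 0.5 for hypermethylation, both strict**, with boundary
values neutral. A fully CpG-methylated control (SssI methylase applied
in vitro) destroys the resistant fraction and is the assay's specificity
check.

The pipeline stages mirror the assay: `simulate_genome()` →
`apply_sssi()` (control arm) → `find_half_sites()`/`mcrbc_digest()` →
`size_select()` → `make_probe_grid()`/`simulate_signals()`/
`normalize_probes()` → `classify_probes()`/`segment_domains()`/
`summarize_chromosomes()` → density tracks and mark/expression correlation →
bisulfite validation → optional two-condition differential stage.

# Digestion: numerical choices

* **Complete, deterministic digestion.** Every eligible consecutive
  half-site pair produces exactly one cut. The assay's gel shows digestion
  to completion; a stochastic efficiency parameter would add a nuisance
  dimension without changing any domain-level conclusion.
* **Cut position = integer midpoint** of the pair (`(p1 + p2) %/% 2`). The
  real enzyme cuts distributively ~30 bp from a half-site; at the ≥ kb
  resolution of array probes the difference is invisible, and the midpoint
  is reproducible. One consequence worth knowing: inserting a half-site
  inside an eligible pair whose gap is in [40, 80) bp can split it into two
  ineligible gaps and *remove* a cut, so "more methylation ⇒ max fragment
  never grows" is a strong generic tendency, not a theorem; the randomized
  perturbation tests probe the generic behaviour.
* **`meth_call_threshold` = 0.5** converts a probabilistic `meth_state` to a
  binary site call before half-site scanning. The generator emits binary
  states, so this threshold only matters for user-constructed models.
* **`size_threshold` = 20,000 bp** stands in for "near the gel top"; no
  number exists for the wet protocol, and the value is exposed everywhere
  (function argument, `--size-threshold` CLI flag). At the simulated
  background cut density (~1 cut / 170 bp) a 20 kb resistant background
  fragment is essentially impossible, so specificity is insensitive to the
  choice; sensitivity at domain *edges* is not (see Limitations).

# Array readout

`signal_total` is 1 per probe (uniform genomic representation);
`signal_resistant` is the fraction of the 60 bp probe footprint covered by
size-selected resistant fragments, floored at ε = 1e−3 (so log ratios stay
finite on zero coverage), times multiplicative lognormal noise whose log-sd
is `noise_sd` (default 0.2 — a typical two-channel array CV). Normalization
rescales the resistant channel so its median matches the total channel's,
the reproducible stand-in for the scanner software's intensity
normalization; it is idempotent and invariant to rescaling either channel.
Because most probes sit in digested background, the median maps background
coverage to fold change ≈ 1 and covered domains to large fold changes, which
is exactly the regime the > 2 / < 0.5 thresholds assume. With `noise_sd = 0`
the readout is fully deterministic.

Segmentation is deliberately threshold-based, not an HMM or CBS: runs of
same-label probes are merged while tolerating up to `max_gap = 2`
interleaved neutral probes (an opposite-label probe always breaks a run),
and runs with fewer than `min_probes = 5` supporting probes are dropped.
The defaults let megabase domains survive sparse noisy probes (a 0.5 Mb
domain spans ~100 probes at 5 kb spacing) while isolated noisy probes
(P(fold change > 2 | background, noise_sd 0.2) ≈ 3e−4) cannot seed a
domain.

# The synthetic world

The generator's defaults state the world the test-suite operates in:

| parameter | default | why |
|---|---|---|
| `genome_length` | 10 Mb | desk-scale chromosome; ~2000 probes at 5 kb |
| `gc_content` | 0.41 | human-like base composition |
| `cpg_rate_high` | 0.01 /bp | ~1 CpG per 100 bp, genome-average density |
| `cpg_rate_low` | 0.001 /bp | deep CpG-poor gene-desert tracts; see below |
| `n_hypo_domains`, length | 3 × 0.5–1 Mb | megabase-scale domains |
| `background_meth` | 0.85 | typical bulk CpG methylation level |
| `domain_meth` | 0.05 | nearly, not perfectly, demethylated domains |
| `expression_coupling` | (+2, −2) | strong, sign-definite mark coupling |
| `noise_sd` | 0.2 | multiplicative array noise (log-sd) |

Methylation is drawn **per CpG as an independent Bernoulli** with the
region's probability, giving binary (clonal, all-or-none) states — the
domain character that bisulfite validation of such domains reports. The
bisulfite module, by contrast, treats `meth_state` as a per-molecule
probability, so intermediate (population-mixture) states can be constructed
and are sampled per read; the generator's 0/1 states behave clonally under
it. CpG-poor tracts are created by construction *as* the hypo domains
(accidental CpGs from the iid background are removed and CpGs injected at
region-specific rates, so density is exactly the dialled variable); with
`cpg_rate_low = 0.001` and `domain_meth = 0.05`, methylated CpGs inside a
domain are ~20 kb apart and eligible pairs rare (interior cut rate ≈
7e−6/bp), so domains are resistant essentially end to end — chosen a priori
from this arithmetic, and not revisited afterwards.

Genes (lognormal lengths 2–200 kb) are placed with 0.3 acceptance inside
domains (gene-poor deserts). Promoters are 1 kb upstream to 500 bp
downstream of the TSS, strand-aware. Genes with TSS outside domains get
promoter CpGs redrawn at `domain_meth` (the active promoter-hypo /
body-hyper pattern); genes inside domains get the inverse. H3K9Ac and
H3K27Me3 are 50 kb window tracks built from the same domain-overlap
fraction with opposite signs plus independent noise — anti-correlated by
construction — and log-expression is `2·K9Ac − 2·K27Me3 + N(0, 0.5)`,
exponentiated. A green correlation-sign test therefore establishes that the
estimators recover the generator's stated couplings, not that real
chromatin behaves this way.

**What the generator does not emulate:** real sequence composition (repeats,
Alu elements, CpG islands as promoter features), dye bias or spatial array
artifacts, probe affinity differences, partial digestion, population
heterogeneity of methylation within a sample, read mapping (bisulfite reads
are born aligned), and sequencing errors.

# Tracks, correlation and patterns

CpG density per 50 kb window is `log10(n) + 2`; log base 10 is chosen so the
+2 offset yields readable non-negative values, and **zero-CpG windows score
0 with a flag** rather than −∞. Correlations are Pearson with two-sided
t-distribution p-values; zero-variance inputs return a flagged undefined
result instead of an error. Gene mark scores are length-weighted means of
overlapping windows (equal to per-bp averaging of the step track); the
mark–expression correlation uses the WHOLE region (promoter ∪ gene span) by
default, with PROMOTER and BODY selectable — BODY excludes the 500 bp of
gene interior covered by the promoter so the promoter/body methylation
contrast is clean. Pattern thresholds sit at 0.5 mean methylation for both
regions; genes lacking CpGs in either region are flagged missing and
labelled MIXED, never an exception.

# Differential stage

The differential track is `control fold change / treated fold change`
per probe — above 1 means methylation was gained after treatment (resistant
signal dropped). Smoothing is a centered moving average over 25 probes with
shrinking edge windows; 25 probes ≈ 125 kb at the default spacing, below
domain scale but wide enough to average probe noise. En-bloc verdicts use a
±0.2 band around 1 on the domain's mean smoothed ratio, with an agreement
score (fraction of probes individually beyond the band) measuring
blockiness. A "differential site" is a probe with discordant hypo/hyper
labels between conditions; swapping conditions inverts the track exactly
(x → 1/x) and mirrors the site directions, which the tests assert as an
algebraic identity.

# Determinism and seeds

Every stochastic stage takes a seed; `simulate_genome()` derives
per-chromosome and per-stage child seeds from the single configured seed
with a fixed affine map, so identical configurations are byte-identical and
no stage reads system entropy. Functions that take seeds restore the
caller's RNG state.

# Known limitations

* **Boundary resolution.** Domain edges are recovered to within a few probe
  spacings on average, but a residual methylated CpG near a domain edge
  (expected every ~20 kb at `domain_meth = 0.05`) occasionally chops the
  edge into sub-threshold fragments that size selection discards, shifting
  the called boundary 10–25 kb inward. This is intrinsic to the
  assay-plus-thresholds model, not to the implementation (the digestion is
  oracle-exact); base-level Jaccard stays ≥ 0.97 in the 10-seed recovery
  tests while the strict 2-probe-spacing boundary bound fails on occasional
  seeds.
* **"Fully demethylated" vs `domain_meth = 0.05`.** With binary per-CpG
  states, ~5% of domain CpGs are truly methylated and bisulfite-call at
  fraction 1.0; a random sample of 39 domain CpGs is therefore all-negative
  only with probability 0.95^39 ≈ 0.14. A validation design that expects
  39/39 unmethylated sites implies a domain methylation level well below
  0.05.
* Threshold segmentation cannot separate abutting domains of the same label
  and splits domains across long under-covered gaps (> `max_gap` probes).
* `hypo_to_hyper_ratio` is `Inf`/`NaN`-sentinelled and flagged when the
  hypermethylated count is zero; downstream consumers must honour the flag.
* The CLI's real-data mode consumes FASTA + methylation bedGraph (and probe
  TSVs produced externally); it does not parse vendor array formats.
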