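---
title: "Quantifying site-specific pseudouridylation from targeted amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying site-specific pseudouridylation from targeted amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psiquant)
```

## The measurement model

Pseudouridine (Ψ) is a rotational isomer of uridine and base-pairs like it,
so sequencing alone cannot see it. psiquant quantifies Ψ stoichiometry at a
pre-chosen site through chemistry-induced reverse-transcription signatures.

**CMC amplicons.** CMC forms an adduct at Ψ; under Mn²⁺ reverse
transcription the adduct makes the polymerase skip the modified base, so
the cDNA of a modified molecule carries a 1-nt deletion at the site. The
amplicon around the site is sequenced with a 10-mer UMI per molecule.
Quantification proceeds in fixed order:

1. **UMI collapse, first occurrence.** For each distinct UMI the first read
   in file order is kept, by exact string identity. Collapsing before
   anchor matching means a molecule whose first copy happens to carry a
   sequencing error in an anchor is lost rather than replaced by a cleaner
   duplicate; this is a deliberate, conservative ordering and matches the
   stated processing order of the protocol this package implements.
2. **Perfect anchor matching.** A read is assigned to the locus only if the
   8-mer anchors on both sides of the target NΨN triplet occur exactly
   (leftmost `anchor_up`, then leftmost `anchor_down` after it — a
   deterministic tie-break for repeated anchors). If the sense scan fails,
   the reverse complement is scanned and the orientation recorded, making
   the counts strand-invariant. Requiring *both* anchors is what makes the
   gap between them well defined; a permissive `single_anchor` mode exists
   that admits reads bearing at least one perfect anchor into the
   denominator (they are tallied under `n_other_gap`, never in a signature
   numerator, preserving the count partition).
3. **Gap classification.** Gap of 2 nt → deletion signature; 3 nt with `T`
   at the central base (the Ψ position, read on the sense strand, where the
   cDNA of an unmodified U reads `T`) → retained unmodified; 3 nt with a
   non-T center → misincorporation signature; any other gap up to
   `max_gap` (default 10) → counted but unclassified. The four buckets
   partition the anchor-matched reads exactly — an invariant asserted on
   every input in the test suite.
4. **Rates.** `deletion_rate = n_del / n_anchor_matched`,
   `mutation_rate = n_ret_nonT / n_anchor_matched`. The denominator
   includes other-gap reads (the conservative reading of "fraction of total
   sequences at a locus"); a strict variant restricted to gap-2/3 reads is
   reported alongside so both conventions are visible. Zero matched reads
   is an explicit error naming the locus — no pseudocounts.
5. **Standard normalization.** The chemistry is incomplete: a 100 % ΨTP
   in-vitro-transcribed standard deletes at rate `p_del_psi < 1`.
   `effective_psi = rate_sample / rate_standard` calibrates this out.
   Values above 1 (sampling noise, calibration bias) are reported as-is
   with a warning by default; clamping to 1 is opt-in, so bias stays
   visible. The headline value uses the deletion rate only; a combined
   deletion + mutation rate is opt-in (`rate = "combined"`).

**BID-seq.** Bisulfite chemistry also converts Ψ into a deletion signature.
Here quantification is per reference position from covering-read records
(`read_id`, `position`, `covered`, `deleted`) — a deliberately
alignment-free input contract so the module is testable without an aligner;
a BAM front-end can populate the same records externally. Sites with
coverage below `min_coverage` (default 100) are a no-call error, never a
spurious 0. The site-level `effective_psi_at_site()` uses the identical
normalization contract as the CMC side.

Under this model the normalized estimator has a known bias when unmodified
U deletes at background rate `p_del_u > 0`:

\[
E[\widehat\theta] \approx \theta + (1-\theta)\,\frac{p_{del,u}}{p_{del,\Psi}},
\]

which the test suite verifies against simulation (20 seeds, 3 standard
errors).

## The synthetic-data generator

`simulate_cmc_reads()` draws, per molecule: Ψ status with probability
`psi_fraction`; deletion with `p_del_psi` (Ψ) or `p_del_u` (U);
misincorporation of the non-deleted Ψ with `p_mut_psi`; a random 10-mer
UMI; a geometric number of PCR duplicates with mean `dup_mean` (the
simplest memoryless amplification model); then per-base sequencing error at
`seq_error`, applied after duplication so duplicates can disagree and
anchors can be corrupted (such reads realistically fail anchor matching).
The UMI sits at the read prefix by default with a configurable offset,
since collapse-by-first-occurrence presupposes a fixed extractable
position. `simulate_standard()` is the same generator with `psi_fraction`
forced to 1 (or 0), which is exactly what a 100 % ΨTP (or unmodified)
in-vitro transcript is.

Default parameter choices, and why:

| parameter | default | rationale |
|---|---|---|
| `p_del_psi` | 0.8 | strong but incomplete chemistry; makes normalization matter |
| `p_del_u` | 0.01 | small background deletion from RT slippage |
| `p_mut_psi` | 0.05 | minority misincorporation channel at adducted Ψ |
| `seq_error` | 0.001 | typical Illumina per-base substitution rate |
| `dup_mean` | 3 | moderate PCR duplication; collapse must undo it |
| `umi_length` | 10 | 4¹⁰ ≈ 10⁶ space; <1 % collisions at 10⁴ molecules |
| Cq baseline | 20 | Cq of unit abundance; only differences propagate |

Seeds are mandatory arguments everywhere; no generator touches global
random state (`withr::local_seed`), and identical parameters and seed
reproduce outputs byte for byte.

What the generator does *not* emulate: full-length transcriptome reads,
paired-end insert-size structure, alignment artifacts, quality-score decay,
UMI errors creating phantom molecules, or CMC side reactions beyond the
deletion/misincorporation signature. Passing recovery tests therefore
demonstrate correctness of the quantification arithmetic and its
calibration under the stated noise model — not robustness to every artifact
of real libraries.

## Assay statistics

* **ΔCq expression.** Amplification efficiency is fixed at perfect doubling
  (no efficiency calibration, matching the protocol), and replicate Cqs are
  averaged on the Cq scale before exponentiation (standard convention;
  averaging ratios instead is exposed as `average = "ratio"`). The
  nuclear/cytosolic enrichment is the ratio of fraction-wise normalized
  expressions; because each fraction normalizes internally to its control
  gene, any per-fraction additive Cq shift — such as the different cDNA
  dilutions used for nuclear and cytosolic fractions — cancels exactly, a
  property asserted for arbitrary shifts. Dual-housekeeping designs are
  handled as separate single-control computations reported side by side.
* **Gel PSI.** Intercalating-dye intensity is proportional to mass, so
  intensities are divided by fragment length before forming the molar
  inclusion fraction. dPSI is treated − control, making exon skipping
  negative.
* **Sanger A>I.** Inosine is read as G, so editing is `G / (A + G)` from a
  peak-height table; chromatogram parsing is out of scope, keeping the
  formula directly testable.
* **Performance correlation.** Per-gene ratios of mean editing
  efficiencies between the two guide constructs, correlated (Pearson, with
  the t-transform p value on n − 2 df) against per-gene covariates such as
  exon count. The synthetic performance table plants the *sample*
  correlation exactly via an orthogonalized-residual construction against
  the integer exon-count covariate, so zero-noise recovery is exact rather
  than approximate — a stronger test than population-level planting.

## Numerical and design choices

* No quality filtering by default (none is part of the protocol); reads are
  only lost by failing UMI extraction or anchor matching.
* `max_gap = 10` bounds the accepted anchor gap; other-gap reads inflate
  the denominator but no numerator.
* Division contracts are strict: zero standard rate, zero anchor-matched
  reads, zero A+G signal, zero molar sum, and zero cadRNA mean are errors
  naming the failing unit, never silent zeros or NaNs.
* Sub-seeds for multi-run workflows are derived as
  `(seed * 7919 + i * 104729) mod (2^31 - 1)` to stay within R's integer
  range while keeping runs independent and reproducible.
* Demo/provenance outputs contain the full configuration, seed and package
  version but no timestamps, so identical configurations are byte-identical
  — the property the determinism check asserts.

## Problem sizes

The validation suite simulates 10,000 molecules per sample library (with
calibration standards at 50,000 molecules, mirroring the deeper sequencing
standards receive in practice), 20 independent seeds for the bias check,
and coverage 10,000 for BID-seq sites. At these sizes the binomial standard
error of a recovered stoichiometry is roughly 0.005–0.012 depending on the
cell, so the 0.02 recovery tolerance corresponds to about 2–3 standard
errors in the worst cells.

## Limitations

* Effective Ψ is a ratio estimator; at low standard rates its variance
  grows and values above 1 occur. The package surfaces rather than hides
  this.
* UMI collapse is exact-match; sequencing errors inside the UMI create
  phantom molecules at a rate ≈ `10 * seq_error` per read, slightly
  inflating `n_after_umi`. Directional/graph-based UMI clustering is out of
  scope.
* The BID-seq module consumes pre-extracted records; pileup conventions of
  an upstream aligner (deletion-length handling, base-quality cutoffs) are
  the caller's responsibility. Deletions longer than 1 nt should mark every
  overlapped position deleted.
* The mutation (misincorporation) rate is computed and reported but does
  not enter the default effective-Ψ normalization, which follows the
  deletion-only convention shared with BID-seq.
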