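---
title: "Autozygosity mapping and recessive-variant prioritization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autozygosity mapping and recessive-variant prioritization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozygmap)
```

## The model

A recessive disease allele in a consanguineous family is transmitted
identical by descent (IBD) through both parents: every affected child is
*autozygous* — homozygous by descent — at the disease locus. The
probability of autozygosity at a random locus is the inbreeding
coefficient F; for offspring of first cousins F = 1/16, and the expected
autozygous fraction of the genome equals F. Autozygous tracts are long
(centimorgan scale) because they are broken only by the handful of
meioses in the pedigree loop, so they are visible as runs of homozygosity
(ROH) in dense SNP-array genotypes.

`autozygmap` maps candidates in four stages, each an exported function
with a corresponding data type:

1. **ROH detection** (`detect_roh`): per sample, maximal marker runs
   containing at most `max_het` heterozygous and `max_missing` missing
   calls, at least `min_markers` markers, spanning at least
   `min_length_bp`.
2. **Shared LOH** (`shared_loh`): per-base intersection of all affected
   samples' ROH minus the union of all unaffected samples' ROH,
   discarding residues shorter than `min_shared_bp`.
3. **Gap merging** (`merge_segments`): segments separated by at most
   `max_gap_bp` are unioned. Whole-genome sequencing of the same
   individuals shows LOH regions are more continuous than fragmented
   array calls suggest, which motivates this step.
4. **Variant cascade** (`run_prioritization`): functional class →
   population rarity → recessive segregation pattern → region
   restriction, with a per-variant audit trail and a parental
   carrier-status check reported (not enforced) for each survivor.

## ROH semantics and tie-breaking

No single published ROH algorithm is canonical; the package uses a
greedy left-to-right scan: starting from the current marker, a run is
extended rightward as far as the heterozygous/missing budget allows, the
run is emitted, and the scan resumes after it. This definition is

* deterministic (ties at a boundary heterozygous call extend rightward),
* exactly reproducible by a brute-force oracle (enumerate all sub-runs
  satisfying the budget, select greedily leftmost-longest), which the
  test suite does on hundreds of random panels, and
* linear-time, since the budget counts are monotone in the right
  endpoint.

A run is reported as `[pos(first marker) − 1, pos(last marker))` in
0-based half-open coordinates. Runs may begin or end on a tolerated
heterozygous call; the tolerance exists to absorb genotyping error, not
to model mutation. An HMM-based caller would model error probabilistically
and is noted as an alternative, not implemented.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `min_markers` | 50 | markers | ~0.5 Mb of support at array densities of ~100 markers/Mb |
| `min_length_bp` | 1e6 | bp | autozygous tracts of interest are Mb-scale; shorter homozygosity is mostly chance IBS |
| `max_het` | 1 | calls/run | absorbs isolated genotyping errors (~0.1% per call on arrays) |
| `max_missing` | 5 | calls/run | array no-call clusters should not split a tract |
| `min_shared_bp` | 1e6 | bp | residual slivers of shared LOH below the tract scale are noise |
| `merge_gap_bp` | 1e5 | bp | array-call fragmentation gaps; small relative to true non-autozygous gaps |
| `max_maf` | 0.01 | fraction | strict `<` in every configured database |
| `window_bp` | 1e5 | bp | windowed heterozygosity resolution along an arm |

All are configurable; the defaults are the package's stated analysis
conditions.

Coordinates: all user-facing positions (VCF, published tables) are
1-based inclusive; everything internal is 0-based half-open (the BED
convention), converted by the single pair
`internal_coords()`/`display_coords()` so that interval arithmetic is
closed under intersection.

## The synthetic-data generator

`sim_config()` fixes the study conditions:

* **Pedigree**: first-cousin parents (a shared grandparental couple,
  two of their children married to unrelated founders, the two parents,
  and the offspring — 13 individuals for the default 3 affected + 2
  unaffected family). F = 1/16 for each offspring, computed
  independently by `inbreeding_coefficient()` via Wright path counting.
* **Genome**: `chr6` 60 Mb + `chr12` 40 Mb (100 Mb total), a
  two-chromosome scale model of the arms where shared LOH is sought.
* **Meiosis**: crossovers as a Poisson process at 0.01 Morgan/Mb
  (Haldane, no interference) — the genome-average 1 cM/Mb. Interference
  shortens the tails of tract-length distributions slightly; it does not
  affect mean fractions.
* **Markers**: 100/Mb (the density of a genome-wide tag-SNP array),
  positions uniform, alternate-allele frequencies uniform on
  (0.05, 0.5) in founders so heterozygosity carries signal for LOH
  detection.
* **Background variants**: 1/Mb, genotypes derived from the same
  transmitted haplotypes (rare variants ride a single founder
  haplotype; common ones are seeded per-haplotype at a drawn
  frequency), consequences drawn from a realistic class mix, population
  AFs drawn per database with occasional missing entries.
* **Causal variant**: one rare (all AFs < 1%) missense change planted
  inside a tract autozygous in every affected offspring and not
  autozygous (for that haplotype) in any unaffected offspring, so that —
  before error injection — affecteds are hom-alt, both parents are
  carriers, and unaffecteds are at most carriers by construction.
* **Genotyping error**: each non-missing panel call independently
  replaced by a uniformly chosen different code with probability 0.001
  (typical array discordance). The causal variant lives in the variant
  table, not the panel, and is exempt; error robustness is tested on
  background markers.

At this 100 Mb scale the probability that a *single* locus is autozygous
in all three affecteds for the same founder haplotype is roughly
(1/16) × (1/4)² ≈ 0.4%, so most replicates contain no plantable tract at
all. `plant_causal_variant()` then raises an explicit error instructing a
reseed — never a silent fallback — and `find_valid_seed()` implements the
deterministic reseed: scan `seed, seed + 1, ...` until a replicate has a
plantable tract and ground truth confirms that no background variant
coincidentally satisfies the full cascade. Uniqueness assertions are
made only on such replicates, since a background variant that happens to
ride the shared haplotype in the shared tract is a genuine (and
biologically real) second candidate.

What the generator does **not** emulate: linkage disequilibrium between
markers, coalescent founder diversity, de novo mutation, X-linked
inheritance, crossover interference, allele-frequency differences
between populations, and array artefacts beyond symmetric genotype
error. Passing tests therefore demonstrate correctness of the interval
logic, the segregation logic, and the calibration of tolerances against
random error — not robustness to LD structure or systematic batch
effects in real arrays.

## Numerical and degenerate-input choices

* Genotype codes are `{0, 1, 2, −1}`; any GT containing `.` becomes the
  single missing sentinel −1. Missing genotypes *fail* the recessive
  filter (a no-call cannot support a candidate) and are excluded from
  allele-frequency denominators.
* Missing population AFs pass the rarity filter by default (absence
  from a database is evidence of rarity); `missing_af_policy = "fail"`
  gives the strict mode for sensitivity analysis.
* MAF comparison is strict `<`; an allele at exactly 1% fails.
* "Not shared by unaffected siblings" subtracts the **union** of
  unaffected ROH (any unaffected homozygosity disqualifies); a flag
  switches to subtracting only their intersection.
* Windowed heterozygosity anchors windows at the supplied region start
  (arm-relative tiling), truncates the last window, counts het (code 1)
  and hom-alt (code 2) calls only — variant-only call sets carry no
  hom-ref rows — and reports windows without variants as missing, never
  as zero. Output is per-sample; averaging across samples is left to
  the caller.
* Multi-allelic VCF records are decomposed per ALT; scalar INFO values
  are duplicated, array values split positionally.
* `merge_segments` is idempotent and the cascade's survivor set is
  invariant under filter-order permutation (the filters are independent
  predicates); both are property-tested.

## Evaluating segment recovery

Simulated recovery benchmarks compare detected ROH with ground-truth
tracts via `segment_recovery()`. Genotyping error fragments long calls,
so recovery of tracts ≥ 2 Mb is evaluated with a two-stage caller:
sensitive runs (25 markers / 0.25 Mb), 100 kb gap merging, then a 0.5 Mb
size filter on the merged segments. A single-stage caller at the final
size threshold drops whole inter-error fragments and understates
coverage. The recovery statistic is the reciprocal overlap between a
truth tract and the union of detected segments touching it,
`min(covered/len_truth, covered/len_union)`: fragmentation is not
penalized twice, while a detected blob far larger than the tract still
scores low. At 0.5% per-call error this recovers ≥ 2 Mb tracts with
reciprocal overlap well above 90% (the acceptance suite verifies ≥ 90%
per tract across ten replicates).

## Problem sizes used in the checks

The test and acceptance workloads use: 200 random 200-marker panels for
the ROH/oracle equivalence, 100 random instances for the shared-LOH set
algebra, 5,000 replicate first-cousin offspring for the autozygous
fraction (standard error ≈ 0.0017, checked within 3 SE of 1/16), and
ten simulated families for segment recovery. These sizes give stable
statistics for the quantities checked while keeping the default run
reproducible on a single CPU.

## Known limitations

* Published LOH boundary tables produced by proprietary array software
  cannot be regenerated exactly; such coordinates are used as interval
  arithmetic fixtures only.
* Protein domain boundaries (e.g. EF-hand positions) are configuration
  input; the shipped examples are placeholders, not curated annotations.
* The disease-activity and histology subscale ranges default to 0–4 per
  component, a common convention for DSS-colitis scoring; published
  scoring sheets vary and the ranges are configuration.
* No CNV detection, no compound-heterozygote or de novo models, no
  annotation engine (consequences must be provided in the VCF INFO
  fields), and no HWE significance testing — these are outside the
  package's scope.
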