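---
title: "Cross-assembly SNP reconciliation: methods and design notes"
author: "flanklift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-assembly SNP reconciliation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The reconciliation model

`flanklift` decides, for every biallelic SNP called against one version
of a reference genome, whether the same polymorphism can be recovered —
coordinate, alleles, and panel genotypes — from a callset made against a
different version of that genome. Its unit of evidence is the *flanking
probe*: the window of `2f + 1` reference bases centered on the SNP
(default `f = 500`, a 1001 bp probe). The underlying assumptions are:

* a SNP position is transferable only if its local sequence context is
  conserved exactly between the versions — the probe must occur in the
  other assembly full-length with zero mismatches;
* a probe occurring at two or more equally perfect placements (counted
  jointly across both strands) cannot disambiguate the transfer and is
  discarded, exactly like a probe occurring nowhere;
* conservation must hold in both directions (A's probe onto B's site and
  B's probe back onto A's site, with agreeing strand calls and equal
  strand-adjusted allele sets); and
* sequence-level transfer is necessary but not sufficient: the panel's
  genotype calls at the paired positions, harmonized to orientation-free
  base multisets, must also agree at a high rate, because residual
  duplication and composition-driven calling noise pass the sequence
  stage but corrupt genotypes.

The center-position arithmetic is the one fixed geometric fact of the
method: a unique occurrence of a symmetric probe starting at 0-based
`start0` places the SNP at 1-based `start0 + f + 1` in the target,
irrespective of strand, because the center of a `(2f + 1)`-mer is `f`
bases from either end. Internally all coordinates are 0-based half-open;
every reported or file-borne position is 1-based (VCF convention).

### Exact matching as "100 % identity"

The mapping stage is specified as full-length exact matching with no
clipping, implemented by a k-mer seed table over the target (forward
strand, default `k = 31`) with every candidate verified over the full
probe on both strands. Completeness — equality with a naive both-strand
window scan — is the contract, and is asserted against that oracle in
the tests. A read aligner could call an alignment "100 % identity"
while soft-clipping its tails; the exact-match reading is deliberately
the more conservative one, and is reproducible and oracle-checkable.
`k = 31` is long enough to make seeds near-unique in plant-sized
genomes and shorter than any legal probe; any `k` not exceeding the
probe length yields identical results, only slower or faster.

An odd-length DNA string cannot equal its own reverse complement (its
center base would have to be self-complementary), so a probe can never
hit the same interval on both strands; this is asserted as a property
test rather than assumed.

### Genotype harmonization and concordance

Unphased diploid calls are stored as alternate-allele dosage (0/1/2,
`NA` missing); for a biallelic site the dosage encodes the unordered
allele pair exactly. A call is harmonized by substituting bases for
allele indices and complementing when the pair's strand relation is
flipped; the comparison is between unordered base multisets, so
complementation need only ever be applied to one side once. The
concordance rate of a pair is `n_match / n_informative` over the shared
panel, a sample being informative when both callsets have a call. The
published protocol's denominator is ambiguous ("90 % of the panel");
with the calling-stage missingness filter (< 5 %) the two readings
nearly coincide, so the informative-sample denominator is the default
and the fixed-denominator reading is available via
`genotype_concordance(..., denominator = "all_shared")`.

## Parameters

All tunables live in one `lift_params()` object:

| parameter | default | meaning |
|---|---|---|
| `flank` | 500 bp | probe half-width; probes are `2f + 1` bases |
| `min_qual` | 30 | variant QUAL, strict `>` |
| `min_mq` | 30 | site mapping quality (INFO/MQ), strict `>` |
| `min_maf` | 0.02 | minor allele frequency, strict `>` |
| `max_missing_call` | 0.05 | missing-call fraction, strict `<` |
| `concordance_threshold` | 0.90 | reliable-set cut, inclusive `>=` |
| `min_informative` | 1 | samples needed for a defined rate |
| `kmer_k` | 3 | word size of the flank signatures |
| `merge_max_missing` | 0.05 | merge-stage cap, `<=` kept |
| `seed` | 1 | recorded in outputs; drives any randomness |

Three deliberate asymmetries are worth stating explicitly, since each
follows the stage's own stated rule rather than a unified convention:

* the four calling-stage thresholds are **strict** inequalities, so
  boundary values (QUAL = 30, MAF = 0.02, missing = 0.05) are rejected;
* the concordance threshold is **inclusive** (a rate of exactly 0.90
  passes);
* the merge-stage missingness rule excludes sites **above** 5 %
  (exactly 5 % is kept), unlike the strict calling-stage filter.

MAF is computed over non-missing allele calls (two per called sample);
the missing fraction over all samples. Mapping quality is read from the
site-level INFO/MQ key — whether the original protocol used site-level
or read-level MQ is not stated anywhere we could verify, so the
site-level reading is exposed and documented here.

Flanks containing `N`, flanks truncated by a contig end, and sites
whose VCF REF disagrees with the assembly base are skipped before
mapping, each with a counted reason. Exact matching cannot meaningfully
match `N`; asymmetric end-flanks would break the center arithmetic; a
REF mismatch signals inconsistent inputs and silently proceeding would
corrupt the harmonization stage.

## The signature module

To characterize sequence context that separates concordant from
discordant SNPs, each probe is reduced to its literal overlapping 3-mer
counts (no canonicalization — a word and its reverse complement are
distinct features; windows touching `N` are skipped) plus GC content,
and each feature is compared between groups with a Welch (unequal
variance) two-sample t-test. The protocol's groups are extremely
unbalanced (on the order of 99 % vs 1 %), where the pooled-variance
test is invalid; Welch is therefore the only test offered. Degenerate
features (both group variances zero) are defined as `t = 0, p = 1` when
the means agree and flagged `DEGENERATE` otherwise. Raw p-values are
starred (`****` at `p <= 1e-4`); a Bonferroni option over the
`4^k + 1` features exists but is off by default, matching the usual
reporting of such panels. The "SNP position" indicator sometimes
listed alongside these features has no workable definition we could
pin down, so it is accepted as a user-supplied numeric column but never
computed.

## Liftover and merging

`liftover_vcf()` re-emits each input site found in the reliable set at
its partner coordinates with the partner's REF/ALT, complementing
alleles on flipped pairs and re-encoding genotype codes so each
sample's base multiset is preserved (when REF and ALT swap roles,
`d -> 2 - d`). The round trip A→B→A is the identity on retained sites;
this is asserted per-site in the tests. `merge_callsets()` intersects
two same-coordinate callsets by position with equal unordered allele
sets (allele-discordant collisions are dropped with a reason, since no
stated rule for resolving them exists), takes the union of the panels —
accessions present in both are kept as two panel-tagged columns, with
an optional de-duplication preferring the panel with fewer missing
calls — applies the merge-stage missingness cap, and reports per-site
cross-panel match rates for accessions shared by name.

## The simulator

The simulator is first-class, tested code: it generates the paired
system every stage is validated against.

* `simulate_reference()` draws i.i.d. uniform A/C/G/T contigs.
* `derive_assembly()` applies a tracked edit spectrum — substitutions,
  small indels, inversions, tandem duplications, a translocation,
  inserted N-runs — and returns the exact base-level coordinate map.
  Canonical truth segments are non-overlapping within each assembly;
  the second copy of a tandem duplication is recorded as an extra
  segment flagged `ambiguous` (those source bases map one-to-many).
  Reverse segments map by `b = b_start0 + (a_end0 - 1 - a)`.
* `simulate_panels()` places SNP sites by intended fate and draws
  per-sample genotypes under Hardy–Weinberg at alternate-allele
  frequencies uniform on [0.05, 0.5], then corrupts the two panel
  copies independently (per-call error replaces the dosage with one of
  the other two; missingness sets it to `NA`).

The default desk-scale scenario — the conditions under which the
package states its own results — is: 2 contigs x 500 kb; 0.05 %
substitutions, 20 indels (1–10 bp), 3 inversions (1–10 kb), 3 tandem
duplications (2–5 kb), 1 translocation (5–20 kb, a length the edit
spectrum leaves open and we fixed once), 2 N-gaps (100–500 bp);
60 samples, 2000 SNP sites, 2 % missing calls, 0.5 % genotype error,
2 % of sites planted discordant with 50 % per-sample error on one
panel, and a 5 % low-quality site subset drawn below the QUAL/MQ
thresholds. Site pools for expected-unmapped (7.5 %) and
expected-multi-mapped (3 %) fates mirror the proportions reported for
real cross-version mapping at this scale. It runs in about half a
minute and exercises every exclusion path.

### Truth labels

Each simulated site carries its expected fate, computed from the
generative record by independent arithmetic — never by running the
pipeline:

* `EXPECT_UNMAPPED`: a planted substitution falls inside the flank
  window (the site base itself is clean), so no exact occurrence
  exists in either direction;
* `EXPECT_MULTI`: the site lies inside a duplicated source region with
  full flank margin, so its probe has two perfect placements;
* `EXPECT_DISCORDANT`: a clean site with the planted 50 % B-panel
  error — the chance such a site reaches a 90 % match rate over ~58
  informative samples is a binomial tail below 1e-9;
* `EXPECT_FILTERED`: the site was drawn low-quality, or its *realized*
  panel MAF/missingness fails the strict calling-stage thresholds in
  either panel. This label exists because the strict filters make such
  losses inevitable rather than exceptional: with 60 samples and 2 %
  missingness, about 12 % of sites per panel draw three or more
  missing calls and legitimately fail `< 0.05`. Folding these into
  the transferable class would misstate what the pipeline can recover;
  scoring them separately keeps precision and recall exact.
* `TRANSFERABLE_CONCORDANT`: everything else — the class
  `evaluate_recovery()` scores precision and recall against.

What the simulator does *not* emulate, and hence what passing tests do
not show about real data: linkage disequilibrium and population
structure in the panel, non-uniform base composition and repeat
families (real multi-mapping is far more pervasive than three planted
duplications), read-level artifacts behind the QUAL/MQ annotations,
indel-adjacent miscalling, and reference bias. The simulator's purpose
is adjudicable correctness of the machinery, not realism of the
genome.

## Numerical and degenerate-input choices

* Ties/boundaries: strict vs inclusive comparisons are exactly as
  tabulated above; no epsilon is applied anywhere.
* A concordance rate is undefined (`NA`), not zero, below
  `min_informative` informative samples; undefined rates never enter
  the reliable set and are tallied separately.
* `filter_variants()` on a zero-sample table, concordance with no
  shared samples, merging with no intersected sites, and an empty
  sample order for the saturation curve are errors, not empty results.
* The saturation curve counts a site as discovered at the first prefix
  sample carrying a non-missing alternate allele; its final value is
  the number of sites with any observed carrier.
* Every stochastic function takes an explicit seed, saves and restores
  the caller's RNG state, and is byte-reproducible; the CLI records
  the seed in output headers. The simulator's stage seeds are derived
  from one master seed by fixed offsets.
* The CLI's `simulate` subcommand scales structural-event lengths
  proportionally when a config requests contigs shorter than the
  default 500 kb (flooring inversion/duplication lengths at one full
  flank window), so demo-sized genomes remain editable; the default
  length keeps the default spectrum.

## Problem sizes used by the test suite

The acceptance-style tests run the default scenario above once and
reuse it (memoised) across checks; oracle-equivalence tests compare
against naive scans on 10-kb genomes with probe lengths 15/101/1001
over 300 randomized instances; filter fidelity is adjudicated
brute-force on 1000 randomized sites including exact boundary values;
the Welch implementation is checked against hand-evaluated closed
forms and a 1000-replicate null calibration. These sizes are the
package's own choice of a desk-scale validation standard.

## Known limitations

* Only biallelic SNPs are handled; multiallelic records and indels are
  skipped with counts, never split into pseudo-biallelic records.
* Exact full-length matching is stricter than an aligner-based
  "100 % identity" that tolerates clipped tails; borderline conserved
  sites that a clipping aligner would transfer are reported unmapped
  here.
* The reliable set is panel-dependent: concordance is evidence about
  the panel used to compute it, and a different panel can admit a
  slightly different set.
* Memory scales with the target-genome k-mer table; the seed index is
  built per assembly and is the dominant cost at whole-genome scale.
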