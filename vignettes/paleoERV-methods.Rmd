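---
title: "Models and methods behind paleoERV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paleoERV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

paleoERV reconstructs the history of a betaretrovirus-like endogenous
retrovirus (ERV) clade from genome assemblies. This vignette explains the
models the package implements, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## The object of study

A provirus is the integrated form of a retrovirus: a 5′ long terminal
repeat (LTR), internal *gag*–*pro*–*pol*–*env* coding sequence, and a 3′
LTR, flanked by a short target-site duplication (TSD) created at
integration. Two facts about this structure carry almost all of the
historical signal the package extracts:

1. The two LTRs are copied from a single template during reverse
   transcription and are therefore **identical at integration**. Their
   subsequent divergence is a molecular clock for the insertion's age.
2. The TSD is a perfect duplication at integration, and the insertion is
   either present or absent at a given orthologous locus across species.
   Junction intactness and empty pre-integration sites therefore give
   presence/absence calls that date insertions relative to speciation
   events, and mismatched TSDs betray post-insertion rearrangement.

The clade modeled here has a distinctive structure: between *env* and the
3′ LTR it carries an HML-8-derived segment — the tail of an HML-8 *env*
(283 b), a 726-b region homologous to HML-8 LTRs (MER11 in repeat
databases), and a 42-b polypurine-tract remnant. The package treats this
recombinant region as a first-class annotation target.

## Mining model

Repeat annotators fragment proviruses into several records (LTRs,
internal sequence, the MER11 region) and often split internal records
further. Mining therefore merges whitelisted records whose gaps are at
most `max_gap` (default 1000 b, read inclusively so that a gap of exactly
1000 merges — the boundary convention of `bedtools merge -d 1000`), takes
the transitive closure, and classifies each merged candidate:

- `off_target` — no whitelisted member (decoy families land here; they
  are reported, never silently dropped, replacing manual curation);
- `solo_ltr` — LTR-family members only, with no internal-family record
  within `max_gap` (solo LTRs are recombination products of a provirus's
  own two LTRs and carry no internal sequence);
- `short_fragment` — merged length under `min_locus_len` (default
  2000 b);
- `provirus` — everything else.

The solo-LTR test precedes the length filter: a single intact LTR
(≈ 588–968 b) is structurally a solo LTR, not an anonymous short
fragment. Strand is taken from the longest member record, since
fragments of one element share strand. Loci whose merged interval spans
an assembly gap (≥ 50 consecutive Ns) are flagged `gapped` and excluded
from structural annotation, since their internal structure cannot be
trusted.

## Alignment substrate

All structure calls sit on global affine-gap alignment (match +2,
mismatch −3, gap open −8, gap extend −1). Two numerical choices matter:

- **Anchor-chained banding.** Loci are ~10 kb; a full dynamic program at
  that size is needlessly slow. When both sequences exceed 4 kb, unique
  shared 16-mers are chained collinearly (longest increasing
  subsequence) and only inter-anchor segments are aligned exactly. On
  substitution-only divergence this reproduces the full alignment
  verbatim; tests assert the equivalence.
- **Leftmost gap normalization.** Around microhomology, score-equivalent
  gap placements exist, and different code paths of any aligner may pick
  different ones. Every gap run is therefore shifted as far left as the
  flanking sequence allows, giving one canonical placement. Deletion
  endpoints are consequently reported at their leftmost equivalent
  position; the shared-deletion catalog match uses a ±20 b endpoint
  tolerance (alignment-placement jitter around repeats), which absorbs
  the normalization.

## ORF model

A gene is read in reference codon space from its start codon and called:

- `absent` when at least half its reference span is missing;
- `disrupted` when, within the first 90% of the protein
  (`completeness = 0.9`), the query carries a premature stop, a
  net-frameshifting indel (length mod 3 ≠ 0), or a large deletion
  (≥ 50 b, even if in frame);
- `intact` otherwise. Small in-frame indels within the first 90% are
  tolerated and flagged — the rule's wording concerns nonsense and
  frameshift mutations, and an in-frame codon indel preserves the
  downstream protein.

The completeness boundary is measured in codons (`floor(0.9 · n_aa)`),
since the rule speaks of nonsense and frameshift events, which live in
codon space. The pro–pol programmed ribosomal frameshift is modeled as a
reference feature: a stop at or after the slip site does not disrupt
*pro*, because the Gag-Pro-Pol polyprotein reads through it.

## Dating model

The clock is the **pairwise** divergence rate between cognate LTRs,
`rate = 0.0034`/site/Myr (0.34%), i.e. each LTR accrues half. This
interpretation makes one difference between two 588-b LTRs correspond to
0.5 Myr, which is the anchor the package reproduces analytically. The
p-distance excludes alignment columns containing a gap entirely — the
clock counts substitutions per site, and indels are handled separately
by the structural annotator.

With zero observed substitutions the age is only bounded: the interval
is [0, T_res] with T_res = (1/compared_sites)/rate, and the reported
point estimate is the midpoint (0.25 Myr for 588 sites). Both the
interval and the point are always reported.

p-distance is used without a multiple-hit correction: the normalization
is linear in divergence, and at the clade's age range (≲ 25 Myr,
divergence ≲ 8.5%) saturation and same-site collisions bias estimates
only a few percent low. The acceptance script measures this directly as
the regression slope of estimated on true age over 200 simulated pairs;
the slope sits a few percent under 1, inside the 1 ± 0.1 acceptance
band, and the bias is documented here rather than corrected, matching
the linear-normalization convention. Ages beyond ~15 Myr should be read
as rough estimates.

**Discordance.** Proviruses whose two LTRs do not cluster together
betray inter-provirus recombination or gene conversion and are excluded
from dating. On the package's NJ trees (maximum-likelihood trees are out
of scope; alignments and distance trees are exported for external ML
tools), a provirus is discordant iff its LTRs do not form a cherry *and*
at least one LTR has a nearer leaf from another provirus (patristic
distance) than its own mate. Pairs at zero distance are never flagged —
NJ topology among identical sequences is arbitrary. The criterion is
configurable; bootstrap clade membership would be the analogue on ML
trees.

## Orthology model

"Present in species X" means at least one provirus–flank junction is
intact in X's assembly. Intactness is a declared proxy: an alignment
covering ≥ `junction_half_window` = 50 b on *both* sides of the junction
at ≥ `min_junction_identity` = 0.90 per side, found by exact 12-mer
seeding, diagonal clustering and banded extension, with a uniqueness
requirement (second-best candidate below 90% of the best score ⇒
`unresolved`, never coerced). The 0.90 threshold tolerates Old World
monkey-scale flank divergence (a 50-b window at ~4–5% divergence still
passes) while rejecting paralogous hits. Queries use 1000-b flanks,
escalating to 5000 b when unresolved; when no junction is intact, an
empty pre-integration site is recognized by the two flanks mapping
uniquely, adjacently (target gap in [−12, 25] b, absorbing the single
retained TSD copy), on the same strand. Proviral sequence without an
intact junction is never counted present — such loci are often assembly
artifacts.

Presence calls roll up to the oldest common ancestor: the MRCA of the
focal species and all present species, ignoring `unresolved`. An
`empty_site` species nested inside the OCA clade triggers a warning (a
true loss, a polymorphism, or a truth inconsistency — the caller
decides).

Genotype statistics use the 3-primer PCR vocabulary {+/+, +/−, −/−,
failed}; failed reactions leave the denominator (two alleles per
non-failed individual), and a locus is polymorphic iff both allele types
are observed. Hemizygous genotypes are not modeled — the 3-primer design
cannot see them.

## Transcript and assay models

Splice junctions are read directly from SAM `N` CIGAR operations: donor
= last exonic base before the gap, acceptor = first exonic base after it
(so N = acceptor − donor − 1 in 1-based coordinates; both directions of
this convention are tested). Aggregated junctions need
`min_support` = 2 reads, replacing manual browser inspection with
thresholded counting. The rec-like spliced ORF (261 + 189 nt coding
exons, exon 1 ending exactly on a codon boundary) translates to a
149-residue protein split 87 + 62 across the junction.

Transport activity is the ratio of GFP to mCherry **arithmetic-mean**
fluorescence intensity over scatter-gated, non-double-negative events —
"mean fluorescence intensity" is read literally; medians or geometric
means are easy to substitute but are not the default. Percent-positive
uses a negative-control 99.9th-percentile threshold when a control table
is supplied. Numeric gate boundaries are configuration, not inference:
real cytometer data should come with its own gates, and FCS parsing is
out of scope (CSV exports only).

## The synthetic-data generator

The generator is the package's ground-truth instrument, and its defaults
are the study conditions the validation runs under:

- **Element library** (`make_element_library`): a 10,539-b recombinant
  consensus with a 968-b full LTR and the 588-b short LTR derived from
  it by the Δ1+Δ2 U3 deletions. The Δ1–Δ7 endpoints are not published as
  exact coordinates (only approximate lengths), so the library fixes
  concrete endpoints with the published lengths (Δ1 110, Δ2 270, Δ3 250,
  Δ4 200, Δ5 370, Δ6 100, Δ7 180 b) such that Δ1+Δ2 yields exactly the
  588-b short LTR; user-supplied endpoints are accepted for real data.
  Internal deletion catalog at consensus coordinates 3384–5639 (pro–pol)
  and 6233–8152 (pol–env). All sequences are synthetic; only structure
  is emulated.
- **LTR ageing** (`mutate_ltr_pair`): substitution-only; each copy draws
  Poisson(L · rate/2 · age) substitutions placed uniformly without
  repeats, so expected pairwise divergence is rate · age. The terminal
  two bases (the conserved integrase attachment dinucleotides TG…CA) are
  never mutated, as in real proviruses. Indels are deliberately absent:
  the dating formula counts substitutions, and indel handling is the
  structural annotator's job.
- **Implantation**: TSD length default 6 (typical betaretroviral range
  4–8; the clade's true TSD length is not asserted anywhere, so it is a
  parameter). Minus-strand implants are reverse-complemented; internal
  sequence is not aged (only the LTR clock and deletions matter
  downstream).
- **Track emission**: LTR records as `LTR5_RM` (or `LTR5B` for
  full-length variants — mirroring the fact that real annotations split
  the clade's LTRs over two family names), internal as `HERVK-int`,
  recombinant region as `MER11A`. The `"split"` fragmentation policy
  cuts internal records with gaps uniform on [50, 900] b — exercising
  the 1-kb merge rule without ever violating it by construction — and
  trims LTR outer edges by up to 3 b.
- **Speciation**: derived genomes mutate at `flank_divergence` × the
  patristic distance from the focal species; absent insertions are
  excised to a clean empty site (one TSD copy retained). With branch
  lengths in Myr, the presence map follows from insertion age versus
  split time (`presence_from_ages`).

What the generator does **not** emulate — and hence what passing tests
do not show about real data: realistic nucleotide composition (no
Markov/HMM background), sequencing error and quality, alignment-induced
annotation errors beyond simple fragmentation, gene conversion between
LTRs (only wholesale swaps for the discordance tests), segmental
duplications (except as constructed test cases), and assembly collapse.
Real-genome concordance of the junction-intactness proxy and of MEGA-style
distance conventions is therefore not asserted; the thresholds are
declared proxies, surfaced as configuration.

## Problem sizes

Validation runs at desk scale, chosen so the whole suite finishes in
minutes on one CPU: end-to-end recovery uses 60 implants (15 full, 5
pro–pol, 10 pol–env, 10 double-deleted, 5 non-recombinant, 8 solo LTRs,
7 decoys) in a 5-Mb two-chromosome genome with ages uniform on
[0, 25] Myr; clock calibration uses 200 LTR pairs with true ages uniform
on [0.5, 25] Myr; discordance uses 12 proviruses with two constructed 3′
LTR swaps; orthology uses a dated 4-taxon tree (macaque-like split times
6/15/25 Myr) with flank divergence capped near 4%; assay recovery uses
50,000 events. Genome-scale counts from real assemblies require
multi-gigabase inputs and are outside what synthetic validation can
reproduce; the recovery rates above are the substituted, testable
claims.

## Known limitations

- p-distance dating saturates above ~15 Myr and inherits any rate
  miscalibration linearly; rates differ between primate lineages, so
  absolute ages are rough.
- The discordance flag depends on NJ topology; very young pairs embedded
  in clades of near-identical LTRs are protected only by the
  zero-distance guard.
- The junction-intactness threshold trades recall against paralog
  rejection at one fixed identity; highly repetitive flanks will go
  `unresolved` rather than resolve.
- The breakpoint scanner reports window-scale intervals (±50 b at the
  default window), not base-exact crossovers — appropriate, since
  template switches themselves are localized only to microhomology
  tracts.
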