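---
title: "Models, parameters and design choices in anthersmallrna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in anthersmallrna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its methods: what each stage
computes, which tunable parameters matter and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
where the design was genuinely open. It states no empirical result that the
test suite does not itself compute.

## The experimental design being modeled

Small RNA libraries from anthers of a genetic-male-sterile (GMS) cotton-type
mutant and its fertile wild type (WT), sampled at meiosis, tetrad and
uninucleate microspore stages, give six count libraries (`Mar-F-1..3` for WT,
`Mar-S-1..3` for the mutant, overridable). The analysis questions are: which
tags are structural ncRNA contamination; which belong to conserved miRNA
families; which unannotated tags are credible novel miRNAs; which miRNAs
differ between genotypes; and which transcripts do the miRNAs cleave, as
witnessed by degradome (PARE) 5′-end signatures.

## Preprocessing

Reads are cleaned by exact string rules: the 3′ adapter is trimmed at the
first occurrence of its ≥8 nt prefix; reads that are pure adapter, contain
the 5′ adapter, are ≥80% adenine after trimming, or carry `N` are dropped.
Exactness (no mismatch tolerance) was chosen because the upstream vendor
pipeline the field delegates this step to is not specified anywhere; an exact
rule is deterministic and fully testable. The length window 18–30 nt is
inclusive on both ends. Tag collapsing is a pure aggregation: per-library
counts sum, and the operation is idempotent — both facts are tested as
invariants.

## Structural annotation

A tag is structural if it, or its reverse complement, is an exact substring
of a reference sequence; ties across classes resolve by the fixed precedence
rRNA > tRNA > snRNA > snoRNA (configurable), the order in which the field
lists these classes. Exact substring matching rather than alignment with
thresholds keeps the stage reproducible when the original match criteria are
unknown; the cost — mismatch-bearing structural reads pass through — is
acceptable because downstream stages re-filter candidates anyway.

## Conserved families: the two-tier rule

Tier 1 compares tags against species-level mature references (with exact
containment in a species precursor as fallback); only tags unassigned there
proceed to the all-plant tier. A mature matches when some alignment has ≤2
substitutions and ≤2 nt 5′/3′ end offset — values not fixed by any published
source for this design, chosen from common small-RNA practice and exposed as
`max_mismatch` / `max_offset`. Fewest mismatches wins; residual ties break
lexicographically by family so results are order-independent. Family names
normalize by stripping the species prefix and variant suffixes
(`ghr-miR156a` → `miR156`). Tier-1 assignments can never change when tier-2
references change; a test asserts this isolation.

"Present in a library" for the unique-miRNA sharing numbers means count ≥ 1;
no abundance floor is applied because none is defined anywhere. Sharing
percentages are computed over pairwise unions (WT vs mutant at one stage).
Computing them over the six-library union instead would shrink all three
numbers proportionally; the pairwise choice matches the two-set Venn reading
of the per-stage comparison.

## Novel miRNA discovery

Unannotated, unassigned tags with pooled count ≥ 4 (the smallest count at
which such tables are published; configurable) are mapped exactly to
transcripts on both strands. Around each hit two candidate windows are cut
(20 nt upstream / 220 nt downstream, and the mirror), bounded to 50–300 nt —
mireap-style conventions, since the actual parameters behind published tables
are not stated.

### The folding proxy

`fold_rna()` maximizes total pair weight (GC/CG 3, AU/UA 2, GU/UG 1, hairpin
loops ≥ 3 nt, pseudoknot-free) by a weighted Nussinov dynamic program in C++
and reports the negated optimum as a proxy energy in kcal/mol. This is *not*
a thermodynamic model: it has no stacking context, no loop penalties, and
published fold energies are not reproducible with it (nor are the precursor
sequences behind them available). A real folder can be substituted through
the `backend` argument of `fold_rna()`/`evaluate_hairpin()` behind the same
contract.

Two numerical choices deserve a note:

* **Tie-breaking.** Among co-optimal structures the traceback pairs each base
  with its *outermost* admissible partner. The opposite preference (leave
  unpaired first) selects tie structures in which loop-proximal mature bases
  fold back into the terminal loop, destroying the mature:star duplex that is
  genuinely present; with the outermost-partner rule the planted-hairpin
  round-trip in the test suite recovers 100% of cases.
* **Strand symmetry.** With the G:U term the model is not reverse-complement
  symmetric: a G:U pair maps to the non-pairing A:C under reverse
  complement. Symmetry holds exactly on wobble-free alphabets and is tested
  there.

### Acceptance criteria

A candidate is accepted when (a) the mature lies wholly in one arm and does
not span the terminal loop; (b) the mature:star duplex — read off the fold
starting from the loop-distal mature end and extended while pairing stays
nested with per-step bulge asymmetry ≤ 2 nt — leaves ≤ 4 mature bases
unpaired; and (c) the proxy energy is ≤ −18 kcal/mol, a threshold consistent
with the weakest published fold energy for comparable tables (−18.33) and
configurable. The duplex walk exists because a maximum-pairing structure may
attach a stray mature base far from the star; such pairs are not duplex
evidence and count as unpaired instead.

## Differential expression

The test is Pearson's χ² without continuity correction on the 2×2 table
(feature count vs rest of library, per library), the standard two-library
proportion test; when any expected cell is below 5 it falls back to Fisher's
exact test and labels the result. Benjamini–Hochberg adjustment runs within
each library pair. Significance defaults — BH-adjusted p < 0.01 and
|log2 fold change| ≥ 1 — are declared package defaults, not sourced values,
and are stamped into output headers. A 0.5 pseudocount enters the CPM ratio
only when a raw count is zero, and never enters the test itself. Dispersion
modeling (negative-binomial DE) is deliberately out of scope: with one
library per condition the χ² on proportions is the appropriate published
procedure.

## Degradome target identification

Duplex scoring uses the plant-target-prediction convention associated with
CleaveLand-style pipelines: mismatch 1, G:U wobble 0.5, single-nt gap 1 (at
most one gap), all doubled at miRNA positions 2–13, threshold score ≤ 4. The
per-position constants are declared package choices — the threshold is the
published one, the constants behind it are not printed anywhere.

Scanning is exhaustive over every window of width L−1, L, L+1 on the sense
strand (C++), and a brute-force R enumeration serves as an independent test
oracle on random transcripts. Overlapping alignments of one locus are
collapsed to the best-scoring one (score, then gapless, then position)
because single-gap variants of a perfect site also pass the threshold; the
oracle equality is asserted on the *un-collapsed* set so the dual route stays
meaningful.

A call requires a 20–21 nt degradome signature whose 5′ end falls exactly on
the target base paired to miRNA position 10 (canonical slicing between
positions 10/11) or position 11; the canonical paired-to-10 position is
always the reported cleavage position (first base of the 3′ fragment,
coordinates 1-based inclusive). TP10M is
`raw / (total genome match − structural) × 10⁷`. Multi-mapping reads credit
their full count at every locus with the hit number recorded — no fractional
splitting, keeping counts integral. Peak categories: 0 unique transcript
maximum, 1 shared maximum, 2 above the median, 3 at/below the median with
raw > 1, 4 singleton; the median runs over positions with ≥1 signature, and
categories 0–2 are scale-invariant (tested).

## The synthetic-data generator

`generate_dataset()` writes every input the pipeline consumes and a planted
ground truth. Its defaults *are* the stated world the package is tested in:

* six libraries of 20,000 reads (tests scale to 8,000 for runtime; the DE
  recovery criterion uses 100,000 as specified for it);
* tag lengths 18–30 nt with mode 24 and the 21–24 nt bulk dominating;
* 4% structural reads, 10% planted-miRNA reads, the rest transcript-derived
  background tags;
* log-uniform tag abundances (an assumption — family-level totals are the
  only published anchor, and they do not constrain per-tag shapes);
* genotype-specific fold changes for a subset of conserved miRNAs, defaulting
  to the families reported as stage-wise differential (miR394/396 at meiosis,
  miR398/399 at tetrad, miR398 at the uninucleate stage);
* a degradome whose signal reads start exactly at the target base paired to
  miRNA position 10 of each planted target (30% of reads), over a uniform
  background — the simplest model yielding category-0 peaks, with one target
  per transcript so the peak is the unique maximum.

Two calibration details exist to keep the stated world self-consistent rather
than to pass any particular test: background tags are stratified by length
with abundance noise normalized within each length class (otherwise per-tag
abundance noise plus 21-nt-biased miRNA reads can flip the pooled mode away
from 24 nt at small depths), and differential miRNAs get a fixed moderate
base abundance (compositional renormalization otherwise drags the realized
fold change well below the nominal one).

`plant_hairpin()` builds precursors as mature + 8 nt C/A loop + full reverse
complement star (+2 nt pad), in either arm orientation. The full complement
makes the planted duplex the unique proxy-energy optimum; a star truncated by
the 2-nt overhang is strictly sub-optimal under pair maximization and the DP
then prefers shifted registers through the loop. The 2-nt 3′ overhang of
Dicer geometry is realized by the pad beyond the star's 3′ end (5p arm) or by
the unpaired loop bases adjacent to it (3p arm).

What the generator does **not** emulate: sequencing errors and quality decay
(qualities are constant by design — no published quality thresholds exist to
exercise), adapter chemistry artifacts, genome-scale depths (10⁷⁺ reads),
hairpin-derived siRNA ladders, and realistic cross-library tag sharing (the
synthetic libraries share most of their tag pool, so Venn sharing numbers are
far higher than in real data). A green test therefore establishes the
correctness of the computations on data with the stated statistical
structure — not that real libraries would reproduce any published magnitude.

## Degenerate inputs and numeric conventions

Zero-read libraries are legal (totals 0, empty histograms); sharing of two
empty sets is an explicit error, as is a non-positive TP10M denominator and a
χ² table with an empty row. All coordinates are 1-based inclusive; sequences
are held internally as DNA (RNA accepted on input, mature references written
back as RNA). All report writers emit fixed `\n` endings so reruns are
byte-identical, and the run manifest records every parameter but no absolute
paths or timestamps for the same reason.
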