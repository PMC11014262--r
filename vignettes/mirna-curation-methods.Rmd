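---
title: "Stringent miRNA curation in AT-rich genomes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stringent miRNA curation in AT-rich genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mircurate)
```

# The curation model

A locus is annotated as a *bona fide* miRNA when three kinds of evidence
coincide: (i) the genomic sequence folds into a single unbranched
stem-loop whose two arms are both covered by reads; (ii) reads are
precisely excised — they share 5' ends, form a mir-5p/mir-3p duplex with
the 2-nt 3' overhangs left by RNase-III enzymes, and the locus produces
essentially nothing else; (iii) the locus is not a fragment of another
structured ncRNA or a transposon. In AT-rich amoebozoan genomes these
checks do nearly all of the work: siRNA loci fail (ii) (diffuse,
double-stranded, heterogeneous ends), structured ncRNAs fail (i) or (iii),
and random AT-rich background fails (i) and the depth threshold.

The pipeline applies them as: clustering of weighted read placements →
per-cluster zero-mismatch profile → MFE fold → hairpin detection → duplex
call → round-1 screen (hairpin + ≥30% 5' precision on both arms) → three
criteria sets with a ≥2-of-3 verdict → annotation-based exclusion.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| folding temperature | 22 | °C | growth temperature of the amoebae; the thermodynamically correct choice for structures that exist in these cells, not the 37 °C of animal pipelines |
| read length window | 18–35 | nt | sRNA-seq insert range retained after trimming |
| alignment mismatches | ≤1 | nt | short AT-rich reads tolerate no more without drowning in spurious placements; 0-mismatch placements outrank 1-mismatch |
| multimapper window | ±50 | bp | neighbourhood of uniquely mapped 5' ends used for fractional placement; the +0.5 pseudocount keeps weights defined where no unique reads exist |
| cluster merge gap | 100 | bp | must exceed the precursor loop so that both arm read blocks land in one cluster: with 75–125 nt precursors and ~21 nt arms, loops reach 83 nt, so a 50 bp gap would split most real loci — this is why the default is 100, not 50 |
| cluster depth | ≥5 | weighted reads | drops background singletons before folding |
| profile flank | 30 | nt | genomic context added before folding so arms near cluster edges can pair |
| round-1 precision | ≥0.30 | fraction | permissive screen; the criteria sets apply the stringent 0.50 |
| precision window | arm ±3 | nt | denominator for 5' precision; a *local* window deliberately excludes loop-derived reads, which are penalized by the duplex-read fraction instead |
| duplex-read slack | 2 | nt | isomiR tolerance when asking what fraction of the locus' reads belong to the duplex |
| ncRNA overlap | ≥0.5 | fraction of precursor | exclusion threshold; transposon overlap is flagged, not rejected, by default |
| homolog search | ≤2 mm/arm, span ≤400 | nt/bp | every reported conserved case differs by ≤2 substitutions per arm; loops are unconstrained |
| synteny merge gap | 5000 | bp | blocks within 5 kb on *both* genomes merge (the conservative joint reading) |

All criteria-set thresholds ship in `inst/extdata/criteria_default.yaml`
and can be overridden wholesale (`criteria_config(path)`).

## The three criteria sets

*Animal-style* encodes processing-centric standards: ≥2 exact-modal reads
in ≥2 replicates on each arm, arm precision ≥0.5, 3' overhangs of 2±1 nt
at both duplex ends, loop ≥8 nt, paired fraction ≥0.6, precursor ≤150 nt.
*Plant-style* tolerates long precursors (≤300 nt) but demands duplex
quality (≤5 mismatches, ≤3 nt asymmetric bulges, lower-end overhang 2±1)
and that ≥75% of locus reads belong to the duplex, expressed in ≥2
replicates. *Combined* is the structural minimum: single stem-loop, both
arms mapped, precision ≥0.5, duplex fraction ≥0.5, no structured-ncRNA
overlap. A candidate needs two of the three; candidates overlapping
annotated structured ncRNAs are excluded outright regardless of the vote,
since requirement (iii) is not negotiable.

# What the simulator emulates — and what it does not

`sim_config()` defaults encode the study conditions: a 500 kb genome at
86% AT (A/T and G/C split evenly, i.i.d. per base), three biological
replicates of 200,000 reads, a 21-nt modal read length, miRNA arms emitted
at a 5:1 5p:3p ratio with 5'-end jitter `{0: 0.85, +1: 0.10, −1: 0.05}`
(85% exact ends) and mild 3'-length jitter, siRNA loci tiled on both
strands with 20–22 nt reads, decoys as two-hairpin structured RNAs with
uniform-random 5' starts (a guaranteed-negative class for the precision
screen), and planted-locus expression absorbing ~97% of each library.
Randomly drawn mature arms start with U half of the time (the 5'-identity
preference of amoebozoan miRNAs) and peak at 21 nt; simulated ortholog loci
are embedded in AT-rich flanks, the composition in which these hairpins
actually fold.
Per-replicate locus counts are multinomial around expected expression, so
locus plus background counts sum exactly to the library size.

Deliberate simplifications:

* **Background reads avoid planted loci** (≥150 bp margin). Real
  degradation products can fall anywhere; here they are kept out of the
  planted read stacks so that the no-jitter limit is exactly clean
  (precision 1.0) for every planted locus at any seed. Consequently the
  pipeline's robustness to *overlapping* foreign reads is exercised only
  by the jitter sweeps, not by the background class.
* No sequencing errors, PCR duplicates, UMIs or quality-score realism
  (qualities are constant `I`); the pipeline never reads qualities.
* One pooled library per replicate; developmental-stage mixing is not
  modelled.
* The background composition model is i.i.d. per base — adequate for AT
  content reporting, but it carries no repeats, no microsatellites and no
  real transposon families.

Passing the recovery tests therefore shows the *procedure* separates the
planted classes under realistic depth, composition and jitter; it does not
certify performance on real libraries with adapter dimers, contamination
or repeat-rich genomes.

# Numerical choices and degenerate inputs

* **Hairpin design.** Designed precursors are `arm5p + loop + arm3p` with
  the 3p arm built as the reverse complement of the 5p paired region;
  loops and bulge/overhang fillers are drawn from {A, C} so they cannot
  pair with each other, and random designs keep mismatches and bulges ≥5
  positions away from the stem ends (terminal pairing is required for
  processing, and interior placement keeps the MFE refold faithful). Each
  design is refolded; if fewer than 90% of intended pairs are recovered,
  loop/filler nucleotides are redrawn (≤10 tries).
* **Duplex calling.** The arm start is the modal weighted 5' end on its
  side of the terminal loop, ties towards the 5'-most position; the arm
  length is the modal read length at that 5' end, ties towards shorter.
  Arms must be 18–25 nt and non-overlapping; a side without reads is a
  rejection with the missing arm named.
* **Geometry.** Computed from the pair table between the called arms:
  consecutive-pair gaps contribute `min(a, b)` mismatches and `|a − b|`
  asymmetric bulge nucleotides; overhangs are signed tail-minus-head
  differences at each duplex end, so +2/+2 is the canonical product.
  Arms that never pair with each other raise a `degenerate_duplex` error.
* **Folding.** Single MFE structure, no ensemble. Clusters outside
  30–1000 nt are not folded (flagged `unfoldable`); mega-clusters of that
  size are never miRNA precursors.
* **Homolog dedup.** Overlapping homolog hits keep the fewest-mismatch
  (then 5'-most) hit, ignoring strand: a hairpin's reverse complement is
  itself nearly a valid arm arrangement, and without strand-blind
  deduplication every locus would be reported twice.
* **Substitution classes.** A differing arm position is `bulge_located`
  when unpaired in the reference, `compensatory` when paired in both
  structures with a canonical (Watson–Crick or G:U) pair in the homolog —
  whether one or both strands changed, since single-sided wobble-preserving
  changes also preserve the duplex — and `pairing_disrupting` otherwise.
* **Zero-read inputs.** Empty FASTQ in, empty (valid) outputs and a
  warning; empty profiles mark the cluster skipped; a zero-count condition
  makes the expression normalization an explicit error rather than NaN.

# Open design points, decided

* The upstream mapper's fractional-placement algorithm is not published in
  detail; the `(U + 0.5)/Σ(U + 0.5)` rendering over ±50 bp of unique 5'
  ends is this package's concrete definition, tested for exact weight
  conservation.
* Whether a read with both exact and 1-mismatch placements kept both
  strata is unknowable from the text; best-stratum retention matches
  standard practice and is assumed.
* The three criteria sets' exact thresholds live in the original study's
  supplement; the shipped defaults encode the community standards the
  procedure references and every number is config-overridable, so a user
  holding the supplementary values can reproduce them exactly.
* Transposon-overlapping candidates are flagged rather than rejected
  (configurable): young miRNAs frequently arise from transposon edges, and
  an irreversible rejection would hide exactly the interesting cases.
* The precision denominator and tie-breaks (above) are this package's
  conventions; both are stated here because the procedure's text defines
  only the numerator concept.

# Problem sizes used by the checks

The end-to-end recovery checks run the generator at its defaults (500 kb,
12 + 20 + 5 loci, 3 × 200,000 reads; ~5 minutes); the no-jitter limit runs
the same design at 100,000 reads per replicate, which leaves thousands of
reads per planted arm — precision estimates are exact there by
construction, not depth-limited. The jitter monotonicity sweep uses a
120 kb genome with 8 + 5 + 2 loci at 40,000 reads per replicate and five
jitter levels (exact-end probability 1.00 → 0.40). Oracle-equivalence
checks (precision tallies, pair-table enumeration, naive alignment and
paralog scans) use small constructed instances where the brute-force
reference is itself trivially correct.

# Known limitations

* Ungapped alignment and homolog matching: indel isomiRs and indel-bearing
  orthologs are invisible. The conserved cases this targets differ by
  substitutions only.
* `RNAfold` is required on the PATH; there is no pure-R fallback.
* The criteria engine evaluates per-candidate features only — no
  cross-locus learning, no expression-rank heuristics, no p-values.
* Synteny blocks are consumed, not computed: whole-genome alignment is out
  of scope.
* The screens are stringent but not airtight: at some seeds a single
  background cluster per ~500 kb can survive all three criteria sets (a
  chance hairpin with a handful of tidily stacked reads). This is the point
  at which miRNA annotation traditionally adds manual inspection of the
  per-candidate density and structure exports.
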