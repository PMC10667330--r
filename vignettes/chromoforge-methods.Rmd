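---
title: "chromoforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromoforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoforge)
```

chromoforge implements the computational workflow around a synthetic
yeast chromosome built to Sc2.0 conventions: rule-driven redesign of a
native chromosome, partitioning of the designed sequence into
hierarchical build units, qPCR-based genotyping of integration strains,
sequencing-based localization and repair planning of growth defects, a
relocated tRNA-array designer, and a simulator for Cre-loxPsym
(SCRaMbLE) rearrangement in synthetic/wild-type hybrid polyploids. This
vignette records the models, the tunable parameters and their defaults,
the numerical choices, and what the synthetic fixtures do and do not
emulate.

## Coordinates and the edit ledger

All internal coordinates are 0-based half-open; GFF3 (1-based inclusive)
is converted only at the I/O boundary. "Downstream" is always taken in
the feature's own orientation: 3' of a minus-strand gene is toward lower
chromosome coordinates.

Every design rule emits *edit records* in native coordinates: `insert`
(zero-length native interval), `delete` (empty payload), or `substitute`
(payload may change length). The ordered, non-overlapping collection is
a `DesignLedger`, and the designed sequence is defined as the ledger
applied to the native sequence in one left-to-right splice. This makes
the design reproducible bit-exactly from native + ledger alone, and
makes the native-to-design coordinate map (`lift_position()`) a pure
function of the ledger. Positions inside deleted intervals or
length-changing substitutions have no image and lift to `NA`;
same-length substitutions (stop swaps, PCR-tag recoding) map their
interiors 1:1, so gene intervals containing them lift cleanly.

## Design rules

The default `design_policy()` encodes the standard redesign:

* **loxPsym insertion.** A 34-bp loxPsym site is inserted 3 bp after the
  stop codon of every non-essential ORF classed Verified or
  Uncharacterized. Dubious ORFs are excluded by default. The loxPsym
  sequence itself, like the synthetic telomere cap and the rox site, is
  a configuration default drawn from the standard Sc2.0 conventions and
  validated only for alphabet (and, for loxPsym, palindromicity): the
  design *rules* concern placement, not the sequences. An insertion
  point that falls strictly inside another annotated feature is skipped
  and logged rather than shifted — shifting would silently change the
  3-bp rule, while a skip is auditable.
* **Intron removal.** All annotated introns are deleted except an
  explicit retention list (stable introns such as the NOG2 intron, whose
  removal costs fitness, are the motivating case). Frame preservation is
  guaranteed by the genome invariant (coding length divisible by three
  after excision) and protein identity is re-checked by
  `verify_design()`.
* **Stop-codon swaps.** TAG stops of Verified/Uncharacterized ORFs are
  substituted to TAA, freeing the TAG codon for future reassignment;
  TAA/TGA stops and dubious ORFs are untouched.
* **Feature removal.** tRNA and transposon features are deleted
  wholesale.
* **Telomere caps.** Each annotated telomere is replaced by a synthetic
  cap; the left cap is reverse complemented so both ends present the
  same outward-facing repeat.
* **PCR-tag recoding.** For each Verified/Uncharacterized ORF long
  enough for a 200–500-bp amplicon, two 24-base windows on codon
  boundaries near the amplicon ends are synonymously recoded. Recoding
  greedily picks, per codon, the most-different synonymous codon
  (processing codons with the most headroom first) until at least 8
  mismatches separate the wild-type and synthetic tags. Tag Tm is
  computed by nearest-neighbor thermodynamics (SantaLucia 1998 unified
  parameters, 50 mM monovalent salt, 500 nM strands) and the amplicon
  start is shifted over a few codon offsets to land both tags in the
  58–62 °C window; when the targets are unattainable (e.g. Met/Trp-rich
  windows) the best effort is emitted with a warning flag. These
  defaults are ordinary qPCR primer engineering constraints; only the
  existence and count of tags is inherited from the chromosome design
  itself. For ORFs with introns, windows are restricted to the first
  exon so tag substitutions can never collide with intron deletions.

Edits are computed independently in the native frame, merged in
canonical order (removal, intron, stop swap, tag recode, loxPsym,
telomere) and applied once. Overlaps between different rationales are a
hard error, with one exception: a stop-swap/tag collision drops the tag
(windows exclude the terminal codon, so this arises only with unusual
annotations).

One subtlety is handled after merging: a deletion can join two flanks
that together spell a forbidden enzyme recognition site (the panel used
for assembly junctions or vector handling, NotI by default) even though
neither flank contained it. After applying the ledger the designed
sequence is scanned; any occurrence not present at the homologous native
location is disrupted by a single-base substitution at an intergenic,
previously untouched position inside the site, recorded as a `repair`
edit so the ledger remains complete. Tag recoding performs the same scan
locally, with flanking context, before emitting its edits.

`verify_design()` audits the result: ledger reproduction, protein
conservation for every retained Verified/Uncharacterized ORF, loxPsym
count against eligibility, absence of swappable stops, and no net
creation of forbidden sites.

## Assembly planning

The designed chromosome is tiled into chunks targeting 10 kb (bounds
5–12 kb by default) with junctions at restriction sites. The boundary
search greedily scans a ±2-kb slack window around each running target
for a site of one of the panel enzymes that occurs exactly once in the
union of the two adjacent chunks — the condition under which digestion
of both neighbours yields exactly the complementary junction ends.
Intergenic candidates are preferred; ties go to the smallest deviation
from the target. The default panel is 8-bp cutters (NotI, AscI, PmeI,
PacI, SbfI, FseI, AsiSI, SrfI) precisely because uniqueness over a
~20-kb union is unattainable for 6-bp sites in yeast-sized sequence.
This planner only *finds* sites; the fixtures module provides
`plant_junction_sites()`, which emulates the build-oriented side of a
real design in which terminal sites are incorporated on purpose at
~10-kb spacing.

Chunks are grouped four to a megachunk (growing to five only when four
fall short of the 30-kb span floor), labeled alphabetically with chunk
ids `A1, A2, …`, and assigned alternating LEU2/URA3 marker cassettes
starting with LEU2, so each SwapIn round selects for the incoming marker
and screens for loss of the previous one. A trailing remainder that
cannot reach four chunks is relaxed to three with a warning rather than
inflating a megachunk past its span cap. Marker cassette sequences are
opaque placeholders: their identity matters to the plan, their sequence
does not. Emitted chunk FASTA records carry the right-hand junction site
as a shared terminal overlap; collapsing each overlap once reconstructs
the chromosome bit-exactly, which the test suite asserts.

## Genotyping and expression

Per-tag presence is called from well-level Cq and melt data: amplified
iff Cq ≤ 35 cycles and the melt peak is within 1.0 °C of the tag's
expected peak from the manifest. Both thresholds are conventional qPCR
practice, exposed as arguments; the expected melt is supplied per tag
rather than predicted from sequence, avoiding a melt-thermodynamics
model. The exclusion rule for "aberrant" tags is control-driven — the
most defensible reading of excluding tags with aberrant amplification: a
tag/allele is excluded from all downstream evidence when its no-template
control amplifies or its wrong-template control does (a SYN primer pair
amplifying wild-type control DNA, or vice versa). Replicate wells
aggregate by majority, ties excluded as aberrant (conservative).

Megachunk integration is accepted iff every informative synthetic tag
amplified and no informative wild-type tag did; rejected otherwise;
indeterminate when no informative tag remains. Exclusion of an aberrant
tag can therefore never flip an accepted call to rejected without new
contrary evidence.

Relative expression uses the efficiency-corrected (modified Livak) form

$$\mathrm{ratio} \;=\; \frac{E_t^{\,Cq_{t,\mathrm{cal}} - Cq_{t,\mathrm{test}}}}{E_r^{\,Cq_{r,\mathrm{cal}} - Cq_{r,\mathrm{test}}}}$$

with per-primer-pair amplification factors $E \in (1, 2]$ measured, not
assumed to be 2. With $E_t = E_r = 2$ this reduces to the classic
$2^{-\Delta\Delta Cq}$, which the tests verify to machine precision.

## Sequencing-based debugging

**Pooled localization.** Fast- and slow-growing segregant pools are
assumed mapped against a hybrid synthetic + wild-type reference, so
each window exists in a synthetic-allele and a wild-type-allele
partition. Each pool's track is normalized by its own median (robust to
depth differences between pools), and the per-window score is
log2(fast/slow), computed per partition. Candidates are maximal runs of
at least 3 windows (1-kb windows) at score ≤ −1, i.e. at least a
two-fold depletion sustained over 3 kb; window size, run length and
threshold are engineering defaults, since the upstream analyses publish
no values. Reciprocal logic is cross-checked: a synthetic region
depleted in the fast pool should show the homologous wild-type windows
enriched (score ≥ +1) — the mirror of wild-type depletion in the slow
pool — and each candidate reports that flag. Zero-depth windows score
−Inf and count toward runs; 0/0 windows are NaN and do not.

**Copy number.** Copies = baseline_copies × mean(target depth) /
mean(baseline depth), with a percentile bootstrap CI over windows. This
is the "coverage relative to surrounding loci" estimator: it recovers a
four-fold integrated chunk as ≈4 copies and expresses a missing
mitochondrial genome as ≈0.

**Discrepancy classification.** Observed variants (minimal VCF: literal
REF/ALT plus symbolic `<DEL>`/`<DUP>` with END) are mapped to exactly one
class by a fixed rule order: duplications are critical (such gains were
actively repaired in practice); deletions covering a loxPsym feature are
a noncritical missing site; a stop codon reading TAG where the design
says TAA in a Verified/Uncharacterized ORF is a critical residual TAG;
any other protein-changing variant in such an ORF is critical
nonsynonymous; synonymous changes inside a PCR-tag window (reverting the
tag toward wild type) and junction-site losses are noncritical; all else
is `synonymous_other`, noncritical. Frameshift-length literal indels are
outside the supported dialect; they would enter as symbolic alleles
upstream.

**Repair planning.** Every critical record is scheduled; each
noncritical record within 5 kb of a scheduled critical repair is bundled
into it — it is worth fixing while the locus is being edited anyway —
and the rest are deferred. The plan is sorted by coordinate and
invariant under permutation of its input, which the tests check.

## tRNA array design

Each relocated tRNA gene receives a 500-bp 5' and a 40-bp 3' flank from
a heterologous donor pool (the real design drew them from *Ashbya
gossypii* and *Eremothecium cymbalariae* to reduce host homology).
Matching is a stable greedy pass in lexicographic tRNA-id order: exact
anticodon match first, then any entry decoding the same amino acid, then
any unused entry; each entry is used at most once. Fallback tiers avoid
consuming an entry whose anticodon a later tRNA still needs, unless that
anticodon is in surplus — this keeps the anticodon-match count maximal,
verified against an exhaustive matching oracle on small instances.
Five-prime flanks are scrubbed of a configurable motif list (standing in
for transcription-start artefacts; the real list is unpublished) by a
single-base substitution at each occurrence's central position,
rescanning until clean, length preserved. The array is emitted as rox +
5' flank + intron-less tRNA + 3' flank per gene plus a terminal rox, so
n genes carry n+1 rox sites; spacing is configurable since the source
design states only that rox sites were placed at 5' and 3' intervals.

## SCRaMbLE simulation

A cell is a multiset of molecules; a molecule is an ordered list of
oriented segments from the reference segmentation of the designed
chromosome at its loxPsym sites (k sites → k+1 segments). Wild-type
molecules carry the same segment ids but no recombinable junctions — the
sites exist only on synthetic DNA. A segment is essential iff it
contains at least one essential ORF.

Each Cre event picks one unordered pair of recombinable junctions
uniformly (intermolecular pairs included unless disabled; contact
probability is not distance-weighted). Within a molecule the intervening
block is deleted — the excised circle is lost — or inverted with equal
probability, justified by loxPsym's palindromic symmetry and exposed as
`p_delete`; between molecules the tails distal to each site are
exchanged reciprocally, so non-allelic exchange between homologues
yields one duplication-bearing and one deletion-bearing molecule while
conserving the cell-wide multiset. Event counts per cell are
Poisson(λ); λ is a free parameter because induction time, not an event
rate, is what experiments control. Consequently the simulator asserts
only *orderings* — viability non-increasing in λ, non-decreasing in the
number of wild-type molecules — and never tries to reproduce measured
viability percentages, which depend on biological rates (calibrating λ
to them would be circular). A cell is viable iff every essential segment
id retains at least one intact copy across all molecules; the optional
strict centromere rule additionally requires exactly one
centromere-bearing segment per molecule (dicentrics and acentrics die).
Excised circles are discarded, never reintegrated; persistent circles
(as extrachromosomal rDNA circles suggest) are future work. An
exhaustive enumeration over all pair choices and branches
(`enumerate_viability()`) serves as the exact oracle for small genomes
and validates the stochastic simulator within binomial error.

**Ploidy classification.** DNA-content histograms are reduced to modes
by local maxima of 3-bin-smoothed counts above 20% of the global
maximum, located at sub-bin resolution by a windowed centroid. The
sample's G1 mode (first major peak) is compared with haploid and diploid
reference peaks on the same fluorescence scale: near the haploid G1 →
1n; near the haploid G2 / diploid G1 → 2n; near the diploid G2 → 4n;
strictly between the diploid G1 and G2, outside the 10% matching
tolerance of both → 3n; otherwise indeterminate.

## Synthetic fixtures: what they emulate, and what they do not

All inputs are generated by seeded, pure functions:

* `make_toy_chromosome()` lays out non-overlapping ORFs (both strands,
  ~20% essential, some Dubious), frame-preserving introns, tRNAs,
  transposon relics and terminal telomeres over a default 60-kb
  chromosome, with a truth table of everything planted. Every ORF
  translates cleanly.
* `simulate_pool_coverage()` draws Poisson per-window depths in which
  the fast pool's synthetic-allele depth at the causal window is
  (1 − s)·mean, recovering linearly over the linkage-decay distance,
  with the displaced reads appearing on the wild-type allele and the
  slow pool mirrored; s is the fraction of fast-pool genomes carrying
  the wild-type allele at the causal locus.
* `simulate_qpcr_table()` draws Cq ~ N(22, 0.5) for present templates
  with on-target melt peaks, leaves absent templates blank except a
  configurable false-amplification rate (emulating cross-contamination:
  late Cq, on-target melt), and includes NTC and positive/negative
  control wells.
* `simulate_pi_histogram()` mixes G1 and G2 Gaussian peaks at positions
  proportional to DNA content (G2 = 2 × G1, CV 7%, 60% of cells in G1).

Deliberately absent: GC-dependent coverage bias, mappability, read-level
error models (the toolkit starts from depth tables, not FASTQ),
melt-curve thermodynamics, plate position effects, and recombination
hot/cold spots. Passing tests therefore demonstrate correctness of the
algorithms under their stated statistical assumptions, not robustness to
every artefact of real sequencing or qPCR data.

## Problem sizes and numerical choices in the test suite

The suites run at sizes chosen to give tight statistical checks while
staying comfortably interactive: ≥1000 random ledger instances against a
naive splice oracle; 200 seeded fixtures for loxPsym placement (compact
15-kb chromosomes) and 200 for chunk tiling (35–60-kb chromosomes with
planted junctions, chunk bounds widened to 4–16 kb to absorb the random
remainder at the right end); 100 seeded replicates each for localizer
recovery (strength 0.8, depth 100) and false positives (strength 0); 200
Poisson seeds for copy-number calibration with a 50-window insert;
10⁴ cells per mask for the buffering ordering; 50 seeds per class for
ploidy recovery. Monte-Carlo assertions use 3–4σ bands around the
analytically expected value, never bands fitted to observed output.

## Known limitations

* The designer finds, and the fixtures plant, junction sites; recoding a
  junction site into existence (as a real design tool could) is not
  implemented.
* Tag windows in intron-containing ORFs are confined to the first exon.
* Literal-allele indels in observed variants are classified via their
  deletion/insertion length only; frameshift consequence calling is
  limited to the symbolic dialect.
* The SCRaMbLE model has no chromatin-contact geometry and discards
  excised circles; both are parameters of interest for future versions.
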