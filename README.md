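# chromoforge

Design, build planning and debugging toolkit for synthetic yeast
chromosomes.

Building a synthetic *Saccharomyces cerevisiae* chromosome to Sc2.0
conventions means rewriting a native chromosome under a fixed rule set —
a loxPsym recombination site 3 bp after the stop codon of every
non-essential gene, introns removed, TAG stop codons swapped to TAA,
open reading frames synonymously recoded to carry allele-distinguishing
PCR tags, telomeres standardized, tRNAs and transposons deleted — then
synthesizing the result as ~10-kb chunks grouped into ~30–60-kb
megachunks that are swapped into the genome one at a time, verifying
each integration by qPCR, and hunting down the design changes that turn
out to cost fitness. chromoforge implements the computational side of
that whole loop for chromosome engineers and for anyone who wants to
study its algorithms on controlled inputs:

* **Design engine** — applies the rules above and records every change
  as an invertible edit ledger, so the designed sequence is reproducible
  bit-exactly from the native one and coordinates lift both ways
  (`apply_design`, `verify_design`, `lift_position`).
* **Assembly planner** — tiles the design into chunks joined at unique
  restriction sites with alternating *LEU2*/*URA3* markers
  (`partition_chunks`, `group_megachunks`, `emit_build_plan`).
* **Genotyping** — calls PCR-tag presence from Cq/melt plates with
  control-driven exclusion of aberrant tags, applies the
  all-synthetic/no-wild-type megachunk acceptance rule, and computes
  efficiency-corrected relative expression
  ratio = E_t^(Cq_t,cal − Cq_t,test) / E_r^(Cq_r,cal − Cq_r,test),
  the modified Livak form that reduces to 2^−ΔΔCq at E = 2
  (`call_tag_presence`, `assess_megachunk`, `relative_expression`).
* **Debug suite** — localizes growth-defect loci from pooled fast/slow
  segregant coverage via median-normalized log2(fast/slow) run
  detection, estimates copy number from depth relative to flanking
  baseline, classifies design-versus-observed discrepancies into
  critical/noncritical classes and plans proximity-bundled repairs
  (`localize_defect`, `estimate_copy_number`, `classify_discrepancies`,
  `plan_repairs`).
* **tRNA array designer** — assigns heterologous 500-bp/40-bp flanks to
  relocated tRNA genes preferentially by anticodon, scrubs 5' flank
  artefacts, excises tRNA introns and interleaves rox sites
  (`assign_flanks`, `build_trna_array`).
* **SCRaMbLE simulator** — models Cre-loxPsym deletion, inversion and
  intermolecular exchange on haploid to tetraploid synthetic/wild-type
  hybrids, scores viability by essential-segment retention, and
  classifies ploidy from propidium-iodide G1/G2 histograms
  (`simulate_population`, `enumerate_viability`, `classify_ploidy`).
* **Fixtures** — seeded generators for every input (annotated toy
  chromosomes with truth tables, pooled coverage, qPCR plates, DNA
  content histograms), so the whole toolkit is testable without any
  external data (`make_toy_chromosome`, `simulate_pool_coverage`,
  `simulate_qpcr_table`, `simulate_pi_histogram`).

## Worked example

Design a synthetic version of a 60-kb toy chromosome, audit it, plan
the build, and compare SCRaMbLE survival of a haploid synthetic strain
against a tetraploid hybrid carrying one wild-type copy:

```r
library(chromoforge)

fx  <- make_toy_chromosome(toy_chromosome_spec(seed = 42))
res <- apply_design(fx$genome)
res
#> Design syn_toy_chr: 60000 -> 58475 bp (-1525, 3% reduction)
#>   loxPsym 14 (+0 skipped), introns removed 2 (retained 0),
#>   stop swaps 8, removals 6, PCR-tag pairs 36 (72 sequences)

verify_design(fx$genome, res$genome, res$ledger)
#> Design verification: PASS
#>                        check pass                        detail
#> 1   ledger_reproduces_design TRUE
#> 2       protein_conservation TRUE
#> 3              loxpsym_count TRUE 14 sites for 14 eligible ORFs
#> 4  no_swappable_stops_remain TRUE
#> 5 no_forbidden_sites_created TRUE

pj   <- plant_junction_sites(res$genome, seed = 42)
plan <- group_megachunks(partition_chunks(pj$genome))
plan
#> ChunkPlan: 6 chunks, 2 megachunks (A-B)

vS    <- simulate_population(build_scramble_genome(res$genome, "S"),
                             lambda = 2, n_cells = 10000, seed = 1)
vWSSS <- simulate_population(build_scramble_genome(res$genome, "WSSS"),
                             lambda = 2, n_cells = 10000, seed = 1)
c(S = vS$viability, WSSS = vWSSS$viability)
#>     S  WSSS
#> 0.531 1.000

relative_expression(1.9, 22, 20, 2, 20, 20)
#> [1] 3.61
```

Reading the numbers: the 14 loxPsym sites match the 14 non-essential
verified/uncharacterized ORFs the generator planted, and every design
edit is reproducible from the ledger (`verify_design` PASS). Under two
Cre events per cell on average, roughly half the haploid synthetic
cells lose an essential segment, while the extra chromosome copies in
the hybrid tetraploid buffer essential-gene loss completely in this
model — the ordering, not the absolute percentages, is the model's
claim. The expression ratio 3.61 is 1.9², the efficiency-corrected
fold change for a 2-cycle shift of the target with an unchanged
reference.

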