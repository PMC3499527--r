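# estmine

Marker and expression mining for allotetraploid EST collections.

Allotetraploid crops such as cultivated cotton (*Gossypium hirsutum* x
*G. barbadense* type species) carry two diverged sub-genomes (A and D), so
an EST assembly from pooled cDNA libraries co-assembles four closely
related sequences per gene: the two homoeologous copies of each of two
genotypes. Variants inside such contigs mix two very different things —
fixed homoeologous differences (present within *every* genotype, useless as
markers) and allelic differences between genotypes (usable for mapping).
`estmine` implements the computational layer such a study needs, end to
end, with a synthetic tetraploid transcriptome generator so every stage is
testable without any downloads:

* **Read simulation** — two sub-genome copies per gene diverged from a
  common ancestor, two genotypes with private allelic substitutions,
  optional silencing of one homoeo-copy, two developmental stages with a
  planted differential-expression fraction, and 454-like reads (mean
  length 353 bp) with full ground truth (`sim_config()`,
  `simulate_transcriptome()`, `simulate_reads()`).
* **I/O and pileups** — FASTA (via Biostrings), ACE assembly parsing, the
  100 bp read-length filter, and per-position allele depths stratified by
  genotype and sub-genome tag (`read_ace()`, `trim_filter_reads()`,
  `build_pileup()`).
* **Sub-genome tagging** — each read is scored against two diploid
  progenitor transcript panels by an 11-mer seeded, ungapped-extension
  local aligner (score = matches − mismatches); a read is tagged `A` or
  `D` only when it hits both panels above threshold with strictly unequal
  scores; ties and one-sided hits stay `unknown` (`tag_library()`).
* **Digital gene expression** — counts per contig normalized per 10,000
  reads; the Stekel–Git–Falciani R statistic
  `R = Σⱼ xⱼ ln( xⱼ / (Nⱼ f) )`, `f = Σxⱼ / ΣNⱼ`, with `2R ~ χ²(k−1)`;
  two-sided Fisher's exact test on (reads-in-contig, other reads) ×
  group; a contig is differential at `p < 0.05` and normalized fold ≥ 2;
  the full factorial of stage / genotype / sub-genome contrasts
  (`stekel_r()`, `fisher_exact_2x2()`, `compare_groups()`,
  `comparison_matrix()`, `platform_concordance()`).
* **SNP mining** — per genotype a position is polymorphic when depth ≥ 6
  and the minor allele reaches 10% of the genotype's depth with ≥ 2
  occurrences; dual-coverage positions partition into case A (both
  genotypes polymorphic: homoeo-SNP), cases B/C (one genotype
  polymorphic: allelic), case D (both monomorphic, different alleles:
  fixed inter-genotypic difference), with Ts/Tv accounting, SNP-density
  summaries, 60 bp flank export and VCF output (`scan_contig()`,
  `snp_summary()`, `export_vcf()`).
* **SSR mining and primers** — MISA-parameterized microsatellite
  detection (≥10 mono, ≥6 di, ≥5 tri–hexa repeats, compound repeats
  within 100 bp), canonical motif classes, design-candidate filtering,
  and allele-specific primer triplets: two tailed forward primers (15-
  and 5-base tails, products differing by exactly 10 bp) ending on their
  target allele with a destabilizing transversion mismatch at position −4
  from the 3' end, plus a common reverse primer (`find_ssrs()`,
  `design_snp_triplet()`).
* **Orchestration** — `run_pipeline()` runs simulate → filter → tag →
  pileup → DGE → SNP → SSR → primers → report deterministically from one
  seeded configuration.

## Worked example

```r
library(estmine)

cfg <- sim_config(n_genes = 20, reads_per_library = 1500, seed = 7)
run <- run_pipeline(cfg)
run
#> EST mining pipeline run
#>   reads: 6000 total, 6000 high-quality (mean 353 bp)
#>   tagged A/D: 2477 / 3464 of 6000 reads
#>   SNPs: 305 positions (A=158 B=89 C=55 D=3); 1/93 bp inter-genotypic
#>   SSRs: 0 (p2-p6 + compound)
#>   primer triplets designed: 49
```

The SNP line is the partition described above: of 305 variant positions
covered ≥6x in both genotypes, 158 are polymorphic in both (homoeo-SNPs,
case A — sub-genome differences, not markers), 89+55 in exactly one
(allelic, cases B/C) and 3 are fixed differences (case D); the
inter-genotypic classes together give one marker-grade SNP every 93 bp of
dual-covered sequence (the planted allelic rate is 1/108 per genotype
before silencing and sampling effects). Random 20-gene sequences rarely
contain qualifying microsatellites, hence 0 SSRs here. Individual stages
are available as plain functions:

```r
stekel_r(c(0, 10), c(100, 100))      # 6.931 (= 10 ln 2)
fisher_exact_2x2(2, 0, 0, 2)         # 0.3333
canonical_motif("TC")$class          # "AG/CT"
```

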