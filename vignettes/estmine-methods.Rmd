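---
title: "Methods: homoeolog-aware EST mining in an allotetraploid transcriptome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homoeolog-aware EST mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estmine)
```

## The problem

An allotetraploid species carries two diverged ancestral sub-genomes (A
and D). When cDNA from such a species is sequenced and assembled, the two
homoeologous copies of a gene usually co-assemble into one contig, and if
two genotypes are pooled (say a *G. hirsutum*-type `Gh` and a
*G. barbadense*-type `Gb`, each at two fiber development stages, giving
four libraries `Gh10, Gb10, Gh22, Gb22`), a contig column can show up to
four distinct bases. Variant positions therefore mix:

* **homoeo-SNPs** — fixed A-vs-D differences, polymorphic *within every
  genotype*; abundant but useless as genetic markers;
* **allelic SNPs** — differences *between* genotypes; these are the
  mappable markers;
* silencing effects — when a genotype expresses only one homoeo-copy of
  a gene, its side of the alignment collapses to one base.

`estmine` implements the full computational chain for this setting:
simulation with ground truth, read filtering, sub-genome read tagging,
stratified pileups, count-based differential expression, the variant
partition, microsatellite detection, and allele-specific primer design.

## The synthetic transcriptome generator

`simulate_transcriptome()` draws, per gene, an ancestral sequence and
derives four haplotypes (copy A/D × genotype Gh/Gb):

* homoeo-substitutions at rate `homoeo_divergence` (default 1/80 per bp)
  applied to the D copy and shared by both genotypes;
* allelic substitutions at rate `allelic_divergence` (default 1/108 per
  bp), each private to one copy in one genotype;
* the two position classes are drawn jointly without replacement, so they
  are disjoint by construction; configurations whose expected edits
  exceed a third of the gene are rejected as collision-prone.

The default rates are the intra- and inter-genotypic SNP density scales
reported for tetraploid cotton ESTs; the default gene-length range
(600–1600 bp) straddles the ~1.1 kb mean contig length of a 454 EST
assembly. Substitutions are uniform over the three alternative bases —
transitions are *not* favoured, so the expected transition fraction among
planted variants is 1/3. This is deliberate: the package tallies Ts/Tv as
an observable, and a uniform model lets the tally be verified against a
known value rather than baking the empirical ~61% transition excess into
the generator.

Expression: each gene gets a lognormal baseline split equally between its
copies. With probability `silenced_fraction` (default 0.05) per gene ×
genotype, one copy's expression is set to zero (the sequence is kept —
silencing is transcriptional, which is what produces the fixed-difference
case D below when the two genotypes silence opposite copies). A fraction
`de_fraction` (default 0.07, the share of stage-differential contigs in
this kind of dataset) of gene-copies receives a `de_fold` (default 4)
multiplier on one stage. `simulate_reads()` then draws
`reads_per_library` reads per library (default 20,000) with gene-copy
probabilities proportional to expression, lengths from a normal model
(353 ± 40 bp, resampled below 1 bp, capped at gene length), uniform start
positions, and uniform substitution errors at `read_error_rate` (default
0.005 per bp, a 454-like substitution component). Because each read
records its placement on the ancestral coordinate system, one truth
alignment per gene is available and assembly is bypassed by construction.

What the generator does **not** emulate: homopolymer-biased 454 errors,
indels, chimeric reads, real assembly artifacts (mis-assembly, collapsed
paralogs), or quality scores. Tests passing on this generator validate
the statistical and algorithmic machinery, not robustness to assembler
pathology.

`simulate_count_table()` is a count-level shortcut (multinomial library
draws over lognormal contig abundances with planted stage effects) used
for calibration and recovery studies of the expression layer, where read-
level detail is irrelevant.

## Sub-genome tagging

Reads are compared against two progenitor transcript panels (A-like and
D-like diploids). The comparison is an 11-mer seeded, ungapped-extension
local alignment implemented in C++: every shared 11-mer seeds a diagonal,
and the best ungapped local alignment on a seeded diagonal is the
maximum-sum segment of the +1 (match) / −1 (mismatch) profile. The score
is matches − mismatches, maximized over panel sequences; no seed means
score 0. This is a deliberately reproducible, dependency-free stand-in
for a Blat-style search — adequate because tagging only needs relative
similarity to two panels, not spliced or translated alignment.

The assignment rule: a read is tagged `A` (or `D`) only when it scores at
least `min_score` against *both* panels with strictly unequal integer
scores. Equal scores are a tie; a hit against only one panel is also left
`unknown` — the conservative rule treats a one-sided hit as possible
contamination or a panel gap rather than evidence. Because the rule is
arguably too strict, `one_sided = "assign"` switches to the permissive
alternative; the literal rule is the default. `min_score = 30` is a
declared default (roughly a 30 bp perfect match), not a literature value.
Symmetry (swapping the panels swaps A and D), monotonicity in
`min_score`, and precision against simulation truth are all tested.

## Digital gene expression

Counts are normalized per 10,000 reads of the relevant total. The
normalization denominator is the reads assembled per library
(reads-in-contigs, the column sums of the count table) because the
counted unit is contig membership; callers can pass raw library totals
via `lib_totals` to switch conventions. Tag-stratified contrasts
normalize by the tagged reads of that tag class in the selected
libraries, since untagged reads carry no A/D information.

Heterogeneity of a contig's counts across libraries is measured by the
log-likelihood-ratio statistic

$$R = \sum_j x_j \ln\!\frac{x_j}{N_j f}, \qquad f = \frac{\sum_j x_j}{\sum_j N_j},$$

with zero-count terms contributing 0. `R` is exactly 0 for counts
proportional to library sizes; `2R` is the deviance of the corresponding
multinomial comparison and is referred to χ² with (number of libraries −
1) degrees of freedom (`stekel_r_pvalue()`). The source method names the
statistic but not the >2-group p-value recipe; the χ² reference is this
package's declared choice. Two-group significance uses the two-sided
Fisher's exact test on the 2×2 table (reads in contig, other reads) ×
group, computed by direct hypergeometric summation of tables no more
probable than the observed one (with the conventional 1 + 1e−7 relative
tolerance; the all-zero table returns p = 1). A contig is flagged
differential for the group with the higher normalized abundance when
`p < alpha` (default 0.05) and fold ≥ `min_fold` (default 2; an infinite
fold from a one-sided zero qualifies, a both-zero contig never does).
No multiple-testing correction is applied by default, matching the
count-based screening practice this pipeline reproduces; results are
plain data frames, so `p.adjust` is one line away.

One numerical point deserves a record. The asymptotic-consistency check
"the χ² p-value of 2R agrees with the exact p within 0.02 when expected
counts reach 10" cannot hold pointwise over the whole unit interval for
*any* implementation: the two-sided exact p saturates at 1 near the
table mode (a discrete test at the mode has p = 1, while a continuous χ²
reference gives, e.g., 0.85 for the same table), and even in the
moderate tail the gap shrinks only slowly with expected counts. The
consistency the pipeline actually relies on — agreement where
significance is decided — does hold: the test suite asserts
|p(χ²) − p(exact)| ≤ 0.02 for seeded tables with all expected counts
≥ 10 and exact p ≤ 0.05.

`comparison_matrix()` enumerates each factor contrast (stage, genotype,
tag) overall and nested within every level and level pair of the other
factors — the full comparison fan of a two-genotype × two-stage tagged
study. Per comparison, the pair of differential counts is itself tested
with a 2×2 Fisher test against the remaining tested contigs (the source
material marks such pairs as significant without stating the
construction; this is the package's declared choice).
`platform_concordance()` tallies direction agreement for genes called
differential on two platforms and reports the rounded percentage.

## The variant partition

Within one genotype, a position is assessable at coverage ≥ `min_depth`
(default 6) and polymorphic when at least two alleles each reach
`min_minor` occurrences (default 2) **and** `maf` (default 0.10) of that
genotype's depth — "10% of the alleles examined" is read as 10% of the
genotype's depth at the position, and both conditions are required.
Monomorphic calls report the majority allele; an exact tie (impossible
under the default thresholds, possible at others) breaks
lexicographically. Pads, read gaps and `N` bases contribute no depth, and
indels are excluded at the pileup level — only base changes are
considered.

Positions covered ≥ `min_depth` by *both* genotypes (the eligible bases,
which form the denominator of the inter-genotypic SNP density) are
classified: both polymorphic → case A (homoeo-SNP); exactly one → case B
(`Gh`) or C (`Gb`); both monomorphic with different alleles → case D
(fixed difference, interpreted as each genotype expressing only one
sub-genome copy). Cases B/C do not additionally require the monomorphic
genotype's allele to match one of the polymorphic genotype's alleles; a
boolean records whether it does. Multi-allelic positions are counted as
single positions. The single-genotype intra scan runs independently of
dual coverage, so contigs covered by only one genotype still contribute
intra-genotypic SNPs.

Flank export writes `LEFT[ref/alt]RIGHT` records with up to 60 bp per
side (truncated at contig ends), named `contig_position` on the unpadded
consensus; the VCF export writes minimal VCF 4.2 with the class in
`INFO/CLASS` and per-genotype `GT` columns, and is round-tripped through
`VariantAnnotation::readVcf` in the tests.

## Microsatellites and primer triplets

`find_ssrs()` follows MISA semantics: maximal perfect tandem runs per
unit length 1–6 with minimum repeat counts 10 / 6 / 5 / 5 / 5 / 5, runs
truncated to complete units, and a run whose unit is itself a repetition
of a shorter unit reported at the shortest unit (so `ATATAT` is p2,
never p6). Detection compares the sequence against itself shifted by the
unit length; maximal runs fall out of the run-length encoding, and the
scanner is verified against an independent regex-backreference oracle.
Qualifying repeats of unit 2–6 separated by ≤ 100 bp merge into compound
records; mononucleotide runs are detected but reported separately and
never join compounds, mirroring the practice of excluding homopolymers
from SSR totals. Motif classes are canonicalized to the
lexicographically smallest member of the rotation ∪ reverse-complement
orbit (`TC → AG/CT`). Design candidates must keep `min_flank` (default
50) non-repeat bases on both sides.

`design_snp_triplet()` builds the allele-specific PCR triplet: two
forward primers ending on their target allele at the 3′ terminus, tailed
with 15 and 5 bases so the two allelic products differ by exactly 10 bp,
each with a destabilizing mismatch at position −4 from the 3′ end. The
mismatch is a transversion of the template base, with a different
transversion mapping per primer (A→C/G→T for one, A→T/G→C for the
other), so the two primers always carry different substituted bases —
the source protocol specifies two different mismatches at −4 without
naming the bases; this is the package's convention. Which allele gets
the long tail is configurable (allele 1 by default). Thermodynamic
optimization is out of scope: primers carry only a GC% and a simple
GC/length melting-temperature heuristic for logging, not a
nearest-neighbor model.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains the stages from one `sim_config()`; every
threshold is an argument with the defaults above, any stage failure
aborts with the stage name, and identical configurations (including the
seed) produce byte-identical outputs — the read simulator consumes
`seed + 1` so transcriptome and read draws are independently
reproducible. The default configuration (200 genes, 4 × 20,000 reads)
runs in well under five minutes on one CPU; the test suite works at
smaller scales chosen for coverage per second: 25 genes × 4 × 2,500
reads (~64× per-genotype coverage) for tagging and variant recovery,
1,000 null contigs for type-I calibration, 200 contigs for
differential-expression recovery, and 100 random 10-kb sequences for the
SSR oracle equivalence.

Recovery testing uses two oracles: the *planted* class of each variant
position, and the class *implied* by the planted truth plus the reads
actually drawn (per-copy coverage pushed through the calling rules).
On error-free data every call must equal the implied class, and every
planted position whose copies are all observably sampled must be
recovered as its planted class — this separates classifier correctness
from sampling starvation (a genotype whose minor copy drew one read at
a position is correctly monomorphic there, and the truth-implied oracle
says so).

## Known limitations

* The tagging aligner is ungapped; a single indel error in a read (not
  simulated) would split its alignment.
* The variant caller does not distinguish heterozygosity from paralogy
  beyond the case logic; truly heterozygous inbred material would
  inflate cases B/C.
* Fisher's test on (contig, rest) pairs treats reads as independent
  draws; fragment-level dependencies (duplicates, expression bursts) are
  not modelled.
* The density denominators count dual-coverage bases only; comparisons
  with densities computed over assembled length must rescale.
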