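cnt <- function(A = 0, C = 0, G = 0, T = 0) c(A = A, C = C, G = G, T = T)

test_that("intra-genotype calls apply depth, MAF and minor-count rules", {
  r <- call_intra_genotype(cnt(A = 6, G = 6))
  expect_true(r$polymorphic)
  expect_equal(r$alleles, c("A", "G"))

  # 2/21 = 9.5% fails the 10% MAF rule despite 2 occurrences
  r <- call_intra_genotype(cnt(A = 19, G = 2))
  expect_false(r$polymorphic)
  expect_equal(r$alleles, "A")

  # minor allele with 1 occurrence fails min_minor even at high frequency
  r <- call_intra_genotype(cnt(A = 5, G = 1))
  expect_false(r$polymorphic)

  # depth below 6 is not assessable
  r <- call_intra_genotype(cnt(A = 5))
  expect_false(r$assessable)
  expect_true(is.na(r$polymorphic))

  # majority tie breaks lexicographically
  r <- call_intra_genotype(cnt(G = 9, T = 9), maf = 0.6)
  expect_equal(r$alleles, "G")
})

test_that("positions partition into the four variant cases", {
  cl <- classify_position(cnt(A = 6, G = 6), cnt(A = 6, G = 6))
  expect_identical(cl$classification, "caseA_homoeo")

  cl <- classify_position(cnt(A = 6, G = 6), cnt(A = 12))
  expect_identical(cl$classification, "caseB_Gh_poly")
  expect_true(cl$mono_allele_shared)

  cl <- classify_position(cnt(A = 12), cnt(A = 6, G = 6))
  expect_identical(cl$classification, "caseC_Gb_poly")

  cl <- classify_position(cnt(A = 10), cnt(G = 10))
  expect_identical(cl$classification, "caseD_fixed_diff")
  expect_equal(cl$alleles, c("A", "G"))

  cl <- classify_position(cnt(A = 10), cnt(A = 10))
  expect_identical(cl$classification, "none")

  # a genotype below 6x is not assessable even if total depth is ample
  cl <- classify_position(cnt(A = 3, G = 2), cnt(A = 12))
  expect_identical(cl$classification, "not_assessable")
})

test_that("transition and transversion classes are assigned correctly", {
  expect_identical(ts_tv(c("A", "G")), "transition")
  expect_identical(ts_tv(c("T", "C")), "transition")
  expect_identical(ts_tv(c("A", "C")), "transversion")
  expect_identical(ts_tv(c("A", "C", "G")), "multi")
  expect_error(ts_tv("A"), "two alleles")
})

test_that("contig scans recover planted variant classes on error-free reads", {
  fx <- clean_sim()
  pus <- clean_pileups()
  planted <- planted_classes(fx$truth)
  for (g in names(pus)[1:8]) {
    sc <- scan_contig(pus[[g]])
    pl <- planted[planted$gene == g, ]
    implied <- truth_implied_classes(fx$truth, fx$sim$reads, g, pl$pos)
    # error-free: no calls outside planted positions
    expect_true(all(sc$calls$pos %in% pl$pos), info = g)
    # every call equals the class the truth reads imply
    m <- merge(sc$calls, implied, by = "pos")
    expect_true(all(m$classification == m$implied), info = g)
    # planted positions with every copy observably sampled are recovered
    # as their planted class
    ws <- merge(pl, implied[implied$well_sampled, ], by = "pos")
    got <- setNames(sc$calls$classification, sc$calls$pos)
    expect_identical(unname(got[as.character(ws$pos)]), ws$class, info = g)
  }
})

test_that("single-genotype coverage still feeds the intra scan", {
  s <- random_dna(1, 60)
  alt <- chartr("ACGT", "GTAC", substr(s, 30, 30))
  s_alt <- s
  substr(s_alt, 30, 30) <- alt
  p <- data.frame(read_id = sprintf("r%d", 1:8), start = 1L, strand = "+",
                  seq = rep(c(s, s_alt), each = 4),
                  stringsAsFactors = FALSE)
  a <- contig_alignment("c1", s, p)
  pu <- build_pileup(a, setNames(rep("Gh10", 8), p$read_id))
  sc <- scan_contig(pu)
  expect_equal(sc$eligible_bases, 0L)         # no dual coverage
  expect_equal(nrow(sc$calls), 0L)
  expect_equal(unname(sc$assessable_bases["Gh"]), 60)
  expect_equal(sc$intra$pos, 30L)
  expect_identical(sc$intra$genotype, "Gh")

  # all-identical reads yield no variants at all
  p2 <- data.frame(read_id = sprintf("q%d", 1:12), start = 1L,
                   strand = "+", seq = s, stringsAsFactors = FALSE)
  pu2 <- build_pileup(contig_alignment("c1", s, p2),
                      setNames(rep(c("Gh10", "Gb10"), 6), p2$read_id))
  sc2 <- scan_contig(pu2)
  expect_equal(nrow(sc2$calls), 0L)
  expect_equal(nrow(sc2$intra), 0L)
  expect_equal(sc2$eligible_bases, 60L)
})

test_that("raising min_depth never increases classified positions", {
  pus <- clean_pileups()
  for (g in names(pus)[1:5]) {
    n6 <- nrow(scan_contig(pus[[g]], min_depth = 6)$calls)
    n12 <- nrow(scan_contig(pus[[g]], min_depth = 12)$calls)
    n20 <- nrow(scan_contig(pus[[g]], min_depth = 20)$calls)
    expect_lte(n12, n6)
    expect_lte(n20, n12)
  }
})

test_that("summaries satisfy the partition identities", {
  mk_calls <- function(nA, nB, nC, nD) {
    n <- nA + nB + nC + nD
    data.frame(
      contig = rep("c", n), pos = seq_len(n),
      classification = rep(c("caseA_homoeo", "caseB_Gh_poly",
                             "caseC_Gb_poly", "caseD_fixed_diff"),
                           c(nA, nB, nC, nD)),
      biallelic = rep(TRUE, n), subst_type = rep("transition", n),
      stringsAsFactors = FALSE)
  }
  s <- snp_summary(mk_calls(18153, 19439, 0, 1507), 2257950)
  expect_equal(s$n_variant_positions, 39099)
  expect_equal(s$n_intergenotypic, 20946)
  expect_equal(s$density_bp, 108)

  s0 <- snp_summary(mk_calls(0, 0, 0, 0), 1000)
  expect_equal(s0$n_variant_positions, 0)
  expect_true(is.na(s0$density_bp))
})

test_that("flank export truncates at contig ends and names by position", {
  cons <- c(c1 = random_dna(1, 200))
  calls <- data.frame(contig = "c1", pos = c(61L, 10L, 195L),
                      alleles = c("A,G", "C,T", "A,C"),
                      stringsAsFactors = FALSE)
  fl <- export_snp_flanks(calls, cons, flank = 60L)
  expect_equal(fl$name, c("c1_61", "c1_10", "c1_195"))
  expect_match(fl$flanked[1], "^[ACGT]{60}\\[A/G\\][ACGT]{60}$")
  expect_match(fl$flanked[2], "^[ACGT]{9}\\[C/T\\][ACGT]{60}$")
  expect_match(fl$flanked[3], "^[ACGT]{60}\\[A/C\\][ACGT]{5}$")
  expect_error(export_snp_flanks(
    data.frame(contig = "c1", pos = 500L, alleles = "A,G"), cons),
    "outside")
})

test_that("VCF export round-trips through a standard VCF reader", {
  skip_if_not_installed("VariantAnnotation")
  fx <- clean_sim()
  pus <- clean_pileups()
  calls <- do.call(rbind, lapply(pus[1:5], function(p) {
    scan_contig(p)$calls
  }))
  tmp <- withr::local_tempfile(fileext = ".vcf")
  export_vcf(calls, fx$truth$ancestral, tmp)
  v <- VariantAnnotation::readVcf(tmp, genome = "sim")
  expect_equal(nrow(v), nrow(calls))
  gr <- SummarizedExperiment::rowRanges(v)
  expect_equal(BiocGenerics::start(gr), calls$pos)
  # REF allele re-maps onto the consensus base at each position
  ref <- as.character(gr$REF)
  cons_base <- substr(fx$truth$ancestral[calls$contig],
                      calls$pos, calls$pos)
  expect_identical(ref, unname(cons_base))
})
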