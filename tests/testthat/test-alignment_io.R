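test_that("FASTA round-trips, normalizes case, and flags malformed input", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  recs <- setNames(random_dna(3, c(50, 80, 120)), c("r1", "r2", "r3"))
  write_fasta(recs, tmp)
  expect_identical(read_fasta(tmp), recs)

  write_fasta(character(0), tmp)
  expect_length(read_fasta(tmp), 0L)

  writeLines(c(">low", "acgtacgt"), tmp)
  expect_identical(unname(read_fasta(tmp)), "ACGTACGT")

  writeLines(c("ACGT", "ACGT"), tmp)
  expect_error(read_fasta(tmp), "malformed")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "no such file")
})

ace_fixture <- function() {
  c("AS 1 2",
    "",
    "CO ctg1 14 2 0 U",
    "ACGT*ACGTACGTA",
    "",
    "AF read1 U 1",
    "AF read2 U 6",
    "",
    "RD read1 9 0 0",
    "ACGT*ACGT",
    "",
    "RD read2 9 0 0",
    "ACGTACGTA",
    "")
}

test_that("ACE parsing honours offsets, pads and complemented reads", {
  tmp <- withr::local_tempfile(fileext = ".ace")
  writeLines(ace_fixture(), tmp)
  ace <- read_ace(tmp)
  expect_length(ace, 1L)
  a <- ace[["ctg1"]]
  expect_equal(a$placements$start, c(1L, 6L))
  expect_equal(a$placements$read_id, c("read1", "read2"))
  # unpadded length = padded length - pad count
  maps <- pad_maps(a$consensus)
  expect_equal(length(maps$unpad_to_pad), nchar(a$consensus) - 1L)

  # complemented read is stored reverse-complemented (consensus-forward)
  fix <- ace_fixture()
  fix[7] <- "AF read2 C 6"
  writeLines(fix, tmp)
  a2 <- read_ace(tmp)[["ctg1"]]
  expect_identical(a2$placements$seq[2], revcomp("ACGTACGTA"))
  expect_identical(a2$placements$strand[2], "-")

  writeLines(character(0), tmp)
  expect_length(read_ace(tmp), 0L)

  writeLines(ace_fixture()[1:9], tmp)  # drop the second RD
  expect_error(read_ace(tmp), "ctg1")
})

test_that("ACE round-trip preserves simulated alignments", {
  fx <- clean_sim()
  tmp <- withr::local_tempfile(fileext = ".ace")
  alns <- fx$sim$alignments[1:3]
  write_ace(alns, tmp)
  back <- read_ace(tmp)
  for (g in names(alns)) {
    expect_identical(back[[g]]$consensus, alns[[g]]$consensus)
    expect_equal(back[[g]]$placements$start, alns[[g]]$placements$start)
    expect_equal(back[[g]]$placements$seq, alns[[g]]$placements$seq)
  }
})

test_that("read-length filter applies the >= boundary and is idempotent", {
  reads <- data.frame(read_id = sprintf("r%d", 1:3), library = "Gh10",
                      sequence = random_dna(3, c(99, 100, 101)),
                      stringsAsFactors = FALSE)
  f <- trim_filter_reads(reads, min_len = 100L)
  expect_equal(nrow(f$kept), 2L)
  expect_equal(f$summary$n_short, 1L)
  f2 <- trim_filter_reads(f$kept, min_len = 100L)
  expect_identical(f2$kept, f$kept)

  all99 <- data.frame(read_id = "r", library = "Gh10",
                      sequence = random_dna(1, 99))
  expect_equal(nrow(trim_filter_reads(all99)$kept), 0L)
})

test_that("pileup counts uniform coverage and stratifies by genotype", {
  s <- random_dna(1, 40)
  p <- data.frame(read_id = sprintf("r%d", 1:10), start = 1L,
                  strand = "+", seq = s, stringsAsFactors = FALSE)
  a <- contig_alignment("c1", s, p)
  libs <- setNames(rep(c("Gh10", "Gb22"), 5), p$read_id)
  pu <- build_pileup(a, libs)
  expect_equal(rowSums(pu$genotype), rep(10, 40))
  expect_true(all(apply(pu$genotype[, , "Gh"] + pu$genotype[, , "Gb"],
                        1, function(x) sum(x > 0)) == 1L))

  # 6 Gh 'A' vs 6 Gb 'G' at one position
  a2 <- contig_alignment(
    "c2", "A",
    data.frame(read_id = sprintf("r%d", 1:12), start = 1L, strand = "+",
               seq = rep(c("A", "G"), each = 6), stringsAsFactors = FALSE))
  libs2 <- setNames(rep(c("Gh10", "Gb10"), each = 6),
                    sprintf("r%d", 1:12))
  pu2 <- build_pileup(a2, libs2)
  expect_equal(pu2$genotype[1, "A", "Gh"], 6L)
  expect_equal(pu2$genotype[1, "G", "Gb"], 6L)
  expect_equal(sum(pu2$genotype), 12L)
})

test_that("pads, gaps and N bases contribute zero depth", {
  a <- contig_alignment(
    "c1", "AC*GT",
    data.frame(read_id = c("r1", "r2"), start = 1L, strand = "+",
               seq = c("AC*GT", "NC*G*"), stringsAsFactors = FALSE))
  pu <- build_pileup(a, setNames(c("Gh10", "Gb10"), c("r1", "r2")))
  expect_equal(pu$length, 4L)
  expect_identical(pu$consensus_unpadded, "ACGT")
  expect_equal(sum(pu$genotype[1, , ]), 1L)  # N excluded
  expect_equal(sum(pu$genotype[4, , ]), 1L)  # r2 gap excluded
  expect_equal(unname(pu$genotype[3, "G", "Gh"]), 1L)

  expect_error(build_pileup(a, c(r1 = "Gh10")), "library")
})

test_that("depth is conserved across genotype and tag stratifications", {
  fx <- clean_sim()
  lib_of <- setNames(fx$sim$reads$library, fx$sim$reads$read_id)
  tag_of <- setNames(sample(c("A", "D", "unknown"), nrow(fx$sim$reads),
                            replace = TRUE), fx$sim$reads$read_id)
  for (a in fx$sim$alignments[1:4]) {
    pu <- build_pileup(a, lib_of, tag_of)
    expect_equal(rowSums(pu$genotype), rowSums(pu$tag))
    # total depth equals total aligned read bases (error-free, no N)
    expect_equal(sum(pu$genotype),
                 sum(nchar(a$placements$seq)))
  }
})

test_that("pileup depths at planted variants match the truth read counts", {
  fx <- clean_sim()
  pus <- clean_pileups()
  reads <- fx$sim$reads
  ap <- fx$truth$allelic
  set.seed(2)
  for (j in sample.int(nrow(ap), 10L)) {
    g <- ap$gene[j]; pos <- ap$pos[j]
    pu <- pus[[g]]
    rr <- reads[reads$gene == g &
                  reads$start <= pos &
                  reads$start + reads$length - 1L >= pos, ]
    for (gt in c("Gh", "Gb")) {
      expect_equal(sum(pu$genotype[pos, , gt]), sum(rr$genotype == gt))
    }
    # the variant allele is carried exactly by the mutated copy's reads
    alt <- substr(fx$truth$sequences[[g]][[ap$copy[j], ap$genotype[j]]],
                  pos, pos)
    expect_equal(unname(pu$genotype[pos, alt, ap$genotype[j]]),
                 sum(rr$genotype == ap$genotype[j] & rr$copy == ap$copy[j]))
  }
})

test_that("padded and unpadded coordinate maps are mutually inverse", {
  cons <- "AC*GT**AAC*G"
  m <- pad_maps(cons)
  expect_equal(m$pad_to_unpad[m$unpad_to_pad], seq_along(m$unpad_to_pad))
  nonpad <- which(!is.na(m$pad_to_unpad))
  expect_equal(m$unpad_to_pad[m$pad_to_unpad[nonpad]], nonpad)
})
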