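# Shared simulated fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# clean, error-free dataset with good depth: the workhorse for tagging and
# SNP-recovery checks (~64x per genotype)
clean_sim <- function() {
  fixture("clean_sim", function() {
    cfg <- sim_config(n_genes = 25L, gene_length = c(900L, 1300L),
                      silenced_fraction = 0, de_fraction = 0,
                      reads_per_library = 2500L, read_error_rate = 0,
                      seed = 42L)
    truth <- simulate_transcriptome(cfg)
    sim <- simulate_reads(truth, cfg)
    list(cfg = cfg, truth = truth, sim = sim)
  })
}

# pileups for the clean dataset
clean_pileups <- function() {
  fixture("clean_pileups", function() {
    fx <- clean_sim()
    lib_of <- stats::setNames(fx$sim$reads$library, fx$sim$reads$read_id)
    lapply(fx$sim$alignments, build_pileup, read_library = lib_of)
  })
}

# expected Fig-5 class per planted position (no silencing, so homoeo
# positions are case A and allelic positions case B (Gh) or C (Gb))
planted_classes <- function(truth) {
  hp <- do.call(rbind, lapply(names(truth$homoeo_pos), function(g) {
    if (!length(truth$homoeo_pos[[g]])) return(NULL)
    data.frame(gene = g, pos = truth$homoeo_pos[[g]],
               class = "caseA_homoeo", stringsAsFactors = FALSE)
  }))
  ap <- truth$allelic
  ap$class <- ifelse(ap$genotype == "Gh", "caseB_Gh_poly", "caseC_Gb_poly")
  rbind(hp, ap[, c("gene", "pos", "class")])
}

# reads annotated with whether they span >= 1 planted homoeo-SNP of their
# source gene
reads_spanning_homoeo <- function(truth, reads) {
  vapply(seq_len(nrow(reads)), function(i) {
    hp <- truth$homoeo_pos[[reads$gene[i]]]
    any(hp >= reads$start[i] & hp <= reads$start[i] + reads$length[i] - 1L)
  }, logical(1))
}

# class implied by the planted truth AND the reads actually drawn: applies
# the depth/MAF/min-minor rule arithmetic to per-copy truth coverage,
# independently of the pileup machinery (error-free data only)
truth_implied_classes <- function(truth, reads, gene, positions,
                                  min_depth = 6L, maf = 0.10,
                                  min_minor = 2L) {
  rr <- reads[reads$gene == gene, ]
  seqs <- truth$sequences[[gene]]
  out <- character(length(positions))
  well <- logical(length(positions))
  for (k in seq_along(positions)) {
    pos <- positions[k]
    cov <- rr[rr$start <= pos & rr$start + rr$length - 1L >= pos, ]
    gcall <- list(); qual_ok <- TRUE
    for (gt in c("Gh", "Gb")) {
      cc <- cov[cov$genotype == gt, ]
      if (!nrow(cc)) {
        gcall[[gt]] <- list(assessable = FALSE)
        qual_ok <- FALSE
        next
      }
      allele_of_copy <- vapply(c("A", "D"), function(cp) {
        substr(seqs[[cp, gt]], pos, pos)
      }, character(1))
      cnt <- table(factor(allele_of_copy[cc$copy],
                          levels = c("A", "C", "G", "T")))
      gcall[[gt]] <- call_intra_genotype(c(cnt), min_depth, maf, min_minor)
      # both copies observably sampled under the rule arithmetic?
      d <- sum(cnt)
      for (cp in c("A", "D")) {
        ncp <- sum(cc$copy == cp)
        if (ncp < min_minor || ncp / max(d, 1) < maf) qual_ok <- FALSE
      }
      if (d < min_depth) qual_ok <- FALSE
    }
    gh <- gcall$Gh; gb <- gcall$Gb
    out[k] <- if (!isTRUE(gh$assessable) || !isTRUE(gb$assessable)) {
      "not_assessable"
    } else if (gh$polymorphic && gb$polymorphic) {
      "caseA_homoeo"
    } else if (gh$polymorphic) {
      "caseB_Gh_poly"
    } else if (gb$polymorphic) {
      "caseC_Gb_poly"
    } else if (gh$alleles != gb$alleles) {
      "caseD_fixed_diff"
    } else "none"
    well[k] <- qual_ok
  }
  data.frame(pos = positions, implied = out, well_sampled = well,
             stringsAsFactors = FALSE)
}
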