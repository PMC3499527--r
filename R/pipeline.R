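#' Run the full synthetic EST mining pipeline
#'
#' Orchestrates every stage on a simulated dataset: transcriptome and read
#' simulation, short-read filtering, sub-genome tagging against the
#' simulated progenitor panels, contig pileups and read counting, the
#' digital-gene-expression comparison factorial, SNP mining and
#' partitioning, SSR detection and primer-triplet design, and the summary
#' report tables. Deterministic given the configuration seed.
#'
#' @param config A [sim_config()].
#' @param min_len Short-read filter in bp (default 100).
#' @param min_score,seed_k Tagging threshold and seed length (defaults 30
#'   and 11).
#' @param min_depth,maf,min_minor SNP-calling thresholds (defaults 6,
#'   0.10, 2).
#' @param alpha,min_fold DGE thresholds (defaults 0.05 and 2).
#' @param ssr_min_repeats,ssr_max_interruption,ssr_min_flank SSR
#'   thresholds (MISA-style defaults; design flank 50 bp).
#' @param max_triplets Cap on the number of SNP primer triplets designed
#'   (default 50).
#' @param output_dir Optional directory; when given, stage outputs are
#'   written there as TSV/FASTA/VCF.
#' @return An object of class `estmine_run`: a list with elements `truth`,
#'   `reads` (filter result), `tags`, `table` (the [count_table()]),
#'   `pileups`, `snp` (`calls`, `summary`, `intra`), `dge` (`matrix`,
#'   `summary`), `ssr` (`records`, `summary`, `candidates`), `primers`,
#'   `report` (`sequencing`, `assembly`, `top`), and `thresholds`.
#' @export
run_pipeline <- function(config = sim_config(),
                         min_len = 100L,
                         min_score = 30L, seed_k = 11L,
                         min_depth = 6L, maf = 0.10, min_minor = 2L,
                         alpha = 0.05, min_fold = 2,
                         ssr_min_repeats = c("1" = 10L, "2" = 6L,
                                             "3" = 5L, "4" = 5L,
                                             "5" = 5L, "6" = 5L),
                         ssr_max_interruption = 100L,
                         ssr_min_flank = 50L,
                         max_triplets = 50L,
                         output_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  thresholds <- list(min_len = min_len, min_score = min_score,
                     seed_k = seed_k, min_depth = min_depth, maf = maf,
                     min_minor = min_minor, alpha = alpha,
                     min_fold = min_fold,
                     ssr_min_repeats = ssr_min_repeats,
                     ssr_max_interruption = ssr_max_interruption,
                     ssr_min_flank = ssr_min_flank)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  truth <- stage("simulate", simulate_transcriptome(config))
  sim <- stage("simulate_reads", simulate_reads(truth, config))
  filt <- stage("filter", trim_filter_reads(sim$reads, min_len = min_len))
  kept <- filt$kept

  tags <- stage("tag", tag_library(kept, truth$panel_a, truth$panel_d,
                                   min_score = min_score, k = seed_k))
  tag_of <- stats::setNames(tags$decisions$tag, tags$decisions$read_id)
  lib_of <- stats::setNames(kept$library, kept$read_id)

  # count table over kept reads
  libs <- config$libraries
  genes <- truth$genes$gene
  counts <- table(factor(kept$gene, levels = genes),
                  factor(kept$library, levels = libs))
  counts <- matrix(as.integer(counts), nrow = length(genes),
                   dimnames = list(genes, libs))
  tag_counts <- array(0L, dim = c(length(genes), length(libs), 3L),
                      dimnames = list(genes, libs, c("A", "D", "unknown")))
  tc <- table(factor(kept$gene, levels = genes),
              factor(kept$library, levels = libs),
              factor(tag_of[kept$read_id],
                     levels = c("A", "D", "unknown")))
  tag_counts[] <- as.integer(tc)
  tbl <- stage("count", count_table(counts, tag_counts = tag_counts))

  # pileups restricted to kept reads
  kept_ids <- kept$read_id
  pileups <- stage("pileup", lapply(sim$alignments, function(a) {
    p <- a$placements[a$placements$read_id %in% kept_ids, , drop = FALSE]
    build_pileup(contig_alignment(a$contig_id, a$consensus, p),
                 lib_of, tag_of)
  }))

  scans <- stage("snp", lapply(pileups, scan_contig, min_depth = min_depth,
                               maf = maf, min_minor = min_minor))
  calls <- do.call(rbind, c(lapply(scans, `[[`, "calls"),
                            list(make.row.names = FALSE)))
  intra <- do.call(rbind, c(lapply(scans, `[[`, "intra"),
                            list(make.row.names = FALSE)))
  eligible <- sum(vapply(scans, `[[`, numeric(1), "eligible_bases"))
  assessable <- Reduce(`+`, lapply(scans, `[[`, "assessable_bases"))
  snp_sum <- snp_summary(calls, eligible, intra, as.list(assessable))

  dge_matrix <- stage("dge", comparison_matrix(tbl, alpha = alpha,
                                               min_fold = min_fold))
  dge_sum <- differential_summary(dge_matrix)

  consensus <- truth$ancestral
  ssr_records <- stage("ssr", do.call(rbind, c(lapply(genes, function(g) {
    find_ssrs(consensus[[g]], min_repeats = ssr_min_repeats,
              max_interruption = ssr_max_interruption, contig_id = g)
  }), list(make.row.names = FALSE))))
  ssr_sum <- ssr_summary(ssr_records)
  contig_lens <- stats::setNames(truth$genes$length, genes)
  ssr_cand <- filter_design_candidates(ssr_records, contig_lens,
                                       min_flank = ssr_min_flank)

  primers <- stage("primers", design_triplets_for_calls(
    utils::head(calls[calls$classification != "caseA_homoeo", , drop = FALSE],
                max_triplets), consensus))

  report <- list(
    sequencing = sequencing_summary(sim$reads, min_len = min_len),
    assembly = assembly_summary(sim$alignments),
    top = top_transcripts(tbl, n = 10L))

  out <- list(truth = truth, reads = filt, tags = tags, table = tbl,
              pileups = pileups,
              snp = list(calls = calls, intra = intra, summary = snp_sum,
                         eligible_bases = eligible),
              dge = list(matrix = dge_matrix, summary = dge_sum),
              ssr = list(records = ssr_records, summary = ssr_sum,
                         candidates = ssr_cand),
              primers = primers, report = report,
              thresholds = thresholds, config = config)
  class(out) <- "estmine_run"
  if (!is.null(output_dir)) write_run_outputs(out, output_dir)
  out
}

#' @export
print.estmine_run <- function(x, ...) {
  cat("EST mining pipeline run\n")
  s <- x$report$sequencing
  tot <- s[s$library == "Total", ]
  cat(sprintf("  reads: %d total, %d high-quality (mean %d bp)\n",
              tot$n_reads, tot$n_kept, tot$mean_length))
  cat(sprintf("  tagged A/D: %d / %d of %d reads\n",
              sum(x$tags$summary$n_A), sum(x$tags$summary$n_D),
              sum(x$tags$summary$n_reads)))
  ss <- x$snp$summary
  cat(sprintf("  SNPs: %d positions (A=%d B=%d C=%d D=%d); 1/%s bp inter-genotypic\n",
              ss$n_variant_positions, ss$n_caseA, ss$n_caseB, ss$n_caseC,
              ss$n_caseD, format(ss$density_bp)))
  cat(sprintf("  SSRs: %d (p2-p6 + compound)\n", x$ssr$summary$total))
  cat(sprintf("  primer triplets designed: %d\n", nrow(x$primers)))
  invisible(x)
}

# write the stage outputs of a run as plain-text files
write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, name) {
    utils::write.table(d, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  for (lib in run$config$libraries) {
    rr <- run$reads$kept[run$reads$kept$library == lib, ]
    write_fasta(stats::setNames(rr$sequence, rr$read_id),
                file.path(dir, paste0(lib, ".fasta")))
  }
  w(run$tags$decisions, "tag_decisions.tsv")
  w(run$tags$summary, "tag_summary.tsv")
  w(data.frame(contig = rownames(run$table$counts), run$table$counts,
               check.names = FALSE), "counts.tsv")
  w(run$snp$calls, "snp_calls.tsv")
  w(run$snp$intra, "snp_intra.tsv")
  w(run$dge$matrix, "dge_comparisons.tsv")
  w(run$ssr$records, "ssr_records.tsv")
  w(run$primers, "snp_primer_triplets.tsv")
  w(run$report$sequencing, "sequencing_summary.tsv")
  w(run$report$top, "top_transcripts.tsv")
  export_vcf(run$snp$calls, run$truth$ancestral,
             file.path(dir, "snp_calls.vcf"))
  flanks <- export_snp_flanks(run$snp$calls, run$truth$ancestral)
  w(flanks, "snp_flanks.tsv")
  invisible(dir)
}
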