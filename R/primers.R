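# default tail sequences for the two allele-specific forward primers;
# lengths 15 and 5 give the 10 bp product-size difference that separates
# the two alleles on a gel
TAIL_LONG <- "GCAACAGGAACCAGC"
TAIL_SHORT <- "GCAAC"

# two distinct transversion substitutions used as the destabilizing
# mismatch (one mapping per forward primer, so the two primers always
# carry different mismatch bases)
TRANSVERSION_1 <- c(A = "C", C = "A", G = "T", T = "G")
TRANSVERSION_2 <- c(A = "T", T = "A", G = "C", C = "G")

#' Design an allele-specific primer triplet for a SNP
#'
#' Builds the three-primer set used for allele-specific PCR genotyping of
#' an inter-genotypic SNP: two tailed forward primers, one per allele,
#' ending on their target allele at the 3' terminus, each carrying a
#' destabilizing mismatch at position -4 from the 3' end (a transversion
#' of the template base, a different one in each primer), plus a common
#' reverse primer downstream. The tails (15 and 5 bases) make the two
#' allelic products differ by exactly 10 bp.
#'
#' @param consensus Unpadded contig consensus (DNA string).
#' @param pos SNP position (1-based) on the consensus.
#' @param allele1,allele2 The two target alleles (single bases); allele 1
#'   receives the long tail by default.
#' @param primer_len Template footprint of each primer in bp (default 20).
#' @param tails Character vector of the two tail sequences (default 15
#'   and 5 bases).
#' @param product_span Distance in bp from the SNP to the 3' end of the
#'   reverse-primer window (default 130, shortened to the contig end).
#' @param snp_id Marker name.
#' @return An object of class `primer_triplet`: list with `snp_id`,
#'   `forward1`, `forward2` (each: `sequence`, `allele`, `tail_length`,
#'   `mismatch_base`, `mismatch_template`, `product_size`, `gc_pct`,
#'   `tm_estimate`), and `reverse` (`sequence`, `gc_pct`, `tm_estimate`).
#' @export
design_snp_triplet <- function(consensus, pos, allele1, allele2,
                               primer_len = 20L, tails = c(TAIL_LONG,
                                                           TAIL_SHORT),
                               product_span = 130L,
                               snp_id = paste0("snp_", pos)) {
  L <- nchar(consensus)
  stopifnot(length(tails) == 2L)
  if (abs(nchar(tails[1]) - nchar(tails[2])) != 10L) {
    stop("tail lengths must differ by 10 bp", call. = FALSE)
  }
  if (pos < primer_len) {
    stop("insufficient upstream flank for the forward primers",
         call. = FALSE)
  }
  pe <- min(pos + product_span, L)
  ps <- pe - primer_len + 1L
  if (ps <= pos) {
    stop("insufficient downstream flank for the reverse primer",
         call. = FALSE)
  }
  template <- substr(consensus, pos - primer_len + 1L, pos - 1L)
  mis_at <- primer_len - 3L                 # -4 from the 3' end
  tmpl_base <- substr(template, mis_at, mis_at)
  if (!tmpl_base %in% DNA_BASES) {
    stop("ambiguous template base at the mismatch position", call. = FALSE)
  }
  gc_pct <- function(s) {
    ch <- seq_chars(s)
    round(100 * mean(ch %in% c("G", "C")), 1)
  }
  tm_est <- function(s) {
    # simple GC%/length heuristic, for logging only (no nearest-neighbor
    # thermodynamics)
    round(81.5 + 0.41 * gc_pct(s) - 675 / nchar(s), 1)
  }
  fwd <- function(tail, allele, trans) {
    mis <- trans[[tmpl_base]]
    body <- template
    substr(body, mis_at, mis_at) <- mis
    sequence <- paste0(tail, body, allele)
    list(sequence = sequence, allele = allele,
         tail_length = nchar(tail), mismatch_base = mis,
         mismatch_template = tmpl_base,
         product_size = (pe - (pos - primer_len + 1L) + 1L) + nchar(tail),
         gc_pct = gc_pct(sequence), tm_estimate = tm_est(sequence))
  }
  rev_seq <- revcomp(substr(consensus, ps, pe))
  out <- list(snp_id = snp_id,
              forward1 = fwd(tails[1], allele1, TRANSVERSION_1),
              forward2 = fwd(tails[2], allele2, TRANSVERSION_2),
              reverse = list(sequence = rev_seq, gc_pct = gc_pct(rev_seq),
                             tm_estimate = tm_est(rev_seq)))
  class(out) <- "primer_triplet"
  out
}

#' @export
print.primer_triplet <- function(x, ...) {
  cat(sprintf("<primer_triplet> %s\n", x$snp_id))
  cat(sprintf("  F1 (%s, tail %d): %s  [%d bp product]\n",
              x$forward1$allele, x$forward1$tail_length,
              x$forward1$sequence, x$forward1$product_size))
  cat(sprintf("  F2 (%s, tail %d): %s  [%d bp product]\n",
              x$forward2$allele, x$forward2$tail_length,
              x$forward2$sequence, x$forward2$product_size))
  cat(sprintf("  R : %s\n", x$reverse$sequence))
  invisible(x)
}

#' Design primer triplets for a set of inter-genotypic SNP calls
#'
#' Selects, for each call, the allele that distinguishes each genotype
#' (for one-genotype-polymorphic calls, the allele private to the
#' polymorphic genotype versus the other genotype's allele; for fixed
#' differences, the two monomorphic alleles) and runs
#' [design_snp_triplet()]. Calls without sufficient flank or without two
#' distinct single-base alleles are skipped.
#'
#' @param calls Dual-scan call data.frame (inter-genotypic classes).
#' @param consensus Named character vector of unpadded consensus
#'   sequences.
#' @param ... Passed to [design_snp_triplet()].
#' @return data.frame, one row per designed triplet: `snp_id`, `contig`,
#'   `pos`, `allele_gh`, `allele_gb`, `primer_f_gh`, `primer_f_gb`,
#'   `primer_r`, `size_gh`, `size_gb`.
#' @export
design_triplets_for_calls <- function(calls, consensus, ...) {
  inter <- calls[calls$classification %in%
                   c("caseB_Gh_poly", "caseC_Gb_poly", "caseD_fixed_diff"), ,
                 drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(inter))) {
    gh <- strsplit(inter$alleles_gh[i], ",", fixed = TRUE)[[1]]
    gb <- strsplit(inter$alleles_gb[i], ",", fixed = TRUE)[[1]]
    # prefer the allele private to a genotype; for the monomorphic side of
    # a hemilogous (case B/C) marker fall back to its single allele
    a_gh <- c(setdiff(gh, gb), gh)[1]
    a_gb <- c(setdiff(gb, gh), gb)[1]
    if (is.na(a_gh) || is.na(a_gb) || a_gh == a_gb) next
    trip <- tryCatch(
      design_snp_triplet(consensus[[inter$contig[i]]], inter$pos[i],
                         a_gh, a_gb,
                         snp_id = paste0(inter$contig[i], "_",
                                         inter$pos[i]), ...),
      error = function(e) NULL)
    if (is.null(trip)) next
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = trip$snp_id, contig = inter$contig[i], pos = inter$pos[i],
      allele_gh = a_gh, allele_gb = a_gb,
      primer_f_gh = trip$forward1$sequence,
      primer_f_gb = trip$forward2$sequence,
      primer_r = trip$reverse$sequence,
      size_gh = trip$forward1$product_size,
      size_gb = trip$forward2$product_size,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows) %||% data.frame(
    snp_id = character(0), contig = character(0), pos = integer(0),
    allele_gh = character(0), allele_gb = character(0),
    primer_f_gh = character(0), primer_f_gb = character(0),
    primer_r = character(0), size_gh = integer(0), size_gb = integer(0))
}
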