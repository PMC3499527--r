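#' Sequencing statistics table (per library and total)
#'
#' Computes the library-level sequencing summary: reads, bases, mean read
#' length, short reads (below `min_len`) and high-quality (kept) reads.
#' Either a read table or pre-tabulated per-library statistics can be
#' supplied (printed report tables are themselves valid inputs).
#'
#' @param reads data.frame with `library` and `sequence` (or `length`)
#'   columns; or `NULL` when `stats` is given.
#' @param stats Pre-tabulated per-library data.frame with columns
#'   `library`, `n_reads`, `n_bases`, `n_short` (any of the last three may
#'   be omitted if not available).
#' @param min_len Short-read threshold in bp (default 100).
#' @return data.frame with one row per library plus a `Total` row:
#'   `library`, `n_reads`, `n_bases`, `mean_length` (integer bp,
#'   total bases / total reads), `n_short`, `n_kept`.
#' @export
sequencing_summary <- function(reads = NULL, stats = NULL, min_len = 100L) {
  if (is.null(stats)) {
    stopifnot(is.data.frame(reads))
    len <- reads$length %||% nchar(reads$sequence)
    libs <- unique(reads$library)
    stats <- do.call(rbind, lapply(libs, function(l) {
      sel <- reads$library == l
      data.frame(library = l, n_reads = sum(sel),
                 n_bases = sum(len[sel]),
                 n_short = sum(sel & len < min_len),
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(stats$n_bases)) stats$n_bases <- NA_real_
  if (is.null(stats$n_short)) stats$n_short <- NA_integer_
  if (any(stats$n_reads == 0)) {
    warning("library with zero reads: ",
            paste(stats$library[stats$n_reads == 0], collapse = ", "),
            call. = FALSE)
  }
  stats$n_kept <- stats$n_reads - stats$n_short
  stats$mean_length <- ifelse(stats$n_reads > 0,
                              round(stats$n_bases / stats$n_reads), 0)
  total <- data.frame(library = "Total",
                      n_reads = sum(stats$n_reads),
                      n_bases = sum(stats$n_bases),
                      n_short = sum(stats$n_short),
                      n_kept = sum(stats$n_kept),
                      mean_length = if (sum(stats$n_reads) > 0)
                        round(sum(stats$n_bases) / sum(stats$n_reads))
                      else 0,
                      stringsAsFactors = FALSE)
  cols <- c("library", "n_reads", "n_bases", "mean_length", "n_short",
            "n_kept")
  rbind(stats[, cols], total[, cols])
}

#' Assembly (unigene) statistics
#'
#' Unigenes are multi-read contigs plus singletons (one-read contigs in
#' the simulator path, where the assembler-level distinction does not
#' exist). The mean reads per contig covers multi-read contigs only and
#' is reported to 1 decimal.
#'
#' @param alignments Named list of [contig_alignment()]; or `NULL` when
#'   the counts are supplied directly.
#' @param n_contigs,n_singletons,reads_in_contigs Direct inputs (printed
#'   assembly tables are valid inputs).
#' @return A list: `n_contigs`, `n_singletons`, `n_unigenes`,
#'   `reads_in_contigs`, `mean_reads_per_contig`, and (from alignments)
#'   `contig_lengths`.
#' @export
assembly_summary <- function(alignments = NULL, n_contigs = NULL,
                             n_singletons = NULL,
                             reads_in_contigs = NULL) {
  lens <- NULL
  if (!is.null(alignments)) {
    nr <- vapply(alignments, function(a) nrow(a$placements), integer(1))
    n_contigs <- sum(nr >= 2L)
    n_singletons <- sum(nr == 1L)
    reads_in_contigs <- sum(nr[nr >= 2L])
    lens <- vapply(alignments, function(a) {
      sum(seq_chars(a$consensus) != "*")
    }, integer(1))[nr >= 2L]
  }
  n_contigs <- n_contigs %||% 0L
  n_singletons <- n_singletons %||% 0L
  reads_in_contigs <- reads_in_contigs %||% 0L
  list(n_contigs = n_contigs, n_singletons = n_singletons,
       n_unigenes = n_contigs + n_singletons,
       reads_in_contigs = reads_in_contigs,
       mean_reads_per_contig = if (n_contigs > 0)
         round(reads_in_contigs / n_contigs, 1) else NA_real_,
       contig_lengths = lens)
}

#' Most abundant transcripts
#'
#' Ranks contigs by total read count and reports the genotype and stage
#' margins, whose sums both equal the total (`Gh + Gb = 10 + 22 = total`).
#' Ties are broken by contig id for a stable order.
#'
#' @param table A [count_table()].
#' @param n Number of top contigs (default 10).
#' @param min_reads Optional floor on total reads (e.g. 1000 to mirror
#'   a ">1,000 reads" table).
#' @return data.frame: `contig`, `total`, `Gh`, `Gb`, `stage10`,
#'   `stage22`.
#' @export
top_transcripts <- function(table, n = 10L, min_reads = 0L) {
  stopifnot(inherits(table, "count_table"))
  cnt <- table$counts
  meta <- table$meta
  total <- rowSums(cnt)
  margin <- function(col, lev) {
    rowSums(cnt[, meta$library[meta[[col]] == lev], drop = FALSE])
  }
  d <- data.frame(contig = rownames(cnt), total = total,
                  Gh = margin("genotype", "Gh"),
                  Gb = margin("genotype", "Gb"),
                  stage10 = margin("stage", "10"),
                  stage22 = margin("stage", "22"),
                  row.names = NULL, stringsAsFactors = FALSE)
  d <- d[d$total >= min_reads, , drop = FALSE]
  d <- d[order(-d$total, d$contig), , drop = FALSE]
  utils::head(d, n)
}

#' Differential-expression roll-up over the comparison matrix
#'
#' Adds, for each unstratified factor comparison, the total number of
#' differential contigs (both directions), the top-line counts of a
#' comparison figure.
#'
#' @param cm Output of [comparison_matrix()].
#' @return A list: `matrix` (the input), `rollup` (data.frame `factor`,
#'   `n_up_group1`, `n_up_group2`, `total` for the overall comparisons).
#' @export
differential_summary <- function(cm) {
  # overall rows are those whose group label carries no conditioning level
  is_overall <- vapply(seq_len(nrow(cm)), function(i) {
    f <- cm$factor[i]
    lhs <- sub(" vs.*", "", cm$comparison[i])
    switch(f,
           stage = lhs %in% c("10", "22"),
           genotype = lhs %in% c("Gh", "Gb"),
           tag = startsWith(lhs, "all_"))
  }, logical(1))
  overall <- cm[is_overall, , drop = FALSE]
  rollup <- data.frame(factor = overall$factor,
                       comparison = overall$comparison,
                       n_up_group1 = overall$n_up_group1,
                       n_up_group2 = overall$n_up_group2,
                       total = overall$n_up_group1 + overall$n_up_group2,
                       stringsAsFactors = FALSE)
  list(matrix = cm, rollup = rollup)
}
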