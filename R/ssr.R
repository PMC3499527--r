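#' Canonical microsatellite motif class
#'
#' The class representative of a repeat motif is the lexicographically
#' smallest string among all cyclic rotations of the motif and of its
#' reverse complement, so that e.g. `TC`, `CT`, `GA` and `AG` all fall in
#' class `AG/CT`. The class label is `X/revcomp(X)` (just `X` when the
#' canonical motif is its own reverse complement, as for `AT`).
#'
#' @param motif Repeat unit, length 1-6, no `N`.
#' @return A list: `canonical` (the representative motif) and `class`
#'   (the rendered label).
#' @export
canonical_motif <- function(motif) {
  motif <- toupper(motif)
  p <- nchar(motif)
  if (p < 1L || p > 6L) stop("motif length must be 1-6", call. = FALSE)
  if (!grepl("^[ACGT]+$", motif)) {
    stop("motif must be over A,C,G,T (no N)", call. = FALSE)
  }
  rots <- function(s) {
    n <- nchar(s)
    vapply(seq_len(n), function(i) {
      paste0(substr(s, i, n), substr(s, 1, i - 1L))
    }, character(1))
  }
  orbit <- c(rots(motif), rots(revcomp(motif)))
  canon <- min(orbit)
  rc <- revcomp(canon)
  list(canonical = canon,
       class = if (rc == canon) canon else paste0(canon, "/", rc))
}

#' Detect microsatellites (SSRs) in a sequence
#'
#' Finds maximal perfect tandem repeats with MISA-style semantics: unit
#' lengths 1-6 bp with per-unit minimum repeat counts (defaults 10 for
#' mononucleotides, 6 for dinucleotides, 5 for tri- to hexanucleotides);
#' a run whose unit is itself a repetition of a shorter unit is reported
#' at the shortest unit; runs are truncated to complete units. Qualifying
#' repeats of unit length 2-6 separated by at most `max_interruption`
#' bases merge into compound records; mononucleotide runs are reported
#' separately (type `p1`) and never join compounds.
#'
#' Detection compares the sequence with itself shifted by the unit length
#' and extracts runs of consecutive agreement, which yields maximal
#' perfect runs directly.
#'
#' @param seq DNA string over `A,C,G,T,N` (`N` interrupts runs).
#' @param min_repeats Named integer vector of minimum repeat counts per
#'   unit length `1`-`6`.
#' @param max_interruption Maximum bases between members of a compound
#'   repeat (default 100).
#' @param contig_id Optional contig name carried into the records.
#' @return data.frame with columns `contig`, `type` (`p1`-`p6` or
#'   `compound`), `start`, `end` (1-based inclusive), `motif` (as found),
#'   `motif_class`, `unit_length`, `repeats`, `n_members`, `members`
#'   (e.g. `"(AAG)5+(CT)7"`; for simple SSRs the same single member).
#' @export
find_ssrs <- function(seq,
                      min_repeats = c("1" = 10L, "2" = 6L, "3" = 5L,
                                      "4" = 5L, "5" = 5L, "6" = 5L),
                      max_interruption = 100L,
                      contig_id = "contig") {
  seq <- toupper(seq)
  if (!grepl("^[ACGTN]*$", seq)) stop("sequence must be over A,C,G,T,N",
                                      call. = FALSE)
  ch <- seq_chars(seq)
  L <- length(ch)
  valid <- ch %in% DNA_BASES
  recs <- list()
  for (p in as.integer(names(min_repeats))) {
    thr <- min_repeats[[as.character(p)]]
    if (L < p * thr) next
    i <- seq_len(L - p)
    eq <- ch[i] == ch[i + p] & valid[i] & valid[i + p]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run_len <- r$lengths[k] + p        # total bases in the tandem region
      count <- run_len %/% p
      if (count < thr) next
      s0 <- starts[k]
      motif <- substr(seq, s0, s0 + p - 1L)
      if (min_period(motif) < p) next    # reported at the shorter unit
      recs[[length(recs) + 1L]] <- data.frame(
        type = paste0("p", p), start = s0, end = s0 + count * p - 1L,
        motif = motif, unit_length = p, repeats = count,
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(contig = character(0), type = character(0),
                      start = integer(0), end = integer(0),
                      motif = character(0), motif_class = character(0),
                      unit_length = integer(0), repeats = integer(0),
                      n_members = integer(0), members = character(0))
  if (!length(recs)) return(empty)
  recs <- do.call(rbind, recs)
  recs <- recs[order(recs$start, recs$unit_length), , drop = FALSE]

  member_str <- function(d) paste(sprintf("(%s)%d", d$motif, d$repeats),
                                  collapse = "+")
  finalize <- function(d) {
    # d: one or more member rows forming one output record
    if (nrow(d) == 1L) {
      type <- d$type
      motif <- d$motif
      unit <- d$unit_length
      reps <- d$repeats
    } else {
      type <- "compound"
      motif <- NA_character_
      unit <- NA_integer_
      reps <- NA_integer_
    }
    data.frame(contig = contig_id, type = type, start = min(d$start),
               end = max(d$end), motif = motif,
               motif_class = if (is.na(motif)) NA_character_
                             else canonical_motif(motif)$class,
               unit_length = unit, repeats = reps, n_members = nrow(d),
               members = member_str(d), stringsAsFactors = FALSE)
  }

  mono <- recs[recs$unit_length == 1L, , drop = FALSE]
  poly <- recs[recs$unit_length > 1L, , drop = FALSE]
  out <- list()
  if (nrow(poly)) {
    gap <- c(Inf, poly$start[-1] - poly$end[-nrow(poly)] - 1L)
    grp <- cumsum(gap > max_interruption)
    for (g in unique(grp)) {
      out[[length(out) + 1L]] <- finalize(poly[grp == g, , drop = FALSE])
    }
  }
  for (k in seq_len(nrow(mono))) {
    out[[length(out) + 1L]] <- finalize(mono[k, , drop = FALSE])
  }
  out <- do.call(rbind, out)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# minimal period of a string (smallest d dividing nchar for which the
# string is a repetition of its first d characters)
min_period <- function(s) {
  n <- nchar(s)
  for (d in seq_len(n)) {
    if (n %% d != 0L) next
    unit <- substr(s, 1L, d)
    if (paste(rep(unit, n %/% d), collapse = "") == s) return(d)
  }
  n
}

#' Summarize an SSR record set
#'
#' Tallies records by type and, within each unit length, the frequency of
#' each canonical motif class. Mononucleotide repeats (`p1`) are reported
#' but excluded from the total, which covers di- to hexanucleotide and
#' compound repeats.
#'
#' @param records data.frame from [find_ssrs()] (possibly rbind over
#'   contigs).
#' @return A list: `by_type` (named counts `p1`-`p6`, `compound`),
#'   `total` (p2-p6 + compound), `class_freq` (data.frame `type`,
#'   `motif_class`, `n`, `pct` within type).
#' @export
ssr_summary <- function(records) {
  types <- c(paste0("p", 1:6), "compound")
  by_type <- vapply(types, function(t) sum(records$type == t), integer(1))
  total <- sum(by_type[c(paste0("p", 2:6), "compound")])
  simple <- records[!is.na(records$motif_class) &
                      records$type != "compound", , drop = FALSE]
  class_freq <- if (nrow(simple)) {
    agg <- stats::aggregate(list(n = simple$start),
                            by = list(type = simple$type,
                                      motif_class = simple$motif_class),
                            FUN = length)
    tot <- stats::ave(agg$n, agg$type, FUN = sum)
    agg$pct <- round(100 * agg$n / tot)
    agg[order(agg$type, -agg$n), ]
  } else {
    data.frame(type = character(0), motif_class = character(0),
               n = integer(0), pct = numeric(0))
  }
  rownames(class_freq) <- NULL
  list(by_type = by_type, total = total, class_freq = class_freq)
}

#' Filter SSRs suitable for primer design
#'
#' Keeps records with at least `min_flank` non-repeat bases on both sides
#' of the repeat within their contig (repeats near contig ends cannot
#' anchor primers).
#'
#' @param records data.frame from [find_ssrs()].
#' @param contig_lengths Named integer vector of contig lengths.
#' @param min_flank Minimum flank in bp (default 50).
#' @return The qualifying subset of `records`.
#' @export
filter_design_candidates <- function(records, contig_lengths,
                                     min_flank = 50L) {
  stopifnot(min_flank >= 1L)
  if (!nrow(records)) return(records)
  len <- contig_lengths[records$contig]
  if (anyNA(len)) stop("missing contig length for: ",
                       paste(unique(records$contig[is.na(len)]),
                             collapse = ", "), call. = FALSE)
  keep <- (records$start - 1L) >= min_flank &
    (len - records$end) >= min_flank
  records[keep, , drop = FALSE]
}
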