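#' Contig alignment container
#'
#' A contig consensus (possibly padded with `*` columns) together with the
#' placed reads, all stored consensus-forward: complemented reads must be
#' reverse-complemented before construction (the ACE reader does this), so
#' downstream pileups never consult strand.
#'
#' @param contig_id Contig name.
#' @param consensus Padded consensus string over `A,C,G,T,N,*`.
#' @param placements data.frame with columns `read_id`, `start` (1-based on
#'   the padded consensus), `strand` (`"+"`/`"-"`, the original orientation,
#'   informational only), `seq` (gapped read string, `*` for gaps).
#' @return An object of class `contig_alignment`.
#' @export
contig_alignment <- function(contig_id, consensus, placements) {
  stopifnot(is.character(contig_id), length(contig_id) == 1L,
            is.character(consensus), length(consensus) == 1L,
            is.data.frame(placements),
            all(c("read_id", "start", "seq") %in% names(placements)))
  if (is.null(placements$strand)) placements$strand <- "+"
  ends <- placements$start + nchar(placements$seq) - 1L
  if (nrow(placements) &&
      (any(placements$start < 1L) || any(ends > nchar(consensus)))) {
    stop("placement outside consensus bounds in contig ", contig_id,
         call. = FALSE)
  }
  structure(list(contig_id = contig_id, consensus = consensus,
                 placements = placements),
            class = "contig_alignment")
}

#' @export
print.contig_alignment <- function(x, ...) {
  cat(sprintf("<contig_alignment> %s: %d bp consensus (%d pads), %d reads\n",
              x$contig_id, nchar(x$consensus),
              sum(seq_chars(x$consensus) == "*"), nrow(x$placements)))
  invisible(x)
}

#' Read and write FASTA
#'
#' Thin wrappers around Biostrings. Sequences are upper-cased on read.
#'
#' @param path File path.
#' @return `read_fasta`: a named character vector of DNA sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  first <- readLines(path, n = 1L)
  if (!startsWith(first, ">")) {
    stop("malformed FASTA (no '>' header): ", path, call. = FALSE)
  }
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param records Named character vector of sequences.
#' @export
write_fasta <- function(records, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(records), path, width = 70L)
  invisible(path)
}

#' Read an ACE assembly file
#'
#' Parses the consed ACE dialect (`AS`, `CO`, optional `BQ`, `AF`, `RD`
#' records) into [contig_alignment()] objects. Reads flagged complemented
#' (`C` in their `AF` line) are stored reverse-complemented so that every
#' placement is consensus-forward. `BQ` and unknown record types are
#' skipped (with a warning for unknown types).
#'
#' @param path Path to an ACE file.
#' @return A named list of `contig_alignment` objects (one per `CO` record).
#' @export
read_ace <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  n <- length(lines)
  read_block <- function(i) {
    # sequence lines until blank line or EOF, starting at i
    if (i > n || !nzchar(lines[i])) return(list(seq = "", nxt = i))
    j <- i
    while (j <= n && nzchar(lines[j])) j <- j + 1L
    list(seq = paste(lines[i:(j - 1L)], collapse = ""), nxt = j)
  }
  warned <- character(0)
  while (i <= n) {
    ln <- lines[i]
    if (!nzchar(ln)) { i <- i + 1L; next }
    tag <- sub(" .*", "", ln)
    if (tag == "AS") {
      i <- i + 1L
    } else if (tag == "CO") {
      fld <- strsplit(ln, " +")[[1]]
      if (length(fld) < 4L) stop("truncated CO record at line ", i,
                                 call. = FALSE)
      contig_id <- fld[2]
      n_reads <- as.integer(fld[4])
      blk <- read_block(i + 1L)
      consensus <- toupper(blk$seq)
      i <- blk$nxt
      # collect AF and RD until the expected read count is satisfied
      af <- list(); rd <- list()
      while (i <= n && (length(rd) < n_reads || length(af) < n_reads)) {
        ln2 <- lines[i]
        if (!nzchar(ln2)) { i <- i + 1L; next }
        t2 <- sub(" .*", "", ln2)
        if (t2 == "AF") {
          f <- strsplit(ln2, " +")[[1]]
          if (length(f) < 4L) stop("truncated AF record in contig ",
                                   contig_id, call. = FALSE)
          af[[f[2]]] <- list(comp = f[3] == "C", start = as.integer(f[4]))
          i <- i + 1L
        } else if (t2 == "RD") {
          f <- strsplit(ln2, " +")[[1]]
          if (length(f) < 2L) stop("truncated RD record in contig ",
                                   contig_id, call. = FALSE)
          blk <- read_block(i + 1L)
          rd[[f[2]]] <- toupper(blk$seq)
          i <- blk$nxt
        } else if (t2 %in% c("BQ", "BS")) {
          blk <- read_block(i + 1L)
          i <- blk$nxt
        } else if (t2 %in% c("QA", "DS", "RT{", "CT{", "WA{")) {
          # per-read metadata; skip single line or brace block
          if (grepl("\\{$", t2)) {
            while (i <= n && !startsWith(lines[i], "}")) i <- i + 1L
          }
          i <- i + 1L
        } else {
          if (!(t2 %in% warned)) {
            warning("skipping unknown ACE record type: ", t2, call. = FALSE)
            warned <- c(warned, t2)
          }
          i <- i + 1L
        }
      }
      if (length(rd) < n_reads) {
        stop("truncated contig record (expected ", n_reads, " reads): ",
             contig_id, call. = FALSE)
      }
      ids <- names(af)
      seqs <- unlist(rd)[ids]
      if (anyNA(seqs)) stop("AF/RD mismatch in contig ", contig_id,
                            call. = FALSE)
      comp <- vapply(af, `[[`, logical(1), "comp")
      if (any(comp)) {
        # reverse-complement, keeping gap characters
        rc <- function(s) {
          ch <- rev(seq_chars(s))
          paste(chartr("ACGTN", "TGCAN", ch), collapse = "")
        }
        seqs[comp] <- vapply(seqs[comp], rc, character(1))
      }
      placements <- data.frame(
        read_id = ids,
        start = vapply(af, `[[`, integer(1), "start"),
        strand = ifelse(comp, "-", "+"),
        seq = unname(seqs), stringsAsFactors = FALSE)
      rownames(placements) <- NULL
      out[[contig_id]] <- contig_alignment(contig_id, consensus, placements)
    } else {
      if (!(tag %in% warned)) {
        warning("skipping unknown ACE record type: ", tag, call. = FALSE)
        warned <- c(warned, tag)
      }
      i <- i + 1L
    }
  }
  out
}

#' Write contig alignments as ACE
#'
#' Emits the subset of the consed dialect that [read_ace()] parses
#' (`AS`, `CO`, `AF`, `RD`); all reads are written uncomplemented.
#'
#' @param alignments List of [contig_alignment()] objects.
#' @param path Output path.
#' @export
write_ace <- function(alignments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("AS %d %d", length(alignments),
                     sum(vapply(alignments, function(a) nrow(a$placements),
                                integer(1)))), con)
  writeLines("", con)
  wrap <- function(s) substring(s, seq(1, nchar(s), 60),
                                pmin(seq(60, nchar(s) + 59, 60), nchar(s)))
  for (a in alignments) {
    p <- a$placements
    writeLines(sprintf("CO %s %d %d 0 U", a$contig_id, nchar(a$consensus),
                       nrow(p)), con)
    writeLines(wrap(a$consensus), con)
    writeLines("", con)
    writeLines(sprintf("AF %s U %d", p$read_id, p$start), con)
    writeLines("", con)
    for (r in seq_len(nrow(p))) {
      writeLines(sprintf("RD %s %d 0 0", p$read_id[r], nchar(p$seq[r])), con)
      writeLines(wrap(p$seq[r]), con)
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Filter reads on minimum length
#'
#' Applies the standard short-read filter (default 100 bp, the high-quality
#' cut used for 454 EST libraries) and reports per-library totals.
#'
#' @param reads data.frame with at least `read_id`, `library`, `sequence`
#'   columns (or a `length` column if sequences are not carried).
#' @param min_len Minimum kept length in bp; a read is kept iff
#'   `length >= min_len`.
#' @return A list with `kept` and `discarded` (both subsets of `reads`) and
#'   `summary` (per-library data.frame: `library`, `n_reads`, `n_short`,
#'   `n_kept`, `mean_length`).
#' @export
trim_filter_reads <- function(reads, min_len = 100L) {
  stopifnot(min_len >= 1L)
  len <- reads$length %||% nchar(reads$sequence)
  keep <- len >= min_len
  libs <- unique(reads$library)
  summary <- do.call(rbind, lapply(libs, function(l) {
    sel <- reads$library == l
    data.frame(library = l, n_reads = sum(sel),
               n_short = sum(sel & !keep), n_kept = sum(sel & keep),
               mean_length = round(mean(len[sel]), 1),
               stringsAsFactors = FALSE)
  }))
  list(kept = reads[keep, , drop = FALSE],
       discarded = reads[!keep, , drop = FALSE],
       summary = summary)
}

#' Map between padded and unpadded consensus coordinates
#'
#' @param consensus Padded consensus string (`*` marks pad columns).
#' @return A list with `pad_to_unpad` (integer vector, `NA` at pads) and
#'   `unpad_to_pad` (integer vector over unpadded positions); the two maps
#'   are mutually inverse on non-pad columns.
#' @export
pad_maps <- function(consensus) {
  ch <- seq_chars(consensus)
  nonpad <- ch != "*"
  pad_to_unpad <- rep(NA_integer_, length(ch))
  pad_to_unpad[nonpad] <- seq_len(sum(nonpad))
  list(pad_to_unpad = pad_to_unpad, unpad_to_pad = which(nonpad))
}

#' Build a stratified allele-count pileup from a contig alignment
#'
#' Counts covering read bases at every unpadded consensus position,
#' stratified by genotype and by sub-genome tag. Pad columns, read gap
#' characters (`*`) and `N` bases contribute zero depth.
#'
#' @param alignment A [contig_alignment()].
#' @param read_library Named character vector mapping read id to library
#'   name (`Gh10`, `Gb10`, `Gh22`, `Gb22`); every placed read must be
#'   present. Genotype is the first two characters of the library name.
#' @param read_tag Optional named character vector mapping read id to
#'   sub-genome tag (`A`, `D`, `unknown`); unmapped reads count as
#'   `unknown`.
#' @return An object of class `pileup`: list with `contig_id`, `length`
#'   (unpadded), `genotype` (array position x base x genotype) and `tag`
#'   (array position x base x tag), plus `consensus_unpadded`.
#' @export
build_pileup <- function(alignment, read_library, read_tag = NULL) {
  stopifnot(inherits(alignment, "contig_alignment"))
  p <- alignment$placements
  lib <- read_library[p$read_id]
  if (anyNA(lib)) {
    stop("reads without a library assignment in contig ",
         alignment$contig_id, ": ",
         paste(utils::head(p$read_id[is.na(lib)], 3), collapse = ", "),
         call. = FALSE)
  }
  geno <- substr(lib, 1, 2)
  tag <- if (is.null(read_tag)) rep("unknown", nrow(p)) else {
    t <- read_tag[p$read_id]
    t[is.na(t)] <- "unknown"
    t
  }
  maps <- pad_maps(alignment$consensus)
  L <- length(maps$unpad_to_pad)
  genotypes <- c("Gh", "Gb")
  tags <- c("A", "D", "unknown")
  cnt_g <- array(0L, dim = c(L, 4L, 2L),
                 dimnames = list(NULL, DNA_BASES, genotypes))
  cnt_t <- array(0L, dim = c(L, 4L, 3L),
                 dimnames = list(NULL, DNA_BASES, tags))
  if (nrow(p)) {
    gi <- match(geno, genotypes)
    ti <- match(tag, tags)
    if (anyNA(gi)) stop("unknown genotype in libraries: ",
                        paste(unique(lib[is.na(gi)]), collapse = ", "))
    # accumulate per read: padded positions -> unpadded; drop pads/gaps/N
    idx_g <- vector("list", nrow(p))
    idx_t <- vector("list", nrow(p))
    for (r in seq_len(nrow(p))) {
      ch <- seq_chars(p$seq[r])
      pos_pad <- p$start[r] + seq_along(ch) - 1L
      bi <- match(ch, DNA_BASES)          # NA for '*' and 'N'
      up <- maps$pad_to_unpad[pos_pad]    # NA at consensus pad columns
      ok <- !is.na(bi) & !is.na(up)
      if (!any(ok)) next
      lin <- up[ok] + (bi[ok] - 1L) * L
      idx_g[[r]] <- lin + (gi[r] - 1L) * (4L * L)
      idx_t[[r]] <- lin + (ti[r] - 1L) * (4L * L)
    }
    tg <- tabulate(unlist(idx_g), nbins = length(cnt_g))
    tt <- tabulate(unlist(idx_t), nbins = length(cnt_t))
    cnt_g[] <- tg
    cnt_t[] <- tt
  }
  structure(list(contig_id = alignment$contig_id, length = L,
                 genotype = cnt_g, tag = cnt_t,
                 consensus_unpadded = paste(
                   seq_chars(alignment$consensus)[maps$unpad_to_pad],
                   collapse = "")),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %s: %d unpadded positions, %d covering bases\n",
              x$contig_id, x$length, sum(x$genotype)))
  invisible(x)
}

#' Export a pileup as a long-format TSV
#'
#' @param pileup A [build_pileup()] result.
#' @param path Output path.
#' @export
write_pileup_tsv <- function(pileup, path) {
  d <- pileup$genotype
  long <- do.call(rbind, lapply(dimnames(d)[[3]], function(g) {
    m <- d[, , g, drop = FALSE]
    idx <- which(m > 0, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(contig = pileup$contig_id, pos = idx[, 1],
               genotype = g, allele = DNA_BASES[idx[, 2]],
               depth = m[idx], stringsAsFactors = FALSE)
  }))
  long <- long[order(long$pos, long$genotype, long$allele), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
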