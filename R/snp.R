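#' Intra-genotype polymorphism call at one position
#'
#' Applies the depth and minor-allele rules of EST SNP mining: the position
#' is assessable for a genotype only at coverage `>= min_depth`; it is
#' polymorphic when at least two alleles each reach `min_minor` occurrences
#' and `maf` of the genotype's depth. A monomorphic call reports the
#' majority allele (lexicographic tie-break).
#'
#' @param counts Named integer vector of allele depths (`A`,`C`,`G`,`T`)
#'   for one genotype at one position.
#' @param min_depth Minimum genotype coverage (default 6).
#' @param maf Minor allele frequency threshold as a fraction of the
#'   genotype's depth (default 0.10).
#' @param min_minor Minimum occurrences of an allele (default 2).
#' @return A list: `assessable` (logical), `polymorphic` (logical, NA when
#'   not assessable), `alleles` (called alleles: all qualifying alleles if
#'   polymorphic, else the majority allele).
#' @export
call_intra_genotype <- function(counts, min_depth = 6L, maf = 0.10,
                                min_minor = 2L) {
  depth <- sum(counts)
  if (depth < min_depth) {
    return(list(assessable = FALSE, polymorphic = NA, alleles = character(0)))
  }
  qual <- counts[counts >= min_minor & counts / depth >= maf]
  if (length(qual) >= 2L) {
    list(assessable = TRUE, polymorphic = TRUE,
         alleles = sort(names(qual)))
  } else {
    maj <- names(counts)[counts == max(counts)]
    list(assessable = TRUE, polymorphic = FALSE,
         alleles = sort(maj)[1L])  # lexicographic tie-break
  }
}

#' Classify a dual-coverage position into the homoeo/allelic partition
#'
#' At a position covered `>= min_depth` by both genotypes:
#' both polymorphic = case A (homoeo-SNP, shared sub-genome difference);
#' exactly one polymorphic = case B (Gh) or case C (Gb), allelic SNPs;
#' both monomorphic with different alleles = case D (fixed inter-genotypic
#' difference, one sub-genome expressed per genotype); both monomorphic on
#' the same allele = no variant.
#'
#' @param counts_gh,counts_gb Named allele-depth vectors for the two
#'   genotypes at the position.
#' @inheritParams call_intra_genotype
#' @return A list: `classification` (one of `caseA_homoeo`, `caseB_Gh_poly`,
#'   `caseC_Gb_poly`, `caseD_fixed_diff`, `none`, or `not_assessable`),
#'   `alleles_gh`, `alleles_gb`, `alleles` (union), `mono_allele_shared`
#'   (for cases B/C: does the monomorphic genotype's allele match one of
#'   the polymorphic genotype's alleles).
#' @export
classify_position <- function(counts_gh, counts_gb, min_depth = 6L,
                              maf = 0.10, min_minor = 2L) {
  gh <- call_intra_genotype(counts_gh, min_depth, maf, min_minor)
  gb <- call_intra_genotype(counts_gb, min_depth, maf, min_minor)
  if (!gh$assessable || !gb$assessable) {
    return(list(classification = "not_assessable",
                alleles_gh = character(0), alleles_gb = character(0),
                alleles = character(0), mono_allele_shared = NA))
  }
  shared <- NA
  cls <- if (gh$polymorphic && gb$polymorphic) {
    "caseA_homoeo"
  } else if (gh$polymorphic) {
    shared <- gb$alleles %in% gh$alleles
    "caseB_Gh_poly"
  } else if (gb$polymorphic) {
    shared <- gh$alleles %in% gb$alleles
    "caseC_Gb_poly"
  } else if (gh$alleles != gb$alleles) {
    "caseD_fixed_diff"
  } else {
    "none"
  }
  list(classification = cls, alleles_gh = gh$alleles,
       alleles_gb = gb$alleles,
       alleles = sort(union(gh$alleles, gb$alleles)),
       mono_allele_shared = shared)
}

#' Transition / transversion class of an allele set
#'
#' @param alleles Character vector of two or more distinct bases.
#' @return `"transition"` (`A/G` or `C/T`), `"transversion"` (any other
#'   biallelic pair), or `"multi"` (more than two alleles).
#' @export
ts_tv <- function(alleles) {
  alleles <- sort(unique(alleles))
  if (length(alleles) < 2L) stop("need at least two alleles", call. = FALSE)
  if (length(alleles) > 2L) return("multi")
  pair <- paste(alleles, collapse = "")
  if (pair %in% c("AG", "CT")) "transition" else "transversion"
}

#' Scan a contig pileup for variants
#'
#' Applies [classify_position()] at every dual-coverage position (both
#' genotypes `>= min_depth`; these positions form the eligible-base
#' denominator for inter-genotypic SNP density) and, independently, the
#' single-genotype intra-SNP scan at every position assessable for that
#' genotype.
#'
#' @param pileup A [build_pileup()] result.
#' @inheritParams call_intra_genotype
#' @return A list with `calls` (data.frame: `contig`, `pos`,
#'   `classification`, `alleles_gh`, `alleles_gb`, `alleles` as
#'   comma-strings, `biallelic`, `subst_type`, `mono_allele_shared`; only
#'   variant positions), `eligible_bases` (dual-coverage bp),
#'   `intra` (per-genotype data.frame of intra-SNP positions `genotype`,
#'   `pos`, `alleles`), `assessable_bases` (named per-genotype counts).
#' @export
scan_contig <- function(pileup, min_depth = 6L, maf = 0.10,
                        min_minor = 2L) {
  stopifnot(inherits(pileup, "pileup"))
  g <- pileup$genotype
  L <- pileup$length
  depth_gh <- rowSums(g[, , "Gh", drop = FALSE])
  depth_gb <- rowSums(g[, , "Gb", drop = FALSE])
  # vectorized per-genotype polymorphism: qualifying allele counts
  qual_n <- function(m, depth) {
    q <- m >= min_minor & m / pmax(depth, 1L) >= maf
    rowSums(q)
  }
  mgh <- g[, , "Gh"]; mgb <- g[, , "Gb"]
  if (L == 1L) { mgh <- matrix(mgh, 1L); mgb <- matrix(mgb, 1L) }
  qa_gh <- qual_n(mgh, depth_gh)
  qa_gb <- qual_n(mgb, depth_gb)
  ok_gh <- depth_gh >= min_depth
  ok_gb <- depth_gb >= min_depth
  poly_gh <- ok_gh & qa_gh >= 2L
  poly_gb <- ok_gb & qa_gb >= 2L
  dual <- ok_gh & ok_gb

  maj <- function(m) DNA_BASES[max.col(m, ties.method = "first")]
  maj_gh <- maj(mgh); maj_gb <- maj(mgb)
  # candidate variant positions under the dual scan
  cand <- which(dual & (poly_gh | poly_gb | maj_gh != maj_gb))
  calls <- lapply(cand, function(i) {
    cl <- classify_position(mgh[i, ], mgb[i, ], min_depth, maf, min_minor)
    if (cl$classification %in% c("none", "not_assessable")) return(NULL)
    data.frame(
      contig = pileup$contig_id, pos = i,
      classification = cl$classification,
      alleles_gh = paste(cl$alleles_gh, collapse = ","),
      alleles_gb = paste(cl$alleles_gb, collapse = ","),
      alleles = paste(cl$alleles, collapse = ","),
      biallelic = length(cl$alleles) == 2L,
      subst_type = if (length(cl$alleles) >= 2L) ts_tv(cl$alleles)
                   else NA_character_,
      mono_allele_shared = if (length(cl$mono_allele_shared) == 1L)
        cl$mono_allele_shared else NA,
      stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls) %||% data.frame(
    contig = character(0), pos = integer(0), classification = character(0),
    alleles_gh = character(0), alleles_gb = character(0),
    alleles = character(0), biallelic = logical(0),
    subst_type = character(0), mono_allele_shared = logical(0))

  intra <- do.call(rbind, lapply(c(Gh = "Gh", Gb = "Gb"), function(gt) {
    poly <- if (gt == "Gh") poly_gh else poly_gb
    m <- if (gt == "Gh") mgh else mgb
    pos <- which(poly)
    if (!length(pos)) return(NULL)
    dep <- if (gt == "Gh") depth_gh else depth_gb
    alle <- vapply(pos, function(i) {
      q <- m[i, ] >= min_minor & m[i, ] / dep[i] >= maf
      paste(DNA_BASES[q], collapse = ",")
    }, character(1))
    data.frame(contig = pileup$contig_id, genotype = gt, pos = pos,
               alleles = alle, stringsAsFactors = FALSE)
  }))
  intra <- intra %||% data.frame(contig = character(0),
                                 genotype = character(0), pos = integer(0),
                                 alleles = character(0))
  rownames(intra) <- NULL
  list(calls = calls,
       eligible_bases = sum(dual),
       intra = intra,
       assessable_bases = c(Gh = sum(ok_gh), Gb = sum(ok_gb)))
}

#' Summarize a variant-call set
#'
#' Tallies the homoeo/allelic partition, inter-genotypic SNP density over
#' the dual-coverage bases, per-genotype intra-SNP densities, and the
#' transition and biallelic fractions.
#'
#' @param calls data.frame of dual-scan calls (rbind of
#'   `scan_contig()$calls`).
#' @param eligible_bases Total dual-coverage bp.
#' @param intra Optional rbind of `scan_contig()$intra`.
#' @param assessable_bases Optional named per-genotype assessable bp.
#' @return A list of counts and densities; `density_bp` is
#'   `eligible_bases / n_intergenotypic` (bp per inter-genotypic SNP,
#'   rounded; `NA` when there are none).
#' @export
snp_summary <- function(calls, eligible_bases, intra = NULL,
                        assessable_bases = NULL) {
  tab <- function(cls) sum(calls$classification == cls)
  nA <- tab("caseA_homoeo"); nB <- tab("caseB_Gh_poly")
  nC <- tab("caseC_Gb_poly"); nD <- tab("caseD_fixed_diff")
  inter <- nB + nC + nD
  n <- nrow(calls)
  stopifnot(n == nA + nB + nC + nD)
  bi <- calls$biallelic
  ts <- calls$subst_type == "transition"
  out <- list(
    n_variant_positions = n,
    n_caseA = nA, n_caseB = nB, n_caseC = nC, n_caseD = nD,
    n_intergenotypic = inter,
    eligible_bases = eligible_bases,
    density_bp = if (inter > 0) round(eligible_bases / inter) else NA_real_,
    ts_fraction = if (n) round(mean(ts[bi]), 3) else NA_real_,
    biallelic_fraction = if (n) round(mean(bi), 3) else NA_real_)
  if (!is.null(intra)) {
    for (gt in c("Gh", "Gb")) {
      k <- sum(intra$genotype == gt)
      out[[paste0("n_intra_", gt)]] <- k
      if (!is.null(assessable_bases)) {
        out[[paste0("density_intra_", gt, "_bp")]] <-
          if (k > 0) round(assessable_bases[[gt]] / k) else NA_real_
      }
    }
  }
  out
}

#' Export SNPs with flanking sequence
#'
#' Writes each variant as `LEFT[ref/alt]RIGHT` with up to `flank` bases on
#' each side (truncated at contig ends), named `contig_pos` on the
#' unpadded consensus, the layout used for marker submission sheets.
#'
#' @param calls Dual-scan call data.frame (with `contig`, `pos`,
#'   `alleles`).
#' @param consensus Named character vector of unpadded contig consensus
#'   sequences.
#' @param flank Flank width in bp (default 60).
#' @return data.frame: `name`, `contig`, `pos`, `flanked`.
#' @export
export_snp_flanks <- function(calls, consensus, flank = 60L) {
  if (!nrow(calls)) {
    return(data.frame(name = character(0), contig = character(0),
                      pos = integer(0), flanked = character(0)))
  }
  flanked <- vapply(seq_len(nrow(calls)), function(i) {
    s <- consensus[[calls$contig[i]]]
    if (is.null(s) || is.na(s)) stop("no consensus for contig ",
                                     calls$contig[i], call. = FALSE)
    p <- calls$pos[i]
    if (p < 1L || p > nchar(s)) stop("position outside consensus: ",
                                     calls$contig[i], ":", p, call. = FALSE)
    left <- substr(s, max(1L, p - flank), p - 1L)
    right <- substr(s, p + 1L, min(nchar(s), p + flank))
    alle <- strsplit(calls$alleles[i], ",", fixed = TRUE)[[1]]
    paste0(left, "[", paste(alle, collapse = "/"), "]", right)
  }, character(1))
  data.frame(name = paste0(calls$contig, "_", calls$pos),
             contig = calls$contig, pos = calls$pos, flanked = flanked,
             stringsAsFactors = FALSE)
}

#' Export variant calls as VCF
#'
#' Writes a minimal VCF 4.2 file with the contig consensus base as REF,
#' the other called alleles as ALT, the Fig-5-style class in INFO and
#' per-genotype genotype columns `Gh`, `Gb` (monomorphic calls as
#' homozygous, polymorphic as heterozygous allele pairs).
#'
#' @param calls Dual-scan call data.frame.
#' @param consensus Named character vector of unpadded consensus
#'   sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_vcf <- function(calls, consensus, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Variant partition class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           "Gh\tGb")), con)
  if (nrow(calls)) {
    for (i in seq_len(nrow(calls))) {
      s <- consensus[[calls$contig[i]]]
      p <- calls$pos[i]
      if (is.null(s) || p < 1L || p > nchar(s)) {
        stop("position outside consensus: ", calls$contig[i], ":", p,
             call. = FALSE)
      }
      ref <- substr(s, p, p)
      alle <- strsplit(calls$alleles[i], ",", fixed = TRUE)[[1]]
      alt <- setdiff(alle, ref)
      if (!length(alt)) alt <- "."
      gt_of <- function(a_str) {
        a <- strsplit(a_str, ",", fixed = TRUE)[[1]]
        code <- match(a, c(ref, alt)) - 1L
        if (anyNA(code)) return("./.")
        if (length(code) == 1L) paste(code, code, sep = "/")
        else paste(sort(code)[1:2], collapse = "/")
      }
      writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tCLASS=%s\tGT\t%s\t%s",
                         calls$contig[i], p,
                         paste0(calls$contig[i], "_", p), ref,
                         paste(alt, collapse = ","),
                         calls$classification[i],
                         gt_of(calls$alleles_gh[i]),
                         gt_of(calls$alleles_gb[i])), con)
    }
  }
  invisible(path)
}
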