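#' Simulation configuration for a synthetic allotetraploid fiber transcriptome
#'
#' Builds and validates the parameter set for [simulate_transcriptome()] and
#' [simulate_reads()]. The defaults emulate the study design the package
#' targets: four pooled cDNA libraries crossing two genotypes (`Gh`, `Gb`)
#' with two developmental stages (`10`, `22` dpa), genes carrying two
#' homoeologous copies (`A`, `D`) diverged from a common ancestor, allelic
#' divergence between genotypes, occasional silencing of one homoeo-copy,
#' and 454-style reads of mean length 353 bp.
#'
#' @param n_genes Number of genes (contigs) to simulate.
#' @param gene_length Length range in bp, `c(min, max)`; lengths are drawn
#'   uniformly. The default straddles the 1,100 bp mean contig length typical
#'   of 454 EST assemblies.
#' @param homoeo_divergence Substitution rate per bp between the A and D
#'   homoeo-copies (shared by both genotypes). Default 1/80, the intra-
#'   genotypic SNP density scale observed in tetraploid cotton ESTs.
#' @param allelic_divergence Substitution rate per bp between the two
#'   genotypes' alleles of a single copy. Default 1/108, the inter-genotypic
#'   density scale.
#' @param silenced_fraction Per gene-by-genotype probability that one
#'   homoeo-copy (chosen uniformly) is transcriptionally silenced.
#' @param de_fraction Per gene-copy probability of differential expression
#'   between stages.
#' @param de_fold Fold multiplier applied to the favoured stage of a
#'   differential copy (must be >= 1).
#' @param reads_per_library Reads drawn for each of the four libraries.
#' @param read_length_mean,read_length_sd Normal read-length model in bp
#'   (truncated below at 1 bp by resampling and capped at gene length).
#' @param read_error_rate Per-base substitution error rate of the sequencer
#'   model (uniform over the three alternative bases).
#' @param seed Integer seed; identical configs give bit-identical output.
#' @param silencing Optional data.frame with columns `gene`, `genotype`,
#'   `copy` that fixes the silencing events instead of drawing them
#'   (used to construct specific expression patterns deterministically).
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 200L,
                       gene_length = c(600L, 1600L),
                       homoeo_divergence = 1 / 80,
                       allelic_divergence = 1 / 108,
                       silenced_fraction = 0.05,
                       de_fraction = 0.07,
                       de_fold = 4,
                       reads_per_library = 20000L,
                       read_length_mean = 353,
                       read_length_sd = 40,
                       read_error_rate = 0.005,
                       seed = 1L,
                       silencing = NULL) {
  if (length(gene_length) == 1L) gene_length <- c(gene_length, gene_length)
  stopifnot_scalar_num(n_genes, "n_genes", 1)
  stopifnot_scalar_num(homoeo_divergence, "homoeo_divergence", 0, 1)
  stopifnot_scalar_num(allelic_divergence, "allelic_divergence", 0, 1)
  stopifnot_scalar_num(silenced_fraction, "silenced_fraction", 0, 1)
  stopifnot_scalar_num(de_fraction, "de_fraction", 0, 1)
  stopifnot_scalar_num(de_fold, "de_fold", 1)
  stopifnot_scalar_num(reads_per_library, "reads_per_library", 1)
  stopifnot_scalar_num(read_length_mean, "read_length_mean", 1)
  stopifnot_scalar_num(read_length_sd, "read_length_sd", 0)
  stopifnot_scalar_num(read_error_rate, "read_error_rate", 0, 1)
  stopifnot_scalar_num(seed, "seed")
  # guard against class collisions: expected variants must leave room for
  # the disjoint-position re-draw
  if (homoeo_divergence + allelic_divergence > 1 / 3) {
    stop("divergence rates too high: expected variants exceed gene_length/3",
         call. = FALSE)
  }
  cfg <- list(
    n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length),
    homoeo_divergence = homoeo_divergence,
    allelic_divergence = allelic_divergence,
    silenced_fraction = silenced_fraction,
    de_fraction = de_fraction,
    de_fold = de_fold,
    reads_per_library = as.integer(reads_per_library),
    read_length_mean = read_length_mean,
    read_length_sd = read_length_sd,
    read_error_rate = read_error_rate,
    seed = as.integer(seed),
    silencing = silencing,
    genotypes = c("Gh", "Gb"),
    stages = c("10", "22"),
    copies = c("A", "D"),
    libraries = c("Gh10", "Gb10", "Gh22", "Gb22")
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic tetraploid transcriptome configuration\n")
  cat(sprintf("  genes: %d (length %d-%d bp)\n", x$n_genes,
              x$gene_length[1], x$gene_length[2]))
  cat(sprintf("  homoeo divergence: %.4g /bp, allelic: %.4g /bp\n",
              x$homoeo_divergence, x$allelic_divergence))
  cat(sprintf("  silenced fraction: %.3g, DE fraction: %.3g (fold %g)\n",
              x$silenced_fraction, x$de_fraction, x$de_fold))
  cat(sprintf("  reads/library: %d, length %g +/- %g bp, error %.3g /bp\n",
              x$reads_per_library, x$read_length_mean, x$read_length_sd,
              x$read_error_rate))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Simulate a tetraploid two-genotype transcriptome with ground truth
#'
#' For each gene an ancestral sequence is drawn, then four sequences are
#' derived: the A and D homoeo-copies for each of the two genotypes.
#' Homoeo-substitutions (A vs D) are shared by both genotypes; allelic
#' substitutions (Gh vs Gb) are private to one genotype and one copy. The
#' two planted position classes are disjoint by construction. Optionally one
#' homoeo-copy per gene x genotype is silenced (expression zero; the
#' sequence is kept), and a fraction of gene-copies is differentially
#' expressed between the two stages.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_truth`: a list with elements
#'   `genes` (data.frame: `gene`, `length`), `ancestral` (named character),
#'   `sequences` (named list; per gene a 2x2 character matrix copy x
#'   genotype), `panel_a`/`panel_d` (the shared pre-allelic A and D copy
#'   sequences, usable as progenitor transcript panels),
#'   `homoeo_pos` (named list of integer positions, 1-based),
#'   `allelic` (data.frame: `gene`, `pos`, `copy`, `genotype`),
#'   `silenced` (data.frame: `gene`, `genotype`, `copy`),
#'   `de` (data.frame: `gene`, `copy`, `up_stage`),
#'   `expression` (4-d array gene x copy x genotype x stage), and the
#'   `config` used.
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  gene_ids <- sprintf("gene%04d", seq_len(n))
  len_range <- seq.int(config$gene_length[1], config$gene_length[2])
  lens <- len_range[sample.int(length(len_range), n, replace = TRUE)]

  ancestral <- character(n)
  panel_d <- character(n)
  sequences <- vector("list", n)
  homoeo_pos <- vector("list", n)
  allelic <- vector("list", n)

  for (i in seq_len(n)) {
    L <- lens[i]
    anc <- sample(DNA_BASES, L, replace = TRUE)
    n_h <- stats::rbinom(1L, L, config$homoeo_divergence)
    n_a <- stats::rbinom(1L, L, config$allelic_divergence)
    # disjoint positions: a joint draw without replacement keeps the two
    # classes from colliding
    pos <- if (n_h + n_a > 0L) sample.int(L, n_h + n_a) else integer(0)
    hp <- sort(pos[seq_len(n_h)])
    ap <- pos[n_h + seq_len(n_a)]

    seqs <- matrix(rep(list(anc), 4L), nrow = 2,
                   dimnames = list(config$copies, config$genotypes))
    # homoeo edits: D copy differs from A copy in both genotypes
    d_edit <- mutate_bases(anc, hp)
    seqs[["D", "Gh"]] <- d_edit
    seqs[["D", "Gb"]] <- d_edit
    # allelic edits: one copy in one genotype
    a_copy <- sample(config$copies, length(ap), replace = TRUE)
    a_geno <- sample(config$genotypes, length(ap), replace = TRUE)
    for (j in seq_along(ap)) {
      s <- seqs[[a_copy[j], a_geno[j]]]
      seqs[[a_copy[j], a_geno[j]]] <- mutate_bases(s, ap[j])
    }
    ancestral[i] <- paste(anc, collapse = "")
    panel_d[i] <- paste(d_edit, collapse = "")
    sequences[[i]] <- matrix(
      vapply(seqs, paste, character(1), collapse = ""),
      nrow = 2, dimnames = dimnames(seqs))
    homoeo_pos[[i]] <- hp
    allelic[[i]] <- if (length(ap)) {
      data.frame(gene = gene_ids[i], pos = ap, copy = a_copy,
                 genotype = a_geno, stringsAsFactors = FALSE)
    } else NULL
  }
  names(ancestral) <- names(panel_d) <- names(sequences) <-
    names(homoeo_pos) <- gene_ids
  allelic <- do.call(rbind, allelic) %||%
    data.frame(gene = character(0), pos = integer(0), copy = character(0),
               genotype = character(0))

  # silencing events
  if (!is.null(config$silencing)) {
    silenced <- config$silencing
  } else {
    grid <- expand.grid(gene = gene_ids, genotype = config$genotypes,
                        stringsAsFactors = FALSE)
    hit <- stats::runif(nrow(grid)) < config$silenced_fraction
    silenced <- grid[hit, , drop = FALSE]
    silenced$copy <- sample(config$copies, nrow(silenced), replace = TRUE)
  }
  rownames(silenced) <- NULL

  # expression: per-gene lognormal baseline split equally across copies,
  # stage fold applied to DE copies, silenced copies zeroed
  base <- stats::rlnorm(n, meanlog = log(10), sdlog = 1)
  expr <- array(rep(base / 2, 8L),
                dim = c(n, 2L, 2L, 2L),
                dimnames = list(gene_ids, config$copies, config$genotypes,
                                config$stages))
  de_grid <- expand.grid(gene = gene_ids, copy = config$copies,
                         stringsAsFactors = FALSE)
  de_hit <- stats::runif(nrow(de_grid)) < config$de_fraction
  de <- de_grid[de_hit, , drop = FALSE]
  de$up_stage <- sample(config$stages, nrow(de), replace = TRUE)
  rownames(de) <- NULL
  for (j in seq_len(nrow(de))) {
    expr[de$gene[j], de$copy[j], , de$up_stage[j]] <-
      expr[de$gene[j], de$copy[j], , de$up_stage[j]] * config$de_fold
  }
  for (j in seq_len(nrow(silenced))) {
    expr[silenced$gene[j], silenced$copy[j], silenced$genotype[j], ] <- 0
  }

  out <- list(genes = data.frame(gene = gene_ids, length = lens,
                                 stringsAsFactors = FALSE),
              ancestral = ancestral, sequences = sequences,
              # progenitor-like transcript panels: the shared (pre-allelic)
              # A and D copies, the references a diploid relative provides
              panel_a = ancestral, panel_d = panel_d,
              homoeo_pos = homoeo_pos, allelic = allelic,
              silenced = silenced, de = de, expression = expr,
              config = config)
  class(out) <- "sim_truth"
  out
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic tetraploid transcriptome: %d genes, %d homoeo-SNPs, %d allelic SNPs, %d silenced copies, %d DE gene-copies\n",
    nrow(x$genes), sum(lengths(x$homoeo_pos)), nrow(x$allelic),
    nrow(x$silenced), nrow(x$de)))
  invisible(x)
}

#' Simulate 454-style reads and truth alignments from a transcriptome
#'
#' Reads are drawn per library (genotype x stage) with gene-copy probability
#' proportional to planted expression; lengths come from a normal model
#' truncated below at 1 bp (by resampling) and capped at gene length; start
#' positions are uniform; sequencing errors are uniform substitutions. Each
#' read keeps its placement on the gene's ancestral coordinate system, so
#' one truth [contig_alignment()] per covered gene is returned and assembly
#' is bypassed by construction.
#'
#' @param truth A `sim_truth` from [simulate_transcriptome()].
#' @param config The same [sim_config()] (seeds the read draw with
#'   `seed + 1`).
#' @return A list with `reads` (data.frame: `read_id`, `library`,
#'   `genotype`, `stage`, `gene`, `copy`, `start`, `length`, `sequence`),
#'   and `alignments` (named list of `contig_alignment`, one per gene with
#'   at least one read; consensus = ancestral sequence, unpadded).
#' @export
simulate_reads <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(config$seed + 1L)
  n <- nrow(truth$genes)
  lens <- truth$genes$length
  gene_ids <- truth$genes$gene

  all_reads <- vector("list", length(config$libraries))
  for (li in seq_along(config$libraries)) {
    lib <- config$libraries[li]
    geno <- substr(lib, 1, 2)
    stage <- substr(lib, 3, nchar(lib))
    w <- as.vector(truth$expression[, , geno, stage])  # gene-major, copy blocks
    if (sum(w) <= 0) stop("library ", lib, " has zero total expression")
    counts <- as.vector(stats::rmultinom(1L, config$reads_per_library, w))
    idx <- rep.int(seq_along(w), counts)           # (gene, copy) index per read
    gi <- ((idx - 1L) %% n) + 1L
    ci <- ((idx - 1L) %/% n) + 1L
    nr <- length(idx)
    # truncated normal lengths, resampled until >= 1
    rl <- as.integer(round(stats::rnorm(nr, config$read_length_mean,
                                        config$read_length_sd)))
    while (any(bad <- rl < 1L)) {
      rl[bad] <- as.integer(round(stats::rnorm(sum(bad),
                                               config$read_length_mean,
                                               config$read_length_sd)))
    }
    rl <- pmin(rl, lens[gi])
    start <- 1L + as.integer(floor(stats::runif(nr) * (lens[gi] - rl + 1L)))
    seqs <- character(nr)
    copy_names <- config$copies
    for (r in seq_len(nr)) {
      src <- truth$sequences[[gi[r]]][copy_names[ci[r]], geno]
      chars <- seq_chars(substr(src, start[r], start[r] + rl[r] - 1L))
      n_err <- stats::rbinom(1L, rl[r], config$read_error_rate)
      if (n_err > 0L) {
        chars <- mutate_bases(chars, sample.int(rl[r], n_err))
      }
      seqs[r] <- paste(chars, collapse = "")
    }
    all_reads[[li]] <- data.frame(
      read_id = sprintf("%s_r%06d", lib, seq_len(nr)),
      library = lib, genotype = geno, stage = stage,
      gene = gene_ids[gi], copy = copy_names[ci],
      start = start, length = rl, sequence = seqs,
      stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, all_reads)
  rownames(reads) <- NULL

  alignments <- lapply(split(reads, reads$gene), function(rr) {
    contig_alignment(
      contig_id = rr$gene[1],
      consensus = truth$ancestral[[rr$gene[1]]],
      placements = data.frame(read_id = rr$read_id, start = rr$start,
                              strand = "+", seq = rr$sequence,
                              stringsAsFactors = FALSE))
  })
  list(reads = reads, alignments = alignments[order(names(alignments))])
}

#' Simulate a contig-by-library read-count table with planted stage effects
#'
#' A lightweight count-level counterpart of the full read simulator, used
#' for digital-gene-expression calibration and recovery studies: contig
#' abundances are lognormal, a fraction of contigs receives a fold change
#' between the two stages, and library counts are multinomial draws of
#' fixed library size.
#'
#' @param n_contigs Number of contigs.
#' @param reads_per_library Total reads per library.
#' @param de_fraction Fraction of contigs with a planted stage effect.
#' @param de_fold Fold change applied to the favoured stage.
#' @param seed Integer seed.
#' @param libraries Library names (genotype x stage, default the four-pool
#'   design).
#' @return A list with `table` (a [count_table()]) and `truth` (data.frame:
#'   `contig`, `de`, `up_stage`).
#' @export
simulate_count_table <- function(n_contigs = 1000L,
                                 reads_per_library = 20000L,
                                 de_fraction = 0,
                                 de_fold = 4,
                                 seed = 1L,
                                 libraries = c("Gh10", "Gb10", "Gh22", "Gb22")) {
  set.seed(as.integer(seed))
  ids <- sprintf("contig%05d", seq_len(n_contigs))
  base <- stats::rlnorm(n_contigs, meanlog = log(10), sdlog = 1)
  de <- stats::runif(n_contigs) < de_fraction
  up <- ifelse(de, sample(c("10", "22"), n_contigs, replace = TRUE), NA)
  counts <- matrix(0L, n_contigs, length(libraries),
                   dimnames = list(ids, libraries))
  for (lib in libraries) {
    stage <- substr(lib, 3, nchar(lib))
    w <- base * ifelse(de & up == stage, de_fold, 1)
    counts[, lib] <- stats::rmultinom(1L, reads_per_library, w)
  }
  list(table = count_table(counts),
       truth = data.frame(contig = ids, de = de, up_stage = up,
                          stringsAsFactors = FALSE))
}
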