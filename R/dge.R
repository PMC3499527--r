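#' Contig-by-library read-count table
#'
#' Container for digital gene expression: a contig x library count matrix
#' with library totals (by default the reads assembled per library, i.e.
#' the column sums) and an optional contig x library x tag count array for
#' sub-genome comparisons.
#'
#' @param counts Integer matrix, contigs in rows, libraries in columns
#'   (column names are library names, `genotype` then `stage`, e.g.
#'   `Gh10`).
#' @param lib_totals Optional named numeric vector of per-library totals
#'   used as the normalization denominator; defaults to `colSums(counts)`
#'   (reads-in-contigs). Supply raw library read totals to switch
#'   normalizers.
#' @param tag_counts Optional 3-d array contig x library x tag with tags
#'   `A`, `D`, `unknown`.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, lib_totals = NULL, tag_counts = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(lib_totals)) lib_totals <- colSums(counts)
  if (is.null(names(lib_totals))) names(lib_totals) <- colnames(counts)
  if (any(colSums(counts) > lib_totals + 1e-9)) {
    stop("per-library contig counts exceed the library total", call. = FALSE)
  }
  meta <- data.frame(library = colnames(counts),
                     genotype = substr(colnames(counts), 1, 2),
                     stage = substr(colnames(counts), 3,
                                    nchar(colnames(counts))),
                     stringsAsFactors = FALSE)
  structure(list(counts = counts, lib_totals = lib_totals,
                 tag_counts = tag_counts, meta = meta),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d contigs x %d libraries (%s); %s reads\n",
              nrow(x$counts), ncol(x$counts),
              paste(colnames(x$counts), collapse = ", "),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Normalize a read count to abundance per 10,000 reads
#'
#' @param x Read count(s).
#' @param N Library (or group) total(s); must be positive.
#' @return `10000 * x / N`.
#' @export
normalize_abundance <- function(x, N) {
  if (any(N <= 0)) stop("library total must be positive", call. = FALSE)
  10000 * x / N
}

#' Normalized fold change between two groups
#'
#' Fold of group 1 over group 2 on the normalized scale,
#' `(x1/N1) / (x2/N2)`. One-sided zeros give `Inf` (or 0); a both-zero
#' contig is undefined (`NaN`) and is never flagged differential.
#'
#' @param x1,x2 Group read counts.
#' @param N1,N2 Group totals (positive).
#' @return Numeric fold change(s).
#' @export
fold_change <- function(x1, N1, x2, N2) {
  if (any(c(N1, N2) <= 0)) stop("group totals must be positive",
                                call. = FALSE)
  r <- (x1 / N1) / (x2 / N2)
  r[x1 == 0 & x2 == 0] <- NaN
  r
}

#' The Stekel-Git-Falciani R statistic
#'
#' Log-likelihood-ratio measure of heterogeneity of a gene's counts across
#' libraries relative to library sizes:
#' `R = sum_j x_j * ln(x_j / (N_j * f))` with `f = sum(x) / sum(N)`;
#' zero-count terms contribute 0. `R = 0` exactly when counts are
#' proportional to library sizes; `2R` is the deviance of the multinomial
#' likelihood-ratio comparison and is asymptotically chi-squared with
#' `length(x) - 1` degrees of freedom under homogeneity.
#'
#' @param x Counts per library (length >= 2).
#' @param N Library totals (positive, same length).
#' @return The R statistic (a single number).
#' @seealso [stekel_r_pvalue()]
#' @export
stekel_r <- function(x, N) {
  if (length(x) != length(N) || length(x) < 2L) {
    stop("x and N must have equal length >= 2", call. = FALSE)
  }
  if (any(N <= 0)) stop("library totals must be positive", call. = FALSE)
  if (all(x == 0)) stop("R is undefined when all counts are zero",
                        call. = FALSE)
  f <- sum(x) / sum(N)
  nz <- x > 0
  sum(x[nz] * log(x[nz] / (N[nz] * f)))
}

#' Chi-squared p-value for the R statistic
#'
#' Upper-tail chi-squared probability of `2R` on `k - 1` degrees of
#' freedom, the asymptotic reference for the multinomial deviance.
#'
#' @inheritParams stekel_r
#' @return A p-value.
#' @export
stekel_r_pvalue <- function(x, N) {
  stats::pchisq(2 * stekel_r(x, N), df = length(x) - 1L, lower.tail = FALSE)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Sums hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table
#' (up to a small relative tolerance, as is conventional). The all-zero
#' table returns 1.
#'
#' @param a,b,c,d Non-negative integer cells of the table
#'   `rbind(c(a, b), c(c, d))`.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  n <- a + b + c + d
  if (n == 0) return(1)
  m1 <- a + b   # row 1 margin
  k1 <- a + c   # column 1 margin
  support <- max(0, k1 - (n - m1)):min(m1, k1)
  probs <- stats::dhyper(support, m1, n - m1, k1)
  p_obs <- stats::dhyper(a, m1, n - m1, k1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Pairwise differential-expression comparison of two library groups
#'
#' For every contig, counts are summed over the libraries (and optionally
#' the tag class) of each group; significance is a two-sided Fisher's
#' exact test of the 2x2 table (reads in contig, other reads) x group;
#' effect size is the normalized fold change; and the R statistic across
#' the individual member libraries is reported alongside. A contig is
#' flagged differential for the group with the higher normalized abundance
#' when `p < alpha` and `fold >= min_fold` (an infinite fold qualifies;
#' both-zero contigs never do).
#'
#' @param table A [count_table()].
#' @param group1,group2 Group selectors: a list with `libraries` (character
#'   vector of library names) and optional `tag` (`"A"` or `"D"`; requires
#'   `tag_counts` in the table). Groups must be non-empty and disjoint
#'   (same library with different tags counts as disjoint).
#' @param alpha Significance level (default 0.05).
#' @param min_fold Minimum normalized fold change (default 2; applied
#'   as `>=`).
#' @return data.frame with one row per contig: `contig`, `x1`, `x2`,
#'   `N1`, `N2`, `fold`, `r_stat`, `p`, `flag` (`"group1"`, `"group2"` or
#'   `"none"`).
#' @export
compare_groups <- function(table, group1, group2, alpha = 0.05,
                           min_fold = 2) {
  stopifnot(inherits(table, "count_table"))
  g1 <- resolve_group(table, group1)
  g2 <- resolve_group(table, group2)
  if (identical(g1$key, g2$key)) stop("groups must be disjoint",
                                      call. = FALSE)
  if (length(intersect(g1$key, g2$key))) {
    stop("groups must be disjoint", call. = FALSE)
  }
  x1 <- g1$counts; x2 <- g2$counts
  N1 <- g1$total; N2 <- g2$total
  if (N1 <= 0 || N2 <= 0) stop("empty group (zero total reads)",
                               call. = FALSE)
  fold <- fold_change(x1, N1, x2, N2)
  p <- mapply(function(a, b, cc, dd) fisher_exact_2x2(a, b, cc, dd),
              x1, N1 - x1, x2, N2 - x2)
  # R across the member libraries of both groups (the multi-library view)
  mem <- cbind(g1$members, g2$members)
  mem_tot <- c(g1$member_totals, g2$member_totals)
  r_stat <- apply(mem, 1L, function(xx) {
    if (all(xx == 0)) NA_real_ else stekel_r(xx, mem_tot)
  })
  flag <- rep("none", length(x1))
  sig <- p < alpha & !is.nan(fold)
  flag[sig & fold >= min_fold] <- "group1"
  flag[sig & fold <= 1 / min_fold] <- "group2"
  data.frame(contig = rownames(table$counts), x1 = x1, x2 = x2,
             N1 = N1, N2 = N2, fold = fold, r_stat = r_stat, p = p,
             flag = flag, row.names = NULL, stringsAsFactors = FALSE)
}

# Sum counts over a group selector; returns per-contig counts, the group
# total (normalizer), member library columns, and a disjointness key.
# Tag-stratified groups normalize by the total reads of that tag class in
# the selected libraries (untagged reads are uninformative for A/D
# contrasts).
resolve_group <- function(table, group) {
  libs <- group$libraries
  if (is.null(libs) || !length(libs)) stop("group has no libraries",
                                           call. = FALSE)
  if (!all(libs %in% colnames(table$counts))) {
    stop("unknown library in group: ",
         paste(setdiff(libs, colnames(table$counts)), collapse = ", "),
         call. = FALSE)
  }
  tag <- group$tag
  if (is.null(tag)) {
    members <- table$counts[, libs, drop = FALSE]
    member_totals <- table$lib_totals[libs]
    key <- paste0(libs, "/*")
  } else {
    if (is.null(table$tag_counts)) {
      stop("tag-stratified group requires tag_counts", call. = FALSE)
    }
    members <- table$tag_counts[, libs, tag, drop = FALSE]
    dim(members) <- dim(members)[1:2]
    member_totals <- colSums(members)
    key <- paste0(libs, "/", tag)
  }
  list(counts = rowSums(members), total = sum(member_totals),
       members = members, member_totals = member_totals, key = key)
}

#' Enumerate the factorial of pairwise group comparisons
#'
#' Runs [compare_groups()] for every contrast of one factor (stage,
#' genotype, or sub-genome tag) overall and nested within each level (and
#' level pair) of the other factors, the comparison framework of a
#' two-genotype x two-stage tagged EST study. Tag contrasts with no tagged
#' counts are skipped with a warning.
#'
#' @param table A [count_table()] (with `tag_counts` for tag contrasts).
#' @param factors Which factors to contrast (default all three when tag
#'   counts are present).
#' @param alpha,min_fold Passed to [compare_groups()].
#' @return data.frame with one row per comparison: `comparison`, `factor`,
#'   `n_up_group1`, `n_up_group2`, `n_tested`, and `p_counts` (Fisher test
#'   of the pair of differential counts against the remaining tested
#'   contigs).
#' @export
comparison_matrix <- function(table,
                              factors = c("stage", "genotype", "tag"),
                              alpha = 0.05, min_fold = 2) {
  stopifnot(inherits(table, "count_table"))
  meta <- table$meta
  has_tags <- !is.null(table$tag_counts)
  if (!has_tags) factors <- setdiff(factors, "tag")

  lib_sel <- function(genotype = NULL, stage = NULL) {
    sel <- rep(TRUE, nrow(meta))
    if (!is.null(genotype)) sel <- sel & meta$genotype == genotype
    if (!is.null(stage)) sel <- sel & meta$stage == stage
    meta$library[sel]
  }
  strata_for <- function(other) {
    # conditioning strata: none, each level of each other factor, and each
    # combination of levels across the other factors
    levs <- list(genotype = unique(meta$genotype),
                 stage = unique(meta$stage),
                 tag = c("A", "D"))
    out <- list(list())
    for (f in other) {
      out <- c(out, lapply(levs[[f]], function(l) {
        s <- list(); s[[f]] <- l; s
      }))
    }
    if (length(other) == 2L) {
      for (l1 in levs[[other[1]]]) for (l2 in levs[[other[2]]]) {
        s <- list(); s[[other[1]]] <- l1; s[[other[2]]] <- l2
        out <- c(out, list(s))
      }
    }
    out
  }

  rows <- list()
  for (f in factors) {
    other <- setdiff(factors, f)
    contrast <- switch(f, stage = c("10", "22"), genotype = c("Gh", "Gb"),
                       tag = c("A", "D"))
    for (st in strata_for(other)) {
      mk_group <- function(level) {
        genotype <- st$genotype; stage <- st$stage; tag <- st$tag
        if (f == "genotype") genotype <- level
        if (f == "stage") stage <- level
        if (f == "tag") tag <- level
        list(libraries = lib_sel(genotype, stage), tag = tag)
      }
      g1 <- mk_group(contrast[1]); g2 <- mk_group(contrast[2])
      label <- function(g, level) {
        base <- paste0(st$genotype %||% "", st$stage %||% "")
        nm <- switch(f,
                     stage = paste0(st$genotype %||% "", level),
                     genotype = paste0(level, st$stage %||% ""),
                     tag = if (nzchar(base)) base else "all")
        tg <- if (f == "tag") level else st$tag
        if (!is.null(tg)) paste0(nm, "_", tg) else nm
      }
      cmp_name <- paste(label(g1, contrast[1]), "vs",
                        label(g2, contrast[2]))
      tot1 <- sum(resolve_group_total(table, g1))
      tot2 <- sum(resolve_group_total(table, g2))
      if (tot1 == 0 || tot2 == 0) {
        warning("skipping comparison with no reads: ", cmp_name,
                call. = FALSE)
        next
      }
      res <- compare_groups(table, g1, g2, alpha = alpha,
                            min_fold = min_fold)
      n1 <- sum(res$flag == "group1")
      n2 <- sum(res$flag == "group2")
      nt <- nrow(res)
      p_counts <- fisher_exact_2x2(n1, nt - n1, n2, nt - n2)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = cmp_name, factor = f, n_up_group1 = n1,
        n_up_group2 = n2, n_tested = nt, p_counts = p_counts,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

resolve_group_total <- function(table, group) {
  tryCatch(resolve_group(table, group)$total, error = function(e) 0)
}

#' Cross-platform direction concordance
#'
#' Tallies, over genes called differential on two platforms (e.g. read
#' counts vs microarray), how many agree on the direction of difference.
#'
#' @param direction_a,direction_b Character vectors in `{"g1", "g2"}`:
#'   the favoured group per gene on each platform.
#' @return A list: `n_common`, `n_same_dir_g1`, `n_same_dir_g2`,
#'   `n_discordant`, `pct_concordant` (rounded to integer percent; `NA`
#'   when empty).
#' @export
platform_concordance <- function(direction_a, direction_b) {
  stopifnot(length(direction_a) == length(direction_b))
  ok <- c("g1", "g2")
  if (length(direction_a) &&
      (!all(direction_a %in% ok) || !all(direction_b %in% ok))) {
    stop('directions must be "g1" or "g2"', call. = FALSE)
  }
  n <- length(direction_a)
  s1 <- sum(direction_a == "g1" & direction_b == "g1")
  s2 <- sum(direction_a == "g2" & direction_b == "g2")
  list(n_common = n, n_same_dir_g1 = s1, n_same_dir_g2 = s2,
       n_discordant = n - s1 - s2,
       pct_concordant = if (n) round(100 * (s1 + s2) / n) else NA_real_)
}
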