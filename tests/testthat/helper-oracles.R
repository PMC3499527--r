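# Independent reference implementations used to check the package's
# algorithms on small inputs. Each deliberately takes a different route
# than the implementation it checks.

# exhaustive seeded-ungapped-alignment score: enumerate every (panel
# sequence, diagonal) pair, mark whether the diagonal carries k
# consecutive matches (a seed), and take the maximum subarray sum of the
# +1/-1 match profile over seeded diagonals
align_score_oracle <- function(read, panel, k = 11L) {
  rb <- strsplit(read, "")[[1]]
  best <- 0
  for (ps in panel) {
    pb <- strsplit(ps, "")[[1]]
    for (diag in (-(length(pb) - 1L)):(length(rb) - 1L)) {
      i <- seq_len(length(rb))
      j <- i - diag
      ok <- j >= 1L & j <= length(pb)
      if (sum(ok) < k) next
      m <- ifelse(rb[i[ok]] == pb[j[ok]] &
                    rb[i[ok]] %in% c("A", "C", "G", "T"), 1L, -1L)
      seeded <- any(stats::filter(m == 1L, rep(1, k), sides = 1) == k,
                    na.rm = TRUE)
      if (!seeded) next
      cur <- 0; loc <- 0
      for (v in m) {
        cur <- max(0, cur + v)
        loc <- max(loc, cur)
      }
      best <- max(best, loc)
    }
  }
  best
}

# two-sided Fisher p by full enumeration of tables with the observed
# margins, probabilities from binomial coefficients
fisher_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  if (n == 0) return(1)
  r1 <- a + b; r2 <- c + d; k1 <- a + c
  support <- max(0, k1 - r2):min(r1, k1)
  pr <- vapply(support, function(x) {
    exp(lchoose(r1, x) + lchoose(r2, k1 - x) - lchoose(n, k1))
  }, numeric(1))
  p_obs <- pr[match(a, support)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# regex-based SSR scanner: for each unit length a greedy backreference
# pattern finds maximal perfect runs; thresholds, shortest-unit priority
# and compound merging are re-applied with plain loops. Matching restarts
# p-1 bases before the end of the previous region (maximal runs of the
# same period can overlap by up to p-1 bases), skipping matches contained
# in an already-found region.
ssr_oracle_matches <- function(seq, p) {
  pat <- sprintf("([ACGT]{%d})\\1+", p)
  L <- nchar(seq)
  out <- list()
  from <- 1L
  prev_start <- -1L; prev_end <- -1L
  while (from <= L - 2L * p + 1L) {
    m <- regexpr(pat, substr(seq, from, L), perl = TRUE)
    if (m == -1L) break
    st <- from + as.integer(m) - 1L
    len <- attr(m, "match.length")
    en <- st + len - 1L
    if (st >= prev_start && en <= prev_end) {
      from <- st + 1L       # contained in the previous maximal region
    } else {
      out[[length(out) + 1L]] <- c(start = st, length = len)
      prev_start <- st; prev_end <- en
      from <- max(en - p + 2L, st + 1L)
    }
  }
  out
}

ssr_oracle <- function(seq, min_repeats = c("1" = 10L, "2" = 6L, "3" = 5L,
                                            "4" = 5L, "5" = 5L, "6" = 5L),
                       max_interruption = 100L) {
  simple <- list()
  for (p in as.integer(names(min_repeats))) {
    for (hit in ssr_oracle_matches(seq, p)) {
      s0 <- hit[["start"]]
      len <- hit[["length"]]
      count <- len %/% p
      if (count < min_repeats[[as.character(p)]]) next
      motif <- substr(seq, s0, s0 + p - 1L)
      # shortest-unit priority
      periodic <- FALSE
      for (d in seq_len(p - 1L)) {
        if (p %% d == 0L &&
            paste(rep(substr(motif, 1, d), p / d), collapse = "") == motif) {
          periodic <- TRUE; break
        }
      }
      if (periodic) next
      simple[[length(simple) + 1L]] <- data.frame(
        type = paste0("p", p), start = s0, end = s0 + count * p - 1L,
        motif = motif, unit_length = p, repeats = count,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(simple)) {
    return(data.frame(type = character(0), start = integer(0),
                      end = integer(0), members = character(0)))
  }
  simple <- do.call(rbind, simple)
  simple <- simple[order(simple$start, simple$unit_length), , drop = FALSE]
  mono <- simple[simple$unit_length == 1L, , drop = FALSE]
  poly <- simple[simple$unit_length > 1L, , drop = FALSE]
  out <- list()
  i <- 1L
  while (i <= nrow(poly)) {
    j <- i
    while (j < nrow(poly) &&
           poly$start[j + 1L] - poly$end[j] - 1L <= max_interruption) {
      j <- j + 1L
    }
    grp <- poly[i:j, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      type = if (nrow(grp) > 1L) "compound" else grp$type,
      start = min(grp$start), end = max(grp$end),
      members = paste(sprintf("(%s)%d", grp$motif, grp$repeats),
                      collapse = "+"),
      stringsAsFactors = FALSE)
    i <- j + 1L
  }
  for (kk in seq_len(nrow(mono))) {
    out[[length(out) + 1L]] <- data.frame(
      type = "p1", start = mono$start[kk], end = mono$end[kk],
      members = sprintf("(%s)%d", mono$motif[kk], mono$repeats[kk]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
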