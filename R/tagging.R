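#' Similarity score of a read against a progenitor transcript panel
#'
#' Emulates a Blat-style search with an 11-mer seeded, ungapped-extension
#' local aligner: every k-mer shared between the read and a panel sequence
#' seeds a diagonal, and the best ungapped local alignment on a seeded
#' diagonal is scored as matches minus mismatches. The score reported is
#' the maximum over all panel sequences; 0 when no seed matches (including
#' reads shorter than `k`).
#'
#' @param read A DNA string (or character vector of them).
#' @param panel Character vector of panel sequences (e.g. a diploid
#'   progenitor EST assembly).
#' @param k Seed length (default 11).
#' @return Integer vector of best-hit scores, one per read.
#' @export
similarity_score <- function(read, panel, k = 11L) {
  if (!length(panel)) stop("empty panel", call. = FALSE)
  cpp_best_scores(as.character(read), as.character(panel), as.integer(k))
}

#' Assign a sub-genome tag to one read
#'
#' Scores the read against both progenitor panels and applies the
#' assignment rule: a tag (`A` or `D`) requires hits above `min_score`
#' against both panels with strictly unequal scores; equal scores are a
#' tie, a hit against only one panel is a single hit, and both are left
#' `unknown` under the literal rule (set `one_sided = "assign"` for the
#' permissive alternative that tags single hits).
#'
#' @param read A DNA string.
#' @param panel_a,panel_d Character vectors: the A- and D-progenitor
#'   transcript panels.
#' @param min_score Minimum alignment score counting as a hit (default 30).
#' @param k Seed length.
#' @param one_sided `"unknown"` (default, literal rule) or `"assign"`.
#' @return A one-row data.frame: `read_id` (NA here; filled by
#'   [tag_library()]), `score_a`, `score_d`, `tag`, `reason`.
#' @export
tag_read <- function(read, panel_a, panel_d, min_score = 30L, k = 11L,
                     one_sided = c("unknown", "assign")) {
  res <- tag_library(data.frame(read_id = NA_character_, sequence = read,
                                stringsAsFactors = FALSE),
                     panel_a, panel_d, min_score = min_score, k = k,
                     one_sided = one_sided)
  res$decisions
}

#' Tag a read set against the two progenitor panels
#'
#' Vectorized application of the [tag_read()] rule to a whole read table,
#' with a per-library tag summary.
#'
#' @param reads data.frame with columns `read_id`, `sequence` and
#'   optionally `library`.
#' @inheritParams tag_read
#' @return A list with `decisions` (data.frame: `read_id`, `score_a`,
#'   `score_d`, `tag`, `reason`) and `summary` (per-library counts of
#'   `A`/`D`/`unknown` and the tagged fraction; a single `all` row when no
#'   library column is present).
#' @export
tag_library <- function(reads, panel_a, panel_d, min_score = 30L, k = 11L,
                        one_sided = c("unknown", "assign")) {
  one_sided <- match.arg(one_sided)
  if (!nrow(reads)) {
    dec <- data.frame(read_id = character(0), score_a = integer(0),
                      score_d = integer(0), tag = character(0),
                      reason = character(0), stringsAsFactors = FALSE)
    return(list(decisions = dec, summary = dec[0, 0]))
  }
  sa <- similarity_score(reads$sequence, panel_a, k)
  sd <- similarity_score(reads$sequence, panel_d, k)
  hit_a <- sa >= min_score
  hit_d <- sd >= min_score
  tag <- rep("unknown", nrow(reads))
  reason <- rep("no_hit", nrow(reads))
  both <- hit_a & hit_d
  reason[both & sa > sd] <- "a_better"
  tag[both & sa > sd] <- "A"
  reason[both & sd > sa] <- "d_better"
  tag[both & sd > sa] <- "D"
  reason[both & sa == sd] <- "tie"
  single <- xor(hit_a, hit_d)
  reason[single] <- "single_hit"
  if (one_sided == "assign") {
    tag[single & hit_a] <- "A"
    tag[single & hit_d] <- "D"
  }
  decisions <- data.frame(read_id = reads$read_id, score_a = sa,
                          score_d = sd, tag = tag, reason = reason,
                          stringsAsFactors = FALSE)
  lib <- reads$library %||% rep("all", nrow(reads))
  summary <- do.call(rbind, lapply(unique(lib), function(l) {
    t <- tag[lib == l]
    data.frame(library = l, n_reads = length(t),
               n_A = sum(t == "A"), n_D = sum(t == "D"),
               n_unknown = sum(t == "unknown"),
               tagged_fraction = round(mean(t != "unknown"), 4),
               stringsAsFactors = FALSE)
  }))
  list(decisions = decisions, summary = summary)
}
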