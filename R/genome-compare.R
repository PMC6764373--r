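#' Global pairwise genome diff
#'
#' Affine-gap global alignment (Needleman-Wunsch, via Biostrings) with
#' event-level counting: substitutions are counted per aligned mismatch
#' column, and each maximal contiguous gap counts as one insertion (gap in
#' A, sequence present in B) or deletion (gap in B) event with its length
#' recorded. Sequences longer than `chain_threshold` are first anchored on
#' unique shared k-mers and aligned piecewise between anchors, keeping the
#' comparison linear at genome scale.
#'
#' @param seq_a,seq_b sequences to compare (`A` is the reference for
#'   positions and the genomic side for editing classification).
#' @param match,mismatch,gap_open,gap_extend scoring scheme (penalties as
#'   negative numbers).
#' @param chain_threshold above this length anchor chaining is used.
#' @return object of class `diff_set`: `substitutions` (data.frame pos_a /
#'   base_a / base_b, 0-based on A), `insertions` and `deletions`
#'   (data.frames pos_a / length), and `totals`.
#' @export
global_diff <- function(seq_a, seq_b, match = 1, mismatch = -1,
                        gap_open = -10, gap_extend = -0.5,
                        chain_threshold = 20000L) {
  stopifnot(nzchar(seq_a), nzchar(seq_b))
  if (max(nchar(seq_a), nchar(seq_b)) <= chain_threshold) {
    d <- .aligned_diff(seq_a, seq_b, match, mismatch, gap_open, gap_extend,
                       offset_a = 0L)
  } else {
    segs <- .anchor_segments(seq_a, seq_b)
    parts <- lapply(seq_len(nrow(segs)), function(i) {
      sa <- substr(seq_a, segs$a0[i] + 1L, segs$a1[i])
      sb <- substr(seq_b, segs$b0[i] + 1L, segs$b1[i])
      if (identical(sa, sb)) return(NULL)       # anchored identical stretch
      .aligned_diff(sa, sb, match, mismatch, gap_open, gap_extend,
                    offset_a = segs$a0[i])
    })
    d <- list(
      substitutions = do.call(rbind, lapply(parts, `[[`, "substitutions")),
      insertions = do.call(rbind, lapply(parts, `[[`, "insertions")),
      deletions = do.call(rbind, lapply(parts, `[[`, "deletions")))
    empty_sub <- data.frame(pos_a = integer(0), base_a = character(0),
                            base_b = character(0), stringsAsFactors = FALSE)
    empty_ind <- data.frame(pos_a = integer(0), length = integer(0))
    d$substitutions <- d$substitutions %||% empty_sub
    d$insertions <- d$insertions %||% empty_ind
    d$deletions <- d$deletions %||% empty_ind
  }
  structure(
    c(d, list(totals = c(substitutions = nrow(d$substitutions),
                         insertions = nrow(d$insertions),
                         deletions = nrow(d$deletions)))),
    class = "diff_set")
}

# Align two (sub)sequences and harvest events; positions reported on A with
# `offset_a` added.
.aligned_diff <- function(sa, sb, match, mismatch, gap_open, gap_extend,
                          offset_a) {
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(sa), Biostrings::DNAString(sb), type = "global",
    substitutionMatrix = sub_mat,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap_a <- pa == "-"; gap_b <- pb == "-"
  pos_a <- cumsum(!gap_a) - 1L + offset_a      # 0-based A position per column
  is_sub <- !gap_a & !gap_b & pa != pb
  subs <- data.frame(pos_a = pos_a[is_sub], base_a = pa[is_sub],
                     base_b = pb[is_sub], stringsAsFactors = FALSE)
  gap_events <- function(gap_mask) {
    r <- rle(gap_mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(pos_a = pos_a[starts[keep]], length = r$lengths[keep])
  }
  list(substitutions = subs,
       insertions = gap_events(gap_a),        # present in B, absent in A
       deletions = gap_events(gap_b))         # present in A, absent in B
}

# Colinear unique shared 31-mer anchors splitting (A, B) into segments to
# align independently. Segment bounds are anchor midpoints.
.anchor_segments <- function(a, b, k = 31L) {
  ka <- kmers_of(a, k); kb <- kmers_of(b, k)
  ua <- ka[!(duplicated(ka) | duplicated(ka, fromLast = TRUE))]
  ub <- kb[!(duplicated(kb) | duplicated(kb, fromLast = TRUE))]
  common <- intersect(ua, ub)
  pa <- match(common, ka) - 1L
  pb <- match(common, kb) - 1L
  o <- order(pa)
  pa <- pa[o]; pb <- pb[o]
  keep <- !is.na(pa) & !is.na(pb)
  pa <- pa[keep]; pb <- pb[keep]
  # longest increasing run in pb (greedy colinear filter)
  sel <- integer(0); last_b <- -1L
  for (i in seq_along(pa)) {
    if (pb[i] > last_b) { sel <- c(sel, i); last_b <- pb[i] }
  }
  pa <- pa[sel]; pb <- pb[sel]
  # thin anchors to roughly 2 kb spacing (relative to the last kept anchor)
  # and cut segments at anchor midpoints
  if (length(pa) > 0L) {
    keep <- logical(length(pa))
    last <- -.Machine$integer.max
    for (i in seq_along(pa)) {
      if (pa[i] - last >= 2000L) { keep[i] <- TRUE; last <- pa[i] }
    }
    pa <- pa[keep]; pb <- pb[keep]
  }
  mids_a <- c(0L, pa + k %/% 2L, nchar(a))
  mids_b <- c(0L, pb + k %/% 2L, nchar(b))
  data.frame(a0 = head(mids_a, -1L), a1 = tail(mids_a, -1L),
             b0 = head(mids_b, -1L), b1 = tail(mids_b, -1L))
}

#' @export
print.diff_set <- function(x, ...) {
  cat(sprintf("Genome diff: %d substitutions, %d insertion events, %d deletion events\n",
              x$totals["substitutions"], x$totals["insertions"],
              x$totals["deletions"]))
  invisible(x)
}

#' Classify substitutions as RNA editing and correct the count
#'
#' With A the genomic and B the transcript-derived sequence, a substitution
#' is C-to-U compatible iff `base_a == "C"` and `base_b == "T"`, and G-to-A
#' compatible iff `base_a == "G"` and `base_b == "A"` (forward strand of the
#' supplied sequences; callers orient transcripts to the coding strand).
#' The corrected count removes editing-compatible substitutions in the
#' chosen mode.
#'
#' @param diffs a [global_diff()] result.
#' @param mode `"CtoU_only"` or `"CtoU_and_GtoA"`.
#' @return object of class `editing_summary`: `n_total`, `n_CtoU`, `n_GtoA`,
#'   `n_corrected`, plus position lists per class.
#' @export
classify_editing <- function(diffs, mode = c("CtoU_only", "CtoU_and_GtoA")) {
  mode <- match.arg(mode)
  s <- diffs$substitutions
  is_cu <- s$base_a == "C" & s$base_b == "T"
  is_ga <- s$base_a == "G" & s$base_b == "A"
  n_total <- nrow(s)
  n_corrected <- n_total - sum(is_cu) -
    if (mode == "CtoU_and_GtoA") sum(is_ga) else 0L
  structure(list(
    mode = mode, n_total = n_total, n_CtoU = sum(is_cu), n_GtoA = sum(is_ga),
    n_corrected = n_corrected,
    positions_CtoU = s$pos_a[is_cu], positions_GtoA = s$pos_a[is_ga]),
    class = "editing_summary")
}

#' @export
print.editing_summary <- function(x, ...) {
  cat(sprintf("Editing summary (%s): %d substitutions, %d C>U, %d G>A, corrected %d\n",
              x$mode, x$n_total, x$n_CtoU, x$n_GtoA, x$n_corrected))
  invisible(x)
}

#' GC-signature classifier configuration
#'
#' Default ranges are the compartment GC signatures of the Andropogoneae:
#' chloroplast 38.4-38.5%, nuclear 41.4-42.7%, mitochondrial 43.07-43.93%.
#' Ranges must not overlap.
#'
#' @param ranges named list of `c(low, high)` percent bounds (inclusive).
#' @return list of class `gc_classifier_config`.
#' @export
gc_classifier_config <- function(ranges = list(
                                   chloroplast = c(38.4, 38.5),
                                   nuclear = c(41.4, 42.7),
                                   mitochondrial = c(43.07, 43.93))) {
  stopifnot(length(ranges) > 0L)
  m <- do.call(rbind, ranges)
  if (any(m[, 1] > m[, 2])) stop("each range needs low <= high")
  o <- order(m[, 1])
  m <- m[o, , drop = FALSE]
  if (nrow(m) > 1L && any(m[-1L, 1] <= m[-nrow(m), 2])) {
    stop("GC ranges overlap")
  }
  structure(list(ranges = ranges), class = "gc_classifier_config")
}

#' Classify a sequence by GC signature
#'
#' GC percent is `100 * (G + C) / (A + C + G + T)` (N ignored); the
#' compartment is the configured range containing that value, else
#' `"unclassified"` with the nearest range reported.
#'
#' @param sequence a DNA string.
#' @param config a [gc_classifier_config()].
#' @return list with `gc_percent`, `compartment` and `nearest`.
#' @export
gc_classify <- function(sequence, config = gc_classifier_config()) {
  stopifnot(nzchar(sequence))
  f <- Biostrings::letterFrequency(Biostrings::DNAString(sequence),
                                   c("A", "C", "G", "T"))
  denom <- sum(f)
  if (denom == 0L) stop("sequence contains no unambiguous bases")
  gc <- 100 * sum(f[c("G", "C")]) / denom
  hit <- names(config$ranges)[vapply(config$ranges, function(r)
    gc >= r[1] && gc <= r[2], TRUE)]
  dist <- vapply(config$ranges, function(r)
    min(abs(gc - r[1]), abs(gc - r[2])), 0)
  list(gc_percent = gc,
       compartment = if (length(hit) > 0L) hit[1] else "unclassified",
       nearest = names(which.min(dist)))
}
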