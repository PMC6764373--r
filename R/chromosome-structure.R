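#' Find regions shared between two chromosomes
#'
#' Reports maximal near-exact matches between two sequences in both
#' orientations: exact k-mer anchors (k = `min_len %/% 2`, at least 15) are
#' grouped by diagonal and extended outward with an X-drop rule (match +1,
#' mismatch -2, cut at the maximum-score extent), then overlapping reports
#' are merged to maximal extents. These shared blocks are the candidate
#' join points through which a master circle would have to pass.
#'
#' @param chrom_a,chrom_b [circular_chromosome()] objects or bare sequences.
#' @param min_len minimum reported length (bases).
#' @param min_identity minimum percent identity.
#' @return data.frame of class `shared_regions`: columns `chrom_a`,
#'   `start_a`, `chrom_b`, `start_b`, `length`, `identity`, `orientation`;
#'   0-based starts on each chromosome's forward strand, sorted by `start_a`.
#' @export
find_shared_regions <- function(chrom_a, chrom_b, min_len = 30L,
                                min_identity = 95) {
  id_a <- if (inherits(chrom_a, "circular_chromosome")) chrom_a$id else "chrom_a"
  id_b <- if (inherits(chrom_b, "circular_chromosome")) chrom_b$id else "chrom_b"
  a <- if (inherits(chrom_a, "circular_chromosome")) chrom_a$sequence else chrom_a
  b <- if (inherits(chrom_b, "circular_chromosome")) chrom_b$sequence else chrom_b
  stopifnot(nzchar(a), nzchar(b))
  k <- max(15L, min_len %/% 2L)
  out <- NULL
  for (orient in c("same", "inverted")) {
    bb <- if (orient == "same") b else revcomp(b)
    segs <- .extended_matches(a, bb, k, min_identity / 100)
    if (is.null(segs) || nrow(segs) == 0L) next
    if (orient == "inverted") {
      nb <- nchar(b)
      tmp <- segs
      segs$s_start <- nb - tmp$s_end
      segs$s_end <- nb - tmp$s_start
    }
    segs$orientation <- orient
    out <- rbind(out, segs)
  }
  if (is.null(out) || nrow(out) == 0L) {
    res <- data.frame(chrom_a = character(), start_a = integer(),
                      chrom_b = character(), start_b = integer(),
                      length = integer(), identity = numeric(),
                      orientation = character(), stringsAsFactors = FALSE)
    class(res) <- c("shared_regions", "data.frame")
    return(res)
  }
  out <- out[out$q_end - out$q_start >= min_len &
             out$identity * 100 >= min_identity, , drop = FALSE]
  if (nrow(out) == 0L) {
    res <- data.frame(chrom_a = character(), start_a = integer(),
                      chrom_b = character(), start_b = integer(),
                      length = integer(), identity = numeric(),
                      orientation = character(), stringsAsFactors = FALSE)
    class(res) <- c("shared_regions", "data.frame")
    return(res)
  }
  res <- data.frame(chrom_a = id_a, start_a = out$q_start,
                    chrom_b = id_b, start_b = out$s_start,
                    length = out$q_end - out$q_start,
                    identity = 100 * out$identity,
                    orientation = out$orientation, stringsAsFactors = FALSE)
  res <- res[order(res$start_a, res$start_b), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("shared_regions", "data.frame")
  res
}

# Anchor, extend (X-drop, cut at max score), and merge overlapping segments
# on the same diagonal. Returns q/s 0-based half-open coords + identity.
.extended_matches <- function(query, subject, k, min_id, xdrop = 8) {
  hits <- .diagonal_hits(query, subject, k)
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  qc <- strsplit(query, "")[[1]]
  sc <- strsplit(subject, "")[[1]]
  nq <- length(qc); ns <- length(sc)
  segs <- list()
  for (i in seq_len(nrow(hits))) {
    q0 <- hits$q_start[i]; q1 <- hits$q_end[i]
    d <- hits$s_start[i] - hits$q_start[i]
    # left extension
    sc_best <- 0; sc_cur <- 0; best_q0 <- q0
    q <- q0
    while (q > 0L && q + d > 0L) {
      q <- q - 1L
      sc_cur <- sc_cur + if (qc[q + 1L] == sc[q + d + 1L] &&
                             qc[q + 1L] != "N") 1 else -2
      if (sc_cur > sc_best) { sc_best <- sc_cur; best_q0 <- q }
      if (sc_cur < sc_best - xdrop) break
    }
    q0 <- best_q0
    # right extension
    sc_best <- 0; sc_cur <- 0; best_q1 <- q1
    q <- q1
    while (q < nq && q + d < ns) {
      sc_cur <- sc_cur + if (qc[q + 1L] == sc[q + d + 1L] &&
                             qc[q + 1L] != "N") 1 else -2
      q <- q + 1L
      if (sc_cur > sc_best) { sc_best <- sc_cur; best_q1 <- q }
      if (sc_cur < sc_best - xdrop) break
    }
    q1 <- best_q1
    segs[[i]] <- c(q0 = q0, q1 = q1, d = d)
  }
  segs <- unique(do.call(rbind, segs))
  # merge overlapping/adjacent segments on the same diagonal
  out <- list()
  for (d in unique(segs[, "d"])) {
    sd <- segs[segs[, "d"] == d, , drop = FALSE]
    sd <- sd[order(sd[, "q0"]), , drop = FALSE]
    cur <- sd[1L, ]
    flush <- function(seg) {
      idy <- seq_identity(substr(query, seg["q0"] + 1L, seg["q1"]),
                          substr(subject, seg["q0"] + d + 1L, seg["q1"] + d))
      out[[length(out) + 1L]] <<- data.frame(
        q_start = unname(seg["q0"]), q_end = unname(seg["q1"]),
        s_start = unname(seg["q0"] + d), s_end = unname(seg["q1"] + d),
        identity = idy)
    }
    if (nrow(sd) > 1L) {
      for (i in 2L:nrow(sd)) {
        if (sd[i, "q0"] <= cur["q1"]) {
          cur["q1"] <- max(cur["q1"], sd[i, "q1"])
        } else {
          flush(cur); cur <- sd[i, ]
        }
      }
    }
    flush(cur)
  }
  do.call(rbind, out)
}

#' Enumerate the four join paths through a shared region
#'
#' A shared block between two circular chromosomes admits four local paths:
#' staying on chromosome A (`ref_a`), staying on B (`ref_b`), or switching
#' chromosomes through the block (`chimera_ab`, `chimera_ba`). Each path is
#' left flank + shared sequence + right flank; flanks wrap the circle's
#' origin where necessary, and inverted-orientation regions traverse the B
#' side in reverse complement.
#'
#' @param region one row of a [find_shared_regions()] table.
#' @param chromosomes list of [circular_chromosome()] objects covering the
#'   region's chromosome ids.
#' @param flank flank length on each side (bases).
#' @return named character vector of the 4 path sequences, each of length
#'   `2 * flank + region$length`.
#' @export
enumerate_join_paths <- function(region, chromosomes, flank = 500L) {
  seqs <- chrom_seqs(chromosomes)
  a <- seqs[[region$chrom_a]]; b <- seqs[[region$chrom_b]]
  if (is.null(a) || is.null(b)) stop("region chromosomes not found")
  len <- region$length
  if (region$start_a < 0L || region$start_a + len > nchar(a) ||
      region$start_b < 0L || region$start_b + len > nchar(b)) {
    stop("region coordinates invalid")
  }
  S_a <- substr(a, region$start_a + 1L, region$start_a + len)
  a_left <- circ_substr(a, region$start_a - flank, flank)
  a_right <- circ_substr(a, region$start_a + len, flank)
  if (identical(region$orientation, "inverted")) {
    # entering the block on B's reverse strand: flanks come from the
    # opposite sides of the B copy, reverse-complemented
    b_left <- revcomp(circ_substr(b, region$start_b + len, flank))
    b_right <- revcomp(circ_substr(b, region$start_b - flank, flank))
  } else {
    b_left <- circ_substr(b, region$start_b - flank, flank)
    b_right <- circ_substr(b, region$start_b + len, flank)
  }
  c(ref_a = paste0(a_left, S_a, a_right),
    ref_b = paste0(b_left, S_a, b_right),
    chimera_ab = paste0(a_left, S_a, b_right),
    chimera_ba = paste0(b_left, S_a, a_right))
}

# Occurrences of `core` (either strand) in each read, allowing `mm`
# mismatches. Returns a data.frame(read, strand, start) of 1-based starts in
# the read's own orientation after optional reverse complement.
.core_occurrences <- function(reads, core, mm) {
  out <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") unname(reads) else revcomp(unname(reads))
    m <- Biostrings::vmatchPattern(core, Biostrings::DNAStringSet(q),
                                   max.mismatch = mm)
    st <- Biostrings::startIndex(m)
    for (i in seq_along(st)) {
      if (length(st[[i]]) == 0L) next
      out <- rbind(out, data.frame(read = i, strand = strand,
                                   start = st[[i]], stringsAsFactors = FALSE))
    }
  }
  out
}

#' Count reads spanning each join path
#'
#' A read supports a path iff it covers the full shared block (at
#' `min_identity` percent identity) plus at least `anchor` flank bases on
#' both sides matching that path's flanks at the same identity. Because the
#' shared block itself is common to all four paths, only the flanking
#' anchors discriminate between them; a read equal to the shared block alone
#' supports nothing.
#'
#' @param reads named character vector.
#' @param paths output of [enumerate_join_paths()].
#' @param region_length length of the shared block (bases).
#' @param flank flank length used to build the paths.
#' @param anchor required matched flank on each side (bases).
#' @param min_identity percent identity (block and each anchor separately).
#' @return named integer vector of per-path support counts.
#' @export
count_spanning_reads <- function(reads, paths, region_length, flank = 500L,
                                 anchor = 20L, min_identity = 95) {
  stopifnot(anchor < flank)
  support <- setNames(integer(length(paths)), names(paths))
  if (length(reads) == 0L) return(support)
  core <- substr(paths[[1L]], flank + 1L, flank + region_length)
  min_id <- min_identity / 100
  mm_core <- floor((1 - min_id) * region_length)
  mm_anchor <- floor((1 - min_id) * anchor)
  occ <- .core_occurrences(reads, core, mm_core)
  if (is.null(occ)) return(support)
  rseq <- unname(reads)
  rlen <- nchar(rseq)
  for (p in seq_along(paths)) {
    la <- substr(paths[[p]], flank - anchor + 1L, flank)
    ra <- substr(paths[[p]], flank + region_length + 1L,
                 flank + region_length + anchor)
    hit_reads <- integer(0)
    for (i in seq_len(nrow(occ))) {
      rid <- occ$read[i]
      s <- occ$start[i]
      if (s <= anchor || s + region_length + anchor - 1L > rlen[rid]) next
      rd <- if (occ$strand[i] == "+") rseq[rid] else revcomp(rseq[rid])
      left <- substr(rd, s - anchor, s - 1L)
      right <- substr(rd, s + region_length, s + region_length + anchor - 1L)
      if (sum(charToRaw(left) != charToRaw(la)) <= mm_anchor &&
          sum(charToRaw(right) != charToRaw(ra)) <= mm_anchor) {
        hit_reads <- c(hit_reads, rid)
      }
    }
    support[p] <- length(unique(hit_reads))
  }
  support
}

#' Classify join candidates and render the master-circle verdict
#'
#' A region is `excluded` iff it is shorter than the read length and no read
#' spans a chimeric path through it; `candidate` iff it is at least as long
#' as the read length (reads of that length cannot resolve it) and has no
#' chimeric support; `supported` iff at least one read spans a chimeric
#' path. The genome is called "master circle present" iff any region is
#' supported.
#'
#' @param regions a [find_shared_regions()] table.
#' @param read_length read length of the dataset used for the spanning test.
#' @param spanning_support optional data.frame with columns `chimera_ab` and
#'   `chimera_ba` (one row per region, from [count_spanning_reads()]);
#'   missing means zero support everywhere.
#' @return list with `regions` (input plus `status` column), `counts`
#'   (total/excluded/candidate/supported) and `verdict`.
#' @export
classify_join_candidates <- function(regions, read_length,
                                     spanning_support = NULL) {
  stopifnot(read_length > 0L)
  n <- nrow(regions)
  chim <- if (is.null(spanning_support)) rep(0L, n)
          else spanning_support$chimera_ab + spanning_support$chimera_ba
  stopifnot(length(chim) == n)
  status <- ifelse(chim >= 1L, "supported",
                   ifelse(regions$length >= read_length, "candidate",
                          "excluded"))
  regions$status <- status
  counts <- c(total = n,
              excluded = sum(status == "excluded"),
              candidate = sum(status == "candidate"),
              supported = sum(status == "supported"))
  verdict <- if (counts["supported"] > 0L) "master circle present"
             else "no master circle"
  structure(list(regions = regions, counts = counts, verdict = verdict),
            class = "join_classification")
}

#' @export
print.join_classification <- function(x, ...) {
  cat(sprintf("Join-candidate classification: %d shared regions\n",
              x$counts["total"]))
  cat(sprintf("  excluded:  %d\n  candidate: %d\n  supported: %d\n",
              x$counts["excluded"], x$counts["candidate"],
              x$counts["supported"]))
  cat("Verdict:", x$verdict, "\n")
  invisible(x)
}

# Does each read span left_ctx + core + right_ctx (either strand)? The core
# may occur with mismatches at min_identity; each anchor context must match
# at the same identity. Returns a logical vector over reads.
.window_votes <- function(reads, left_ctx, core, right_ctx, min_identity) {
  votes <- logical(length(reads))
  if (length(reads) == 0L) return(votes)
  min_id <- min_identity / 100
  mm_core <- floor((1 - min_id) * nchar(core))
  anchor <- nchar(left_ctx)
  mm_anchor <- floor((1 - min_id) * anchor)
  occ <- .core_occurrences(reads, core, mm_core)
  if (is.null(occ)) return(votes)
  rseq <- unname(reads)
  rlen <- nchar(rseq)
  for (i in seq_len(nrow(occ))) {
    rid <- occ$read[i]
    if (votes[rid]) next
    s <- occ$start[i]
    if (s <= anchor || s + nchar(core) + anchor - 1L > rlen[rid]) next
    rd <- if (occ$strand[i] == "+") rseq[rid] else revcomp(rseq[rid])
    left <- substr(rd, s - anchor, s - 1L)
    right <- substr(rd, s + nchar(core), s + nchar(core) + anchor - 1L)
    if (sum(charToRaw(left) != charToRaw(left_ctx)) <= mm_anchor &&
        sum(charToRaw(right) != charToRaw(right_ctx)) <= mm_anchor) {
      votes[rid] <- TRUE
    }
  }
  votes
}

#' Detect alternative conformations at a long repeat
#'
#' For an inverted repeat, the alternative arrangement reverse-complements
#' the segment between the two copies; for a direct repeat, recombination
#' splits the circle into two subgenomic circles, each keeping one repeat
#' copy. Reads spanning a repeat copy with at least `anchor` matched flank
#' bases on both sides vote for the arrangement whose flank context they
#' match; reads matching both arrangements are uninformative and dropped.
#'
#' @param long_reads named character vector.
#' @param repeat_annotation one row of the truth repeats table (columns
#'   `type`, `chrom`, `start1`, `end1`, `start2`, `end2`).
#' @param chromosomes list of [circular_chromosome()] objects.
#' @param anchor matched flank required on each side of a repeat copy.
#' @param min_identity percent identity (repeat copy and anchors).
#' @return object of class `conformation_report` with per-arrangement counts.
#' @export
detect_alternative_conformations <- function(long_reads, repeat_annotation,
                                             chromosomes, anchor = 100L,
                                             min_identity = 95) {
  ra <- repeat_annotation
  if (ra$end1 > ra$start2) stop("repeat copies overlap")
  chrom <- chrom_seqs(chromosomes)[[ra$chrom]]
  n <- nchar(chrom)
  ctx <- function(seq, s, e) {
    list(left = circ_substr(seq, s - anchor, anchor),
         core = substr(seq, s + 1L, e),
         right = circ_substr(seq, e, anchor))
  }
  if (ra$type == "inverted") {
    alt <- paste0(substr(chrom, 1L, ra$end1),
                  revcomp(substr(chrom, ra$end1 + 1L, ra$start2)),
                  substr(chrom, ra$start2 + 1L, n))
    arrangements <- list(
      reference = list(ctx(chrom, ra$start1, ra$end1),
                       ctx(chrom, ra$start2, ra$end2)),
      inverted = list(ctx(alt, ra$start1, ra$end1),
                      ctx(alt, ra$start2, ra$end2))
    )
    labels <- c("reference", "inverted")
  } else {
    unit <- substr(chrom, ra$start1 + 1L, ra$end1)
    # subcircle junctions: approach copy 2, emerge after copy 1 (and the
    # mirror image for the other subcircle)
    arrangements <- list(
      single_circle = list(ctx(chrom, ra$start1, ra$end1),
                           ctx(chrom, ra$start2, ra$end2)),
      subcircles = list(
        list(left = circ_substr(chrom, ra$start2 - anchor, anchor),
             core = unit, right = circ_substr(chrom, ra$end1, anchor)),
        list(left = circ_substr(chrom, ra$start1 - anchor, anchor),
             core = substr(chrom, ra$start2 + 1L, ra$end2),
             right = circ_substr(chrom, ra$end2, anchor))
      )
    )
    labels <- c("single_circle", "subcircles")
  }

  counts <- setNames(integer(2L), labels)
  if (length(long_reads) > 0L) {
    votes <- matrix(FALSE, nrow = length(long_reads), ncol = 2L)
    for (j in 1:2) {
      for (w in arrangements[[j]]) {
        votes[, j] <- votes[, j] |
          .window_votes(long_reads, w$left, w$core, w$right, min_identity)
      }
    }
    informative <- xor(votes[, 1], votes[, 2])
    counts[1] <- sum(votes[informative, 1])
    counts[2] <- sum(votes[informative, 2])
  }
  total <- sum(counts)
  structure(
    list(repeat_type = ra$type, counts = counts,
         ratio = if (total > 0L) unname(counts / total) else c(NA_real_, NA_real_),
         verdict = if (total == 0L) "indeterminate"
                   else sprintf("%d:%d (%s:%s)", counts[2], counts[1],
                                labels[2], labels[1])),
    class = "conformation_report")
}

#' @export
print.conformation_report <- function(x, ...) {
  cat(sprintf("Conformation report (%s repeat):\n", x$repeat_type))
  for (i in seq_along(x$counts)) {
    cat(sprintf("  %-14s %d reads\n", names(x$counts)[i], x$counts[i]))
  }
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}
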