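#' Extract splice junctions from spliced alignments
#'
#' Every `N` (skip) operation yields one junction: the donor is the last
#' aligned base before the skip and the acceptor the first aligned base
#' after it (0-based, exon-side definition — organellar group-II splicing
#' does not follow GT-AG reliably, so no motif assumption is made).
#' Identical (donor, acceptor) events are aggregated into a support count,
#' coordinates are lifted back to per-chromosome space, and junctions whose
#' donor and acceptor lift to different chromosomes are flagged
#' cross-chromosomal. Records whose skip extends past the reference end are
#' rejected and tallied.
#'
#' @param alignments an [alignment_table()] over the concatenated
#'   pseudo-chromosome.
#' @param concat_map the [build_concat_map()] used for the concatenation.
#' @param min_support junctions with fewer supporting reads are dropped.
#' @param forward_only keep only forward-strand alignments first (the
#'   paper-style strand filter).
#' @return data.frame of class `splice_junctions` with columns
#'   `donor_chrom`, `donor_pos`, `acceptor_chrom`, `acceptor_pos`,
#'   `support`, `cross_chromosomal`; attribute `qc_rejected` counts records
#'   rejected for running off the reference.
#' @export
extract_junctions <- function(alignments, concat_map, min_support = 10L,
                              forward_only = FALSE) {
  if (forward_only) {
    alignments <- alignments[alignments$strand == "+", , drop = FALSE]
  }
  empty <- data.frame(donor_chrom = character(), donor_pos = integer(),
                      acceptor_chrom = character(), acceptor_pos = integer(),
                      support = integer(), cross_chromosomal = logical(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("splice_junctions", "data.frame")
  attr(empty, "qc_rejected") <- 0L
  if (nrow(alignments) == 0L) return(empty)
  has_skip <- grepl("N", alignments$cigar, fixed = TRUE)
  aln <- alignments[has_skip, , drop = FALSE]
  if (nrow(aln) == 0L) return(empty)
  qc_rejected <- 0L
  donors <- integer(0); acceptors <- integer(0)
  ops_list <- cigar_ops(aln$cigar)
  for (i in seq_len(nrow(aln))) {
    ops <- ops_list[[i]]
    refpos <- aln$pos[i]                        # 0-based
    ok <- TRUE
    dtmp <- integer(0); atmp <- integer(0)
    for (j in seq_len(nrow(ops))) {
      op <- ops$op[j]; len <- ops$len[j]
      if (op == "N") {
        dtmp <- c(dtmp, refpos - 1L)
        atmp <- c(atmp, refpos + len)
        refpos <- refpos + len
      } else if (op %in% c("M", "D")) {
        refpos <- refpos + len
      }
    }
    if (refpos > concat_map$total) { qc_rejected <- qc_rejected + 1L; ok <- FALSE }
    if (ok) { donors <- c(donors, dtmp); acceptors <- c(acceptors, atmp) }
  }
  if (length(donors) == 0L) {
    attr(empty, "qc_rejected") <- qc_rejected
    return(empty)
  }
  key <- paste(donors, acceptors)
  tab <- table(key)
  uk <- strsplit(names(tab), " ", fixed = TRUE)
  d <- vapply(uk, function(x) as.integer(x[1]), 0L)
  a <- vapply(uk, function(x) as.integer(x[2]), 0L)
  dd <- from_concat(concat_map, d)
  aa <- from_concat(concat_map, a)
  res <- data.frame(donor_chrom = dd$chrom, donor_pos = dd$pos,
                    acceptor_chrom = aa$chrom, acceptor_pos = aa$pos,
                    support = as.integer(tab),
                    cross_chromosomal = dd$chrom != aa$chrom,
                    stringsAsFactors = FALSE)
  res <- res[res$support >= min_support, , drop = FALSE]
  res <- res[order(res$donor_chrom, res$donor_pos, res$acceptor_chrom,
                   res$acceptor_pos), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("splice_junctions", "data.frame")
  attr(res, "qc_rejected") <- qc_rejected
  res
}

#' Cluster junctions into splice hotspots
#'
#' Single-linkage clustering: two junctions join the same hotspot iff their
#' donor positions are within `window` bases and their acceptor positions
#' are within `window` bases (same chromosome pair, same cross-chromosomal
#' orientation). Hotspots are reported sorted by total support, mirroring
#' the observation that organellar splice events target loci spanning a few
#' hundred to a few thousand bases rather than exact sites.
#'
#' @param junctions a [extract_junctions()] table.
#' @param window clustering window (bases).
#' @return data.frame of class `splice_hotspots`: one row per hotspot with
#'   donor/acceptor windows, member count and total support; member indices
#'   into `junctions` in the `members` list column.
#' @export
cluster_hotspots <- function(junctions, window = 1000L) {
  n <- nrow(junctions)
  empty <- data.frame(donor_chrom = character(), donor_start = integer(),
                      donor_end = integer(), acceptor_chrom = character(),
                      acceptor_start = integer(), acceptor_end = integer(),
                      n_junctions = integer(), total_support = integer())
  if (n == 0L) {
    empty$members <- list()
    class(empty) <- c("splice_hotspots", "data.frame")
    return(empty)
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  grp_key <- paste(junctions$donor_chrom, junctions$acceptor_chrom)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (grp_key[i] == grp_key[j] &&
          abs(junctions$donor_pos[i] - junctions$donor_pos[j]) <= window &&
          abs(junctions$acceptor_pos[i] - junctions$acceptor_pos[j]) <= window) {
        union_(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  out <- list()
  for (r in unique(roots)) {
    m <- which(roots == r)
    out[[length(out) + 1L]] <- data.frame(
      donor_chrom = junctions$donor_chrom[m[1]],
      donor_start = min(junctions$donor_pos[m]),
      donor_end = max(junctions$donor_pos[m]) + 1L,
      acceptor_chrom = junctions$acceptor_chrom[m[1]],
      acceptor_start = min(junctions$acceptor_pos[m]),
      acceptor_end = max(junctions$acceptor_pos[m]) + 1L,
      n_junctions = length(m),
      total_support = sum(junctions$support[m]),
      stringsAsFactors = FALSE)
    out[[length(out)]]$members <- list(m)
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$total_support), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("splice_hotspots", "data.frame")
  res
}

# Shared percentage arithmetic for the splice summary. Percentages are
# reported to two decimals and, separately, one decimal.
.splice_summary <- function(total, n_in_cds, n_cross) {
  if (total == 0L) {
    return(structure(list(total = 0L, n_in_cds = 0L, n_cross = 0L,
                          pct_in_cds = NA_real_, pct_cross = NA_real_,
                          pct_in_cds_1dp = NA_real_, pct_cross_1dp = NA_real_,
                          undefined = TRUE),
                     class = "splice_summary"))
  }
  structure(list(
    total = total, n_in_cds = n_in_cds, n_cross = n_cross,
    pct_in_cds = round(100 * n_in_cds / total, 2),
    pct_cross = round(100 * n_cross / total, 2),
    pct_in_cds_1dp = round(100 * n_in_cds / total, 1),
    pct_cross_1dp = round(100 * n_cross / total, 1),
    undefined = FALSE), class = "splice_summary")
}

#' Summarise junctions by CDS context and chromosome span
#'
#' A junction is inside coding sequence iff its donor or acceptor position
#' lies inside any CDS interval (the splice *sites* are tested, not the
#' skipped interval). Percentages are reported to two decimals and one
#' decimal; a zero-junction input flags them undefined.
#'
#' @param junctions a [extract_junctions()] table.
#' @param annotations an [annotation_table()] providing CDS features.
#' @return object of class `splice_summary` with `total`, `n_in_cds`,
#'   `n_cross`, `pct_in_cds`, `pct_cross` (2 dp) and `*_1dp` variants.
#' @export
classify_and_summarize <- function(junctions, annotations) {
  cds <- annotations[annotations$feature_type == "CDS", , drop = FALSE]
  in_iv <- function(chrom, pos) {
    any(cds$chrom == chrom & cds$start <= pos & pos < cds$end)
  }
  n <- nrow(junctions)
  in_cds <- vapply(seq_len(n), function(i)
    in_iv(junctions$donor_chrom[i], junctions$donor_pos[i]) ||
    in_iv(junctions$acceptor_chrom[i], junctions$acceptor_pos[i]), TRUE)
  .splice_summary(n, sum(in_cds), sum(junctions$cross_chromosomal))
}

#' @export
print.splice_summary <- function(x, ...) {
  if (x$undefined) {
    cat("Splice summary: no junctions (percentages undefined)\n")
    return(invisible(x))
  }
  cat(sprintf("Splice summary: %d junctions\n", x$total))
  cat(sprintf("  in CDS:            %d (%.2f%%)\n", x$n_in_cds, x$pct_in_cds))
  cat(sprintf("  cross-chromosomal: %d (%.1f%%)\n", x$n_cross, x$pct_cross_1dp))
  invisible(x)
}

#' Search for split guide-RNA loci around a junction
#'
#' Reconstructs the mature-transcript window across a junction (the last
#' `split` exonic bases up to the donor plus the first `window - split`
#' bases from the acceptor) and searches each half genome-wide on both
#' strands with at most `max_mismatch` mismatches, excluding the junction's
#' own donor/acceptor loci. Each pair of hit loci is a candidate guide
#' generatable by intra-chromosomal splicing. Reverse-strand hits are
#' reported with decreasing coordinates.
#'
#' @param junction one row of a [extract_junctions()] table.
#' @param chromosomes list of [circular_chromosome()] objects.
#' @param window mature-transcript window length (bases).
#' @param split bases of the window taken from the donor side.
#' @param max_mismatch mismatches tolerated per half.
#' @return data.frame of class `guide_candidates`: one row per (5' locus,
#'   3' locus) pair with strands, mismatch counts and report coordinates
#'   (1-based, decreasing for minus-strand hits).
#' @export
guide_rna_search <- function(junction, chromosomes, window = 54L,
                             split = 28L, max_mismatch = 1L) {
  stopifnot(split > 0L, split < window)
  seqs <- chrom_seqs(chromosomes)
  dseq <- seqs[[junction$donor_chrom]]
  aseq <- seqs[[junction$acceptor_chrom]]
  if (junction$donor_pos + 1L < split ||
      junction$acceptor_pos + (window - split) > nchar(aseq)) {
    stop("window larger than the available exon context around the junction")
  }
  half5 <- substr(dseq, junction$donor_pos - split + 2L, junction$donor_pos + 1L)
  half3 <- substr(aseq, junction$acceptor_pos + 1L,
                  junction$acceptor_pos + window - split)

  search_half <- function(half, own_chrom, own_start0) {
    hits <- NULL
    for (cid in names(seqs)) {
      subj <- Biostrings::DNAString(seqs[[cid]])
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") half else revcomp(half)
        m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch)
        if (length(m) == 0L) next
        st <- Biostrings::start(m) - 1L           # 0-based
        en <- Biostrings::end(m)                  # half-open end
        for (i in seq_along(st)) {
          if (cid == own_chrom && st[i] == own_start0) next   # its own locus
          mism <- nchar(half) -
            round(seq_identity(as.character(m[[i]]), pat) * nchar(half))
          hits <- rbind(hits, data.frame(
            chrom = cid, start = st[i], end = en[i], strand = strand,
            mismatches = mism,
            report_from = if (strand == "+") st[i] + 1L else en[i],
            report_to = if (strand == "+") en[i] else st[i] + 1L,
            stringsAsFactors = FALSE))
        }
      }
    }
    hits
  }
  h5 <- search_half(half5, junction$donor_chrom, junction$donor_pos - split + 1L)
  h3 <- search_half(half3, junction$acceptor_chrom, junction$acceptor_pos)
  if (is.null(h5) || is.null(h3)) {
    res <- data.frame(h5_chrom = character(), h5_from = integer(),
                      h5_to = integer(), h5_strand = character(),
                      h5_mismatches = integer(), h3_chrom = character(),
                      h3_from = integer(), h3_to = integer(),
                      h3_strand = character(), h3_mismatches = integer(),
                      stringsAsFactors = FALSE)
    class(res) <- c("guide_candidates", "data.frame")
    return(res)
  }
  res <- merge(
    stats::setNames(h5[c("chrom", "report_from", "report_to", "strand",
                         "mismatches")],
                    c("h5_chrom", "h5_from", "h5_to", "h5_strand",
                      "h5_mismatches")),
    stats::setNames(h3[c("chrom", "report_from", "report_to", "strand",
                         "mismatches")],
                    c("h3_chrom", "h3_from", "h3_to", "h3_strand",
                      "h3_mismatches")))
  class(res) <- c("guide_candidates", "data.frame")
  res
}
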