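#' Construct a circular chromosome
#'
#' The unit all pipeline stages operate on: an identifier plus a DNA string,
#' flagged circular or linear.
#'
#' @param id chromosome identifier (unique within a genome).
#' @param sequence DNA string over `{A,C,G,T,N}`.
#' @param circular logical; `TRUE` for a closed circle.
#' @return an object of class `circular_chromosome`.
#' @export
circular_chromosome <- function(id, sequence, circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence of '", id, "' contains characters outside {A,C,G,T,N}")
  }
  structure(
    list(id = id, sequence = sequence, circular = circular,
         length = nchar(sequence)),
    class = "circular_chromosome"
  )
}

#' @export
print.circular_chromosome <- function(x, ...) {
  cat(sprintf("<circular_chromosome> %s: %d bp (%s), GC %.2f%%\n",
              x$id, x$length, if (x$circular) "circular" else "linear",
              100 * gc_fraction(x$sequence)))
  invisible(x)
}

# Named character vector of sequences from a list of circular_chromosome
chrom_seqs <- function(chromosomes) {
  setNames(vapply(chromosomes, `[[`, "", "sequence"),
           vapply(chromosomes, `[[`, "", "id"))
}

#' Create an annotation table
#'
#' Internal coordinates are 0-based half-open (BED convention); exported GFF3
#' is 1-based inclusive. Features spanning the origin of a circle are split
#' into two records sharing a name.
#'
#' @param chrom,start,end,strand,feature_type,name vectors of equal length.
#' @return a `data.frame` with class `annotation_table`.
#' @export
annotation_table <- function(chrom = character(), start = integer(),
                             end = integer(), strand = character(),
                             feature_type = character(), name = character()) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   feature_type = as.character(feature_type),
                   name = as.character(name), stringsAsFactors = FALSE)
  if (any(df$start < 0L) || any(df$start >= df$end)) {
    stop("annotation coordinates must satisfy 0 <= start < end")
  }
  class(df) <- c("annotation_table", "data.frame")
  df
}

## ---- FASTA / FASTQ ---------------------------------------------------------

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings keeping sequences as named character vectors.
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Read and write FASTQ
#'
#' Qualities are carried as a uniform placeholder (`I`, Q40) on write; reads
#' come back as a named character vector on read.
#'
#' @param path file path.
#' @param seqs named character vector of read sequences.
#' @return `read_fastq` returns a named character vector.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' @rdname read_fastq
#' @export
write_fastq <- function(seqs, path) {
  if (length(seqs) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- as.vector(rbind(
    paste0("@", names(seqs)),
    unname(seqs),
    "+",
    strrep("I", nchar(seqs))
  ))
  writeLines(lines, path)
  invisible(path)
}

## ---- SAM text --------------------------------------------------------------

#' Alignment record table
#'
#' Alignments are plain data frames with columns `read_id`, `chrom`, `pos`
#' (0-based), `strand`, `cigar`, `seq` and optional mate columns. This
#' constructor validates CIGAR/position consistency.
#'
#' @param read_id,chrom,pos,strand,cigar,seq vectors of equal length; `pos` is
#'   0-based; `cigar` uses ops `M`, `I`, `D`, `N`, `S`.
#' @return `data.frame` of class `alignment_table`.
#' @export
alignment_table <- function(read_id = character(), chrom = character(),
                            pos = integer(), strand = character(),
                            cigar = character(), seq = character()) {
  df <- data.frame(read_id = as.character(read_id), chrom = as.character(chrom),
                   pos = as.integer(pos), strand = as.character(strand),
                   cigar = as.character(cigar), seq = as.character(seq),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    qlen <- cigar_query_length(df$cigar)
    bad <- nchar(df$seq) > 0 & qlen != nchar(df$seq)
    if (any(bad)) stop("CIGAR does not consume the read length for ",
                       sum(bad), " record(s)")
  }
  class(df) <- c("alignment_table", "data.frame")
  df
}

# Parse CIGAR strings into a list of (op, len) matrices.
cigar_ops <- function(cigar) {
  lapply(cigar, function(cg) {
    if (cg == "*" || !nzchar(cg)) return(data.frame(op = character(0), len = integer(0)))
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MIDNS]", cg))[[1]]
    if (length(lens) != length(ops)) stop("malformed CIGAR: ", cg)
    data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
  })
}

# Read-consuming span (M, I, S) of each CIGAR.
cigar_query_length <- function(cigar) {
  vapply(cigar_ops(cigar), function(d) sum(d$len[d$op %in% c("M", "I", "S")]), 0L)
}

# Reference-consuming span (M, D, N) of each CIGAR.
cigar_ref_length <- function(cigar) {
  vapply(cigar_ops(cigar), function(d) sum(d$len[d$op %in% c("M", "D", "N")]), 0L)
}

#' Write alignments as SAM text
#'
#' @param alignments an [alignment_table()].
#' @param ref_lengths named integer vector of reference lengths for the
#'   header `@SQ` lines.
#' @param path output path.
#' @export
write_sam <- function(alignments, ref_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), as.integer(ref_lengths)))
  if (nrow(alignments) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  flag <- ifelse(alignments$strand == "-", 16L, 0L)
  body <- paste(alignments$read_id, flag, alignments$chrom,
                alignments$pos + 1L, 60L, alignments$cigar, "*", 0L, 0L,
                alignments$seq, strrep("I", nchar(alignments$seq)),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read SAM text into an alignment table
#'
#' Unmapped records (`flag & 4`) are dropped. Positions are converted to the
#' package's 0-based convention.
#'
#' @param path SAM text file.
#' @return an [alignment_table()].
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) return(alignment_table())
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), 0L)
  keep <- bitwAnd(flag, 4L) == 0L
  f <- f[keep]; flag <- flag[keep]
  alignment_table(
    read_id = vapply(f, `[[`, "", 1L),
    chrom = vapply(f, `[[`, "", 3L),
    pos = vapply(f, function(x) as.integer(x[4]), 0L) - 1L,
    strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
    cigar = vapply(f, `[[`, "", 6L),
    seq = vapply(f, `[[`, "", 10L)
  )
}

#' Remove duplicate alignments
#'
#' Duplicates share (chrom, pos, strand, cigar); the first record is kept.
#' Stands in for the usual Picard-style duplicate marking step.
#'
#' @param alignments an [alignment_table()].
#' @return the deduplicated table.
#' @export
dedup_alignments <- function(alignments) {
  key <- paste(alignments$chrom, alignments$pos, alignments$strand,
               alignments$cigar, sep = "\r")
  alignments[!duplicated(key), , drop = FALSE]
}

## ---- GFF3 / BED ------------------------------------------------------------

#' Write annotations as GFF3
#'
#' Internal 0-based half-open coordinates become GFF3 1-based inclusive.
#'
#' @param annotations an [annotation_table()].
#' @param path output path.
#' @export
write_gff3 <- function(annotations, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$chrom,
    ranges = IRanges::IRanges(start = annotations$start + 1L, end = annotations$end),
    strand = ifelse(annotations$strand %in% c("+", "-"), annotations$strand, "*")
  )
  gr$type <- annotations$feature_type
  gr$ID <- annotations$name
  gr$Name <- annotations$name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read GFF3 into an annotation table
#'
#' @param path GFF3 file.
#' @return an [annotation_table()].
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  nm <- if (!is.null(gr$Name)) as.character(gr$Name) else as.character(gr$ID)
  annotation_table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_type = as.character(gr$type),
    name = nm
  )
}

#' Write intervals as BED
#'
#' @param annotations an [annotation_table()] (already 0-based half-open).
#' @param path output path.
#' @export
write_bed <- function(annotations, path) {
  df <- data.frame(annotations$chrom, annotations$start, annotations$end,
                   annotations$name, 0L,
                   ifelse(annotations$strand %in% c("+", "-"), annotations$strand, "."))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  annotation_table(chrom = df[[1]], start = df[[2]], end = df[[3]],
                   strand = if (ncol(df) >= 6) df[[6]] else ".",
                   feature_type = "region",
                   name = if (ncol(df) >= 4) df[[4]] else ".")
}

## ---- Concatenated coordinate map ------------------------------------------

#' Build the concatenated-coordinate map over ordered chromosomes
#'
#' Chromosomes are laid end to end into a single pseudo-chromosome so that
#' spliced alignments can cross chromosome bounds; the map lifts coordinates
#' in both directions.
#'
#' @param chromosomes ordered list of [circular_chromosome()] objects.
#' @return object of class `concat_map` with offsets and boundaries.
#' @export
build_concat_map <- function(chromosomes) {
  stopifnot(length(chromosomes) >= 1L)
  ids <- vapply(chromosomes, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate chromosome ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  lens <- vapply(chromosomes, `[[`, 0L, "length")
  offsets <- cumsum(c(0L, head(lens, -1L)))
  structure(
    list(ids = ids, lengths = setNames(lens, ids),
         offsets = setNames(offsets, ids),
         boundaries = cumsum(lens), total = sum(lens),
         concat_id = "mt_concat"),
    class = "concat_map"
  )
}

#' Lift per-chromosome coordinates to concatenated space
#'
#' @param map a [build_concat_map()] result.
#' @param chrom chromosome id vector.
#' @param pos 0-based position vector.
#' @return integer vector of concatenated 0-based positions.
#' @export
to_concat <- function(map, chrom, pos) {
  if (any(!chrom %in% map$ids)) stop("unknown chromosome id")
  pos <- as.integer(pos)
  if (any(pos < 0L | pos >= map$lengths[chrom])) stop("position outside chromosome")
  unname(map$offsets[chrom] + pos)
}

#' Lift concatenated coordinates back to chromosomes
#'
#' @param map a [build_concat_map()] result.
#' @param cpos 0-based concatenated position vector.
#' @return data.frame with columns `chrom`, `pos`.
#' @export
from_concat <- function(map, cpos) {
  cpos <- as.integer(cpos)
  if (any(cpos < 0L | cpos >= map$total)) stop("position outside concatenated space")
  idx <- findInterval(cpos, c(0L, map$boundaries), rightmost.closed = FALSE)
  data.frame(chrom = map$ids[idx], pos = cpos - unname(map$offsets[map$ids[idx]]),
             stringsAsFactors = FALSE)
}

## ---- Seed-and-extend read mapper ------------------------------------------

#' Map reads to circular references by seed-and-extend
#'
#' An ungapped mapper sufficient for the substitution-only error model the
#' simulator produces: exact k-mer seeds anchor candidate placements on the
#' doubled reference (so placements cross the origin of a circle), candidates
#' are scored by full-length identity, and the best placement at or above
#' `min_identity` is reported. Both strands are searched; ties break to the
#' lowest (chrom id, position). `N` bases never match.
#'
#' @param reads named character vector of read sequences.
#' @param reference list of [circular_chromosome()] objects.
#' @param seed_k seed length (default 15). Reads shorter than `seed_k` are
#'   reported unmapped.
#' @param min_identity minimum identity over the read (default 0.9).
#' @param circular search across the origin (default TRUE).
#' @return an [alignment_table()] with an extra `identity` column; unmapped
#'   reads get `chrom = NA`.
#' @export
map_reads <- function(reads, reference, seed_k = 15L, min_identity = 0.9,
                      circular = TRUE) {
  stopifnot(length(reads) > 0L, all(nzchar(reads)))
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  refs <- chrom_seqs(reference)
  ref_is_circ <- vapply(reference, `[[`, TRUE, "circular") & circular
  search_space <- ifelse(ref_is_circ, paste0(refs, refs), refs)

  out <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    rd <- reads[[i]]
    rlen <- nchar(rd)
    best <- NULL
    if (rlen >= seed_k) {
      # several seed offsets so a substitution cannot kill every seed
      offs <- unique(pmin(c(0L, rlen %/% 2L, rlen - seed_k), rlen - seed_k))
      for (strand in c("+", "-")) {
        qry <- if (strand == "+") rd else revcomp(rd)
        for (off in offs) {
          seed <- substr(qry, off + 1L, off + seed_k)
          for (ci in seq_along(refs)) {
            hits <- gregexpr(seed, search_space[[ci]], fixed = TRUE)[[1]]
            if (hits[1] == -1L) next
            L <- nchar(refs[[ci]])
            for (h in hits) {
              start0 <- h - 1L - off          # implied read start, 0-based
              if (ref_is_circ[ci]) {
                start0 <- ((start0 %% L) + L) %% L
              } else if (start0 < 0L || start0 + rlen > L) next
              if (rlen > L) next
              ref_piece <- if (ref_is_circ[ci]) circ_substr(refs[[ci]], start0, rlen)
                           else substr(refs[[ci]], start0 + 1L, start0 + rlen)
              idy <- seq_identity(qry, ref_piece)
              cand <- list(chrom = names(refs)[ci], pos = start0,
                           strand = strand, identity = idy)
              if (idy >= min_identity &&
                  (is.null(best) || idy > best$identity ||
                   (idy == best$identity &&
                    (cand$chrom < best$chrom ||
                     (cand$chrom == best$chrom && cand$pos < best$pos))))) {
                best <- cand
              }
            }
          }
        }
      }
    }
    out[[i]] <- if (is.null(best)) {
      data.frame(read_id = names(reads)[i], chrom = NA_character_,
                 pos = NA_integer_, strand = NA_character_,
                 cigar = "*", seq = rd, identity = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(read_id = names(reads)[i], chrom = best$chrom,
                 pos = best$pos, strand = best$strand,
                 cigar = paste0(rlen, "M"), seq = rd,
                 identity = best$identity, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("alignment_table", "data.frame")
  res
}
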