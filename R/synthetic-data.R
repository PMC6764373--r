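#' Simulation configuration for the toy two-chromosome mitogenome
#'
#' Defaults emulate the sugarcane-like mitogenome at one tenth scale: two
#' circular chromosomes (30 and 15 kb), a dozen short (30-360 bp, 2%
#' mismatched) regions shared between chromosomes, one long direct repeat and
#' one inverted repeat on chromosome 1, eight genes of which one is
#' trans-spliced with exons on both chromosomes, a plastid-derived segment
#' with chloroplast-like GC, C-to-U editing sites inside coding sequence, and
#' polyA-tagged degradation regions.
#'
#' @param seed RNG seed; a fixed seed gives byte-identical outputs.
#' @param chr_lengths lengths of the circular chromosomes (bases).
#' @param n_shared_regions number of inter-chromosomal shared regions.
#' @param shared_len_range length range (bases) of shared regions.
#' @param shared_mismatch_rate per-base substitution rate applied to the
#'   second copy of each shared region.
#' @param direct_repeat_len,inverted_repeat_len lengths of the chromosome-1
#'   long repeats (bases).
#' @param n_genes,n_trans_spliced_genes gene counts; trans-spliced genes have
#'   exons on both chromosomes.
#' @param plastid_segment_len,plastid_gc_target plastid-derived segment length
#'   and GC fraction.
#' @param mito_gc_target backbone GC fraction.
#' @param editing_sites number of C-to-U editing sites planted inside CDS.
#' @param degradation_regions number of polyA degradation regions.
#' @param read_len_short,insert_mean,insert_sd short-read geometry (bases).
#' @param long_read_mean,long_read_sd long-read length distribution (bases).
#' @param error_rate per-base substitution error rate for simulated reads.
#' @param coverage fold coverage for simulated genomic reads.
#' @param degradation_depth plateau depth of polyA islands (must exceed
#'   `polya_threshold`).
#' @param polya_threshold island depth threshold the generator targets.
#' @param conformation_mix fraction of long reads drawn from the inverted
#'   arrangement of the chromosome-1 inverted repeat.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 42L,
                              chr_lengths = c(30000L, 15000L),
                              n_shared_regions = 12L,
                              shared_len_range = c(30L, 360L),
                              shared_mismatch_rate = 0.02,
                              direct_repeat_len = 1500L,
                              inverted_repeat_len = 400L,
                              n_genes = 8L,
                              n_trans_spliced_genes = 1L,
                              plastid_segment_len = 1000L,
                              plastid_gc_target = 0.384,
                              mito_gc_target = 0.435,
                              editing_sites = 20L,
                              degradation_regions = 4L,
                              read_len_short = 120L,
                              insert_mean = 400L,
                              insert_sd = 40L,
                              long_read_mean = 2000L,
                              long_read_sd = 200L,
                              error_rate = 0,
                              coverage = 20,
                              degradation_depth = 600L,
                              polya_threshold = 500L,
                              conformation_mix = 0) {
  cfg <- as.list(environment())
  if (any(chr_lengths <= 2L * direct_repeat_len)) {
    stop("every chromosome must be longer than twice the direct repeat")
  }
  if (length(shared_len_range) != 2L || shared_len_range[2] >= 361L ||
      shared_len_range[1] < 10L || shared_len_range[1] > shared_len_range[2]) {
    stop("shared_len_range must lie within [10, 360]")
  }
  for (g in c(plastid_gc_target, mito_gc_target)) {
    if (g <= 0 || g >= 1) stop("GC targets must lie in (0, 1)")
  }
  if (error_rate < 0 || coverage < 0) stop("error_rate and coverage must be >= 0")
  if (degradation_depth <= polya_threshold) {
    stop("degradation_depth must exceed polya_threshold")
  }
  structure(cfg, class = "simulation_config")
}

# Allocate `len` bases on chromosome `chrom`, avoiding `occupied` intervals
# (0-based half-open, with a small buffer). Errors if nothing fits.
.alloc_interval <- function(occupied, chrom, len, chrom_len, margin = 100L,
                            buffer = 20L, tries = 400L) {
  lo <- margin
  hi <- chrom_len - margin - len
  if (hi < lo) stop("infeasible packing: feature of ", len,
                    " bp exceeds the room on chromosome '", chrom, "'")
  occ <- occupied[occupied$chrom == chrom, , drop = FALSE]
  for (i in seq_len(tries)) {
    s <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    e <- s + len
    if (nrow(occ) == 0L ||
        all(e + buffer <= occ$start | s >= occ$end + buffer)) {
      return(c(start = s, end = e))
    }
  }
  # dense chromosome: place at the start of the largest free gap, keeping
  # the remaining free space contiguous for later features
  occ <- occ[order(occ$start), , drop = FALSE]
  edges <- c(lo, as.vector(rbind(occ$start - buffer, occ$end + buffer)),
             chrom_len - margin)
  gap_start <- edges[seq(1L, length(edges), by = 2L)]
  gap_end <- edges[seq(2L, length(edges), by = 2L)]
  widths <- gap_end - gap_start
  g <- which.max(widths)
  if (length(g) == 1L && widths[g] >= len) {
    return(c(start = gap_start[g], end = gap_start[g] + len))
  }
  stop("infeasible packing: could not place a ", len,
       " bp feature on overfull chromosome '", chrom, "'")
}

#' Generate a toy multichromosomal mitogenome with ground truth
#'
#' Plants, at disjoint loci: a long direct repeat and an inverted repeat on
#' chromosome 1, a plastid-derived segment with its own GC signature,
#' inter-chromosomal shared regions copied at the configured mismatch rate,
#' and gene models (single- and multi-exon, one trans-spliced across
#' chromosomes, one multi-exon gene left non-coding). Every planted structure
#' is recorded in the returned ground truth with exact coordinates.
#'
#' @param config a [simulation_config()].
#' @return list with elements `chromosomes` (list of
#'   [circular_chromosome()]), `annotations` (an [annotation_table()]) and
#'   `truth` (class `ground_truth`).
#' @export
generate_mitogenome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_chr <- length(config$chr_lengths)
  ids <- paste0("chr", seq_len(n_chr))
  seqs <- setNames(
    vapply(config$chr_lengths, random_dna, "", gc = config$mito_gc_target),
    ids
  )
  occupied <- data.frame(chrom = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
  note <- function(chrom, iv) {
    occupied <<- rbind(occupied, data.frame(chrom = chrom, start = iv["start"],
                                            end = iv["end"]))
  }
  ann <- list()
  add_ann <- function(chrom, start, end, strand, type, name) {
    ann[[length(ann) + 1L]] <<- data.frame(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      strand = strand, feature_type = type, name = name,
      stringsAsFactors = FALSE)
  }

  ## gene models: exon structure per gene, one trans-spliced, one non-coding
  genes <- list()
  junctions <- NULL
  if (config$n_genes > 0L) {
    n_multi_extra <- max(0L, min(config$n_genes - config$n_trans_spliced_genes,
                                 ceiling(config$n_genes / 2)))
    gene_plan <- character(config$n_genes)
    gene_plan[seq_len(min(config$n_trans_spliced_genes, config$n_genes))] <- "trans"
    idx <- which(gene_plan == "")
    gene_plan[head(idx, n_multi_extra)] <- "multi"
    gene_plan[gene_plan == ""] <- "single"
    noncoding_gene <- if (sum(gene_plan == "multi") > 1L) which(gene_plan == "multi")[2] else 0L
    alt <- 0L
    for (g in seq_len(config$n_genes)) {
      gname <- sprintf("gene%02d", g)
      kind <- gene_plan[g]
      exons <- NULL
      if (kind == "trans" && n_chr >= 2L) {
        ex_lens <- sample(150:300, 3L, replace = TRUE)
        intron <- sample(300:600, 1L)
        foot <- ex_lens[1] + intron + ex_lens[2]
        iv <- .alloc_interval(occupied, "chr1", foot, config$chr_lengths[1])
        note("chr1", iv)
        e1s <- unname(iv["start"]); e1e <- e1s + ex_lens[1]
        e2s <- e1e + intron; e2e <- e2s + ex_lens[2]
        iv2 <- .alloc_interval(occupied, "chr2", ex_lens[3], config$chr_lengths[2])
        note("chr2", iv2)
        exons <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                            start = c(e1s, e2s, unname(iv2["start"])),
                            end = c(e1e, e2e, unname(iv2["end"])),
                            stringsAsFactors = FALSE)
      } else {
        # multi-exon genes stay on the roomy chromosome 1; single-exon
        # genes alternate chromosomes
        if (kind == "multi") {
          chrom <- "chr1"
        } else {
          chrom <- ids[(alt %% n_chr) + 1L]; alt <- alt + 1L
        }
        n_ex <- if (kind == "multi") sample(2:3, 1L) else 1L
        ex_lens <- sample(150:300, n_ex, replace = TRUE)
        introns <- if (n_ex > 1L) sample(300:600, n_ex - 1L, replace = TRUE) else integer(0)
        foot <- sum(ex_lens) + sum(introns)
        iv <- .alloc_interval(occupied, chrom, foot,
                              config$chr_lengths[match(chrom, ids)])
        note(chrom, iv)
        pos <- unname(iv["start"])
        ex <- list()
        for (e in seq_len(n_ex)) {
          ex[[e]] <- data.frame(chrom = chrom, start = pos, end = pos + ex_lens[e],
                                stringsAsFactors = FALSE)
          pos <- pos + ex_lens[e] + if (e < n_ex) introns[e] else 0L
        }
        exons <- do.call(rbind, ex)
      }
      coding <- g != noncoding_gene
      genes[[gname]] <- list(name = gname, strand = "+", coding = coding,
                             exons = exons)
      add_ann(exons$chrom[1], min(exons$start), max(exons$end[exons$chrom == exons$chrom[1]]),
              "+", "gene", gname)
      for (e in seq_len(nrow(exons))) {
        add_ann(exons$chrom[e], exons$start[e], exons$end[e], "+", "exon",
                sprintf("%s.exon%d", gname, e))
        if (coding) add_ann(exons$chrom[e], exons$start[e], exons$end[e], "+",
                            "CDS", sprintf("%s.cds%d", gname, e))
      }
      if (nrow(exons) >= 2L) {
        for (e in seq_len(nrow(exons) - 1L)) {
          add_intron <- exons$chrom[e] == exons$chrom[e + 1L]
          if (add_intron) {
            add_ann(exons$chrom[e], exons$end[e], exons$start[e + 1L], "+",
                    "intron", sprintf("%s.intron%d", gname, e))
          }
          junctions <- rbind(junctions, data.frame(
            gene = gname,
            donor_chrom = exons$chrom[e], donor_pos = exons$end[e] - 1L,
            acceptor_chrom = exons$chrom[e + 1L], acceptor_pos = exons$start[e + 1L],
            support = NA_integer_, stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(junctions)) {
    junctions <- data.frame(gene = character(), donor_chrom = character(),
                            donor_pos = integer(), acceptor_chrom = character(),
                            acceptor_pos = integer(), support = integer(),
                            stringsAsFactors = FALSE)
  }

  ## long repeats on chromosome 1
  repeats <- NULL
  plant_repeat <- function(type, len) {
    a <- .alloc_interval(occupied, "chr1", len, config$chr_lengths[1]); note("chr1", a)
    b <- .alloc_interval(occupied, "chr1", len, config$chr_lengths[1]); note("chr1", b)
    if (a["start"] > b["start"]) { tmp <- a; a <- b; b <- tmp }
    unit <- substr(seqs[["chr1"]], a["start"] + 1L, a["end"])
    copy <- if (type == "inverted") revcomp(unit) else unit
    substr(seqs[["chr1"]], b["start"] + 1L, b["end"]) <<- copy
    tag <- if (type == "direct") "DR" else "IR"
    add_ann("chr1", a["start"], a["end"], "+", "repeat", paste0(tag, "_1"))
    add_ann("chr1", b["start"], b["end"], if (type == "inverted") "-" else "+",
            "repeat", paste0(tag, "_2"))
    rbind(repeats, data.frame(
      type = type, chrom = "chr1",
      start1 = unname(a["start"]), end1 = unname(a["end"]),
      start2 = unname(b["start"]), end2 = unname(b["end"]),
      stringsAsFactors = FALSE))
  }
  repeats <- plant_repeat("direct", config$direct_repeat_len)
  repeats <- plant_repeat("inverted", config$inverted_repeat_len)

  ## plastid-derived segment (distinct GC signature)
  pl <- .alloc_interval(occupied, "chr1", config$plastid_segment_len,
                        config$chr_lengths[1])
  note("chr1", pl)
  substr(seqs[["chr1"]], pl["start"] + 1L, pl["end"]) <-
    random_dna(config$plastid_segment_len, config$plastid_gc_target)
  add_ann("chr1", pl["start"], pl["end"], "+", "plastid_derived", "plastid_seg_1")
  plastid_segments <- data.frame(chrom = "chr1", start = unname(pl["start"]),
                                 end = unname(pl["end"]), stringsAsFactors = FALSE)

  ## inter-chromosomal shared regions (chr1 source -> chr2 copy)
  shared <- NULL
  if (config$n_shared_regions > 0L && n_chr >= 2L) {
    for (i in seq_len(config$n_shared_regions)) {
      len <- sample(config$shared_len_range[1]:config$shared_len_range[2], 1L)
      a <- .alloc_interval(occupied, "chr1", len, config$chr_lengths[1]); note("chr1", a)
      b <- .alloc_interval(occupied, "chr2", len, config$chr_lengths[2]); note("chr2", b)
      orient <- sample(c("same", "inverted"), 1L, prob = c(0.75, 0.25))
      src <- substr(seqs[["chr1"]], a["start"] + 1L, a["end"])
      n_mm <- rbinom(1L, len, config$shared_mismatch_rate)
      copy <- mutate_substitutions(src, n_mm)
      if (orient == "inverted") copy <- revcomp(copy)
      substr(seqs[["chr2"]], b["start"] + 1L, b["end"]) <- copy
      shared <- rbind(shared, data.frame(
        chrom_a = "chr1", start_a = unname(a["start"]),
        chrom_b = "chr2", start_b = unname(b["start"]),
        length = len, identity = 100 * (len - n_mm) / len,
        orientation = orient, stringsAsFactors = FALSE))
    }
    shared <- shared[order(shared$start_a), , drop = FALSE]
    rownames(shared) <- NULL
  } else {
    shared <- data.frame(chrom_a = character(), start_a = integer(),
                         chrom_b = character(), start_b = integer(),
                         length = integer(), identity = numeric(),
                         orientation = character(), stringsAsFactors = FALSE)
  }

  ## C->U editing sites inside coding exons
  editing <- data.frame(chrom = character(), pos = integer(),
                        genomic_base = character(), edited_base = character(),
                        stringsAsFactors = FALSE)
  if (config$editing_sites > 0L && length(genes) > 0L) {
    cds_pos <- NULL
    for (gn in genes) {
      if (!gn$coding) next
      for (e in seq_len(nrow(gn$exons))) {
        piece <- substr(seqs[[gn$exons$chrom[e]]], gn$exons$start[e] + 1L,
                        gn$exons$end[e])
        hits <- gregexpr("C", piece, fixed = TRUE)[[1]]
        if (hits[1] == -1L) next
        cds_pos <- rbind(cds_pos, data.frame(
          chrom = gn$exons$chrom[e], pos = gn$exons$start[e] + hits - 1L,
          stringsAsFactors = FALSE))
      }
    }
    if (!is.null(cds_pos) && nrow(cds_pos) > 0L) {
      take <- sample.int(nrow(cds_pos), min(config$editing_sites, nrow(cds_pos)))
      editing <- data.frame(chrom = cds_pos$chrom[take], pos = cds_pos$pos[take],
                            genomic_base = "C", edited_base = "T",
                            stringsAsFactors = FALSE)
      editing <- editing[order(editing$chrom, editing$pos), , drop = FALSE]
      rownames(editing) <- NULL
    }
  }

  ## polyA degradation regions: cycle over intron / plastid / repeat / intergenic
  degr <- NULL
  if (config$degradation_regions > 0L) {
    intron_rows <- do.call(rbind, ann)[, , drop = FALSE]
    intron_rows <- intron_rows[intron_rows$feature_type == "intron", , drop = FALSE]
    kinds <- rep(c("intron", "plastid", "intergenic", "repeat"),
                 length.out = config$degradation_regions)
    for (i in seq_len(config$degradation_regions)) {
      len <- sample(150:300, 1L)
      kind <- kinds[i]
      if (kind == "intron" && nrow(intron_rows) > 0L) {
        r <- intron_rows[1L, ]
        len <- min(len, r$end - r$start - 20L)
        degr <- rbind(degr, data.frame(chrom = r$chrom, start = r$start + 10L,
                                       end = r$start + 10L + len))
        intron_rows <- intron_rows[-1L, , drop = FALSE]
      } else if (kind == "plastid") {
        len <- min(len, config$plastid_segment_len - 20L)
        degr <- rbind(degr, data.frame(chrom = "chr1", start = unname(pl["start"]) + 10L,
                                       end = unname(pl["start"]) + 10L + len))
      } else if (kind == "repeat") {
        len <- min(len, config$direct_repeat_len - 20L)
        degr <- rbind(degr, data.frame(chrom = "chr1",
                                       start = repeats$start1[1] + 10L,
                                       end = repeats$start1[1] + 10L + len))
      } else {
        iv <- .alloc_interval(occupied, "chr2", len, config$chr_lengths[min(2L, n_chr)])
        note(if (n_chr >= 2L) "chr2" else "chr1", iv)
        degr <- rbind(degr, data.frame(chrom = if (n_chr >= 2L) "chr2" else "chr1",
                                       start = unname(iv["start"]),
                                       end = unname(iv["end"])))
      }
    }
    degr$target_depth <- config$degradation_depth
  } else {
    degr <- data.frame(chrom = character(), start = integer(), end = integer(),
                       target_depth = integer(), stringsAsFactors = FALSE)
  }

  annotations <- do.call(rbind, ann)
  annotations <- annotation_table(annotations$chrom, annotations$start,
                                  annotations$end, annotations$strand,
                                  annotations$feature_type, annotations$name)
  chromosomes <- lapply(seq_len(n_chr), function(i)
    circular_chromosome(ids[i], seqs[[i]], circular = TRUE))
  truth <- structure(
    list(seed = config$seed,
         shared_regions = shared, repeats = repeats, genes = genes,
         junctions = junctions, editing_sites = editing,
         degradation_regions = degr, polya_islands = NULL,
         plastid_segments = plastid_segments,
         conformation_mix = config$conformation_mix),
    class = "ground_truth")
  list(chromosomes = chromosomes, annotations = annotations, truth = truth)
}

#' Simulate genomic reads from circular chromosomes
#'
#' Read start positions are uniform over each circle (sampled on the doubled
#' sequence and taken modulo length, so reads wrap the origin); strands are
#' random. With `error_rate = 0` every read is an exact, possibly wrapped,
#' possibly reverse-complemented substring. `master_circle = TRUE` fuses the
#' chromosomes through a shared region into a single chimeric circle as a
#' positive control for the master-circle test.
#'
#' @param chromosomes list of [circular_chromosome()].
#' @param config a [simulation_config()].
#' @param layout `"long"` for single long reads, `"paired"` for paired-end
#'   short reads.
#' @param master_circle simulate from the fused chimeric circle instead.
#' @param fuse_region a row of the truth `shared_regions` table (orientation
#'   `"same"`) through which to fuse; required when `master_circle = TRUE`.
#' @return list with `reads` (named character; for `"paired"`, `reads1` and
#'   `reads2`) and `placements` (truth positions).
#' @export
simulate_genomic_reads <- function(chromosomes, config, layout = c("long", "paired"),
                                   master_circle = FALSE, fuse_region = NULL) {
  layout <- match.arg(layout)
  stopifnot(config$coverage >= 0)
  set.seed(config$seed + if (layout == "long") 1001L else 1002L)
  if (master_circle) {
    if (is.null(fuse_region)) stop("master_circle = TRUE requires fuse_region")
    chromosomes <- list(fuse_chromosomes(chromosomes, fuse_region))
  }
  seqs <- chrom_seqs(chromosomes)
  reads <- character(0); reads1 <- character(0); reads2 <- character(0)
  placements <- NULL
  for (ci in seq_along(seqs)) {
    L <- nchar(seqs[[ci]])
    doubled <- paste0(seqs[[ci]], seqs[[ci]])
    if (layout == "long") {
      n <- round(config$coverage * L / config$long_read_mean)
      if (n == 0L) next
      starts <- sample.int(L, n, replace = TRUE) - 1L
      lens <- pmin(L, pmax(500L, round(rnorm(n, config$long_read_mean,
                                             config$long_read_sd))))
      seqv <- substring(doubled, starts + 1L, starts + lens)
      strand <- ifelse(runif(n) < 0.5, "+", "-")
      seqv[strand == "-"] <- revcomp(seqv[strand == "-"])
      ids <- sprintf("%s_long_%05d", names(seqs)[ci], seq_len(n))
      reads <- c(reads, setNames(seqv, ids))
      placements <- rbind(placements, data.frame(
        read_id = ids, chrom = names(seqs)[ci], start = starts, len = lens,
        strand = strand, stringsAsFactors = FALSE))
    } else {
      r <- config$read_len_short
      n <- round(config$coverage * L / (2L * r))
      if (n == 0L) next
      frag <- pmin(L, pmax(2L * r, round(rnorm(n, config$insert_mean,
                                               config$insert_sd))))
      starts <- sample.int(L, n, replace = TRUE) - 1L
      fseq <- substring(doubled, starts + 1L, starts + frag)
      r1 <- substr(fseq, 1L, r)
      r2 <- revcomp(substr(fseq, frag - r + 1L, frag))
      ids <- sprintf("%s_pair_%05d", names(seqs)[ci], seq_len(n))
      reads1 <- c(reads1, setNames(r1, paste0(ids, "/1")))
      reads2 <- c(reads2, setNames(r2, paste0(ids, "/2")))
      placements <- rbind(placements, data.frame(
        read_id = ids, chrom = names(seqs)[ci], start = starts, len = frag,
        strand = "+", stringsAsFactors = FALSE))
    }
  }
  apply_errors <- function(v) {
    if (config$error_rate == 0 || length(v) == 0L) return(v)
    n_err <- rbinom(length(v), nchar(v), config$error_rate)
    for (i in which(n_err > 0L)) v[i] <- mutate_substitutions(v[i], n_err[i])
    v
  }
  if (layout == "long") {
    list(reads = apply_errors(reads), placements = placements)
  } else {
    list(reads1 = apply_errors(reads1), reads2 = apply_errors(reads2),
         placements = placements)
  }
}

#' Fuse two chromosomes through a shared region into one chimeric circle
#'
#' Models the recombination a master circle would require: the result carries
#' both chromosomes in full, with the shared block present twice. Used as the
#' positive control for the master-circle spanning-read test.
#'
#' @param chromosomes list of the two [circular_chromosome()] objects.
#' @param region one row of the truth `shared_regions` table with
#'   `orientation == "same"`.
#' @return a single [circular_chromosome()] of combined length.
#' @export
fuse_chromosomes <- function(chromosomes, region) {
  seqs <- chrom_seqs(chromosomes)
  stopifnot(region$orientation == "same")
  a <- seqs[[region$chrom_a]]; b <- seqs[[region$chrom_b]]
  a_end <- region$start_a + region$length     # end of shared block on A
  b_end <- region$start_b + region$length
  fused <- paste0(
    substr(a, 1L, a_end),                          # A up to and through block
    substr(b, b_end + 1L, nchar(b)),               # B after block, around the circle
    substr(b, 1L, b_end),                          # B through its block copy
    substr(a, a_end + 1L, nchar(a))                # remainder of A
  )
  circular_chromosome("fused_master", fused, circular = TRUE)
}

#' Simulate spliced, edited, polyA-tagged transcript alignments
#'
#' Emits truth alignments in SAM-style records over the concatenated
#' pseudo-chromosome rather than re-mapping reads, so splice analysis does
#' not depend on a spliced aligner. Spliced reads carry `N` skip operations
#' across introns (including junctions crossing the chromosome boundary);
#' all transcript reads are drawn from the edited genome so mismatches occur
#' exactly at truth editing sites; polyA reads tile each degradation region
#' deterministically to a depth plateau above the island threshold.
#'
#' @param chromosomes,annotations,truth output of [generate_mitogenome()].
#' @param config the same [simulation_config()].
#' @return list with `spliced` and `polya` [alignment_table()]s, the updated
#'   `truth` (junction supports and achieved polyA islands filled in) and the
#'   `concat_map`.
#' @export
simulate_transcript_alignments <- function(chromosomes, annotations, truth, config) {
  set.seed(config$seed + 3001L)
  cmap <- build_concat_map(chromosomes)
  concat <- paste(chrom_seqs(chromosomes), collapse = "")
  r <- config$read_len_short

  # transcribed genome: apply C->U (seen as T) editing at truth sites
  edited <- concat
  if (nrow(truth$editing_sites) > 0L) {
    cpos <- to_concat(cmap, truth$editing_sites$chrom, truth$editing_sites$pos)
    for (i in seq_along(cpos)) {
      substr(edited, cpos[i] + 1L, cpos[i] + 1L) <- truth$editing_sites$edited_base[i]
    }
  }

  rec <- list()
  emit <- function(id, pos0, cigar, seq) {
    rec[[length(rec) + 1L]] <<- data.frame(
      read_id = id, chrom = cmap$concat_id, pos = pos0, strand = "+",
      cigar = cigar, seq = seq, stringsAsFactors = FALSE)
  }

  jn <- truth$junctions
  if (length(truth$genes) > 0L && nrow(jn) > 0L) {
    anchor <- 15L
    for (j in seq_len(nrow(jn))) {
      donor <- to_concat(cmap, jn$donor_chrom[j], jn$donor_pos[j])
      acceptor <- to_concat(cmap, jn$acceptor_chrom[j], jn$acceptor_pos[j])
      stopifnot(acceptor > donor + 1L)
      s <- sample(5:40, 1L)
      jn$support[j] <- s
      for (k in seq_len(s)) {
        u <- sample(anchor:(r - anchor), 1L)
        left_start <- donor - u + 1L
        gap <- acceptor - donor - 1L
        seqk <- paste0(substr(edited, left_start + 1L, donor + 1L),
                       substr(edited, acceptor + 1L, acceptor + (r - u)))
        emit(sprintf("%s_junc%02d_%03d", jn$gene[j], j, k), left_start,
             sprintf("%dM%dN%dM", u, gap, r - u), seqk)
      }
    }
  }

  if (length(truth$genes) > 0L) {
    # unspliced coverage: light genome-wide tiling (complete transcription)
    step_bg <- max(1L, round(r / 3))
    for (s0 in seq(0L, cmap$total - r, by = step_bg)) {
      emit(sprintf("bg_%06d", s0), s0, paste0(r, "M"),
           substr(edited, s0 + 1L, s0 + r))
    }
    # deeper tiling over exons so editing sites are well covered
    for (gn in truth$genes) {
      for (e in seq_len(nrow(gn$exons))) {
        es <- to_concat(cmap, gn$exons$chrom[e], gn$exons$start[e])
        ee <- es + (gn$exons$end[e] - gn$exons$start[e])
        if (ee - es < r) next
        for (s0 in seq(es, ee - r, by = max(1L, round(r / 12)))) {
          emit(sprintf("%s_ex%d_%06d", gn$name, e, s0), s0, paste0(r, "M"),
               substr(edited, s0 + 1L, s0 + r))
        }
      }
    }
  }
  spliced <- if (length(rec) > 0L) {
    df <- do.call(rbind, rec)
    alignment_table(df$read_id, df$chrom, df$pos, df$strand, df$cigar, df$seq)
  } else alignment_table()

  ## polyA degradation reads: m full cycles of every start covering the region
  prec <- list()
  islands <- NULL
  if (nrow(truth$degradation_regions) > 0L) {
    m <- ceiling(config$degradation_depth / r)
    x_max <- floor(r - config$polya_threshold / m)
    for (i in seq_len(nrow(truth$degradation_regions))) {
      dg <- truth$degradation_regions[i, ]
      s <- to_concat(cmap, dg$chrom, dg$start)
      e <- s + (dg$end - dg$start)
      starts <- rep(seq(max(0L, s - r + 1L), e - 1L), m)
      for (k in seq_along(starts)) {
        prec[[length(prec) + 1L]] <- data.frame(
          read_id = sprintf("polyA_%d_%05d", i, k), chrom = cmap$concat_id,
          pos = starts[k], strand = "+", cigar = paste0(r, "M"),
          seq = substr(edited, starts[k] + 1L, starts[k] + r),
          stringsAsFactors = FALSE)
      }
      islands <- rbind(islands, data.frame(
        chrom = cmap$concat_id, start = max(0L, s - x_max), end = e + x_max,
        plateau_depth = m * r, region_chrom = dg$chrom,
        region_start = dg$start, region_end = dg$end, stringsAsFactors = FALSE))
    }
  }
  polya <- if (length(prec) > 0L) {
    df <- do.call(rbind, prec)
    alignment_table(df$read_id, df$chrom, df$pos, df$strand, df$cigar, df$seq)
  } else alignment_table()

  truth$junctions <- jn
  truth$polya_islands <- islands
  list(spliced = spliced, polya = polya, truth = truth, concat_map = cmap)
}

#' Serialise and restore ground truth
#'
#' Lossless JSON round trip of every planted structure.
#'
#' @param truth a `ground_truth` object.
#' @param path JSON file path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$genes <- lapply(x$genes, function(g) {
    g$exons <- as.data.frame(g$exons, stringsAsFactors = FALSE)
    g
  })
  structure(x, class = "ground_truth")
}
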