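test_that("junctions are extracted, aggregated and support-filtered", {
  chrs <- list(circular_chromosome("chr1", strrep("A", 30000)),
               circular_chromosome("chr2", strrep("A", 15000)))
  cm <- build_concat_map(chrs)
  mk <- function(n, pos, cigar, prefix) {
    alignment_table(read_id = sprintf("%s_%02d", prefix, seq_len(n)),
                    chrom = "mt_concat", pos = rep(pos, n), strand = "+",
                    cigar = rep(cigar, n), seq = rep(strrep("A", 100), n))
  }
  aln <- rbind(mk(12, 1000L, "40M500N60M", "a"),    # junction x12
               mk(9, 5000L, "50M300N50M", "b"))     # junction x9
  j10 <- extract_junctions(aln, cm, min_support = 10L)
  expect_equal(nrow(j10), 1L)
  expect_equal(j10$support, 12L)
  expect_equal(j10$donor_pos, 1039L)
  expect_equal(j10$acceptor_pos, 1540L)
  expect_false(j10$cross_chromosomal)

  j1 <- extract_junctions(aln, cm, min_support = 1L)
  expect_equal(nrow(j1), 2L)
  expect_true(nrow(extract_junctions(aln, cm, 13L)) <=
              nrow(extract_junctions(aln, cm, 10L)))   # monotone in support

  # no skip operations -> empty table
  plain <- mk(5, 100L, "100M", "p")
  expect_equal(nrow(extract_junctions(plain, cm, 1L)), 0L)

  # a skip across the concatenation boundary lifts to two chromosomes
  cross <- mk(11, 29950L, "40M60N60M", "x")   # donor 29989, acceptor 30050
  jx <- extract_junctions(cross, cm, min_support = 10L)
  expect_equal(jx$donor_chrom, "chr1")
  expect_equal(jx$donor_pos, 29989L)
  expect_equal(jx$acceptor_chrom, "chr2")
  expect_equal(jx$acceptor_pos, 50L)
  expect_true(jx$cross_chromosomal)

  # a skip running past the reference end is rejected and tallied
  off <- mk(1, 44900L, "40M500N60M", "bad")
  joff <- extract_junctions(off, cm, min_support = 1L)
  expect_equal(nrow(joff), 0L)
  expect_equal(attr(joff, "qc_rejected"), 1L)
})

test_that("simulator truth junctions are recovered exactly at min_support 1", {
  cfg <- h_small_config()
  g <- generate_mitogenome(cfg)
  tr <- simulate_transcript_alignments(g$chromosomes, g$annotations,
                                       g$truth, cfg)
  j <- extract_junctions(tr$spliced, tr$concat_map, min_support = 1L)
  tj <- tr$truth$junctions
  tj <- tj[order(tj$donor_chrom, tj$donor_pos, tj$acceptor_chrom,
                 tj$acceptor_pos), ]
  expect_equal(nrow(j), nrow(tj))
  expect_equal(j$donor_chrom, tj$donor_chrom)
  expect_equal(j$donor_pos, tj$donor_pos)
  expect_equal(j$acceptor_chrom, tj$acceptor_chrom)
  expect_equal(j$acceptor_pos, tj$acceptor_pos)
  expect_equal(j$support, tj$support)
  expect_equal(sum(j$cross_chromosomal),
               sum(tj$donor_chrom != tj$acceptor_chrom))
})

test_that("hotspot clustering is single-linkage on donor and acceptor windows", {
  jn <- function(dp, ap, support = 10L) {
    data.frame(donor_chrom = "chr1", donor_pos = dp, acceptor_chrom = "chr1",
               acceptor_pos = ap, support = support,
               cross_chromosomal = FALSE, stringsAsFactors = FALSE)
  }
  three <- rbind(jn(1000L, 5000L), jn(1200L, 5300L), jn(1400L, 5100L))
  h <- cluster_hotspots(three, window = 1000L)
  expect_equal(nrow(h), 1L)
  expect_equal(h$n_junctions, 3L)
  expect_equal(h$total_support, 30L)
  expect_equal(h$donor_start, 1000L)
  expect_equal(h$donor_end, 1401L)

  far <- rbind(jn(1000L, 5000L), jn(6000L, 5100L))
  expect_equal(nrow(cluster_hotspots(far, 1000L)), 2L)

  # close donors but far acceptors stay apart
  split_acc <- rbind(jn(1000L, 5000L), jn(1100L, 9000L))
  expect_equal(nrow(cluster_hotspots(split_acc, 1000L)), 2L)

  one <- cluster_hotspots(jn(42L, 999L), 1000L)
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_junctions, 1L)

  # membership partitions the junction set
  set.seed(31)
  many <- do.call(rbind, lapply(1:20, function(i)
    jn(sample.int(20000L, 1), sample.int(20000L, 1))))
  hm <- cluster_hotspots(many, 800L)
  expect_equal(sum(hm$n_junctions), 20L)
  expect_setequal(unlist(hm$members), 1:20)
})

test_that("splice summary reproduces the published percentage arithmetic", {
  mk_j <- function(n, in_cds, cross) {
    data.frame(
      donor_chrom = ifelse(seq_len(n) <= cross, "chr1", "chr1"),
      donor_pos = seq_len(n) * 10L,
      acceptor_chrom = ifelse(seq_len(n) <= cross, "chr2", "chr1"),
      acceptor_pos = 100000L + seq_len(n) * 10L,
      support = 10L,
      cross_chromosomal = seq_len(n) <= cross,
      stringsAsFactors = FALSE)
  }
  # CDS annotation covering the donors of the first `in_cds` junctions
  j222 <- mk_j(222L, 110L, 0L)
  ann <- annotation_table(chrom = "chr1", start = 0L, end = 110L * 10L + 1L,
                          strand = "+", feature_type = "CDS", name = "cds1")
  s <- classify_and_summarize(j222, ann)
  expect_equal(s$total, 222L)
  expect_equal(s$n_in_cds, 110L)
  expect_equal(s$pct_in_cds, 49.55)

  j111 <- mk_j(111L, 0L, 23L)
  s2 <- classify_and_summarize(j111, annotation_table())
  expect_equal(s2$n_cross, 23L)
  expect_equal(s2$pct_cross_1dp, 20.7)

  s0 <- classify_and_summarize(j222[0, ], ann)
  expect_true(s0$undefined)
  expect_equal(s0$total, 0L)
})

test_that("guide search finds planted split halves and nothing else", {
  set.seed(32)
  c1 <- h_random_dna(6000, 0.44)
  c2 <- h_random_dna(4000, 0.44)
  junction <- list(donor_chrom = "c1", donor_pos = 2999L,
                   acceptor_chrom = "c2", acceptor_pos = 500L)
  half5 <- substr(c1, 2973, 3000)          # last 28 nt through the donor
  half3 <- substr(c2, 501, 526)            # first 26 nt from the acceptor
  substr(c1, 4001, 4028) <- half5                    # forward-strand plant
  substr(c1, 4101, 4126) <- h_revcomp(half3)         # reverse-strand plant
  chroms <- list(circular_chromosome("c1", c1), circular_chromosome("c2", c2))
  gc <- guide_rna_search(junction, chroms, window = 54L, split = 28L,
                         max_mismatch = 1L)
  expect_equal(nrow(gc), 1L)
  expect_equal(gc$h5_chrom, "c1")
  expect_equal(gc$h5_from, 4001L)
  expect_equal(gc$h5_to, 4028L)
  expect_equal(gc$h5_strand, "+")
  expect_equal(gc$h5_mismatches, 0L)
  expect_equal(gc$h3_strand, "-")
  expect_gt(gc$h3_from, gc$h3_to)          # minus-strand coordinates decrease

  # unplanted genome: no candidate pairs
  none <- guide_rna_search(junction,
                           list(circular_chromosome("c1", h_random_dna(6000, 0.44)),
                                circular_chromosome("c2", c2)))
  expect_equal(nrow(none), 0L)

  # insufficient exon context errors out
  early <- list(donor_chrom = "c1", donor_pos = 10L,
                acceptor_chrom = "c2", acceptor_pos = 500L)
  expect_error(guide_rna_search(early, chroms), "context")
})
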