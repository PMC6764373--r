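test_that("planted shared blocks are found at exact coordinates", {
  set.seed(30)
  A <- h_random_dna(10000, 0.44)
  B <- h_random_dna(6000, 0.44)
  blk <- h_random_dna(188, 0.44)
  # force the flank bases on A and B to differ from each other, so the
  # maximal shared match is exactly the planted block
  plant <- function(seq, at, piece, edge) {
    substr(seq, at - 1L, at - 1L) <- edge
    substr(seq, at + nchar(piece), at + nchar(piece)) <- edge
    substr(seq, at, at + nchar(piece) - 1L) <- piece
    seq
  }
  A <- plant(A, 2001, blk, "A")
  B <- plant(B, 4001, blk, "C")
  sr <- find_shared_regions(A, B, min_len = 30, min_identity = 95)
  expect_equal(nrow(sr), 1L)
  expect_equal(sr$start_a, 2000L)
  expect_equal(sr$start_b, 4000L)
  expect_equal(sr$length, 188L)
  expect_equal(sr$identity, 100)
  expect_equal(sr$orientation, "same")

  # two mismatches -> identity 186/188
  blk2 <- blk
  substr(blk2, 50, 50) <- setdiff(c("A", "C", "G", "T"), substr(blk, 50, 50))[1]
  substr(blk2, 120, 120) <- setdiff(c("A", "C", "G", "T"),
                                    substr(blk, 120, 120))[1]
  B2 <- plant(h_random_dna(6000, 0.44), 1001, blk2, "C")
  sr2 <- find_shared_regions(A, B2, min_len = 30, min_identity = 95)
  expect_equal(nrow(sr2), 1L)
  expect_equal(sr2$identity, 100 * 186 / 188, tolerance = 1e-6)

  # inverted copy round-trips through reverse complement
  B3 <- plant(h_random_dna(6000, 0.44), 2501, h_revcomp(blk), "C")
  sr3 <- find_shared_regions(A, B3)
  expect_equal(sr3$orientation, "inverted")
  got <- substr(B3, sr3$start_b + 1L, sr3$start_b + sr3$length)
  expect_identical(h_revcomp(got),
                   substr(A, sr3$start_a + 1L, sr3$start_a + sr3$length))

  # unrelated sequences share nothing
  expect_equal(nrow(find_shared_regions(h_random_dna(10000, 0.44),
                                        h_random_dna(10000, 0.44))), 0L)
})

test_that("join paths have the right arithmetic and content", {
  cfg <- h_small_config()
  g <- generate_mitogenome(cfg)
  sr <- find_shared_regions(g$chromosomes[[1]], g$chromosomes[[2]],
                            min_identity = 90)
  expect_gte(nrow(sr), 1L)
  r <- sr[1, ]
  p <- enumerate_join_paths(r, g$chromosomes, flank = 400L)
  expect_named(p, c("ref_a", "ref_b", "chimera_ab", "chimera_ba"))
  expect_true(all(nchar(p) == 2L * 400L + r$length))

  # the reference path occurs in its source circle; chimeras occur nowhere
  doubled_a <- paste0(g$chromosomes[[1]]$sequence, g$chromosomes[[1]]$sequence)
  expect_true(grepl(p[["ref_a"]], doubled_a, fixed = TRUE))
  expect_false(grepl(p[["chimera_ab"]], doubled_a, fixed = TRUE))

  # flank wrapping the origin still yields full-length paths
  r0 <- r
  r0$start_a <- 10L
  r0$length <- min(r0$length, 50L)
  p0 <- enumerate_join_paths(r0, g$chromosomes, flank = 400L)
  expect_true(all(nchar(p0) == 2L * 400L + r0$length))

  bad <- r; bad$start_a <- -5L
  expect_error(enumerate_join_paths(bad, g$chromosomes), "invalid")
})

test_that("spanning-read support separates reference from chimeric genomes", {
  cfg <- h_small_config()
  g <- generate_mitogenome(cfg)
  sr <- find_shared_regions(g$chromosomes[[1]], g$chromosomes[[2]],
                            min_identity = 90)
  rd <- simulate_genomic_reads(g$chromosomes, cfg, "long")
  r <- sr[1, ]
  paths <- enumerate_join_paths(r, g$chromosomes)
  sup <- count_spanning_reads(rd$reads, paths, r$length)
  expect_equal(unname(sup["chimera_ab"] + sup["chimera_ba"]), 0L)
  expect_gt(sup[["ref_a"]], 0L)

  # a read equal to the shared block alone supports nothing
  blk_read <- substr(g$chromosomes[[1]]$sequence, r$start_a + 1L,
                     r$start_a + r$length)
  sup0 <- count_spanning_reads(c(blk = blk_read), paths, r$length)
  expect_true(all(sup0 == 0L))

  # chimeric genome: support appears on a chimeric path and equals the
  # brute-force count of truth reads overlapping the join with both anchors
  fuse <- g$truth$shared_regions[g$truth$shared_regions$orientation == "same", ][1, ]
  rdm <- simulate_genomic_reads(g$chromosomes, cfg, "long",
                                master_circle = TRUE, fuse_region = fuse)
  fr <- sr[abs(sr$start_a - fuse$start_a) <= 5 &
           sr$orientation == "same", ][1, ]
  pm <- enumerate_join_paths(fr, g$chromosomes)
  supm <- count_spanning_reads(rdm$reads, pm, fr$length)
  expect_gt(supm[["chimera_ab"]] + supm[["chimera_ba"]], 0L)

  # oracle: reads whose truth placement covers the ab-join interval with
  # 20 matched bases on both sides (the fused circle starts as chromosome A
  # and switches to B right after the block); modular arithmetic handles
  # reads wrapping the fused circle's origin
  j0 <- fr$start_a - 20L
  span <- fr$length + 40L
  Lf <- sum(vapply(g$chromosomes, `[[`, 0L, "length"))
  pl <- rdm$placements
  offset <- (j0 - pl$start) %% Lf
  covers <- offset + span <= pl$len
  expect_equal(unname(supm[["chimera_ab"]]), sum(covers))
})

test_that("join-candidate bookkeeping is conserved and drives the verdict", {
  regions <- data.frame(
    chrom_a = "chr1", start_a = seq_len(10L) * 100L, chrom_b = "chr2",
    start_b = seq_len(10L) * 50L,
    length = c(296L, 177L, 188L, rep(60L, 7L)),
    identity = 100, orientation = "same", stringsAsFactors = FALSE)
  sup <- data.frame(chimera_ab = c(rep(0L, 9L), 2L), chimera_ba = 0L)
  res <- classify_join_candidates(regions, read_length = 101L, sup)
  expect_equal(unname(res$counts["excluded"] + res$counts["candidate"] +
                      res$counts["supported"]),
               unname(res$counts["total"]))
  expect_equal(unname(res$counts["candidate"]), 3L)
  expect_equal(unname(res$counts["supported"]), 1L)
  expect_equal(res$verdict, "master circle present")

  res0 <- classify_join_candidates(regions, read_length = 101L)
  expect_equal(unname(res0$counts["supported"]), 0L)
  expect_equal(res0$verdict, "no master circle")
  expect_equal(res0$regions$status[4], "excluded")
})

test_that("alternative conformations are counted per arrangement", {
  cfg <- h_small_config()
  g <- generate_mitogenome(cfg)
  chrom <- g$chromosomes[[1]]$sequence
  ra <- g$truth$repeats[g$truth$repeats$type == "inverted", ]

  alt <- paste0(substr(chrom, 1, ra$end1),
                h_revcomp(substr(chrom, ra$end1 + 1, ra$start2)),
                substr(chrom, ra$start2 + 1, nchar(chrom)))
  mk <- function(seq, starts) {
    setNames(vapply(starts, function(s) circ_substr(seq, s, 1500L), ""),
             paste0("lr", starts))
  }
  ref_reads <- mk(chrom, ra$start1 - c(700, 650, 600, 550, 500))
  inv_reads <- mk(alt, ra$start1 - c(700, 640, 580))
  rep1 <- detect_alternative_conformations(c(ref_reads, inv_reads), ra,
                                           g$chromosomes)
  expect_equal(unname(rep1$counts["reference"]), 5L)
  expect_equal(unname(rep1$counts["inverted"]), 3L)

  # direct repeat: reads across a subcircle junction vote subcircles
  rd <- g$truth$repeats[g$truth$repeats$type == "direct", ]
  subA <- paste0(circ_substr(chrom, rd$start2 - 1000L, 1000L),
                 substr(chrom, rd$start1 + 1L, rd$end1),
                 circ_substr(chrom, rd$end1, 1000L))
  jr <- setNames(vapply(c(750L, 800L, 850L), function(s)
    substr(subA, s, s + 1499L), ""), c("j1", "j2", "j3"))
  rep2 <- detect_alternative_conformations(jr, rd, g$chromosomes)
  expect_equal(unname(rep2$counts["subcircles"]), 3L)
  expect_equal(unname(rep2$counts["single_circle"]), 0L)

  # no informative reads -> indeterminate
  rep3 <- detect_alternative_conformations(character(0), ra, g$chromosomes)
  expect_equal(rep3$verdict, "indeterminate")

  bad <- ra; bad$end1 <- bad$start2 + 10L
  expect_error(detect_alternative_conformations(ref_reads, bad,
                                                g$chromosomes), "overlap")
})
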