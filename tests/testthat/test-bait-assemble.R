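test_that("baiting agrees with the brute-force k-mer intersection oracle", {
  set.seed(10)
  for (i in 1:15) {
    k <- sample(c(15L, 21L, 32L), 1)
    n <- sample(c(1L, 5L, 20L), 1)
    bait <- h_random_dna(sample(100:200, 1), 0.45)
    reads <- setNames(c(
      h_random_dna(120, 0.45),
      paste0(h_random_dna(30), substr(bait, 1, 60), h_random_dna(30)),
      h_revcomp(paste0(h_random_dna(10), substr(bait, 20, 130 %% nchar(bait) + 20)))
    ), c("noise", "partial", "rc_partial"))
    bs <- build_bait_set(bait, k = k, min_hits = n)
    got <- names(bait_reads(reads, bs))
    expected <- names(reads)[vapply(reads, h_brute_baited, TRUE,
                                    baits = bait, k = k, n = n)]
    expect_identical(got, expected)
  }
})

test_that("an 81-nt bait block yields exactly 50 shared 32-mers", {
  set.seed(11)
  bait <- h_random_dna(81, 0.5)                 # 81 - 32 + 1 = 50 k-mers
  read <- paste0(h_random_dna(60, 0.5), bait, h_random_dna(60, 0.5))
  expect_length(bait_reads(c(r = read), build_bait_set(bait, 32, 50)), 1L)
  expect_length(bait_reads(c(r = read), build_bait_set(bait, 32, 51)), 0L)
  # disjoint alphabets share nothing
  expect_length(bait_reads(c(r = strrep("A", 100)),
                           build_bait_set(strrep("C", 100), 32, 1)), 0L)
})

test_that("greedy assembly merges by suffix-prefix overlap deterministically", {
  set.seed(12)
  one <- greedy_assemble(c(solo = h_random_dna(500)), overlap_params(100, 75))
  expect_length(one, 1L)
  expect_identical(one[[1]]$member_read_ids, "solo")

  S <- h_random_dna(1800, 0.45)
  a <- substr(S, 1, 1500); b <- substr(S, 301, 1800)
  merged <- greedy_assemble(c(a = a, b = b), overlap_params(1000, 75))
  expect_length(merged, 1L)
  expect_true(merged[[1]]$sequence %in% c(S, h_revcomp(S)))
  expect_setequal(merged[[1]]$member_read_ids, c("a", "b"))

  split2 <- greedy_assemble(c(a = a, b = b), overlap_params(1300, 75))
  expect_length(split2, 2L)

  # reverse-complement orientation still merges
  merged_rc <- greedy_assemble(c(a = a, b = h_revcomp(b)),
                               overlap_params(1000, 75))
  expect_length(merged_rc, 1L)

  # determinism and read-membership conservation on a larger instance
  set.seed(13)
  genome <- h_random_dna(4000, 0.45)
  starts <- sort(sample(0:3400, 24))
  reads <- setNames(substring(genome, starts + 1, starts + 600),
                    sprintf("r%02d", seq_along(starts)))
  c1 <- greedy_assemble(reads, overlap_params(150, 75))
  c2 <- greedy_assemble(reads, overlap_params(150, 75))
  expect_identical(lapply(c1, `[[`, "sequence"), lapply(c2, `[[`, "sequence"))
  expect_setequal(unlist(lapply(c1, `[[`, "member_read_ids")), names(reads))
})

test_that("circularity test detects and trims end duplication", {
  set.seed(14)
  C <- h_random_dna(5000, 0.45)
  res <- test_circularity(paste0(C, substr(C, 1, 500)))
  expect_true(res$circular)
  expect_equal(nchar(res$sequence), 5000L)
  expect_identical(res$sequence, canonical_circular(C))

  expect_false(test_circularity(C)$circular)
  expect_warning(short <- test_circularity(h_random_dna(150), 100), "short")
  expect_false(short$circular)

  # idempotence: an already-trimmed circular contig stays as-is
  ct <- list(id = "c", sequence = res$sequence, circular = TRUE)
  again <- test_circularity(ct)
  expect_true(again$circular)
  expect_identical(again$sequence, res$sequence)
  expect_equal(again$trimmed, 0L)
})

test_that("homology filter retains hits and excludes covered contigs", {
  set.seed(15)
  ref <- h_random_dna(8000, 0.44)
  exact <- substr(ref, 3001, 5000)
  unrelated <- h_random_dna(1000, 0.44)
  hp <- homology_params()
  part <- homology_filter(c(hit = exact, miss = unrelated), ref, hp,
                          "retain_hits")
  expect_equal(vapply(part$kept, `[[`, "", "id"), "hit")
  expect_equal(vapply(part$removed, `[[`, "", "id"), "miss")

  # 95% covered by the reference -> excluded at the 0.9 threshold
  mostly <- paste0(substr(ref, 1001, 2900), h_random_dna(100, 0.44))
  excl <- homology_filter(c(m = mostly), ref, hp, "exclude_covered")
  expect_length(excl$kept, 0L)
  # 50% covered -> kept
  half <- paste0(substr(ref, 1001, 2000), h_random_dna(1000, 0.44))
  keep <- homology_filter(c(h = half), ref, hp, "exclude_covered")
  expect_length(keep$kept, 1L)
})

test_that("gap closing patches N-runs with spanning reads and reports the rest", {
  set.seed(16)
  truth <- h_random_dna(5000, 0.44)
  reads <- setNames(substring(paste0(truth, truth),
                              seq(1, 4801, by = 120), seq(480, 5280, by = 120)),
                    sprintf("r%02d", 1:41))
  gapped <- paste0(substr(truth, 1, 2000), strrep("N", 100),
                   substr(truth, 2101, 5000))
  res <- close_gaps(gapped, reads, flank = 1000L)
  expect_identical(res$sequence, truth)
  expect_equal(nrow(res$unresolved), 0L)

  untouched <- close_gaps(truth, reads)
  expect_identical(untouched$sequence, truth)

  # a gap nothing spans stays open and is listed
  lonely <- paste0(h_random_dna(1500, 0.44), strrep("N", 50),
                   h_random_dna(1500, 0.44))
  res2 <- close_gaps(lonely, reads, flank = 500L)
  expect_identical(res2$sequence, lonely)
  expect_equal(nrow(res2$unresolved), 1L)
})

test_that("majority-vote polishing corrects planted errors above thresholds", {
  set.seed(17)
  truth <- h_random_dna(4000, 0.44)
  asm <- truth
  pos <- seq(200, 2000, by = 200)
  for (p in pos) {
    substr(asm, p, p) <- setdiff(c("A", "C", "G", "T"), substr(truth, p, p))[1]
  }
  reads <- setNames(vapply(0:119, function(i)
    circ_substr(truth, round(i * 4000 / 120), 400), ""),
    sprintf("r%03d", 0:119))
  aln <- map_reads(reads, list(circular_chromosome("asm", asm)),
                   min_identity = 0.9)
  pol <- polish_consensus(asm, aln, min_depth = 5L, majority_fraction = 0.7)
  expect_identical(pol$sequence, truth)
  expect_equal(sort(pol$changes$pos), pos - 1L)

  nothing <- polish_consensus(asm, alignment_table())
  expect_identical(nothing$sequence, asm)

  # depth below threshold: discordant position left unchanged
  few <- aln[aln$pos < 50, , drop = FALSE][1:4, ]
  pol2 <- polish_consensus(asm, few, min_depth = 5L)
  expect_identical(pol2$sequence, asm)
})

test_that("the iterative loop reconstructs a small genome and excludes plastid", {
  cfg <- h_small_config(seed = 19)
  g <- generate_mitogenome(cfg)
  rd <- simulate_genomic_reads(g$chromosomes, cfg, "long")
  baits <- c(substr(g$chromosomes[[1]]$sequence, 1000, 2500),
             substr(g$chromosomes[[2]]$sequence, 1000, 2500))

  # spike unrelated plastid reads; none may survive into the contigs
  set.seed(20)
  plastid <- h_random_dna(8000, 0.384)
  pl_reads <- setNames(substring(paste0(plastid, plastid),
                                 seq(1, 7001, by = 400),
                                 seq(2000, 9000, by = 400)),
                       sprintf("pl%02d", 1:18))
  pool <- c(rd$reads, pl_reads)
  res <- iterative_bait_assemble(pool, baits, plastid_refs = plastid)
  expect_length(res$circular, 2L)
  truthset <- sort(vapply(g$chromosomes, function(ch)
    canonical_circular(ch$sequence), ""))
  expect_identical(sort(vapply(res$circular, `[[`, "", "sequence")), truthset)
  # no surviving contig carries a long plastid-aligned segment
  for (ct in c(res$circular, res$linear)) {
    hits <- homology_filter(setNames(ct$sequence, ct$id), plastid,
                            homology_params(min_hit_len = 500L,
                                            min_hit_identity = 90),
                            "retain_hits")
    expect_length(hits$kept, 0L)
  }

  expect_warning(empty <- iterative_bait_assemble(character(0), baits),
                 "empty")
  expect_length(empty$circular, 0L)
})
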