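test_that("generator is deterministic and every truth structure is re-findable", {
  cfg <- h_small_config()
  g1 <- generate_mitogenome(cfg)
  g2 <- generate_mitogenome(cfg)
  expect_identical(lapply(g1$chromosomes, `[[`, "sequence"),
                   lapply(g2$chromosomes, `[[`, "sequence"))
  expect_identical(g1$truth$shared_regions, g2$truth$shared_regions)

  seqs <- setNames(vapply(g1$chromosomes, `[[`, "", "sequence"),
                   vapply(g1$chromosomes, `[[`, "", "id"))
  # shared regions: source substring occurs at its recorded coordinate
  # (brute substring scan) and the copy matches at the recorded identity
  sr <- g1$truth$shared_regions
  for (i in seq_len(nrow(sr))) {
    src <- substr(seqs[[sr$chrom_a[i]]], sr$start_a[i] + 1L,
                  sr$start_a[i] + sr$length[i])
    hits <- gregexpr(src, seqs[[sr$chrom_a[i]]], fixed = TRUE)[[1]]
    expect_true((sr$start_a[i] + 1L) %in% as.integer(hits))
    cpy <- substr(seqs[[sr$chrom_b[i]]], sr$start_b[i] + 1L,
                  sr$start_b[i] + sr$length[i])
    if (sr$orientation[i] == "inverted") cpy <- h_revcomp(cpy)
    obs_id <- 100 * mean(charToRaw(src) == charToRaw(cpy))
    expect_equal(obs_id, sr$identity[i], tolerance = 1e-9)
  }
  # long repeats: copy 2 equals copy 1 (reverse complement for inverted)
  rp <- g1$truth$repeats
  for (i in seq_len(nrow(rp))) {
    u1 <- substr(seqs[[rp$chrom[i]]], rp$start1[i] + 1L, rp$end1[i])
    u2 <- substr(seqs[[rp$chrom[i]]], rp$start2[i] + 1L, rp$end2[i])
    if (rp$type[i] == "inverted") u2 <- h_revcomp(u2)
    expect_identical(u1, u2)
  }
  # editing sites address a genomic C
  ed <- g1$truth$editing_sites
  for (i in seq_len(nrow(ed))) {
    expect_identical(substr(seqs[[ed$chrom[i]]], ed$pos[i] + 1L, ed$pos[i] + 1L),
                     "C")
  }
})

test_that("plastid segment hits its GC target within tolerance", {
  g <- generate_mitogenome(h_small_config())
  pl <- g$truth$plastid_segments
  seg <- substr(g$chromosomes[[1]]$sequence, pl$start + 1L, pl$end)
  expect_gte(gc_fraction(seg), 0.384 - 0.01)
  expect_lte(gc_fraction(seg), 0.384 + 0.01)
})

test_that("infeasible packing errors name the overfull chromosome", {
  cfg <- simulation_config(seed = 1, chr_lengths = c(3500L, 3200L),
                           direct_repeat_len = 1500L)
  expect_error(generate_mitogenome(cfg), "chr")
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(chr_lengths = c(2000L, 1000L),
                                 direct_repeat_len = 1500L), "direct repeat")
  expect_error(simulation_config(shared_len_range = c(30L, 500L)), "360")
  expect_error(simulation_config(mito_gc_target = 1.2), "GC")
  expect_error(simulation_config(coverage = -1), "coverage")
  expect_error(simulation_config(degradation_depth = 400L), "exceed")
})

test_that("error-free genomic reads are exact circular substrings", {
  cfg <- h_small_config()
  g <- generate_mitogenome(cfg)
  rd <- simulate_genomic_reads(g$chromosomes, cfg, "long")
  doubled <- vapply(g$chromosomes, function(ch)
    paste0(ch$sequence, ch$sequence), "")
  names(doubled) <- vapply(g$chromosomes, `[[`, "", "id")
  found <- vapply(seq_along(rd$reads), function(i) {
    ch <- rd$placements$chrom[i]
    grepl(rd$reads[i], doubled[[ch]], fixed = TRUE) ||
      grepl(h_revcomp(rd$reads[i]), doubled[[ch]], fixed = TRUE)
  }, TRUE)
  expect_true(all(found))
  # placements match the reads
  for (i in seq_len(min(25L, nrow(rd$placements)))) {
    pl <- rd$placements[i, ]
    piece <- substr(doubled[[pl$chrom]], pl$start + 1L, pl$start + pl$len)
    rdseq <- if (pl$strand == "-") h_revcomp(rd$reads[[i]]) else rd$reads[[i]]
    expect_identical(piece, rdseq)
  }
})

test_that("read simulation honors coverage and insert geometry", {
  cfg <- h_small_config()
  g <- generate_mitogenome(cfg)
  empty <- simulate_genomic_reads(
    g$chromosomes, simulation_config(seed = 7, coverage = 0), "long")
  expect_length(empty$reads, 0L)

  cfg20 <- simulation_config(seed = 11, chr_lengths = c(12000L, 6000L),
                             direct_repeat_len = 600L,
                             inverted_repeat_len = 250L,
                             n_shared_regions = 5L, n_genes = 5L,
                             coverage = 20)
  g20 <- generate_mitogenome(cfg20)
  rd <- simulate_genomic_reads(g20$chromosomes, cfg20, "long")
  mean_depth <- sum(nchar(rd$reads)) / sum(vapply(g20$chromosomes, `[[`,
                                                  0L, "length"))
  expect_lt(abs(mean_depth - 20) / 20, 0.1)

  rp <- simulate_genomic_reads(g20$chromosomes, cfg20, "paired")
  ins <- rp$placements$len
  se <- sd(ins) / sqrt(length(ins))
  expect_lt(abs(mean(ins) - 400), 3 * se + 1)   # +1 guards the clamp bias
})

test_that("transcript SAM has no skip operations without genes", {
  cfg <- simulation_config(seed = 5, chr_lengths = c(8000L, 5000L),
                           direct_repeat_len = 600L,
                           inverted_repeat_len = 250L,
                           n_shared_regions = 3L, n_genes = 0L,
                           editing_sites = 0L)
  g <- generate_mitogenome(cfg)
  tr <- simulate_transcript_alignments(g$chromosomes, g$annotations,
                                       g$truth, cfg)
  expect_equal(nrow(tr$spliced), 0L)
})

test_that("ground truth serialises losslessly", {
  g <- generate_mitogenome(h_small_config())
  path <- tempfile(fileext = ".json")
  write_truth(g$truth, path)
  back <- read_truth(path)
  expect_equal(back$shared_regions$start_a, g$truth$shared_regions$start_a)
  expect_equal(back$editing_sites$pos, g$truth$editing_sites$pos)
  expect_equal(back$genes[["gene01"]]$exons$start,
               g$truth$genes[["gene01"]]$exons$start)
  expect_equal(back$degradation_regions$end, g$truth$degradation_regions$end)
})
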