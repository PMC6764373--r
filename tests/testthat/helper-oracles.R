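# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

h_random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

h_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(x, ""), function(ch)
    paste(rev(ch), collapse = ""), ""))
}

# Brute-force baiting oracle: shared distinct canonical k-mers >= n
h_brute_baited <- function(read, baits, k, n) {
  canon <- function(kms) {
    rc <- h_revcomp(kms)
    ifelse(kms <= rc, kms, rc)
  }
  all_kms <- function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1), k:L))
  }
  bait_set <- unique(canon(unlist(lapply(baits, all_kms))))
  length(intersect(unique(canon(all_kms(read))), bait_set)) >= n
}

# Quadratic affine-gap global alignment score (Gotoh), same conventions as
# Biostrings: gap of length L costs open + ext * L.
h_nw_affine_score <- function(a, b, match = 1, mismatch = -1,
                              open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  V <- matrix(NEG, n + 1, m + 1); E <- V; F <- V
  V[1, 1] <- 0
  for (j in 2:(m + 1)) { E[1, j] <- -open - ext * (j - 1); V[1, j] <- E[1, j] }
  for (i in 2:(n + 1)) { F[i, 1] <- -open - ext * (i - 1); V[i, 1] <- F[i, 1] }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      E[i, j] <- max(E[i, j - 1] - ext, V[i, j - 1] - open - ext)
      F[i, j] <- max(F[i - 1, j] - ext, V[i - 1, j] - open - ext)
      V[i, j] <- max(V[i - 1, j - 1] + s, E[i, j], F[i, j])
    }
  }
  V[n + 1, m + 1]
}

# Score a diff_set under the same scheme, reconstructing column counts.
h_diff_score <- function(d, len_a, len_b, match = 1, mismatch = -1,
                         open = 10, ext = 0.5) {
  n_sub <- nrow(d$substitutions)
  ins_b <- sum(d$insertions$length)
  del_b <- sum(d$deletions$length)
  n_match <- len_a - n_sub - del_b
  n_match * match + n_sub * mismatch -
    nrow(d$insertions) * open - ins_b * ext -
    nrow(d$deletions) * open - del_b * ext
}

# Brute-force pileup from alignment records (M/D consume reference).
h_brute_pileup <- function(alignments, L) {
  depth <- integer(L)
  for (i in seq_len(nrow(alignments))) {
    cg <- alignments$cigar[i]
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MIDNS]", cg))[[1]]
    p <- alignments$pos[i]
    for (k in seq_along(ops)) {
      if (ops[k] %in% c("M", "D")) {
        depth[(p + 1):(p + lens[k])] <- depth[(p + 1):(p + lens[k])] + 1L
        p <- p + lens[k]
      } else if (ops[k] == "N") p <- p + lens[k]
    }
  }
  depth
}

# Exhaustive best ungapped placement of a read on a circular reference.
h_brute_best_map <- function(read, ref) {
  L <- nchar(ref)
  doubled <- paste0(ref, ref)
  best <- list(identity = -1)
  for (strand in c("+", "-")) {
    q <- if (strand == "+") read else h_revcomp(read)
    for (s in 0:(L - 1)) {
      piece <- substr(doubled, s + 1, s + nchar(q))
      idy <- mean(charToRaw(piece) == charToRaw(q))
      if (idy > best$identity) best <- list(pos = s, strand = strand,
                                            identity = idy)
    }
  }
  best
}

# Small shared config used by several slow-ish tests
h_small_config <- function(seed = 7L) {
  simulation_config(seed = seed, chr_lengths = c(12000L, 6000L),
                    direct_repeat_len = 600L, inverted_repeat_len = 250L,
                    n_shared_regions = 5L, n_genes = 4L, coverage = 10)
}
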