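#' Build a k-mer bait set
#'
#' K-mers are stored in canonical form (lexicographic minimum of the k-mer
#' and its reverse complement) so baiting is strand-agnostic.
#'
#' @param bait_sequences character vector of bait sequences.
#' @param k k-mer size; must not exceed the shortest bait.
#' @param min_hits number of distinct shared canonical k-mers required to
#'   bait a read (the baiting `n` parameter).
#' @return object of class `bait_set`.
#' @export
build_bait_set <- function(bait_sequences, k = 32L, min_hits = 50L) {
  stopifnot(length(bait_sequences) > 0L, k >= 1L)
  if (k > min(nchar(bait_sequences))) {
    stop("k exceeds the shortest bait sequence")
  }
  kms <- unique(unlist(lapply(bait_sequences, kmers_of, k = k)))
  structure(list(k = as.integer(k), kmers = unique(canonical_kmers(kms)),
                 min_hits = as.integer(min_hits)),
            class = "bait_set")
}

#' @export
print.bait_set <- function(x, ...) {
  cat(sprintf("<bait_set> k=%d, %d canonical k-mers, n=%d\n",
              x$k, length(x$kmers), x$min_hits))
  invisible(x)
}

#' Bait reads by shared canonical k-mers
#'
#' A read is baited iff it shares at least `baits$min_hits` distinct
#' canonical k-mers with the bait set. Input order is preserved. Reads
#' shorter than `k` are never baited.
#'
#' @param reads named character vector.
#' @param baits a [build_bait_set()] result.
#' @return the baited subset of `reads`, in input order.
#' @export
bait_reads <- function(reads, baits) {
  if (length(reads) == 0L) return(reads)
  keep <- vapply(reads, function(rd) {
    if (nchar(rd) < baits$k) return(FALSE)
    km <- unique(canonical_kmers(unique(kmers_of(rd, baits$k))))
    sum(km %in% baits$kmers) >= baits$min_hits
  }, TRUE)
  reads[keep]
}

## ---- Greedy overlap assembly ----------------------------------------------

# Best suffix(A)->prefix(B) overlap >= min_overlap at >= min_identity.
# Candidate overlap lengths are anchored by locating k-mers from B's prefix
# inside A, so detection is O(|A|) per anchor rather than quadratic.
.best_overlap <- function(a, b, min_overlap, min_identity, anchor_k = 24L) {
  na <- nchar(a); nb <- nchar(b)
  if (min(na, nb) < min_overlap) return(NULL)
  best <- NULL
  # anchors at a few offsets into B so a sequencing error cannot hide the join
  offs <- unique(pmin(c(0L, 11L, 23L), nb - anchor_k))
  offs <- offs[offs >= 0L]
  seen <- integer(0)
  for (off in offs) {
    seed <- substr(b, off + 1L, off + anchor_k)
    hits <- gregexpr(seed, a, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    for (h in hits) {
      L <- na - (h - 1L - off)             # implied overlap length
      if (L %in% seen) next
      seen <- c(seen, L)
      if (L < min_overlap || L > min(na, nb)) next
      idy <- seq_identity(substr(a, na - L + 1L, na), substr(b, 1L, L))
      if (idy >= min_identity && (is.null(best) || L * idy > best$score)) {
        best <- list(len = L, identity = idy, score = L * idy)
      }
    }
  }
  best
}

# Is b contained in a (allowing mismatches up to identity)? Anchored like
# .best_overlap; returns TRUE/FALSE.
.is_contained <- function(a, b, min_identity, anchor_k = 24L) {
  na <- nchar(a); nb <- nchar(b)
  if (nb > na || nb < anchor_k) return(FALSE)
  for (off in unique(pmin(c(0L, 11L), nb - anchor_k))) {
    seed <- substr(b, off + 1L, off + anchor_k)
    hits <- gregexpr(seed, a, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    for (h in hits) {
      s <- h - 1L - off
      if (s < 0L || s + nb > na) next
      if (seq_identity(substr(a, s + 1L, s + nb), b) >= min_identity) return(TRUE)
    }
  }
  FALSE
}

#' Overlap-assembly parameters
#'
#' @param min_overlap minimum suffix-prefix overlap (bases).
#' @param min_identity_pct minimum percent identity over the overlap.
#' @param max_rounds maximum bait/assemble rounds for the iterative loop.
#' @return list of class `overlap_params`.
#' @export
overlap_params <- function(min_overlap = 1000L, min_identity_pct = 75,
                           max_rounds = 4L) {
  stopifnot(min_overlap >= 1L, min_identity_pct > 0, min_identity_pct <= 100)
  structure(list(min_overlap = as.integer(min_overlap),
                 min_identity_pct = min_identity_pct,
                 max_rounds = as.integer(max_rounds)),
            class = "overlap_params")
}

#' Greedy overlap-layout assembly
#'
#' Repeatedly merges the contig pair with the highest-scoring suffix-prefix
#' overlap (score = overlap length times identity) satisfying `min_overlap`
#' and `min_identity_pct`, in either orientation, until no merge is possible.
#' Contigs contained within another contig are absorbed into it. Candidate
#' overlaps are found by indexing short anchor k-mers from every contig
#' prefix and scanning each contig's k-mer list against the index, so the
#' search is linear in total sequence rather than quadratic. Every input
#' read is represented in exactly one output contig; ties break to the
#' lexicographically smallest contig-id pair, so the result is deterministic
#' under a fixed input order.
#'
#' @param reads named character vector of reads.
#' @param params an [overlap_params()].
#' @return list of contigs, each a list with `id`, `sequence`, `circular`
#'   (always `FALSE` here; see [test_circularity()]) and `member_read_ids`,
#'   sorted by decreasing length.
#' @export
greedy_assemble <- function(reads, params = overlap_params()) {
  stopifnot(length(reads) > 0L)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  min_id <- params$min_identity_pct / 100
  anchor_k <- 24L
  anchor_offs <- c(0L, 11L, 23L)

  seqs <- setNames(as.list(unname(reads)), names(reads))
  rcs <- lapply(seqs, revcomp)                       # cached reverse complements
  members <- setNames(as.list(names(reads)), names(reads))
  kms <- lapply(seqs, kmers_of, k = anchor_k)        # fwd k-mers per contig

  # prefix anchors of both orientations of each contig
  anchor_rows <- function(id) {
    s <- seqs[[id]]
    n <- nchar(s)
    offs <- unique(pmin(anchor_offs, max(0L, n - anchor_k)))
    offs <- offs[offs >= 0L & offs + anchor_k <= n]
    if (length(offs) == 0L) return(NULL)
    rbind(
      data.frame(bid = id, ori = "F", off = offs,
                 kmer = substring(s, offs + 1L, offs + anchor_k),
                 stringsAsFactors = FALSE),
      data.frame(bid = id, ori = "R", off = offs,
                 kmer = substring(rcs[[id]], offs + 1L, offs + anchor_k),
                 stringsAsFactors = FALSE)
    )
  }
  anchors <- do.call(rbind, lapply(names(seqs), anchor_rows))

  # candidates where `aid` is the left (suffix) contig: returns edges and
  # containments of other contigs inside `aid`
  scan_left <- function(aid, anchors_sub) {
    ka <- kms[[aid]]
    if (length(ka) == 0L || is.null(anchors_sub) || nrow(anchors_sub) == 0L) {
      return(NULL)
    }
    hit <- which(ka %in% anchors_sub$kmer)
    if (length(hit) == 0L) return(NULL)
    out <- list()
    na <- nchar(seqs[[aid]])
    for (p0 in hit) {
      rows <- which(anchors_sub$kmer == ka[p0])
      for (rr in rows) {
        bid <- anchors_sub$bid[rr]
        if (bid == aid) next
        bseq <- if (anchors_sub$ori[rr] == "F") seqs[[bid]] else rcs[[bid]]
        nb <- nchar(bseq)
        s <- (p0 - 1L) - anchors_sub$off[rr]       # 0-based start of B in A
        if (s < 0L) next
        if (s + nb <= na) {                        # containment candidate
          if (seq_identity(substr(seqs[[aid]], s + 1L, s + nb), bseq) >= min_id) {
            out[[length(out) + 1L]] <- data.frame(
              x = aid, y = bid, ori = anchors_sub$ori[rr], len = nb,
              score = Inf, contain = TRUE, stringsAsFactors = FALSE)
          }
        } else {
          L <- na - s
          if (L < params$min_overlap || L > min(na, nb)) next
          idy <- seq_identity(substr(seqs[[aid]], na - L + 1L, na),
                              substr(bseq, 1L, L))
          if (idy >= min_id) {
            out[[length(out) + 1L]] <- data.frame(
              x = aid, y = bid, ori = anchors_sub$ori[rr], len = L,
              score = L * idy, contain = FALSE, stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(out) == 0L) return(NULL)
    ed <- do.call(rbind, out)
    ed[!duplicated(ed[c("x", "y", "ori", "len")]), , drop = FALSE]
  }

  # candidates where `bid` is the right (prefix) contig: scan all other
  # contigs' k-mer lists for bid's anchors in one pass
  scan_right <- function(bid) {
    arows <- anchors[anchors$bid == bid, , drop = FALSE]
    if (nrow(arows) == 0L) return(NULL)
    others <- setdiff(names(seqs), bid)
    if (length(others) == 0L) return(NULL)
    lens <- lengths(kms[others])
    allk <- unlist(kms[others], use.names = FALSE)
    owner <- rep(others, lens)
    pos <- unlist(lapply(lens, seq_len), use.names = FALSE)
    hit <- which(allk %in% arows$kmer)
    if (length(hit) == 0L) return(NULL)
    out <- list()
    for (h in hit) {
      aid <- owner[h]; p0 <- pos[h]
      rows <- which(arows$kmer == allk[h])
      for (rr in rows) {
        bseq <- if (arows$ori[rr] == "F") seqs[[bid]] else rcs[[bid]]
        na <- nchar(seqs[[aid]]); nb <- nchar(bseq)
        s <- (p0 - 1L) - arows$off[rr]
        if (s < 0L) next
        if (s + nb <= na) {
          if (seq_identity(substr(seqs[[aid]], s + 1L, s + nb), bseq) >= min_id) {
            out[[length(out) + 1L]] <- data.frame(
              x = aid, y = bid, ori = arows$ori[rr], len = nb,
              score = Inf, contain = TRUE, stringsAsFactors = FALSE)
          }
        } else {
          L <- na - s
          if (L < params$min_overlap || L > min(na, nb)) next
          idy <- seq_identity(substr(seqs[[aid]], na - L + 1L, na),
                              substr(bseq, 1L, L))
          if (idy >= min_id) {
            out[[length(out) + 1L]] <- data.frame(
              x = aid, y = bid, ori = arows$ori[rr], len = L,
              score = L * idy, contain = FALSE, stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(out) == 0L) return(NULL)
    ed <- do.call(rbind, out)
    ed[!duplicated(ed[c("x", "y", "ori", "len")]), , drop = FALSE]
  }

  drop_contig <- function(id) {
    seqs[[id]] <<- NULL; rcs[[id]] <<- NULL; members[[id]] <<- NULL; kms[[id]] <<- NULL
    anchors <<- anchors[anchors$bid != id, , drop = FALSE]
  }

  ## initial edge set: scan every contig as the left side
  edges <- do.call(rbind, lapply(names(seqs), function(a)
    scan_left(a, anchors[anchors$bid != a, , drop = FALSE])))

  absorb_containments <- function() {
    repeat {
      if (is.null(edges) || nrow(edges) == 0L) break
      ci <- which(edges$contain)
      if (length(ci) == 0L) break
      e <- edges[ci[order(edges$x[ci], edges$y[ci])][1L], ]
      members[[e$x]] <<- c(members[[e$x]], members[[e$y]])
      drop_contig(e$y)
      edges <<- edges[edges$x != e$y & edges$y != e$y, , drop = FALSE]
    }
  }
  absorb_containments()

  merge_counter <- 0L
  while (!is.null(edges) && nrow(edges) > 0L) {
    edges <- edges[order(-edges$score, edges$x, edges$y), , drop = FALSE]
    e <- edges[1L, ]
    sy <- if (e$ori == "F") seqs[[e$y]] else rcs[[e$y]]
    merged <- paste0(seqs[[e$x]], substr(sy, e$len + 1L, nchar(sy)))
    merged_members <- c(members[[e$x]], members[[e$y]])
    drop_contig(e$x); drop_contig(e$y)
    edges <- edges[!(edges$x %in% c(e$x, e$y) | edges$y %in% c(e$x, e$y)), ,
                   drop = FALSE]
    merge_counter <- merge_counter + 1L
    nid <- sprintf("ctg%05d", merge_counter)
    seqs[[nid]] <- merged
    rcs[[nid]] <- revcomp(merged)
    members[[nid]] <- merged_members
    kms[[nid]] <- kmers_of(merged, anchor_k)
    anchors <- rbind(anchors, anchor_rows(nid))
    new_edges <- rbind(scan_left(nid, anchors[anchors$bid != nid, , drop = FALSE]),
                       scan_right(nid))
    if (!is.null(new_edges)) edges <- rbind(edges, new_edges)
    absorb_containments()
  }

  out <- lapply(names(seqs), function(id) {
    list(id = id, sequence = seqs[[id]], circular = FALSE,
         member_read_ids = unique(members[[id]]))
  })
  out[order(-vapply(out, function(x) nchar(x$sequence), 0))]
}

#' Test a contig for circularity
#'
#' A contig is circular iff a suffix of at least `min_end_overlap` bases
#' matches a prefix at the identity threshold (the redundant join an
#' assembler leaves when reads wrap a circle). The duplicated copy is
#' trimmed and the sequence is reported in canonical rotation. A contig
#' already flagged circular is returned unchanged.
#'
#' @param contig a contig list (from [greedy_assemble()]) or a bare sequence.
#' @param min_end_overlap minimum end duplication (bases).
#' @param min_identity_pct identity threshold over the duplicated end.
#' @return list with `circular`, `sequence` (trimmed + canonically rotated if
#'   circular) and `trimmed` (bases removed).
#' @export
test_circularity <- function(contig, min_end_overlap = 100L,
                             min_identity_pct = 95) {
  if (is.character(contig)) contig <- list(id = "contig", sequence = contig,
                                           circular = FALSE)
  if (isTRUE(contig$circular)) {
    return(list(circular = TRUE, sequence = contig$sequence, trimmed = 0L))
  }
  s <- contig$sequence
  n <- nchar(s)
  if (n <= 2L * min_end_overlap) {
    warning("contig '", contig$id, "' too short for circularity testing")
    return(list(circular = FALSE, sequence = s, trimmed = 0L))
  }
  min_id <- min_identity_pct / 100
  anchor_k <- min(24L, min_end_overlap)
  seed <- substr(s, 1L, anchor_k)
  hits <- gregexpr(seed, s, fixed = TRUE)[[1]]
  hits <- hits[hits > 1L]
  best_L <- 0L
  for (h in hits) {
    L <- n - h + 1L
    if (L < min_end_overlap || L > n %/% 2L) next
    if (seq_identity(substr(s, n - L + 1L, n), substr(s, 1L, L)) >= min_id &&
        L > best_L) best_L <- L
  }
  if (best_L == 0L) return(list(circular = FALSE, sequence = s, trimmed = 0L))
  core <- substr(s, 1L, n - best_L)
  list(circular = TRUE, sequence = canonical_circular(core), trimmed = best_L)
}

## ---- Homology filtering ----------------------------------------------------

# Exact-anchor local hits between query and subject on the forward strand:
# shared k-mers grouped by diagonal, merged across small gaps, verified by
# direct identity. Returns data.frame(q_start, q_end, s_start, s_end,
# length, identity) in 0-based half-open query/subject coordinates.
.diagonal_hits <- function(query, subject, k, max_gap = 60L) {
  qk <- kmers_of(query, k)
  sk <- kmers_of(subject, k)
  if (length(qk) == 0L || length(sk) == 0L) {
    return(data.frame(q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      length = integer(0), identity = numeric(0)))
  }
  sp <- split(seq_along(sk) - 1L, sk)          # k-mer -> 0-based subject pos
  qpos <- which(qk %in% names(sp)) - 1L
  if (length(qpos) == 0L) {
    return(data.frame(q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      length = integer(0), identity = numeric(0)))
  }
  qp <- integer(0); spos <- integer(0)
  for (q in qpos) {
    sv <- sp[[qk[q + 1L]]]
    qp <- c(qp, rep.int(q, length(sv)))
    spos <- c(spos, sv)
  }
  diag <- spos - qp
  out <- list()
  for (d in unique(diag)) {
    qq <- sort(qp[diag == d])
    brk <- c(0L, which(diff(qq) > max_gap), length(qq))
    for (i in seq_len(length(brk) - 1L)) {
      run <- qq[(brk[i] + 1L):brk[i + 1L]]
      q0 <- run[1L]; q1 <- run[length(run)] + k
      idy <- seq_identity(substr(query, q0 + 1L, q1),
                          substr(subject, q0 + d + 1L, q1 + d))
      out[[length(out) + 1L]] <- data.frame(
        q_start = q0, q_end = q1, s_start = q0 + d, s_end = q1 + d,
        length = q1 - q0, identity = idy)
    }
  }
  do.call(rbind, out)
}

#' Homology-filter parameters
#'
#' Replaces a BLAST e-value cut-off with explicit hit criteria: a hit must be
#' at least `min_hit_len` bases at `min_hit_identity` percent identity.
#'
#' @param min_hit_len minimum hit length (bases).
#' @param min_hit_identity minimum hit identity (percent).
#' @param plastid_exclusion_coverage contigs whose hit-covered fraction
#'   against the exclusion reference reaches this value are removed.
#' @return list of class `homology_params`.
#' @export
homology_params <- function(min_hit_len = 100L, min_hit_identity = 80,
                            plastid_exclusion_coverage = 0.9) {
  stopifnot(min_hit_len >= 1L, min_hit_identity > 0, min_hit_identity <= 100,
            plastid_exclusion_coverage > 0, plastid_exclusion_coverage <= 1)
  structure(list(min_hit_len = as.integer(min_hit_len),
                 min_hit_identity = min_hit_identity,
                 plastid_exclusion_coverage = plastid_exclusion_coverage),
            class = "homology_params")
}

# Fraction of the contig covered by qualifying hits against any reference
# (both strands), plus whether any hit exists.
.hit_coverage <- function(contig, references, params, k = 21L) {
  cov <- logical(nchar(contig))
  any_hit <- FALSE
  for (ref in references) {
    for (qry in c(contig, revcomp(contig))) {
      h <- .diagonal_hits(qry, ref, k)
      if (is.null(h) || nrow(h) == 0L) next
      h <- h[h$length >= params$min_hit_len &
             h$identity * 100 >= params$min_hit_identity, , drop = FALSE]
      if (nrow(h) == 0L) next
      any_hit <- TRUE
      n <- nchar(contig)
      for (i in seq_len(nrow(h))) {
        if (identical(qry, contig)) {
          cov[(h$q_start[i] + 1L):h$q_end[i]] <- TRUE
        } else {
          cov[(n - h$q_end[i] + 1L):(n - h$q_start[i])] <- TRUE
        }
      }
    }
  }
  list(any_hit = any_hit, coverage = mean(cov))
}

#' Filter contigs by homology to a reference set
#'
#' `retain_hits` keeps contigs with at least one qualifying hit (the
#' "matches the mitochondrial dataset" step); `exclude_covered` removes
#' contigs whose hit-covered fraction reaches
#' `params$plastid_exclusion_coverage` (the plastid-exclusion step).
#'
#' @param contigs list of contig lists or a named character vector.
#' @param references character vector of reference sequences.
#' @param params a [homology_params()].
#' @param mode `"retain_hits"` or `"exclude_covered"`.
#' @return list with `kept` and `removed` contig lists.
#' @export
homology_filter <- function(contigs, references, params = homology_params(),
                            mode = c("retain_hits", "exclude_covered")) {
  mode <- match.arg(mode)
  stopifnot(length(references) > 0L)
  if (is.character(contigs)) {
    contigs <- lapply(seq_along(contigs), function(i)
      list(id = names(contigs)[i] %||% paste0("ctg", i),
           sequence = unname(contigs[[i]]), circular = FALSE,
           member_read_ids = character(0)))
  }
  kept <- list(); removed <- list()
  for (ct in contigs) {
    hc <- .hit_coverage(ct$sequence, references, params)
    keep <- if (mode == "retain_hits") hc$any_hit
            else hc$coverage < params$plastid_exclusion_coverage
    if (keep) kept[[length(kept) + 1L]] <- ct
    else removed[[length(removed) + 1L]] <- ct
  }
  list(kept = kept, removed = removed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Iterative bait-and-assemble loop
#'
#' Each round baits the read pool against the current bait set (initial baits
#' plus surviving contigs), assembles the baited reads, keeps contigs with
#' homology to the initial bait set, removes contigs covered by the plastid
#' reference, and sets circular contigs aside as potentially complete
#' (excluding them from further baiting). Terminates after the schedule or
#' when the contig set stops changing.
#'
#' @param reads named character vector (the read pool).
#' @param initial_baits character vector of starting bait sequences.
#' @param schedule data.frame with columns `k` and `n`, one row per round.
#' @param params an [overlap_params()].
#' @param hom_params a [homology_params()].
#' @param plastid_refs optional character vector; contigs covered by these at
#'   the exclusion threshold are dropped each round.
#' @param circ_min_end_overlap,circ_min_identity_pct circularity test
#'   thresholds.
#' @return list with `circular` and `linear` contig lists and a per-round
#'   `log` data.frame.
#' @export
iterative_bait_assemble <- function(reads, initial_baits,
                                    schedule = data.frame(k = c(32L, 27L, 31L, 31L),
                                                          n = c(50L, 1L, 1L, 1L)),
                                    params = overlap_params(),
                                    hom_params = homology_params(),
                                    plastid_refs = NULL,
                                    circ_min_end_overlap = 100L,
                                    circ_min_identity_pct = 95) {
  stopifnot(nrow(schedule) >= 1L)
  if (length(reads) == 0L) {
    warning("empty read pool")
    return(list(circular = list(), linear = list(),
                log = data.frame(round = integer(0), baited = integer(0),
                                 contigs = integer(0), circular = integer(0))))
  }
  bait_pool <- initial_baits
  circular <- list()
  linear <- list()
  log <- NULL
  prev_sig <- ""
  for (rnd in seq_len(min(nrow(schedule), params$max_rounds))) {
    k <- schedule$k[rnd]; n <- schedule$n[rnd]
    usable <- bait_pool[nchar(bait_pool) >= k]
    bs <- build_bait_set(usable, k = k, min_hits = n)
    baited <- bait_reads(reads, bs)
    if (length(baited) == 0L) break
    contigs <- greedy_assemble(baited, params)
    contigs <- homology_filter(contigs, initial_baits, hom_params,
                               "retain_hits")$kept
    if (!is.null(plastid_refs) && length(plastid_refs) > 0L) {
      contigs <- homology_filter(contigs, plastid_refs, hom_params,
                                 "exclude_covered")$kept
    }
    new_linear <- list()
    for (ct in contigs) {
      circ <- test_circularity(ct, circ_min_end_overlap, circ_min_identity_pct)
      if (circ$circular) {
        ct$sequence <- circ$sequence
        ct$circular <- TRUE
        circular[[length(circular) + 1L]] <- ct
      } else {
        new_linear[[length(new_linear) + 1L]] <- ct
      }
    }
    linear <- new_linear
    # reads explained by a potentially complete circle leave the pool
    circ_members <- unlist(lapply(circular, `[[`, "member_read_ids"))
    reads <- reads[!names(reads) %in% circ_members]
    log <- rbind(log, data.frame(round = rnd, baited = length(baited),
                                 contigs = length(contigs),
                                 circular = length(circular)))
    if (length(reads) == 0L || (length(linear) == 0L && length(circular) > 0L &&
                                rnd > 1L)) break
    sig <- paste(sort(c(vapply(circular, `[[`, "", "sequence"),
                        vapply(linear, `[[`, "", "sequence"))), collapse = "|")
    if (identical(sig, prev_sig)) break
    prev_sig <- sig
    bait_pool <- c(initial_baits, vapply(linear, `[[`, "", "sequence"))
    if (length(bait_pool) == 0L) break
  }
  ## deduplicate circular contigs that are the same molecule
  if (length(circular) > 1L) {
    canon <- vapply(circular, `[[`, "", "sequence")
    circular <- circular[!duplicated(canon)]
  }
  list(circular = circular, linear = linear, log = log)
}

#' Close N-gaps by local re-baiting and assembly
#'
#' For each maximal N-run, the flanks bait reads, the baited reads are
#' assembled, and a closure contig patches the gap iff it spans both flank
#' anchors at high identity. Gaps no closure spans are reported unresolved.
#'
#' @param assembly a sequence containing N-runs.
#' @param reads named character vector.
#' @param flank bases of flank used for baiting on each side.
#' @param anchor bases of flank that the closure contig must match on each
#'   side (at `anchor_identity_pct`).
#' @param anchor_identity_pct identity threshold for the anchors.
#' @param params assembly parameters for the local assembly.
#' @return list with `sequence` (patched) and `unresolved` (data.frame of
#'   gaps left open).
#' @export
close_gaps <- function(assembly, reads, flank = 2000L, anchor = 100L,
                       anchor_identity_pct = 95,
                       params = overlap_params(min_overlap = 200L)) {
  stopifnot(flank > 0L)
  gaps <- gregexpr("N+", assembly)[[1]]
  if (gaps[1] == -1L) {
    return(list(sequence = assembly,
                unresolved = data.frame(start = integer(0), end = integer(0))))
  }
  glen <- attr(gaps, "match.length")
  unresolved <- NULL
  # patch right-to-left so earlier coordinates stay valid
  for (i in rev(seq_along(gaps))) {
    gs <- gaps[i]; ge <- gaps[i] + glen[i] - 1L        # 1-based inclusive
    lf <- substr(assembly, max(1L, gs - flank), gs - 1L)
    rf <- substr(assembly, ge + 1L, min(nchar(assembly), ge + flank))
    k <- 31L
    usable <- c(lf, rf); usable <- usable[nchar(usable) >= k]
    patched <- FALSE
    if (length(usable) > 0L) {
      bs <- build_bait_set(usable, k = k, min_hits = 1L)
      baited <- bait_reads(reads, bs)
      if (length(baited) > 0L) {
        contigs <- greedy_assemble(baited, params)
        la <- substr(lf, nchar(lf) - anchor + 1L, nchar(lf))
        ra <- substr(rf, 1L, anchor)
        for (ct in contigs) {
          for (cs in c(ct$sequence, revcomp(ct$sequence))) {
            lp <- .find_anchor(cs, la, anchor_identity_pct / 100)
            rp <- .find_anchor(cs, ra, anchor_identity_pct / 100)
            if (!is.null(lp) && !is.null(rp) && rp > lp + anchor) {
              fill <- substr(cs, lp + anchor, rp - 1L)   # between anchors
              assembly <- paste0(substr(assembly, 1L, gs - 1L), fill,
                                 substr(assembly, ge + 1L, nchar(assembly)))
              patched <- TRUE
              break
            }
          }
          if (patched) break
        }
      }
    }
    if (!patched) unresolved <- rbind(
      data.frame(start = gs - 1L, end = ge), unresolved)
  }
  list(sequence = assembly,
       unresolved = unresolved %||% data.frame(start = integer(0),
                                               end = integer(0)))
}

# 1-based start of the best occurrence of `pat` in `s` at >= min_id, or NULL.
.find_anchor <- function(s, pat, min_id) {
  hits <- gregexpr(substr(pat, 1L, min(18L, nchar(pat))), s, fixed = TRUE)[[1]]
  if (hits[1] == -1L) {
    m <- Biostrings::matchPattern(pat, s,
                                  max.mismatch = floor((1 - min_id) * nchar(pat)))
    if (length(m) == 0L) return(NULL)
    return(Biostrings::start(m)[1L])
  }
  for (h in hits) {
    if (h + nchar(pat) - 1L > nchar(s)) next
    if (seq_identity(substr(s, h, h + nchar(pat) - 1L), pat) >= min_id) return(h)
  }
  NULL
}

#' Majority-vote consensus polishing
#'
#' Pileup-based polishing standing in for a full realignment pipeline: a base
#' is replaced iff its depth reaches `min_depth` and the leading alternative
#' allele fraction reaches `majority_fraction`.
#'
#' @param assembly sequence to polish.
#' @param alignments an [alignment_table()] of reads mapped to `assembly`
#'   (ungapped, as produced by [map_reads()]); read sequences are taken from
#'   the table's `seq` column.
#' @param min_depth minimum pileup depth for a call.
#' @param majority_fraction minimum fraction of the alternative allele.
#' @param circular treat the assembly as circular (alignments may wrap).
#' @return list with `sequence` and `changes` (data.frame pos/ref/alt, 0-based).
#' @export
polish_consensus <- function(assembly, alignments, min_depth = 5L,
                             majority_fraction = 0.7, circular = TRUE) {
  n <- nchar(assembly)
  if (nrow(alignments) == 0L) {
    return(list(sequence = assembly,
                changes = data.frame(pos = integer(0), ref = character(0),
                                     alt = character(0))))
  }
  aln <- alignments[!is.na(alignments$chrom), , drop = FALSE]
  base_code <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)
  idx <- integer(0); val <- integer(0)
  for (i in seq_len(nrow(aln))) {
    rd <- if (aln$strand[i] == "-") revcomp(aln$seq[i]) else aln$seq[i]
    L <- nchar(rd)
    pos <- aln$pos[i] + seq_len(L) - 1L
    if (circular) pos <- pos %% n else {
      keep <- pos < n; pos <- pos[keep]; rd <- substr(rd, 1L, sum(keep)); L <- sum(keep)
    }
    b <- base_code[strsplit(rd, "")[[1]]]
    idx <- c(idx, pos)
    val <- c(val, b)
  }
  counts <- matrix(0L, nrow = 5L, ncol = n)
  tab <- tapply(rep.int(1L, length(idx)), list(val, idx), sum)
  counts[cbind(as.integer(rep(rownames(tab), ncol(tab))),
               as.integer(rep(colnames(tab), each = nrow(tab))) + 1L)] <-
    ifelse(is.na(as.vector(tab)), 0L, as.vector(tab))
  depth <- colSums(counts[1:4, , drop = FALSE])
  ref <- strsplit(assembly, "")[[1]]
  top <- apply(counts[1:4, , drop = FALSE], 2L, which.max)
  top_base <- c("A", "C", "G", "T")[top]
  top_frac <- counts[cbind(top, seq_len(n))] / pmax(depth, 1L)
  change <- depth >= min_depth & top_frac >= majority_fraction & top_base != ref
  changes <- data.frame(pos = which(change) - 1L, ref = ref[change],
                        alt = top_base[change], stringsAsFactors = FALSE)
  ref[change] <- top_base[change]
  list(sequence = paste(ref, collapse = ""), changes = changes)
}
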