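#' @import methods
#' @importFrom stats rbinom rnorm runif setNames
#' @importFrom utils head tail write.table read.table
NULL

#' Reverse complement of DNA strings
#'
#' Vectorised over a character vector; `N` is its own complement.
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s)))),
         "", USE.NAMES = FALSE)
}

#' Extract a substring from a circular sequence
#'
#' Coordinates are 0-based; the extraction wraps across the origin. `start`
#' may be negative or exceed the sequence length and is normalised modulo
#' the length.
#'
#' @param seq a single DNA string.
#' @param start 0-based start position.
#' @param len number of bases to extract (must be <= sequence length).
#' @return character scalar of length `len`.
#' @export
circ_substr <- function(seq, start, len) {
  n <- nchar(seq)
  stopifnot(len <= n)
  s <- ((start %% n) + n) %% n           # normalise to [0, n)
  if (s + len <= n) return(substr(seq, s + 1L, s + len))
  paste0(substr(seq, s + 1L, n), substr(seq, 1L, s + len - n))
}

# Fraction of identical aligned positions between two equal-length strings.
# N never matches (counts as mismatch on either side).
seq_identity <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  if (length(ra) == 0L) return(NA_real_)
  nraw <- charToRaw("N")
  sum(ra == rb & ra != nraw) / length(ra)
}

# Random DNA with exact base composition: round(n * gc) G/C bases, the rest
# A/T, in shuffled order. Guarantees the GC fraction to within 1/(2n).
random_dna <- function(n, gc = 0.5) {
  n_gc <- round(n * gc)
  n_at <- n - n_gc
  bases <- c(
    sample(c("G", "C"), n_gc, replace = TRUE),
    sample(c("A", "T"), n_at, replace = TRUE)
  )
  paste(sample(bases), collapse = "")
}

#' GC fraction of a sequence
#'
#' @param seq a single DNA string; `N` bases are ignored in the denominator.
#' @return fraction in `[0, 1]`.
#' @export
gc_fraction <- function(seq) {
  f <- Biostrings::letterFrequency(Biostrings::DNAString(seq), c("G", "C", "A", "T"))
  sum(f[c("G", "C")]) / sum(f)
}

# All k-mers of a sequence as a character vector (positions 1..n-k+1).
kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), k:n)
}

# Canonical form: lexicographic min of each k-mer and its reverse complement.
canonical_kmers <- function(kms) {
  if (length(kms) == 0L) return(character(0))
  pmin(kms, revcomp(kms))
}

# Lexicographically minimal rotation of a circular sequence, considering both
# strands, so that assemblies of the same circle compare equal regardless of
# the rotation or orientation they were built in.
canonical_rotation <- function(seq) {
  n <- nchar(seq)
  if (n <= 1L) return(seq)
  doubled <- paste0(seq, seq)
  ch <- strsplit(seq, "")[[1]]
  cand <- which(ch == min(ch))           # starts at the minimal character
  off <- 0L
  block <- 64L
  while (length(cand) > 1L && off < n) {
    w <- min(block, n - off)
    pieces <- substr(rep(doubled, length(cand)), cand + off, cand + off + w - 1L)
    cand <- cand[pieces == min(pieces)]
    off <- off + w
  }
  substr(doubled, cand[1L], cand[1L] + n - 1L)
}

#' Canonical representation of a circular DNA molecule
#'
#' The lexicographically minimal rotation over both strands. Two assemblies
#' of the same circle are equal under this form whatever rotation and
#' orientation the assembler produced.
#'
#' @param seq a single DNA string (one full turn of the circle).
#' @return character scalar.
#' @export
canonical_circular <- function(seq) {
  min(canonical_rotation(seq), canonical_rotation(revcomp(seq)))
}

# Apply n_sub random substitutions (to a different base) at distinct positions.
mutate_substitutions <- function(seq, n_sub) {
  if (n_sub == 0L) return(seq)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(ch), n_sub)
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}
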