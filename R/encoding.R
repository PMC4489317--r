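# Z-curve feature encodings: the 765-variable phase-specific k-mer encoding
# (9 mono + 36 di + 144 tri + 576 tetra) and the legacy 33-variable one.

#' Z transformation of four base frequencies
#'
#' Maps the frequencies of A, C, G, T (in that order) onto three axes:
#' purine vs pyrimidine (`x = (A+G) - (C+T)`), amino vs keto
#' (`y = (A+C) - (G+T)`) and weak vs strong hydrogen bonding
#' (`z = (A+T) - (G+C)`). When the four frequencies sum to 1, each
#' component lies in `[-1, 1]`. The map is linear, which is why every group
#' of four k-mer frequencies reduces to three Z variables (the 3/4 factor
#' in the encoding's dimension arithmetic).
#'
#' @param freq Numeric vector of four nonnegative frequencies (A, C, G, T).
#' @return Named numeric vector `c(x, y, z)`.
#' @examples
#' z_transform(c(0.25, 0.25, 0.25, 0.25))
#' z_transform(c(1, 0, 0, 0))
#' @export
z_transform <- function(freq) {
  if (length(freq) != 4L || !is.numeric(freq)) {
    stop("freq must be four numbers (A, C, G, T)", call. = FALSE)
  }
  if (any(freq < 0)) stop("frequencies must be nonnegative", call. = FALSE)
  c(x = freq[[1L]] + freq[[3L]] - freq[[2L]] - freq[[4L]],
    y = freq[[1L]] + freq[[2L]] - freq[[3L]] - freq[[4L]],
    z = freq[[1L]] + freq[[4L]] - freq[[2L]] - freq[[3L]])
}

#' Phase-specific k-mer counts
#'
#' Counts k-mer occurrences stratified by the codon position (phase 1, 2 or
#' 3) of the k-mer's leading base. For `k = 2` the three phases correspond
#' to dinucleotides at codon positions 1-2, 2-3 and 3-1 (the last spanning
#' the codon boundary). Windows containing `N` are skipped.
#'
#' @param seq ORF sequence (length divisible by 3). The stop codon is *not*
#'   removed here; [encode_orf()] strips it before counting.
#' @param k Word size, 1 to 4.
#' @return Integer matrix of dimension `4^k` by 3: rows index k-mers in
#'   lexicographic A<C<G<T order, columns the phase of the leading base.
#' @export
count_phase_kmers <- function(seq, k) {
  stopifnot(k %in% 1:4)
  b <- if (is.character(seq)) seq_to_int(seq) else as.integer(seq)
  if (length(b) %% 3L != 0L) {
    stop("ORF length must be divisible by 3", call. = FALSE)
  }
  if (length(b) < 3L * k) {
    stop("sequence too short for a window of size ", k, call. = FALSE)
  }
  counts_phase_kmers_int(b, k)
}

counts_phase_kmers_int <- function(b, k) {
  L <- length(b)
  n <- L - k + 1L
  code <- b[seq_len(n)]
  if (k > 1L) for (j in 2:k) code <- 4L * code + b[seq.int(j, j + n - 1L)]
  phase <- rep_len(1:3, n)
  out <- matrix(0L, nrow = 4L^k, ncol = 3L,
                dimnames = list(kmer_names(k), paste0("phase", 1:3)))
  for (p in 1:3) {
    v <- code[phase == p]
    v <- v[!is.na(v)]
    out[, p] <- tabulate(v + 1L, nbins = 4L^k)
  }
  out
}

kmer_names <- function(k) {
  g <- do.call(expand.grid, c(rep(list(BASES), k), KEEP.OUT.ATTRS = FALSE,
                              stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; we want the last position
  # fastest (lexicographic order), so build in reverse
  do.call(paste0, rev(g))
}

# Z variables for one k (k >= 1) from a phase-count matrix: for every
# (phase, (k-1)-mer prefix) group, the conditional distribution of the final
# base is Z-transformed after adding `pseudocount` observations spread
# uniformly over the four bases (shrinkage toward the uninformative point;
# rarely-seen prefix groups of short ORFs otherwise contribute pure noise).
# Groups with zero occurrences give (0, 0, 0). Order: phase outer, prefix
# lexicographic, (x, y, z) innermost.
z_block <- function(counts, k, pseudocount = 0) {
  nprefix <- 4L^(k - 1L)
  out <- numeric(3L * nprefix * 3L)
  pos <- 0L
  for (p in 1:3) {
    m <- matrix(as.numeric(counts[, p]), nrow = 4L)  # rows: final base A,C,G,T
    tot <- colSums(m) + pseudocount
    tot[tot == 0] <- Inf  # zero groups -> all-zero frequencies
    f <- sweep(m + pseudocount / 4, 2L, tot, "/")
    x <- f[1L, ] + f[3L, ] - f[2L, ] - f[4L, ]
    y <- f[1L, ] + f[2L, ] - f[3L, ] - f[4L, ]
    z <- f[1L, ] + f[4L, ] - f[2L, ] - f[3L, ]
    out[pos + seq_len(3L * nprefix)] <- as.vector(rbind(x, y, z))
    pos <- pos + 3L * nprefix
  }
  out
}

encode_orf_int <- function(b, legacy = FALSE, pseudocount = 0.5) {
  # stop codon carries no discriminative signal; exclude it
  if (length(b) >= 6L) b <- b[seq_len(length(b) - 3L)]
  mono <- z_block(counts_phase_kmers_int(b, 1L), 1L, pseudocount)
  di <- counts_phase_kmers_int(b, 2L)
  if (legacy) {
    v <- numeric(33L)
    v[1:9] <- mono
    blk <- z_block(di, 2L, pseudocount)  # phases 1-2, 2-3, 3-1 (12 each)
    v[10:33] <- blk[1:24]                # positions 1-2 and 2-3 only
    return(v)
  }
  v <- numeric(765L)
  v[1:9] <- mono
  v[10:45] <- z_block(di, 2L, pseudocount)
  v[46:189] <- z_block(counts_phase_kmers_int(b, 3L), 3L, pseudocount)
  v[190:765] <- z_block(counts_phase_kmers_int(b, 4L), 4L, pseudocount)
  v
}

#' Encode an ORF as the 765-variable Z-curve feature vector
#'
#' Builds the full phase-specific Z-curve encoding of one ORF: 9 variables
#' from codon-position-dependent single-nucleotide frequencies, 36 from
#' phase-specific dinucleotides (codon positions 1-2, 2-3 and 3-1), 144
#' from the 192 phase-specific trinucleotide frequencies and 576 from the
#' 768 phase-specific tetranucleotide frequencies, each group of four
#' frequencies reduced to three variables by [z_transform()] (hence the 3/4
#' factor: 9 + 36 + 144 + 576 = 765). For `k >= 2` the four frequencies fed
#' to the transform are conditional on the preceding `k - 1` bases and the
#' phase; prefix groups never observed give `(0, 0, 0)`. The stop codon is
#' excluded from counting. Block order is mono, di, tri, tetra; within a
#' block, phase outer, prefix lexicographic, `(x, y, z)` innermost.
#'
#' @param seq ORF sequence (start codon through stop codon, length
#'   divisible by 3) or its integer base codes.
#' @param pseudocount Total pseudo-observations added to every conditional
#'   frequency group, spread uniformly over the four bases (default 0.5).
#'   Shrinks rarely-observed groups -- dominant in the tetranucleotide
#'   block of short ORFs -- toward the uninformative point `(0, 0, 0)`;
#'   `0` gives raw maximum-likelihood frequencies.
#' @return Numeric vector of length 765, every component in `[-1, 1]`, with
#'   attribute `blocks = c(mono = 9, di = 36, tri = 144, tetra = 576)`.
#' @seealso [encode_orf_legacy()] for the 33-variable encoding.
#' @export
encode_orf <- function(seq, pseudocount = 0.5) {
  b <- if (is.character(seq)) seq_to_int(seq) else as.integer(seq)
  if (length(b) %% 3L != 0L || length(b) < 15L) {
    stop("ORF sequence must have length divisible by 3 and >= 15 nt",
         call. = FALSE)
  }
  structure(encode_orf_int(b, pseudocount = pseudocount),
            blocks = c(mono = 9L, di = 36L, tri = 144L, tetra = 576L))
}

#' Encode an ORF as the legacy 33-variable Z-curve feature vector
#'
#' The original encoding: codon-position-dependent single nucleotides
#' (4 x 3 x 3/4 = 9 variables) plus phase-specific dinucleotides at codon
#' positions 1-2 and 2-3 (4^2 x 2 x 3/4 = 24 variables). Its mono block is
#' identical to the first nine components of [encode_orf()].
#'
#' @inheritParams encode_orf
#' @return Numeric vector of length 33 with attribute
#'   `blocks = c(mono = 9, di = 24)`.
#' @export
encode_orf_legacy <- function(seq, pseudocount = 0.5) {
  b <- if (is.character(seq)) seq_to_int(seq) else as.integer(seq)
  if (length(b) %% 3L != 0L || length(b) < 9L) {
    stop("ORF sequence must have length divisible by 3 and >= 9 nt",
         call. = FALSE)
  }
  structure(encode_orf_int(b, legacy = TRUE, pseudocount = pseudocount),
            blocks = c(mono = 9L, di = 24L))
}

#' Encode a set of ORF sequences as a feature matrix
#'
#' @param seqs Character vector of ORF sequences.
#' @param encoding `"z765"` (default) or `"z33"` (legacy).
#' @inheritParams encode_orf
#' @return Numeric matrix, one row per sequence.
#' @export
encode_matrix <- function(seqs, encoding = c("z765", "z33"),
                          pseudocount = 0.5) {
  encoding <- match.arg(encoding)
  d <- if (encoding == "z765") 765L else 33L
  legacy <- encoding == "z33"
  out <- matrix(0, nrow = length(seqs), ncol = d)
  for (i in seq_along(seqs)) {
    b <- if (is.character(seqs)) seq_to_int(seqs[[i]]) else seqs[[i]]
    out[i, ] <- encode_orf_int(b, legacy = legacy, pseudocount = pseudocount)
  }
  out
}
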