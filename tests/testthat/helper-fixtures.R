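# Shared fixtures and independent oracles used across the test files.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Brute-force six-frame ORF oracle: enumerate every (start, stop) pair by
# walking triplet windows. Independent of the package's scanning code.
brute_orf_pairs <- function(seq, min_len = 90L,
                            starts = c("ATG", "GTG", "TTG"),
                            stops = c("TAA", "TAG", "TGA")) {
  one_strand <- function(s) {
    L <- nchar(s)
    out <- list()
    for (i in seq_len(max(L - 5L, 0L))) {
      if (!(substr(s, i, i + 2L) %in% starts)) next
      j <- i + 3L
      while (j + 2L <= L) {
        cd <- substr(s, j, j + 2L)
        if (cd %in% stops) {
          if (j + 2L - i + 1L >= min_len) {
            out[[length(out) + 1L]] <- c(i, j + 2L)
          }
          break
        }
        j <- j + 3L
      }
    }
    if (length(out)) do.call(rbind, out) else matrix(0L, 0L, 2L)
  }
  fwd <- one_strand(seq)
  rc <- one_strand(reverse_complement(seq))
  L <- nchar(seq)
  rbind(
    if (nrow(fwd)) data.frame(strand = "+", start = fwd[, 1], end = fwd[, 2])
    else NULL,
    if (nrow(rc)) data.frame(strand = "-", start = L - rc[, 2] + 1L,
                             end = L - rc[, 1] + 1L)
    else NULL)
}

# Expand a candidate-ORF table into the full set of (strand, start, end)
# pairs it represents (every alternative start paired with its stop).
expand_orf_pairs <- function(orfs) {
  if (!nrow(orfs)) return(data.frame(strand = character(0),
                                     start = integer(0), end = integer(0)))
  rows <- lapply(seq_len(nrow(orfs)), function(i) {
    alt <- orfs$alt_starts[[i]]
    if (orfs$strand[i] == "+") {
      data.frame(strand = "+", start = alt, end = orfs$end[i])
    } else {
      data.frame(strand = "-", start = orfs$start[i], end = alt)
    }
  })
  do.call(rbind, rows)
}

pair_key <- function(df) sort(paste(df$strand, df$start, df$end))

# Rank-based AUC (the Wilcoxon statistic definition).
auc_rank <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Exhaustive best-subset total score under the pairwise overlap cap
# (oracle for the greedy overlap resolver; feasible for ~10 ORFs).
best_subset_score <- function(starts, ends, scores, cap) {
  n <- length(starts)
  conflict <- outer(seq_len(n), seq_len(n), function(i, j) {
    ov <- pmin(ends[i], ends[j]) - pmax(starts[i], starts[j]) + 1L
    ov > cap & i != j
  })
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(sel) > 1L && any(conflict[sel, sel])) next
    best <- max(best, sum(scores[sel]))
  }
  best
}

stopkey <- function(df) paste(df$contig, df$strand,
                              ifelse(df$strand == "+", df$end, df$start))

# Small synthetic genome + fit, cached per test run (several tests reuse it).
small_fit_env <- new.env()
get_small_fit <- function() {
  if (is.null(small_fit_env$fit)) {
    s <- synth_genome(length = 80000L, n_genes = 65L, seed = 301L)
    small_fit_env$synth <- s
    small_fit_env$fit <- zgene(s$genome, seed = 301L, min_positives = 25L)
  }
  list(synth = small_fit_env$synth, fit = small_fit_env$fit)
}
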