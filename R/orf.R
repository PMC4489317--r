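# Candidate ORF enumeration in all six frames, with circular wrap handling.

CODE11_STARTS <- c("ATG", "GTG", "TTG")
CODE11_STOPS <- c("TAA", "TAG", "TGA")

codon_code <- function(codons) {
  vapply(codons, function(cd) {
    x <- seq_to_int(cd, what = paste0("codon '", cd, "'"))
    if (length(x) != 3L || anyNA(x)) stop("bad codon: ", cd, call. = FALSE)
    16L * x[1L] + 4L * x[2L] + x[3L]
  }, 0L, USE.NAMES = FALSE)
}

#' Reverse complement of a nucleotide string
#'
#' Standard Watson-Crick complement, reversed; `N` maps to `N`. Applying it
#' twice is the identity.
#'
#' @param seq Nucleotide string over `{A,C,G,T,N}` (case-insensitive).
#' @return The reverse complement, uppercase.
#' @examples
#' reverse_complement("ATGC")
#' @export
reverse_complement <- function(seq) {
  x <- utf8ToInt(toupper(seq))
  ok <- x %in% utf8ToInt("ACGTN")
  if (!all(ok)) {
    stop(sprintf("non-nucleotide character '%s' in sequence",
                 intToUtf8(x[which(!ok)[1L]])), call. = FALSE)
  }
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", intToUtf8(x)))))
}

comp_int <- function(b) {
  out <- 3L - b  # A<->T, C<->G on the 0:3 coding; NA (N) propagates
  out
}

# Scan one strand (given as base codes) for ORFs: for every stop codon, the
# compatible in-frame starts since the previous in-frame stop. Returns one
# row per stop with the longest start as canonical plus the full start list.
scan_strand <- function(b, min_len, start_codes, stop_codes) {
  L <- length(b)
  empty <- list(start = integer(0), end = integer(0), frame = integer(0),
                alt = list())
  if (L < max(min_len, 3L)) return(empty)
  i <- seq_len(L - 2L)
  cod <- 16L * b[i] + 4L * b[i + 1L] + b[i + 2L]
  is_stop <- !is.na(cod) & cod %in% stop_codes
  is_start <- !is.na(cod) & cod %in% start_codes
  res_start <- integer(0); res_end <- integer(0); res_frame <- integer(0)
  res_alt <- list()
  for (f in 0:2) {
    if (f + 1L > L - 2L) next
    p <- seq.int(f + 1L, L - 2L, 3L)
    stops <- p[is_stop[p]]
    starts <- p[is_start[p]]
    if (!length(stops) || !length(starts)) next
    grp <- findInterval(starts, stops) + 1L
    ok <- grp <= length(stops)
    starts <- starts[ok]; grp <- grp[ok]
    stop_pos <- stops[grp]
    len <- stop_pos + 3L - starts
    ok <- len >= min_len
    starts <- starts[ok]; stop_pos <- stop_pos[ok]
    if (!length(starts)) next
    alt <- split(starts, stop_pos)
    ends <- as.integer(names(alt)) + 2L
    canon <- vapply(alt, min, 0L)
    res_start <- c(res_start, unname(canon))
    res_end <- c(res_end, ends)
    res_frame <- c(res_frame, rep(f, length(ends)))
    res_alt <- c(res_alt, lapply(alt, unname))
  }
  list(start = res_start, end = res_end, frame = res_frame, alt = res_alt)
}

orf_frame <- function(strand_rows) strand_rows

#' Enumerate candidate open reading frames
#'
#' Scans all six reading frames of a contig for open reading frames: a
#' stretch beginning at an allowed start codon and ending at the first
#' in-frame stop codon, with no internal in-frame stop. For every stop
#' codon the longest compatible start is reported as the canonical ORF and
#' all alternative in-frame starts are retained (`alt_starts`) for later
#' start relocation, so the full set of (start, stop) pairs is represented.
#' Codons containing `N` are never start or stop candidates. For circular
#' contigs origin-crossing ORFs are found by scanning a doubled sequence
#' (see [wrap_orfs()]); these carry `start > end` with `wrap = TRUE`.
#'
#' @param genome A [genome_sequence()] record.
#' @param min_len Minimum ORF length in nt, stop codon included; must be
#'   at least 6 and divisible by 3. Default 90.
#' @param start_codons,stop_codons Codon sets (genetic code 11 defaults:
#'   ATG/GTG/TTG and TAA/TAG/TGA).
#' @return A data.frame, ordered by (contig, strand, end, start), with
#'   columns `contig`, `strand`, `frame` (0..2 on its own strand), `start`,
#'   `end` (1-based inclusive genomic, `start <= end` unless `wrap`),
#'   `length`, `wrap`, `n_starts` and list-column `alt_starts` holding every
#'   candidate gene-start coordinate (values the 5' coordinate may take).
#' @export
extract_orfs <- function(genome, min_len = 90L,
                         start_codons = CODE11_STARTS,
                         stop_codons = CODE11_STOPS) {
  stopifnot(inherits(genome, "zgene_genome"))
  if (min_len < 6L || min_len %% 3L != 0L) {
    stop("min_len must be >= 6 and divisible by 3", call. = FALSE)
  }
  if (genome$circular) {
    return(wrap_orfs(genome, min_len, start_codons, stop_codons))
  }
  b <- seq_to_int(genome$seq, what = sprintf("record '%s'", genome$id))
  start_codes <- codon_code(start_codons)
  stop_codes <- codon_code(stop_codons)
  L <- genome$length

  fwd <- scan_strand(b, min_len, start_codes, stop_codes)
  rev_ <- scan_strand(rev(comp_int(b)), min_len, start_codes, stop_codes)

  n_f <- length(fwd$start); n_r <- length(rev_$start)
  orfs <- data.frame(
    contig = rep(genome$id, n_f + n_r),
    strand = rep(c("+", "-"), c(n_f, n_r)),
    frame = c(fwd$frame, rev_$frame),
    start = c(fwd$start, L - rev_$end + 1L),
    end = c(fwd$end, L - rev_$start + 1L),
    wrap = rep(FALSE, n_f + n_r),
    stringsAsFactors = FALSE)
  orfs$length <- orfs$end - orfs$start + 1L
  orfs$alt_starts <- c(fwd$alt, lapply(rev_$alt, function(a) L - a + 1L))
  orfs$n_starts <- lengths(orfs$alt_starts)
  finish_orfs(orfs, genome)
}

#' Enumerate ORFs on a circular contig, including origin-crossing ones
#'
#' Scans a doubled copy of the sequence so that ORFs crossing the origin are
#' seen linearly, maps coordinates back modulo the contig length, and keeps
#' one ORF per (strand, stop codon) -- the instance with the longest
#' canonical span, whose start list covers both sides of the origin.
#' Origin-crossing ORFs are reported with `start > end` and `wrap = TRUE`.
#'
#' @inheritParams extract_orfs
#' @export
wrap_orfs <- function(genome, min_len = 90L,
                      start_codons = CODE11_STARTS,
                      stop_codons = CODE11_STOPS) {
  stopifnot(inherits(genome, "zgene_genome"))
  if (!genome$circular) stop("wrap_orfs requires a circular genome", call. = FALSE)
  b <- seq_to_int(genome$seq, what = sprintf("record '%s'", genome$id))
  start_codes <- codon_code(start_codons)
  stop_codes <- codon_code(stop_codons)
  L <- genome$length
  d <- c(b, b)
  modL <- function(x) ((x - 1L) %% L) + 1L

  collect <- function(sc, to_genomic) {
    keep <- which(sc$start <= L & (sc$end - sc$start + 1L) <= L)
    if (!length(keep)) {
      out <- data.frame(strand = character(0), frame = integer(0),
                        start = integer(0), end = integer(0), wrap = logical(0),
                        length = integer(0), stringsAsFactors = FALSE)
      out$alt_starts <- I(list())
      return(out)
    }
    rows <- lapply(keep, function(i) to_genomic(sc$start[i], sc$end[i],
                                                sc$frame[i], sc$alt[[i]]))
    do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  }

  fwd <- scan_strand(d, min_len, start_codes, stop_codes)
  fwd_rows <- collect(fwd, function(s, e, f, alt) {
    gs <- modL(s); ge <- modL(e)
    data.frame(strand = "+", frame = f, start = gs, end = ge,
               wrap = gs > ge, length = e - s + 1L,
               alt_starts = I(list(modL(alt))), stringsAsFactors = FALSE)
  })
  rd <- scan_strand(rev(comp_int(d)), min_len, start_codes, stop_codes)
  rev_rows <- collect(rd, function(s, e, f, alt) {
    # rc-space position r (1..2L) -> genomic L - ((r-1) mod L)
    gmap <- function(r) L - ((r - 1L) %% L)
    gs <- gmap(e); ge <- gmap(s)  # gene runs ge -> gs on '-'
    data.frame(strand = "-", frame = f, start = gs, end = ge,
               wrap = gs > ge, length = e - s + 1L,
               alt_starts = I(list(gmap(alt))), stringsAsFactors = FALSE)
  })
  orfs <- rbind(fwd_rows, rev_rows)
  if (!nrow(orfs)) {
    orfs$contig <- character(0)
    orfs$n_starts <- integer(0)
    return(finish_orfs(orfs, genome))
  }
  # one ORF per (strand, stop codon): stop terminus is end on '+', start on '-'
  stop_key <- paste(orfs$strand, ifelse(orfs$strand == "+", orfs$end, orfs$start))
  ord <- order(stop_key, -orfs$length)
  orfs <- orfs[ord[!duplicated(stop_key[ord])], , drop = FALSE]
  orfs$contig <- genome$id
  orfs$n_starts <- lengths(orfs$alt_starts)
  finish_orfs(orfs, genome)
}

finish_orfs <- function(orfs, genome) {
  if (nrow(orfs)) {
    orfs$seq <- vapply(seq_len(nrow(orfs)), function(i)
      gene_dna(genome, orfs$start[i], orfs$end[i], orfs$strand[i], orfs$wrap[i]),
      "")
    orfs <- orfs[order(orfs$contig, orfs$strand, orfs$end, orfs$start), ,
                 drop = FALSE]
  } else {
    orfs$seq <- character(0)
  }
  rownames(orfs) <- NULL
  orfs[c("contig", "strand", "frame", "start", "end", "length", "wrap",
         "n_starts", "alt_starts", "seq")]
}
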