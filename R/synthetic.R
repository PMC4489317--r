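# Synthetic benchmark data: genomes with planted genes drawn from a biased
# codon-usage table in compositionally distinct intergenic background, plus
# reference-organism fixtures with known ortholog structure and
# essentiality labels.

SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(sort(all3), c("TAA", "TAG", "TGA"))
})

#' Sample a biased codon-usage table
#'
#' Draws probabilities over the 61 sense codons by exponentially tilting
#' the uniform table with Gaussian log-weights: `p proportional to
#' exp(bias * z)` with `z ~ N(0, 1)` fixed by the seed. `bias = 0` gives
#' exactly the uniform table; larger `bias` concentrates the table further
#' from uniform (monotone in Kullback-Leibler divergence for a fixed
#' seed).
#'
#' @param bias_strength Nonnegative concentration parameter.
#' @param seed Integer seed.
#' @return Named numeric vector of 61 probabilities summing to 1.
#' @export
sample_codon_table <- function(bias_strength, seed = 1L) {
  stopifnot(bias_strength >= 0)
  z <- with_seed(seed, stats::rnorm(length(SENSE_CODONS)))
  w <- exp(bias_strength * z)
  stats::setNames(w / sum(w), SENSE_CODONS)
}

#' Generate a synthetic genome with planted genes
#'
#' Plants `n_genes` non-overlapping genes on both strands of an iid
#' intergenic background with the given GC content. Gene interiors are iid
#' draws from a biased codon table ([sample_codon_table()]); every gene
#' begins with an allowed start codon and ends with a stop codon, so each
#' planted gene is a valid candidate ORF. Gene lengths are
#' `min + 3 * Geometric` in nt with the requested mean. Optionally a
#' Shine-Dalgarno motif is written into the intergenic gap upstream of
#' each gene. A configurable fraction of genes is labelled essential for
#' essentiality fixtures. Fully reproducible from the seed.
#'
#' @param length Genome length in nt (default 200000).
#' @param n_genes Number of planted genes (default 150).
#' @param gene_len_min,gene_len_mean Gene length distribution in nt
#'   (defaults 150 and 900; geometric tail above the minimum).
#' @param codon_bias Concentration of the codon table away from uniform
#'   (default 0.5; 0 = no signal).
#' @param intergenic_gc GC fraction of the intergenic background
#'   (default 0.5).
#' @param circular Mark the genome circular (default `FALSE`).
#' @param essential_frac Fraction of genes labelled essential
#'   (default 0.1).
#' @param plant_sd Write the SD motif upstream of each gene? Default
#'   `TRUE`.
#' @param sd_motif,sd_spacer Motif and spacer (nt between motif and start
#'   codon; defaults `"AGGAGG"` and 7).
#' @param contig_id Contig identifier (default `"synth"`).
#' @param codon_table Optional codon probability table over the 61 sense
#'   codons to use instead of sampling one (lets several genomes share a
#'   codon usage).
#' @param seed Integer seed.
#' @return List with `genome` (a [genome_sequence()]), `annotation`
#'   (data.frame `gene_id`, `contig`, `start`, `end`, `strand`,
#'   `essential`) and `codon_table`.
#' @export
synth_genome <- function(length = 200000L, n_genes = 150L,
                         gene_len_min = 150L, gene_len_mean = 900L,
                         codon_bias = 0.5, intergenic_gc = 0.5,
                         circular = FALSE, essential_frac = 0.1,
                         plant_sd = TRUE, sd_motif = "AGGAGG",
                         sd_spacer = 7L, contig_id = "synth",
                         codon_table = NULL, seed = 1L) {
  stopifnot(gene_len_min %% 3L == 0L, gene_len_min >= 15L,
            gene_len_mean >= gene_len_min)
  tab <- codon_table %||% sample_codon_table(codon_bias, seed = seed)
  stopifnot(length(tab) == length(SENSE_CODONS), abs(sum(tab) - 1) < 1e-8)
  with_seed(seed + 1L, {
    extra_codons_mean <- (gene_len_mean - gene_len_min) / 3
    lens <- gene_len_min + 3L * (if (extra_codons_mean > 0)
      stats::rgeom(n_genes, 1 / (1 + extra_codons_mean)) else
        integer(n_genes))
    min_gap <- 30L
    slack <- length - sum(lens) - (n_genes + 1L) * min_gap
    if (slack < 0L) {
      stop("planted genes do not fit in the requested genome length",
           call. = FALSE)
    }
    gaps <- min_gap + drop(stats::rmultinom(1L, slack,
                                            rep(1, n_genes + 1L)))
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    starts_cd <- sample(c("ATG", "GTG", "TTG"), n_genes, replace = TRUE,
                        prob = c(0.8, 0.1, 0.1))
    stops_cd <- sample(c("TAA", "TAG", "TGA"), n_genes, replace = TRUE,
                       prob = c(0.5, 0.2, 0.3))
    gc2 <- intergenic_gc / 2
    bg <- function(n) if (n > 0L)
      paste(sample(BASES, n, replace = TRUE,
                   prob = c(0.5 - gc2, gc2, gc2, 0.5 - gc2)), collapse = "")
      else ""
    gene_seq <- function(i) {
      n_inner <- lens[i] / 3L - 2L
      inner <- paste(sample(SENSE_CODONS, n_inner, replace = TRUE,
                            prob = tab), collapse = "")
      paste0(starts_cd[i], inner, stops_cd[i])
    }
    pieces <- character(2L * n_genes + 1L)
    ann_start <- integer(n_genes); ann_end <- integer(n_genes)
    pos <- 0L
    for (i in seq_len(n_genes)) {
      gap <- bg(gaps[i])
      if (plant_sd) {
        m <- nchar(sd_motif)
        if (strands[i] == "+" && gaps[i] >= sd_spacer + m) {
          substr(gap, gaps[i] - sd_spacer - m + 1L,
                 gaps[i] - sd_spacer) <- sd_motif
        }
      }
      pieces[2L * i - 1L] <- gap
      pos <- pos + gaps[i]
      gs <- gene_seq(i)
      if (strands[i] == "-") gs <- reverse_complement(gs)
      pieces[2L * i] <- gs
      ann_start[i] <- pos + 1L
      ann_end[i] <- pos + lens[i]
      pos <- pos + lens[i]
    }
    last_gap <- bg(gaps[n_genes + 1L])
    pieces[2L * n_genes + 1L] <- last_gap
    # SD motifs for '-' strand genes live in the gap to their right
    seq <- paste(pieces, collapse = "")
    if (plant_sd) {
      m <- nchar(sd_motif)
      rc_motif <- reverse_complement(sd_motif)
      for (i in which(strands == "-")) {
        from <- ann_end[i] + sd_spacer + 1L
        if (from + m - 1L <= nchar(seq) &&
            (i == n_genes || from + m - 1L < ann_start[i + 1L] - 0L)) {
          substr(seq, from, from + m - 1L) <- rc_motif
        }
      }
    }
    essential <- rep(FALSE, n_genes)
    essential[sample(n_genes, round(essential_frac * n_genes))] <- TRUE
    ann <- data.frame(gene_id = sprintf("planted_%04d", seq_len(n_genes)),
                      contig = contig_id, start = ann_start, end = ann_end,
                      strand = strands, essential = essential,
                      stringsAsFactors = FALSE)
    list(genome = genome_sequence(contig_id, seq, circular = circular),
         annotation = ann, codon_table = tab)
  })
}

#' Planted-gene protein sequences of a synthetic genome
#'
#' @param synth Result of [synth_genome()].
#' @return Named character vector of conceptual translations (genetic code
#'   11), names = planted gene ids.
#' @export
synth_proteins <- function(synth) {
  ann <- synth$annotation
  dna <- vapply(seq_len(nrow(ann)), function(i)
    gene_dna(synth$genome, ann$start[i], ann$end[i], ann$strand[i]), "")
  stats::setNames(translate_genes(dna), ann$gene_id)
}

#' Generate a synthetic reference-organism set
#'
#' Builds reference organisms whose ortholog evidence against a set of
#' labelled query genes follows a Bernoulli design: for each query gene and
#' each reference, the reference carries an ortholog under the query's id;
#' the ortholog is labelled essential with probability
#' `p_essential_hit` when the query is truly essential and
#' `p_nonessential_hit` otherwise. With [matcher_id()] this reproduces the
#' intended hit pattern exactly.
#'
#' @param truth_essential Named logical vector over query gene ids.
#' @param n_refs Number of reference organisms (default 5).
#' @param p_essential_hit,p_nonessential_hit Bernoulli probabilities
#'   (defaults 0.9 and 0.1).
#' @param distances Numeric vector of evolutionary distances, recycled to
#'   `n_refs` (default all 1).
#' @param seed Integer seed.
#' @return List of [reference_organism()] objects.
#' @export
synth_reference_set <- function(truth_essential, n_refs = 5L,
                                p_essential_hit = 0.9,
                                p_nonessential_hit = 0.1,
                                distances = 1, seed = 1L) {
  stopifnot(p_essential_hit >= 0, p_essential_hit <= 1,
            p_nonessential_hit >= 0, p_nonessential_hit <= 1,
            n_refs >= 1L)
  distances <- rep_len(distances, n_refs)
  ids <- names(truth_essential)
  with_seed(seed, {
    lapply(seq_len(n_refs), function(r) {
      p <- ifelse(truth_essential, p_essential_hit, p_nonessential_hit)
      ess <- stats::runif(length(ids)) < p
      reference_organism(sprintf("ref_%02d", r),
                         proteome = stats::setNames(rep("M", length(ids)), ids),
                         essential_ids = ids[ess],
                         distance = distances[r])
    })
  })
}

#' Length-matched null ORF set
#'
#' Draws stop-free ORF-like sequences (start codon, iid uniform sense
#' codons, stop codon) of prescribed lengths. Because candidate ORFs are
#' stop-free by definition, these -- not base-shuffles, which reintroduce
#' in-frame stops -- are the correct null for measuring codon-usage signal
#' in classifier scores.
#'
#' @param lengths Integer vector of ORF lengths in nt (divisible by 3,
#'   >= 15).
#' @param seed Integer seed.
#' @return Character vector of sequences.
#' @export
null_orf_set <- function(lengths, seed = 1L) {
  stopifnot(all(lengths %% 3L == 0L), all(lengths >= 15L))
  with_seed(seed, {
    vapply(lengths, function(L) {
      paste0(sample(c("ATG", "GTG", "TTG"), 1L, prob = c(0.8, 0.1, 0.1)),
             paste(sample(SENSE_CODONS, L / 3L - 2L, replace = TRUE),
                   collapse = ""),
             sample(c("TAA", "TAG", "TGA"), 1L, prob = c(0.5, 0.2, 0.3)))
    }, "")
  })
}

#' Gene DNA sequences of a synthetic genome's planted genes
#'
#' @param synth Result of [synth_genome()].
#' @return Named character vector of gene DNA (5'->3').
#' @export
synth_gene_dna <- function(synth) {
  ann <- synth$annotation
  stats::setNames(vapply(seq_len(nrow(ann)), function(i)
    gene_dna(synth$genome, ann$start[i], ann$end[i], ann$strand[i]), ""),
    ann$gene_id)
}
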