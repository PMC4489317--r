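# The gene-calling pipeline: ORF enumeration -> encoding -> scoring ->
# overlap resolution -> start relocation.

#' Call protein-coding genes in a prokaryotic genome
#'
#' The main fitting function. For a genome (or a set of draft contigs) it
#' enumerates candidate ORFs in all six frames, builds genome-specific
#' training sets by self-training (long-ORF seeds vs shuffled and shadow
#' negatives), fits a linear max-margin classifier on the Z-curve encoding,
#' scores every canonical ORF, resolves overlaps greedily by score, and
#' relocates translation starts among the in-frame candidates using the
#' coding score plus a Shine-Dalgarno motif term. The whole run is
#' deterministic given `seed`.
#'
#' @param genomes A [genome_sequence()] record, a list of them, or a path
#'   to a FASTA file.
#' @param min_orf_len Minimum ORF length in nt including the stop codon
#'   (default 90).
#' @param start_codons,stop_codons Codon sets (genetic code 11 defaults).
#' @param seed_min_len Seed length for self-training positives (default
#'   480 nt).
#' @param negative_policy Negative-set policy, see [build_training_sets()].
#' @param encoding `"z765"` (default) or the legacy `"z33"`.
#' @param cost Soft-margin cost C (default 1).
#' @param threshold Decision cutoff on the signed coding score (default 0).
#' @param max_overlap Maximum tolerated overlap between retained genes in
#'   nt (default 30).
#' @param relocate Relocate translation starts? Default `TRUE`.
#' @param sd_motif Shine-Dalgarno motif for start relocation (default
#'   `"AGGAGG"`).
#' @param sd_weight Weight of the SD term relative to the coding score;
#'   `NULL` (default) picks it so the two terms have comparable spread.
#' @param self_train_iterations Self-training refinement passes: confident
#'   calls of the current model become the next training sets (default 1).
#' @param min_positives Minimum acceptable number of seed positives
#'   (default 50), see [build_training_sets()].
#' @param seed Integer seed driving all randomness (default 1).
#' @param circular Logical, recycled: marks contigs circular when `genomes`
#'   is a path.
#' @return An object of class `zgene`: list with `predictions` (data.frame
#'   sorted by contig and start: `gene_id`, `contig`, `strand`, `frame`,
#'   `start`, `end`, `length`, `wrap`, `coding_score`, `start_relocated`),
#'   `model` (the fitted `zgene_model`), `training` (seed-set summary),
#'   `orf_scores` (scores of all candidate ORFs), `config` and `call`.
#' @seealso [predict.zgene()], [score_gene_essentiality()],
#'   [write_gene_outputs()]
#' @export
zgene <- function(genomes, min_orf_len = 90L,
                  start_codons = CODE11_STARTS, stop_codons = CODE11_STOPS,
                  seed_min_len = 480L,
                  negative_policy = "shuffle+shadow",
                  encoding = c("z765", "z33"), cost = 1, threshold = 0,
                  max_overlap = 30L, relocate = TRUE, sd_motif = "AGGAGG",
                  sd_weight = NULL, self_train_iterations = 1L,
                  min_positives = 50L, seed = 1L, circular = FALSE) {
  encoding <- match.arg(encoding)
  cl <- match.call()
  if (is.character(genomes)) genomes <- read_genome_fasta(genomes, circular)
  genomes <- as_genome_list(genomes)

  orfs <- do.call(rbind, lapply(genomes, extract_orfs, min_len = min_orf_len,
                                start_codons = start_codons,
                                stop_codons = stop_codons))
  rownames(orfs) <- NULL
  config <- list(min_orf_len = min_orf_len, start_codons = start_codons,
                 stop_codons = stop_codons, seed_min_len = seed_min_len,
                 negative_policy = negative_policy, encoding = encoding,
                 cost = cost, threshold = threshold,
                 max_overlap = max_overlap, relocate = relocate,
                 sd_motif = sd_motif, sd_weight = sd_weight, seed = seed)

  if (!nrow(orfs)) {
    return(new_zgene(empty_predictions(), NULL, NULL, numeric(0), config, cl,
                     genomes))
  }

  sets <- build_training_sets(orfs, seed_min_len = seed_min_len,
                              negative_policy = negative_policy,
                              max_overlap = max_overlap,
                              min_positives = min_positives, seed = seed)
  model <- train_coding_model(sets, encoding = encoding, cost = cost,
                              threshold = threshold)
  if (self_train_iterations > 0L) {
    model <- retrain_iteration(model, orfs$seq, iterations = self_train_iterations)
  }

  scores <- score_orfs(model, encode_matrix(orfs$seq, encoding))
  orfs$coding_score <- scores
  called <- orfs[scores > threshold, , drop = FALSE]
  called <- resolve_overlaps(called, max_overlap = max_overlap)

  if (relocate && nrow(called)) {
    if (is.null(sd_weight)) {
      spread <- stats::sd(called$coding_score)
      sd_weight <- if (is.finite(spread) && spread > 0)
        spread / nchar(sd_motif) else 1 / nchar(sd_motif)
      config$sd_weight <- sd_weight
    }
    called <- relocate_starts(called, genomes, model, sd_motif = sd_motif,
                              sd_weight = sd_weight)
  } else {
    called$start_relocated <- logical(nrow(called))
  }

  preds <- called[order(called$contig, called$start), , drop = FALSE]
  preds$gene_id <- sprintf("gene_%04d", seq_len(nrow(preds)))
  preds <- preds[c("gene_id", "contig", "strand", "frame", "start", "end",
                   "length", "wrap", "coding_score", "start_relocated")]
  rownames(preds) <- NULL
  new_zgene(preds, model, sets, scores, config, cl, genomes)
}

new_zgene <- function(predictions, model, training, orf_scores, config, call,
                      genomes) {
  structure(list(predictions = predictions, model = model,
                 training = if (is.null(training)) NULL else
                   list(n_positives = length(training$positives),
                        n_negatives = length(training$negatives),
                        provenance = table(training$provenance$negatives)),
                 orf_scores = orf_scores, config = config, call = call,
                 genomes = genomes),
            class = "zgene")
}

empty_predictions <- function() {
  data.frame(gene_id = character(0), contig = character(0),
             strand = character(0), frame = integer(0), start = integer(0),
             end = integer(0), length = integer(0), wrap = logical(0),
             coding_score = numeric(0), start_relocated = logical(0),
             stringsAsFactors = FALSE)
}

#' Resolve overlapping scored ORFs greedily
#'
#' Retains candidates in order of descending coding score (ties broken by
#' longer length, then leftmost start); a candidate is dropped when it
#' overlaps an already-retained gene on either strand by more than
#' `max_overlap` nt.
#'
#' @param scored_orfs ORF data.frame carrying a `coding_score` column.
#' @param max_overlap Overlap cap in nt (default 30).
#' @return The retained subset, original columns preserved.
#' @export
resolve_overlaps <- function(scored_orfs, max_overlap = 30L) {
  n <- nrow(scored_orfs)
  if (n <= 1L) return(scored_orfs)
  ord <- order(-scored_orfs$coding_score, -scored_orfs$length,
               scored_orfs$start)
  o <- scored_orfs[ord, , drop = FALSE]
  if (is.null(o$wrap)) o$wrap <- FALSE
  # origin-wrapping genes contribute two genomic intervals
  iv_start1 <- o$start; iv_end1 <- ifelse(o$wrap, .Machine$integer.max, o$end)
  iv_start2 <- ifelse(o$wrap, 1L, NA_integer_); iv_end2 <- ifelse(o$wrap, o$end, NA_integer_)
  keep <- logical(n)
  ks1 <- ke1 <- ks2 <- ke2 <- integer(0); kc <- character(0)
  for (i in seq_len(n)) {
    same <- kc == o$contig[i]
    ov <- 0L
    if (any(same)) {
      ovl <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
      ov <- max(ovl(iv_start1[i], iv_end1[i], ks1[same], ke1[same]),
                if (!is.na(iv_start2[i]))
                  max(ovl(iv_start2[i], iv_end2[i], ks1[same], ke1[same])) else 0L,
                if (any(!is.na(ks2[same])))
                  max(ovl(iv_start1[i], iv_end1[i], ks2[same], ke2[same]),
                      na.rm = TRUE) else 0L)
    }
    if (ov <= max_overlap) {
      keep[i] <- TRUE
      ks1 <- c(ks1, iv_start1[i]); ke1 <- c(ke1, iv_end1[i])
      ks2 <- c(ks2, iv_start2[i]); ke2 <- c(ke2, iv_end2[i])
      kc <- c(kc, o$contig[i])
    }
  }
  o[keep, , drop = FALSE]
}

# Ungapped best match of the SD motif against the region 5-13 nt upstream
# of a candidate start (gene orientation); score = identities (0..nchar).
sd_score <- function(genome, start_coord, strand, sd_motif) {
  m <- nchar(sd_motif)
  motif <- utf8ToInt(sd_motif)
  L <- genome$length
  best <- 0L
  for (spacer in 5:13) {
    if (strand == "+") {
      to <- start_coord - spacer - 1L
      from <- to - m + 1L
      if (from < 1L) {
        if (!genome$circular) next
        from <- from + L; to <- to + L
        win <- paste0(substr(genome$seq, from, L), substr(genome$seq, 1L, to - L))
      } else win <- substr(genome$seq, from, to)
    } else {
      from <- start_coord + spacer + 1L
      to <- from + m - 1L
      if (to > L) {
        if (!genome$circular) next
        win <- reverse_complement(paste0(substr(genome$seq, from, L),
                                         substr(genome$seq, 1L, to - L)))
      } else win <- reverse_complement(substr(genome$seq, from, to))
    }
    if (nchar(win) != m) next
    best <- max(best, sum(utf8ToInt(win) == motif))
  }
  best
}

#' Relocate translation starts
#'
#' For each prediction with more than one in-frame candidate start, choose
#' the start maximising `coding_score(truncated ORF) + sd_weight * SD`,
#' where `SD` is the best ungapped identity count of the Shine-Dalgarno
#' motif within a 5-13 nt upstream spacer window. The 3' terminus (stop
#' codon) is never changed; ties keep the longer (more upstream) start.
#'
#' @param predictions Prediction/ORF data.frame carrying `alt_starts`.
#' @param genomes Genome record or list covering all contigs.
#' @param model Fitted `zgene_model` used to score truncated ORFs.
#' @param sd_motif Motif string (default `"AGGAGG"`).
#' @param sd_weight Weight of the SD identity count (default 1).
#' @return The data.frame with updated `start`/`end`, `length`, recomputed
#'   `coding_score` and a logical `start_relocated` column.
#' @export
relocate_starts <- function(predictions, genomes, model, sd_motif = "AGGAGG",
                            sd_weight = 1) {
  genomes <- as_genome_list(genomes)
  p <- predictions
  p$start_relocated <- FALSE
  if (!nrow(p)) return(p)
  for (i in seq_len(nrow(p))) {
    cand <- p$alt_starts[[i]]
    if (length(cand) <= 1L || p$wrap[i]) next
    g <- genomes[[p$contig[i]]]
    # candidate values of the gene 5' coordinate; longest first for ties
    cand <- if (p$strand[i] == "+") sort(cand) else sort(cand, decreasing = TRUE)
    seqs <- vapply(cand, function(s5) {
      if (p$strand[i] == "+") gene_dna(g, s5, p$end[i], "+")
      else gene_dna(g, p$start[i], s5, "-")
    }, "")
    long_enough <- nchar(seqs) >= 15L
    if (!any(long_enough)) next
    cand <- cand[long_enough]; seqs <- seqs[long_enough]
    cod <- score_orfs(model, encode_matrix(seqs, model$encoding))
    # never relocate onto a start whose truncated ORF fails the coding cutoff
    viable <- cod > model$threshold
    if (any(viable)) {
      cand <- cand[viable]; seqs <- seqs[viable]; cod <- cod[viable]
    }
    sdv <- vapply(cand, function(s5) sd_score(g, s5, p$strand[i], sd_motif), 0L)
    total <- cod + sd_weight * sdv
    j <- which.max(total)  # first maximum = longest start on ties
    s5 <- cand[j]
    old5 <- if (p$strand[i] == "+") p$start[i] else p$end[i]
    if (s5 != old5) {
      if (p$strand[i] == "+") p$start[i] <- s5 else p$end[i] <- s5
      p$length[i] <- p$end[i] - p$start[i] + 1L
      p$coding_score[i] <- cod[j]
      p$start_relocated[i] <- TRUE
    }
  }
  p
}

#' @export
print.zgene <- function(x, ...) {
  cat(sprintf("<zgene> %d predicted genes on %d contig(s), %s encoding\n",
              nrow(x$predictions), length(x$genomes),
              x$config$encoding))
  if (!is.null(x$training)) {
    cat(sprintf("  self-training: %d positives, %d negatives\n",
                x$training$n_positives, x$training$n_negatives))
  }
  invisible(x)
}

#' @method summary zgene
#' @export
summary.zgene <- function(object, ...) {
  p <- object$predictions
  cat(sprintf("Z-curve gene finder fit (%s encoding)\n",
              object$config$encoding))
  cat(sprintf("Contigs: %d (%s nt total)\n", length(object$genomes),
              format(sum(vapply(object$genomes, `[[`, 0L, "length")),
                     big.mark = ",")))
  if (!is.null(object$training)) {
    cat(sprintf("Training: %d long-ORF positives, %d negatives; separation %.1f%%\n",
                object$training$n_positives, object$training$n_negatives,
                100 * object$model$train_accuracy))
  }
  cat(sprintf("Candidate ORFs scored: %d; called genes: %d (threshold %g)\n",
              length(object$orf_scores), nrow(p), object$config$threshold))
  if (nrow(p)) {
    cat(sprintf("Gene length: median %d nt (range %d-%d)\n",
                as.integer(stats::median(p$length)), min(p$length),
                max(p$length)))
    cat(sprintf("Starts relocated: %d; strand +/-: %d/%d\n",
                sum(p$start_relocated), sum(p$strand == "+"),
                sum(p$strand == "-")))
  }
  invisible(object)
}

#' Model coefficients of a gene-finder fit
#'
#' @param object A `zgene` fit.
#' @param ... Unused.
#' @return Named numeric vector: decision-function weights plus `(bias)`.
#' @method coef zgene
#' @export
coef.zgene <- function(object, ...) {
  if (is.null(object$model)) return(numeric(0))
  w <- object$model$weights
  names(w) <- paste0("w", seq_along(w))
  c(w, "(bias)" = object$model$bias)
}

#' Score new sequences or genomes with a fitted gene finder
#'
#' With `newdata` a character vector of ORF sequences, returns their signed
#' coding scores. With `newdata` a genome (or list/FASTA path), runs the
#' full calling pipeline on it using the already-fitted model (no
#' retraining) and returns a prediction data.frame.
#'
#' @param object A `zgene` fit.
#' @param newdata ORF sequences, genome record(s), or FASTA path. Omitted:
#'   returns the fit's own predictions.
#' @param ... Unused.
#' @export
predict.zgene <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$predictions)
  if (is.character(newdata) && !any(file.exists(newdata))) {
    return(score_orfs(object$model,
                      encode_matrix(newdata, object$model$encoding)))
  }
  if (is.character(newdata)) newdata <- read_genome_fasta(newdata)
  genomes <- as_genome_list(newdata)
  cfg <- object$config
  orfs <- do.call(rbind, lapply(genomes, extract_orfs,
                                min_len = cfg$min_orf_len,
                                start_codons = cfg$start_codons,
                                stop_codons = cfg$stop_codons))
  if (!nrow(orfs)) return(empty_predictions())
  orfs$coding_score <- score_orfs(object$model,
                                  encode_matrix(orfs$seq, cfg$encoding))
  called <- orfs[orfs$coding_score > cfg$threshold, , drop = FALSE]
  called <- resolve_overlaps(called, max_overlap = cfg$max_overlap)
  called$start_relocated <- FALSE
  preds <- called[order(called$contig, called$start), , drop = FALSE]
  if (nrow(preds)) preds$gene_id <- sprintf("gene_%04d", seq_len(nrow(preds)))
  else preds$gene_id <- character(0)
  preds <- preds[c("gene_id", "contig", "strand", "frame", "start", "end",
                   "length", "wrap", "coding_score", "start_relocated")]
  rownames(preds) <- NULL
  preds
}

#' Plot the coding-score distribution of a fit
#'
#' Histogram of the signed coding scores of all candidate ORFs with the
#' decision threshold marked; called genes sit to the right.
#'
#' @param x A `zgene` fit.
#' @param ... Passed to [graphics::hist()].
#' @method plot zgene
#' @export
plot.zgene <- function(x, ...) {
  sc <- x$orf_scores
  graphics::hist(sc, breaks = 60, col = "grey80", border = "grey40",
                 main = "Candidate ORF coding scores",
                 xlab = "signed decision score", ...)
  graphics::abline(v = x$config$threshold, col = "red3", lwd = 2)
  graphics::legend("topright", legend = sprintf("threshold = %g",
                                                x$config$threshold),
                   lty = 1, lwd = 2, col = "red3", bty = "n")
  invisible(x)
}
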