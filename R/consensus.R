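# Joint application of two gene finders: retain shared predictions, pass
# program-specific ones through a homology-confirmation hook.

dedup_by_stop <- function(df, label) {
  k <- stop_key(df)
  if (anyDuplicated(k)) {
    warning(sprintf("duplicate 3' termini in %s; keeping higher-score/longer form",
                    label), call. = FALSE)
    score <- if (!is.null(df$coding_score)) df$coding_score else rep(0, nrow(df))
    len <- df$end - df$start + 1L
    ord <- order(k, -score, -len)
    df <- df[ord[!duplicated(k[ord])], , drop = FALSE]
  }
  df
}

#' Split two prediction sets into shared and program-specific genes
#'
#' Two predictions agree when they share contig, strand and 3' terminus
#' (the same matching rule as the evaluation statistics); starts may
#' differ. The three parts partition the union of distinct 3' termini
#' exactly.
#'
#' @param set_a,set_b Prediction data.frames (`contig`, `strand`, `start`,
#'   `end`, optionally `coding_score`).
#' @return List with `shared` (rows of `set_a` whose terminus also occurs
#'   in `set_b`), `a_specific`, `b_specific`.
#' @export
split_predictions <- function(set_a, set_b) {
  set_a <- dedup_by_stop(set_a, "set_a")
  set_b <- dedup_by_stop(set_b, "set_b")
  ka <- stop_key(set_a); kb <- stop_key(set_b)
  list(shared = set_a[ka %in% kb, , drop = FALSE],
       a_specific = set_a[!(ka %in% kb), , drop = FALSE],
       b_specific = set_b[!(kb %in% ka), , drop = FALSE])
}

#' Confirm program-specific predictions with a homology hook
#'
#' The hook abstracts a homology search (e.g. a BLAST of each gene against
#' a protein database excluding the query's own taxon): any predicate that
#' maps a gene's DNA sequence to `TRUE` (hit in another species) or
#' `FALSE`. Predictions for which the oracle errors are marked unresolved,
#' excluded from the confirmed set and reported with a warning.
#'
#' @param specific Prediction data.frame; sequences are taken from a `seq`
#'   column, or extracted from `genomes` when provided.
#' @param homology_oracle Function `(seq, exclude_taxon) -> logical`.
#' @param genomes Optional genome record/list to extract sequences from.
#' @param exclude_taxon Optional taxon label forwarded to the oracle
#'   (self-exclusion when simulating an anonymous genome).
#' @return The confirmed subset, with an added logical `unresolved` column
#'   on the input (attribute `"unresolved"` lists unresolved row indices).
#' @export
confirm_specific <- function(specific, homology_oracle, genomes = NULL,
                             exclude_taxon = NULL) {
  if (!nrow(specific)) return(specific)
  seqs <- if (!is.null(specific$seq)) {
    specific$seq
  } else {
    stopifnot(!is.null(genomes))
    genomes <- as_genome_list(genomes)
    wrap <- if (is.null(specific$wrap)) rep(FALSE, nrow(specific)) else specific$wrap
    vapply(seq_len(nrow(specific)), function(i)
      gene_dna(genomes[[specific$contig[i]]], specific$start[i],
               specific$end[i], specific$strand[i], wrap[i]), "")
  }
  confirmed <- logical(length(seqs))
  unresolved <- integer(0)
  for (i in seq_along(seqs)) {
    res <- tryCatch(isTRUE(homology_oracle(seqs[i], exclude_taxon)),
                    error = function(e) NA)
    if (is.na(res)) {
      unresolved <- c(unresolved, i)
      confirmed[i] <- FALSE
    } else confirmed[i] <- res
  }
  if (length(unresolved)) {
    warning(sprintf("homology oracle failed on %d gene(s); marked unresolved",
                    length(unresolved)), call. = FALSE)
  }
  out <- specific[confirmed, , drop = FALSE]
  attr(out, "unresolved") <- unresolved
  out
}

#' Combine two prediction sets (joint-application pipeline)
#'
#' Shared predictions (same contig, strand and 3' terminus) are retained
#' directly; program-specific predictions are retained only when the
#' homology oracle confirms them. The aim is more true genes with fewer
#' additional predictions than either input alone.
#'
#' @inheritParams split_predictions
#' @inheritParams confirm_specific
#' @return List with `combined` (final prediction data.frame) and `report`
#'   (counts per category: shared, specific and confirmed-specific per
#'   input).
#' @export
combine_predictions <- function(set_a, set_b, homology_oracle,
                                genomes = NULL, exclude_taxon = NULL) {
  parts <- split_predictions(set_a, set_b)
  conf_a <- confirm_specific(parts$a_specific, homology_oracle, genomes,
                             exclude_taxon)
  conf_b <- confirm_specific(parts$b_specific, homology_oracle, genomes,
                             exclude_taxon)
  common <- intersect(intersect(names(parts$shared), names(conf_a)),
                      names(conf_b))
  combined <- rbind(parts$shared[common], conf_a[common], conf_b[common])
  combined <- combined[order(combined$contig, combined$start), , drop = FALSE]
  rownames(combined) <- NULL
  list(combined = combined,
       report = list(n_shared = nrow(parts$shared),
                     n_a_specific = nrow(parts$a_specific),
                     n_b_specific = nrow(parts$b_specific),
                     n_a_confirmed = nrow(conf_a),
                     n_b_confirmed = nrow(conf_b),
                     n_combined = nrow(combined),
                     n_union = nrow(parts$shared) + nrow(parts$a_specific) +
                       nrow(parts$b_specific)))
}
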