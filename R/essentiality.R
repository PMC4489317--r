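# Distance-weighted ortholog-evidence scoring of gene essentiality across
# reference organisms, and thresholded essential/nonessential calls.

#' Construct a reference organism
#'
#' A reference organism carries a proteome, the subset of its gene ids
#' known to be essential, and its evolutionary distance to the query
#' organism (used to weight its evidence).
#'
#' @param id Organism identifier.
#' @param proteome Named character vector: gene id -> amino-acid sequence.
#' @param essential_ids Character vector, subset of the proteome's ids.
#' @param distance Nonnegative finite evolutionary distance to the query.
#' @return Object of class `zgene_reference`.
#' @export
reference_organism <- function(id, proteome, essential_ids, distance) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!all(essential_ids %in% names(proteome))) {
    stop("essential_ids must be a subset of proteome ids", call. = FALSE)
  }
  if (!is.finite(distance) || distance < 0) {
    stop("distance must be finite and >= 0", call. = FALSE)
  }
  structure(list(id = id, proteome = proteome,
                 essential_ids = essential_ids, distance = distance),
            class = "zgene_reference")
}

#' Load a reference-organism set from a directory
#'
#' Expects, per organism `X`: `X.faa` (FASTA proteome) and `X.tsv` (two
#' columns: gene id, essential flag 0/1), plus one `distances.tsv` (two
#' columns: organism id, distance).
#'
#' @param dir Directory path.
#' @return List of [reference_organism()] objects.
#' @export
read_reference_set <- function(dir) {
  dist_file <- file.path(dir, "distances.tsv")
  if (!file.exists(dist_file)) stop("missing ", dist_file, call. = FALSE)
  dists <- utils::read.table(dist_file, sep = "\t", header = FALSE,
                             col.names = c("id", "distance"),
                             stringsAsFactors = FALSE)
  lapply(seq_len(nrow(dists)), function(i) {
    org <- dists$id[i]
    aa <- Biostrings::readAAStringSet(file.path(dir, paste0(org, ".faa")))
    proteome <- stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
    ess <- utils::read.table(file.path(dir, paste0(org, ".tsv")), sep = "\t",
                             header = FALSE, col.names = c("id", "essential"),
                             stringsAsFactors = FALSE)
    reference_organism(org, proteome, ess$id[ess$essential != 0],
                       dists$distance[i])
  })
}

#' Exact-identifier ortholog matcher
#'
#' Fixture-grade matcher: the query protein's `id` attribute (or name) is
#' looked up in the reference proteome. Useful for tests and synthetic
#' reference sets where ortholog structure is encoded in shared ids.
#'
#' @param query Named/attributed protein sequence (see
#'   [ortholog_presence()]).
#' @param reference A `zgene_reference`.
#' @return The matched reference gene id, or `NA_character_`.
#' @export
matcher_id <- function(query, reference) {
  id <- attr(query, "id") %||% names(query)
  if (!is.null(id) && id %in% names(reference$proteome)) id else NA_character_
}

#' Reciprocal-best-hit ortholog matcher
#'
#' Scores the query against every reference protein by global pairwise
#' alignment (BLOSUM62, affine gaps) and accepts the best hit only if the
#' hit's own best match among the supplied query proteins is the query
#' (reciprocity). Quadratic in proteome size; intended for the small
#' reference sets this module works with.
#'
#' @param query_set Named character vector of all query proteins (the
#'   reciprocity universe).
#' @return A matcher function `(query, reference) -> reference id or NA`.
#' @export
matcher_rbh <- function(query_set) {
  align_score <- function(a, b) {
    Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                  Biostrings::AAString(b),
                                  substitutionMatrix = "BLOSUM62",
                                  gapOpening = 10, gapExtension = 0.5,
                                  scoreOnly = TRUE)
  }
  function(query, reference) {
    qid <- attr(query, "id") %||% names(query)
    qseq <- as.character(query)
    if (!length(reference$proteome)) return(NA_character_)
    fwd <- vapply(reference$proteome, function(s) align_score(qseq, s), 0)
    best_ref <- names(which.max(fwd))
    back <- vapply(query_set, function(s)
      align_score(reference$proteome[[best_ref]], s), 0)
    if (names(which.max(back)) == qid) best_ref else NA_character_
  }
}

#' Ortholog presence category of one query protein in one reference
#'
#' Applies the pluggable matcher; a match whose reference gene is in the
#' reference's essential set is an `essential_hit`, any other match a
#' `nonessential_hit`, no match (or matcher failure, which is logged) a
#' `no_hit`.
#'
#' @param query Protein sequence, carrying its id as the `id` attribute or
#'   as its name.
#' @param reference A `zgene_reference`.
#' @param matcher Function `(query, reference) -> reference gene id or NA`
#'   (default [matcher_id()]).
#' @return One of `"essential_hit"`, `"nonessential_hit"`, `"no_hit"`.
#' @export
ortholog_presence <- function(query, reference, matcher = matcher_id) {
  hit <- tryCatch(matcher(query, reference), error = function(e) {
    warning("matcher failed (", conditionMessage(e), "); treating as no_hit",
            call. = FALSE)
    NA_character_
  })
  if (is.na(hit) || !nzchar(hit)) return("no_hit")
  if (hit %in% reference$essential_ids) "essential_hit" else "nonessential_hit"
}

#' Distance-weighted essentiality scores
#'
#' For each query protein, evidence from every reference organism is the
#' indicator of an `essential_hit`; the score is the weighted mean
#' `sum(w_i e_i) / sum(w_i)` with weights from `weight_fn` applied to the
#' reference distances (default `exp(-d)`). By construction the score is a
#' convex combination of 0/1 evidence and lies in `[0, 1]`.
#'
#' @param queries Named character vector of query protein sequences.
#' @param references List of `zgene_reference` objects (at least one).
#' @param weight_fn Distance-to-weight function, nonnegative (default
#'   `function(d) exp(-d)`).
#' @param matcher Ortholog matcher, see [ortholog_presence()].
#' @return Named numeric vector of scores in `[0, 1]`.
#' @export
essentiality_scores <- function(queries, references,
                                weight_fn = function(d) exp(-d),
                                matcher = matcher_id) {
  if (!length(references)) stop("at least one reference organism required",
                                call. = FALSE)
  w <- vapply(references, function(r) weight_fn(r$distance), 0)
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (sum(w) == 0) stop("all reference weights are zero", call. = FALSE)
  ids <- names(queries)
  out <- vapply(seq_along(queries), function(i) {
    q <- structure(queries[[i]], id = ids[[i]])
    e <- vapply(references, function(r)
      as.numeric(ortholog_presence(q, r, matcher) == "essential_hit"), 0)
    sum(w * e) / sum(w)
  }, 0)
  stats::setNames(out, ids)
}

#' Threshold essentiality scores into calls
#'
#' @param scores Named numeric vector in `[0, 1]`.
#' @param cutoff Scores `>= cutoff` are called essential; must lie in
#'   `[0, 1]` (default 0.5).
#' @return Data.frame with `gene_id`, `score`, `call` (`"essential"` /
#'   `"nonessential"`).
#' @export
classify_essentiality <- function(scores, cutoff = 0.5) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 || cutoff > 1) {
    stop("cutoff must be a single value in [0, 1]", call. = FALSE)
  }
  data.frame(gene_id = names(scores), score = unname(scores),
             call = ifelse(scores >= cutoff, "essential", "nonessential"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Post-score a gene-finder fit for essentiality
#'
#' Translates the predicted genes and scores each against the reference
#' set, attaching `essentiality_score` and `essential_call` columns to the
#' fit's predictions.
#'
#' @param fit A `zgene` fit.
#' @param references List of `zgene_reference` objects.
#' @param cutoff Call cutoff in `[0, 1]` (default 0.5).
#' @inheritParams essentiality_scores
#' @return The fit with augmented `$predictions`.
#' @export
score_gene_essentiality <- function(fit, references, cutoff = 0.5,
                                    weight_fn = function(d) exp(-d),
                                    matcher = matcher_id) {
  stopifnot(inherits(fit, "zgene"))
  p <- fit$predictions
  if (!nrow(p)) return(fit)
  if (is.null(p$wrap)) p$wrap <- FALSE
  dna <- vapply(seq_len(nrow(p)), function(i)
    gene_dna(fit$genomes[[p$contig[i]]], p$start[i], p$end[i], p$strand[i],
             p$wrap[i]), "")
  prot <- stats::setNames(translate_genes(dna), p$gene_id)
  sc <- essentiality_scores(prot, references, weight_fn, matcher)
  calls <- classify_essentiality(sc, cutoff)
  p$essentiality_score <- calls$score
  p$essential_call <- calls$call
  fit$predictions <- p
  fit
}
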