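# Evaluation statistics for coding prediction (Sn, PPV, Accuracy, APR) and
# essentiality prediction (OA, Sn, Sp), with the 3'-terminus matching rule.

stop_key <- function(df) {
  stop_coord <- ifelse(df$strand == "+", df$end, df$start)
  paste(df$contig, df$strand, stop_coord, sep = "|")
}

#' Match predictions to annotation by 3' terminus
#'
#' A prediction is correct iff it shares an annotated gene's stop-codon
#' terminus -- same contig, same strand, same 3' coordinate (the `end` on
#' the forward strand, the `start` on the reverse strand). Start positions
#' are deliberately ignored. Duplicate stop keys within one table are
#' de-duplicated (first kept) with a warning.
#'
#' @param predicted,annotated Data.frames with columns `contig`, `strand`,
#'   `start`, `end` in the 1-based inclusive output convention.
#' @return List with `matched` (data.frame of paired row indices
#'   `pred_row`, `ann_row` and the shared `key`), `pred_only` and
#'   `ann_only` (row indices).
#' @export
match_by_stop <- function(predicted, annotated) {
  pk <- stop_key(predicted)
  ak <- stop_key(annotated)
  if (anyDuplicated(pk)) {
    warning("duplicate 3' termini in predictions; keeping first of each",
            call. = FALSE)
  }
  if (anyDuplicated(ak)) {
    warning("duplicate 3' termini in annotation; keeping first of each",
            call. = FALSE)
  }
  pi_ <- which(!duplicated(pk)); ai <- which(!duplicated(ak))
  m <- match(pk[pi_], ak[ai])
  hit <- !is.na(m)
  list(matched = data.frame(pred_row = pi_[hit], ann_row = ai[m[hit]],
                            key = pk[pi_][hit], stringsAsFactors = FALSE),
       pred_only = pi_[!hit],
       ann_only = setdiff(ai, ai[m[hit]]))
}

#' Accuracy as the midpoint of sensitivity and precision
#'
#' The summary accuracy used for coding prediction: because true negatives
#' cannot be counted in this setting, accuracy is defined as
#' `(Sn + PPV) / 2` rather than via specificity.
#'
#' @param sn,ppv Sensitivity and precision, each in `[0, 1]`.
#' @return `(sn + ppv) / 2`.
#' @export
coding_accuracy <- function(sn, ppv) {
  stopifnot(all(sn >= 0 & sn <= 1), all(ppv >= 0 & ppv <= 1))
  (sn + ppv) / 2
}

coding_stats <- function(n_correct, n_annotated, n_predicted) {
  if (n_annotated == 0L) stop("no annotated genes: statistics undefined",
                              call. = FALSE)
  sn <- n_correct / n_annotated
  ppv <- if (n_predicted > 0L) n_correct / n_predicted else NA_real_
  list(n_annotated = n_annotated, n_predicted = n_predicted,
       n_correct = n_correct, n_additional = n_predicted - n_correct,
       Sn = sn, PPV = ppv, Accuracy = coding_accuracy(sn, ppv),
       APR = (n_predicted - n_correct) / n_annotated)
}

#' Coding-prediction evaluation report
#'
#' Computes the four coding-prediction statistics under the 3'-terminus
#' correctness rule: sensitivity `Sn = correct / annotated`, precision
#' `PPV = correct / predicted`, `Accuracy = (Sn + PPV) / 2` and the
#' additional positive rate `APR = (predicted - correct) / annotated`
#' (which may exceed 1).
#'
#' @param predicted,annotated Data.frames with `contig`, `strand`, `start`,
#'   `end` columns; alternatively pass precomputed counts via `n_correct`,
#'   `n_annotated`, `n_predicted` (and leave the data.frames `NULL`).
#' @param n_correct,n_annotated,n_predicted Optional raw counts.
#' @return Object of class `coding_eval`: the counts and statistics.
#' @export
coding_report <- function(predicted = NULL, annotated = NULL,
                          n_correct = NULL, n_annotated = NULL,
                          n_predicted = NULL) {
  if (is.null(n_correct)) {
    m <- match_by_stop(predicted, annotated)
    n_correct <- nrow(m$matched)
    n_annotated <- nrow(m$matched) + length(m$ann_only)
    n_predicted <- nrow(m$matched) + length(m$pred_only)
  }
  structure(coding_stats(n_correct, n_annotated, n_predicted),
            class = "coding_eval")
}

#' @export
print.coding_eval <- function(x, digits = 4, ...) {
  cat(sprintf("Coding prediction: %d annotated, %d predicted, %d correct (3' rule)\n",
              x$n_annotated, x$n_predicted, x$n_correct))
  cat(sprintf("  Sn = %.*f  PPV = %.*f  Accuracy = %.*f  APR = %.*f\n",
              digits, x$Sn, digits, x$PPV, digits, x$Accuracy, digits, x$APR))
  invisible(x)
}

#' Essentiality-prediction evaluation report
#'
#' A gene counts as correctly predicted only if it was both found by the
#' gene caller and assigned the right essentiality class; an annotated gene
#' the caller missed is incorrect for its class. Statistics: sensitivity
#' `Sn` over annotated essential genes, specificity `Sp` over annotated
#' nonessential genes, and overall accuracy `OA` over all genes.
#'
#' @param truth_essential Named logical vector over annotated gene ids:
#'   `TRUE` = essential.
#' @param predicted_essential Named logical vector over predicted gene ids:
#'   the essentiality call.
#' @param matched Data.frame linking annotated to predicted genes, columns
#'   `ann_id`, `pred_id` (genes absent from it count as not found). Pass
#'   ids shared 1:1 when evaluating on the annotated set directly.
#' @return Object of class `essentiality_eval` with counts and `Sn`, `Sp`,
#'   `OA`. `Sn` is `NA` (with a warning) when the truth has no essential
#'   genes.
#' @export
essentiality_report <- function(truth_essential, predicted_essential,
                                matched = NULL) {
  ann_ids <- names(truth_essential)
  if (is.null(matched)) {
    matched <- data.frame(ann_id = ann_ids, pred_id = ann_ids,
                          stringsAsFactors = FALSE)
  }
  call_for <- rep(NA, length(ann_ids))
  names(call_for) <- ann_ids
  hit <- matched$ann_id %in% ann_ids & matched$pred_id %in% names(predicted_essential)
  call_for[matched$ann_id[hit]] <- predicted_essential[matched$pred_id[hit]]
  correct <- !is.na(call_for) & call_for == truth_essential
  n_ess <- sum(truth_essential)
  n_non <- sum(!truth_essential)
  sn <- if (n_ess == 0L) {
    warning("no essential genes in truth; Sn undefined", call. = FALSE)
    NA_real_
  } else sum(correct & truth_essential) / n_ess
  sp <- if (n_non == 0L) NA_real_ else sum(correct & !truth_essential) / n_non
  structure(list(n_essential = n_ess, n_nonessential = n_non,
                 n_correct_essential = sum(correct & truth_essential),
                 n_correct_nonessential = sum(correct & !truth_essential),
                 Sn = sn, Sp = sp,
                 OA = sum(correct) / length(truth_essential)),
            class = "essentiality_eval")
}

#' @export
print.essentiality_eval <- function(x, digits = 3, ...) {
  cat(sprintf("Essentiality prediction: %d essential, %d nonessential\n",
              x$n_essential, x$n_nonessential))
  cat(sprintf("  Sn = %.*f  Sp = %.*f  OA = %.*f\n",
              digits, x$Sn, digits, x$Sp, digits, x$OA))
  invisible(x)
}

#' Aggregate evaluation reports across genomes
#'
#' Mean and standard deviation per statistic over a list of reports (or a
#' numeric data.frame of per-genome statistics), as used for benchmark
#' tables.
#'
#' @param reports List of `coding_eval` / `essentiality_eval` objects, or a
#'   data.frame with one row per genome.
#' @param sd_type `"sample"` (default, n-1 denominator) or `"population"`.
#' @return Data.frame with rows `mean` and `sd`, one column per statistic.
#' @export
aggregate_reports <- function(reports, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (is.data.frame(reports)) {
    tab <- reports
  } else {
    stopifnot(length(reports) >= 1L)
    stats_names <- intersect(c("Sn", "PPV", "Accuracy", "APR", "Sp", "OA"),
                             names(reports[[1L]]))
    tab <- as.data.frame(lapply(stats_names, function(s)
      vapply(reports, function(r) as.numeric(r[[s]]), 0)),
      col.names = stats_names)
  }
  n <- nrow(tab)
  mu <- vapply(tab, mean, 0, na.rm = TRUE)
  sdev <- if (n == 1L) {
    if (sd_type == "sample") {
      warning("sample SD undefined for a single report; reporting 0",
              call. = FALSE)
    }
    stats::setNames(rep(0, ncol(tab)), names(tab))
  } else {
    s <- vapply(tab, stats::sd, 0, na.rm = TRUE)
    if (sd_type == "population") s <- s * sqrt((n - 1) / n)
    s
  }
  out <- rbind(mean = mu, sd = sdev)
  as.data.frame(out)
}
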