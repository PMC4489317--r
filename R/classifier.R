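# Genome-specific coding/non-coding classifier: self-training set
# construction (long-ORF seeds vs shuffled + shadow negatives) and a linear
# max-margin decision function.

#' Build self-training sets from an anonymous genome
#'
#' No external labels are used: positives are long canonical ORFs (random
#' ORFs of such length are rare under a null model), filtered so that no
#' seed overlaps a longer candidate on either strand by more than
#' `max_overlap` nt. Negatives are derived from the positives according to
#' `negative_policy`: nucleotide-order shuffles (identical base composition,
#' codon-phase structure destroyed) and/or opposite-strand shadows (the
#' reverse complement of each seed).
#'
#' @param orfs Candidate ORF table from [extract_orfs()].
#' @param seed_min_len Minimum seed ORF length in nt (default 480).
#' @param negative_policy One of `"shuffle+shadow"` (default), `"shuffle"`,
#'   `"shadow"`.
#' @param max_overlap Overlap cap in nt used in the seed filter (default 30).
#' @param min_positives Fewer seed positives than this is an error advising
#'   a relaxed `seed_min_len` (default 50).
#' @param seed Integer seed driving the shuffles.
#' @return An object of class `zgene_training`: list with `positives`,
#'   `negatives` (character vectors of sequences) and `provenance` tags
#'   (`long_orf` for positives; `shuffled` / `shadow` for negatives).
#' @export
build_training_sets <- function(orfs, seed_min_len = 480L,
                                negative_policy = c("shuffle+shadow",
                                                    "shuffle", "shadow"),
                                max_overlap = 30L, min_positives = 50L,
                                seed = 1L) {
  negative_policy <- match.arg(negative_policy)
  seeds <- orfs[orfs$length >= seed_min_len, , drop = FALSE]
  keep <- rep(TRUE, nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    longer <- orfs$length > seeds$length[i] & orfs$contig == seeds$contig[i]
    if (!any(longer)) next
    ov <- pmin(orfs$end[longer], seeds$end[i]) -
      pmax(orfs$start[longer], seeds$start[i]) + 1L
    if (any(ov > max_overlap)) keep[i] <- FALSE
  }
  seeds <- seeds[keep, , drop = FALSE]
  if (nrow(seeds) < min_positives) {
    stop(sprintf(paste("only %d seed ORFs of length >= %d nt; relax",
                       "seed_min_len to obtain at least %d positives"),
                 nrow(seeds), seed_min_len, min_positives), call. = FALSE)
  }
  pos <- seeds$seq
  neg <- character(0); neg_tag <- character(0)
  if (negative_policy %in% c("shuffle+shadow", "shuffle")) {
    sh <- with_seed(seed, vapply(pos, shuffle_orf_seq, "", USE.NAMES = FALSE))
    neg <- c(neg, sh); neg_tag <- c(neg_tag, rep("shuffled", length(sh)))
  }
  if (negative_policy %in% c("shuffle+shadow", "shadow")) {
    sd_ <- vapply(pos, reverse_complement, "", USE.NAMES = FALSE)
    neg <- c(neg, sd_); neg_tag <- c(neg_tag, rep("shadow", length(sd_)))
  }
  structure(list(positives = pos, negatives = neg,
                 provenance = list(positives = rep("long_orf", length(pos)),
                                   negatives = neg_tag)),
            class = "zgene_training")
}

# Shuffle the base order of an ORF body, keeping the stop codon in place:
# same mononucleotide composition, no codon-phase structure.
shuffle_orf_seq <- function(seq) {
  n <- nchar(seq)
  body <- utf8ToInt(substr(seq, 1L, n - 3L))
  paste0(intToUtf8(sample(body)), substr(seq, n - 2L, n))
}

#' @export
print.zgene_training <- function(x, ...) {
  cat(sprintf("<zgene_training> %d positives (long ORFs), %d negatives (%s)\n",
              length(x$positives), length(x$negatives),
              paste(unique(x$provenance$negatives), collapse = " + ")))
  invisible(x)
}

#' Fit the linear coding/non-coding decision function
#'
#' Encodes the training sequences and fits a linear max-margin (soft-margin
#' SVM, linear kernel) classifier. Features are standardised to zero mean
#' and unit variance on the training data; centring and scaling are folded
#' into the stored weights so that scoring works on raw feature vectors.
#' The decision function is `f(v) = w . v + b`; an ORF is called coding
#' when `f(v) > threshold`.
#'
#' @param sets A `zgene_training` object from [build_training_sets()], or a
#'   list with `positives` and `negatives` character vectors.
#' @param encoding `"z765"` (default) or `"z33"`.
#' @param cost Soft-margin cost C (default 1, the solver's default).
#' @param threshold Decision cutoff on the signed score (default 0).
#' @return An object of class `zgene_model`: `weights`, `bias`,
#'   `threshold`, `encoding`, `train_accuracy` (training-set separation).
#' @export
train_coding_model <- function(sets, encoding = c("z765", "z33"), cost = 1,
                               threshold = 0) {
  encoding <- match.arg(encoding)
  pos <- sets$positives; neg <- sets$negatives
  if (!length(pos) || !length(neg)) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  x <- encode_matrix(c(pos, neg), encoding)
  y <- factor(rep(c("coding", "noncoding"), c(length(pos), length(neg))),
              levels = c("coding", "noncoding"))
  if (nrow(unique(x)) < 2L) {
    stop("degenerate training data: all feature vectors identical", call. = FALSE)
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  fit <- e1071::svm(xs, y, kernel = "linear", cost = cost, scale = FALSE)
  w_s <- drop(crossprod(fit$coefs, fit$SV))
  b_s <- -fit$rho
  # orient so that coding scores are positive
  dv <- drop(xs %*% w_s) + b_s
  if (mean(dv[y == "coding"]) < mean(dv[y == "noncoding"])) {
    w_s <- -w_s; b_s <- -b_s; dv <- -dv
  }
  w <- w_s / scl
  b <- b_s - sum(w_s * ctr / scl)
  structure(list(weights = unname(w), bias = unname(b),
                 threshold = threshold, encoding = encoding, cost = cost,
                 train_accuracy = mean((dv > 0) == (y == "coding"))),
            class = "zgene_model")
}

#' @export
print.zgene_model <- function(x, ...) {
  cat(sprintf("<zgene_model> linear, %s encoding (%d weights), threshold %g\n",
              x$encoding, length(x$weights), x$threshold))
  cat(sprintf("  training-set separation: %.1f%%\n", 100 * x$train_accuracy))
  invisible(x)
}

#' Score feature vectors with a fitted model
#'
#' Returns the signed decision value `w . v + b`; classification is
#' `score > threshold`.
#'
#' @param model A `zgene_model`.
#' @param x Feature vector or matrix (rows = ORFs) matching the model's
#'   encoding dimension.
#' @return Numeric score(s).
#' @export
score_orfs <- function(model, x) {
  stopifnot(inherits(model, "zgene_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model$weights)) {
    stop(sprintf("feature dimension %d does not match model dimension %d",
                 ncol(x), length(model$weights)), call. = FALSE)
  }
  drop(x %*% model$weights) + model$bias
}

#' One self-training refinement pass
#'
#' Rescores the candidate ORFs with the current model and rebuilds the
#' training sets from confident calls (`score > margin` as positives,
#' `score < -margin` as negatives), then refits. If either side is empty
#' the previous model is kept with a warning.
#'
#' @param model A fitted `zgene_model`.
#' @param seqs Character vector of candidate ORF sequences.
#' @param margin Confidence margin on the signed score (default 1).
#' @param iterations Number of passes (default 1; 0 returns the model
#'   unchanged).
#' @return A `zgene_model`.
#' @export
retrain_iteration <- function(model, seqs, margin = 1, iterations = 1L) {
  if (iterations <= 0L) return(model)
  for (it in seq_len(iterations)) {
    sc <- score_orfs(model, encode_matrix(seqs, model$encoding))
    pos <- seqs[sc > margin]
    neg <- seqs[sc < -margin]
    if (!length(pos) || !length(neg)) {
      warning("self-training pass collapsed to a single class; keeping ",
              "previous model", call. = FALSE)
      return(model)
    }
    model <- train_coding_model(list(positives = pos, negatives = neg),
                                encoding = model$encoding, cost = model$cost,
                                threshold = model$threshold)
  }
  model
}

#' Save / load a fitted model as a plain-text file
#'
#' The layout is a versioned TSV-style text file; reloading reproduces
#' scores exactly.
#'
#' @param model A `zgene_model`.
#' @param path File path.
#' @return `write_model` returns `path` invisibly; `read_model` the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "zgene_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# zgene model v1"),
               sprintf("encoding\t%s", model$encoding),
               sprintf("bias\t%s", format(model$bias, digits = 17)),
               sprintf("threshold\t%s", format(model$threshold, digits = 17)),
               sprintf("cost\t%s", format(model$cost, digits = 17)),
               sprintf("train_accuracy\t%s",
                       format(model$train_accuracy, digits = 17)),
               "weights"), con)
  writeLines(format(model$weights, digits = 17, trim = TRUE, scientific = TRUE),
             con)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "# zgene model")) {
    stop("not a zgene model file: ", path, call. = FALSE)
  }
  kv <- strsplit(lines[2:6], "\t", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[[`, "", 2L), vapply(kv, `[[`, "", 1L))
  w_at <- match("weights", lines)
  structure(list(weights = as.numeric(lines[(w_at + 1L):length(lines)]),
                 bias = as.numeric(vals[["bias"]]),
                 threshold = as.numeric(vals[["threshold"]]),
                 encoding = vals[["encoding"]],
                 cost = as.numeric(vals[["cost"]]),
                 train_accuracy = as.numeric(vals[["train_accuracy"]])),
            class = "zgene_model")
}
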