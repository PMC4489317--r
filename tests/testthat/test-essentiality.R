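ref_fix <- function(id, ess, dist = 1, ids = c("p1", "p2", "p3")) {
  reference_organism(id, stats::setNames(rep("MKT", length(ids)), ids),
                     essential_ids = ess, distance = dist)
}

test_that("reference organisms validate their invariants", {
  expect_error(reference_organism("r", c(a = "M"), "b", 1), "subset")
  expect_error(reference_organism("r", c(a = "M"), "a", -1), "finite")
  expect_error(reference_organism("r", c(a = "M"), "a", Inf), "finite")
})

test_that("ortholog presence categories follow the matcher", {
  r <- ref_fix("r1", ess = "p1")
  q_ess <- structure("MKT", id = "p1")
  q_non <- structure("MKT", id = "p2")
  q_abs <- structure("MKT", id = "p9")
  expect_equal(ortholog_presence(q_ess, r), "essential_hit")
  expect_equal(ortholog_presence(q_non, r), "nonessential_hit")
  expect_equal(ortholog_presence(q_abs, r), "no_hit")
  # matcher failure degrades to no_hit with a warning
  expect_warning(
    res <- ortholog_presence(q_ess, r, matcher = function(q, r) stop("boom")),
    "no_hit")
  expect_equal(res, "no_hit")
})

test_that("a non-mutual best hit is rejected by the reciprocal matcher", {
  # reference holds a better partner for the query's best hit
  ref <- reference_organism(
    "r", c(a = "MKLVVFAACDE", b = "MWWWHHHYYYR"), character(0), 1)
  queries <- c(q1 = "MKLVVFAACDQ",   # close to 'a'
               q2 = "MKLVVFAACDE")   # identical to 'a' -- the mutual partner
  m <- matcher_rbh(queries)
  expect_equal(m(structure(queries[["q2"]], id = "q2"), ref), "a")
  expect_true(is.na(m(structure(queries[["q1"]], id = "q1"), ref)))
})

test_that("essentiality scores are distance-weighted convex evidence", {
  refs <- list(ref_fix("r1", "p1", dist = 0.2),
               ref_fix("r2", "p1", dist = 1.5),
               ref_fix("r3", "p1", dist = 3.0))
  q <- stats::setNames("MKT", "p1")
  expect_equal(unname(essentiality_scores(q, refs)), 1)
  none <- stats::setNames("MKT", "p9")
  expect_equal(unname(essentiality_scores(none, refs)), 0)
  # two references, equal weights, one essential hit -> 0.5
  refs2 <- list(ref_fix("r1", "p1", dist = 1), ref_fix("r2", character(0),
                                                       dist = 1))
  expect_equal(unname(essentiality_scores(q, refs2)), 0.5)
  # a zero-weight reference never changes any score
  wf <- function(d) ifelse(d > 100, 0, exp(-d))
  refs3 <- c(refs2, list(ref_fix("r3", "p1", dist = 200)))
  expect_equal(essentiality_scores(q, refs3, weight_fn = wf),
               essentiality_scores(q, refs2, weight_fn = wf))
  expect_error(essentiality_scores(q, list()), "at least one")
  expect_error(essentiality_scores(q, refs2, weight_fn = function(d) 0),
               "zero")
  # monotonicity: one more essential hit never lowers the score
  set.seed(15)
  for (i in 1:10) {
    ess_flags <- stats::runif(4) < 0.5
    dists <- stats::runif(4, 0.1, 2)
    mk <- function(flags) lapply(1:4, function(j)
      ref_fix(sprintf("r%d", j), if (flags[j]) "p1" else character(0),
              dist = dists[j]))
    base <- essentiality_scores(q, mk(ess_flags))
    j <- which(!ess_flags)[1L]
    if (!is.na(j)) {
      more <- ess_flags; more[j] <- TRUE
      expect_gte(essentiality_scores(q, mk(more))[[1L]], base[[1L]])
    }
  }
})

test_that("classification thresholds scores with a monotone call count", {
  sc <- stats::setNames(c(0, 0.2, 0.5, 0.8, 1), sprintf("g%d", 1:5))
  expect_equal(sum(classify_essentiality(sc, 0)$call == "essential"), 5L)
  expect_error(classify_essentiality(sc, 1.2), "\\[0, 1\\]")
  counts <- vapply(c(0, 0.25, 0.5, 0.75, 1),
                   function(ct) sum(classify_essentiality(sc, ct)$call ==
                                      "essential"), 0L)
  expect_true(all(diff(counts) <= 0L))
})

test_that("deterministic reference limits give exact 0/1 scores", {
  truth <- stats::setNames(stats::runif(40) < 0.3, sprintf("g%02d", 1:40))
  refs <- synth_reference_set(truth, n_refs = 5L, p_essential_hit = 1,
                              p_nonessential_hit = 0, seed = 2L)
  sc <- essentiality_scores(stats::setNames(rep("M", 40), names(truth)), refs)
  expect_equal(unname(sc[truth]), rep(1, sum(truth)))
  expect_equal(unname(sc[!truth]), rep(0, sum(!truth)))
})

test_that("the 5-reference 0.9/0.1 fixture recovers essentiality (OA >= 0.85)", {
  set.seed(33)
  truth <- stats::setNames(stats::runif(200) < 0.1, sprintf("g%03d", 1:200))
  refs <- synth_reference_set(truth, n_refs = 5L, p_essential_hit = 0.9,
                              p_nonessential_hit = 0.1, seed = 33L)
  sc <- essentiality_scores(stats::setNames(rep("M", 200), names(truth)),
                            refs)
  calls <- classify_essentiality(sc, 0.5)
  r <- essentiality_report(truth,
                           stats::setNames(calls$call == "essential",
                                           calls$gene_id))
  expect_gte(r$OA, 0.85)
})

test_that("a gene-finder fit can be post-scored for essentiality", {
  sf <- get_small_fit()
  truth <- stats::setNames(sf$synth$annotation$essential,
                           sf$synth$annotation$gene_id)
  # references keyed by predicted ids via position on the genome: use a
  # matcher that maps a predicted protein to the planted gene at its stop
  prot <- synth_proteins(sf$synth)
  refs <- synth_reference_set(truth, n_refs = 5L, p_essential_hit = 1,
                              p_nonessential_hit = 0, seed = 9L)
  by_protein <- function(query, reference) {
    hit <- names(prot)[match(as.character(query), prot)]
    if (!is.na(hit) && hit %in% names(reference$proteome)) hit
    else NA_character_
  }
  fit2 <- score_gene_essentiality(sf$fit, refs, matcher = by_protein)
  p <- fit2$predictions
  expect_true(all(p$essentiality_score >= 0 & p$essentiality_score <= 1))
  expect_true(all(p$essential_call %in% c("essential", "nonessential")))
  # genes whose protein matches a planted essential gene are called essential
  matched_truth <- truth[match(translate_genes(
    synth_gene_dna(list(genome = sf$synth$genome,
                        annotation = data.frame(
                          gene_id = p$gene_id, contig = p$contig,
                          start = p$start, end = p$end, strand = p$strand)))),
    prot)]
  known <- !is.na(matched_truth)
  expect_equal(p$essential_call[known] == "essential",
               unname(matched_truth[known]))
})
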