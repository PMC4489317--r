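test_that("self-training set construction is composition-preserving", {
  sf <- get_small_fit()
  orfs <- extract_orfs(sf$synth$genome)
  sets <- build_training_sets(orfs, seed_min_len = 480L, min_positives = 20L,
                              seed = 5L)
  expect_s3_class(sets, "zgene_training")
  expect_true(length(sets$positives) >= 20L)
  expect_true(all(sets$provenance$positives == "long_orf"))
  expect_setequal(unique(sets$provenance$negatives), c("shuffled", "shadow"))
  # every shuffled negative has exactly the base composition of its source
  n_pos <- length(sets$positives)
  shuf <- sets$negatives[sets$provenance$negatives == "shuffled"]
  comp <- function(s) table(factor(strsplit(s, "")[[1]],
                                   levels = c("A", "C", "G", "T")))
  for (i in seq_len(min(10L, n_pos))) {
    expect_equal(comp(shuf[i]), comp(sets$positives[i]))
  }
  # shadows are the reverse complements
  shad <- sets$negatives[sets$provenance$negatives == "shadow"]
  expect_equal(shad[1L], reverse_complement(sets$positives[1L]))
  # determinism under the seed
  sets2 <- build_training_sets(orfs, seed_min_len = 480L,
                               min_positives = 20L, seed = 5L)
  expect_identical(sets$negatives, sets2$negatives)
})

test_that("a genome of pure random sequence yields too few seed positives", {
  set.seed(88)
  g <- genome_sequence("r", rand_seq(50000))
  orfs <- extract_orfs(g)
  expect_error(build_training_sets(orfs), "relax")
})

test_that("training separates a separable toy problem and scores linearly", {
  pos_seq <- strrep("ATGGAAGAAGAAGAAGAAGAAGAAGAA", 3)  # Glu-rich, phase-locked
  neg_seq <- strrep("ATGAGAGAGAGAGAGAGAGAGAGAGAG", 3)
  sets <- list(positives = rep(c(pos_seq, paste0(pos_seq, "GAAGAA")), 4),
               negatives = rep(c(neg_seq, paste0(neg_seq, "AGAGAG")), 4))
  m <- train_coding_model(sets)
  sp <- score_orfs(m, encode_matrix(sets$positives))
  sn <- score_orfs(m, encode_matrix(sets$negatives))
  expect_true(all(sp > 0))
  expect_true(all(sn < 0))
  expect_equal(m$train_accuracy, 1)
  # score is affine: f(v) = w.v + b
  v1 <- encode_orf(pos_seq); v2 <- encode_orf(neg_seq)
  expect_equal(score_orfs(m, as.numeric(v1)) + score_orfs(m, as.numeric(v2)),
               score_orfs(m, as.numeric(v1) + as.numeric(v2)) + m$bias)
  expect_equal(score_orfs(m, rep(0, 765)), m$bias)
  expect_error(score_orfs(m, rep(0, 33)), "dimension")
  # class-consistent duplication leaves the decision unchanged
  m2 <- train_coding_model(list(positives = c(sets$positives,
                                              sets$positives[1L]),
                                negatives = sets$negatives))
  expect_equal(sign(score_orfs(m2, encode_matrix(c(sets$positives,
                                                   sets$negatives)))),
               sign(c(sp, sn)))
  expect_error(train_coding_model(list(positives = character(0),
                                       negatives = sets$negatives)),
               "non-empty")
  expect_error(train_coding_model(list(positives = rep(pos_seq, 4),
                                       negatives = rep(pos_seq, 4))),
               "degenerate")
})

test_that("swapping the training labels negates the decision function", {
  sf <- get_small_fit()
  orfs <- extract_orfs(sf$synth$genome)
  sets <- build_training_sets(orfs, min_positives = 20L, seed = 2L)
  m <- train_coding_model(sets)
  m_sw <- train_coding_model(list(positives = sets$negatives,
                                  negatives = sets$positives))
  x <- encode_matrix(c(sets$positives[1:5], sets$negatives[1:5]))
  expect_equal(score_orfs(m, x), -score_orfs(m_sw, x), tolerance = 5e-3)
})

test_that("model serialization round-trips scores exactly", {
  sf <- get_small_fit()
  m <- sf$fit$model
  f <- withr::local_tempfile(fileext = ".txt")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(m2$weights, m$weights, tolerance = 0)
  expect_equal(m2$bias, m$bias, tolerance = 0)
  x <- encode_matrix(null_orf_set(rep(90L, 5L), seed = 3L))
  expect_identical(score_orfs(m, x), score_orfs(m2, x))
})

test_that("held-out planted genes outscore shuffled negatives (AUC >= 0.95)", {
  sf <- get_small_fit()
  genes <- synth_gene_dna(sf$synth)
  set.seed(41)
  shuf <- vapply(genes, function(x) {
    n <- nchar(x)
    paste0(paste(sample(strsplit(substr(x, 1, n - 3), "")[[1]]),
                 collapse = ""), substr(x, n - 2, n))
  }, "", USE.NAMES = FALSE)
  a <- auc_rank(score_orfs(sf$fit$model, encode_matrix(genes)),
                score_orfs(sf$fit$model, encode_matrix(shuf)))
  expect_gte(a, 0.95)
})

test_that("the legacy 33-variable model is not materially better than 765", {
  sf <- get_small_fit()
  orfs <- extract_orfs(sf$synth$genome)
  sets <- build_training_sets(orfs, min_positives = 20L, seed = 3L)
  m765 <- train_coding_model(sets, "z765")
  m33 <- train_coding_model(sets, "z33")
  genes <- synth_gene_dna(sf$synth)
  nul <- null_orf_set(nchar(genes), seed = 13L)
  a765 <- auc_rank(score_orfs(m765, encode_matrix(genes, "z765")),
                   score_orfs(m765, encode_matrix(nul, "z765")))
  a33 <- auc_rank(score_orfs(m33, encode_matrix(genes, "z33")),
                  score_orfs(m33, encode_matrix(nul, "z33")))
  expect_lte(a33, a765 + 0.02)
})

test_that("self-training refinement is safe and well-behaved", {
  sf <- get_small_fit()
  orfs <- extract_orfs(sf$synth$genome)
  sets <- build_training_sets(orfs, min_positives = 20L, seed = 4L)
  m <- train_coding_model(sets)
  # iteration count 0 is the identity
  expect_identical(retrain_iteration(m, orfs$seq, iterations = 0L), m)
  # an infinite margin leaves no confident samples: warn, keep the model
  expect_warning(m_inf <- retrain_iteration(m, orfs$seq, margin = Inf), "collaps")
  expect_identical(m_inf, m)
  # one pass must not degrade held-out separation materially
  genes <- synth_gene_dna(sf$synth)
  nul <- null_orf_set(nchar(genes), seed = 19L)
  m1 <- retrain_iteration(m, orfs$seq)
  a0 <- auc_rank(score_orfs(m, encode_matrix(genes)),
                 score_orfs(m, encode_matrix(nul)))
  a1 <- auc_rank(score_orfs(m1, encode_matrix(genes)),
                 score_orfs(m1, encode_matrix(nul)))
  expect_gte(a1, a0 - 0.01)
})
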