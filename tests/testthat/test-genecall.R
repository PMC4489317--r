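test_that("overlap resolution keeps dominant ORFs and tolerates small overlaps", {
  df <- data.frame(contig = "c", strand = c("+", "+"),
                   start = c(100L, 150L), end = c(400L, 390L),
                   length = c(301L, 241L), coding_score = c(2, 1),
                   stringsAsFactors = FALSE)
  kept <- resolve_overlaps(df, max_overlap = 30L)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$coding_score, 2)

  df2 <- data.frame(contig = "c", strand = c("+", "-"),
                    start = c(100L, 291L), end = c(300L, 500L),
                    length = c(201L, 210L), coding_score = c(2, 1),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(resolve_overlaps(df2, max_overlap = 30L)), 2L)
})

test_that("greedy overlap resolution reaches >= 0.9 x the exhaustive optimum", {
  # instances drawn from the pipeline itself: windows of scored candidate
  # ORFs from a synthetic fit, compared against exhaustive enumeration
  sf <- get_small_fit()
  orfs <- extract_orfs(sf$synth$genome)
  orfs$coding_score <- sf$fit$orf_scores
  cand <- orfs[orfs$coding_score > 0, ]
  cand <- cand[order(cand$start), ]
  set.seed(404)
  n_checked <- 0L
  for (w in seq(1L, nrow(cand) - 11L, by = 11L)) {
    df <- cand[w:(w + 10L), ]
    kept <- resolve_overlaps(df, max_overlap = 30L)
    opt <- best_subset_score(df$start, df$end, df$coding_score, 30L)
    expect_gte(sum(kept$coding_score), 0.9 * opt)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 4L)
})

test_that("start relocation prefers a true start marked by a perfect SD motif", {
  sf <- get_small_fit()
  model <- sf$fit$model
  tab <- sf$synth$codon_table
  set.seed(61)
  body <- paste(sample(names(tab), 80, replace = TRUE, prob = tab),
                collapse = "")
  gene <- paste0("ATG", body, "TAA")
  # upstream in-frame decoy ATG, no stop between: decoy..gene is one ORF
  decoy_fill <- paste(sample(setdiff(names(tab), "ATG"), 9, replace = TRUE),
                      collapse = "")
  upstream <- paste0("ATG", decoy_fill)               # 30 nt, in frame
  sd_box <- paste0("AGGAGG", strrep("C", 9))          # perfect SD, 9 nt spacer
  contig <- paste0(strrep("T", 30), upstream, sd_box, gene, strrep("T", 30))
  g <- genome_sequence("fix", contig)
  true_start <- 30L + nchar(upstream) + nchar(sd_box) + 1L
  decoy_start <- 31L
  orfs <- extract_orfs(g, min_len = 90L)
  row <- orfs[orfs$strand == "+" & orfs$end == true_start + nchar(gene) - 1L, ]
  expect_equal(nrow(row), 1L)
  expect_true(all(c(decoy_start, true_start) %in% row$alt_starts[[1L]]))
  row$coding_score <- score_orfs(model, encode_matrix(row$seq))
  rel <- relocate_starts(row, g, model, sd_weight = 0.5)
  expect_equal(rel$start, true_start)
  expect_true(rel$start_relocated)

  # single-candidate predictions are never moved
  one <- orfs[orfs$n_starts == 1L, ][1L, ]
  if (nrow(one) == 1L && !is.na(one$start)) {
    one$coding_score <- score_orfs(model, encode_matrix(one$seq))
    rel1 <- relocate_starts(one, g, model)
    expect_false(rel1$start_relocated)
    expect_equal(rel1$start, one$start)
  }
})

test_that("relocation never changes the 3' terminus", {
  sf <- get_small_fit()
  orfs <- extract_orfs(sf$synth$genome)
  orfs$coding_score <- sf$fit$orf_scores
  cand <- orfs[orfs$coding_score > 0, ]
  rel <- relocate_starts(cand, sf$synth$genome, sf$fit$model, sd_weight = 0.3)
  expect_equal(stopkey(rel), stopkey(cand))
  moved <- rel$start_relocated
  expect_equal(ifelse(cand$strand == "+", rel$end, rel$start)[moved],
               ifelse(cand$strand == "+", cand$end, cand$start)[moved])
})

test_that("gene calling is deterministic and writes byte-identical output", {
  sf <- get_small_fit()
  fit2 <- zgene(sf$synth$genome, seed = 301L, min_positives = 25L)
  expect_identical(sf$fit$predictions, fit2$predictions)
  d <- withr::local_tempdir()
  write_gene_outputs(sf$fit$predictions, sf$synth$genome,
                     file.path(d, "a"), what = "coords", params = "run")
  write_gene_outputs(fit2$predictions, sf$synth$genome,
                     file.path(d, "b"), what = "coords", params = "run")
  expect_identical(readLines(file.path(d, "a_genes.tsv")),
                   readLines(file.path(d, "b_genes.tsv")))
})

test_that("raising the decision threshold never adds predictions", {
  sf <- get_small_fit()
  n_preds <- vapply(c(0, 0.5, 1, 2), function(th) {
    fit <- zgene(sf$synth$genome, seed = 301L, min_positives = 25L,
                 threshold = th, relocate = FALSE)
    nrow(fit$predictions)
  }, 0L)
  expect_true(all(diff(n_preds) <= 0L))
})

test_that("prediction invariants hold on a synthetic fit", {
  sf <- get_small_fit()
  p <- sf$fit$predictions
  expect_true(all((p$end - p$start + 1L) %% 3L == 0L | p$wrap))
  expect_true(all(p$coding_score > sf$fit$config$threshold))
  expect_false(is.unsorted(p$start[p$contig == p$contig[1L]]))
  # stop codon at the 3' terminus of every called gene
  dna <- synth_gene_dna(list(genome = sf$synth$genome,
                             annotation = data.frame(
                               gene_id = p$gene_id, contig = p$contig,
                               start = p$start, end = p$end,
                               strand = p$strand)))
  expect_true(all(substr(dna, nchar(dna) - 2L, nchar(dna)) %in%
                    c("TAA", "TAG", "TGA")))
})

test_that("a genome with no qualifying ORF gives an empty, successful fit", {
  g <- genome_sequence("empty", strrep("A", 400))
  fit <- zgene(g)
  expect_s3_class(fit, "zgene")
  expect_equal(nrow(fit$predictions), 0L)
})

test_that("fit methods expose the model in the usual R idiom", {
  sf <- get_small_fit()
  expect_output(print(sf$fit), "predicted genes")
  expect_output(summary(sf$fit), "Training:")
  co <- coef(sf$fit)
  expect_length(co, 766L)
  expect_equal(unname(co["(bias)"]), sf$fit$model$bias)
  # predict with new ORF sequences returns their scores
  seqs <- null_orf_set(rep(300L, 3L), seed = 9L)
  expect_length(predict(sf$fit, seqs), 3L)
  # predict with a new genome reuses the fitted model, no retraining
  s2 <- synth_genome(length = 30000L, n_genes = 18L,
                     codon_table = sf$synth$codon_table, seed = 777L)
  p2 <- predict(sf$fit, s2$genome)
  r <- coding_report(p2, s2$annotation)
  expect_gte(r$Sn, 0.8)
  pf <- file.path(withr::local_tempdir(), "sc.pdf")
  grDevices::pdf(pf); plot(sf$fit); grDevices::dev.off()
  expect_true(file.exists(pf))
})
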