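test_that("tissue ratios reproduce the fraction of non-expressed samples exactly", {
  states <- cbind(matrix(0L, 3, 9), matrix(1L, 3, 1)) # 9 of 10 not expressed
  cohort <- make_cohort(states, rep("liver", 10))
  r <- tissue_ratios(cohort, min_m = 1)
  expect_equal(r$non_expressed_ratio, rep(0.9, 3))
  expect_equal(r$expressed_ratio, rep(0.1, 3))
  expect_equal(r$m, rep(10L, 3))
  expect_equal(r$non_expressed_ratio + r$expressed_ratio, rep(1, 3),
               tolerance = 1e-12)

  # all expressed
  cohort2 <- make_cohort(matrix(1L, 2, 5), rep("lung", 5))
  r2 <- tissue_ratios(cohort2, min_m = 1)
  expect_equal(r2$non_expressed_ratio, c(0, 0))
  expect_equal(r2$expressed_ratio, c(1, 1))

  # m = 7, states (0,0,0,1,1,1,1) -> 3/7
  cohort3 <- make_cohort(matrix(c(0L, 0L, 0L, 1L, 1L, 1L, 1L), 1, 7),
                         rep("ovary", 7))
  expect_equal(tissue_ratios(cohort3, min_m = 1)$non_expressed_ratio, 3 / 7)
})

test_that("cohort construction rejects unlabeled samples and non-binary states", {
  states <- matrix(0L, 2, 3,
                   dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  expect_error(cohort_states(states, c(s1 = "liver", s2 = "liver")),
               class = "ts_mapping_error")
  bad <- states; bad[1, 1] <- 2L
  expect_error(cohort_states(bad, c(s1 = "a", s2 = "a", s3 = "a")),
               class = "ts_shape_error")
})

test_that("ratios are invariant to sample order within a tissue", {
  set.seed(3)
  states <- matrix(rbinom(200, 1, 0.4), 20, 10)
  cohort <- make_cohort(states, rep(c("liver", "lung"), each = 5))
  r1 <- tissue_ratios(cohort, min_m = 1)
  perm <- c(sample(1:5), sample(6:10))
  cohort2 <- cohort_states(cohort$states[, perm], cohort$tissue_of[perm])
  r2 <- tissue_ratios(cohort2, min_m = 1)
  key <- function(r) r[order(r$gene_id, r$tissue), ]
  expect_equal(key(r1)$non_expressed_ratio, key(r2)$non_expressed_ratio)
})

test_that("dormancy rule: >= 0.9 in every non-testis tissue, testis-exclusive strictly > 10%", {
  genes <- c("gA", "gB", "gC", "gD")
  summaries <- expand.grid(gene_id = genes,
                           tissue = c("liver", "lung", "testis"),
                           stringsAsFactors = FALSE)
  summaries$m <- 10L
  ne <- c(gA = 1.0, gB = 1.0, gC = 0.89, gD = 0.9)
  summaries$non_expressed_ratio <- ne[summaries$gene_id]
  # gC fails only in liver (boundary 0.89 < 0.9)
  summaries$non_expressed_ratio[summaries$gene_id == "gC" &
                                  summaries$tissue == "lung"] <- 0.95
  # testis column: gA fully expressed, gB silent, gD exactly at 10%
  te <- c(gA = 0.0, gB = 1.0, gC = 0.5, gD = 0.9)
  idx <- summaries$tissue == "testis"
  summaries$non_expressed_ratio[idx] <- te[summaries$gene_id[idx]]
  summaries$expressed_ratio <- 1 - summaries$non_expressed_ratio

  d <- identify_dormant_genes(summaries)
  expect_setequal(d$gene_id, c("gA", "gB", "gD"))
  expect_equal(d$category[d$gene_id == "gA"], "testis_exclusive")   # ratio 1.00
  expect_equal(d$category[d$gene_id == "gB"], "silent_everywhere")  # ratio 0
  expect_equal(d$category[d$gene_id == "gD"], "silent_everywhere")  # 0.10 not > 0.10
})

test_that("dormancy handles an atlas without a testis tissue", {
  summaries <- data.frame(gene_id = rep(c("g1", "g2"), each = 2),
                          tissue = rep(c("liver", "lung"), 2),
                          m = 5L,
                          non_expressed_ratio = c(1, 1, 0.5, 1))
  summaries$expressed_ratio <- 1 - summaries$non_expressed_ratio
  d <- identify_dormant_genes(summaries, testis_label = "testis")
  expect_equal(d$gene_id, "g1")
  expect_true(is.na(d$testis_expressed_ratio))
  expect_equal(d$category, "silent_everywhere")
})

test_that("an incomplete atlas is a named error", {
  summaries <- data.frame(gene_id = c("g1", "g1", "g2"),
                          tissue = c("liver", "lung", "liver"),
                          m = 5L, non_expressed_ratio = 1)
  summaries$expressed_ratio <- 0
  err <- tryCatch(identify_dormant_genes(summaries),
                  ts_incomplete_atlas = function(e) e)
  expect_s3_class(err, "ts_incomplete_atlas")
  expect_match(conditionMessage(err), "g2")
  expect_match(conditionMessage(err), "lung")
})

test_that("dormant sets nest across cutoffs", {
  set.seed(4)
  genes <- sprintf("g%02d", 1:40)
  summaries <- expand.grid(gene_id = genes, tissue = c("a", "b", "c"),
                           stringsAsFactors = FALSE)
  summaries$m <- 20L
  summaries$non_expressed_ratio <- sample(seq(0, 1, by = 0.05),
                                          nrow(summaries), replace = TRUE)
  summaries$expressed_ratio <- 1 - summaries$non_expressed_ratio
  sets <- lapply(c(0.95, 0.90, 0.80), function(ct) {
    identify_dormant_genes(summaries, testis_label = "none",
                           ratio_cutoff = ct)$gene_id
  })
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))
})

test_that("TAA prediction applies the inclusive 5% rule over dormant genes only", {
  genes <- c("d1", "d2", "n1")
  states <- matrix(0L, 3, 100, dimnames = list(genes, sprintf("t%03d", 1:100)))
  states["d1", 1:5] <- 1L   # 5/100 -> candidate at 0.05
  states["d2", 1:4] <- 1L   # 4/100 -> excluded
  states["n1", 1:50] <- 1L  # not dormant -> excluded
  cohort <- make_cohort(states, rep("LIHC", 100))
  dormant <- data.frame(gene_id = c("d1", "d2"))
  cand <- predict_taas(cohort, dormant, expressed_cutoff = 0.05)
  expect_equal(cand$gene_id, "d1")
  expect_equal(cand$tumor_expressed_ratio, 0.05)
  expect_equal(cand$n_expressed, 5L)
  expect_setequal(cand$expressed_sample_ids[[1]], sprintf("t%03d", 1:5))
  expect_error(predict_taas(cohort, dormant, expressed_cutoff = 0),
               class = "ts_parameter_error")
  expect_error(predict_taas(cohort, dormant, expressed_cutoff = 1.5),
               class = "ts_parameter_error")
})

test_that("per-patient coverage equals the union of expressed sample sets", {
  set.seed(6)
  genes <- sprintf("d%02d", 1:8)
  states <- matrix(rbinom(8 * 50, 1, 0.15), 8, 50,
                   dimnames = list(genes, sprintf("t%03d", 1:50)))
  cohort <- make_cohort(states, rep("OV", 50))
  cand <- predict_taas(cohort, data.frame(gene_id = genes),
                       expressed_cutoff = 0.02)
  covered <- unique(unlist(cand$expressed_sample_ids))
  direct <- colnames(states)[colSums(states[cand$gene_id, , drop = FALSE]) > 0]
  expect_setequal(covered, direct)
})

test_that("candidate annotation flags follow set membership", {
  cand <- data.frame(gene_id = c("g1", "g2", "g3"), cancer_type = "X",
                     tumor_expressed_ratio = 0.2, n_expressed = 2L, m = 10L,
                     membrane = FALSE, known_cta = FALSE,
                     testis_specific = FALSE)
  out <- annotate_candidates(cand, membrane = c("g1"),
                             cta = c("g2", "g3"),
                             testis_specific = c("g2"))
  expect_equal(out$membrane, c(TRUE, FALSE, FALSE))
  expect_equal(out$known_cta, c(FALSE, TRUE, TRUE))
  expect_equal(out$testis_specific, c(FALSE, TRUE, FALSE))
  # a gene may carry several flags at once
  expect_true(out$known_cta[2] && out$testis_specific[2])
  # empty sets -> all flags false
  out2 <- annotate_candidates(cand)
  expect_false(any(out2$membrane | out2$known_cta | out2$testis_specific))
})

test_that("cutoff sweep counts are non-increasing and nested", {
  set.seed(8)
  genes <- sprintf("d%02d", 1:30)
  states <- matrix(rbinom(30 * 100, 1, 0.08), 30, 100,
                   dimnames = list(genes, sprintf("t%03d", 1:100)))
  cohort <- make_cohort(states, rep("UCS", 100))
  dormant <- data.frame(gene_id = genes)
  sweep <- cutoff_sweep(cohort, dormant, c(0.01, 0.05, 0.50))
  expect_true(all(diff(sweep$candidate_count) <= 0))
  # subset nesting
  c1 <- predict_taas(cohort, dormant, 0.01)$gene_id
  c2 <- predict_taas(cohort, dormant, 0.05)$gene_id
  expect_true(all(c2 %in% c1))
  # cutoff 1.0 with no universally expressed gene -> zero
  sweep2 <- cutoff_sweep(cohort, dormant, c(0.5, 1.0))
  expect_equal(sweep2$candidate_count[sweep2$cutoff == 1.0], 0L)
  expect_error(cutoff_sweep(cohort, dormant, c(0.5, 0.1)),
               class = "ts_parameter_error")
  expect_error(cutoff_sweep(cohort, dormant, c(0, 0.5)),
               class = "ts_parameter_error")
})

test_that("planted reactivation counts drive the sweep exactly under perfect calls", {
  # 30 dormant genes reactivated in exactly 10 of 100 tumors each
  genes <- sprintf("d%02d", 1:30)
  states <- matrix(0L, 30, 100, dimnames = list(genes, sprintf("t%03d", 1:100)))
  set.seed(10)
  for (g in genes) states[g, sample.int(100, 10)] <- 1L
  cohort <- make_cohort(states, rep("SKCM", 100))
  sweep <- cutoff_sweep(cohort, data.frame(gene_id = genes),
                        c(0.05, 0.50))
  expect_equal(sweep$candidate_count, c(30L, 0L))
})
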