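# brute-force AUPRC oracle: enumerate every distinct threshold, compute the
# confusion table directly, and integrate by trapezoid with the anchor at
# (recall 0, precision of the top-ranked prediction set)
brute_force_auprc <- function(score, inactive) {
  ths <- sort(unique(score), decreasing = TRUE)
  pts <- t(vapply(ths, function(t) {
    pred <- score >= t
    c(recall = sum(pred & inactive) / sum(inactive),
      precision = sum(pred & inactive) / sum(pred))
  }, numeric(2)))
  r <- c(0, pts[, "recall"])
  p <- c(pts[1, "precision"], pts[, "precision"])
  sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
}

ratios_df <- function(gene_id, ratio, tissue = "liver") {
  data.frame(gene_id = gene_id, tissue = tissue, m = 10L,
             non_expressed_ratio = ratio, expressed_ratio = 1 - ratio)
}

test_that("per-sample metrics reproduce forced confusion-matrix arithmetic", {
  genes <- paste0("g", 1:8)
  ref <- make_ref(genes, rep(c("active", "inactive"), each = 4))
  # flip one active -> non-expressed and one inactive -> expressed
  states <- setNames(c(0L, 1L, 1L, 1L, 1L, 0L, 0L, 0L), genes)
  rep1 <- evaluate_per_sample(calls_from_states(states), ref)
  s <- rep1$summary
  get <- function(cls, metric) s$mean[s$class == cls & s$metric == metric]
  expect_equal(get("expressed", "precision"), 3 / 4)
  expect_equal(get("expressed", "recall"), 3 / 4)
  expect_equal(get("non_expressed", "precision"), 3 / 4)
  expect_equal(get("non_expressed", "recall"), 3 / 4)
})

test_that("mean and SD are taken across samples (n-1 denominator)", {
  genes <- paste0("g", 1:10)
  ref <- make_ref(genes, rep(c("active", "inactive"), each = 5))
  perfect <- setNames(rep(c(1L, 0L), each = 5), genes)
  # sample 2: one inactive gene called expressed -> expressed precision 5/6
  off <- perfect; off["g6"] <- 1L
  rep2 <- evaluate_per_sample(list(calls_from_states(perfect, "s1"),
                                   calls_from_states(off, "s2")), ref)
  s <- rep2$summary
  ep <- s[s$class == "expressed" & s$metric == "precision", ]
  expect_equal(ep$mean, mean(c(1, 5 / 6)))
  expect_equal(ep$sd, sd(c(1, 5 / 6)))
  expect_equal(ep$n_samples, 2L)
  # identical predictions -> all metrics 1, SD 0
  rep3 <- evaluate_per_sample(list(calls_from_states(perfect, "s1"),
                                   calls_from_states(perfect, "s2")), ref)
  expect_true(all(rep3$summary$mean == 1))
  expect_true(all(rep3$summary$sd == 0))
})

test_that("undefined precision is excluded with a logged count", {
  genes <- paste0("g", 1:6)
  ref <- make_ref(genes, rep(c("active", "inactive"), each = 3))
  all_on <- setNames(rep(1L, 6), genes) # zero predicted non-expressed
  rep1 <- suppressMessages(evaluate_per_sample(calls_from_states(all_on), ref))
  s <- rep1$summary
  row <- s[s$class == "non_expressed" & s$metric == "precision", ]
  expect_equal(row$n_undefined, 1L)
  expect_equal(row$n_samples, 0L)
})

test_that("evaluation is invariant to gene and sample order", {
  set.seed(33)
  genes <- sprintf("g%02d", 1:30)
  ref <- make_ref(genes, sample(c("active", "inactive"), 30, replace = TRUE))
  st1 <- setNames(rbinom(30, 1, 0.5), genes)
  st2 <- setNames(rbinom(30, 1, 0.5), genes)
  r1 <- evaluate_per_sample(list(calls_from_states(st1, "a"),
                                 calls_from_states(st2, "b")), ref)
  perm <- sample(30)
  r2 <- evaluate_per_sample(list(calls_from_states(st2, "b"),
                                 calls_from_states(st1[perm], "a")), ref)
  expect_equal(r1$summary$mean, r2$summary$mean)
  expect_equal(r1$summary$sd, r2$summary$sd)
})

test_that("PR curve matches exhaustive threshold enumeration on the 6-gene toy", {
  score <- c(1.0, 0.9, 0.8, 0.6, 0.3, 0.1)
  labels <- c("inactive", "inactive", "active", "inactive", "active", "active")
  ratios <- ratios_df(paste0("g", 1:6), score)
  ref <- make_ref(paste0("g", 1:6), labels)
  pr <- tissue_pr_curve(ratios, ref, min_overlap = 5L)
  # frozen value computed by hand from the enumeration: 65/72
  expect_equal(pr$auprc, 65 / 72, tolerance = 1e-12)
  expect_equal(pr$auprc, brute_force_auprc(score, labels == "inactive"),
               tolerance = 1e-12)
  expect_true(all(diff(pr$points$recall) >= 0))
})

test_that("perfect separation gives AUPRC 1; constant scores give prevalence", {
  genes <- sprintf("g%02d", 1:20)
  labels <- rep(c("inactive", "active"), each = 10)
  perfect <- ratios_df(genes, ifelse(labels == "inactive", 1.0, 0.0))
  ref <- make_ref(genes, labels)
  pr <- tissue_pr_curve(perfect, ref)
  expect_equal(pr$auprc, 1.0, tolerance = 1e-12)
  expect_equal(pr$precision_at_fixed, 1.0)
  flat <- ratios_df(genes, rep(0.5, 20))
  pr2 <- tissue_pr_curve(flat, ref)
  expect_true(all(pr2$points$precision == 0.5)) # prevalence of inactive
  expect_equal(pr2$auprc, 0.5, tolerance = 1e-12)
})

test_that("AUPRC is invariant under strictly monotone score transforms", {
  set.seed(35)
  genes <- sprintf("g%02d", 1:50)
  score <- round(runif(50), 2)
  labels <- ifelse(runif(50) < score, "inactive", "active")
  ref <- make_ref(genes, labels)
  a1 <- tissue_pr_curve(ratios_df(genes, score), ref)$auprc
  a2 <- tissue_pr_curve(ratios_df(genes, score^3), ref)$auprc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("PR curve demands overlap and both classes", {
  ratios <- ratios_df(paste0("g", 1:6), seq(0, 1, length.out = 6))
  ref <- make_ref(paste0("h", 1:6), rep(c("active", "inactive"), 3))
  expect_error(tissue_pr_curve(ratios, ref, min_overlap = 5L),
               class = "ts_evaluation_error")
  ref2 <- make_ref(paste0("g", 1:6), rep("inactive", 6))
  expect_error(tissue_pr_curve(ratios, ref2, min_overlap = 5L),
               class = "ts_evaluation_error")
})

test_that("the mixture method is balanced where a misplaced fixed threshold is not", {
  # separable sample; fixed cutoff placed 2 log2 units below the true boundary
  s <- separable_sample(n = 4000, seed = 37, mu_ne = -1, mu_e = 6,
                        sigma = 0.9, zero_inflation = 0.7)
  ref <- make_ref(names(s$tpm),
                  ifelse(s$latent == 1L, "active", "inactive"))
  var_calls <- infer_sample_states(s$tpm, s$housekeeping)
  misplaced <- 2^((-1 + 6) / 2 - 2)
  fix_calls <- fixed_threshold_states(s$tpm, cutoff = misplaced)
  var_rep <- evaluate_per_sample(var_calls, ref)
  fix_rep <- evaluate_per_sample(fix_calls, ref)
  expect_true(all(var_rep$summary$mean > 0.9))
  # Table-1 style ordering: the mixture method's worst metric beats the
  # misplaced threshold's worst metric (stability/balance)
  expect_gt(min(var_rep$summary$mean), min(fix_rep$summary$mean))
})
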