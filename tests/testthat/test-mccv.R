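# small simulated cohort with one strong protective gene among nulls
one_gene_cohort <- function(seed, n = 200, n_null = 20, beta = -1) {
  sim <- simulate_cohort(sim_params(
    n_sources = 1, samples_per_source = n, n_genes = n_null + 1,
    n_prognostic = 1, effect_sizes = abs(beta),
    fraction_protective = as.numeric(beta < 0), batch_shift_sd = 0,
    seed = seed))
  list(bundle = z_transform_within_source(sim$bundle),
       gene = sim$truth$prognostic_gene_ids)
}

test_that("constant features are never selected", {
  b <- random_bundle(n_genes = 10, samples = 60, seed = 61, event_p = 0.5)
  b$expression[3, ] <- 7
  res <- mccv_screen(b, mccv_config(n_iterations = 10, seed = 1))
  expect_false(res$mccv_selected[3])
  expect_equal(res$mccv_mean_p[3], 1)
})

test_that("a strong protective gene is selected with perfect consistency", {
  hits <- cons <- logical(15)
  for (i in 1:15) {
    oc <- one_gene_cohort(600 + i)
    res <- mccv_screen(oc$bundle, mccv_config(n_iterations = 50, seed = i))
    row <- res[res$feature_id == oc$gene, ]
    hits[i] <- row$mccv_selected
    cons[i] <- row$mccv_consistency == 1
  }
  expect_gte(mean(hits), 0.95)
  expect_gte(mean(cons), 0.95)
})

test_that("null genes essentially never pass the joint criterion", {
  sim <- simulate_cohort(sim_params(
    n_sources = 1, samples_per_source = 135, n_genes = 1500,
    n_prognostic = 0, batch_shift_sd = 0, seed = 62))
  zb <- z_transform_within_source(sim$bundle)
  res <- mccv_screen(zb, mccv_config(seed = 7))
  expect_lt(mean(res$mccv_selected), 0.005)
  # joint criterion is a subset of the P criterion alone
  expect_true(all(res$mccv_mean_p[res$mccv_selected] < 0.01))
})

test_that("the screen is deterministic given a seed and sample-order proof", {
  b <- random_bundle(n_genes = 40, samples = 80, seed = 63, event_p = 0.4)
  cfg <- mccv_config(n_iterations = 20, seed = 11)
  r1 <- mccv_screen(b, cfg)
  r2 <- mccv_screen(b, cfg)
  expect_identical(r1, r2)
  perm <- hrnegsig:::subset_samples(b, sample(colnames(b$expression)))
  r3 <- mccv_screen(perm, cfg)
  expect_identical(r1[order(r1$feature_id), ], r3[order(r3$feature_id), ])
})

test_that("selection probability is monotone in effect size", {
  prob <- vapply(c(0, 0.5, 1), function(beta) {
    sel <- vapply(1:12, function(i) {
      oc <- one_gene_cohort(700 + i + round(1000 * beta), n = 150,
                            n_null = 5,
                            beta = if (beta == 0) -0.0001 else -beta)
      if (beta == 0) {  # true null: neutralize the planted column
        oc$bundle$expression[oc$gene, ] <-
          rnorm(ncol(oc$bundle$expression))
      }
      res <- mccv_screen(oc$bundle,
                         mccv_config(n_iterations = 30, seed = i))
      res$mccv_selected[res$feature_id == oc$gene]
    }, logical(1))
    mean(sel)
  }, numeric(1))
  expect_true(all(diff(prob) >= 0))
  expect_lt(prob[1], 0.2)
  expect_gt(prob[3], 0.8)
})

test_that("sign-consistency filtering keeps single and collinear candidates", {
  b <- random_bundle(n_genes = 12, samples = 80, seed = 64, event_p = 0.5)
  one <- cox_consistency_filter("g001", b)
  expect_true(one$kept)
  expect_equal(one$uni_coef, one$multi_coef)

  # exact duplicates: joint fit degenerate, ridge fallback keeps both
  b$expression[2, ] <- b$expression[1, ]
  dup <- cox_consistency_filter(c("g001", "g002"), b)
  expect_equal(unique(dup$note), "ridge_fallback")
  expect_true(all(dup$kept))
})

test_that("a multivariate sign flip drops a confounded candidate", {
  # x1 truly protective; x2 = x1 + noise + independent harmful component:
  # marginally protective (via x1) but positive in the joint model
  set.seed(65)
  n <- 400
  x1 <- rnorm(n)
  h <- rnorm(n)
  x2 <- 0.9 * x1 + 0.5 * h
  lp <- -1.5 * x1 + 1.2 * h
  t <- rexp(n, 0.005 * exp(lp))
  cens <- runif(n, 36, 96)
  b <- tiny_bundle(rbind(x1 = x1, x2 = x2),
                   time = pmin(t, cens), event = as.integer(t <= cens))
  res <- cox_consistency_filter(c("x1", "x2"), b)
  expect_true(res$kept[res$feature_id == "x1"])
  expect_false(res$kept[res$feature_id == "x2"])
})

test_that("hold-out confirmation gates on coefficient sign", {
  oc <- one_gene_cohort(66, n = 150, n_null = 3)
  rec <- data.frame(feature_id = oc$gene, uni_coef = -0.5)
  ho <- simulate_cohort(sim_params(
    n_sources = 1, samples_per_source = 64, n_genes = 4, n_prognostic = 0,
    batch_shift_sd = 0, seed = 67))$bundle
  rownames(ho$expression)[1] <- oc$gene
  conf <- holdout_confirm(rec, ho)
  expect_identical(conf$final_selected, sign(conf$holdout_coef) == -1)

  # absent feature dropped with warning; empty records pass through
  rec2 <- data.frame(feature_id = "MISSING", uni_coef = 1)
  expect_warning(out <- holdout_confirm(rec2, ho), "absent")
  expect_equal(nrow(out), 0)
  empty <- holdout_confirm(rec2[0, ], ho)
  expect_equal(nrow(empty), 0)
  expect_true("final_selected" %in% names(empty))
})

test_that("a true gene is confirmed in most replicates at holdout n = 64", {
  confirmed <- vapply(1:20, function(i) {
    sim <- simulate_cohort(sim_params(
      n_sources = 2, samples_per_source = c(135, 64), n_genes = 5,
      n_prognostic = 1, effect_sizes = 1, fraction_protective = 1,
      batch_shift_sd = 0.3, seed = 800 + i))
    g <- sim$truth$prognostic_gene_ids
    parts <- split_cohort(sim$bundle, "S1", "S2")
    rec <- data.frame(feature_id = g, uni_coef = -1)
    out <- holdout_confirm(rec, parts$holdout)
    out$final_selected
  }, logical(1))
  expect_gte(mean(confirmed), 0.9)
})
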