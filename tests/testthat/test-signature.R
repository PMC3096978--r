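test_that("signature construction validates members", {
  expect_error(gene_signature("s", character(), numeric()), "at least one")
  expect_error(gene_signature("s", c("A", "A"), 1), "duplicate")
  expect_error(gene_signature("s", c("A", "B"), c(1, 2)), "\\+1 or -1")
})

test_that("packaged signatures carry the published structure", {
  sigs <- hrnegsig_signatures()
  expect_true(all(c("hrneg_tneg_14", "hrneg_11", "tneg_7",
                    "hrneg_tneg_truncated_7") %in% names(sigs)))
  m14 <- sigs$hrneg_tneg_14$members
  expect_equal(nrow(m14), 14)
  expect_setequal(m14$gene_symbol[m14$direction == 1], c("RGS4", "HAPLN1"))
  expect_equal(sum(m14$direction == -1), 12)
  # the 14-gene set is the union of the 11- and 7-gene candidate lists
  u <- union(sigs$hrneg_11$members$gene_symbol,
             sigs$tneg_7$members$gene_symbol)
  expect_setequal(u, m14$gene_symbol)
})

test_that("index formula reproduces the hand-computed 3-gene example", {
  expr <- matrix(c(1.0, 0.5, 0.5), 3, 4,
                 dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  b <- tiny_bundle(expr)
  sig <- gene_signature("ex", c("g1", "g2", "g3"), c(1, -1, -1))
  idx <- compute_index(b, sig)
  expect_equal(unname(idx$score), rep(0, 4))   # (1.0 - 0.5 - 0.5)/3

  zero <- b; zero$expression[] <- 0
  expect_equal(unname(compute_index(zero, sig)$score), rep(0, 4))
})

test_that("missing genes shrink the index denominator (13 of 14 mapped)", {
  sigs <- hrnegsig_signatures()
  genes <- setdiff(sigs$hrneg_tneg_14$members$gene_symbol, "PRRG3")
  expr <- matrix(rnorm(13 * 6), 13, 6, dimnames = list(genes, NULL))
  b <- tiny_bundle(expr)
  mapped <- map_signature(sigs$hrneg_tneg_14, b)
  expect_equal(attr(mapped, "n_mapped"), 13)
  idx <- compute_index(b, sigs$hrneg_tneg_14)
  expect_equal(idx$n_mapped, 13)
  expect_equal(idx$mapped_fraction, 13 / 14)
  nosig <- tiny_bundle(matrix(rnorm(12), 2, 6,
                              dimnames = list(c("q1", "q2"), NULL)))
  expect_error(compute_index(nosig, sigs$hrneg_tneg_14), "no genes map")
})

test_that("index is linear in constant shifts and direction flips", {
  set.seed(71)
  b <- random_bundle(n_genes = 10, samples = 20, seed = 71)
  sig <- gene_signature("s", rownames(b$expression)[1:5],
                        c(1, 1, -1, -1, -1))
  idx <- compute_index(b, sig)
  shifted <- b
  shifted$expression <- b$expression + 2.5
  idx_s <- compute_index(shifted, sig)
  expect_equal(idx_s$score, idx$score + 2.5 * (2 - 3) / 5,
               tolerance = 1e-10)

  flip <- gene_signature("s2", rownames(b$expression)[1:5],
                         c(1, 1, 1, -1, -1))    # g3 moved from N to P
  idx_f <- compute_index(b, flip)
  expect_equal(idx_f$score - idx$score,
               2 * b$expression[3, ] / 5, tolerance = 1e-10)
})

test_that("percentile dichotomization yields the exact group sizes", {
  set.seed(72)
  b <- random_bundle(n_genes = 5, samples = c(100, 100), seed = 72,
                     event_p = 0.5)
  score <- setNames(rnorm(200), colnames(b$expression))
  cp75 <- dichotomize_index(score, b, percentile = 75)
  expect_equal(cp75$n_low, 150)
  expect_equal(cp75$n_high, 50)
  cp50 <- dichotomize_index(score, b, percentile = 50)
  expect_equal(cp50$n_low, 100)
  expect_equal(cp50$n_high, 100)
  expect_error(dichotomize_index(setNames(rep(1, 200), names(score)), b),
               "no valid cut")
})

test_that("cut-point search respects percentile bounds and finds a step", {
  hits <- vapply(1:25, function(i) {
    set.seed(900 + i)
    n <- 400
    score <- rnorm(n)
    thr <- quantile(score, 0.70)
    lp <- ifelse(score >= thr, 1.3, 0)      # hazard step at the 70th pct
    t <- rexp(n, 0.01 * exp(lp))
    cens <- runif(n, 36, 96)
    b <- tiny_bundle(matrix(0, 1, n), time = pmin(t, cens),
                     event = as.integer(t <= cens))
    opt <- optimize_cutpoint(setNames(score, colnames(b$expression)), b)
    expect_gte(opt$percentile, 20)
    expect_lte(opt$percentile, 80)
    opt$percentile
  }, numeric(1))
  expect_lt(abs(median(hits) - 70), 5)
})

test_that("degenerate cut-point searches fail loudly", {
  b <- random_bundle(n_genes = 2, samples = 20, seed = 73, event_p = 0.5)
  score <- setNames(rep(3, 20), colnames(b$expression))
  expect_error(optimize_cutpoint(score, b), "no valid cut")
})

test_that("stepwise addition starts from the strongest gene", {
  firsts <- vapply(1:15, function(i) {
    sim <- simulate_cohort(sim_params(
      n_sources = 1, samples_per_source = 250, n_genes = 6,
      n_prognostic = 6, effect_sizes = c(1, rep(0.2, 5)),
      fraction_protective = 1, batch_shift_sd = 0, risk_loading = 0.2,
      seed = 1100 + i))
    strong <- names(which.min(sim$truth$true_betas))
    zb <- z_transform_within_source(sim$bundle)
    cand <- data.frame(feature_id = names(sim$truth$true_betas),
                       direction = sign(sim$truth$true_betas))
    sw <- stepwise_addition(cand, zb)
    sw$order[1] == strong
  }, logical(1))
  expect_gte(mean(firsts), 0.9)
})

test_that("stepwise bookkeeping covers single genes and noise additions", {
  b <- random_bundle(n_genes = 8, samples = 60, seed = 74, event_p = 0.5)
  one <- stepwise_addition(data.frame(feature_id = "g001", direction = -1), b)
  expect_identical(one$order, "g001")
  expect_equal(nrow(one$steps), 1)

  cand <- data.frame(feature_id = rownames(b$expression),
                     direction = rep(c(1, -1), 4))
  sw <- stepwise_addition(cand, b)
  expect_equal(nrow(sw$steps), 8)           # nothing pruned, all recorded
  expect_setequal(sw$order, cand$feature_id)
  expect_true(all(sw$best_subset == sw$order[seq_along(sw$best_subset)]))
})

test_that("stepwise subtraction degrades when the prognostic gene leaves", {
  sim <- simulate_cohort(sim_params(
    n_sources = 1, samples_per_source = 300, n_genes = 2, n_prognostic = 1,
    effect_sizes = 1.2, fraction_protective = 1, batch_shift_sd = 0,
    seed = 75))
  zb <- z_transform_within_source(sim$bundle)
  g <- sim$truth$prognostic_gene_ids
  other <- setdiff(rownames(zb$expression), g)
  sig <- gene_signature("two", c(g, other), c(-1, -1))
  sw <- stepwise_subtraction(sig, zb)
  # removing the noise gene first leaves the prognostic one: better P
  expect_identical(sw$removal_order[1], other)

  single <- gene_signature("one", g, -1)
  sw1 <- stepwise_subtraction(single, zb)
  expect_length(sw1$removal_order, 0)
})
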