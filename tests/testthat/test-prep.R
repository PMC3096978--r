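test_that("mean centering zeroes per-source feature means and is idempotent", {
  b <- tiny_bundle(matrix(c(1, 2, 3), 1, 3))
  cb <- mean_center_within_source(b)
  expect_equal(unname(cb$expression[1, ]), c(-1, 0, 1))

  b2 <- random_bundle(n_genes = 30, samples = c(10, 15), seed = 2)
  b2$expression[, b2$clinical$source == "S1"] <-
    b2$expression[, b2$clinical$source == "S1"] + 5
  b2$expression[, b2$clinical$source == "S2"] <-
    b2$expression[, b2$clinical$source == "S2"] - 5
  cb2 <- mean_center_within_source(b2)
  for (s in c("S1", "S2"))
    expect_lt(max(abs(rowMeans(
      cb2$expression[, cb2$clinical$source == s]))), 1e-9)
  twice <- mean_center_within_source(cb2)
  expect_equal(twice$expression, cb2$expression, tolerance = 1e-12)

  one <- tiny_bundle(matrix(1, 1, 1))
  expect_error(mean_center_within_source(one), "fewer than 2")
})

test_that("Z-transform standardizes per source with sample SD", {
  b <- tiny_bundle(matrix(c(1, 2, 3), 1, 3))
  zb <- z_transform_within_source(b)
  expect_equal(unname(zb$expression[1, ]), c(-1, 0, 1))  # SD = 1 (n-1)

  const <- tiny_bundle(matrix(c(5, 5, 5, 1, 2, 3), 2, 3, byrow = TRUE))
  zc <- z_transform_within_source(const)
  expect_equal(unname(zc$expression[1, ]), c(0, 0, 0))
  tr <- zc$transforms[[length(zc$transforms)]]
  expect_true("g01" %in% tr$params$zero_variance_features)

  mixed <- random_bundle(n_genes = 20, samples = c(8, 12), seed = 3)
  zm <- z_transform_within_source(mixed)
  for (s in c("S1", "S2")) {
    x <- zm$expression[, zm$clinical$source == s]
    expect_lt(max(abs(rowMeans(x))), 1e-9)
    expect_lt(max(abs(apply(x, 1, sd) - 1)), 1e-9)
  }
})

test_that("variance filter applies the strict >twofold, >=10% rule", {
  # 100 samples; feature deviating by 1.2 in exactly 10 samples is kept
  x10 <- c(rep(1.2, 10), rep(0, 90)); x10 <- x10 - mean(x10)
  x9 <- c(rep(1.5, 9), rep(0, 91)); x9 <- x9 - mean(x9)
  expr <- rbind(kept = x10 + 5, dropped = x9 + 5, constant = rep(2, 100))
  b <- tiny_bundle(expr, time = rexp(100), event = rbinom(100, 1, 0.5))
  vf <- variance_filter(b)
  expect_identical(vf$kept, "kept")
  expect_identical(rownames(vf$bundle$expression), "kept")
})

test_that("variance filter is monotone in min_fraction", {
  b <- random_bundle(n_genes = 100, samples = 30, seed = 4)
  b$expression <- b$expression * matrix(runif(100, 0.3, 2), 100, 30)
  kept_loose <- variance_filter(b, min_fraction = 0.05)$kept
  kept_tight <- variance_filter(b, min_fraction = 0.20)$kept
  expect_true(all(kept_tight %in% kept_loose))
})

test_that("probe collapse averages probes and drops unmapped ones", {
  expr <- matrix(c(0.4, 0.6, 1.0, 9.9), 4, 1,
                 dimnames = list(c("p1", "p2", "p3", "p4"), "s1"))
  expr <- cbind(expr, expr)  # two samples to satisfy bundle invariants
  colnames(expr) <- c("s1", "s2")
  b <- cohort_bundle(expr,
                     data.frame(sample_id = c("s1", "s2"), source = "A",
                                dmfs_months = c(1, 2), dmfs_event = c(1, 0)),
                     feature_map = data.frame(
                       probe_id = c("p1", "p2", "p3"),
                       gene_symbol = c("GENEA", "GENEA", "GENEB")))
  cb <- collapse_probes(b)
  expect_equal(unname(cb$expression["GENEA", "s1"]), 0.5)
  expect_equal(unname(cb$expression["GENEB", "s1"]), 1.0)  # single probe
  expect_false("p4" %in% rownames(cb$expression))
  tr <- cb$transforms[[length(cb$transforms)]]
  expect_equal(tr$params$n_unmapped_dropped, 1)
  b$feature_map <- NULL
  expect_error(collapse_probes(b), "feature_map")
})

test_that("probe collapse commutes with sample subsetting", {
  set.seed(9)
  expr <- matrix(rnorm(40), 8, 5,
                 dimnames = list(paste0("p", 1:8), paste0("s", 1:5)))
  fm <- data.frame(probe_id = paste0("p", 1:8),
                   gene_symbol = rep(c("GA", "GB", "GC", "GD"), 2))
  clin <- data.frame(sample_id = paste0("s", 1:5), source = "A",
                     dmfs_months = 1:5, dmfs_event = rep(c(0, 1), c(2, 3)))
  b <- cohort_bundle(expr, clin, feature_map = fm)
  sub_then_collapse <- collapse_probes(
    hrnegsig:::subset_samples(b, c("s2", "s4")))
  collapse_then_sub <- hrnegsig:::subset_samples(
    collapse_probes(b), c("s2", "s4"))
  expect_equal(sub_then_collapse$expression, collapse_then_sub$expression)
})

test_that("HER2 assignment centers per source and cuts at zero", {
  expr <- rbind(ERBB2 = c(1, 2, 9), other = c(0, 0, 0))
  b <- tiny_bundle(expr, time = c(3, 2, 1), event = c(1, 1, 1))
  hb <- assign_her2_status(b)
  expect_equal(hb$clinical$her2_status, c("neg", "neg", "pos"))
  expect_equal(hb$clinical$tneg, c(TRUE, TRUE, FALSE))

  # boundary: all-equal ERBB2 centers to 0, which is not > 0 -> all negative
  expr2 <- rbind(ERBB2 = c(4, 4, 4), other = c(1, 2, 3))
  hb2 <- assign_her2_status(tiny_bundle(expr2))
  expect_true(all(hb2$clinical$her2_status == "neg"))
  expect_true(all(hb2$clinical$tneg))

  expect_error(assign_her2_status(tiny_bundle(expr2), "ABSENT"),
               "not present")
})

test_that("HER2 recovery on simulated bimodal ERBB2 is accurate", {
  sim <- simulate_cohort(sim_params(n_genes = 200, seed = 21))
  hb <- assign_her2_status(sim$bundle)
  acc <- mean((hb$clinical$her2_status == "pos") ==
                unname(sim$truth$her2_positive))
  expect_gt(acc, 0.9)
})

test_that("merging removes an exact inter-source shift (both strategies)", {
  # every gene is a permutation of one base vector, so all within-source
  # variances are exactly equal and the batch gap is a pure translation
  set.seed(6)
  base_v <- rnorm(15)
  expr <- t(vapply(1:40, function(i) sample(base_v), numeric(15)))
  rownames(expr) <- sprintf("g%03d", 1:40)
  base <- tiny_bundle(expr, source = rep("S1", 15),
                      time = rexp(15), event = rbinom(15, 1, 0.5))
  shifted <- base
  shifted$expression <- base$expression + 3        # pure location batch
  shifted$clinical$source <- "S2"
  shifted$clinical$sample_id <- paste0("T_", seq_len(15))
  colnames(shifted$expression) <- shifted$clinical$sample_id
  for (strat in c("center", "dwd_lite")) {
    m <- merge_cohorts(list(base, shifted), strategy = strat)
    mu1 <- rowMeans(m$expression[, m$clinical$source == "S1"])
    mu2 <- rowMeans(m$expression[, m$clinical$source == "S2"])
    expect_lt(max(abs(mu1 - mu2)), 1e-6)
  }
})

test_that("dwd_lite is a pure translation preserving within-source geometry", {
  a <- random_bundle(n_genes = 30, samples = 12, seed = 7)
  b <- random_bundle(n_genes = 30, samples = 10, seed = 8)
  b$clinical$source <- "S2"
  b$clinical$sample_id <- paste0("B_", seq_len(10))
  colnames(b$expression) <- b$clinical$sample_id
  m <- merge_cohorts(list(a, b), strategy = "dwd_lite")
  xb <- m$expression[, m$clinical$source == "S2"]
  expect_equal(c(dist(t(xb))), c(dist(t(b$expression))), tolerance = 1e-10)
})

test_that("merge intersects features and passes single bundles through", {
  mk <- function(genes, pre, seed) {
    b <- random_bundle(n_genes = length(genes), samples = 6, seed = seed)
    rownames(b$expression) <- genes
    b$clinical$source <- pre
    b$clinical$sample_id <- paste0(pre, "_", 1:6)
    colnames(b$expression) <- b$clinical$sample_id
    b
  }
  b1 <- mk(c("A", "B", "C"), "X", 1)
  b2 <- mk(c("B", "C", "D"), "Y", 2)
  b3 <- mk(c("B", "C"), "Z", 3)
  m <- merge_cohorts(list(b1, b2, b3))
  expect_setequal(rownames(m$expression), c("B", "C"))
  expect_error(merge_cohorts(list(b1, mk("Q", "W", 4))),
               "empty feature intersection")
  single <- merge_cohorts(list(b1))
  expect_equal(single$expression, b1$expression)
})

test_that("transforms are invariant to sample and feature permutations", {
  b <- random_bundle(n_genes = 25, samples = c(10, 10), seed = 11)
  ps <- sample(colnames(b$expression))
  pf <- sample(rownames(b$expression))
  perm <- hrnegsig:::subset_samples(b, ps)
  perm$expression <- perm$expression[pf, ]
  z1 <- z_transform_within_source(b)
  z2 <- z_transform_within_source(perm)
  expect_equal(z2$expression, z1$expression[pf, ps], tolerance = 1e-12)
})

test_that("center-merging after Z-transform is a no-op", {
  b <- random_bundle(n_genes = 20, samples = c(10, 12), seed = 12)
  zb <- z_transform_within_source(b)
  halves <- lapply(hrnegsig:::bundle_by_source(zb), identity)
  m <- merge_cohorts(halves, strategy = "center")
  m_expr <- m$expression[rownames(zb$expression), colnames(zb$expression)]
  expect_equal(m_expr, zb$expression, tolerance = 1e-9)
})
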