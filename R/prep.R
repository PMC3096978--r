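#' Mean-center expression within each data source
#'
#' Subtracts, for every (source, feature) pair, the mean over that source's
#' samples, removing additive batch offsets to first order. Idempotent.
#'
#' @param bundle a [cohort_bundle()] with log2-scale expression.
#' @return the centered bundle, with a transform record appended.
#' @export
mean_center_within_source <- function(bundle) {
  src <- bundle$clinical$source
  cnt <- table(src)
  if (any(cnt < 2))
    stop("source(s) with fewer than 2 samples: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  means <- list()
  for (s in unique(src)) {
    cols <- which(src == s)
    m <- rowMeans(bundle$expression[, cols, drop = FALSE])
    bundle$expression[, cols] <- bundle$expression[, cols, drop = FALSE] - m
    means[[s]] <- unname(m)
  }
  record_transform(bundle, "mean_center_within_source",
                   list(sources = unique(src)))
}

#' Z-transform expression within each data source
#'
#' Per (source, feature), centers to mean 0 and scales to unit sample SD
#' (n - 1 denominator). Zero-variance features are left centered at zero and
#' flagged in the transform record rather than divided by zero.
#'
#' @inheritParams mean_center_within_source
#' @return the standardized bundle.
#' @export
z_transform_within_source <- function(bundle) {
  src <- bundle$clinical$source
  cnt <- table(src)
  if (any(cnt < 2))
    stop("source(s) with fewer than 2 samples: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  flagged <- character()
  for (s in unique(src)) {
    cols <- which(src == s)
    x <- bundle$expression[, cols, drop = FALSE]
    m <- rowMeans(x)
    x <- x - m
    sd_ <- sqrt(rowSums(x^2) / (length(cols) - 1))
    zv <- sd_ <= 0
    sd_[zv] <- 1                       # leave constant features at 0
    bundle$expression[, cols] <- x / sd_
    flagged <- union(flagged, rownames(x)[zv])
  }
  record_transform(bundle, "z_transform_within_source",
                   list(sources = unique(src),
                        zero_variance_features = flagged))
}

#' Minimum-variation filter
#'
#' Keeps a feature iff at least `min_fraction` of samples deviate from the
#' feature's mean by strictly more than `log2_fold` log2 units (the default
#' of 1.0 corresponds to greater-than-twofold variation on the natural
#' scale).
#'
#' @inheritParams mean_center_within_source
#' @param min_fraction minimum proportion of samples that must exceed the
#'   deviation threshold (default 0.10).
#' @param log2_fold deviation threshold in log2 units (default 1.0).
#' @return list with `bundle` (filtered) and `kept` (surviving feature ids).
#' @export
variance_filter <- function(bundle, min_fraction = 0.10, log2_fold = 1.0) {
  x <- bundle$expression
  if (nrow(x) == 0 || ncol(x) == 0) stop("empty expression matrix")
  dev <- abs(x - rowMeans(x))
  frac <- rowMeans(dev > log2_fold)
  kept <- rownames(x)[frac >= min_fraction]
  b <- bundle
  b$expression <- x[kept, , drop = FALSE]
  b <- record_transform(b, "variance_filter",
                        list(min_fraction = min_fraction,
                             log2_fold = log2_fold,
                             n_in = nrow(x), n_kept = length(kept)))
  list(bundle = b, kept = kept)
}

#' Collapse probe-level rows to gene symbols
#'
#' Re-keys the expression matrix by gene symbol using the bundle's
#' `feature_map`; a gene measured by several probes gets the unweighted mean
#' of its probes' values. Probes without a symbol are dropped and counted in
#' the transform record.
#'
#' @inheritParams mean_center_within_source
#' @return a bundle keyed by gene symbol (feature_map cleared).
#' @export
collapse_probes <- function(bundle) {
  fm <- bundle$feature_map
  if (is.null(fm) || nrow(fm) == 0) stop("feature_map is empty")
  fm <- fm[!is.na(fm$gene_symbol) & fm$gene_symbol != "", , drop = FALSE]
  fm <- fm[fm$probe_id %in% rownames(bundle$expression), , drop = FALSE]
  n_unmapped <- sum(!rownames(bundle$expression) %in% fm$probe_id)
  if (nrow(fm) == 0) stop("no probes could be mapped to gene symbols")
  sym <- factor(fm$gene_symbol, levels = unique(fm$gene_symbol))
  x <- bundle$expression[fm$probe_id, , drop = FALSE]
  collapsed <- rowsum(x, sym, reorder = FALSE) / as.vector(table(sym))
  b <- bundle
  b$expression <- as.matrix(collapsed)
  b$feature_map <- NULL
  record_transform(b, "collapse_probes",
                   list(n_probes = nrow(fm), n_genes = nrow(collapsed),
                        n_unmapped_dropped = n_unmapped))
}

#' Assign HER2 status from an ERBB2-like transcript
#'
#' Per data source, ERBB2 expression is mean-centered; samples with a
#' centered value strictly greater than `threshold` are labeled
#' HER2-positive, all others HER2-negative. A `tneg` (triple-negative) flag
#' is derived as: estrogen receptor negative AND progesterone receptor
#' negative-or-unknown AND HER2-negative.
#'
#' @inheritParams mean_center_within_source
#' @param erbb2_feature_id row name of the ERBB2 transcript (default
#'   `"ERBB2"`).
#' @param threshold cut on the per-source centered log2 value (default 0;
#'   the boundary value itself is labeled negative).
#' @return bundle with `her2_status` filled and a logical `tneg` clinical
#'   column added.
#' @export
assign_her2_status <- function(bundle, erbb2_feature_id = "ERBB2",
                               threshold = 0) {
  if (!erbb2_feature_id %in% rownames(bundle$expression))
    stop("feature `", erbb2_feature_id, "` not present in expression matrix")
  e <- bundle$expression[erbb2_feature_id, ]
  src <- bundle$clinical$source
  centered <- e - stats::ave(e, src)
  pos <- centered > threshold
  bundle$clinical$her2_status <- ifelse(pos, "pos", "neg")
  bundle$clinical$tneg <- bundle$clinical$er_status == "neg" &
    bundle$clinical$pr_status %in% c("neg", "unknown") & !pos
  record_transform(bundle, "assign_her2_status",
                   list(erbb2_feature_id = erbb2_feature_id,
                        threshold = threshold,
                        n_positive = sum(pos)))
}

#' Merge cohorts from different sources into one bundle
#'
#' Intersects features across bundles and removes inter-source location
#' shifts before concatenation. Strategy `"center"` mean-centers every
#' feature within each source. Strategy `"dwd_lite"` translates each bundle
#' toward a reference along a margin-weighted discriminant direction (the
#' between-bundle mean difference standardized by pooled within-bundle SD),
#' so that the projected batch means coincide; being a pure translation it
#' preserves all within-source sample geometry exactly.
#'
#' @param bundles list of [cohort_bundle()] objects (a single bundle is
#'   returned unchanged apart from feature ordering).
#' @param strategy `"center"` or `"dwd_lite"`.
#' @param reference index of the reference bundle for `"dwd_lite"`.
#' @return a merged [cohort_bundle()].
#' @export
merge_cohorts <- function(bundles, strategy = c("center", "dwd_lite"),
                          reference = 1L) {
  strategy <- match.arg(strategy)
  if (inherits(bundles, "cohort_bundle")) bundles <- list(bundles)
  feats <- Reduce(intersect, lapply(bundles, function(b) rownames(b$expression)))
  if (length(feats) == 0) stop("empty feature intersection across bundles")
  bundles <- lapply(bundles, subset_features, feature_ids = feats)
  if (length(bundles) == 1) return(bundles[[1]])

  if (strategy == "center") {
    bundles <- lapply(bundles, function(b) {
      for (s in unique(b$clinical$source)) {
        cols <- which(b$clinical$source == s)
        b$expression[, cols] <- b$expression[, cols, drop = FALSE] -
          rowMeans(b$expression[, cols, drop = FALSE])
      }
      b
    })
  } else {
    ref <- bundles[[reference]]
    mu_ref <- rowMeans(ref$expression)
    pooled_sd <- function(a, b) {
      va <- apply(a, 1, stats::var)
      vb <- apply(b, 1, stats::var)
      sqrt(((ncol(a) - 1) * va + (ncol(b) - 1) * vb) /
             (ncol(a) + ncol(b) - 2))
    }
    for (i in setdiff(seq_along(bundles), reference)) {
      x <- bundles[[i]]$expression
      mu_i <- rowMeans(x)
      s <- pooled_sd(ref$expression, x)
      s0 <- stats::median(s)
      w <- (mu_ref - mu_i) / (s + s0)     # margin-weighted discriminant
      nw <- sqrt(sum(w^2))
      if (nw > 0) {
        w <- w / nw
        shift <- sum((mu_ref - mu_i) * w)  # projected mean gap
        bundles[[i]]$expression <- x + shift * w
      }
    }
  }
  expr <- do.call(cbind, lapply(bundles, function(b) b$expression))
  clin <- do.call(rbind, lapply(bundles, function(b) b$clinical))
  merged <- cohort_bundle(expr, clin)
  merged$transforms <- do.call(c, lapply(bundles, function(b) b$transforms))
  record_transform(merged, "merge_cohorts",
                   list(strategy = strategy, n_bundles = length(bundles),
                        n_features = length(feats)))
}
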