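#' Discovery pipeline configuration
#'
#' @param pam_top_k target per-source PAM feature count (default 300).
#' @param pam_labels class labels for the PAM screen: `"event"` (distant
#'   metastasis event vs event-free, the default) or `"landmark5y"` (event
#'   within 60 months vs event-free with at least 60 months of follow-up;
#'   censored short-follow-up cases excluded).
#' @param min_fraction,log2_fold variance-filter parameters (see
#'   [variance_filter()]).
#' @param mccv an [mccv_config()].
#' @param candidate_merge how the PAM and MC-CV candidate sets combine
#'   before Cox filtering: `"union"` (default) or `"intersection"`.
#' @return list of class `discovery_config`.
#' @export
discovery_config <- function(pam_top_k = 300L,
                             pam_labels = c("event", "landmark5y"),
                             min_fraction = 0.10, log2_fold = 1.0,
                             mccv = mccv_config(),
                             candidate_merge = c("union", "intersection")) {
  structure(list(pam_top_k = as.integer(pam_top_k),
                 pam_labels = match.arg(pam_labels),
                 min_fraction = min_fraction, log2_fold = log2_fold,
                 mccv = mccv,
                 candidate_merge = match.arg(candidate_merge)),
            class = "discovery_config")
}

# PAM class labels under the configured rule; NA = excluded sample
pam_class_labels <- function(clinical, rule) {
  if (rule == "event") return(clinical$dmfs_event)
  ifelse(clinical$dmfs_event == 1 & clinical$dmfs_months <= 60, 1L,
         ifelse(clinical$dmfs_event == 0 & clinical$dmfs_months >= 60, 0L,
                NA_integer_))
}

# one full screening chain (PAM + MC-CV + Cox consistency + hold-out) on a
# sample subset; returns the per-candidate audit records
run_discovery_chain <- function(bundle, discovery_sources, holdout_sources,
                                config) {
  parts <- split_cohort(bundle, discovery_sources, holdout_sources)
  disc <- parts$discovery
  hold <- parts$holdout

  # PAM screen per discovery source, intersected across sources
  labels <- pam_class_labels(disc$clinical, config$pam_labels)
  pam_bundle <- disc
  if (anyNA(labels)) {
    keep <- !is.na(labels)
    pam_bundle <- subset_samples(disc, disc$clinical$sample_id[keep])
    labels <- labels[keep]
  }
  screens <- pam_screen(pam_bundle, labels, top_k = config$pam_top_k)
  pam_set <- if (length(screens) >= 2) pam_intersect(screens)
  else screens[[1]]$feature_id[screens[[1]]$selected]

  # variance filter on log2 deviations, then Z-transform within source
  vf <- variance_filter(disc, config$min_fraction, config$log2_fold)
  zdisc <- z_transform_within_source(vf$bundle)

  # MC-CV univariate Cox screen
  mccv <- mccv_screen(zdisc, config$mccv)
  mccv_set <- mccv$feature_id[mccv$mccv_selected]

  pool <- switch(config$candidate_merge,
                 union = union(pam_set, mccv_set),
                 intersection = intersect(pam_set, mccv_set))
  pool <- intersect(pool, rownames(bundle$expression))

  if (!length(pool)) {
    rec <- data.frame(feature_id = character(), uni_coef = numeric(),
                      uni_p = numeric(), multi_coef = numeric(),
                      multi_p = numeric(), kept = logical(),
                      note = character(), stringsAsFactors = FALSE)
  } else {
    # Cox consistency on Z-transformed discovery data (all features, so the
    # candidate pool is not limited to variance-filter survivors)
    zfull <- z_transform_within_source(disc)
    rec <- cox_consistency_filter(pool, zfull)
  }
  rec$pam_selected <- rec$feature_id %in% pam_set
  rec$mccv_selected <- rec$feature_id %in% mccv_set
  rec$mccv_mean_p <- mccv$mccv_mean_p[match(rec$feature_id, mccv$feature_id)]
  rec$mccv_consistency <-
    mccv$mccv_consistency[match(rec$feature_id, mccv$feature_id)]

  confirmed <- holdout_confirm(rec[rec$kept, , drop = FALSE], hold)
  rec$holdout_coef <- confirmed$holdout_coef[match(rec$feature_id,
                                                   confirmed$feature_id)]
  rec$holdout_p <- confirmed$holdout_p[match(rec$feature_id,
                                             confirmed$feature_id)]
  rec$final_selected <- rec$feature_id %in%
    confirmed$feature_id[confirmed$final_selected]
  rec$direction <- sign(rec$uni_coef)
  rec
}

#' Discover a prognostic gene signature from a multi-source cohort
#'
#' The package's central fitting function. Runs the full candidate-selection
#' chain twice -- once on all (hormone receptor-negative) samples and once
#' on the triple-negative subset -- and combines the two confirmed candidate
#' lists into one non-redundant signature with per-gene hazard directions
#' taken from the discovery univariate Cox coefficient signs.
#'
#' Each chain: (1) PAM nearest-shrunken-centroid screen per discovery
#' source, intersected across sources keeping only sign-consistent scores;
#' (2) minimum-variation filter, per-source Z-transform, and Monte-Carlo
#' cross-validation univariate Cox screen; (3) union of the two candidate
#' sets, filtered for univariate/multivariate Cox coefficient sign
#' consistency on the discovery data; (4) hold-out confirmation by
#' coefficient sign in the reserved source(s).
#'
#' @param bundle a [cohort_bundle()] whose clinical table carries a `tneg`
#'   flag (run [assign_her2_status()] first).
#' @param discovery character vector of discovery source labels.
#' @param holdout hold-out source labels (default: the remaining sources).
#' @param config a [discovery_config()].
#' @return an object of class `signature_fit` with elements
#'   `hrneg_records`, `tneg_records` (per-candidate audit tables),
#'   `hrneg_genes`, `tneg_genes`, `signature` (the combined
#'   [gene_signature()]), `config`, `n`, `call`. Methods: `print`,
#'   `summary`, `coef` (Table-style candidate matrix), `predict` (composite
#'   index on a new bundle), `plot` (Kaplan-Meier curves of the
#'   dichotomized index).
#' @export
discover_signature <- function(bundle, discovery, holdout = NULL,
                               config = discovery_config()) {
  if (is.null(bundle$clinical$tneg))
    stop("bundle has no `tneg` flag; run assign_her2_status() first")
  hr_rec <- run_discovery_chain(bundle, discovery, holdout, config)
  tneg_ids <- bundle$clinical$sample_id[bundle$clinical$tneg]
  tn_bundle <- subset_samples(bundle, tneg_ids)
  tn_rec <- run_discovery_chain(tn_bundle, discovery, holdout, config)

  hr_genes <- hr_rec$feature_id[hr_rec$final_selected]
  tn_genes <- tn_rec$feature_id[tn_rec$final_selected]
  combined <- union(hr_genes, tn_genes)
  dir_of <- function(g) {
    d <- hr_rec$direction[match(g, hr_rec$feature_id)]
    d2 <- tn_rec$direction[match(g, tn_rec$feature_id)]
    out <- ifelse(is.na(d), d2, d)
    conflict <- !is.na(d) & !is.na(d2) & d != d2
    if (any(conflict))
      warning("hazard-direction conflict for: ",
              paste(g[conflict], collapse = ", "),
              " (HRneg direction kept)")
    out
  }
  sig <- if (length(combined))
    gene_signature("HRneg/Tneg (discovered)", combined, dir_of(combined),
                   provenance = "discover_signature()")
  else NULL
  structure(list(hrneg_records = hr_rec, tneg_records = tn_rec,
                 hrneg_genes = hr_genes, tneg_genes = tn_genes,
                 signature = sig, config = config,
                 n = ncol(bundle$expression), n_tneg = length(tneg_ids),
                 call = match.call()),
            class = "signature_fit")
}

#' @export
print.signature_fit <- function(x, ...) {
  cat("Prognostic signature fit\n")
  cat(sprintf("  cohort: %d samples (%d triple-negative)\n", x$n, x$n_tneg))
  cat(sprintf("  HRneg candidates confirmed: %d\n", length(x$hrneg_genes)))
  cat(sprintf("  Tneg  candidates confirmed: %d\n", length(x$tneg_genes)))
  cat(sprintf("  combined signature size:    %d\n",
              if (is.null(x$signature)) 0L else nrow(x$signature$members)))
  invisible(x)
}

#' @export
summary.signature_fit <- function(object, ...) {
  cat("HRneg chain candidate records:\n")
  print(object$hrneg_records, digits = 3)
  cat("\nTneg chain candidate records:\n")
  print(object$tneg_records, digits = 3)
  invisible(object)
}

#' @export
coef.signature_fit <- function(object, ...) {
  rec <- rbind(object$hrneg_records, object$tneg_records)
  rec <- rec[rec$final_selected, , drop = FALSE]
  rec <- rec[!duplicated(rec$feature_id), , drop = FALSE]
  out <- rec[, c("feature_id", "uni_coef", "uni_p", "multi_coef", "multi_p"),
             drop = FALSE]
  names(out)[1] <- "gene"
  rownames(out) <- NULL
  out
}

#' @export
predict.signature_fit <- function(object, newdata, ...) {
  if (is.null(object$signature)) stop("empty signature: nothing to predict")
  compute_index(newdata, object$signature)
}

#' @export
plot.signature_fit <- function(x, bundle, percentile = 75, ...) {
  idx <- predict(x, bundle)
  cp <- dichotomize_index(idx, bundle, percentile = percentile)
  km <- km_estimate(bundle$clinical$dmfs_months, bundle$clinical$dmfs_event,
                    cp$groups)
  plot_km(km, main = sprintf("Composite index, cut at %gth percentile",
                             percentile), ...)
  invisible(cp)
}

# base-graphics KM step plot used by plot methods
plot_km <- function(km, main = "", col = c("darkgreen", "red3", "blue3",
                                           "orange3")) {
  graphics::plot(NA, xlim = c(0, max(unlist(lapply(km$curves, function(d)
    max(c(0, d$time)))))), ylim = c(0, 1),
    xlab = "Months", ylab = "DMFS probability", main = main)
  i <- 0
  for (g in names(km$curves)) {
    i <- i + 1
    cv <- km$curves[[g]]
    graphics::lines(stats::stepfun(cv$time, c(1, cv$surv)),
                    do.points = FALSE, col = col[(i - 1) %% length(col) + 1])
  }
  graphics::legend("bottomleft", legend = names(km$curves),
                   col = col[seq_along(km$curves)], lty = 1, bty = "n")
  if (!is.na(km$logrank_p))
    graphics::mtext(sprintf("log-rank P = %.2g", km$logrank_p), side = 3,
                    line = 0, cex = 0.8)
  invisible(NULL)
}
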