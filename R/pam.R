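#' Nearest-shrunken-centroid (PAM) feature screen per source
#'
#' Implements the prediction-analysis-of-microarrays feature scores for a
#' binary outcome, applied independently within each data source. For
#' feature i and class k the standardized centroid deviation is
#' `d_ik = (xbar_ik - xbar_i) / (m_k * (s_i + s0))` with
#' `m_k = sqrt(1/n_k - 1/n)`, `s_i` the pooled within-class SD and `s0` the
#' median of the `s_i`. Scores are soft-thresholded by a shrinkage `Delta`
#' chosen per source so the number of surviving features is closest to
#' `top_k`; the reported per-feature score is the signed (shrunken) deviation
#' for the event class.
#'
#' @param bundle a multi-source [cohort_bundle()]; the screen runs on each
#'   source separately using that source's log2 expression.
#' @param labels binary class labels (0/1) per sample, aligned with the
#'   bundle's samples; by default the distant-metastasis event flag.
#' @param top_k target number of surviving features per source (default 300).
#' @return object of class `pam_screen`: named list per source, each a
#'   data.frame with `feature_id`, `score` (shrunken event-class deviation),
#'   `selected`.
#' @export
pam_screen <- function(bundle, labels = NULL, top_k = 300L) {
  if (is.null(labels)) labels <- bundle$clinical$dmfs_event
  if (length(labels) != ncol(bundle$expression))
    stop("labels must align with bundle samples")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  out <- list()
  for (s in unique(bundle$clinical$source)) {
    cols <- which(bundle$clinical$source == s)
    y <- labels[cols]
    if (length(unique(y)) < 2)
      stop("source `", s, "`: both classes must be present")
    if (min(table(y)) < 2)
      stop("source `", s, "`: at least 2 samples per class required")
    out[[s]] <- pam_scores_one(bundle$expression[, cols, drop = FALSE], y,
                               top_k)
  }
  structure(out, class = "pam_screen")
}

# nearest-shrunken-centroid scores for one source; y in {0,1}, event class 1
pam_scores_one <- function(X, y, top_k) {
  n <- ncol(X)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  xbar <- rowMeans(X)
  xbar1 <- rowMeans(X[, y == 1, drop = FALSE])
  xbar0 <- rowMeans(X[, y == 0, drop = FALSE])
  # pooled within-class SD
  ss <- rowSums((X[, y == 1, drop = FALSE] - xbar1)^2) +
    rowSums((X[, y == 0, drop = FALSE] - xbar0)^2)
  s_i <- sqrt(ss / (n - 2))
  s0 <- stats::median(s_i)
  m1 <- sqrt(1 / n1 - 1 / n)
  m0 <- sqrt(1 / n0 - 1 / n)
  d1 <- (xbar1 - xbar) / (m1 * (s_i + s0))
  d0 <- (xbar0 - xbar) / (m0 * (s_i + s0))
  dmax <- pmax(abs(d1), abs(d0))
  # shrinkage chosen so the surviving count is closest to top_k
  cand <- sort(unique(c(0, dmax)), decreasing = TRUE)
  surv_counts <- vapply(cand, function(dl) sum(dmax > dl), integer(1))
  delta <- cand[which.min(abs(surv_counts - min(top_k, nrow(X))))]
  shrink <- function(d) sign(d) * pmax(abs(d) - delta, 0)
  d1s <- shrink(d1)
  selected <- dmax > delta
  data.frame(feature_id = rownames(X), score = d1s, selected = selected,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Intersect per-source PAM selections
#'
#' Keeps features selected in every screened source whose score carries the
#' same sign in all sources; a sign disagreement drops the feature.
#'
#' @param screens a [pam_screen()] result covering at least 2 sources.
#' @return character vector of surviving feature ids.
#' @export
pam_intersect <- function(screens) {
  if (length(screens) < 2)
    stop("pam_intersect requires screens from at least 2 sources")
  sel <- lapply(screens, function(d) d[d$selected, , drop = FALSE])
  common <- Reduce(intersect, lapply(sel, `[[`, "feature_id"))
  if (!length(common)) return(character())
  signs <- vapply(sel, function(d)
    sign(d$score[match(common, d$feature_id)]), numeric(length(common)))
  signs <- matrix(signs, nrow = length(common))
  agree <- apply(signs, 1, function(v) all(v == v[1]) && v[1] != 0)
  common[agree]
}
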