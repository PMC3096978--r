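#' Compare prognostic performance of several signatures at a common cut
#'
#' Maps each signature onto the cohort, computes its composite index, and
#' dichotomizes every signature at the same cut (the median by default --
#' the anti-bias rule when comparing a newly trained signature against
#' established ones). Reports the Cox hazard ratio of the high vs low group
#' with 95% CI and Wald P, and the log-rank P.
#'
#' @param bundle transformed/merged [cohort_bundle()] keyed by gene symbol.
#' @param library named list of [gene_signature()] objects.
#' @param percentile common dichotomization percentile (default 50).
#' @return data.frame of class `comparison_report`, one row per signature:
#'   `signature`, `n_mapped`, `mapped_fraction`, `hr`, `ci_lower`,
#'   `ci_upper`, `cox_p`, `logrank_p`.
#' @export
compare_prognosis <- function(bundle, library, percentile = 50) {
  if (is.null(names(library)))
    names(library) <- vapply(library, `[[`, "", "name")
  rows <- lapply(names(library), function(nm) {
    idx <- compute_index(bundle, library[[nm]])
    cp <- dichotomize_index(idx, bundle, percentile = percentile)
    data.frame(signature = nm, n_mapped = idx$n_mapped,
               mapped_fraction = idx$mapped_fraction,
               hr = cp$hr_high_vs_low, ci_lower = cp$ci95[1],
               ci_upper = cp$ci95[2], cox_p = cp$cox_p,
               logrank_p = cp$logrank_p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' Pairwise Pearson correlations between signature indices
#'
#' Correlates every pair of per-sample signature indices (Pearson, two-sided
#' P from the t distribution on n - 2 df). Given a second cohort's index
#' set, a pair is flagged "consistent" iff the correlation signs agree
#' across the two cohorts. Constant indices yield NA correlations and are
#' listed in the `degenerate` attribute.
#'
#' @param indices named list of per-sample index vectors (or
#'   `index_vector`s), all over the same samples.
#' @param indices2 optional second cohort's indices (same names) for
#'   cross-cohort consistency flags.
#' @return list with symmetric matrices `r` and `p` (unit/zero diagonal)
#'   and, when `indices2` is given, a logical matrix `consistent` plus `r2`,
#'   `p2` for the second cohort.
#' @export
correlate_indices <- function(indices, indices2 = NULL) {
  if (length(indices) < 2) stop("at least 2 indices required")
  mat_of <- function(lst) {
    m <- vapply(lst, index_scores, numeric(length(index_scores(lst[[1]]))))
    colnames(m) <- names(lst)
    m
  }
  corr <- function(m) {
    n <- nrow(m)
    degenerate <- colnames(m)[apply(m, 2, stats::sd) == 0]
    r <- suppressWarnings(stats::cor(m))
    r[degenerate, ] <- NA; r[, degenerate] <- NA
    diag(r) <- ifelse(colnames(m) %in% degenerate, NA, 1)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    diag(p) <- 0
    list(r = r, p = p, degenerate = degenerate)
  }
  c1 <- corr(mat_of(indices))
  out <- list(r = c1$r, p = c1$p)
  attr(out, "degenerate") <- c1$degenerate
  if (!is.null(indices2)) {
    if (!setequal(names(indices), names(indices2)))
      stop("indices and indices2 must cover the same signatures")
    c2 <- corr(mat_of(indices2)[, colnames(c1$r), drop = FALSE])
    out$r2 <- c2$r
    out$p2 <- c2$p
    out$consistent <- sign(c1$r) == sign(c2$r)
  }
  out
}

#' Lymphocyte infiltration scores and their index correlations
#'
#' Computes per-sample T-cell and B-cell scores as the unweighted mean
#' expression of each lymphocyte signature's mapped genes (direction-free),
#' and their Pearson correlations with any supplied prognostic indices.
#' Because prognostic indices are sign-corrected (higher = worse), negative
#' correlations are the expected direction when lymphocyte infiltration is
#' protective.
#'
#' @param bundle [cohort_bundle()] keyed by gene symbol.
#' @param t_signature,b_signature [gene_signature()] objects listing T-cell
#'   and B-cell marker genes (directions ignored).
#' @param indices named list of per-sample prognostic indices to correlate
#'   against (optional).
#' @return list with `t_score`, `b_score` (named numerics) and
#'   `correlations` (data.frame `index`, `cell_type`, `r`, `p`).
#' @export
lymphocyte_scores <- function(bundle, t_signature, b_signature,
                              indices = list()) {
  mean_score <- function(sig) {
    mapped <- map_signature(sig, bundle)
    colMeans(bundle$expression[mapped$members$gene_symbol, , drop = FALSE])
  }
  ts <- mean_score(t_signature)
  bs <- mean_score(b_signature)
  cors <- NULL
  for (nm in names(indices)) {
    v <- index_scores(indices[[nm]])
    for (ct in c("T", "B")) {
      s <- if (ct == "T") ts else bs
      ct_test <- stats::cor.test(v, s, method = "pearson")
      cors <- rbind(cors, data.frame(index = nm, cell_type = ct,
                                     r = unname(ct_test$estimate),
                                     p = ct_test$p.value,
                                     stringsAsFactors = FALSE))
    }
  }
  list(t_score = ts, b_score = bs, correlations = cors)
}
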