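#' Gene signature with hazard directions
#'
#' A named set of gene symbols, each annotated with its direction of
#' association with hazard: +1 (hazard-increasing; the set P of the index
#' formula) or -1 (hazard-decreasing / protective; the set N).
#'
#' @param name signature name.
#' @param symbols character vector of unique gene symbols.
#' @param directions numeric vector of +1/-1, recycled to the number of
#'   symbols.
#' @param provenance free-text provenance note.
#' @return object of class `gene_signature` with a `members` data.frame
#'   (`gene_symbol`, `direction`).
#' @export
gene_signature <- function(name, symbols, directions, provenance = "") {
  if (!length(symbols)) stop("a signature must contain at least one gene")
  if (anyDuplicated(symbols)) stop("duplicate gene symbols in signature")
  directions <- rep_len(directions, length(symbols))
  if (!all(directions %in% c(-1, 1)))
    stop("directions must be +1 or -1")
  structure(list(name = name,
                 members = data.frame(gene_symbol = as.character(symbols),
                                      direction = as.numeric(directions),
                                      stringsAsFactors = FALSE),
                 provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  m <- x$members
  cat(sprintf("gene_signature `%s`: %d genes (%d hazard-increasing, %d protective)\n",
              x$name, nrow(m), sum(m$direction > 0), sum(m$direction < 0)))
  invisible(x)
}

#' Read / write signature TSV files
#'
#' The on-disk format is a two-column TSV: `gene_symbol` and `direction`
#' (+1/-1).
#'
#' @param path TSV path.
#' @param name signature name; defaults to the file name without extension.
#' @return [gene_signature()] for `read_signature`; invisibly `path` for
#'   `write_signature`.
#' @export
read_signature <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene_signature(name, d$gene_symbol, d$direction,
                 provenance = paste0("file:", basename(path)))
}

#' @rdname read_signature
#' @param signature a [gene_signature()].
#' @export
write_signature <- function(signature, path) {
  utils::write.table(signature$members, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Packaged published signatures
#'
#' Loads the signature files shipped with the package: the combined 14-gene
#' HRneg/Tneg prognostic signature, the 11-gene HRneg and 7-gene Tneg
#' candidate lists it unites, and the truncated 7-gene index. Directions
#' follow the published univariate Cox coefficient signs: RGS4 and HAPLN1
#' are hazard-increasing (+1), all other genes protective (-1). The symbol
#' RFXDC2 is retained throughout (its current official symbol is RFX7).
#'
#' @return named list of [gene_signature()] objects.
#' @export
hrnegsig_signatures <- function() {
  dir <- system.file("extdata", "signatures", package = "hrnegsig")
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  out <- lapply(files, read_signature)
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Map a signature onto a cohort
#'
#' Restricts a signature to the gene symbols present among the cohort's
#' features; the index denominator `n` shrinks accordingly. Matching is
#' case-sensitive by symbol.
#'
#' @param signature a [gene_signature()].
#' @param bundle a [cohort_bundle()] keyed by gene symbol.
#' @return the restricted [gene_signature()] with attributes `n_mapped` and
#'   `mapped_fraction`.
#' @export
map_signature <- function(signature, bundle) {
  m <- signature$members
  present <- m$gene_symbol %in% rownames(bundle$expression)
  if (!any(present))
    stop("signature `", signature$name, "`: no genes map to the cohort")
  out <- gene_signature(signature$name, m$gene_symbol[present],
                        m$direction[present], signature$provenance)
  attr(out, "n_mapped") <- sum(present)
  attr(out, "mapped_fraction") <- mean(present)
  out
}

#' Sign-corrected composite expression index
#'
#' Per-sample score `(sum_{i in P} x_i - sum_{j in N} x_j) / n`, where P and
#' N are the hazard-increasing and protective members of the signature that
#' map to the cohort and `n` is the mapped count. Genes are equally
#' weighted; higher scores predict worse prognosis.
#'
#' @param bundle a [cohort_bundle()] of transformed/merged expression keyed
#'   by gene symbol.
#' @param signature a [gene_signature()].
#' @return object of class `index_vector`: list with `score` (named numeric
#'   per sample), `n_mapped`, `mapped_fraction`, `signature` (name).
#' @export
compute_index <- function(bundle, signature) {
  sig <- map_signature(signature, bundle)
  m <- sig$members
  x <- bundle$expression[m$gene_symbol, , drop = FALSE]
  score <- as.numeric(crossprod(x, m$direction)) / nrow(m)
  structure(list(score = stats::setNames(score, colnames(x)),
                 n_mapped = nrow(m),
                 mapped_fraction = attr(sig, "mapped_fraction"),
                 signature = sig$name),
            class = "index_vector")
}

#' @export
print.index_vector <- function(x, ...) {
  cat(sprintf("index_vector `%s`: %d samples, %d mapped genes (%.0f%%)\n",
              x$signature, length(x$score), x$n_mapped,
              100 * x$mapped_fraction))
  print(summary(x$score))
  invisible(x)
}

# accept an index_vector or plain numeric
index_scores <- function(index) {
  if (inherits(index, "index_vector")) index$score else index
}

#' Dichotomize an index and evaluate the split
#'
#' Cuts the per-sample index at a percentile (or an explicit value); the
#' high-risk group is `score >= cut`. With distinct scores and a percentile
#' cut, the low group contains `ceiling(n * percentile / 100)` samples.
#' Kaplan-Meier, log-rank and Cox group-indicator statistics are computed
#' against the bundle's survival outcome.
#'
#' @param index an `index_vector` or named numeric of per-sample scores.
#' @param bundle the [cohort_bundle()] carrying the survival outcome (or any
#'   object with `dmfs_months`/`dmfs_event` in `$clinical`).
#' @param percentile percentile cut in (0, 100); 50 = median, 75 = upper
#'   third quartile.
#' @param cut_value explicit index cut; overrides `percentile`.
#' @return object of class `cutpoint_result`: `cut_value`, `percentile`
#'   (empirical percentile of the cut), `n_high`, `n_low`, `logrank_chi2`,
#'   `logrank_p`, `hr_high_vs_low`, `ci95`, `cox_p`, `groups` (factor
#'   low/high per sample).
#' @export
dichotomize_index <- function(index, bundle, percentile = 75,
                              cut_value = NULL) {
  score <- index_scores(index)
  n <- length(score)
  if (n < 4) stop("at least 4 samples required")
  if (is.null(cut_value)) {
    srt <- sort(score)
    k <- ceiling(n * percentile / 100)
    if (k < 1 || k >= n) stop("percentile leaves an empty group")
    cut_value <- srt[k + 1]
  }
  high <- score >= cut_value
  if (all(high) || !any(high))
    stop("no valid cut: index does not separate the cohort")
  groups <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  time <- bundle$clinical$dmfs_months
  event <- bundle$clinical$dmfs_event
  lr <- logrank_test(time, event, groups)
  cx <- cox_fit(time, event, matrix(as.numeric(high), ncol = 1,
                                    dimnames = list(NULL, "high")))
  structure(list(cut_value = cut_value,
                 percentile = 100 * mean(score < cut_value),
                 n_high = sum(high), n_low = sum(!high),
                 logrank_chi2 = lr$chi2, logrank_p = lr$p,
                 hr_high_vs_low = unname(cx$hr["high"]),
                 ci95 = unname(cx$ci95["high", ]),
                 cox_p = unname(cx$wald_p["high"]),
                 groups = groups),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("cut %.4f (%.1fth pct): low n=%d, high n=%d\n", x$cut_value,
              x$percentile, x$n_low, x$n_high))
  cat(sprintf("  HR high vs low = %.2f (95%% CI %.2f-%.2f), Cox P = %.3g\n",
              x$hr_high_vs_low, x$ci95[1], x$ci95[2], x$cox_p))
  cat(sprintf("  log-rank P = %.3g\n", x$logrank_p))
  invisible(x)
}

#' Optimal cut-point search within central percentiles
#'
#' Evaluates the log-rank P value at every distinct index value whose
#' empirical percentile lies within `[lower_pct, upper_pct]` (restricting
#' the search prevents extreme group sizes and limits over-fitting) and
#' returns the minimizing cut. Ties on P are broken toward the cut closest
#' to the 75th percentile. The returned P value is exploratory: no
#' multiple-testing correction is applied across the grid.
#'
#' @inheritParams dichotomize_index
#' @param lower_pct,upper_pct percentile bounds of the search (defaults 20
#'   and 80).
#' @return a `cutpoint_result` with an additional `grid` data.frame
#'   (`cut_value`, `percentile`, `logrank_p`) covering the whole search.
#' @export
optimize_cutpoint <- function(index, bundle, lower_pct = 20, upper_pct = 80) {
  score <- index_scores(index)
  n <- length(score)
  time <- bundle$clinical$dmfs_months
  event <- bundle$clinical$dmfs_event
  cand <- sort(unique(score))
  pct <- vapply(cand, function(v) 100 * mean(score < v), numeric(1))
  ok <- pct >= lower_pct & pct <= upper_pct & pct > 0 & pct < 100
  cand <- cand[ok]; pct <- pct[ok]
  if (!length(cand)) stop("no valid cut-points in the percentile range")
  pvals <- vapply(cand, function(v) {
    g <- factor(score >= v, levels = c(FALSE, TRUE))
    logrank_test(time, event, g)$p
  }, numeric(1))
  best <- which(pvals == min(pvals))
  if (length(best) > 1) best <- best[which.min(abs(pct[best] - 75))]
  out <- dichotomize_index(score, bundle, cut_value = cand[best])
  out$grid <- data.frame(cut_value = cand, percentile = pct,
                         logrank_p = pvals)
  out
}

# univariate Cox (continuous) of an index candidate set; returns coef & p
index_cox_p <- function(symbols, directions, bundle) {
  sig <- gene_signature("tmp", symbols, directions)
  idx <- compute_index(bundle, sig)
  sc <- cox_screen(matrix(idx$score, nrow = 1),
                   bundle$clinical$dmfs_months,
                   bundle$clinical$dmfs_event)
  c(coef = sc$coef, p = sc$p)
}

#' Stepwise forward gene prioritization
#'
#' Greedy forward ordering of candidate genes into a composite index.
#' Starts from the gene with the smallest univariate Cox Wald P; at each
#' step every possible addition is scored by the Wald P of a univariate Cox
#' regression of survival on the resulting (continuous) index, and the
#' minimizing gene is added (ties broken lexicographically). No gene is
#' pruned: non-improving steps are recorded. The best subset is the prefix
#' with the globally smallest step P.
#'
#' @param candidates data.frame with columns `feature_id` (or `gene`) and
#'   `direction` (+1/-1), e.g. discovery records.
#' @param bundle transformed/merged [cohort_bundle()] with survival outcome.
#' @return list with `order` (genes in order of addition), `steps`
#'   (data.frame `step`, `gene`, `coef`, `p`), `best_subset`.
#' @export
stepwise_addition <- function(candidates, bundle) {
  genes <- candidates$feature_id %||% candidates$gene
  dirs <- stats::setNames(candidates$direction, genes)
  if (!length(genes)) stop("no candidates supplied")
  if (length(genes) == 1) {
    st <- index_cox_p(genes, dirs[genes], bundle)
    return(list(order = genes,
                steps = data.frame(step = 1L, gene = genes,
                                   coef = st["coef"], p = st["p"],
                                   row.names = NULL),
                best_subset = genes))
  }
  remaining <- sort(genes)
  chosen <- character()
  steps <- NULL
  while (length(remaining)) {
    stat <- vapply(remaining, function(g)
      index_cox_p(c(chosen, g), dirs[c(chosen, g)], bundle), c(coef = 0, p = 0))
    best <- remaining[which.min(stat["p", ])]   # lexicographic tie-break
    chosen <- c(chosen, best)
    remaining <- setdiff(remaining, best)
    steps <- rbind(steps, data.frame(step = length(chosen), gene = best,
                                     coef = stat["coef", best],
                                     p = stat["p", best], row.names = NULL))
  }
  list(order = chosen, steps = steps,
       best_subset = chosen[seq_len(which.min(steps$p))])
}

#' Stepwise backward gene prioritization
#'
#' Greedy backward analogue of [stepwise_addition()]: genes are removed one
#' at a time from a full signature, at each step removing the gene whose
#' removal minimizes the index Cox Wald P (ties lexicographic), down to a
#' single remaining gene. A size-1 signature yields an empty removal
#' sequence.
#'
#' @param signature a [gene_signature()].
#' @inheritParams stepwise_addition
#' @return list with `removal_order` and `steps` (data.frame `step`,
#'   `removed`, `size_after`, `coef`, `p`).
#' @export
stepwise_subtraction <- function(signature, bundle) {
  m <- signature$members
  dirs <- stats::setNames(m$direction, m$gene_symbol)
  current <- sort(m$gene_symbol)
  removed <- character()
  steps <- NULL
  while (length(current) > 1) {
    stat <- vapply(current, function(g) {
      rest <- setdiff(current, g)
      index_cox_p(rest, dirs[rest], bundle)
    }, c(coef = 0, p = 0))
    worst <- current[which.min(stat["p", ])]
    removed <- c(removed, worst)
    current <- setdiff(current, worst)
    steps <- rbind(steps,
                   data.frame(step = length(removed), removed = worst,
                              size_after = length(current),
                              coef = stat["coef", worst],
                              p = stat["p", worst], row.names = NULL))
  }
  list(removal_order = removed, steps = steps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
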