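#' Multi-source expression/survival cohort container
#'
#' A `cohort_bundle` couples a log2-scale expression matrix (features x
#' samples) with a per-sample clinical table and an optional probe-to-gene
#' map. It is the unit every pipeline stage consumes: preprocessing,
#' screening, index computation and signature comparison all take and return
#' bundles. An append-only `transforms` list records every transform applied
#' (operation name, parameters, timestamp) so a processed bundle carries its
#' own audit trail.
#'
#' @param expression numeric matrix of log2 expression values; rownames are
#'   feature ids (probe ids or gene symbols), colnames are sample ids.
#' @param clinical data.frame with one row per sample; required columns
#'   `sample_id`, `source`, `dmfs_months` (distant metastasis-free survival
#'   time, months), `dmfs_event` (0/1). Optional `er_status`, `pr_status`,
#'   `her2_status` (each "pos"/"neg"/"unknown", default "unknown").
#' @param feature_map optional data.frame with columns `probe_id`,
#'   `gene_symbol` mapping expression rows to gene symbols.
#' @param transforms list of transform audit records (normally empty at
#'   construction).
#'
#' @return an object of class `cohort_bundle`.
#' @export
cohort_bundle <- function(expression, clinical, feature_map = NULL,
                          transforms = list()) {
  if (!is.matrix(expression) || !is.numeric(expression))
    stop("`expression` must be a numeric matrix")
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stop("`expression` must have feature rownames and sample colnames")
  clinical <- as.data.frame(clinical, stringsAsFactors = FALSE)
  req <- c("sample_id", "source", "dmfs_months", "dmfs_event")
  miss <- setdiff(req, names(clinical))
  if (length(miss))
    stop("clinical table is missing column(s): ", paste(miss, collapse = ", "))
  for (st in c("er_status", "pr_status", "her2_status"))
    if (is.null(clinical[[st]])) clinical[[st]] <- "unknown"
  if (anyDuplicated(clinical$sample_id))
    stop("duplicate sample ids in clinical table")
  if (anyDuplicated(colnames(expression)))
    stop("duplicate sample ids in expression matrix")
  if (!setequal(clinical$sample_id, colnames(expression)))
    stop("clinical samples and expression columns do not match")
  # align clinical row order to expression column order
  clinical <- clinical[match(colnames(expression), clinical$sample_id), ,
                       drop = FALSE]
  rownames(clinical) <- NULL
  if (any(clinical$dmfs_months < 0)) stop("negative dmfs_months")
  if (!all(clinical$dmfs_event %in% c(0, 1)))
    stop("dmfs_event must be 0/1")
  if (!is.null(feature_map)) {
    feature_map <- as.data.frame(feature_map, stringsAsFactors = FALSE)
    if (!all(c("probe_id", "gene_symbol") %in% names(feature_map)))
      stop("feature_map needs columns probe_id, gene_symbol")
  }
  structure(list(expression = expression, clinical = clinical,
                 feature_map = feature_map, transforms = transforms),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cl <- x$clinical
  cat("cohort_bundle: ", nrow(x$expression), " features x ",
      ncol(x$expression), " samples\n", sep = "")
  cat("  sources: ", paste(sprintf("%s (n=%d)", names(table(cl$source)),
                                   as.integer(table(cl$source))),
                           collapse = ", "), "\n", sep = "")
  cat("  events:  ", sum(cl$dmfs_event), " / ", nrow(cl),
      sprintf(" (%.0f%%)", 100 * mean(cl$dmfs_event)), "\n", sep = "")
  if (length(x$transforms))
    cat("  transforms applied: ",
        paste(vapply(x$transforms, `[[`, "", "operation"), collapse = " -> "),
        "\n", sep = "")
  invisible(x)
}

# subset a bundle to a set of sample ids (order preserved as given)
subset_samples <- function(bundle, sample_ids) {
  missing_ids <- setdiff(sample_ids, colnames(bundle$expression))
  if (length(missing_ids))
    stop("unknown sample id(s): ", paste(utils::head(missing_ids, 5),
                                         collapse = ", "))
  cohort_bundle(bundle$expression[, sample_ids, drop = FALSE],
                bundle$clinical[match(sample_ids, bundle$clinical$sample_id), ,
                                drop = FALSE],
                feature_map = bundle$feature_map,
                transforms = bundle$transforms)
}

# subset a bundle to a set of feature ids
subset_features <- function(bundle, feature_ids) {
  missing_ids <- setdiff(feature_ids, rownames(bundle$expression))
  if (length(missing_ids))
    stop("unknown feature id(s): ", paste(utils::head(missing_ids, 5),
                                          collapse = ", "))
  b <- bundle
  b$expression <- bundle$expression[feature_ids, , drop = FALSE]
  b
}

# split a multi-source bundle into a named list of single-source bundles
bundle_by_source <- function(bundle) {
  src <- unique(bundle$clinical$source)
  out <- lapply(src, function(s)
    subset_samples(bundle, bundle$clinical$sample_id[bundle$clinical$source == s]))
  names(out) <- src
  out
}

# append a transform audit record
record_transform <- function(bundle, operation, params = list()) {
  bundle$transforms <- c(bundle$transforms,
                         list(list(operation = operation, params = params,
                                   timestamp = format(Sys.time(), tz = "UTC"))))
  bundle
}

#' Write a cohort bundle to TSV files
#'
#' Writes `<prefix>_expression.tsv` (first column `feature_id`, one column
#' per sample) and `<prefix>_clinical.tsv`, plus a JSON audit log of applied
#' transforms when any exist.
#'
#' @param bundle a [cohort_bundle()].
#' @param dir output directory (created if absent).
#' @param prefix file name prefix, default `"cohort"`.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(bundle, dir, prefix = "cohort") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ep <- file.path(dir, paste0(prefix, "_expression.tsv"))
  cp <- file.path(dir, paste0(prefix, "_clinical.tsv"))
  em <- data.frame(feature_id = rownames(bundle$expression),
                   bundle$expression, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(em, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$clinical, cp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(expression = ep, clinical = cp)
  if (length(bundle$transforms)) {
    tp <- file.path(dir, paste0(prefix, "_transforms.json"))
    jsonlite::write_json(bundle$transforms, tp, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, transforms = tp)
  }
  invisible(paths)
}

#' Read a cohort bundle from TSV files
#'
#' @param expression_path TSV with a `feature_id` first column and one column
#'   per sample (log2 values).
#' @param clinical_path TSV clinical table (see [cohort_bundle()]).
#' @param feature_map_path optional 2-column TSV (`probe_id`, `gene_symbol`).
#' @return a [cohort_bundle()].
#' @export
read_cohort <- function(expression_path, clinical_path,
                        feature_map_path = NULL) {
  em <- utils::read.delim(expression_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(em)[1] != "feature_id")
    stop("expression TSV must have `feature_id` as its first column")
  expr <- as.matrix(em[, -1, drop = FALSE])
  rownames(expr) <- em$feature_id
  clin <- utils::read.delim(clinical_path, stringsAsFactors = FALSE,
                            colClasses = c(sample_id = "character",
                                           source = "character"))
  fm <- NULL
  if (!is.null(feature_map_path))
    fm <- utils::read.delim(feature_map_path, stringsAsFactors = FALSE)
  cohort_bundle(expr, clin, feature_map = fm)
}
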