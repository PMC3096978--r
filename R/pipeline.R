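#' Read or round-trip a pipeline configuration
#'
#' Configurations are plain lists with optional stage blocks `simulate`,
#' `prep`, `discover`, `index`, `compare`, plus a global `seed`. On disk
#' they are YAML (or JSON); [read_pipeline_config()] and
#' [write_pipeline_config()] round-trip losslessly.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) file.
#' @return the configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' @rdname read_pipeline_config
#' @param config configuration list.
#' @export
write_pipeline_config <- function(config, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(config, path)
  invisible(path)
}

# stable per-stage sub-seed derived from the global seed and stage name,
# kept below 2^31 so stage insertion does not reshuffle other stages
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# md5 of an R object via canonical JSON serialization
object_md5 <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the requested stages in order
#' `simulate -> prep -> discover -> index -> compare`, writing each stage's
#' artifacts (TSV/JSON) into `out_dir` before the next stage begins, and
#' returns a run manifest with the configuration hash, package version,
#' per-artifact md5 checksums and per-stage wall-clock seconds. Re-running
#' with the same configuration and seed reproduces identical checksums.
#'
#' Stage blocks (all optional except that `prep` and later stages need
#' either a `simulate` block or input paths under `config$paths`):
#' \describe{
#'   \item{simulate}{fields of [sim_params()]; writes the cohort TSVs and a
#'     ground-truth JSON sidecar.}
#'   \item{prep}{`erbb2_feature_id` (default "ERBB2") and `transform`
#'     ("center", the default, or "z"); assigns HER2/triple-negative status
#'     and applies the per-source transform.}
#'   \item{discover}{`discovery` and `holdout` source labels plus any
#'     [discovery_config()] fields; writes the candidate table and the
#'     discovered signature TSV.}
#'   \item{index}{`percentiles` (default c(50, 75)) and cut-point search
#'     bounds `lower_pct`/`upper_pct` (defaults 20/80); writes per-sample
#'     index, cut-point grid and Kaplan-Meier coordinates.}
#'   \item{compare}{`signature_dir` of TSV signatures (defaults to the
#'     packaged signature files); writes the comparison table and index
#'     correlation matrix.}
#' }
#'
#' @param config configuration list or path to a YAML/JSON file.
#' @param out_dir output directory (default `config$out_dir`, else a
#'   tempdir).
#' @param seed global seed overriding `config$seed`; each stochastic stage
#'   derives a stable sub-seed from it.
#' @return the run manifest (list), invisibly written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir %||% tempfile("hrnegsig_run_")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- seed %||% config$seed %||% 1L
  manifest <- list(config_hash = object_md5(config),
                   package_version =
                     as.character(utils::packageVersion("hrnegsig")),
                   seed = seed, stages = character(),
                   checksums = list(), timing = list())
  artifacts <- character()
  stage_done <- function(stage, paths, t0) {
    manifest$stages <<- c(manifest$stages, stage)
    # audit logs carry wall-clock timestamps; checksums cover data artifacts
    paths <- paths[!grepl("transforms", basename(paths))]
    manifest$checksums[[stage]] <<-
      as.list(tools::md5sum(unname(paths)))
    manifest$timing[[stage]] <<-
      round(as.numeric(Sys.time()) - t0, 3)
  }
  fail <- function(stage, err) {
    rec <- list(stage = stage, message = conditionMessage(err))
    jsonlite::write_json(rec, file.path(out_dir, "error.json"),
                         auto_unbox = TRUE)
    stop("pipeline stage `", stage, "` failed: ", conditionMessage(err),
         call. = FALSE)
  }

  bundle <- NULL
  truth <- NULL

  if (!is.null(config$simulate)) {
    t0 <- as.numeric(Sys.time())
    tryCatch({
      sp <- config$simulate
      sp$seed <- stage_seed(seed, "simulate")
      sim <- simulate_cohort(do.call(sim_params, sp))
      bundle <- sim$bundle
      truth <- sim$truth
      paths <- write_cohort(bundle, out_dir, "simulated")
      gt <- file.path(out_dir, "ground_truth.json")
      write_ground_truth(truth, gt)
      stage_done("simulate", c(paths, gt), t0)
    }, error = function(e) fail("simulate", e))
  }
  if (is.null(bundle) && !is.null(config$paths)) {
    bundle <- read_cohort(config$paths$expression, config$paths$clinical,
                          config$paths$probe_map)
  }

  if (!is.null(config$prep)) {
    t0 <- as.numeric(Sys.time())
    tryCatch({
      if (is.null(bundle)) stop("no input cohort for prep stage")
      pc <- config$prep
      if (!is.null(bundle$feature_map)) bundle <- collapse_probes(bundle)
      erbb2 <- pc$erbb2_feature_id %||% "ERBB2"
      if (erbb2 %in% rownames(bundle$expression))
        bundle <- assign_her2_status(bundle, erbb2,
                                     threshold = pc$threshold %||% 0)
      bundle <- switch(pc$transform %||% "center",
                       center = mean_center_within_source(bundle),
                       z = z_transform_within_source(bundle),
                       stop("unknown prep transform"))
      paths <- write_cohort(bundle, out_dir, "prepped")
      stage_done("prep", paths, t0)
    }, error = function(e) fail("prep", e))
  }

  fit <- NULL
  if (!is.null(config$discover)) {
    t0 <- as.numeric(Sys.time())
    tryCatch({
      if (is.null(bundle)) stop("no input cohort for discover stage")
      dc <- config$discover
      mc <- do.call(mccv_config, c(dc$mccv,
                                   list(seed = stage_seed(seed, "discover"))))
      cfg <- discovery_config(pam_top_k = dc$pam_top_k %||% 300L,
                              pam_labels = dc$pam_labels %||% "event",
                              min_fraction = dc$min_fraction %||% 0.10,
                              log2_fold = dc$log2_fold %||% 1.0,
                              mccv = mc,
                              candidate_merge = dc$candidate_merge %||%
                                "union")
      fit <- discover_signature(bundle, dc$discovery, dc$holdout, cfg)
      cand_path <- file.path(out_dir, "candidates.tsv")
      rec <- rbind(cbind(chain = "HRneg", fit$hrneg_records),
                   cbind(chain = "Tneg", fit$tneg_records))
      utils::write.table(rec, cand_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- cand_path
      if (!is.null(fit$signature)) {
        sig_path <- file.path(out_dir, "discovered_signature.tsv")
        write_signature(fit$signature, sig_path)
        paths <- c(paths, sig_path)
      }
      stage_done("discover", paths, t0)
    }, error = function(e) fail("discover", e))
  }

  index <- NULL
  if (!is.null(config$index)) {
    t0 <- as.numeric(Sys.time())
    tryCatch({
      if (is.null(bundle)) stop("no input cohort for index stage")
      ic <- config$index
      sig <- if (!is.null(ic$signature_file))
        read_signature(ic$signature_file)
      else if (!is.null(fit) && !is.null(fit$signature)) fit$signature
      else stop("no signature available for index stage")
      index <- compute_index(bundle, sig)
      ip <- file.path(out_dir, "index.tsv")
      utils::write.table(data.frame(sample_id = names(index$score),
                                    index = index$score),
                         ip, sep = "\t", quote = FALSE, row.names = FALSE)
      cuts <- lapply(ic$percentiles %||% c(50, 75), function(pc) {
        cp <- dichotomize_index(index, bundle, percentile = pc)
        km <- suppressWarnings(
          km_estimate(bundle$clinical$dmfs_months,
                      bundle$clinical$dmfs_event, cp$groups))
        list(percentile = pc, cut_value = cp$cut_value,
             n_low = cp$n_low, n_high = cp$n_high,
             hr = cp$hr_high_vs_low, ci95 = cp$ci95, cox_p = cp$cox_p,
             logrank_p = cp$logrank_p,
             km_curves = km$curves)
      })
      opt <- optimize_cutpoint(index, bundle,
                               lower_pct = ic$lower_pct %||% 20,
                               upper_pct = ic$upper_pct %||% 80)
      gp <- file.path(out_dir, "cutpoint_grid.tsv")
      utils::write.table(opt$grid, gp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      jp <- file.path(out_dir, "index_evaluation.json")
      jsonlite::write_json(list(signature = index$signature,
                                n_mapped = index$n_mapped,
                                cuts = cuts,
                                optimal_cut = list(
                                  cut_value = opt$cut_value,
                                  percentile = opt$percentile,
                                  logrank_p = opt$logrank_p)),
                           jp, auto_unbox = TRUE, digits = NA)
      stage_done("index", c(ip, gp, jp), t0)
    }, error = function(e) fail("index", e))
  }

  if (!is.null(config$compare)) {
    t0 <- as.numeric(Sys.time())
    tryCatch({
      if (is.null(bundle)) stop("no input cohort for compare stage")
      cc <- config$compare
      lib <- if (!is.null(cc$signature_dir)) {
        fl <- list.files(cc$signature_dir, pattern = "\\.tsv$",
                         full.names = TRUE)
        stats::setNames(lapply(fl, read_signature),
                        sub("\\.tsv$", "", basename(fl)))
      } else hrnegsig_signatures()
      if (!is.null(fit) && !is.null(fit$signature))
        lib <- c(lib, list(discovered = fit$signature))
      lib <- Filter(function(s)
        any(s$members$gene_symbol %in% rownames(bundle$expression)), lib)
      if (!length(lib)) stop("no comparison signature maps to the cohort")
      rep_ <- compare_prognosis(bundle, lib,
                                percentile = cc$percentile %||% 50)
      tp <- file.path(out_dir, "comparison.tsv")
      utils::write.table(rep_, tp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- tp
      if (length(lib) >= 2) {
        idx <- lapply(lib, function(s) compute_index(bundle, s)$score)
        cor_ <- correlate_indices(idx)
        cp <- file.path(out_dir, "index_correlations.json")
        jsonlite::write_json(list(signatures = names(idx),
                                  r = cor_$r, p = cor_$p),
                             cp, digits = NA, matrix = "rowmajor")
        paths <- c(paths, cp)
      }
      stage_done("compare", paths, t0)
    }, error = function(e) fail("compare", e))
  }

  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  manifest$out_dir <- out_dir
  invisible(manifest)
}

#' Human-readable report of a pipeline run
#'
#' Assembles the candidate table, index evaluation, signature comparison
#' and correlation matrix from a completed run directory into a plain-text
#' report; missing stage outputs are flagged as gaps rather than errors.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @param path report destination (default `report.txt` inside `out_dir`).
#' @return character vector of report lines, invisibly; also written to
#'   `path`.
#' @export
pipeline_report <- function(out_dir, path = file.path(out_dir, "report.txt")) {
  lines <- c("hrnegsig pipeline report", strrep("=", 24), "")
  fp <- function(...) file.path(out_dir, ...)
  if (file.exists(fp("candidates.tsv"))) {
    cand <- utils::read.delim(fp("candidates.tsv"))
    sel <- cand[cand$final_selected, , drop = FALSE]
    lines <- c(lines, "Candidate table (confirmed candidates):",
               utils::capture.output(print(
                 sel[, c("chain", "feature_id", "uni_coef", "uni_p",
                         "multi_coef", "multi_p")], digits = 3)), "")
  } else lines <- c(lines, "[gap] no discovery stage output", "")
  if (file.exists(fp("index_evaluation.json"))) {
    ev <- jsonlite::read_json(fp("index_evaluation.json"),
                              simplifyVector = TRUE)
    lines <- c(lines, sprintf("Index `%s` (%d mapped genes):",
                              ev$signature, ev$n_mapped))
    for (i in seq_len(length(ev$cuts$percentile))) {
      lines <- c(lines, sprintf(
        "  cut at %gth pct: HR %.2f, Cox P %.3g, log-rank P %.3g",
        ev$cuts$percentile[i], ev$cuts$hr[i], ev$cuts$cox_p[i],
        ev$cuts$logrank_p[i]))
    }
    lines <- c(lines, sprintf(
      "  optimal cut %.4f (%.1fth pct), log-rank P %.3g (exploratory)",
      ev$optimal_cut$cut_value, ev$optimal_cut$percentile,
      ev$optimal_cut$logrank_p), "")
  } else lines <- c(lines, "[gap] no index stage output", "")
  if (file.exists(fp("comparison.tsv"))) {
    cmp <- utils::read.delim(fp("comparison.tsv"))
    lines <- c(lines, "Signature comparison (common median cut):",
               utils::capture.output(print(cmp, digits = 3)), "")
  } else lines <- c(lines, "[gap] no compare stage output", "")
  if (file.exists(fp("index_correlations.json"))) {
    cor_ <- jsonlite::read_json(fp("index_correlations.json"),
                                simplifyVector = TRUE)
    r <- matrix(unlist(cor_$r), length(cor_$signatures), byrow = TRUE,
                dimnames = list(cor_$signatures, cor_$signatures))
    lines <- c(lines, "Index correlation matrix (Pearson R):",
               utils::capture.output(print(round(r, 2))), "")
  }
  writeLines(lines, path)
  invisible(lines)
}
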