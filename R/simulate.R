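#' Simulation parameters for a synthetic multi-source cohort
#'
#' Defines the generating model for [simulate_cohort()]. The defaults emulate
#' the structure of pooled node-negative, hormone receptor-negative breast
#' cancer microarray cohorts: three sources of 69/66/64 samples (199 total),
#' 10,000 log2-scale genes with per-source additive batch shifts, a small set
#' of truly prognostic genes that are mostly protective (higher expression,
#' lower hazard), an exponential baseline hazard with uniform administrative
#' censoring calibrated so roughly a third of cases relapse and ~85% of
#' observed relapses fall within 5 years of diagnosis, and one bimodal
#' ERBB2-like gene so HER2 stratification can be exercised downstream.
#'
#' Prognostic-gene expression is built from a shared latent risk factor:
#' `x_g = loading * u_g * z + sqrt(1 - loading^2) * e`, scaled to SD
#' `noise_sd`, where `z` is the per-sample latent risk and `u_g` the gene's
#' hazard direction. The log-hazard linear predictor is `sum_g beta_g * x_g`
#' with `x_g` on the 1-SD scale, so `effect_sizes` are log hazard ratios per
#' standard deviation of expression. The shared factor makes signature genes
#' weakly correlated, so a composite index carries more signal than any
#' single gene.
#'
#' @param n_sources number of data sources (batches); defaults to the length
#'   of `samples_per_source`.
#' @param samples_per_source integer vector of per-source sample counts
#'   (recycled to `n_sources`).
#' @param n_genes total number of simulated genes.
#' @param n_prognostic number of truly prognostic genes.
#' @param effect_sizes absolute log-hazard coefficients per 1 SD of
#'   expression for the prognostic genes (recycled to `n_prognostic`).
#' @param fraction_protective proportion of prognostic genes with negative
#'   hazard association (higher expression, better prognosis).
#' @param baseline_hazard_rate exponential baseline hazard, events/month.
#' @param censor_time_range months; administrative censoring is drawn
#'   uniformly on this window.
#' @param batch_shift_sd SD (log2 units) of additive per-(source, gene)
#'   offsets.
#' @param batch_scale_sd SD of per-(source, gene) log expression-scale
#'   distortions; 0 (the default) disables scale batch effects.
#' @param noise_sd residual SD of expression (log2 units).
#' @param risk_loading loading of prognostic genes on the shared latent risk
#'   factor, in (0, 1).
#' @param erbb2_positive_fraction proportion of samples with the elevated
#'   ERBB2-like mode (HER2-positive analogue).
#' @param erbb2_shift log2 separation between ERBB2 modes.
#' @param erbb2_noise_sd residual SD of the ERBB2-like gene.
#' @param seed integer RNG seed; identical seed and parameters reproduce the
#'   cohort bit-for-bit.
#'
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(n_sources = length(samples_per_source),
                       samples_per_source = c(69L, 66L, 64L),
                       n_genes = 10000L,
                       n_prognostic = 14L,
                       effect_sizes = 0.15,
                       fraction_protective = 12 / 14,
                       baseline_hazard_rate = 0.0055,
                       censor_time_range = c(36, 96),
                       batch_shift_sd = 0.5,
                       batch_scale_sd = 0,
                       noise_sd = 1.0,
                       risk_loading = 0.3,
                       erbb2_positive_fraction = 0.23,
                       erbb2_shift = 4,
                       erbb2_noise_sd = 0.5,
                       seed = 1L) {
  p <- list(n_sources = as.integer(n_sources),
            samples_per_source = as.integer(rep_len(samples_per_source,
                                                    n_sources)),
            n_genes = as.integer(n_genes),
            n_prognostic = as.integer(n_prognostic),
            effect_sizes = abs(rep_len(effect_sizes, max(n_prognostic, 1L))),
            fraction_protective = fraction_protective,
            baseline_hazard_rate = baseline_hazard_rate,
            censor_time_range = censor_time_range,
            batch_shift_sd = batch_shift_sd,
            batch_scale_sd = batch_scale_sd,
            noise_sd = noise_sd,
            risk_loading = risk_loading,
            erbb2_positive_fraction = erbb2_positive_fraction,
            erbb2_shift = erbb2_shift,
            erbb2_noise_sd = erbb2_noise_sd,
            seed = as.integer(seed))
  bad <- function(field, why) stop("invalid `", field, "`: ", why,
                                   call. = FALSE)
  if (p$n_sources < 1) bad("n_sources", "must be positive")
  if (any(p$samples_per_source < 1))
    bad("samples_per_source", "all counts must be positive")
  if (p$n_genes < 1) bad("n_genes", "must be positive")
  if (p$n_prognostic < 0) bad("n_prognostic", "must be non-negative")
  if (p$n_prognostic > p$n_genes)
    bad("n_prognostic", "cannot exceed n_genes")
  if (p$fraction_protective < 0 || p$fraction_protective > 1)
    bad("fraction_protective", "must lie in [0, 1]")
  if (p$baseline_hazard_rate <= 0)
    bad("baseline_hazard_rate", "must be > 0")
  if (length(p$censor_time_range) != 2 ||
      any(p$censor_time_range < 0) ||
      diff(p$censor_time_range) < 0)
    bad("censor_time_range", "must be an increasing non-negative pair")
  if (p$noise_sd <= 0) bad("noise_sd", "must be > 0")
  if (p$risk_loading <= 0 || p$risk_loading >= 1)
    bad("risk_loading", "must lie in (0, 1)")
  if (p$erbb2_positive_fraction < 0 || p$erbb2_positive_fraction > 1)
    bad("erbb2_positive_fraction", "must lie in [0, 1]")
  class(p) <- "sim_params"
  p
}

#' Simulate a multi-source expression/survival cohort with known truth
#'
#' Draws a [cohort_bundle()] under the proportional-hazards generating model
#' described in [sim_params()], together with a ground-truth record for
#' parameter-recovery testing. Event times are exponential with rate
#' `baseline_hazard_rate * exp(lp)`; observed time is the minimum of the
#' event and censoring times and the event flag is 1 iff the event came
#' first. One gene is named `ERBB2` and drawn from a two-component mixture;
#' its HER2 label is *not* written to the clinical table, so
#' [assign_her2_status()] is exercised honestly downstream.
#'
#' @param params a [sim_params()] object.
#' @return a list with elements `bundle` (a [cohort_bundle()], estrogen and
#'   progesterone status "neg" throughout, HER2 "unknown") and `truth` (a
#'   list: `prognostic_gene_ids`, `true_betas` named by gene,
#'   `per_sample_linear_predictor`, `true_event_times`, `censoring_times`,
#'   `her2_positive` logical, `latent_risk`).
#' @export
#' @examples
#' sim <- simulate_cohort(sim_params(n_genes = 200, seed = 7))
#' sim$bundle
simulate_cohort <- function(params = sim_params()) {
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, params)
  p <- params
  set.seed(p$seed)
  n <- sum(p$samples_per_source)
  src <- rep(paste0("S", seq_len(p$n_sources)), p$samples_per_source)
  sample_ids <- sprintf("%s_%03d", src, unlist(lapply(p$samples_per_source,
                                                      seq_len)))
  gene_ids <- sprintf("G%05d", seq_len(p$n_genes))

  # designate prognostic genes and the ERBB2-like gene (never prognostic)
  n_prog <- p$n_prognostic
  prog_idx <- if (n_prog > 0) sort(sample.int(p$n_genes, n_prog)) else integer()
  erbb2_idx <- if (p$n_genes > n_prog)
    resample(setdiff(seq_len(p$n_genes), prog_idx), 1L) else NA_integer_
  if (!is.na(erbb2_idx)) gene_ids[erbb2_idx] <- "ERBB2"

  betas <- numeric(0)
  if (n_prog > 0) {
    mag <- p$effect_sizes[seq_len(n_prog)]
    n_protect <- round(p$fraction_protective * n_prog)
    sgn <- rep(1, n_prog)
    if (n_protect > 0) sgn[sample.int(n_prog, n_protect)] <- -1
    betas <- mag * sgn
  }

  # expression: gene baseline + per-source batch offset + signal + noise
  mu <- stats::rnorm(p$n_genes, mean = 7, sd = 1)
  batch <- matrix(stats::rnorm(p$n_genes * p$n_sources, 0, p$batch_shift_sd),
                  p$n_genes, p$n_sources)
  scale_fac <- if (p$batch_scale_sd > 0)
    matrix(exp(stats::rnorm(p$n_genes * p$n_sources, 0, p$batch_scale_sd)),
           p$n_genes, p$n_sources)
  else matrix(1, p$n_genes, p$n_sources)
  src_i <- rep(seq_len(p$n_sources), p$samples_per_source)

  z <- stats::rnorm(n)                      # shared latent risk per sample
  centered <- matrix(stats::rnorm(p$n_genes * n), p$n_genes, n)
  if (n_prog > 0) {
    a <- p$risk_loading
    u <- sign(betas)                        # hazard direction of each gene
    centered[prog_idx, ] <- a * (u %o% z) +
      sqrt(1 - a^2) * centered[prog_idx, , drop = FALSE]
  }
  # linear predictor uses the unit-SD signal component (beta per 1 SD)
  lp <- if (n_prog > 0)
    as.numeric(crossprod(centered[prog_idx, , drop = FALSE], betas))
  else numeric(n)

  expr <- mu + p$noise_sd * centered * scale_fac[, src_i] + batch[, src_i]

  her2_pos <- rep(FALSE, n)
  if (!is.na(erbb2_idx)) {
    her2_pos <- stats::runif(n) < p$erbb2_positive_fraction
    expr[erbb2_idx, ] <- mu[erbb2_idx] + batch[erbb2_idx, src_i] +
      p$erbb2_shift * her2_pos + stats::rnorm(n, 0, p$erbb2_noise_sd)
  }
  dimnames(expr) <- list(gene_ids, sample_ids)

  t_event <- stats::rexp(n, rate = p$baseline_hazard_rate * exp(lp))
  t_cens <- stats::runif(n, p$censor_time_range[1], p$censor_time_range[2])
  obs_time <- pmin(t_event, t_cens)
  obs_event <- as.integer(t_event <= t_cens)

  clinical <- data.frame(sample_id = sample_ids, source = src,
                         dmfs_months = obs_time, dmfs_event = obs_event,
                         er_status = "neg", pr_status = "neg",
                         her2_status = "unknown", stringsAsFactors = FALSE)
  bundle <- cohort_bundle(expr, clinical)
  truth <- list(prognostic_gene_ids = gene_ids[prog_idx],
                true_betas = stats::setNames(betas, gene_ids[prog_idx]),
                per_sample_linear_predictor = stats::setNames(lp, sample_ids),
                true_event_times = stats::setNames(t_event, sample_ids),
                censoring_times = stats::setNames(t_cens, sample_ids),
                her2_positive = stats::setNames(her2_pos, sample_ids),
                latent_risk = stats::setNames(z, sample_ids),
                params = unclass(p))
  list(bundle = bundle, truth = truth)
}

#' Split a cohort into discovery and hold-out bundles by source
#'
#' Emulates the two-stage training design in which candidates are screened
#' in an initial subset of sources and confirmed in the remaining one(s).
#'
#' @param bundle a [cohort_bundle()].
#' @param discovery character vector of source labels assigned to discovery.
#' @param holdout character vector of source labels assigned to hold-out;
#'   defaults to all remaining sources.
#' @return list with `discovery` and `holdout` bundles; together they
#'   partition the input samples.
#' @export
split_cohort <- function(bundle, discovery, holdout = NULL) {
  src <- unique(bundle$clinical$source)
  if (is.null(holdout)) holdout <- setdiff(src, discovery)
  unknown <- setdiff(c(discovery, holdout), src)
  if (length(unknown))
    stop("unknown source label(s): ", paste(unknown, collapse = ", "))
  if (length(intersect(discovery, holdout)))
    stop("discovery and holdout source sets overlap")
  cl <- bundle$clinical
  list(discovery = subset_samples(bundle,
                                  cl$sample_id[cl$source %in% discovery]),
       holdout = subset_samples(bundle,
                                cl$sample_id[cl$source %in% holdout]))
}

#' Write simulation ground truth as a JSON sidecar
#'
#' @param truth the `truth` element of [simulate_cohort()] output.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
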