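#' Monte-Carlo cross-validation screen configuration
#'
#' @param n_iterations number of random learning/test splits (default 100).
#' @param p_threshold mean Wald P selection threshold (default 0.01).
#' @param consistency_threshold minimum fraction of iterations in which the
#'   learning- and test-group Cox coefficients share a sign (default 0.80;
#'   selection requires strictly more than this).
#' @param split_fraction proportion of samples assigned to the learning
#'   group (default 0.5); splits are stratified on the event flag so event
#'   counts are balanced to within one.
#' @param p_aggregate `"arithmetic"` (default) or `"geometric"` mean of the
#'   per-group Wald P values.
#' @param seed integer seed; the screen is deterministic given a seed.
#' @return list of class `mccv_config`.
#' @export
mccv_config <- function(n_iterations = 100L, p_threshold = 0.01,
                        consistency_threshold = 0.80, split_fraction = 0.5,
                        p_aggregate = c("arithmetic", "geometric"),
                        seed = 1L) {
  p_aggregate <- match.arg(p_aggregate)
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (p_threshold <= 0 || p_threshold >= 1)
    stop("p_threshold must lie in (0, 1)")
  if (consistency_threshold <= 0 || consistency_threshold >= 1)
    stop("consistency_threshold must lie in (0, 1)")
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must lie in (0, 1)")
  structure(list(n_iterations = as.integer(n_iterations),
                 p_threshold = p_threshold,
                 consistency_threshold = consistency_threshold,
                 split_fraction = split_fraction,
                 p_aggregate = p_aggregate, seed = as.integer(seed)),
            class = "mccv_config")
}

# sample() without the scalar-x surprise
resample <- function(x, k) x[sample.int(length(x), k)]

# stratified learning/test split on the event flag; returns learning indices
mccv_split <- function(event, split_fraction) {
  ev <- which(event == 1)
  ne <- which(event == 0)
  n_ev <- max(1L, round(split_fraction * length(ev)))
  n_ne <- round(split_fraction * length(ne))
  c(resample(ev, min(n_ev, length(ev) - 1L)),
    resample(ne, n_ne))
}

#' Monte-Carlo cross-validation Cox screen
#'
#' Repeatedly splits the cohort into learning and test groups (stratified on
#' the event flag, so metastatic-case counts are controlled), fits a
#' univariate Cox model per feature in each group, and aggregates: a
#' feature's `mccv_mean_p` is the mean Wald P over all `2 * n_iterations`
#' group fits and its `mccv_consistency` is the fraction of iterations in
#' which the learning and test coefficients share a sign. A feature is
#' selected iff `mccv_mean_p < p_threshold` and
#' `mccv_consistency > consistency_threshold`. A split that leaves a group
#' with zero events is re-drawn (at most 10 times, then an error).
#'
#' Samples are put in canonical (sample-id) order internally, so the
#' selected set does not depend on the column order of the input bundle.
#'
#' @param bundle a merged, Z-transformed, variance-filtered
#'   [cohort_bundle()].
#' @param config an [mccv_config()].
#' @return data.frame with `feature_id`, `mccv_mean_p`, `mccv_consistency`,
#'   `mccv_selected`.
#' @export
mccv_screen <- function(bundle, config = mccv_config()) {
  ord <- order(bundle$clinical$sample_id)
  X <- bundle$expression[, ord, drop = FALSE]
  time <- bundle$clinical$dmfs_months[ord]
  event <- bundle$clinical$dmfs_event[ord]
  if (sum(event) < 2) stop("at least 2 events are required")
  set.seed(config$seed)
  G <- nrow(X)
  n <- ncol(X)
  p_sum <- numeric(G)
  logp_sum <- numeric(G)
  agree <- numeric(G)
  for (it in seq_len(config$n_iterations)) {
    for (try_ in 1:11) {
      learn <- mccv_split(event, config$split_fraction)
      test <- setdiff(seq_len(n), learn)
      if (sum(event[learn]) >= 1 && sum(event[test]) >= 1) break
      if (try_ == 11) stop("could not draw a split with events in both groups")
    }
    sl <- cox_screen(X[, learn, drop = FALSE], time[learn], event[learn])
    st <- cox_screen(X[, test, drop = FALSE], time[test], event[test])
    p_sum <- p_sum + sl$p + st$p
    logp_sum <- logp_sum + log(pmax(sl$p, 1e-300)) +
      log(pmax(st$p, 1e-300))
    agree <- agree + (sign(sl$coef) == sign(st$coef) & sl$coef != 0)
  }
  mean_p <- if (config$p_aggregate == "arithmetic")
    p_sum / (2 * config$n_iterations)
  else exp(logp_sum / (2 * config$n_iterations))
  consistency <- agree / config$n_iterations
  data.frame(feature_id = rownames(X),
             mccv_mean_p = mean_p,
             mccv_consistency = consistency,
             mccv_selected = mean_p < config$p_threshold &
               consistency > config$consistency_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Univariate/multivariate Cox sign-consistency filter
#'
#' Fits, on the discovery data, a univariate Cox model per candidate and one
#' multivariate Cox model with all candidates jointly, and keeps candidates
#' whose coefficients carry the same sign in both settings. If the joint fit
#' fails to converge (collinear or separated designs) a ridge-stabilized fit
#' (penalty 1e-4) is used instead and noted in the `note` column.
#'
#' @param candidates character vector of candidate feature ids.
#' @param bundle the (Z-transformed, merged) discovery [cohort_bundle()].
#' @return data.frame with `feature_id`, `uni_coef`, `uni_p`, `multi_coef`,
#'   `multi_p`, `kept`, `note`.
#' @export
cox_consistency_filter <- function(candidates, bundle) {
  candidates <- intersect(candidates, rownames(bundle$expression))
  if (!length(candidates)) stop("no candidates present in the bundle")
  time <- bundle$clinical$dmfs_months
  event <- bundle$clinical$dmfs_event
  X <- bundle$expression[candidates, , drop = FALSE]
  uni <- cox_screen(X, time, event)
  note <- ""
  if (length(candidates) == 1) {
    multi_coef <- uni$coef
    multi_p <- uni$p
  } else {
    Xt <- t(X)
    fit <- cox_fit(time, event, Xt)
    if (!fit$converged || any(!is.finite(fit$se))) {
      rfit <- survival::coxph(survival::Surv(time, event) ~
                                survival::ridge(Xt, theta = 1e-4))
      multi_coef <- unname(stats::coef(rfit))
      multi_se <- sqrt(diag(rfit$var))
      multi_p <- 2 * stats::pnorm(-abs(multi_coef / multi_se))
      note <- "ridge_fallback"
    } else {
      multi_coef <- unname(fit$coefficients)
      multi_p <- unname(fit$wald_p)
    }
  }
  data.frame(feature_id = candidates,
             uni_coef = uni$coef, uni_p = uni$p,
             multi_coef = multi_coef, multi_p = multi_p,
             kept = sign(uni$coef) == sign(multi_coef) & uni$coef != 0,
             note = note, stringsAsFactors = FALSE, row.names = NULL)
}

#' Hold-out confirmation of discovery candidates
#'
#' Mean-centers the hold-out bundle within its own source(s) (idempotent if
#' already centered), fits a univariate Cox model per candidate, and
#' confirms candidates whose hold-out coefficient sign matches the
#' discovery sign. Candidates absent from the hold-out features are dropped
#' with a warning.
#'
#' @param records data.frame with at least `feature_id` and `uni_coef`
#'   (discovery univariate coefficients), e.g. from
#'   [cox_consistency_filter()].
#' @param holdout a [cohort_bundle()] of the confirmation samples.
#' @return `records` with `holdout_coef`, `holdout_p`, `final_selected`
#'   columns appended (absent features removed).
#' @export
holdout_confirm <- function(records, holdout) {
  if (nrow(records) == 0) {
    records$holdout_coef <- numeric(0)
    records$holdout_p <- numeric(0)
    records$final_selected <- logical(0)
    return(records)
  }
  absent <- setdiff(records$feature_id, rownames(holdout$expression))
  if (length(absent)) {
    warning("candidate(s) absent from hold-out, dropped: ",
            paste(absent, collapse = ", "))
    records <- records[!records$feature_id %in% absent, , drop = FALSE]
  }
  if (nrow(records) == 0) {
    records$holdout_coef <- numeric(0)
    records$holdout_p <- numeric(0)
    records$final_selected <- logical(0)
    return(records)
  }
  holdout <- mean_center_within_source(holdout)
  sc <- cox_screen(holdout$expression[records$feature_id, , drop = FALSE],
                   holdout$clinical$dmfs_months,
                   holdout$clinical$dmfs_event)
  records$holdout_coef <- sc$coef
  records$holdout_p <- sc$p
  records$final_selected <- sign(sc$coef) == sign(records$uni_coef) &
    sc$coef != 0
  rownames(records) <- NULL
  records
}
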