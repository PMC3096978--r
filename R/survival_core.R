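#' Kaplan-Meier estimate with log-rank comparison
#'
#' Product-limit survival curves per group (via [survival::survfit()]) with
#' an unweighted log-rank test across groups. The test is skipped with a
#' warning when only one group is supplied or any group contains zero
#' events; the curves themselves remain valid.
#'
#' @param time follow-up times (months, non-negative).
#' @param event 0/1 event flags.
#' @param groups group labels (one group if `NULL`).
#' @return object of class `km_result`: list with `curves` (per-group
#'   data.frame of `time`, `n_risk`, `n_event`, `surv`), `logrank_chi2`,
#'   `logrank_df`, `logrank_p` (NA when skipped).
#' @export
km_estimate <- function(time, event, groups = NULL) {
  check_surv(time, event)
  if (is.null(groups)) groups <- rep("all", length(time))
  groups <- as.factor(groups)
  if (any(table(groups) == 0)) groups <- droplevels(groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ groups)
  k <- nlevels(groups)
  if (k == 1) {
    curves <- list(data.frame(time = fit$time, n_risk = fit$n.risk,
                              n_event = fit$n.event, surv = fit$surv))
    names(curves) <- levels(groups)
  } else {
    strata_id <- rep(seq_len(k), fit$strata)
    curves <- lapply(seq_len(k), function(i) {
      sel <- strata_id == i
      data.frame(time = fit$time[sel], n_risk = fit$n.risk[sel],
                 n_event = fit$n.event[sel], surv = fit$surv[sel])
    })
    names(curves) <- sub("^groups=", "", names(fit$strata))
  }
  chi2 <- df <- p <- NA_real_
  ev_per_group <- tapply(event, groups, sum)
  if (k < 2) {
    warning("single group: log-rank test skipped")
  } else if (any(ev_per_group == 0)) {
    warning("group(s) with zero events: log-rank test skipped")
  } else {
    lr <- logrank_test(time, event, groups)
    chi2 <- lr$chi2; df <- lr$df; p <- lr$p
  }
  structure(list(curves = curves, logrank_chi2 = chi2, logrank_df = df,
                 logrank_p = p),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat("Kaplan-Meier estimate,", length(x$curves), "group(s)\n")
  for (g in names(x$curves)) {
    cv <- x$curves[[g]]
    cat(sprintf("  %s: n=%d at risk, %d events\n", g,
                if (nrow(cv)) cv$n_risk[1] else 0L, sum(cv$n_event)))
  }
  if (!is.na(x$logrank_p))
    cat(sprintf("  log-rank chi2 = %.3f (df %d), P = %.3g\n",
                x$logrank_chi2, x$logrank_df, x$logrank_p))
  invisible(x)
}

#' Unweighted log-rank test
#'
#' @inheritParams km_estimate
#' @param groups group labels; at least two non-empty groups required.
#' @return list with `chi2`, `df` (k - 1), `p`.
#' @export
logrank_test <- function(time, event, groups) {
  check_surv(time, event)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("log-rank test requires at least 2 groups")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ groups, rho = 0)
  df <- nlevels(groups) - 1L
  list(chi2 = unname(sd_$chisq), df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood with Efron tie handling (delegating
#' to [survival::coxph()]). Constant covariates are flagged and reported
#' with coefficient 0 and P = 1 rather than breaking the fit; monotone
#' likelihood / non-convergence is flagged in `$flags`, not raised.
#'
#' @inheritParams km_estimate
#' @param covariates numeric matrix or data.frame, samples x variables.
#' @param ties tie-handling method, `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_fit`: `coefficients`, `se`, `z`, `wald_p`,
#'   `hr` (= exp(coef)), `ci95` (matrix, exp(coef +/- 1.96 se)), `loglik`
#'   (partial log-likelihood at the estimate), `n`, `n_events`, `flags`,
#'   `converged`.
#' @export
cox_fit <- function(time, event, covariates, ties = "efron") {
  check_surv(time, event)
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!all(is.finite(X))) stop("covariates must be finite")
  if (sum(event) < 1) stop("at least one event is required")
  vars <- colnames(X)
  const <- apply(X, 2, function(v) max(v) - min(v) == 0)
  flags <- stats::setNames(rep("", ncol(X)), vars)
  flags[const] <- "constant"
  coefs <- stats::setNames(rep(0, ncol(X)), vars)
  ses <- stats::setNames(rep(Inf, ncol(X)), vars)
  converged <- TRUE
  ll <- NA_real_
  if (any(!const)) {
    Xf <- X[, !const, drop = FALSE]
    warn <- character()
    fit <- withCallingHandlers(
      survival::coxph(survival::Surv(time, event) ~ Xf, ties = ties),
      warning = function(w) {
        warn <<- c(warn, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    cf <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    coefs[!const] <- unname(cf)
    ses[!const] <- unname(se)
    ll <- fit$loglik[length(fit$loglik)]
    bad <- grepl("converge|infinite|beta may be infinite|loglik", warn,
                 ignore.case = TRUE)
    if (any(bad) || any(is.na(cf))) {
      converged <- FALSE
      flags[!const] <- paste(flags[!const], "nonconverged")
      coefs[is.na(coefs)] <- 0
      ses[is.na(ses)] <- Inf
    }
  }
  z <- ifelse(is.finite(ses) & ses > 0, coefs / ses, 0)
  p <- ifelse(flags == "constant" | !is.finite(ses), 1,
              2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = coefs, se = ses, z = z, wald_p = p,
                 hr = exp(coefs),
                 ci95 = cbind(lower = exp(coefs - 1.96 * ses),
                              upper = exp(coefs + 1.96 * ses)),
                 loglik = ll, n = length(time), n_events = sum(event),
                 flags = trimws(flags), converged = converged),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  tab <- data.frame(coef = x$coefficients, se = x$se, hr = x$hr,
                    lower95 = x$ci95[, "lower"], upper95 = x$ci95[, "upper"],
                    wald_p = x$wald_p)
  cat(sprintf("Cox PH fit: n = %d, events = %d%s\n", x$n, x$n_events,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' Vectorized per-feature univariate Cox screen
#'
#' Fits an independent one-covariate Cox model to every row of `X` by
#' Newton-Raphson on the Efron-adjusted partial likelihood, vectorized
#' across features so that screening thousands of genes inside a resampling
#' loop is practical. Constant features are reported with coefficient 0 and
#' P = 1 (`constant` flag); features whose likelihood is monotone (risk-set
#' separation) are flagged `diverged`. Agreement with per-gene
#' [survival::coxph()] fits is part of the package's test suite.
#'
#' @param X numeric matrix, features x samples.
#' @inheritParams km_estimate
#' @param max_iter maximum Newton iterations (default 30).
#' @param tol convergence tolerance on the absolute score (default 1e-8).
#' @return data.frame with one row per feature: `feature_id`, `coef`, `se`,
#'   `z`, `p`, `constant`, `converged`.
#' @export
cox_screen <- function(X, time, event, max_iter = 30L, tol = 1e-8) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  n <- ncol(X)
  check_surv(time, event)
  if (length(time) != n) stop("length(time) must equal ncol(X)")
  if (sum(event) < 1) stop("at least one event is required")
  G <- nrow(X)
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("f", seq_len(G))

  ord <- order(time)
  X <- X[, ord, drop = FALSE]
  tt <- time[ord]; dd <- event[ord]
  dead <- which(dd == 1)
  ut <- unique(tt[dead])
  K <- length(ut)
  grp <- match(tt[dead], ut)
  dk <- tabulate(grp, K)
  RiskInd <- outer(tt, ut, ">=") + 0          # n x K
  Dind <- outer(grp, seq_len(K), "==") + 0    # ndead x K
  ll <- unlist(lapply(dk, function(d) seq_len(d) - 1))
  kk <- rep.int(seq_len(K), dk)
  frac <- ll / dk[kk]
  L <- length(kk)

  xsum_dead <- rowSums(X[, dead, drop = FALSE])
  const <- rowSums(abs(X - X[, 1])) == 0
  untied <- all(dk == 1L)              # Efron = Breslow, skip adjustments
  if (!untied) FRa <- matrix(frac, sum(!const), L, byrow = TRUE)
  beta <- numeric(G)
  info <- rep(NA_real_, G)
  # active-set Newton: converged features drop out of the matrix work
  act <- which(!const)
  for (it in seq_len(max_iter)) {
    if (!length(act)) break
    Xa <- X[act, , drop = FALSE]
    W <- exp(Xa * beta[act])           # row-wise scaling (column-major)
    XW <- Xa * W
    X2W <- Xa * XW
    if (untied) {
      F0 <- W %*% RiskInd
      F1 <- XW %*% RiskInd
      F2 <- X2W %*% RiskInd
    } else {
      F0 <- (W %*% RiskInd)[, kk, drop = FALSE] -
        (W[, dead, drop = FALSE] %*% Dind)[, kk, drop = FALSE] * FRa
      F1 <- (XW %*% RiskInd)[, kk, drop = FALSE] -
        (XW[, dead, drop = FALSE] %*% Dind)[, kk, drop = FALSE] * FRa
      F2 <- (X2W %*% RiskInd)[, kk, drop = FALSE] -
        (X2W[, dead, drop = FALSE] %*% Dind)[, kk, drop = FALSE] * FRa
    }
    R1 <- F1 / F0
    U <- xsum_dead[act] - rowSums(R1)
    I <- rowSums(F2 / F0 - R1^2)
    info[act] <- I
    conv <- abs(U) < tol | I <= 0
    if (!all(conv)) {
      step <- pmin(pmax(ifelse(I > 0, U / I, 0), -2), 2)
      beta[act[!conv]] <- beta[act[!conv]] + step[!conv]
    }
    act <- act[!conv]
    if (!untied && length(act) < nrow(FRa))
      FRa <- FRa[seq_along(act), , drop = FALSE]
  }
  diverged <- !const & (abs(beta) > 15 | is.na(info) | info <= 0)
  se <- ifelse(!const & !is.na(info) & info > 0, 1 / sqrt(info), Inf)
  z <- ifelse(is.finite(se), beta / se, 0)
  p <- ifelse(const | diverged, 1, 2 * stats::pnorm(-abs(z)))
  data.frame(feature_id = ids, coef = ifelse(const, 0, beta), se = se,
             z = z, p = p, constant = const,
             converged = !const & !diverged,
             stringsAsFactors = FALSE, row.names = NULL)
}

# shared argument checks for survival inputs
check_surv <- function(time, event) {
  if (length(time) != length(event))
    stop("time and event must have equal length")
  if (any(time < 0)) stop("negative survival times")
  if (!all(event %in% c(0, 1))) stop("event flags must be 0/1")
  invisible(TRUE)
}
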