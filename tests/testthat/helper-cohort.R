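# shared fixtures built in code: tiny bundles and survival draws

# small deterministic bundle with explicit values
tiny_bundle <- function(expr, source = NULL, time = NULL, event = NULL) {
  n <- ncol(expr)
  if (is.null(colnames(expr))) colnames(expr) <- sprintf("smp%02d", seq_len(n))
  if (is.null(rownames(expr))) rownames(expr) <- sprintf("g%02d", seq_len(nrow(expr)))
  cohort_bundle(expr,
                data.frame(sample_id = colnames(expr),
                           source = source %||% rep("A", n),
                           dmfs_months = time %||% seq_len(n),
                           dmfs_event = event %||% rep(1L, n),
                           er_status = "neg", pr_status = "neg",
                           stringsAsFactors = FALSE))
}

# random multi-source bundle with survival independent of expression
random_bundle <- function(n_genes = 50, samples = c(20, 20), seed = 1,
                          event_p = 0.4) {
  set.seed(seed)
  n <- sum(samples)
  src <- rep(paste0("S", seq_along(samples)), samples)
  expr <- matrix(rnorm(n_genes * n), n_genes, n,
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                 sprintf("%s_%02d", src,
                                         unlist(lapply(samples, seq_len)))))
  cohort_bundle(expr,
                data.frame(sample_id = colnames(expr), source = src,
                           dmfs_months = rexp(n, 0.02),
                           dmfs_event = rbinom(n, 1, event_p),
                           stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
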