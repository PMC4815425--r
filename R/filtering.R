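#' Probe-set inclusion filters
#'
#' Applies the two standard pre-processing filters to the pooled cross-study
#' sample set before any statistics: (i) a gene's log2 value must reach
#' `log2(intensity_threshold_raw)` (raw fluorescence 100 by default) in at
#' least `intensity_min_fraction` of all samples, and (ii) the interquartile
#' range of its log2 values across all samples must be at least
#' `iqr_threshold_log2`. Quantiles use the linear-interpolation convention
#' (`stats::quantile` type 7), so tie handling is fully determined.
#'
#' @param expr an [expression_study()], or a list of them; multiple studies
#'   are pooled column-wise (gene sets must agree).
#' @param cfg a [run_config()].
#' @return A list with elements `filtered` (the retained-gene
#'   `expression_study`, input gene order preserved) and `report` (a
#'   `filter_report`: counts plus per-gene pass flags).
#' @examples
#' m <- matrix(rnorm(40, 8), 10, 4,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' filter_probesets(expression_study(m), run_config())$report$n_retained
#' @export
filter_probesets <- function(expr, cfg = run_config()) {
  cfg <- validate_run_config(cfg)
  expr <- pool_studies(expr)
  m <- expr$matrix
  if (ncol(m) == 0) stop("no samples to filter on", call. = FALSE)
  cutoff <- switch(cfg$intensity_scale,
                   raw = log2(cfg$intensity_threshold_raw),
                   log2_literal = cfg$intensity_threshold_raw)
  frac_above <- rowMeans(m >= cutoff)
  pass_intensity <- frac_above >= cfg$intensity_min_fraction
  iqr <- apply(m, 1, function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    q[2] - q[1]
  })
  pass_iqr <- iqr >= cfg$iqr_threshold_log2
  keep <- pass_intensity & pass_iqr
  report <- structure(list(
    n_input = nrow(m),
    n_pass_intensity = sum(pass_intensity),
    n_pass_iqr = sum(pass_iqr),
    n_retained = sum(keep),
    flags = data.frame(gene_id = rownames(m),
                       frac_above_intensity = frac_above,
                       iqr_log2 = iqr,
                       pass_intensity = pass_intensity,
                       pass_iqr = pass_iqr,
                       retained = keep,
                       row.names = NULL)
  ), class = "filter_report")
  filtered <- expr
  filtered$matrix <- m[keep, , drop = FALSE]
  pipeline_log("filter_probesets", n_input = report$n_input,
               n_retained = report$n_retained,
               intensity_cutoff_log2 = signif(cutoff, 6),
               min_fraction = cfg$intensity_min_fraction,
               min_iqr = cfg$iqr_threshold_log2)
  list(filtered = filtered, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n",
      sprintf("  input genes:        %d\n", x$n_input),
      sprintf("  pass intensity:     %d\n", x$n_pass_intensity),
      sprintf("  pass IQR:           %d\n", x$n_pass_iqr),
      sprintf("  retained (both):    %d\n", x$n_retained), sep = "")
  invisible(x)
}

# Pool a list of expression studies column-wise over a shared gene set.
pool_studies <- function(expr) {
  if (inherits(expr, "expression_study")) return(expr)
  stopifnot(is.list(expr), length(expr) >= 1)
  genes <- rownames(expr[[1]]$matrix)
  for (e in expr) {
    stopifnot(inherits(e, "expression_study"))
    if (!identical(rownames(e$matrix), genes)) {
      stop("studies to pool must share an identical gene set and order",
           call. = FALSE)
    }
  }
  mat <- do.call(cbind, lapply(expr, function(e) e$matrix))
  samples <- do.call(rbind, lapply(expr, function(e) e$samples))
  expression_study(mat, samples)
}
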