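#' Run configuration for the meta-analysis pipeline
#'
#' Collects every tunable setting of the pipeline in one validated object.
#' The defaults reproduce the published analysis settings: significance level
#' 0.05, REML between-study variance for the per-gene meta-analysis,
#' DerSimonian-Laird for the meta-regression, Student-t confidence intervals
#' with K-1 degrees of freedom, a raw-fluorescence intensity filter at 100 in
#' at least 10% of samples, and a log2 interquartile-range filter at 0.5.
#'
#' @param alpha significance / FDR level in (0, 1).
#' @param tau2_method_meta between-study variance estimator for the per-gene
#'   random-effects meta-analysis: `"reml"` (default) or `"dl"`.
#' @param tau2_method_metareg estimator for the meta-regression residual
#'   heterogeneity: `"dl"` (default) or `"reml"`.
#' @param ci_distribution reference distribution for the 95% confidence
#'   interval of the weighted mean effect: `"student_t"` (K-1 df, default) or
#'   `"normal"`.
#' @param test_distribution reference distribution for the two-sided test of
#'   the weighted mean effect: `"normal"` (default, as in the published
#'   method) or `"student_t"` (K-1 df, the small-K calibrated choice; see the
#'   methods vignette).
#' @param intensity_threshold_raw raw-scale fluorescence cutoff for the
#'   intensity filter; genes must reach `log2(intensity_threshold_raw)` on the
#'   log2 scale. Must be positive.
#' @param intensity_scale `"raw"` (default) interprets
#'   `intensity_threshold_raw` as a raw fluorescence value, so the log2 cutoff
#'   is `log2(threshold)`; `"log2_literal"` applies the threshold directly to
#'   the log2 values.
#' @param intensity_min_fraction minimum fraction of samples that must reach
#'   the intensity cutoff.
#' @param iqr_threshold_log2 minimum interquartile range of a gene's log2
#'   values across all pooled samples.
#' @param qm_df_convention degrees of freedom for the moderator test:
#'   `"m_minus_1"` (default; equality of the m level means, chi-square with
#'   m - 1 df) or `"m"` (omnibus test that all m coefficients are zero).
#' @param effect_scale scale on which the log expression ratio is computed:
#'   `"as_given"` (default; ratio of means of the values as provided, i.e.
#'   log2-scale means) or `"delog2"` (replicates are back-transformed with
#'   `2^x` before means and variances are taken).
#' @param variance_floor smallest admissible sampling variance for an effect
#'   size; zero variances are raised to this floor before weighting.
#' @param seed integer seed recorded with the configuration.
#'
#' @return An object of class `"run_config"`: a validated named list.
#' @examples
#' cfg <- run_config()
#' cfg$alpha
#' @export
run_config <- function(alpha = 0.05,
                       tau2_method_meta = c("reml", "dl"),
                       tau2_method_metareg = c("dl", "reml"),
                       ci_distribution = c("student_t", "normal"),
                       test_distribution = c("normal", "student_t"),
                       intensity_threshold_raw = 100,
                       intensity_scale = c("raw", "log2_literal"),
                       intensity_min_fraction = 0.10,
                       iqr_threshold_log2 = 0.5,
                       qm_df_convention = c("m_minus_1", "m"),
                       effect_scale = c("as_given", "delog2"),
                       variance_floor = 1e-8,
                       seed = 1L) {
  cfg <- list(
    alpha = alpha,
    tau2_method_meta = match.arg(tau2_method_meta),
    tau2_method_metareg = match.arg(tau2_method_metareg),
    ci_distribution = match.arg(ci_distribution),
    test_distribution = match.arg(test_distribution),
    intensity_threshold_raw = intensity_threshold_raw,
    intensity_scale = match.arg(intensity_scale),
    intensity_min_fraction = intensity_min_fraction,
    iqr_threshold_log2 = iqr_threshold_log2,
    qm_df_convention = match.arg(qm_df_convention),
    effect_scale = match.arg(effect_scale),
    variance_floor = variance_floor,
    seed = as.integer(seed)
  )
  class(cfg) <- "run_config"
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.numeric(cfg$alpha) || length(cfg$alpha) != 1 ||
      cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("`alpha` must be a single number in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(cfg$intensity_threshold_raw) ||
      cfg$intensity_threshold_raw <= 0) {
    stop("`intensity_threshold_raw` must be positive", call. = FALSE)
  }
  if (!is.numeric(cfg$intensity_min_fraction) ||
      cfg$intensity_min_fraction < 0) {
    stop("`intensity_min_fraction` must be nonnegative", call. = FALSE)
  }
  if (!is.numeric(cfg$iqr_threshold_log2) || cfg$iqr_threshold_log2 < 0) {
    stop("`iqr_threshold_log2` must be nonnegative", call. = FALSE)
  }
  if (!is.numeric(cfg$variance_floor) || cfg$variance_floor < 0) {
    stop("`variance_floor` must be nonnegative", call. = FALSE)
  }
  cfg
}

#' Read or write a run configuration as a key-value text file
#'
#' Configurations are stored as flat YAML; unknown keys are rejected so typos
#' cannot silently fall back to defaults.
#'
#' @param path file path.
#' @param cfg a [run_config()] object (for writing).
#' @return `read_run_config()` returns a `run_config`; `write_run_config()`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  cfg <- validate_run_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# One log line per pipeline stage: stage name plus settings/shapes.
pipeline_log <- function(stage, ...) {
  info <- c(...)
  msg <- if (length(info)) {
    paste0(stage, ": ", paste(names(info), unname(info), sep = "=",
                              collapse = ", "))
  } else {
    stage
  }
  message("[metaexpr] ", msg)
  invisible(msg)
}
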