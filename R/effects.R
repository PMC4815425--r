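#' Per-contrast replicate summaries
#'
#' Reduces replicate-level expression to per-gene, per-contrast arm means and
#' unbiased (n - 1 denominator) variances. A contrast is one treated-vs-
#' control comparison within one study and plant part (`study_id.part`);
#' within a study that assayed several plant parts, each part forms its own
#' contrast and is treated downstream as an independent study.
#'
#' @param expr an annotated [expression_study()].
#' @param cfg a [run_config()]; `cfg$effect_scale = "delog2"` back-transforms
#'   replicates with `2^x` before summarizing.
#' @param contrast_id optional character vector restricting to specific
#'   contrasts.
#' @return A list with `summaries` (data.frame: `gene_id`, `contrast_id`,
#'   `ybar1`, `s2_1`, `n1`, `ybar2`, `s2_2`, `n2`, `part`, `method`) and
#'   `rejected` (data.frame of contrasts with fewer than 2 replicates in an
#'   arm, with reasons).
#' @export
summarize_contrasts <- function(expr, cfg = run_config(), contrast_id = NULL) {
  stopifnot(inherits(expr, "expression_study"))
  if (is.null(expr$samples)) {
    stop("expression study has no sample annotations; see read_sample_sheet()",
         call. = FALSE)
  }
  cfg <- validate_run_config(cfg)
  s <- expr$samples
  m <- expr$matrix
  if (cfg$effect_scale == "delog2") m <- 2^m
  s$contrast_id <- paste(s$study_id, s$part, sep = ".")
  wanted <- if (is.null(contrast_id)) unique(s$contrast_id) else contrast_id
  unknown <- setdiff(wanted, s$contrast_id)
  if (length(unknown) > 0) {
    stop("unknown contrast id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  summaries <- vector("list", length(wanted))
  rejected <- list()
  arm_stats <- function(cols) {
    x <- m[, cols, drop = FALSE]
    n <- length(cols)
    mu <- rowMeans(x)
    list(mean = mu, var = rowSums((x - mu)^2) / (n - 1), n = n)
  }
  for (i in seq_along(wanted)) {
    cid <- wanted[i]
    rows <- s[s$contrast_id == cid, , drop = FALSE]
    t_cols <- rows$sample_id[rows$arm == "treated"]
    c_cols <- rows$sample_id[rows$arm == "control"]
    if (length(t_cols) < 2 || length(c_cols) < 2) {
      rejected[[length(rejected) + 1L]] <- data.frame(
        contrast_id = cid,
        reason = sprintf("needs >=2 replicates per arm (treated=%d, control=%d)",
                         length(t_cols), length(c_cols)))
      next
    }
    a1 <- arm_stats(t_cols)
    a2 <- arm_stats(c_cols)
    summaries[[i]] <- data.frame(
      gene_id = rownames(m), contrast_id = cid,
      ybar1 = a1$mean, s2_1 = a1$var, n1 = a1$n,
      ybar2 = a2$mean, s2_2 = a2$var, n2 = a2$n,
      part = rows$part[1], method = rows$method[1],
      row.names = NULL)
  }
  rejected <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(contrast_id = character(), reason = character())
  if (nrow(rejected) > 0) {
    message("[metaexpr] rejected contrast(s): ",
            paste(rejected$contrast_id, collapse = ", "))
  }
  summaries <- summaries[!vapply(summaries, is.null, logical(1))]
  summaries <- if (length(summaries)) do.call(rbind, summaries) else
    data.frame(gene_id = character(), contrast_id = character(),
               ybar1 = numeric(), s2_1 = numeric(), n1 = integer(),
               ybar2 = numeric(), s2_2 = numeric(), n2 = integer(),
               part = character(), method = character())
  pipeline_log("summarize_contrasts",
               contrasts = length(unique(summaries$contrast_id)),
               rejected = nrow(rejected), scale = cfg$effect_scale)
  list(summaries = summaries, rejected = rejected)
}

#' Log expression ratio effect sizes
#'
#' Computes, for every gene x contrast summary, the log expression ratio
#' `lnr = ln(ybar1 / ybar2)` and its approximated sampling variance
#' `v = s2_1 / (n1 * ybar1^2) + s2_2 / (n2 * ybar2^2)`. Genes with a
#' nonpositive arm mean in a contrast cannot be expressed as a log ratio
#' there; those records are excluded and reported. Zero sampling variances
#' are raised to `cfg$variance_floor` so inverse-variance weights stay
#' finite.
#'
#' @param summaries the `summaries` data.frame from [summarize_contrasts()]
#'   (or the list it returns).
#' @param cfg a [run_config()].
#' @return A list with `effects` (data.frame: `gene_id`, `contrast_id`,
#'   `lnr`, `v`, `part`, `method`, `n1`, `n2`), `excluded` (records dropped
#'   for nonpositive means) and `n_floored` (count of floored variances).
#' @export
effect_sizes <- function(summaries, cfg = run_config()) {
  if (is.list(summaries) && !is.data.frame(summaries) &&
      !is.null(summaries$summaries)) {
    summaries <- summaries$summaries
  }
  cfg <- validate_run_config(cfg)
  stopifnot(is.data.frame(summaries))
  bad <- summaries$ybar1 <= 0 | summaries$ybar2 <= 0
  excluded <- summaries[bad, c("gene_id", "contrast_id"), drop = FALSE]
  if (nrow(excluded) > 0) {
    message("[metaexpr] excluded ", nrow(excluded),
            " gene x contrast record(s) with nonpositive arm mean")
  }
  ok <- summaries[!bad, , drop = FALSE]
  lnr <- log(ok$ybar1) - log(ok$ybar2)
  v <- ok$s2_1 / (ok$n1 * ok$ybar1^2) + ok$s2_2 / (ok$n2 * ok$ybar2^2)
  n_floored <- sum(v < cfg$variance_floor)
  v <- pmax(v, cfg$variance_floor)
  effects <- data.frame(gene_id = ok$gene_id, contrast_id = ok$contrast_id,
                        lnr = lnr, v = v, part = ok$part, method = ok$method,
                        n1 = ok$n1, n2 = ok$n2, row.names = NULL)
  pipeline_log("effect_sizes", records = nrow(effects),
               excluded = nrow(excluded), floored = n_floored)
  list(effects = effects, excluded = excluded, n_floored = n_floored)
}
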