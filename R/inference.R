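#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts p-values by the step-up procedure
#' `q_(i) = min_{j >= i} (m * p_(j) / j)` capped at 1 and mapped back to
#' input order (via `stats::p.adjust`, the implementation the published
#' analysis used). Inputs outside (0, 1] are fatal with the offending index
#' named. FDR is applied separately per analysis family (the genome-wide
#' meta-analysis, each meta-regression moderator, each per-study contrast).
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return Adjusted values in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  bad <- which(!is.finite(pvals) | pvals <= 0 | pvals > 1)
  if (length(bad) > 0) {
    stop(sprintf("p-value out of (0, 1] at index %d (value %s)",
                 bad[1], format(pvals[bad[1]])), call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Classify genes from meta-analysis fits
#'
#' Applies genome-wide BH adjustment to the meta-analysis p-values and calls
#' each gene `up` (q < alpha and positive mean effect), `down` (q < alpha
#' and negative), or `ns`. Also records `ci_gap`, the distance from the
#' nearer 95% CI bound to zero (0 when the interval spans zero), used for
#' the forest ordering.
#'
#' @param fits data.frame from [fit_random_effects()].
#' @param alpha FDR level.
#' @return Data.frame per gene: `gene_id`, `mu_hat`, `ci_lo`, `ci_hi`, `q`,
#'   `call`, `ci_gap`.
#' @export
classify_genes <- function(fits, alpha = 0.05) {
  stopifnot(is.data.frame(fits),
            all(c("gene_id", "mu_hat", "ci_lo", "ci_hi", "p") %in%
                  names(fits)))
  q <- bh_adjust(fits$p)
  call <- rep("ns", nrow(fits))
  call[q < alpha & fits$mu_hat > 0] <- "up"
  call[q < alpha & fits$mu_hat < 0] <- "down"
  ci_gap <- rep(0, nrow(fits))
  above <- !is.na(fits$ci_lo) & fits$ci_lo > 0
  below <- !is.na(fits$ci_hi) & fits$ci_hi < 0
  ci_gap[above] <- fits$ci_lo[above]
  ci_gap[below] <- -fits$ci_hi[below]
  out <- data.frame(gene_id = fits$gene_id, mu_hat = fits$mu_hat,
                    ci_lo = fits$ci_lo, ci_hi = fits$ci_hi, q = q,
                    call = call, ci_gap = ci_gap, row.names = NULL)
  pipeline_log("classify_genes", up = sum(call == "up"),
               down = sum(call == "down"), ns = sum(call == "ns"),
               alpha = alpha)
  out
}

#' Forest-plot gene orderings
#'
#' Orders genes the way the two genome-wide forest displays do. Mode
#' `"ci_gap"`: genes whose CI excludes zero first, by descending distance of
#' the nearer CI bound from zero; genes whose CI spans zero after, by
#' descending `|mu_hat|`. Mode `"mu_magnitude"`: all genes by descending
#' `|mu_hat|`. Ties are broken by gene_id lexicographic order (C collation)
#' for determinism.
#'
#' @param calls data.frame from [classify_genes()].
#' @param mode `"ci_gap"` or `"mu_magnitude"`.
#' @return The reordered `calls` data.frame.
#' @export
sort_forest <- function(calls, mode = c("ci_gap", "mu_magnitude")) {
  mode <- match.arg(mode)
  id_rank <- withr_collate_c_order(calls$gene_id)
  ord <- if (mode == "ci_gap") {
    order(calls$ci_gap == 0,                      # excluders first
          ifelse(calls$ci_gap > 0, -calls$ci_gap, -abs(calls$mu_hat)),
          id_rank)
  } else {
    order(-abs(calls$mu_hat), id_rank)
  }
  out <- calls[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# rank of strings under C collation, independent of the session locale
withr_collate_c_order <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  match(x, sort(unique(x)))
}

#' Compare meta-analysis and per-study gene sets
#'
#' Intersection bookkeeping between the meta-analysis discoveries and the
#' per-contrast moderated-t discoveries: per-contrast DEG counts and their
#' intersections with the meta set, the per-gene count of supporting
#' contrasts (and its histogram), and the three-way partition of the
#' discovery universe (meta-only, both, t-only). A contrast with zero DEGs
#' is a legitimate outcome and contributes zeros. Meta-only genes are
#' additionally flagged when their mean effect is extremely small
#' (|mu_hat| < `small_effect`), the signature of genes only a synthesis can
#' detect.
#'
#' @param meta_calls data.frame from [classify_genes()].
#' @param per_study_calls named list of per-contrast data.frames carrying
#'   `gene_id` and `q` (e.g. [moderated_t()] results); names are contrast
#'   ids.
#' @param alpha FDR level defining a discovery (`q < alpha`).
#' @param small_effect threshold for the small-effect annotation.
#' @return List with `per_contrast` (contrast_id, n_deg, n_intersect_meta),
#'   `support` (gene_id, n_contrasts for every gene discovered by at least
#'   one t-test), `support_hist` (table), `meta_only`, `both`, `t_only`
#'   (gene-id vectors), `meta_only_small` (data.frame gene_id, mu_hat,
#'   small_effect flag), and `counts` (named totals).
#' @export
compare_gene_sets <- function(meta_calls, per_study_calls, alpha = 0.05,
                              small_effect = 0.05) {
  stopifnot(is.data.frame(meta_calls), is.list(per_study_calls))
  universe <- meta_calls$gene_id
  for (nm in names(per_study_calls)) {
    g <- per_study_calls[[nm]]$gene_id
    if (!setequal(g, universe)) {
      stop("gene universe mismatch between meta results and contrast '",
           nm, "'", call. = FALSE)
    }
  }
  meta_set <- meta_calls$gene_id[meta_calls$call != "ns"]
  study_sets <- lapply(per_study_calls, function(d)
    d$gene_id[d$q < alpha])
  per_contrast <- data.frame(
    contrast_id = names(per_study_calls),
    n_deg = vapply(study_sets, length, integer(1)),
    n_intersect_meta = vapply(study_sets,
                              function(s) length(intersect(s, meta_set)),
                              integer(1)),
    row.names = NULL)
  support_counts <- table(unlist(study_sets, use.names = FALSE))
  t_union <- names(support_counts)
  support <- data.frame(gene_id = t_union,
                        n_contrasts = as.integer(support_counts),
                        row.names = NULL)
  meta_only <- setdiff(meta_set, t_union)
  both <- intersect(meta_set, t_union)
  t_only <- setdiff(t_union, meta_set)
  mo <- meta_calls[match(meta_only, meta_calls$gene_id), , drop = FALSE]
  meta_only_small <- data.frame(gene_id = meta_only, mu_hat = mo$mu_hat,
                                small_effect = abs(mo$mu_hat) < small_effect,
                                row.names = NULL)
  list(per_contrast = per_contrast,
       support = support,
       support_hist = table(factor(support$n_contrasts,
                                   levels = seq_along(per_study_calls))),
       meta_only = meta_only, both = both, t_only = t_only,
       meta_only_small = meta_only_small,
       counts = c(n_meta = length(meta_set), n_t_union = length(t_union),
                  n_meta_only = length(meta_only), n_both = length(both),
                  n_t_only = length(t_only)))
}
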