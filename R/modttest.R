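#' Per-study moderated t-tests
#'
#' The per-study comparison baseline: for one contrast, each gene gets a
#' two-sample test whose residual variance is shrunk toward a genome-wide
#' prior by empirical Bayes. The prior (`d0` degrees of freedom, `s0^2`
#' scale) is estimated across genes by the method of moments on the log
#' residual variances under the scaled-F model (`s2_g ~ s0^2 * F(d, d0)`
#' marginally): with `e_g = log(s2_g) - digamma(d/2) + log(d/2)`,
#' `Var(e) = trigamma(d/2) + trigamma(d0/2)` determines `d0` (by inverting
#' the trigamma function) and `mean(e) = log(s0^2) + log(d0/2) -
#' digamma(d0/2)` determines `s0^2`. The posterior variance is
#' `s2_post = (d0 * s0^2 + d * s2_g) / (d0 + d)` and the moderated t,
#' `log_fc / sqrt(s2_post * (1/n1 + 1/n2))`, is referred to Student's t with
#' `d + d0` degrees of freedom.
#'
#' @param expr an annotated [expression_study()].
#' @param contrast_id the contrast (`study_id.part`) to test.
#' @param cfg a [run_config()] (only `alpha` is used, for the FDR column).
#' @param prior_df_override force the prior degrees of freedom: `0` gives
#'   ordinary two-sample t-tests (no shrinkage), `Inf` complete pooling to
#'   `s0^2`; `NULL` (default) estimates `d0` from the data.
#' @return A data.frame per gene: `gene_id`, `contrast_id`, `log_fc`
#'   (treated minus control mean on the provided log2 scale), `s2_g`,
#'   `s2_post`, `t_mod`, `df_total`, `p`, `q` (BH within the contrast), with
#'   attributes `d0` and `s0_sq`.
#' @export
moderated_t <- function(expr, contrast_id, cfg = run_config(),
                        prior_df_override = NULL) {
  stopifnot(inherits(expr, "expression_study"))
  if (is.null(expr$samples)) {
    stop("expression study has no sample annotations", call. = FALSE)
  }
  s <- expr$samples
  s$contrast_id <- paste(s$study_id, s$part, sep = ".")
  rows <- s[s$contrast_id == contrast_id, , drop = FALSE]
  if (nrow(rows) == 0) stop("unknown contrast id: ", contrast_id,
                            call. = FALSE)
  t_cols <- rows$sample_id[rows$arm == "treated"]
  c_cols <- rows$sample_id[rows$arm == "control"]
  n1 <- length(t_cols)
  n2 <- length(c_cols)
  if (n1 < 2 || n2 < 2) {
    stop(sprintf("contrast '%s' needs >=2 replicates per arm (%d, %d)",
                 contrast_id, n1, n2), call. = FALSE)
  }
  m <- expr$matrix
  x1 <- m[, t_cols, drop = FALSE]
  x2 <- m[, c_cols, drop = FALSE]
  mu1 <- rowMeans(x1)
  mu2 <- rowMeans(x2)
  d <- n1 + n2 - 2
  s2_g <- (rowSums((x1 - mu1)^2) + rowSums((x2 - mu2)^2)) / d
  log_fc <- mu1 - mu2

  prior <- estimate_variance_prior(s2_g, d)
  d0 <- if (is.null(prior_df_override)) prior$d0 else prior_df_override
  s0_sq <- prior$s0_sq
  if (is.na(d0)) {
    warning("variance prior could not be estimated (all residual variances ",
            "zero); falling back to ordinary t-tests", call. = FALSE)
    d0 <- 0
    s0_sq <- NA_real_
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2_g)) else
    (d0 * s0_sq + d * s2_g) / (d0 + d)
  df_total <- d + d0
  t_mod <- log_fc / sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- pmax(2 * stats::pt(-abs(t_mod), df_total), .Machine$double.xmin)
  res <- data.frame(gene_id = rownames(m), contrast_id = contrast_id,
                    log_fc = log_fc, s2_g = s2_g, s2_post = s2_post,
                    t_mod = t_mod, df_total = df_total, p = p,
                    q = bh_adjust(p), row.names = NULL)
  attr(res, "d0") <- d0
  attr(res, "s0_sq") <- s0_sq
  pipeline_log("moderated_t", contrast = contrast_id, genes = nrow(res),
               n1 = n1, n2 = n2, d0 = signif(d0, 4))
  res
}

#' Genome-wide variance prior by method of moments
#'
#' Estimates the scaled-inverse-chi-square prior on gene-wise residual
#' variances from their log values. Genes with zero residual variance are
#' excluded from the moment equations (log undefined); if all are zero the
#' prior is inestimable and `d0` is `NA`. When the observed spread of log
#' variances is no larger than expected from sampling alone
#' (`var(e) <= trigamma(d/2)`), the prior degrees of freedom are infinite
#' (complete pooling).
#'
#' @param s2 gene-wise residual variances.
#' @param d residual degrees of freedom (scalar, shared by all genes).
#' @return List with `d0` and `s0_sq`.
#' @export
estimate_variance_prior <- function(s2, d) {
  pos <- s2 > 0
  if (!any(pos)) return(list(d0 = NA_real_, s0_sq = NA_real_))
  e <- log(s2[pos]) - digamma(d / 2) + log(d / 2)
  ve <- stats::var(e)
  excess <- ve - trigamma(d / 2)
  if (!is.finite(excess) || excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(mean(e) - log(d0 / 2) + digamma(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Invert y = trigamma(x) for x > 0 by Newton iteration on 1/trigamma,
# which is nearly linear in x.
trigamma_inverse <- function(y) {
  stopifnot(y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}
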