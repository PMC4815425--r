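#' Default multi-study roster
#'
#' Ten two-arm contrasts mirroring the structure of a typical collection of
#' ATH1 water-stress series: one study sampling seedlings under PEG (so the
#' plant-part and method models each have exactly one excluded contrast),
#' two root studies, a deracination study, and mostly 3+3 designs with two
#' 2+2 studies. Parts leaf/rosette are coded as shoot.
#'
#' @return data.frame with columns `study_id`, `part`, `method`, `n1`, `n2`.
#' @export
default_study_roster <- function() {
  data.frame(
    study_id = sprintf("S%02d", 1:10),
    part = c("root", "shoot", "root", "shoot", "seedling",
             "shoot", "shoot", "shoot", "shoot", "shoot"),
    method = c("water_withholding", "water_withholding", "mannitol",
               "mannitol", "peg", "water_withholding", "water_withholding",
               "water_withholding", "water_withholding", "deracination"),
    n1 = c(3, 3, 3, 3, 3, 3, 2, 3, 2, 3),
    n2 = c(3, 3, 3, 3, 3, 3, 2, 3, 2, 3),
    stringsAsFactors = FALSE)
}

#' Simulation parameters
#'
#' Defines a synthetic multi-study collection with known truth. True per-gene
#' mean effects and all shifts are on the analysis (ln-ratio) scale; baseline
#' intensities and replicate noise are on the log2 expression scale.
#'
#' @param n_genes number of genes.
#' @param studies roster data.frame (`study_id`, `part`, `method`, `n1`,
#'   `n2`); defaults to [default_study_roster()].
#' @param pi0 fraction of null genes (mean effect and all shifts zero).
#' @param effect_sd sd of the true mean effect for non-null genes.
#' @param tau2 between-study variance of the true study-level effects.
#' @param part_effect_sd sd of the root-vs-shoot differential: a non-null
#'   gene draws one shift `delta` and receives `+delta` in root contrasts and
#'   `-delta` in shoot contrasts (opposing-response construction); 0
#'   disables part moderation.
#' @param method_effect_sd sd of independent per-method-level shifts for
#'   non-null genes; 0 disables method moderation.
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-gene
#'   control-arm log2 intensity.
#' @param noise_sd replicate-level log2 noise sd.
#' @param batch_sd sd of the per-study additive log2 shift applied to both
#'   arms (cancels in the expected effect size).
#' @param asym_batch_sd sd of an additional treated-arm-only batch shift
#'   (default 0; nonzero values stress-test robustness to arm-asymmetric
#'   batches).
#' @param seed integer seed.
#' @return Object of class `"sim_params"`.
#' @export
sim_params <- function(n_genes = 2000,
                       studies = default_study_roster(),
                       pi0 = 0.8,
                       effect_sd = 0.5,
                       tau2 = 0.05,
                       part_effect_sd = 0,
                       method_effect_sd = 0,
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 0.8,
                       noise_sd = 0.25,
                       batch_sd = 0.2,
                       asym_batch_sd = 0,
                       seed = 1L) {
  p <- list(n_genes = as.integer(n_genes), studies = studies, pi0 = pi0,
            effect_sd = effect_sd, tau2 = tau2,
            part_effect_sd = part_effect_sd,
            method_effect_sd = method_effect_sd,
            baseline_log2_mean = baseline_log2_mean,
            baseline_log2_sd = baseline_log2_sd,
            noise_sd = noise_sd, batch_sd = batch_sd,
            asym_batch_sd = asym_batch_sd, seed = as.integer(seed))
  class(p) <- "sim_params"
  stopifnot(p$n_genes >= 1,
            is.data.frame(p$studies),
            all(c("study_id", "part", "method", "n1", "n2") %in%
                  names(p$studies)),
            all(p$studies$n1 >= 2), all(p$studies$n2 >= 2),
            p$pi0 >= 0, p$pi0 <= 1,
            p$effect_sd >= 0, p$tau2 >= 0, p$part_effect_sd >= 0,
            p$method_effect_sd >= 0, p$baseline_log2_sd >= 0,
            p$noise_sd >= 0, p$batch_sd >= 0, p$asym_batch_sd >= 0)
  p
}

#' Simulate a multi-study expression collection with known truth
#'
#' For each gene: a null indicator (probability `pi0`), a true mean effect
#' `mu` (0 for nulls, otherwise Normal(0, effect_sd^2)), moderator shifts
#' (see [sim_params()]), and per-study true effects
#' `theta = mu + shift(level) + Normal(0, tau2)`. For each study, control
#' replicates are Normal around the gene baseline plus the study batch shift
#' on the log2 scale; treated replicates are Normal around
#' `(baseline + batch) * exp(theta)`, so the expected log expression ratio of
#' the arm means equals `theta` and batch shifts cancel. Genes whose implied
#' treated mean is nonpositive in any study are redrawn (count reported).
#' Deterministic given `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @return List with `study` (a pooled annotated [expression_study()]),
#'   `truth` (list: `genes` data.frame with `gene_id`, `is_null`, `mu_true`,
#'   `part_delta`, method shifts; `theta` and `theta_mean` G x contrasts
#'   matrices; `batch`; `params`) and `n_redrawn`.
#' @export
simulate_collection <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  st <- params$studies
  S <- nrow(st)
  G <- params$n_genes
  gene_ids <- sprintf("%d_at", 250000 + seq_len(G))
  contrast_ids <- paste(st$study_id, st$part, sep = ".")
  method_levels <- METHOD_LEVELS

  draw_genes <- function(n) {
    is_null <- stats::runif(n) < params$pi0
    mu <- ifelse(is_null, 0, stats::rnorm(n, 0, params$effect_sd))
    part_delta <- ifelse(is_null, 0,
                         stats::rnorm(n, 0, params$part_effect_sd))
    mshift <- matrix(stats::rnorm(n * length(method_levels), 0,
                                  params$method_effect_sd),
                     n, length(method_levels),
                     dimnames = list(NULL, method_levels))
    mshift[is_null, ] <- 0
    baseline <- stats::rnorm(n, params$baseline_log2_mean,
                             params$baseline_log2_sd)
    list(is_null = is_null, mu = mu, part_delta = part_delta,
         mshift = mshift, baseline = baseline)
  }
  part_sign <- ifelse(st$part == "root", 1, ifelse(st$part == "shoot", -1, 0))
  mean_theta <- function(gd) {
    outer(gd$mu, rep(1, S)) +
      outer(gd$part_delta, part_sign) +
      gd$mshift[, st$method, drop = FALSE]
  }

  batch <- stats::rnorm(S, 0, params$batch_sd)
  gd <- draw_genes(G)
  theta_mean <- mean_theta(gd)
  theta <- theta_mean + matrix(stats::rnorm(G * S, 0, sqrt(params$tau2)),
                               G, S)
  implied_ok <- function(gd, theta) {
    m2 <- outer(gd$baseline, batch, `+`)
    rowSums(m2 <= 0 | m2 * exp(theta) <= 0) == 0
  }
  n_redrawn <- 0L
  for (attempt in 1:100) {
    ok <- implied_ok(gd, theta)
    if (all(ok)) break
    idx <- which(!ok)
    n_redrawn <- n_redrawn + length(idx)
    rep_gd <- draw_genes(length(idx))
    for (f in c("is_null", "mu", "part_delta", "baseline")) {
      gd[[f]][idx] <- rep_gd[[f]]
    }
    gd$mshift[idx, ] <- rep_gd$mshift
    theta_mean[idx, ] <- mean_theta(rep_gd)
    theta[idx, ] <- theta_mean[idx, ] +
      matrix(stats::rnorm(length(idx) * S, 0, sqrt(params$tau2)),
             length(idx), S)
  }
  if (n_redrawn > 0) {
    message("[metaexpr] redrew ", n_redrawn,
            " gene draw(s) with nonpositive implied treated mean")
  }

  mats <- vector("list", S)
  sheets <- vector("list", S)
  for (s in seq_len(S)) {
    n1 <- st$n1[s]
    n2 <- st$n2[s]
    m2 <- gd$baseline + batch[s]
    m1 <- m2 * exp(theta[, s]) +
      if (params$asym_batch_sd > 0)
        stats::rnorm(1, 0, params$asym_batch_sd) else 0
    x1 <- matrix(stats::rnorm(G * n1, mean = m1, sd = params$noise_sd),
                 G, n1)
    x2 <- matrix(stats::rnorm(G * n2, mean = m2, sd = params$noise_sd),
                 G, n2)
    ids <- c(sprintf("%s_t%d", st$study_id[s], seq_len(n1)),
             sprintf("%s_c%d", st$study_id[s], seq_len(n2)))
    mat <- cbind(x1, x2)
    dimnames(mat) <- list(gene_ids, ids)
    mats[[s]] <- mat
    sheets[[s]] <- data.frame(
      sample_id = ids, study_id = st$study_id[s],
      arm = c(rep("treated", n1), rep("control", n2)),
      part = st$part[s], method = st$method[s],
      replicate_index = c(seq_len(n1), seq_len(n2)),
      stringsAsFactors = FALSE)
  }
  study <- expression_study(do.call(cbind, mats), do.call(rbind, sheets))
  dimnames(theta) <- dimnames(theta_mean) <- list(gene_ids, contrast_ids)
  genes <- data.frame(gene_id = gene_ids, is_null = gd$is_null,
                      mu_true = gd$mu, part_delta = gd$part_delta,
                      baseline_log2 = gd$baseline, row.names = NULL)
  genes <- cbind(genes, stats::setNames(as.data.frame(gd$mshift),
                                        paste0("shift_", method_levels)))
  pipeline_log("simulate_collection", genes = G, studies = S,
               samples = ncol(study$matrix), seed = params$seed,
               redrawn = n_redrawn)
  list(study = study,
       truth = list(genes = genes, theta = theta, theta_mean = theta_mean,
                    batch = stats::setNames(batch, st$study_id),
                    params = params),
       n_redrawn = n_redrawn)
}

#' Calibration summary against simulation truth
#'
#' Compares fitted per-gene meta-analysis (and optionally classification and
#' meta-regression) results with the generator's ground truth. The per-gene
#' estimand for the mean effect is the roster average of the deterministic
#' part of the study-level effects (equal to `mu_true` when moderator shifts
#' are disabled).
#'
#' @param truth the `truth` element of [simulate_collection()].
#' @param fits data.frame from [fit_random_effects()].
#' @param calls optional data.frame from [classify_genes()] (enables the
#'   realized false-discovery proportion).
#' @param metareg_fits optional per-gene `fits` from
#'   [fit_meta_regression()] (enables the moderator-test type-I rate among
#'   genes with no moderator shift).
#' @param alpha significance level for the FDP and type-I summaries.
#' @return List of calibration numbers: `bias_mu`, `rmse_mu`,
#'   `median_tau2`, `true_tau2`, `ci_coverage`, and where inputs allow,
#'   `fdp`, `n_discoveries`, `qm_type1_rate`.
#' @export
recovery_report <- function(truth, fits, calls = NULL, metareg_fits = NULL,
                            alpha = 0.05) {
  genes <- truth$genes
  idx <- match(fits$gene_id, genes$gene_id)
  if (anyNA(idx)) stop("gene ids in fits do not match simulation truth",
                       call. = FALSE)
  target <- rowMeans(truth$theta_mean)[idx]
  out <- list(
    bias_mu = mean(fits$mu_hat - target),
    rmse_mu = sqrt(mean((fits$mu_hat - target)^2)),
    median_tau2 = stats::median(fits$tau2),
    true_tau2 = truth$params$tau2,
    ci_coverage = mean(fits$ci_lo <= target & target <= fits$ci_hi,
                       na.rm = TRUE))
  if (!is.null(calls)) {
    ci <- match(calls$gene_id, genes$gene_id)
    if (anyNA(ci)) stop("gene ids in calls do not match simulation truth",
                        call. = FALSE)
    disc <- calls$call != "ns"
    out$n_discoveries <- sum(disc)
    out$fdp <- if (any(disc)) mean(genes$is_null[ci][disc]) else 0
  }
  if (!is.null(metareg_fits)) {
    mi <- match(metareg_fits$gene_id, genes$gene_id)
    if (anyNA(mi)) stop("gene ids in metareg fits do not match truth",
                        call. = FALSE)
    shift_cols <- c("part_delta", grep("^shift_", names(genes), value = TRUE))
    no_shift <- rowSums(abs(genes[shift_cols])) == 0
    sel <- no_shift[mi] & !is.na(metareg_fits$p_qm)
    out$qm_type1_rate <- mean(metareg_fits$p_qm[sel] < alpha)
  }
  out
}
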