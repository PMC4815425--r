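#' DerSimonian-Laird between-study variance
#'
#' Moment estimator of the between-study variance tau^2 from K effect sizes
#' and their sampling variances: with fixed-effect weights `w = 1/v`,
#' `Q = sum(w * (theta - theta_fe)^2)` and
#' `tau2 = max(0, (Q - (K - 1)) / (sum(w) - sum(w^2) / sum(w)))`.
#'
#' @param theta numeric vector of effect sizes for one gene (one per
#'   contrast).
#' @param v numeric vector of their sampling variances (positive).
#' @return Nonnegative scalar tau^2 estimate. For K < 2 the estimate is 0
#'   with a warning (a single contrast carries no heterogeneity information).
#' @examples
#' dl_tau2(c(0, 2), c(1, 1)) # Q = 2, c = 1 -> tau2 = 1
#' @export
dl_tau2 <- function(theta, v) {
  stopifnot(length(theta) == length(v), all(v > 0))
  k <- length(theta)
  if (k < 2) {
    warning("tau^2 set to 0 for a single-contrast gene", call. = FALSE)
    return(0)
  }
  w <- 1 / v
  mu_fe <- sum(w * theta) / sum(w)
  q <- sum(w * (theta - mu_fe)^2)
  c_dl <- sum(w) - sum(w^2) / sum(w)
  max(0, (q - (k - 1)) / c_dl)
}

#' REML between-study variance
#'
#' Restricted maximum-likelihood estimate of tau^2 for the intercept-only
#' random-effects model, by Fisher scoring with truncation at zero.
#' Convergence is declared when the step is below `tol` (default 1e-8);
#' if 100 iterations do not converge, the DerSimonian-Laird value is
#' returned with attribute `converged = FALSE` and a warning.
#'
#' @inheritParams dl_tau2
#' @param tol convergence tolerance on the change in tau^2.
#' @param max_iter iteration cap.
#' @return Nonnegative scalar tau^2; attribute `converged` reports whether
#'   Fisher scoring converged.
#' @export
reml_tau2 <- function(theta, v, tol = 1e-8, max_iter = 100) {
  stopifnot(length(theta) == length(v), all(v > 0))
  k <- length(theta)
  if (k < 2) {
    warning("tau^2 set to 0 for a single-contrast gene", call. = FALSE)
    return(structure(0, converged = TRUE))
  }
  res <- reml_tau2_matrix(matrix(theta, 1), matrix(v, 1),
                          tol = tol, max_iter = max_iter)
  structure(res$tau2[1], converged = res$converged[1])
}

# Vectorized DL over a G x K matrix pair with NA entries allowed
# (NA marks a gene absent from that contrast).
dl_tau2_matrix <- function(theta, v) {
  obs <- !is.na(theta)
  k <- rowSums(obs)
  w <- ifelse(obs, 1 / v, 0)
  th0 <- ifelse(obs, theta, 0)
  sw <- rowSums(w)
  mu_fe <- rowSums(w * th0) / sw
  q <- rowSums(w * (th0 - mu_fe)^2 * obs)
  c_dl <- sw - rowSums(w^2) / sw
  tau2 <- ifelse(k >= 2, pmax(0, (q - (k - 1)) / c_dl), 0)
  list(tau2 = tau2, q = q, k = k)
}

# Vectorized REML iteration across genes; starts from the DL value.
# Uses the observed-information (Newton) step where the curvature is
# negative -- quadratic convergence near the optimum -- and the expected-
# information (Fisher scoring) step otherwise. A gene converges when its
# step is < tol or it is pinned at the zero boundary with a nonpositive
# score.
reml_tau2_matrix <- function(theta, v, tol = 1e-8, max_iter = 100) {
  obs <- !is.na(theta)
  k <- rowSums(obs)
  dl <- dl_tau2_matrix(theta, v)
  tau2 <- dl$tau2
  th0 <- ifelse(obs, theta, 0)
  converged <- k < 2   # single-contrast genes stay at 0, nothing to iterate
  tau2[k < 2] <- 0
  active <- !converged
  iter <- 0
  while (any(active) && iter < max_iter) {
    iter <- iter + 1
    w <- ifelse(obs, 1 / (v + tau2), 0)
    sw <- rowSums(w)
    mu <- rowSums(w * th0) / sw
    r <- th0 - mu
    sw2 <- rowSums(w^2)
    sw3 <- rowSums(w^3)
    r2w2 <- rowSums(w^2 * r^2 * obs)
    r2w3 <- rowSums(w^3 * r^2 * obs)
    a <- rowSums(w^2 * r * obs)
    score <- 0.5 * (r2w2 - sw + sw2 / sw)
    info_exp <- 0.5 * (sw2 - 2 * sw3 / sw + (sw2 / sw)^2)
    # negated second derivative of the restricted log-likelihood
    info_obs <- -0.5 * (-2 * r2w3 + 2 * a^2 / sw + sw2 +
                          (-2 * sw3 * sw + sw2^2) / sw^2)
    info <- ifelse(info_obs > 0, info_obs, info_exp)
    step <- score / info
    newtau <- pmax(0, tau2 + step)
    done <- active & (abs(newtau - tau2) < tol |
                        (tau2 == 0 & newtau == 0))
    tau2[active] <- newtau[active]
    converged <- converged | done
    active <- !converged
  }
  if (any(active)) {
    warning(sum(active), " gene(s) did not converge in REML; ",
            "falling back to DerSimonian-Laird", call. = FALSE)
    tau2[active] <- dl$tau2[active]
  }
  list(tau2 = tau2, converged = converged | !active, fallback = active,
       k = k, q_fe = dl$q)
}

#' Per-gene random-effects meta-analysis
#'
#' Fits, for every gene, the inverse-variance weighted random-effects model:
#' weights `w_i = 1 / (v_i + tau^2)`, weighted mean effect
#' `mu_hat = sum(w * theta) / sum(w)`, variance `s2_mu = 1 / sum(w)`, a 95%
#' confidence interval using Student's t with K - 1 degrees of freedom
#' (default) or the normal multiplier, and a two-sided test of
#' `mu_hat / s_mu` against the reference named by `cfg$test_distribution`
#' (normal by default, as in the published method; Student t with K - 1 df is
#' the small-K calibrated alternative).
#'
#' @param effects effect-size data.frame (`gene_id`, `contrast_id`, `lnr`,
#'   `v`), or the list returned by [effect_sizes()].
#' @param cfg a [run_config()]; `tau2_method_meta` selects REML (default) or
#'   DL.
#' @param include_weights if `TRUE`, attach the normalized per-contrast
#'   weights as a list column `weights`.
#' @param tau2_fixed hold the between-study variance at this value instead
#'   of estimating it (`0` gives the classical fixed-effects inverse-variance
#'   fit); `NULL` (default) estimates per gene.
#' @return A data.frame with one row per gene: `gene_id`, `k`, `tau2`,
#'   `mu_hat`, `se_mu`, `ci_lo`, `ci_hi`, `z`, `p`, `q_cochran`,
#'   `single_contrast` flag and `reml_fallback` flag.
#' @examples
#' eff <- data.frame(gene_id = "g1", contrast_id = c("a", "b"),
#'                   lnr = c(1, 3), v = c(1, 1))
#' fit_random_effects(eff, run_config(tau2_method_meta = "dl"))
#' @export
fit_random_effects <- function(effects, cfg = run_config(),
                               include_weights = FALSE, tau2_fixed = NULL) {
  if (is.list(effects) && !is.data.frame(effects) &&
      !is.null(effects$effects)) {
    effects <- effects$effects
  }
  cfg <- validate_run_config(cfg)
  stopifnot(is.data.frame(effects),
            all(c("gene_id", "contrast_id", "lnr", "v") %in% names(effects)))
  if (nrow(effects) == 0) stop("no effect-size records", call. = FALSE)
  wide <- effects_to_matrices(effects)
  theta <- wide$theta
  v <- wide$v
  obs <- !is.na(theta)
  k <- rowSums(obs)

  if (!is.null(tau2_fixed)) {
    stopifnot(is.numeric(tau2_fixed), tau2_fixed >= 0)
    tau2 <- rep(tau2_fixed, nrow(theta))
    fallback <- rep(FALSE, nrow(theta))
  } else if (cfg$tau2_method_meta == "reml") {
    est <- reml_tau2_matrix(theta, v)
    tau2 <- est$tau2
    fallback <- est$fallback
  } else {
    est <- dl_tau2_matrix(theta, v)
    tau2 <- est$tau2
    fallback <- rep(FALSE, length(tau2))
  }

  th0 <- ifelse(obs, theta, 0)
  w <- ifelse(obs, 1 / (v + tau2), 0)
  sw <- rowSums(w)
  mu_hat <- rowSums(w * th0) / sw
  se_mu <- sqrt(1 / sw)

  # Cochran Q with fixed-effect weights (heterogeneity diagnostic)
  wfe <- ifelse(obs, 1 / v, 0)
  mu_fe <- rowSums(wfe * th0) / rowSums(wfe)
  q_cochran <- rowSums(wfe * (th0 - mu_fe)^2 * obs)

  mult <- switch(cfg$ci_distribution,
                 student_t = ifelse(k > 1, stats::qt(0.975, k - 1), NA_real_),
                 normal = stats::qnorm(0.975))
  stat <- mu_hat / se_mu
  p <- switch(cfg$test_distribution,
              normal = 2 * stats::pnorm(-abs(stat)),
              student_t = ifelse(k > 1, 2 * stats::pt(-abs(stat), k - 1),
                                 2 * stats::pnorm(-abs(stat))))
  p <- pmax(p, .Machine$double.xmin)   # guard underflow for the BH step

  fit <- data.frame(
    gene_id = rownames(theta), k = k, tau2 = tau2,
    mu_hat = mu_hat, se_mu = se_mu,
    ci_lo = mu_hat - mult * se_mu, ci_hi = mu_hat + mult * se_mu,
    z = stat, p = p, q_cochran = q_cochran,
    single_contrast = k == 1, reml_fallback = fallback,
    row.names = NULL)
  if (include_weights) {
    fit$weights <- lapply(seq_len(nrow(theta)), function(i) {
      wi <- w[i, obs[i, ]]
      stats::setNames(wi / sum(wi), colnames(theta)[obs[i, ]])
    })
  }
  pipeline_log("fit_random_effects", genes = nrow(fit),
               tau2_method = cfg$tau2_method_meta,
               ci = cfg$ci_distribution, test = cfg$test_distribution)
  fit
}

# Long effect-size records -> G x K matrices (NA where a gene is absent
# from a contrast), preserving first-appearance order of genes/contrasts.
effects_to_matrices <- function(effects) {
  genes <- unique(effects$gene_id)
  contrasts <- unique(effects$contrast_id)
  gi <- match(effects$gene_id, genes)
  ci <- match(effects$contrast_id, contrasts)
  if (anyDuplicated(cbind(gi, ci))) {
    stop("duplicate gene x contrast effect-size records", call. = FALSE)
  }
  theta <- matrix(NA_real_, length(genes), length(contrasts),
                  dimnames = list(genes, contrasts))
  v <- theta
  theta[cbind(gi, ci)] <- effects$lnr
  v[cbind(gi, ci)] <- effects$v
  list(theta = theta, v = v)
}
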