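#' Build the moderator design for meta-regression
#'
#' Cell-means (no-intercept) coding with one indicator column per moderator
#' level, so each coefficient is directly the mean true effect for its level.
#' For the plant-part moderator the levels are root and shoot, and seedling
#' contrasts are excluded; for the stress-method moderator the levels are
#' water withholding, mannitol and deracination, and PEG contrasts are
#' excluded. Levels left with no contrast are dropped with a warning; fewer
#' than two remaining levels is fatal (the moderator is inestimable).
#'
#' @param effects effect-size data.frame (see [effect_sizes()]) carrying
#'   `part` and `method` columns.
#' @param moderator `"part"` or `"method"`.
#' @param cfg a [run_config()].
#' @return A `metareg_design`: list with `moderator`, `levels`, `contrasts`
#'   (data.frame contrast_id/level), `X` (contrasts x levels one-hot matrix)
#'   and `exclusions` (data.frame contrast_id/reason).
#' @export
build_design <- function(effects, moderator = c("part", "method"),
                         cfg = run_config()) {
  if (is.list(effects) && !is.data.frame(effects) &&
      !is.null(effects$effects)) {
    effects <- effects$effects
  }
  moderator <- match.arg(moderator)
  if (!moderator %in% names(effects)) {
    stop("effects carry no '", moderator, "' column", call. = FALSE)
  }
  contr <- unique(effects[c("contrast_id", moderator)])
  names(contr)[2] <- "level"
  if (anyDuplicated(contr$contrast_id)) {
    stop("moderator value is not constant within contrast(s): ",
         paste(unique(contr$contrast_id[duplicated(contr$contrast_id)]),
               collapse = ", "), call. = FALSE)
  }
  spec <- switch(moderator,
                 part = list(levels = c("root", "shoot"),
                             drop = "seedling"),
                 method = list(levels = c("water_withholding", "mannitol",
                                          "deracination"),
                               drop = "peg"))
  out <- contr$level %in% spec$drop
  exclusions <- data.frame(
    contrast_id = contr$contrast_id[out],
    reason = sprintf("level '%s' excluded from the %s model",
                     contr$level[out], moderator))
  contr <- contr[!out, , drop = FALSE]
  levels <- spec$levels[spec$levels %in% contr$level]
  empty <- setdiff(spec$levels, levels)
  if (length(empty) > 0) {
    warning("moderator level(s) with no contrast dropped: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  if (length(levels) < 2) {
    stop("fewer than 2 moderator levels with contrasts; the '", moderator,
         "' meta-regression is inestimable", call. = FALSE)
  }
  X <- sapply(levels, function(l) as.numeric(contr$level == l))
  X <- matrix(X, nrow = nrow(contr),
              dimnames = list(contr$contrast_id, levels))
  rownames(contr) <- NULL
  structure(list(moderator = moderator, levels = levels, contrasts = contr,
                 X = X, exclusions = exclusions),
            class = "metareg_design")
}

#' @export
print.metareg_design <- function(x, ...) {
  cat(sprintf("<metareg_design> moderator=%s, %d contrasts, levels: %s\n",
              x$moderator, nrow(x$X), paste(x$levels, collapse = ", ")))
  if (nrow(x$exclusions)) {
    cat("  excluded:", paste(x$exclusions$contrast_id, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-gene mixed-effects meta-regression
#'
#' For every gene, fits the weighted least-squares regression of effect sizes
#' on the no-intercept moderator design. Residual heterogeneity tau^2 is
#' estimated by the moderator-adjusted (generalized) DerSimonian-Laird
#' estimator: with fixed-effect weights `W = diag(1/v)` and hat-complement
#' `P = W - W X (X'WX)^-1 X'W`, `tau2 = max(0, (Q_E - (K - m)) / tr(P))`
#' where `Q_E` is the weighted residual sum of squares. Final coefficients
#' are the WLS solution with weights `1 / (v + tau2)`; because the coding is
#' cell-means, each coefficient is its level's mean effect. Per-coefficient
#' tests and 95% CIs use the normal reference. The moderator test `Q_M` is a
#' Wald chi-square: by default (`qm_df_convention = "m_minus_1"`) it tests
#' equality of the m level means on m - 1 degrees of freedom; the `"m"`
#' convention tests that all m coefficients are zero.
#'
#' @param effects effect-size data.frame or [effect_sizes()] result.
#' @param design a [build_design()] object.
#' @param cfg a [run_config()]; `tau2_method_metareg` selects DL (default)
#'   or REML (Fisher scoring on the restricted likelihood of the regression
#'   model).
#' @return A list with `fits` (per gene: `gene_id`, `k`, `tau2_resid`, `qm`,
#'   `qm_df`, `p_qm`) and `coefficients` (long data.frame per gene x level:
#'   `beta`, `se`, `z`, `p`, `ci_lo`, `ci_hi`).
#' @export
fit_meta_regression <- function(effects, design, cfg = run_config()) {
  if (is.list(effects) && !is.data.frame(effects) &&
      !is.null(effects$effects)) {
    effects <- effects$effects
  }
  stopifnot(inherits(design, "metareg_design"))
  cfg <- validate_run_config(cfg)
  eff <- effects[effects$contrast_id %in% rownames(design$X), , drop = FALSE]
  if (nrow(eff) == 0) stop("no effect-size records match the design",
                           call. = FALSE)
  wide <- effects_to_matrices(eff)
  cid <- intersect(rownames(design$X), colnames(wide$theta))
  theta <- wide$theta[, cid, drop = FALSE]
  v <- wide$v[, cid, drop = FALSE]
  Xfull <- design$X[cid, , drop = FALSE]
  m <- ncol(Xfull)
  genes <- rownames(theta)
  G <- length(genes)
  zq <- stats::qnorm(0.975)

  fits <- data.frame(gene_id = genes, k = NA_integer_,
                     tau2_resid = NA_real_, qm = NA_real_,
                     qm_df = NA_integer_, p_qm = NA_real_)
  coef_list <- vector("list", G)
  for (g in seq_len(G)) {
    o <- !is.na(theta[g, ])
    y <- theta[g, o]
    vi <- v[g, o]
    X <- Xfull[o, , drop = FALSE]
    used <- colSums(X) > 0
    X <- X[, used, drop = FALSE]
    k <- length(y)
    if (k < sum(used)) next  # inestimable for this gene; left NA
    qrX <- qr(sqrt(1 / vi) * X)
    if (qrX$rank < ncol(X)) {
      stop("singular design for gene ", genes[g], "; collinear level(s): ",
           paste(colnames(X), collapse = ", "), call. = FALSE)
    }
    tau2 <- switch(cfg$tau2_method_metareg,
                   dl = gendl_tau2(y, vi, X),
                   reml = metareg_reml_tau2(y, vi, X))
    w <- 1 / (vi + tau2)
    XtWX <- crossprod(X, w * X)
    Vb <- solve(XtWX)
    b <- drop(Vb %*% crossprod(X, w * y))
    se <- sqrt(diag(Vb))
    qm <- qm_stat(b, Vb, cfg$qm_df_convention)
    fits$k[g] <- k
    fits$tau2_resid[g] <- tau2
    fits$qm[g] <- qm$qm
    fits$qm_df[g] <- qm$df
    fits$p_qm[g] <- qm$p
    coef_list[[g]] <- data.frame(
      gene_id = genes[g], level = colnames(X), beta = b, se = se,
      z = b / se,
      p = pmax(2 * stats::pnorm(-abs(b / se)), .Machine$double.xmin),
      ci_lo = b - zq * se, ci_hi = b + zq * se, row.names = NULL)
  }
  coefs <- do.call(rbind, coef_list[!vapply(coef_list, is.null, logical(1))])
  pipeline_log("fit_meta_regression", moderator = design$moderator,
               genes = G, levels = m, tau2_method = cfg$tau2_method_metareg,
               qm_df = cfg$qm_df_convention)
  list(fits = fits, coefficients = coefs, design = design)
}

# Generalized (moderator-adjusted) DerSimonian-Laird residual tau^2.
gendl_tau2 <- function(y, v, X) {
  k <- length(y)
  m <- ncol(X)
  if (k <= m) return(0)  # saturated: no residual degrees of freedom
  W <- 1 / v
  XtWX <- crossprod(X, W * X)
  b_fe <- solve(XtWX, crossprod(X, W * y))
  r <- y - drop(X %*% b_fe)
  q_e <- sum(W * r^2)
  # tr(P) with P = W - W X (X'WX)^-1 X'W
  tr_p <- sum(W) - sum(diag(solve(XtWX, crossprod(X, W^2 * X))))
  max(0, (q_e - (k - m)) / tr_p)
}

# REML for the regression model: Fisher scoring (generalized DL start),
# with a direct likelihood maximization as the slow-convergence polish.
metareg_reml_tau2 <- function(y, v, X, tol = 1e-8, max_iter = 100) {
  k <- length(y)
  m <- ncol(X)
  if (k <= m) return(0)
  tau2 <- gendl_tau2(y, v, X)
  for (i in seq_len(max_iter)) {
    w <- 1 / (v + tau2)
    XtWX <- crossprod(X, w * X)
    H <- (w * X) %*% solve(XtWX, t(w * X))   # W X (X'WX)^-1 X' W
    P <- diag(w) - H
    r <- drop(P %*% y)
    score <- 0.5 * (sum(r^2) - sum(diag(P)))
    info <- 0.5 * sum(P * P)
    newtau <- max(0, tau2 + score / info)
    if (abs(newtau - tau2) < tol || (tau2 == 0 && newtau == 0)) {
      return(newtau)
    }
    tau2 <- newtau
  }
  rll <- function(t2) {
    w <- 1 / (v + t2)
    XtWX <- crossprod(X, w * X)
    b <- solve(XtWX, crossprod(X, w * y))
    r <- y - drop(X %*% b)
    -0.5 * (sum(log(v + t2)) + determinant(XtWX)$modulus + sum(w * r^2))
  }
  opt <- stats::optimize(rll, c(0, max(10, 4 * tau2 + 1)), maximum = TRUE,
                         tol = 1e-10)
  if (rll(0) >= opt$objective) 0 else opt$maximum
}

#' Moderator Wald test
#'
#' Computes the Q_M chi-square statistic from a coefficient vector and its
#' covariance. Under the default `"m_minus_1"` convention the statistic
#' tests equality of all level means (contrasts `beta_j - beta_1`) on m - 1
#' degrees of freedom, matching the chi-square reference with one fewer
#' degree than the number of coefficients; the `"m"` convention is the
#' omnibus test that every coefficient is zero, on m degrees of freedom.
#'
#' @param beta coefficient vector (length m >= 2).
#' @param vcov m x m covariance matrix of `beta`.
#' @param convention `"m_minus_1"` (default) or `"m"`.
#' @return List with `qm`, `df`, `p`.
#' @export
qm_stat <- function(beta, vcov, convention = c("m_minus_1", "m")) {
  convention <- match.arg(convention)
  m <- length(beta)
  if (m < 2) {
    return(list(qm = NA_real_, df = NA_integer_, p = NA_real_))
  }
  if (convention == "m_minus_1") {
    L <- cbind(-1, diag(m - 1))          # beta_j - beta_1, j = 2..m
    d <- drop(L %*% beta)
    qm <- drop(crossprod(d, solve(L %*% vcov %*% t(L), d)))
    df <- m - 1L
  } else {
    qm <- drop(crossprod(beta, solve(vcov, beta)))
    df <- m
  }
  list(qm = qm, df = df,
       p = max(stats::pchisq(qm, df, lower.tail = FALSE),
               .Machine$double.xmin))
}

#' Post-hoc moderation labels
#'
#' Labels genes whose moderator test survives FDR adjustment, using
#' coefficient signs and per-coefficient significance (each FDR-adjusted
#' across genes within its level): `"sign_reversal"` when two significant
#' level means have opposite signs (up-regulated in one level, down in
#' another), `"level_specific"` when exactly one level mean is significant,
#' `"magnitude_difference"` otherwise. Genes whose Q_M does not survive FDR
#' are labeled `"ns"`.
#'
#' @param fit result of [fit_meta_regression()].
#' @param alpha FDR level.
#' @return The per-gene `fits` data.frame with added `q_qm` and
#'   `moderation` columns, plus per-coefficient `q` in `coefficients`.
#' @export
classify_moderation <- function(fit, alpha = 0.05) {
  fits <- fit$fits
  coefs <- fit$coefficients
  ok <- !is.na(fits$p_qm)
  fits$q_qm <- NA_real_
  fits$q_qm[ok] <- bh_adjust(fits$p_qm[ok])
  coefs$q <- NA_real_
  for (lev in unique(coefs$level)) {
    sel <- coefs$level == lev & !is.na(coefs$p)
    coefs$q[sel] <- bh_adjust(coefs$p[sel])
  }
  sig <- !is.na(coefs$q) & coefs$q < alpha
  f <- factor(coefs$gene_id, levels = fits$gene_id)
  n_sig <- tapply(sig, f, sum, default = 0L)
  any_up <- tapply(sig & coefs$beta > 0, f, any, default = FALSE)
  any_dn <- tapply(sig & coefs$beta < 0, f, any, default = FALSE)
  lab <- rep("ns", nrow(fits))
  qm_sig <- !is.na(fits$q_qm) & fits$q_qm < alpha
  lab[qm_sig] <- "magnitude_difference"
  lab[qm_sig & n_sig == 1] <- "level_specific"
  lab[qm_sig & n_sig >= 2 & any_up & any_dn] <- "sign_reversal"
  fits$moderation <- lab
  list(fits = fits, coefficients = coefs)
}
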