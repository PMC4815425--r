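roster_effects <- function(theta_by_contrast, v = 0.02) {
  # one gene spread over the default roster's contrasts
  st <- default_study_roster()
  cid <- paste(st$study_id, st$part, sep = ".")
  data.frame(gene_id = "g1", contrast_id = cid,
             lnr = theta_by_contrast, v = v,
             part = st$part, method = st$method)
}

test_that("moderator designs encode the exclusion rules as one-hot rows", {
  eff <- roster_effects(rnorm(10))
  dp <- build_design(eff, "part")
  expect_identical(dim(dp$X), c(9L, 2L))
  expect_identical(colnames(dp$X), c("root", "shoot"))
  expect_true(all(rowSums(dp$X) == 1))
  expect_identical(dp$exclusions$contrast_id, "S05.seedling")

  dm <- build_design(eff, "method")
  expect_identical(dim(dm$X), c(9L, 3L))
  expect_identical(colnames(dm$X),
                   c("water_withholding", "mannitol", "deracination"))
  expect_identical(dm$exclusions$contrast_id, "S05.seedling")  # the PEG study

  # all contrasts on one level -> inestimable
  eff1 <- eff
  eff1$part <- "root"
  expect_error(suppressWarnings(build_design(eff1, "part")), "fewer than 2")

  # permuting contrast order permutes rows, nothing else
  effp <- eff[sample(nrow(eff)), ]
  dpp <- build_design(effp, "part")
  expect_identical(dp$X[rownames(dpp$X), ], dpp$X)
})

test_that("saturated and one-per-level designs reduce to level means", {
  st <- default_study_roster()[1:4, ]   # root, shoot, root, shoot
  cid <- paste(st$study_id, st$part, sep = ".")
  eff <- data.frame(gene_id = "g1", contrast_id = cid,
                    lnr = c(0.6, -0.2, 0.6, -0.2), v = 0.05,
                    part = st$part, method = st$method)
  d <- build_design(eff, "part")
  fit <- suppressMessages(fit_meta_regression(eff, d))
  b <- fit$coefficients
  expect_equal(b$beta[b$level == "root"], 0.6)
  expect_equal(b$beta[b$level == "shoot"], -0.2)
  expect_equal(fit$fits$tau2_resid, 0)

  # one contrast per level: coefficients equal the single effects, tau2 = 0
  eff2 <- eff[1:2, ]
  d2 <- build_design(eff2, "part")
  fit2 <- suppressMessages(fit_meta_regression(eff2, d2))
  expect_equal(fit2$fits$tau2_resid, 0)
  expect_equal(fit2$coefficients$beta, c(0.6, -0.2))
})

test_that("coefficients match a generalized-least-squares oracle exactly", {
  set.seed(17)
  for (i in 1:10) {
    eff <- roster_effects(rnorm(10, 0, 0.5), v = runif(10, 0.01, 0.2))
    d <- build_design(eff, "part")
    fit <- suppressMessages(fit_meta_regression(eff, d))
    keep <- eff$contrast_id %in% rownames(d$X)
    y <- eff$lnr[keep]; v <- eff$v[keep]
    X <- d$X[eff$contrast_id[keep], , drop = FALSE]
    orc <- gls_oracle(y, v, X, fit$fits$tau2_resid)
    expect_equal(fit$coefficients$beta, unname(orc$beta), tolerance = 1e-10)
    expect_equal(fit$coefficients$se, unname(sqrt(diag(orc$vcov))),
                 tolerance = 1e-10)
  }
})

test_that("the fit agrees with an independent mixed-effects reference", {
  skip_if_not_installed("metafor")
  set.seed(18)
  for (i in 1:5) {
    eff <- roster_effects(rnorm(10, 0, 0.5), v = runif(10, 0.01, 0.2))
    d <- build_design(eff, "part")
    fit <- suppressMessages(fit_meta_regression(eff, d))
    keep <- eff$contrast_id %in% rownames(d$X)
    part <- factor(eff$part[keep], levels = c("root", "shoot"))
    ref <- metafor::rma(yi = eff$lnr[keep], vi = eff$v[keep],
                        mods = ~ part - 1, method = "DL")
    expect_equal(fit$fits$tau2_resid, ref$tau2, tolerance = 1e-8)
    expect_equal(fit$coefficients$beta, as.numeric(ref$beta),
                 tolerance = 1e-8)
    # equality-of-level-means Wald test vs metafor's linear-combination test
    equal_test <- anova(ref, X = c(1, -1))
    expect_equal(fit$fits$qm, as.numeric(equal_test$QM), tolerance = 1e-8)
    expect_identical(fit$fits$qm_df, 1L)
    # the omnibus convention reproduces metafor's default QM (all betas = 0)
    fit_m <- suppressMessages(fit_meta_regression(
      eff, d, run_config(qm_df_convention = "m")))
    expect_equal(fit_m$fits$qm, as.numeric(ref$QM), tolerance = 1e-8)
    expect_identical(fit_m$fits$qm_df, 2L)
  }
})

test_that("Q_M follows the chosen degrees-of-freedom convention", {
  # equal coefficients -> equality test is exactly null
  q0 <- qm_stat(c(0.4, 0.4), diag(c(0.01, 0.02)))
  expect_equal(q0$qm, 0)
  expect_equal(q0$p, 1)
  # independent coefficients (0, x), equal SEs -> Q_M = x^2 / (2 s^2)
  x <- 0.9; s <- 0.2
  q1 <- qm_stat(c(0, x), diag(c(s^2, s^2)))
  expect_equal(q1$qm, x^2 / (2 * s^2))
  expect_identical(q1$df, 1L)
  # the omnibus convention tests all coefficients against zero on m df
  q2 <- qm_stat(c(0.5, 0.5), diag(c(0.01, 0.01)), convention = "m")
  expect_equal(q2$qm, 2 * 0.5^2 / 0.01)
  expect_identical(q2$df, 2L)
  # single coefficient: undefined, reported as missing
  expect_true(is.na(qm_stat(0.3, matrix(0.01))$qm))
})

test_that("coefficients are invariant to contrast relabeling and level order", {
  eff <- roster_effects(rnorm(10, 0, 0.4), v = runif(10, 0.02, 0.1))
  d <- build_design(eff, "part")
  fit <- suppressMessages(fit_meta_regression(eff, d))
  effp <- eff[sample(nrow(eff)), ]
  fitp <- suppressMessages(fit_meta_regression(effp, build_design(effp,
                                                                  "part")))
  expect_equal(fitp$coefficients$beta, fit$coefficients$beta)
  expect_equal(fitp$fits$qm, fit$fits$qm)
})

test_that("a single-level design degenerates to the random-effects mean", {
  # with every contrast on one level, the cell-means fit must equal the
  # intercept-only random-effects fit at the same tau^2 estimator (DL)
  fx <- random_effects_fixture(6, seed = 9)
  eff <- data.frame(gene_id = "g1", contrast_id = sprintf("c%d", 1:6),
                    lnr = fx$theta, v = fx$v,
                    part = "root", method = "mannitol")
  design <- structure(list(
    moderator = "part", levels = "root",
    contrasts = data.frame(contrast_id = eff$contrast_id, level = "root"),
    X = matrix(1, 6, 1, dimnames = list(eff$contrast_id, "root")),
    exclusions = data.frame(contrast_id = character(),
                            reason = character())), class = "metareg_design")
  fit <- suppressMessages(fit_meta_regression(eff, design))
  meta <- suppressMessages(
    fit_random_effects(eff, run_config(tau2_method_meta = "dl")))
  expect_equal(fit$coefficients$beta, meta$mu_hat, tolerance = 1e-10)
  expect_equal(fit$fits$tau2_resid, meta$tau2, tolerance = 1e-10)
})

test_that("moderation labels reflect coefficient signs and significance", {
  set.seed(31)
  st <- default_study_roster()
  cid <- paste(st$study_id, st$part, sep = ".")
  mk_gene <- function(g, root_mu, shoot_mu, noise = 0.02) {
    mu <- ifelse(st$part == "root", root_mu,
                 ifelse(st$part == "shoot", shoot_mu, 0))
    data.frame(gene_id = g, contrast_id = cid,
               lnr = mu + rnorm(10, 0, noise), v = 0.001,
               part = st$part, method = st$method)
  }
  eff <- rbind(mk_gene("rev", 1, -1), mk_gene("spec", 1.5, 0),
               mk_gene("null", 0, 0))
  d <- build_design(eff, "part")
  fit <- suppressMessages(fit_meta_regression(eff, d))
  cl <- classify_moderation(fit, alpha = 0.05)
  lab <- setNames(cl$fits$moderation, cl$fits$gene_id)
  expect_identical(unname(lab["rev"]), "sign_reversal")
  expect_identical(unname(lab["spec"]), "level_specific")
  expect_identical(unname(lab["null"]), "ns")
})
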