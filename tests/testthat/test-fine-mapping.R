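test_that("correlation pruning keeps the more frequent of each correlated pair", {
  set.seed(3)
  n <- 400
  base <- rbinom(n, 2, 0.3)
  D <- cbind(v1 = base, v2 = base,                       # duplicated column
             v3 = rbinom(n, 2, 0.25), v4 = rbinom(n, 2, 0.4))
  dm <- dosage_matrix(D)
  pruned <- prune_correlated(dm, 0.97)
  expect_equal(sum(variant_info(pruned)$id %in% c("v1", "v2")), 1L)
  expect_true(all(c("v3", "v4") %in% variant_info(pruned)$id))
  # 10-column toy versus an independent exhaustive-check oracle
  D10 <- sapply(1:10, function(j) rbinom(n, 2, runif(1, 0.1, 0.5)))
  D10[, 4] <- D10[, 2] + rbinom(n, 1, 0.01)            # near-duplicate pair
  D10[, 9] <- pmin(2, D10[, 7])
  colnames(D10) <- paste0("m", 1:10)
  dm10 <- dosage_matrix(pmin(D10, 2))
  got <- variant_info(prune_correlated(dm10, 0.97))$id
  # oracle: explicit greedy pass over the correlation matrix
  f <- colSums(dm10$dosages) / (2 * n)
  ord <- order(-f, colnames(dm10$dosages))
  keep <- integer()
  for (j in ord) {
    ok <- TRUE
    for (k in keep) if (cor(dm10$dosages[, j], dm10$dosages[, k])^2 > 0.97) ok <- FALSE
    if (ok) keep <- c(keep, j)
  }
  expect_setequal(got, colnames(dm10$dosages)[keep])
})

test_that("conditioning covariates follow the m-1 / reference / pruning rules", {
  cfg <- psv_sim_config(n_case = 500, n_control = 700)
  sim <- simulate_cohort(cfg, seed = 14)
  cls <- sim$classical
  resid <- expand_to_residue_dosages(
    cls[, which(variant_info(cls)$gene %in% unique(cfg$dictionary$gene))],
    cfg$dictionary)
  # HLA-B position 45 has residues E, T, K, M: 3 non-reference columns
  cc <- build_conditioning_covariates(conditioning_spec("aa:HLA-B:45"),
                                      cls, resid)
  expect_equal(ncol(cc$dosages), 3L)
  f45 <- allele_frequencies(resid[, grep("AA_B_45", variant_info(resid)$id)])
  ref <- names(which.max(f45))
  expect_false(ref %in% variant_info(cc)$id)
  # empty spec gives an empty matrix
  empty <- build_conditioning_covariates(conditioning_spec(), cls, resid)
  expect_equal(ncol(empty$dosages), 0L)
  # two alleles in perfect LD: one column retained after pruning
  dup <- classical_dm(cbind("Z*01:01" = rbinom(50, 2, 0.3)))
  dup2 <- dosage_matrix(cbind(dup$dosages, dup$dosages[, 1]),
                        rbind(variant_info(dup),
                              data.frame(id = "HLA_Z_0202", gene = "HLA-Z",
                                         kind = "classical_allele_4digit",
                                         position = NA, label = "Z*02:02")))
  pr <- prune_correlated(dup2, 0.97)
  expect_equal(ncol(pr$dosages), 1L)
  # unresolvable items are reported by name
  expect_error(build_conditioning_covariates(conditioning_spec("marker:X*99:99"),
                                             cls, resid),
               "X\\*99:99", class = "hlafinemap_lookup_error")
  expect_error(conditioning_spec(c("aa:HLA-B:45", "aa:HLA-B:45")),
               class = "hlafinemap_validation_error")
})

test_that("stepwise returns an empty trace under the null and is idempotent", {
  cfg <- null_config(800, 800)
  sim <- simulate_cohort(cfg, seed = 33)
  panel <- full_panel(sim, cfg$dictionary)
  sw <- stepwise_forward(panel, sim$cohort)
  expect_equal(nrow(sw$trace), 0L)
  expect_equal(sw$reason, "no_variant_below_threshold")
  # planted-signal cohort: rerunning with the final conditioning yields nothing
  cfg2 <- psv_sim_config(n_case = 1500, n_control = 2200)
  sim2 <- simulate_cohort(cfg2, seed = 34)
  panel2 <- full_panel(sim2, cfg2$dictionary)
  sw2 <- stepwise_forward(panel2, sim2$cohort, scope = "HLA-C")
  expect_gt(nrow(sw2$trace), 0L)
  cls2 <- sim2$classical
  resid2 <- expand_to_residue_dosages(
    cls2[, which(variant_info(cls2)$gene %in% unique(cfg2$dictionary$gene))],
    cfg2$dictionary)
  again <- stepwise_forward(panel2, sim2$cohort,
                            initial = conditioning_spec(sw2$selected),
                            scope = "HLA-C", classical = cls2,
                            residues = resid2)
  expect_equal(nrow(again$trace), 0L)
})

test_that("a single-variant multivariate model equals the plain logistic fit", {
  cfg <- null_config(500, 500, collections = 2)
  sim <- simulate_cohort(cfg, seed = 41)
  mv <- fit_full_multivariate("marker:G1*02:01", sim$classical, NULL, sim$cohort)
  y <- contrast_phenotype(sim$cohort)
  X0 <- build_design(sim$cohort)
  direct <- fit_logistic(y, cbind(X0, v = sim$classical$dosages[, "HLA_G1_0201"]))
  row <- mv$table[!mv$table$reference, ]
  expect_equal(row$beta, unname(coef(direct)["v"]), tolerance = 1e-10)
  expect_equal(row$se, unname(sqrt(diag(vcov(direct))["v"])), tolerance = 1e-10)
  expect_true(any(mv$table$reference))
  # CI contains the point estimate
  expect_true(row$or_lo < row$or & row$or < row$or_hi)
})

test_that("liability-threshold variance explained behaves like the theory", {
  expect_equal(variance_explained_liability(0.2, 1, 0.02), 0)
  # monotone in |log OR| and symmetric-ish around OR = 1
  ors <- c(1.1, 1.3, 1.8, 2.5, 4)
  v <- sapply(ors, function(o) variance_explained_liability(0.2, o, 0.02))
  expect_true(all(diff(v) > 0))
  expect_gt(variance_explained_liability(0.2, 1 / 1.5, 0.02), 0)
  expect_error(variance_explained_liability(0, 2, 0.02),
               class = "hlafinemap_validation_error")
  expect_error(variance_explained_liability(0.2, -1, 0.02),
               class = "hlafinemap_validation_error")
  expect_error(variance_explained_liability(0.2, 2, 1.5),
               class = "hlafinemap_validation_error")
})

test_that("liability variance matches a Monte-Carlo threshold-model oracle", {
  p <- 0.2; or <- 1.5; K <- 0.02
  got <- variance_explained_liability(p, or, K, scale = "proportion")
  # oracle: simulate individuals under the threshold model and measure the
  # share of liability variance carried by the genotype means
  set.seed(99)
  n <- 2e6
  g <- rbinom(n, 2, p)
  f <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  pen <- K * or^(0:2) / sum(f * or^(0:2))
  mu <- qnorm(1 - K) - qnorm(1 - pen)
  liab <- mu[g + 1] + rnorm(n)
  oracle <- var(mu[g + 1]) / var(liab)
  expect_equal(got, oracle, tolerance = 0.02)
  # regression of liability on dosage gives the same variance share here
  # (genotype means are nearly linear in dosage at this effect size)
  r2 <- summary(lm(liab ~ g))$r.squared
  expect_equal(got, r2, tolerance = 0.02)
})

test_that("joint variance explained is additive and consistent across methods", {
  tab <- data.frame(freq = c(0.2, 0.2), or = c(1.5, 1.5))
  single <- variance_explained_liability(0.2, 1.5, 0.02)
  expect_equal(variance_explained_joint(tab, 0.02), 2 * single)
  none <- data.frame(freq = c(0.1, 0.3), or = c(1, 1))
  expect_equal(variance_explained_joint(none, 0.02), 0)
  sim_est <- variance_explained_joint(tab, 0.02, method = "simulation",
                                      n_sim = 5e5, seed = 4)
  expect_equal(sim_est, 2 * single, tolerance = 0.02)
})
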