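test_that("MAF filter keeps strictly-above-threshold markers and matches a scan", {
  set.seed(11)
  n <- 1000
  D <- sapply(1:100, function(j) rbinom(n, 2, runif(1, 0.0002, 0.6)))
  colnames(D) <- paste0("rs", 1:100)
  dm <- dosage_matrix(D)
  kept <- filter_by_maf(dm, 0.001)
  # brute-force frequency scan oracle
  f <- colSums(D) / (2 * n)
  expect_equal(variant_info(kept)$id, colnames(D)[pmin(f, 1 - f) > 0.001])
  # boundary cases: 0.0005 removed at 0.001; 0.5 retained
  edge <- dosage_matrix(cbind(rare = c(rep(1, 1), rep(0, 999)),
                              common = rep(0:1, 500)))
  kept2 <- filter_by_maf(edge, 0.001)
  expect_equal(variant_info(kept2)$id, "common")
  expect_error(filter_by_maf(dm, 0.7), class = "hlafinemap_validation_error")
})

test_that("design matrix has intercept, K-1 indicators and K x L PC columns", {
  mk <- function(K, L, n = 60) {
    cohort_table(paste0("S", 1:n), rep(c("case", "control"), n / 2),
                 collection = rep(paste0("C", 1:K), length.out = n),
                 pcs = if (L > 0) matrix(rnorm(n * L), n) else NULL)
  }
  set.seed(2)
  expect_equal(ncol(build_design(mk(1, 0))), 1L)             # intercept only
  expect_equal(ncol(build_design(mk(2, 2))), 1L + 1L + 4L)
  expect_equal(ncol(build_design(mk(3, 10))), 1L + 2L + 30L)
  cond <- matrix(rnorm(60 * 3), 60, dimnames = list(paste0("S", 1:60),
                                                    paste0("v", 1:3)))
  expect_equal(ncol(build_design(mk(3, 10), cond)), 33L + 3L)
  # pooled-PC mode collapses the interaction block
  expect_equal(ncol(build_design(mk(3, 10), pcs = "pooled")), 1L + 2L + 10L)
})

test_that("logistic fit reproduces the closed-form 2x2 log odds", {
  # controls split 50/50 over x = 0/1; cases split 25/75
  x <- c(rep(0:1, c(50, 50)), rep(0:1, c(25, 75)))
  y <- rep(0:1, each = 100)
  f <- fit_logistic(y, cbind("(Intercept)" = 1, dosage = x))
  expect_equal(unname(coef(f)["dosage"]), log(3), tolerance = 1e-7)
  expect_equal(unname(coef(f)["(Intercept)"]), log(0.5), tolerance = 1e-7)
  expect_true(f$converged && f$reliable)
  expect_lte(f$logLik, 0)
  V <- vcov(f)
  expect_equal(V, t(V))
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
})

test_that("degenerate inputs raise classed errors; separation is flagged not fatal", {
  y <- rep(0:1, 50)
  expect_error(fit_logistic(y, cbind(1, dosage = rep(0, 100))),
               class = "hlafinemap_degenerate")
  expect_error(fit_logistic(rep(1, 100), cbind(1, x = rnorm(100))),
               class = "hlafinemap_degenerate")
  # perfectly separating predictor: flagged unreliable, no crash
  sep <- fit_logistic(y, cbind(1, x = ifelse(y == 1, 2, 0)))
  expect_false(sep$reliable)
})

test_that("null dosage-phenotype simulations keep |beta| under 3 SE", {
  set.seed(31)
  n <- 2000
  inside <- replicate(200, {
    x <- rbinom(n, 2, 0.3)
    y <- rbinom(n, 1, 0.5)
    f <- fit_logistic(y, cbind(1, dosage = x))
    abs(coef(f)["dosage"]) < 3 * sqrt(diag(vcov(f))["dosage"])
  })
  expect_gte(mean(inside), 0.95)
})

test_that("omnibus test reduces to the 1-df LRT for biallelic markers", {
  cfg <- null_config(400, 400, collections = 2, shift_sd = 0.1)
  sim <- simulate_cohort(cfg, seed = 21)
  res <- omnibus_test("HLA_G1_0201", sim$classical, sim$cohort)
  y <- contrast_phenotype(sim$cohort)
  X0 <- build_design(sim$cohort)
  x <- sim$classical$dosages[, "HLA_G1_0201"]
  dev <- 2 * (fit_logistic(y, cbind(X0, v = x))$logLik - fit_logistic(y, X0)$logLik)
  expect_equal(res$df, 1L)
  expect_equal(res$deviance, dev, tolerance = 1e-8)
  expect_equal(res$p, pchisq(dev, 1, lower.tail = FALSE))
  # conditioning on a constant column changes nothing
  const <- matrix(1, nrow(sim$cohort), 1,
                  dimnames = list(sim$cohort$sample_id, "const"))
  res2 <- suppressWarnings(
    omnibus_test("HLA_G1_0201", sim$classical, sim$cohort, conditioning = const))
  expect_equal(res2$deviance, res$deviance, tolerance = 1e-10)
  expect_equal(res2$p, res$p, tolerance = 1e-10)
})

test_that("multiallelic omnibus deviance matches a direct-optimisation oracle", {
  cfg <- null_config(250, 250, collections = 1, shift_sd = 0)
  sim <- simulate_cohort(cfg, seed = 77)
  resid <- expand_to_residue_dosages(sim$classical, cfg$dictionary)
  g <- group_multiallelic_positions(resid[, 1:3])  # 3-residue position, n = 500
  res <- omnibus_test(g[1, ], resid, sim$cohort)
  y <- contrast_phenotype(sim$cohort)
  members <- g$members[[1]]
  X0 <- matrix(1, 500, 1)
  X1 <- cbind(X0, resid$dosages[, members[-1]])
  expect_equal(res$df, 2L)
  expect_equal(res$deviance, oracle_deviance(y, X0, X1), tolerance = 1e-6)
})

test_that("variant columns inside the conditioning span give df = 0, p = 1", {
  cfg <- null_config(300, 300, collections = 1, shift_sd = 0)
  sim <- simulate_cohort(cfg, seed = 5)
  self <- sim$classical[, "HLA_G1_0101"]
  res <- omnibus_test("HLA_G1_0101", sim$classical, sim$cohort,
                      conditioning = self)
  expect_equal(res$df, 0L)
  expect_equal(res$p, 1)
  expect_true("no_information" %in% res$flags)
})

test_that("scans are deterministic, complete, and attenuate conditioned signals", {
  cfg <- null_config(400, 400)
  sim <- simulate_cohort(cfg, seed = 8)
  panel <- cbind(sim$classical,
                 expand_to_residue_dosages(sim$classical, cfg$dictionary))
  s1 <- scan_region(panel, sim$cohort)
  s2 <- scan_region(panel, sim$cohort)
  expect_identical(s1, s2)
  # 4 classical + 4 residues + 1 position group
  expect_equal(nrow(s1), 9L)
  expect_false(any(is.na(s1$p)))
  cond <- sim$classical[, "HLA_G1_0101"]
  s3 <- scan_region(panel, sim$cohort, conditioning = cond)
  expect_equal(s3$p[s3$id == "HLA_G1_0101"], 1)
  expect_equal(s3$df[s3$id == "HLA_G1_0101"], 0L)
})

test_that("collection indicators remove collection-level confounding", {
  # marker frequency and case rate both differ by collection, but within a
  # collection genotype and phenotype are independent
  set.seed(19)
  n <- 4000
  coll <- rep(c("A", "B"), each = n / 2)
  freq <- ifelse(coll == "A", 0.15, 0.45)
  x <- rbinom(n, 2, freq)
  y <- rbinom(n, 1, ifelse(coll == "A", 0.25, 0.7))
  with_ind <- fit_logistic(y, cbind(1, collB = as.numeric(coll == "B"),
                                    dosage = x))
  without <- fit_logistic(y, cbind(1, dosage = x))
  z_with <- abs(coef(with_ind)["dosage"]) / sqrt(diag(vcov(with_ind))["dosage"])
  z_without <- abs(coef(without)["dosage"]) / sqrt(diag(vcov(without))["dosage"])
  expect_lt(z_with, 3.5)       # calibrated
  expect_gt(z_without, 6)      # grossly inflated without the indicator
})
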