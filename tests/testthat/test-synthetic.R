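test_that("cohort simulation is byte-identical for identical (config, seed)", {
  cfg <- psv_sim_config(n_case = 300, n_control = 400)
  a <- simulate_cohort(cfg, seed = 101)
  b <- simulate_cohort(cfg, seed = 101)
  expect_identical(a$classical$dosages, b$classical$dosages)
  expect_identical(as.data.frame(a$cohort), as.data.frame(b$cohort))
  c <- simulate_cohort(cfg, seed = 102)
  expect_false(identical(a$classical$dosages, c$classical$dosages))
  # a seed is mandatory
  expect_error(simulate_cohort(cfg, seed = NULL),
               class = "hlafinemap_validation_error")
  # hard calls sum to 2 per gene
  for (g in names(cfg$genes)) {
    sel <- variant_info(a$classical)$gene == g
    expect_equal(unname(rowSums(a$classical$dosages[, sel])), rep(2, 700))
  }
})

test_that("simulated allele frequencies recover the configured values", {
  cfg <- null_config(4000, 4000, collections = 1, shift_sd = 0,
                     prevalence = 0.5)
  sim <- simulate_cohort(cfg, seed = 9)
  ctrl <- sim$classical[sim$cohort$status == "control", ]
  f <- allele_frequencies(ctrl)
  target <- cfg$genes[["G1"]]
  for (a in names(target)) {
    id <- hlafinemap:::classical_marker_id(a)
    sd3 <- 3 * sqrt(target[[a]] * (1 - target[[a]]) / (2 * 4000))
    expect_lt(abs(f[[id]] - target[[a]]), sd3)
  }
})

test_that("haplotype coupling spans independence to determinism", {
  two_gene <- function(tab) sim_config(
    genes = list("GA" = c("GA*01:01" = 0.6, "GA*02:01" = 0.4),
                 "GB" = c("GB*01:01" = 0.5, "GB*02:01" = 0.5)),
    coupling = if (is.null(tab)) list() else list("GA>GB" = tab),
    prevalence = 0.5)
  hap_r2 <- function(haps) {
    a <- as.numeric(haps[["GA"]] == "GA*01:01")   # both copies stacked
    b <- as.numeric(haps[["GB"]] == "GB*01:01")
    cor(a, b)^2
  }
  # independence: R^2 near zero at 50,000 haplotypes
  h <- simulate_haplotypes(two_gene(NULL), 25000, seed = 3)
  expect_lt(hap_r2(h), 0.01)
  # deterministic coupling: R^2 = 1
  det <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
                dimnames = list(c("GA*01:01", "GA*02:01"),
                                c("GB*01:01", "GB*02:01")))
  hd <- simulate_haplotypes(two_gene(det), 5000, seed = 4)
  expect_equal(hap_r2(hd), 1)
  # intermediate table: two-locus haplotype frequencies within 3 binomial SDs
  mid <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE,
                dimnames = dimnames(det))
  hm <- simulate_haplotypes(two_gene(mid), 25000, seed = 5)
  n_hap <- 50000
  for (i in 1:2) for (j in 1:2) {
    pa <- c(0.6, 0.4)[i]
    expected <- pa * mid[i, j]
    obs <- mean(hm[["GA"]] == rownames(mid)[i] & hm[["GB"]] == colnames(mid)[j])
    expect_lt(abs(obs - expected),
              3 * sqrt(expected * (1 - expected) / n_hap))
  }
  # malformed coupling rows are rejected
  bad <- matrix(c(0.8, 0.3, 0.3, 0.7), 2, byrow = TRUE, dimnames = dimnames(det))
  expect_error(two_gene(bad), class = "hlafinemap_validation_error")
})

test_that("phenotype assignment calibrates prevalence and planted odds ratios", {
  # no effects: case status independent of genotype, prevalence on target
  cfg0 <- null_config(100, 100, collections = 1, shift_sd = 0, prevalence = 0.3)
  h <- simulate_haplotypes(cfg0, 20000, seed = 31)
  ph <- assign_phenotypes(h, cfg0, seed = 32)
  expect_lt(abs(mean(ph$status == "case") - 0.3),
            3 * sqrt(0.3 * 0.7 / 20000))
  # a single planted marker: population 2x2 allele-count OR recovers e^logOR
  cfg1 <- sim_config(
    genes = list("GC" = c("GC*06:02" = 0.093, "GC*07:01" = 0.907)),
    effects_disease = data.frame(kind = "allele", gene = "GC",
                                 label = "GC*06:02", position = NA,
                                 log_or = log(3.26)),
    prevalence = 0.02)
  h1 <- simulate_haplotypes(cfg1, 100000, seed = 33)
  p1 <- assign_phenotypes(h1, cfg1, seed = 34)
  case <- p1$status == "case"
  copies <- (h1[["GC"]][, 1] == "GC*06:02") + (h1[["GC"]][, 2] == "GC*06:02")
  a <- sum(copies[case]); b <- 2 * sum(case) - a
  c_ <- sum(copies[!case]); d <- 2 * sum(!case) - c_
  or_hat <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  expect_lt(abs(log(or_hat) - log(3.26)), 3 * se)
})

test_that("the subtype effect reproduces the PsA > PsC residue frequency gap", {
  cfg <- psv_sim_config(n_case = 3000, n_control = 1000)
  sim <- simulate_cohort(cfg, seed = 77)
  cls <- sim$classical
  resid <- expand_to_residue_dosages(
    cls[, which(variant_info(cls)$gene == "HLA-B")], cfg$dictionary)
  glu <- resid$dosages[, "AA_B_45_E"]
  f_psa <- sum(glu[sim$cohort$subtype == "PsA"]) /
    (2 * sum(sim$cohort$subtype == "PsA"))
  f_psc <- sum(glu[sim$cohort$subtype == "PsC"]) /
    (2 * sum(sim$cohort$subtype == "PsC"))
  expect_gt(f_psa, f_psc)
})

test_that("a zero-effect scan stays above the genome-wide threshold", {
  cfg <- null_config(1000, 1000)
  sim <- simulate_cohort(cfg, seed = 202)
  panel <- full_panel(sim, cfg$dictionary)
  sc <- scan_region(panel, sim$cohort)
  expect_gt(min(sc$p, na.rm = TRUE), 5e-8)
})

test_that("unattainable group sizes raise an error", {
  cfg <- null_config(5000, 100, prevalence = 0.01)
  expect_error(simulate_cohort(cfg, seed = 1, pool_factor = 0.001,
                               max_batches = 1),
               class = "hlafinemap_validation_error")
})
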