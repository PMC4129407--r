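# shared fixtures and independent oracles, built in code

# two-allele toy dictionary over HLA-B positions 9, 45, 67
toy_dict_df <- function() {
  data.frame(gene = "HLA-B",
             allele = rep(c("B*27:05", "B*07:02"), each = 3),
             position = rep(c(9, 45, 67), 2),
             residue = c("H", "E", "C", "Y", "K", "Y"))
}

toy_dict <- function() allele_dictionary(toy_dict_df())

# classical dosage matrix from explicit per-sample allele dosages
classical_dm <- function(dosage_by_label, samples = NULL) {
  labs <- colnames(dosage_by_label)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosage_by_label)))
  rownames(dosage_by_label) <- samples
  meta <- do.call(rbind, lapply(labs, function(l) {
    data.frame(id = hlafinemap:::classical_marker_id(l),
               gene = paste0("HLA-", sub("\\*.*", "", l)),
               kind = "classical_allele_4digit", position = NA_integer_,
               label = l, stringsAsFactors = FALSE)
  }))
  colnames(dosage_by_label) <- meta$id
  dosage_matrix(dosage_by_label, meta)
}

# hard-call classical matrix for one gene drawn from allele frequencies
random_classical <- function(n, freqs, seed = 1) {
  withr::with_seed(seed, {
    labs <- names(freqs)
    h1 <- sample(labs, n, TRUE, freqs)
    h2 <- sample(labs, n, TRUE, freqs)
    D <- sapply(labs, function(a) (h1 == a) + (h2 == a))
    classical_dm(D)
  })
}

# single-gene null simulation config (no phenotype effects)
null_config <- function(n_case = 1000, n_control = 1000, collections = 3,
                        shift_sd = 0.15, prevalence = 0.5) {
  sim_config(
    genes = list("G1" = c("G1*01:01" = 0.4, "G1*02:01" = 0.3,
                          "G1*03:01" = 0.2, "G1*04:01" = 0.1)),
    dictionary = allele_dictionary(data.frame(
      gene = "G1", allele = c("G1*01:01", "G1*02:01", "G1*03:01", "G1*04:01"),
      position = 1, residue = c("A", "C", "D", "E"))),
    prevalence = prevalence, n_case = n_case, n_control = n_control,
    collections = collections, shift_sd = shift_sd)
}

# independent maximum-likelihood oracle: direct BFGS optimisation of the
# binomial log-likelihood with analytic gradient
oracle_loglik <- function(y, X) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  gr <- function(b) {
    p <- stats::plogis(drop(X %*% b))
    -drop(crossprod(X, y - p))
  }
  opt <- stats::optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
  -opt$value
}

oracle_deviance <- function(y, X0, X1) {
  2 * (oracle_loglik(y, X1) - oracle_loglik(y, X0))
}

# residue panel + marker panel built from a simulated cohort
full_panel <- function(sim, dict) {
  cls <- sim$classical
  dg <- unique(dict$gene)
  sel <- which(variant_info(cls)$gene %in% dg)
  resid <- expand_to_residue_dosages(cls[, sel], dict)
  cbind(cls, collapse_to_two_digit(cls), resid)
}
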