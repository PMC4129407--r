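#' Simulation configuration for synthetic case-control cohorts
#'
#' Describes the generative model of a synthetic multi-collection HLA
#' case-control study: per-gene classical-allele frequencies, inter-gene
#' haplotype coupling (conditional allele tables creating LD along the gene
#' chain), an allele-to-residue dictionary through which amino-acid effects
#' are realised, per-marker log odds ratios for overall disease and for
#' subtype membership among cases, disease prevalence, collection structure
#' (count, allele-frequency shift magnitude, PC count and separation) and
#' target sample sizes.
#'
#' Effects placed on residues act through the dictionary: every classical
#' allele carrying the residue inherits the effect, so LD between residue
#' and allele signals arises mechanically.
#'
#' @param genes named list: gene -> named numeric vector of 4-digit allele
#'   frequencies summing to 1.
#' @param coupling named list of conditional tables, name `"parent>child"`,
#'   each a matrix with rownames = parent alleles, colnames = child alleles,
#'   rows summing to 1. Genes without a coupling entry are drawn
#'   independently; genes are drawn in the order they appear in `genes`.
#' @param dictionary an [allele_dictionary()] or NULL.
#' @param effects_disease,effects_subtype data.frames with columns `kind`
#'   (`"allele"` or `"residue"`), `gene`, `label` (allele name or residue
#'   letter), `position` (NA for alleles) and `log_or`. `effects_subtype`
#'   drives PsA-versus-PsC membership among cases.
#' @param prevalence population disease prevalence (default 0.02).
#' @param n_case,n_control target sample sizes.
#' @param collections number of data-set collections K.
#' @param shift_sd SD of per-collection log-scale allele-frequency
#'   perturbations (0 = identical frequencies everywhere).
#' @param n_pcs number of simulated principal components L.
#' @param pc_shift separation of collection PC means (PCs are
#'   collection-mean-shifted unit Gaussians; they exercise the covariate
#'   machinery and are not computed from genotypes).
#' @param psa_fraction expected PsA fraction among subtype-labelled cases.
#' @param unknown_fraction fraction of cases left with unknown subtype.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(genes, coupling = list(), dictionary = NULL,
                       effects_disease = NULL, effects_subtype = NULL,
                       prevalence = 0.02, n_case = 1000, n_control = 1000,
                       collections = 1, shift_sd = 0, n_pcs = 0,
                       pc_shift = 0.5, psa_fraction = 0.5,
                       unknown_fraction = 0) {
  if (!length(genes) || is.null(names(genes)))
    stop_hfm("genes must be a named list of frequency vectors", "hlafinemap_validation_error")
  for (g in names(genes)) {
    f <- genes[[g]]
    if (is.null(names(f)) || any(f < 0) || abs(sum(f) - 1) > 1e-6)
      stop_hfm(paste0("allele frequencies of ", g, " must be named and sum to 1"),
               "hlafinemap_validation_error")
  }
  for (nm in names(coupling)) {
    pc <- strsplit(nm, ">", fixed = TRUE)[[1]]
    if (length(pc) != 2 || !all(pc %in% names(genes)))
      stop_hfm(paste0("coupling name must be 'parent>child' over known genes: ", nm),
               "hlafinemap_validation_error")
    tab <- coupling[[nm]]
    if (!identical(sort(rownames(tab)), sort(names(genes[[pc[1]]]))) ||
        !identical(sort(colnames(tab)), sort(names(genes[[pc[2]]]))))
      stop_hfm(paste0("coupling table ", nm, " rows/cols must match allele sets"),
               "hlafinemap_validation_error")
    if (any(tab < 0) || any(abs(rowSums(tab) - 1) > 1e-6))
      stop_hfm(paste0("coupling table ", nm, " rows must sum to 1"),
               "hlafinemap_validation_error")
  }
  if (prevalence <= 0 || prevalence >= 1)
    stop_hfm("prevalence must lie in (0, 1)", "hlafinemap_validation_error")
  check_eff <- function(eff) {
    if (is.null(eff)) return(invisible())
    req <- c("kind", "gene", "label", "position", "log_or")
    if (!all(req %in% names(eff)))
      stop_hfm(paste0("effects need columns ", paste(req, collapse = ", ")),
               "hlafinemap_validation_error")
    for (i in seq_len(nrow(eff))) {
      if (eff$kind[i] == "allele") {
        if (!eff$label[i] %in% names(genes[[eff$gene[i]]]))
          stop_hfm(paste0("effect references unknown allele ", eff$label[i]),
                   "hlafinemap_validation_error")
      } else {
        if (is.null(dictionary))
          stop_hfm("residue effects require a dictionary", "hlafinemap_validation_error")
        hit <- dictionary$gene == eff$gene[i] &
               dictionary$position == eff$position[i] &
               dictionary$residue == eff$label[i]
        if (!any(hit))
          stop_hfm(paste0("effect references unknown residue ", eff$gene[i], ":",
                          eff$position[i], ":", eff$label[i]),
                   "hlafinemap_validation_error")
      }
    }
  }
  check_eff(effects_disease); check_eff(effects_subtype)
  structure(list(genes = genes, coupling = coupling, dictionary = dictionary,
                 effects_disease = effects_disease,
                 effects_subtype = effects_subtype, prevalence = prevalence,
                 n_case = n_case, n_control = n_control,
                 collections = collections, shift_sd = shift_sd,
                 n_pcs = n_pcs, pc_shift = pc_shift,
                 psa_fraction = psa_fraction,
                 unknown_fraction = unknown_fraction),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:\n")
  cat("  genes:", paste(sprintf("%s (%d alleles)", names(x$genes),
                                lengths(x$genes)), collapse = ", "), "\n")
  cat("  coupling:", if (length(x$coupling)) paste(names(x$coupling), collapse = ", ")
                     else "none", "\n")
  cat(sprintf("  prevalence %.3f; %d cases / %d controls; K = %d, shift_sd = %.2f, L = %d\n",
              x$prevalence, x$n_case, x$n_control, x$collections, x$shift_sd,
              x$n_pcs))
  cat(sprintf("  disease effects: %d; subtype effects: %d; unknown fraction %.2f\n",
              NROW(x$effects_disease), NROW(x$effects_subtype),
              x$unknown_fraction))
  invisible(x)
}

# per-collection multiplicative frequency perturbations, one delta per allele
draw_shifts <- function(config) {
  lapply(seq_len(config$collections), function(k) {
    lapply(config$genes, function(f) {
      if (config$shift_sd == 0) rep(0, length(f))
      else stats::rnorm(length(f), 0, config$shift_sd)
    })
  })
}

#' Simulate per-individual haplotypes along the gene chain
#'
#' Draws two independent haplotypes per individual. The first gene (or any
#' gene without a coupling entry) is drawn from its allele frequencies;
#' coupled genes are drawn from the conditional table row of the parent
#' allele on the same haplotype. Optional per-collection frequency shifts
#' multiply frequencies (and coupling rows) by `exp(delta)` before
#' renormalisation.
#'
#' @param config a [sim_config()].
#' @param n number of individuals.
#' @param seed RNG seed (NULL = use current RNG state).
#' @param collection optional integer vector (1..K) assigning individuals to
#'   collections; required when `shifts` is given.
#' @param shifts optional per-collection shift list (internal format from
#'   the cohort simulator); NULL = no shifts.
#' @return named list: gene -> n x 2 character matrix of allele names.
#' @export
simulate_haplotypes <- function(config, n, seed = NULL, collection = NULL,
                                shifts = NULL) {
  with_seed(seed, {
    if (is.null(collection)) collection <- rep(1L, n)
    child_of <- vapply(names(config$coupling),
                       function(nm) strsplit(nm, ">", fixed = TRUE)[[1]][2], "")
    haps <- list()
    for (g in names(config$genes)) {
      f <- config$genes[[g]]
      labs <- names(f)
      cp_i <- match(g, child_of)
      cp <- if (is.na(cp_i)) NA_character_ else names(config$coupling)[cp_i]
      out <- matrix(NA_character_, n, 2)
      if (!is.na(cp)) {
        parent <- strsplit(cp, ">", fixed = TRUE)[[1]][1]
        tab <- config$coupling[[cp]][, labs, drop = FALSE]
        for (copy in 1:2) {
          pa <- haps[[parent]][, copy]
          for (k in unique(collection)) {
            delta <- if (is.null(shifts)) rep(0, length(labs)) else shifts[[k]][[g]]
            w <- exp(delta)
            for (a in unique(pa[collection == k])) {
              idx <- which(pa == a & collection == k)
              pr <- tab[a, ] * w
              out[idx, copy] <- labs[sample.int(length(labs), length(idx),
                                                replace = TRUE,
                                                prob = pr / sum(pr))]
            }
          }
        }
      } else {
        for (copy in 1:2) {
          for (k in unique(collection)) {
            idx <- which(collection == k)
            delta <- if (is.null(shifts)) rep(0, length(labs)) else shifts[[k]][[g]]
            pr <- f * exp(delta)
            out[idx, copy] <- labs[sample.int(length(labs), length(idx),
                                              replace = TRUE,
                                              prob = pr / sum(pr))]
          }
        }
      }
      haps[[g]] <- out
    }
    haps
  })
}

# per-individual dosage of each effect target, as a matrix (n x n_effects)
effect_dosages <- function(haps, config, effects) {
  if (is.null(effects) || !nrow(effects))
    return(matrix(0, nrow(haps[[1]]), 0))
  cols <- lapply(seq_len(nrow(effects)), function(i) {
    g <- effects$gene[i]
    if (effects$kind[i] == "allele") {
      carriers <- effects$label[i]
    } else {
      d <- config$dictionary
      carriers <- unique(d$allele[d$gene == g & d$position == effects$position[i] &
                                  d$residue == effects$label[i]])
    }
    (haps[[g]][, 1] %in% carriers) + (haps[[g]][, 2] %in% carriers)
  })
  do.call(cbind, cols)
}

# calibrate an intercept so mean(plogis(b0 + lp)) hits a target rate
calibrate_intercept <- function(lp, target) {
  fn <- function(b0) mean(stats::plogis(b0 + lp)) - target
  lo <- -40; hi <- 40
  if (fn(lo) > 0 || fn(hi) < 0)
    stop_hfm("cannot calibrate intercept to the requested rate",
             "hlafinemap_validation_error")
  stats::uniroot(fn, c(lo, hi), tol = 1e-10)$root
}

#' Assign disease and subtype labels to simulated individuals
#'
#' Disease status is drawn from the additive-dosage logistic model with the
#' configured disease log-ORs, the intercept calibrated (by root finding) so
#' the expected population prevalence matches the config. Among cases,
#' subtype (PsA versus PsC) is drawn from a second logistic model with the
#' subtype log-ORs, its intercept calibrated to the configured PsA fraction;
#' a configurable fraction of cases is then relabelled `unknown`.
#'
#' @param haps haplotype list from [simulate_haplotypes()].
#' @param config a [sim_config()].
#' @param seed RNG seed (NULL = current RNG state).
#' @param intercepts optional list(disease=, subtype=) of pre-calibrated
#'   intercepts (used internally for multi-batch pools).
#' @return data.frame with columns `status`, `subtype`; attributes
#'   `intercept_disease`, `intercept_subtype`.
#' @export
assign_phenotypes <- function(haps, config, seed = NULL, intercepts = NULL) {
  with_seed(seed, {
    n <- nrow(haps[[1]])
    ed <- effect_dosages(haps, config, config$effects_disease)
    lp <- if (ncol(ed)) drop(ed %*% config$effects_disease$log_or) else rep(0, n)
    b0 <- intercepts$disease %||% calibrate_intercept(lp, config$prevalence)
    status <- ifelse(stats::rbinom(n, 1, stats::plogis(b0 + lp)) == 1,
                     "case", "control")
    es <- effect_dosages(haps, config, config$effects_subtype)
    lps <- if (ncol(es)) drop(es %*% config$effects_subtype$log_or) else rep(0, n)
    cases <- which(status == "case")
    b0s <- intercepts$subtype %||%
      (if (length(cases)) calibrate_intercept(lps[cases], config$psa_fraction)
       else 0)
    subtype <- ifelse(status == "case", "unknown", "control")
    if (length(cases)) {
      is_psa <- stats::rbinom(length(cases), 1, stats::plogis(b0s + lps[cases]))
      subtype[cases] <- ifelse(is_psa == 1, "PsA", "PsC")
      if (config$unknown_fraction > 0) {
        nu <- round(config$unknown_fraction * length(cases))
        subtype[sample(cases, nu)] <- "unknown"
      }
    }
    out <- data.frame(status = status, subtype = subtype,
                      stringsAsFactors = FALSE)
    attr(out, "intercept_disease") <- b0
    attr(out, "intercept_subtype") <- b0s
    out
  })
}

#' Simulate a complete case-control cohort
#'
#' Composes [simulate_haplotypes()] and [assign_phenotypes()] with
#' retrospective (case-control) ascertainment: a large population pool is
#' simulated at the configured prevalence, then the requested numbers of
#' cases and controls are sampled from it, keeping the logistic odds ratios
#' interpretable. Collection labels, per-collection allele-frequency shifts
#' and collection-mean-shifted PCs are attached. Fully reproducible from
#' `(config, seed)`.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed (mandatory).
#' @param pool_factor oversampling factor for the population pool.
#' @param max_batches pool draws attempted before declaring the group sizes
#'   unattainable.
#' @return An object of class `simulated_cohort`: `classical` (a
#'   [dosage_matrix()] of hard-call 4-digit allele dosages), `cohort` (a
#'   [cohort_table()]) and `truth` (generative parameters: config,
#'   calibrated intercepts, realised control allele frequencies).
#' @export
simulate_cohort <- function(config, seed, pool_factor = 1.3, max_batches = 5) {
  if (missing(seed) || is.null(seed))
    stop_hfm("a seed is mandatory for cohort simulation", "hlafinemap_validation_error")
  with_seed(seed, {
    K <- config$collections
    prev <- config$prevalence
    batch_n <- ceiling(pool_factor * max(config$n_case / prev,
                                         config$n_control / (1 - prev)))
    shifts <- draw_shifts(config)
    haps <- NULL; pheno <- NULL; collection <- integer()
    intercepts <- NULL
    for (b in seq_len(max_batches)) {
      coll_b <- sample.int(K, batch_n, replace = TRUE)
      haps_b <- simulate_haplotypes(config, batch_n, seed = NULL,
                                    collection = coll_b, shifts = shifts)
      ph_b <- assign_phenotypes(haps_b, config, seed = NULL,
                                intercepts = intercepts)
      if (is.null(intercepts))
        intercepts <- list(disease = attr(ph_b, "intercept_disease"),
                           subtype = attr(ph_b, "intercept_subtype"))
      haps <- if (is.null(haps)) haps_b
              else Map(function(a, b) rbind(a, b), haps, haps_b)
      pheno <- if (is.null(pheno)) ph_b else rbind(pheno, ph_b)
      collection <- c(collection, coll_b)
      if (sum(pheno$status == "case") >= config$n_case &&
          sum(pheno$status == "control") >= config$n_control) break
      if (b == max_batches)
        stop_hfm("requested group sizes unattainable at this prevalence",
                 "hlafinemap_validation_error")
    }
    take <- c(sample(which(pheno$status == "case"), config$n_case),
              sample(which(pheno$status == "control"), config$n_control))
    take <- sort(take)
    haps <- lapply(haps, function(m) m[take, , drop = FALSE])
    pheno <- pheno[take, , drop = FALSE]
    collection <- collection[take]
    n <- length(take)
    ids <- sprintf("S%06d", seq_len(n))

    # hard-call classical dosage matrix over the full configured allele sets
    mats <- list(); meta <- list()
    for (g in names(config$genes)) {
      labs <- names(config$genes[[g]])
      m <- sapply(labs, function(a)
        (haps[[g]][, 1] == a) + (haps[[g]][, 2] == a))
      mats[[g]] <- m
      meta[[g]] <- data.frame(id = vapply(labs, classical_marker_id, ""),
                              gene = g, kind = "classical_allele_4digit",
                              position = NA_integer_, label = labs,
                              stringsAsFactors = FALSE)
    }
    dm <- do.call(cbind, mats)
    rownames(dm) <- ids
    classical <- dosage_matrix(dm, do.call(rbind, meta))

    pcs <- NULL
    if (config$n_pcs > 0) {
      pcs <- sapply(seq_len(config$n_pcs), function(l)
        stats::rnorm(n, mean = config$pc_shift *
                       (collection - (K + 1) / 2) / l, sd = 1))
    }
    cohort <- cohort_table(ids, pheno$status, pheno$subtype,
                           paste0("C", collection), pcs)
    ctrl <- classical[cohort$status == "control", ]
    truth <- list(config = config, intercepts = intercepts,
                  control_freqs = allele_frequencies(ctrl), seed = seed)
    structure(list(classical = classical, cohort = cohort, truth = truth),
              class = "simulated_cohort")
  })
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("Simulated cohort\n")
  print(x$cohort)
  print(x$classical)
  invisible(x)
}

#' Published multivariate model of psoriasis MHC risk
#'
#' The multivariate full-model summary shipped with the package: per-variant
#' case/control frequencies and odds ratios for the classical HLA-C alleles,
#' HLA-B amino-acid positions 67 and 9, HLA-A position 95 and HLA-DQalpha1
#' position 53, with reference rows marked. Used as the default effect
#' structure of [psv_sim_config()] and as input for combined
#' variance-explained calculations.
#'
#' @return data.frame with columns locus, gene, kind, label, position,
#'   freq_case, freq_control, or, reference.
#' @export
psv_published_model <- function() {
  path <- system.file("extdata", "psv_multivariate_model.tsv",
                      package = "hlafinemap", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$reference <- as.logical(tab$reference)
  tab
}

#' Study-scale default simulation configuration
#'
#' A ready-made [sim_config()] emulating a European multi-collection
#' psoriasis case-control study: four HLA genes with realistic classical
#' allele sets, a synthetic allele-to-residue dictionary covering HLA-B
#' positions 9, 45 and 67, HLA-A position 95 and HLA-DQalpha1 position 53,
#' mild HLA-C to HLA-B haplotype coupling, disease effects taken from the
#' published multivariate model ([psv_published_model()]) and a
#' subtype-differentiating effect on HLA-B position 45 (Glu, PsA-versus-PsC
#' OR 1.46). HLA-C deliberately has no dictionary entries: its published
#' risk is allele-level, and a residue private to one allele would duplicate
#' that allele's dosage column.
#'
#' @param n_case,n_control sample sizes (defaults 9000 / 13000).
#' @param collections,shift_sd,n_pcs,pc_shift collection structure, see
#'   [sim_config()].
#' @param unknown_fraction fraction of cases with unknown subtype.
#' @param prevalence disease prevalence (default 0.02).
#' @param subtype_or PsA-versus-PsC odds ratio planted on HLA-B Glu45.
#' @return a [sim_config()].
#' @export
psv_sim_config <- function(n_case = 9000, n_control = 13000, collections = 3,
                           shift_sd = 0.15, n_pcs = 2, pc_shift = 0.5,
                           unknown_fraction = 1 / 3, prevalence = 0.02,
                           subtype_or = 1.46) {
  genes <- list(
    "HLA-C" = c("C*06:02" = 0.093, "C*12:03" = 0.056, "C*07:01" = 0.22,
                "C*04:01" = 0.13, "C*03:04" = 0.12, "C*05:01" = 0.10,
                "C*01:02" = 0.08, "C*02:02" = 0.08, "C*08:02" = 0.121),
    "HLA-B" = c("B*07:02" = 0.16, "B*08:01" = 0.08, "B*27:05" = 0.04,
                "B*57:01" = 0.046, "B*44:02" = 0.14, "B*40:01" = 0.12,
                "B*35:01" = 0.12, "B*51:01" = 0.094, "B*18:01" = 0.10,
                "B*13:02" = 0.10),
    "HLA-A" = c("A*02:01" = 0.29, "A*03:01" = 0.12, "A*01:01" = 0.18,
                "A*24:02" = 0.12, "A*11:01" = 0.10, "A*68:01" = 0.09,
                "A*26:01" = 0.10),
    "HLA-DQA1" = c("DQA1*05:01" = 0.29, "DQA1*01:01" = 0.23,
                   "DQA1*01:02" = 0.20, "DQA1*03:01" = 0.16,
                   "DQA1*02:01" = 0.12))
  # synthetic residue assignments chosen so pooled residue frequencies mirror
  # the published control frequencies at each fine-mapped position
  b <- data.frame(
    allele = names(genes[["HLA-B"]]),
    p9  = c("Y", "H", "Y", "Y", "H", "Y", "Y", "D", "Y", "Y"),
    p45 = c("E", "E", "E", "E", "T", "T", "K", "K", "M", "M"),
    p67 = c("Y", "C", "C", "M", "F", "F", "S", "S", "S", "S"))
  dict <- rbind(
    data.frame(gene = "HLA-B", allele = rep(b$allele, 3),
               position = rep(c(9, 45, 67), each = nrow(b)),
               residue = c(b$p9, b$p45, b$p67)),
    data.frame(gene = "HLA-A", allele = names(genes[["HLA-A"]]), position = 95,
               residue = c("V", "L", "I", "I", "I", "I", "I")),
    data.frame(gene = "HLA-DQA1", allele = names(genes[["HLA-DQA1"]]),
               position = 53, residue = c("R", "K", "K", "Q", "Q")))
  dictionary <- allele_dictionary(dict)

  # mild HLA-C -> HLA-B haplotype coupling: each C allele mixes the marginal
  # B frequencies with a preferred partner (classic psoriasis/ancestral
  # haplotypes), creating realistic inter-gene LD
  fB <- genes[["HLA-B"]]
  pref <- c("C*06:02" = "B*57:01", "C*07:01" = "B*08:01", "C*05:01" = "B*44:02",
            "C*01:02" = "B*27:05")
  tab <- t(vapply(names(genes[["HLA-C"]]), function(a) {
    row <- 0.8 * fB
    if (a %in% names(pref)) row[pref[[a]]] <- row[pref[[a]]] + 0.2
    else row <- fB
    row / sum(row)
  }, fB))
  coupling <- list("HLA-C>HLA-B" = tab)

  pub <- psv_published_model()
  eff <- pub[!pub$reference & pub$or != 1, ]
  effects_disease <- data.frame(kind = eff$kind, gene = eff$gene,
                                label = eff$label, position = eff$position,
                                log_or = log(eff$or), stringsAsFactors = FALSE)
  effects_subtype <- data.frame(kind = "residue", gene = "HLA-B", label = "E",
                                position = 45, log_or = log(subtype_or),
                                stringsAsFactors = FALSE)
  sim_config(genes = genes, coupling = coupling, dictionary = dictionary,
             effects_disease = effects_disease,
             effects_subtype = effects_subtype, prevalence = prevalence,
             n_case = n_case, n_control = n_control,
             collections = collections, shift_sd = shift_sd, n_pcs = n_pcs,
             pc_shift = pc_shift, unknown_fraction = unknown_fraction)
}
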