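#' Omnibus likelihood-ratio association test
#'
#' Tests one HLA variant -- a biallelic marker (SNP, classical allele or
#' residue marker) or a multiallelic amino-acid position group -- for
#' association with a binary phenotype under the additive-dosage logistic
#' model. For a variant with m alleles the m - 1 non-reference dosage columns
#' (the most frequent allele is the reference) are added to a null model that
#' carries the intercept, collection indicators, collection-specific PCs and
#' any conditioning dosages; the deviance `2 * (logLik_full - logLik_null)`
#' is referred to a chi-square distribution with m - 1 degrees of freedom.
#'
#' Variant columns that are collinear with the null design (e.g. a variant
#' conditioned on itself) are dropped and the degrees of freedom reduced; if
#' nothing remains the result carries `df = 0`, `p = 1` and a flag.
#'
#' @param variant a variant ID present in `dosages`, or a one-row
#'   `aa_position_group` descriptor (a row of
#'   [group_multiallelic_positions()] output), or a group ID present in
#'   `groups`.
#' @param dosages a [dosage_matrix()] holding the marker columns.
#' @param cohort a [cohort_table()].
#' @param conditioning optional [dosage_matrix()] (or matrix) of conditioning
#'   dosage covariates, e.g. from [build_conditioning_covariates()].
#' @param contrast a [contrast_spec()] or its name.
#' @param groups optional data.frame of position-group descriptors used to
#'   resolve a group ID.
#' @param pcs PC covariate mode, see [build_design()].
#' @return An object of class `hla_assoc`: variant descriptor, `df`,
#'   `deviance`, `p`, per-allele effect table (`beta`, `se`, `or`, CI,
#'   case/control frequencies), the reference label, conditioning
#'   description, and flags.
#' @export
omnibus_test <- function(variant, dosages, cohort, conditioning = NULL,
                         contrast = "PsV_vs_control", groups = NULL,
                         pcs = "by_collection") {
  contrast <- as_contrast(contrast)
  y <- contrast_phenotype(cohort, contrast)
  sub <- cohort[match(names(y), cohort$sample_id), , drop = FALSE]
  X0 <- suppressWarnings(build_design(sub, conditioning, pcs = pcs))
  fit0 <- fit_logistic(y, X0)
  omnibus_core(resolve_variant(variant, dosages, groups), dosages, y, X0, fit0,
               conditioning_label(conditioning))
}

# turn the user's `variant` argument into a descriptor row
resolve_variant <- function(variant, dosages, groups = NULL) {
  if (is.data.frame(variant)) return(variant[1, , drop = FALSE])
  info <- variant_info(dosages)
  i <- match(variant, info$id)
  if (!is.na(i)) return(info[i, , drop = FALSE])
  if (!is.null(groups)) {
    i <- match(variant, groups$id)
    if (!is.na(i)) return(groups[i, , drop = FALSE])
  }
  stop_hfm(paste0("unknown variant: ", variant), "hlafinemap_lookup_error")
}

# member columns of a variant, reference excluded for multiallelic groups
variant_columns <- function(desc, dosages) {
  if (identical(desc$kind, "aa_position_group")) {
    members <- desc$members[[1]]
    list(cols = dosages$dosages[, members[-1], drop = FALSE],
         labels = variant_info(dosages[, members[-1]])$label,
         reference = variant_info(dosages[, members[1]])$label,
         m = length(members))
  } else {
    v <- dosages$dosages[, desc$id, drop = FALSE]
    list(cols = v, labels = desc$label, reference = NA_character_, m = 2L)
  }
}

conditioning_label <- function(conditioning) {
  if (is.null(conditioning)) return("none")
  if (inherits(conditioning, "conditioning_spec")) return(format(conditioning))
  nm <- if (inherits(conditioning, "dosage_matrix"))
    variant_info(conditioning)$id else colnames(conditioning)
  if (!length(nm)) "none" else paste(nm, collapse = "+")
}

# shared core: assumes y/X0/fit0 already prepared (so scans reuse the null fit)
omnibus_core <- function(desc, dosages, y, X0, fit0, cond_label) {
  vc <- variant_columns(desc, dosages)
  V <- vc$cols[match(names(y), sample_ids(dosages)), , drop = FALSE]
  if (anyNA(V))
    stop_hfm("dosage matrix missing some cohort samples", "hlafinemap_validation_error")
  flags <- character()
  # which variant columns add rank beyond the null design?
  Xa <- X0; rank_a <- qr(X0, tol = 1e-7)$rank; keep <- integer()
  for (j in seq_len(ncol(V))) {
    cand <- cbind(Xa, V[, j, drop = FALSE])
    r <- qr(cand, tol = 1e-7)$rank
    if (r > rank_a) { Xa <- cand; rank_a <- r; keep <- c(keep, j) }
  }
  df <- length(keep)
  eff <- data.frame(id = colnames(V), label = vc$labels,
                    beta = NA_real_, se = NA_real_,
                    or = NA_real_, or_lo = NA_real_, or_hi = NA_real_,
                    freq_case = colSums(V[y == 1, , drop = FALSE]) / (2 * sum(y == 1)),
                    freq_control = colSums(V[y == 0, , drop = FALSE]) / (2 * sum(y == 0)),
                    stringsAsFactors = FALSE)
  if (df == 0L) {
    flags <- c(flags, "no_information")
    res <- list(variant = desc, df = 0L, deviance = 0, p = 1, effects = eff,
                reference = vc$reference, conditioning = cond_label,
                flags = flags, n = length(y))
    class(res) <- "hla_assoc"
    return(res)
  }
  if (df < ncol(V)) flags <- c(flags, "df_reduced")
  fit1 <- suppressWarnings(fit_logistic(y, cbind(X0, V[, keep, drop = FALSE])))
  if (!fit1$reliable) flags <- c(flags, "unreliable_fit")
  dev <- max(0, 2 * (fit1$logLik - fit0$logLik))
  ids <- colnames(V)[keep]
  b <- fit1$coefficients[ids]
  se <- sqrt(diag(fit1$vcov))[ids]
  i <- match(ids, eff$id)
  eff$beta[i] <- b; eff$se[i] <- se
  eff$or[i] <- exp(b)
  eff$or_lo[i] <- exp(b - Z975 * se); eff$or_hi[i] <- exp(b + Z975 * se)
  res <- list(variant = desc, df = df, deviance = dev,
              p = chisq_upper(dev, df), effects = eff,
              reference = vc$reference, conditioning = cond_label,
              flags = flags, n = length(y))
  class(res) <- "hla_assoc"
  res
}

#' @export
print.hla_assoc <- function(x, ...) {
  cat(sprintf("Omnibus test of %s (%s, %s)\n", x$variant$id, x$variant$gene,
              x$variant$kind))
  cat(sprintf("  conditioning: %s\n", x$conditioning))
  cat(sprintf("  deviance = %.3f on %d df, p_omnibus = %.3g, n = %d\n",
              x$deviance, x$df, x$p, x$n))
  if (!is.na(x$reference)) cat(sprintf("  reference: %s\n", x$reference))
  print(cbind(x$effects[c("label", "freq_case", "freq_control")],
              round(x$effects[c("beta", "se", "or")], 3)), row.names = FALSE)
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Association scan over a marker panel
#'
#' Runs [omnibus_test()] for every marker in the panel and every multiallelic
#' amino-acid position group (rebuilt after MAF filtering), under a common
#' conditioning set. The null model is fitted once and shared. Per-variant
#' failures are reported as flagged rows; the scan never aborts.
#'
#' @param dosages a [dosage_matrix()] of the markers to scan.
#' @param cohort a [cohort_table()].
#' @param conditioning optional conditioning dosages (see [omnibus_test()]).
#' @param contrast a [contrast_spec()] or its name.
#' @param maf_threshold pooled-MAF filter applied before scanning.
#' @param include_groups also test multiallelic position groups built from
#'   the surviving residue markers (default TRUE).
#' @param pcs PC covariate mode, see [build_design()].
#' @return An object of class `hla_scan`: a data.frame with one row per
#'   variant (id, gene, kind, position, label, df, deviance, p, beta, se,
#'   or, freq_case, freq_control, flag), ordered by gene then position.
#' @export
scan_region <- function(dosages, cohort, conditioning = NULL,
                        contrast = "PsV_vs_control", maf_threshold = 0.001,
                        include_groups = TRUE, pcs = "by_collection") {
  contrast <- as_contrast(contrast)
  dosages <- filter_by_maf(dosages, maf_threshold)
  info <- variant_info(dosages)
  y <- contrast_phenotype(cohort, contrast)
  sub <- cohort[match(names(y), cohort$sample_id), , drop = FALSE]
  X0 <- suppressWarnings(build_design(sub, conditioning, pcs = pcs))
  fit0 <- fit_logistic(y, X0)
  cond <- conditioning_label(conditioning)

  descs <- split(info, seq_len(nrow(info)))
  if (include_groups && any(info$kind == "aa_residue")) {
    resid <- dosages[, which(info$kind == "aa_residue")]
    grp <- group_multiallelic_positions(resid, maf_threshold)
    if (nrow(grp)) descs <- c(descs, split(grp, seq_len(nrow(grp))))
  }
  rows <- lapply(descs, function(d) {
    out <- tryCatch(omnibus_core(d, dosages, y, X0, fit0, cond),
                    error = function(e) e)
    if (inherits(out, "error")) {
      data.frame(id = d$id, gene = d$gene, kind = d$kind, position = d$position,
                 label = if (identical(d$kind, "aa_position_group")) d$label else d$label,
                 df = NA_integer_, deviance = NA_real_, p = NA_real_,
                 beta = NA_real_, se = NA_real_, or = NA_real_,
                 freq_case = NA_real_, freq_control = NA_real_,
                 flag = paste0("error: ", conditionMessage(out)),
                 stringsAsFactors = FALSE)
    } else {
      bi <- nrow(out$effects) == 1L
      data.frame(id = d$id, gene = d$gene, kind = d$kind, position = d$position,
                 label = d$label,
                 df = out$df, deviance = out$deviance, p = out$p,
                 beta = if (bi) out$effects$beta else NA_real_,
                 se = if (bi) out$effects$se else NA_real_,
                 or = if (bi) out$effects$or else NA_real_,
                 freq_case = if (bi) out$effects$freq_case else NA_real_,
                 freq_control = if (bi) out$effects$freq_control else NA_real_,
                 flag = paste(out$flags, collapse = ","),
                 stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$gene, tab$position, tab$id, method = "radix"), ]
  rownames(tab) <- NULL
  attr(tab, "contrast") <- contrast$name
  attr(tab, "conditioning") <- cond
  class(tab) <- c("hla_scan", "data.frame")
  tab
}

#' @export
print.hla_scan <- function(x, n = 10, ...) {
  cat(sprintf("Association scan: %d variants, contrast %s, conditioning %s\n",
              nrow(x), attr(x, "contrast"), attr(x, "conditioning")))
  ord <- order(x$p)
  cat("Top associations:\n")
  print(as.data.frame(x)[utils::head(ord, n),
                         c("id", "gene", "kind", "df", "deviance", "p")],
        row.names = FALSE)
  invisible(x)
}

#' Plot an association scan
#'
#' Draws -log10(p) per variant, grouped by gene along the x axis, with a
#' dotted line at the genome-wide significance threshold.
#'
#' @param x an `hla_scan` object.
#' @param threshold significance threshold to draw (default 5e-8).
#' @param ... passed to [graphics::plot()].
#' @export
plot.hla_scan <- function(x, threshold = 5e-8, ...) {
  ok <- !is.na(x$p)
  genes <- factor(x$gene[ok])
  lp <- -log10(pmax(x$p[ok], 1e-300))
  graphics::plot(seq_along(lp), lp, col = as.integer(genes), pch = 18,
                 xlab = "variant (by gene, position)",
                 ylab = expression(-log[10](p[omnibus])), ...)
  graphics::abline(h = -log10(threshold), lty = 3)
  graphics::legend("topright", legend = levels(genes), col = seq_len(nlevels(genes)),
                   pch = 18, cex = 0.8, bty = "n")
  invisible(x)
}
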