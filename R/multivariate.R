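#' Multivariate full regression model
#'
#' Fits one joint additive-dosage logistic model containing all selected risk
#' variants simultaneously (plus collection indicators and PCs), and lays the
#' result out as a per-locus table: for each amino-acid position the m - 1
#' non-reference residues with a marked reference row, and for each gene's
#' classical alleles the named alleles with an "other alleles" reference row.
#' Odds ratios are `exp(beta)` with 95% Wald confidence intervals.
#'
#' @param selected a [conditioning_spec()] (or character vector of items)
#'   naming the risk variants: `marker:` items for classical alleles, `aa:`
#'   items for amino-acid positions, `gene:` items for a gene's pruned
#'   classical-allele set.
#' @param classical [dosage_matrix()] of 4-digit classical alleles.
#' @param residues [dosage_matrix()] of residue markers (needed for `aa:`
#'   items); e.g. from [expand_to_residue_dosages()].
#' @param cohort a [cohort_table()].
#' @param contrast a [contrast_spec()] or its name.
#' @param maf_threshold MAF filter used when resolving `aa:` items.
#' @param pcs PC covariate mode, see [build_design()].
#' @return An object of class `hla_mvfit`: `table` (locus, label, freq_case,
#'   freq_control, beta, se, or, or_lo, or_hi, p, reference flag) and `fit`
#'   (the underlying [fit_logistic()] object). Methods: `print`, `summary`,
#'   `coef`, `vcov`, `confint`, `predict`, `residuals`, `simulate`,
#'   [variance_explained()].
#' @export
fit_full_multivariate <- function(selected, classical, residues = NULL,
                                  cohort, contrast = "PsV_vs_control",
                                  maf_threshold = 0.001, pcs = "by_collection") {
  if (!inherits(selected, "conditioning_spec"))
    selected <- conditioning_spec(selected)
  if (!length(selected$items))
    stop_hfm("no variants selected for the multivariate model",
             "hlafinemap_validation_error")
  contrast <- as_contrast(contrast)

  blocks <- list()   # per item: locus label, predictor dosage_matrix, ref row info
  for (item in selected$items) {
    if (item$type == "aa") {
      cols <- build_conditioning_covariates(
        conditioning_spec(paste0("aa:", item$gene, ":", item$position)),
        classical, residues, maf_threshold)
      info <- variant_info(residues)
      sel <- which(info$gene == item$gene & info$position == item$position)
      sub <- residues[, sel]
      f <- allele_frequencies(sub)
      ref_i <- order_by_freq(f, variant_info(sub)$label)[1]
      blocks[[length(blocks) + 1L]] <- list(
        locus = paste0(item$gene, " position ", item$position),
        dm = cols, ref_label = variant_info(sub)$label[ref_i],
        ref_id = variant_info(sub)$id[ref_i])
    } else if (item$type == "marker") {
      hit <- resolve_marker(item$ref, classical, residues)
      if (is.null(hit))
        stop_hfm(paste0("cannot resolve item marker:", item$ref),
                 "hlafinemap_lookup_error")
      blocks[[length(blocks) + 1L]] <- list(
        locus = variant_info(hit)$gene, dm = hit,
        ref_label = NA_character_, ref_id = NA_character_)
    } else {  # gene
      cols <- build_conditioning_covariates(
        conditioning_spec(paste0("gene:", item$gene)), classical, residues,
        maf_threshold)
      blocks[[length(blocks) + 1L]] <- list(
        locus = item$gene, dm = cols,
        ref_label = "most frequent allele", ref_id = NA_character_)
    }
  }
  pred <- do.call(cbind, c(lapply(blocks, `[[`, "dm"), list(deparse.level = 0)))

  y <- contrast_phenotype(cohort, contrast)
  sub <- cohort[match(names(y), cohort$sample_id), , drop = FALSE]
  X0 <- suppressWarnings(build_design(sub, pcs = pcs))
  P <- pred$dosages[match(names(y), sample_ids(pred)), , drop = FALSE]
  fit <- fit_logistic(y, cbind(X0, P))

  est <- fit$coefficients
  se_all <- rep(NA_real_, length(est)); names(se_all) <- names(est)
  se_all[colnames(fit$X)] <- sqrt(diag(fit$vcov))

  rows <- list()
  # group classical-allele marker items per gene so each gene gets one reference row
  marker_genes <- unique(vapply(Filter(function(b) is.na(b$ref_label), blocks),
                                `[[`, "", "locus"))
  for (b in blocks) {
    ids <- variant_info(b$dm)$id
    labs <- variant_info(b$dm)$label
    for (i in seq_along(ids)) {
      id <- ids[i]
      beta <- est[id]; se <- se_all[id]
      col <- b$dm$dosages[match(names(y), sample_ids(b$dm)), i]
      rows[[length(rows) + 1L]] <- data.frame(
        locus = b$locus, label = labs[i], id = id,
        freq_case = sum(col[y == 1]) / (2 * sum(y == 1)),
        freq_control = sum(col[y == 0]) / (2 * sum(y == 0)),
        beta = beta, se = se, or = exp(beta),
        or_lo = exp(beta - Z975 * se), or_hi = exp(beta + Z975 * se),
        p = 2 * stats::pnorm(-abs(beta / se)), reference = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  # reference rows: per amino-acid position its most frequent residue; per
  # classical-allele locus the complement of the listed alleles
  refs <- list()
  for (b in blocks) {
    if (!is.na(b$ref_id)) {
      col <- residues$dosages[match(names(y), sample_ids(residues)), b$ref_id]
      refs[[length(refs) + 1L]] <- data.frame(
        locus = b$locus, label = b$ref_label, id = b$ref_id,
        freq_case = sum(col[y == 1]) / (2 * sum(y == 1)),
        freq_control = sum(col[y == 0]) / (2 * sum(y == 0)),
        beta = NA_real_, se = NA_real_, or = NA_real_, or_lo = NA_real_,
        or_hi = NA_real_, p = NA_real_, reference = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  for (b in Filter(function(b) identical(b$ref_label, "most frequent allele"),
                   blocks)) {
    refs[[length(refs) + 1L]] <- data.frame(
      locus = b$locus, label = "most frequent allele", id = NA_character_,
      freq_case = NA_real_, freq_control = NA_real_, beta = NA_real_,
      se = NA_real_, or = NA_real_, or_lo = NA_real_, or_hi = NA_real_,
      p = NA_real_, reference = TRUE, stringsAsFactors = FALSE)
  }
  for (g in marker_genes) {
    inc <- tab$locus == g & !tab$reference
    refs[[length(refs) + 1L]] <- data.frame(
      locus = g, label = paste0("other ", g, " alleles"), id = NA_character_,
      freq_case = 1 - sum(tab$freq_case[inc]),
      freq_control = 1 - sum(tab$freq_control[inc]),
      beta = NA_real_, se = NA_real_, or = NA_real_, or_lo = NA_real_,
      or_hi = NA_real_, p = NA_real_, reference = TRUE, stringsAsFactors = FALSE)
  }
  tab <- rbind(tab, do.call(rbind, refs))
  tab <- tab[order(match(tab$locus, vapply(blocks, `[[`, "", "locus")),
                   tab$reference, -ifelse(is.na(tab$or), 0, tab$or)), ]
  rownames(tab) <- NULL
  structure(list(table = tab, fit = fit, contrast = contrast$name,
                 items = selected$strings), class = "hla_mvfit")
}

#' @export
print.hla_mvfit <- function(x, digits = 3, ...) {
  cat(sprintf("Multivariate full model (%s): %d variants, n = %d\n",
              x$contrast, sum(!x$table$reference), x$fit$n))
  t <- x$table
  out <- data.frame(locus = t$locus, variant = t$label,
                    freq_case = round(t$freq_case, 3),
                    freq_control = round(t$freq_control, 3),
                    `OR (95% CI)` = ifelse(t$reference, "reference",
                      sprintf("%.2f (%.2f-%.2f)", t$or, t$or_lo, t$or_hi)),
                    p = ifelse(t$reference, "reference",
                               sprintf("%.2g", t$p)),
                    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
summary.hla_mvfit <- function(object, ...) summary(object$fit, ...)

#' @export
coef.hla_mvfit <- function(object, ...) {
  t <- object$table[!object$table$reference, ]
  stats::setNames(t$beta, t$id)
}

#' @export
vcov.hla_mvfit <- function(object, ...) {
  ids <- intersect(object$table$id[!object$table$reference],
                   colnames(object$fit$vcov))
  object$fit$vcov[ids, ids, drop = FALSE]
}

#' @export
confint.hla_mvfit <- function(object, parm, level = 0.95, ...) {
  t <- object$table[!object$table$reference, ]
  ci <- cbind(lower = t$beta - Z975 * t$se, upper = t$beta + Z975 * t$se)
  rownames(ci) <- t$id
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.hla_mvfit <- function(object, ...) predict(object$fit, ...)

#' @export
residuals.hla_mvfit <- function(object, ...) residuals(object$fit, ...)

#' @export
simulate.hla_mvfit <- function(object, nsim = 1, seed = NULL, ...)
  simulate(object$fit, nsim = nsim, seed = seed, ...)
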