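#' Forward stepwise conditional fine-mapping
#'
#' Repeatedly scans a marker panel with [scan_region()] and, at each step,
#' adds the most significant variant to the conditioning set, until no
#' variant reaches the significance threshold. Selecting a multiallelic
#' amino-acid position adds its m - 1 non-reference residue dosage columns as
#' covariates (an `aa:` conditioning item); selecting a biallelic marker adds
#' its dosage column (a `marker:` item). Ties on the p-value are broken by
#' the larger deviance, then by lexicographic variant ID.
#'
#' @param markers a [dosage_matrix()] panel to scan (classical alleles,
#'   residue markers, SNPs; multiallelic groups are built internally).
#' @param cohort a [cohort_table()].
#' @param initial starting conditioning: a [conditioning_spec()] (resolved
#'   against `classical`/`residues`), a [dosage_matrix()], or NULL.
#' @param scope optional character vector of gene names: only variants of
#'   these genes are candidates for selection (the conditioning may still
#'   reference other genes).
#' @param threshold selection threshold on the omnibus p-value; default the
#'   genome-wide 5e-8.
#' @param contrast a [contrast_spec()] or its name.
#' @param maf_threshold pooled-MAF filter for the panel.
#' @param classical,residues dosage matrices used to resolve `gene:`/`aa:`
#'   items of `initial`; default to slices of `markers`.
#' @param max_steps safety cap on the number of selection steps.
#' @param pcs PC covariate mode, see [build_design()].
#' @return An object of class `hla_stepwise`: a per-step data.frame
#'   (`id`, `gene`, `kind`, `position`, `p`, `deviance`, `conditioning`),
#'   the stopping reason, and the final conditioning description.
#' @export
stepwise_forward <- function(markers, cohort, initial = NULL, scope = NULL,
                             threshold = 5e-8, contrast = "PsV_vs_control",
                             maf_threshold = 0.001, classical = NULL,
                             residues = NULL, max_steps = 20,
                             pcs = "by_collection") {
  panel <- filter_by_maf(markers, maf_threshold)
  info <- variant_info(panel)
  if (is.null(classical) && any(info$kind == "classical_allele_4digit"))
    classical <- panel[, which(info$kind == "classical_allele_4digit")]
  if (is.null(residues) && any(info$kind == "aa_residue"))
    residues <- panel[, which(info$kind == "aa_residue")]
  groups <- if (!is.null(residues))
    group_multiallelic_positions(residues, maf_threshold)
  else data.frame()

  cond_dm <- if (is.null(initial)) NULL
             else if (inherits(initial, "dosage_matrix")) initial
             else build_conditioning_covariates(initial, classical, residues,
                                                maf_threshold, extra = panel)
  cond_items <- if (inherits(initial, "conditioning_spec")) initial$strings
                else character()
  scan_panel <- if (is.null(scope)) panel
                else panel[, which(info$gene %in% scope)]

  steps <- list(); reason <- NULL
  for (s in seq_len(max_steps)) {
    scan <- scan_region(scan_panel, cohort, conditioning = cond_dm,
                        contrast = contrast, maf_threshold = maf_threshold,
                        pcs = pcs)
    cand <- scan[!is.na(scan$p), , drop = FALSE]
    if (!nrow(cand)) { reason <- "no_testable_variant"; break }
    best <- cand[order(cand$p, -cand$deviance, cand$id, method = "radix"), ][1, ]
    if (best$p >= threshold) { reason <- "no_variant_below_threshold"; break }
    new_cols <- if (best$kind == "aa_position_group") {
      members <- groups$members[[match(best$id, groups$id)]]
      item <- paste0("aa:", best$gene, ":", best$position)
      residues[, members[-1]]
    } else {
      item <- paste0("marker:", best$id)
      panel[, best$id]
    }
    cond_items <- c(cond_items, item)
    cond_dm <- if (is.null(cond_dm)) new_cols else cbind(cond_dm, new_cols)
    steps[[s]] <- data.frame(step = length(steps) + 1L, id = best$id,
                             gene = best$gene, kind = best$kind,
                             position = best$position, p = best$p,
                             deviance = best$deviance,
                             conditioning = paste(cond_items, collapse = " + "),
                             stringsAsFactors = FALSE)
  }
  if (is.null(reason)) reason <- "max_steps"
  trace <- if (length(steps)) do.call(rbind, steps)
           else data.frame(step = integer(), id = character(), gene = character(),
                           kind = character(), position = integer(),
                           p = numeric(), deviance = numeric(),
                           conditioning = character())
  structure(list(trace = trace, reason = reason, selected = cond_items,
                 threshold = threshold,
                 contrast = as_contrast(contrast)$name),
            class = "hla_stepwise")
}

#' @export
print.hla_stepwise <- function(x, ...) {
  cat(sprintf("Forward stepwise selection (%s, threshold %.2g): %d step(s)\n",
              x$contrast, x$threshold, nrow(x$trace)))
  if (nrow(x$trace))
    print(x$trace[c("step", "id", "gene", "kind", "p", "deviance")],
          row.names = FALSE)
  cat("Stopped:", x$reason, "\n")
  invisible(x)
}
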