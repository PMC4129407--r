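#' Cohort sample table
#'
#' Per-individual phenotype information for a multi-collection case-control
#' cohort: disease status, clinical subphenotype (psoriatic arthritis `PsA`,
#' cutaneous psoriasis `PsC`, or `unknown` for unclassified cases), the
#' data-set collection each sample was genotyped in, and principal-component
#' values used as ancestry covariates. PCs are consumed as covariates, never
#' computed here.
#'
#' @param sample_id character vector of unique sample IDs.
#' @param status `"case"` or `"control"` per sample.
#' @param subtype `"PsA"`, `"PsC"` or `"unknown"` for cases; `"control"` for
#'   controls. Defaults to `"unknown"`/`"control"` by status.
#' @param collection collection identifier per sample (coerced to factor).
#' @param pcs numeric matrix (samples x L) of principal components, or NULL.
#' @return An object of class `cohort_table` (a data.frame with PC columns
#'   `PC1..PCL`).
#' @export
cohort_table <- function(sample_id, status, subtype = NULL, collection = NULL,
                         pcs = NULL) {
  n <- length(sample_id)
  if (anyDuplicated(sample_id))
    stop_hfm("duplicated sample IDs", "hlafinemap_validation_error")
  if (length(status) != n || !all(status %in% c("case", "control")))
    stop_hfm("status must be 'case'/'control' for every sample", "hlafinemap_validation_error")
  if (is.null(subtype)) subtype <- ifelse(status == "case", "unknown", "control")
  if (!all(subtype %in% c("PsA", "PsC", "unknown", "control")))
    stop_hfm("subtype must be PsA/PsC/unknown/control", "hlafinemap_validation_error")
  if (any(status == "control" & subtype != "control") ||
      any(status == "case" & subtype == "control"))
    stop_hfm("subtype labels inconsistent with case/control status", "hlafinemap_validation_error")
  if (is.null(collection)) collection <- rep("C1", n)
  if (length(collection) != n || anyNA(collection))
    stop_hfm("every sample needs exactly one collection", "hlafinemap_validation_error")
  tab <- data.frame(sample_id = as.character(sample_id), status = status,
                    subtype = subtype, collection = factor(collection),
                    stringsAsFactors = FALSE)
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    if (nrow(pcs) != n || anyNA(pcs))
      stop_hfm("PC matrix must be complete with one row per sample", "hlafinemap_validation_error")
    colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    tab <- cbind(tab, as.data.frame(pcs))
  }
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort: %d samples (%d cases / %d controls), %d collection(s), %d PC(s)\n",
              nrow(x), sum(x$status == "case"), sum(x$status == "control"),
              nlevels(x$collection), n_pcs(x)))
  st <- table(x$subtype[x$status == "case"])
  if (length(st)) cat("  case subtypes:",
                      paste(names(st), st, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

n_pcs <- function(cohort) sum(grepl("^PC[0-9]+$", names(cohort)))

pc_matrix <- function(cohort) {
  cols <- grep("^PC[0-9]+$", names(cohort), value = TRUE)
  as.matrix(cohort[cols])
}

#' Phenotype contrast specification
#'
#' The four binary phenotype contrasts of the analysis: overall disease
#' (`PsV_vs_control`), each subphenotype against controls (`PsA_vs_control`,
#' `PsC_vs_control`), and the intra-case comparison `PsA_vs_PsC`.
#'
#' @param name one of `"PsV_vs_control"`, `"PsA_vs_control"`,
#'   `"PsC_vs_control"`, `"PsA_vs_PsC"`.
#' @return An object of class `contrast_spec` with the case and reference
#'   label sets.
#' @export
contrast_spec <- function(name = c("PsV_vs_control", "PsA_vs_control",
                                   "PsC_vs_control", "PsA_vs_PsC")) {
  name <- match.arg(name)
  spec <- switch(name,
    PsV_vs_control = list(case = c("PsA", "PsC", "unknown"), ref = "control"),
    PsA_vs_control = list(case = "PsA", ref = "control"),
    PsC_vs_control = list(case = "PsC", ref = "control"),
    PsA_vs_PsC     = list(case = "PsA", ref = "PsC"))
  structure(c(list(name = name), spec), class = "contrast_spec")
}

as_contrast <- function(x) {
  if (inherits(x, "contrast_spec")) x else contrast_spec(x)
}

#' Binary phenotype vector for a contrast
#'
#' @param cohort a [cohort_table()].
#' @param contrast a [contrast_spec()] or its name.
#' @return named logical-as-numeric vector (1 = case class, 0 = reference
#'   class) over the samples belonging to the contrast; samples in neither
#'   group are omitted.
#' @export
contrast_phenotype <- function(cohort, contrast = "PsV_vs_control") {
  contrast <- as_contrast(contrast)
  in_case <- cohort$subtype %in% contrast$case
  in_ref <- cohort$subtype %in% contrast$ref
  keep <- in_case | in_ref
  y <- as.numeric(in_case[keep])
  names(y) <- cohort$sample_id[keep]
  y
}
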