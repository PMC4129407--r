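#' Conditioning-set specification
#'
#' A conditioning set lists previously identified signals to be held as
#' covariates when testing for residual association. Items are strings:
#'
#' * `"gene:HLA-C"` -- all 2- and 4-digit classical alleles of the gene
#'   (reference excluded, correlated alleles pruned at R^2 > 0.97);
#' * `"aa:HLA-B:45"` -- the multiallelic amino-acid position: its m - 1
#'   non-reference residue dosage columns;
#' * `"marker:C*06:02"` -- one marker column, referenced by allele label or
#'   marker ID.
#'
#' @param items character vector of items (may be empty).
#' @return An object of class `conditioning_spec`.
#' @export
conditioning_spec <- function(items = character()) {
  if (anyDuplicated(items))
    stop_hfm("duplicate conditioning items", "hlafinemap_validation_error")
  parsed <- lapply(items, function(s) {
    if (grepl("^gene:", s)) {
      list(type = "gene", gene = sub("^gene:", "", s))
    } else if (grepl("^aa:", s)) {
      rest <- sub("^aa:", "", s)
      pos <- sub("^.*:", "", rest)
      gene <- sub(":[^:]*$", "", rest)
      if (!grepl("^-?[0-9]+$", pos))
        stop_hfm(paste0("bad aa conditioning item: ", s), "hlafinemap_parse_error")
      list(type = "aa", gene = gene, position = as.integer(pos))
    } else if (grepl("^marker:", s)) {
      list(type = "marker", ref = sub("^marker:", "", s))
    } else {
      stop_hfm(paste0("unrecognised conditioning item: ", s), "hlafinemap_parse_error")
    }
  })
  structure(list(items = parsed, strings = items), class = "conditioning_spec")
}

#' @export
format.conditioning_spec <- function(x, ...) {
  if (!length(x$strings)) "none" else paste(x$strings, collapse = " + ")
}

#' @export
print.conditioning_spec <- function(x, ...) {
  cat("Conditioning spec:", format(x), "\n")
  invisible(x)
}

#' @export
length.conditioning_spec <- function(x) length(x$items)

#' Append items to a conditioning spec
#' @param x a [conditioning_spec()].
#' @param ... item strings or further specs.
#' @export
c.conditioning_spec <- function(x, ...) {
  extra <- unlist(lapply(list(...), function(e)
    if (inherits(e, "conditioning_spec")) e$strings else as.character(e)))
  conditioning_spec(c(x$strings, extra))
}

#' Greedy pruning of correlated dosage columns
#'
#' One pass in descending pooled-frequency order: a column is dropped when
#' its squared Pearson correlation with any already-retained column exceeds
#' `r2_max`, so of each strongly correlated pair the more frequent column is
#' kept. Constant columns carry no information and are dropped first.
#'
#' @param x a [dosage_matrix()] (at least one column).
#' @param r2_max squared-correlation ceiling; default 0.97.
#' @return the pruned [dosage_matrix()].
#' @export
prune_correlated <- function(x, r2_max = 0.97) {
  if (ncol(x$dosages) == 0L)
    stop_hfm("nothing to prune: no columns", "hlafinemap_validation_error")
  D <- x$dosages
  sdv <- apply(D, 2, stats::sd)
  idx <- which(sdv > 0)
  if (!length(idx)) return(x[, integer()])
  f <- allele_frequencies(x)[idx]
  lab <- variant_info(x)$id[idx]
  ord <- idx[order_by_freq(f, lab)]
  retained <- integer()
  for (j in ord) {
    if (!length(retained)) { retained <- j; next }
    r2 <- suppressWarnings(stats::cor(D[, j], D[, retained, drop = FALSE]))^2
    if (all(r2 <= r2_max, na.rm = TRUE)) retained <- c(retained, j)
  }
  x[, sort(retained)]
}

#' Build conditioning dosage covariates from a spec
#'
#' Resolves each item of a [conditioning_spec()] into dosage columns:
#' `aa` items contribute the m - 1 non-reference residue columns of the
#' position (reference = most frequent residue); `gene` items contribute the
#' gene's 2- and 4-digit classical allele columns with the most frequent
#' allele excluded as reference and correlated columns pruned at
#' `R^2 > r2_max`; `marker` items contribute the named column.
#'
#' @param spec a [conditioning_spec()] (or character vector of items).
#' @param classical [dosage_matrix()] of 4-digit classical alleles (2-digit
#'   groups are derived internally).
#' @param residues [dosage_matrix()] of residue markers (required for `aa`
#'   items), e.g. from [expand_to_residue_dosages()].
#' @param maf_threshold MAF filter applied when picking qualifying residues.
#' @param r2_max pruning ceiling for gene items.
#' @param extra optional additional [dosage_matrix()] searched when resolving
#'   `marker` items (e.g. a panel holding 2-digit allele groups).
#' @return a [dosage_matrix()] of covariate columns (zero columns for an
#'   empty spec).
#' @export
build_conditioning_covariates <- function(spec, classical, residues = NULL,
                                          maf_threshold = 0.001, r2_max = 0.97,
                                          extra = NULL) {
  if (!inherits(spec, "conditioning_spec")) spec <- conditioning_spec(spec)
  n <- nrow(classical$dosages)
  empty <- dosage_matrix(
    matrix(numeric(0), n, 0, dimnames = list(sample_ids(classical), NULL)),
    data.frame(id = character(), gene = character(), kind = character(),
               position = integer(), label = character()))
  if (!length(spec$items)) return(empty)
  parts <- lapply(spec$items, function(item) {
    switch(item$type,
      gene = {
        info <- variant_info(classical)
        sel <- which(info$gene == item$gene & info$kind == "classical_allele_4digit")
        if (!length(sel))
          stop_hfm(paste0("no classical alleles for conditioning item gene:",
                          item$gene), "hlafinemap_lookup_error")
        four <- classical[, sel]
        both <- cbind(collapse_to_two_digit(four), four)
        f <- allele_frequencies(both)
        ref <- order_by_freq(f, variant_info(both)$id)[1]
        pruned <- prune_correlated(both[, -ref], r2_max)
        pruned
      },
      aa = {
        if (is.null(residues))
          stop_hfm("residue matrix required for aa conditioning items",
                   "hlafinemap_validation_error")
        info <- variant_info(residues)
        sel <- which(info$gene == item$gene & info$position == item$position &
                     info$kind == "aa_residue")
        if (!length(sel))
          stop_hfm(paste0("no residues for conditioning item aa:", item$gene,
                          ":", item$position), "hlafinemap_lookup_error")
        sub <- residues[, sel]
        f <- allele_frequencies(sub)
        qual <- which(pmin(f, 1 - f) > maf_threshold)
        if (length(qual) < 2L)
          stop_hfm(paste0("position ", item$gene, ":", item$position,
                          " is monomorphic after MAF filtering"),
                   "hlafinemap_lookup_error")
        sub <- sub[, qual]
        ref <- order_by_freq(allele_frequencies(sub), variant_info(sub)$label)[1]
        sub[, -ref]
      },
      marker = {
        hit <- resolve_marker(item$ref, classical, residues, extra)
        if (is.null(hit))
          stop_hfm(paste0("cannot resolve conditioning item marker:", item$ref),
                   "hlafinemap_lookup_error")
        hit
      })
  })
  do.call(cbind, c(parts, list(deparse.level = 0)))
}

# find a single marker column by ID or classical-allele label in the matrices
resolve_marker <- function(ref, classical, residues = NULL, extra = NULL) {
  strip <- sub("^HLA-", "", ref)
  for (dm in Filter(Negate(is.null), list(classical, residues, extra))) {
    info <- variant_info(dm)
    i <- match(ref, info$id)
    if (is.na(i)) i <- match(strip, info$label)
    if (is.na(i)) i <- match(ref, info$label)
    if (!is.na(i)) return(dm[, i])
  }
  NULL
}
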