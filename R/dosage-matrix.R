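#' Dosage matrix of HLA variant markers
#'
#' Container for additive allele dosages: an `n_samples x n_variants` dense
#' matrix of real values in `[0, 2]` plus per-variant metadata. A dosage is
#' the (possibly fractional, e.g. imputed) expected count of the allele or
#' residue carried by an individual.
#'
#' Variant kinds follow the marker taxonomy used in SNP2HLA-style panels:
#' `SNP`, `classical_allele_2digit`, `classical_allele_4digit` and
#' `aa_residue` (a biallelic indicator of carrying one residue at one
#' amino-acid position). Multiallelic amino-acid positions are represented as
#' groups of residue markers (see [group_multiallelic_positions()]), not as
#' matrix columns.
#'
#' @param dosages numeric matrix, samples in rows (rownames = sample IDs),
#'   variants in columns.
#' @param variants data.frame with one row per column of `dosages` and columns
#'   `id`, `gene`, `kind`, `position`, `label`. Defaults are parsed from the
#'   column names of `dosages` via [parse_marker_id()].
#' @return An object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(dosages, variants = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("S", seq_len(nrow(dosages)))
  if (is.null(variants)) {
    if (is.null(colnames(dosages)))
      stop_hfm("variant metadata or column names required", "hlafinemap_validation_error")
    variants <- do.call(rbind, lapply(colnames(dosages), parse_marker_id))
  }
  variants <- as.data.frame(variants)
  req <- c("id", "gene", "kind", "position", "label")
  if (!all(req %in% names(variants)))
    stop_hfm(paste0("variant metadata needs columns ", paste(req, collapse = ", ")),
             "hlafinemap_validation_error")
  variants <- variants[req]
  if (nrow(variants) != ncol(dosages))
    stop_hfm("variant metadata rows must match dosage columns", "hlafinemap_validation_error")
  if (anyDuplicated(variants$id))
    stop_hfm("duplicated variant IDs", "hlafinemap_validation_error")
  if (anyDuplicated(rownames(dosages)))
    stop_hfm("duplicated sample IDs", "hlafinemap_validation_error")
  if (anyNA(dosages))
    stop_hfm("missing dosages are not allowed", "hlafinemap_validation_error")
  if (any(dosages < -1e-9 | dosages > 2 + 1e-9))
    stop_hfm("dosages must lie in [0, 2]", "hlafinemap_validation_error")
  dosages[dosages < 0] <- 0
  dosages[dosages > 2] <- 2
  colnames(dosages) <- variants$id
  rownames(variants) <- NULL
  structure(list(dosages = dosages, variants = variants), class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("Dosage matrix: %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  tab <- table(x$variants$kind)
  for (k in names(tab)) cat(sprintf("  %s: %d\n", k, tab[[k]]))
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosages)

#' Sample IDs of a dosage matrix
#' @param x a [dosage_matrix()].
#' @return character vector.
#' @export
sample_ids <- function(x) rownames(x$dosages)

#' Variant metadata of a dosage matrix
#' @param x a [dosage_matrix()].
#' @return data.frame with columns id, gene, kind, position, label.
#' @export
variant_info <- function(x) x$variants

#' Subset a dosage matrix
#'
#' @param x a [dosage_matrix()].
#' @param i sample index (logical/integer/character).
#' @param j variant index (logical/integer) or variant IDs (character).
#' @param ... unused.
#' @export
`[.dosage_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  if (is.character(j)) {
    jj <- match(j, x$variants$id)
    if (anyNA(jj))
      stop_hfm(paste0("unknown variant ID(s): ", paste(j[is.na(jj)], collapse = ", ")),
               "hlafinemap_lookup_error")
    j <- jj
  }
  dosage_matrix(x$dosages[i, j, drop = FALSE], x$variants[j, , drop = FALSE])
}

#' Combine dosage matrices over the same samples
#' @param ... dosage matrices sharing identical sample IDs.
#' @param deparse.level unused.
#' @export
cbind.dosage_matrix <- function(..., deparse.level = 1) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  ids <- sample_ids(parts[[1]])
  for (p in parts[-1])
    if (!identical(sample_ids(p), ids))
      stop_hfm("dosage matrices must share identical sample IDs", "hlafinemap_validation_error")
  dosage_matrix(do.call(cbind, lapply(parts, `[[`, "dosages")),
                do.call(rbind, lapply(parts, `[[`, "variants")))
}

#' Pooled dosage-based allele frequencies
#'
#' Frequency of each marker as `sum(dosage) / (2 N)` over all samples.
#'
#' @param x a [dosage_matrix()].
#' @return named numeric vector.
#' @export
allele_frequencies <- function(x) {
  colSums(x$dosages) / (2 * nrow(x$dosages))
}

# ---- marker-ID dialect ------------------------------------------------------

GENE_SHORT <- c("HLA-A" = "A", "HLA-B" = "B", "HLA-C" = "C",
                "HLA-DRB1" = "DRB1", "HLA-DQA1" = "DQA1", "HLA-DQB1" = "DQB1",
                "HLA-DPA1" = "DPA1", "HLA-DPB1" = "DPB1", "MICA" = "MICA")

short_gene <- function(gene) {
  s <- GENE_SHORT[gene]
  ifelse(is.na(s), gene, s)
}

long_gene <- function(short) {
  lg <- names(GENE_SHORT)[match(short, GENE_SHORT)]
  ifelse(is.na(lg), short, lg)
}

#' Parse a SNP2HLA-style marker ID into a variant descriptor
#'
#' Recognised dialects: `HLA_B_27` (2-digit classical allele), `HLA_B_2705`
#' (4-digit), `MICA_008` / `MICA_00801` (MICA classical alleles) and
#' `AA_B_45_E` (amino-acid residue marker: gene, mature-protein position,
#' residue). Anything else is loaded as `kind = "SNP"`.
#'
#' @param id marker ID string.
#' @return one-row data.frame with columns id, gene, kind, position, label.
#' @export
parse_marker_id <- function(id) {
  desc <- function(gene, kind, position, label)
    data.frame(id = id, gene = gene, kind = kind, position = position,
               label = label, stringsAsFactors = FALSE)
  m <- regmatches(id, regexec("^AA_([A-Za-z0-9]+)_(-?[0-9]+)_(.+)$", id))[[1]]
  if (length(m))
    return(desc(long_gene(m[2]), "aa_residue", as.integer(m[3]), m[4]))
  m <- regmatches(id, regexec("^HLA_([A-Z0-9]+)_([0-9]{2})$", id))[[1]]
  if (length(m))
    return(desc(long_gene(m[2]), "classical_allele_2digit", NA_integer_,
                paste0(m[2], "*", m[3])))
  m <- regmatches(id, regexec("^HLA_([A-Z0-9]+)_([0-9]{4})$", id))[[1]]
  if (length(m))
    return(desc(long_gene(m[2]), "classical_allele_4digit", NA_integer_,
                paste0(m[2], "*", substr(m[3], 1, 2), ":", substr(m[3], 3, 4))))
  m <- regmatches(id, regexec("^MICA_([0-9]{3})$", id))[[1]]
  if (length(m))
    return(desc("MICA", "classical_allele_2digit", NA_integer_, paste0("MICA*", m[2])))
  m <- regmatches(id, regexec("^MICA_([0-9]{3})([0-9]{2})$", id))[[1]]
  if (length(m))
    return(desc("MICA", "classical_allele_4digit", NA_integer_,
                paste0("MICA*", m[2], ":", m[3])))
  desc(NA_character_, "SNP", NA_integer_, id)
}

# build the marker ID for a classical allele label like "B*27:05" or "MICA*008:01"
classical_marker_id <- function(label) {
  parts <- strsplit(label, "[*:]")[[1]]
  gene <- parts[1]
  fields <- parts[-1]
  if (gene == "MICA") paste0("MICA_", paste0(fields, collapse = ""))
  else paste0("HLA_", gene, "_", paste0(fields, collapse = ""))
}

aa_marker_id <- function(gene, position, residue)
  paste0("AA_", short_gene(gene), "_", position, "_", residue)

# ---- allele-model operations ------------------------------------------------

#' Expand classical-allele dosages into residue dosages
#'
#' For each (gene, amino-acid position, residue) observed among the alleles in
#' the matrix, emits a biallelic residue marker whose dosage is the sum of the
#' dosages of the alleles carrying that residue at that position. Expansion is
#' linear in the allele dosages, and per-individual dosages at one position
#' sum to 2 when the gene's allele set is complete. Positions at which all
#' alleles in the panel carry the same residue are dropped as monomorphic.
#'
#' @param classical a [dosage_matrix()] holding only 4-digit classical alleles
#'   of genes present in `dict`.
#' @param dict an [allele_dictionary()].
#' @return a [dosage_matrix()] of `aa_residue` markers.
#' @export
expand_to_residue_dosages <- function(classical, dict) {
  info <- variant_info(classical)
  if (!all(info$kind == "classical_allele_4digit"))
    stop_hfm("expansion requires 4-digit classical alleles only", "hlafinemap_validation_error")
  cols <- list(); meta <- list()
  for (g in unique(info$gene)) {
    gi <- info[info$gene == g, ]
    known <- dict_alleles(dict, g)
    missing <- setdiff(gi$label, known)
    if (length(missing))
      stop_hfm(paste0("allele(s) absent from dictionary: ",
                      paste(missing, collapse = ", ")), "hlafinemap_lookup_error")
    sub <- dict[dict$gene == g & dict$allele %in% gi$label, ]
    for (pos in dict_positions(dict, g)) {
      at <- sub[sub$position == pos, ]
      res_of <- at$residue[match(gi$label, at$allele)]
      resid <- unique(res_of)
      if (length(resid) < 2L) next  # monomorphic in this panel
      for (r in sort(resid)) {
        carrier <- gi$id[res_of == r]
        cols[[length(cols) + 1L]] <-
          rowSums(classical$dosages[, carrier, drop = FALSE])
        meta[[length(meta) + 1L]] <-
          data.frame(id = aa_marker_id(g, pos, r), gene = g, kind = "aa_residue",
                     position = pos, label = r, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cols))
    stop_hfm("no polymorphic amino-acid positions found", "hlafinemap_validation_error")
  dm <- do.call(cbind, cols)
  rownames(dm) <- sample_ids(classical)
  dosage_matrix(dm, do.call(rbind, meta))
}

#' Group residue markers into multiallelic amino-acid positions
#'
#' One `aa_position_group` descriptor is produced per (gene, position) with at
#' least two residue markers passing the minor-allele-frequency filter.
#' Members are ordered by descending pooled frequency (ties broken
#' lexicographically); the most frequent member is the reference residue,
#' which omnibus tests exclude from the tested columns.
#'
#' @param residues a [dosage_matrix()] of `aa_residue` markers.
#' @param maf_threshold pooled MAF below/at which a residue does not qualify.
#' @return data.frame with columns `id`, `gene`, `kind`, `position`, `label`
#'   (= reference residue) and a list-column `members` of member marker IDs.
#' @export
group_multiallelic_positions <- function(residues, maf_threshold = 0.001) {
  info <- variant_info(residues)
  if (!all(info$kind == "aa_residue"))
    stop_hfm("grouping requires aa_residue markers", "hlafinemap_validation_error")
  f <- allele_frequencies(residues)
  maf <- pmin(f, 1 - f)
  out <- list()
  for (g in unique(info$gene)) {
    for (pos in sort(unique(info$position[info$gene == g]))) {
      sel <- info$gene == g & info$position == pos & maf > maf_threshold
      if (sum(sel) < 2L) next
      ids <- info$id[sel]
      ord <- order_by_freq(f[ids], info$label[sel])
      ids <- ids[ord]
      out[[length(out) + 1L]] <- data.frame(
        id = paste0("AA_", short_gene(g), "_", pos), gene = g,
        kind = "aa_position_group", position = pos,
        label = info$label[sel][ord][1], members = I(list(ids)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(id = character(), gene = character(), kind = character(),
                      position = integer(), label = character(),
                      members = I(list())))
  do.call(rbind, out)
}

#' Collapse 4-digit classical dosages to 2-digit groups
#'
#' Sums dosages of 4-digit alleles sharing the first (colon-delimited) field
#' of the allele name, e.g. `B*27:05 + B*27:02 -> B*27`. Per-gene dosage
#' totals are preserved.
#'
#' @param classical a [dosage_matrix()] of 4-digit classical alleles.
#' @return a [dosage_matrix()] of `classical_allele_2digit` markers.
#' @export
collapse_to_two_digit <- function(classical) {
  info <- variant_info(classical)
  if (!all(info$kind == "classical_allele_4digit"))
    stop_hfm("collapse requires 4-digit classical alleles only", "hlafinemap_validation_error")
  two <- sub("^([^*]+\\*[^:]+):.*$", "\\1", info$label)
  groups <- unique(data.frame(gene = info$gene, label = two, stringsAsFactors = FALSE))
  groups <- groups[order(groups$gene, groups$label), ]
  cols <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- info$gene == groups$gene[i] & two == groups$label[i]
    rowSums(classical$dosages[, sel, drop = FALSE])
  })
  dm <- do.call(cbind, cols)
  rownames(dm) <- sample_ids(classical)
  meta <- data.frame(id = vapply(groups$label, classical_marker_id, ""),
                     gene = groups$gene, kind = "classical_allele_2digit",
                     position = NA_integer_, label = groups$label,
                     stringsAsFactors = FALSE)
  dosage_matrix(dm, meta)
}

#' Filter markers by pooled minor-allele frequency
#'
#' Retains markers whose pooled (cases + controls) minor-allele frequency is
#' strictly greater than `threshold`, mirroring a post-imputation
#' MAF > 0.1 percent QC step. Multiallelic position groups must be rebuilt
#' afterwards with [group_multiallelic_positions()].
#'
#' @param x a [dosage_matrix()].
#' @param threshold MAF threshold in (0, 0.5); default 0.001.
#' @return the filtered [dosage_matrix()].
#' @export
filter_by_maf <- function(x, threshold = 0.001) {
  if (threshold <= 0 || threshold >= 0.5)
    stop_hfm("threshold must be in (0, 0.5)", "hlafinemap_validation_error")
  f <- allele_frequencies(x)
  keep <- pmin(f, 1 - f) > threshold
  x[, which(keep)]
}
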