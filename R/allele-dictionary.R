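#' Allele-to-protein dictionary
#'
#' An `allele_dictionary` maps classical 4-digit HLA (or HLA-like, e.g. MICA)
#' alleles to the amino-acid residue they carry at each aligned protein
#' position. It is the bridge between allele-level dosages and residue-level
#' markers: every 4-digit allele names a unique protein sequence, so carrying
#' an allele implies carrying its residues.
#'
#' Position numbering follows the mature-protein convention: position 1 is the
#' first residue of the mature protein and positions 5' of it are negative
#' (-1, -2, ...); there is no position 0. Residues are the 20 amino-acid
#' one-letter codes plus `"-"` for an alignment gap/indel, which is treated as
#' one extra residue level at its position.
#'
#' @param entries data.frame with columns `gene`, `allele`, `position`
#'   (integer) and `residue` (single character), one row per (allele,
#'   position).
#' @return An object of class `allele_dictionary`: the validated data.frame.
#' @examples
#' d <- allele_dictionary(data.frame(
#'   gene = "HLA-B",
#'   allele = rep(c("B*27:05", "B*07:02"), each = 2),
#'   position = c(9, 45, 9, 45),
#'   residue = c("H", "E", "Y", "E")))
#' residue_at(d, "B*27:05", 45)
#' @export
allele_dictionary <- function(entries) {
  req <- c("gene", "allele", "position", "residue")
  if (!all(req %in% names(entries)))
    stop_hfm(paste0("dictionary must have columns ", paste(req, collapse = ", ")),
             "hlafinemap_parse_error")
  entries <- entries[req]
  entries$gene <- as.character(entries$gene)
  entries$allele <- as.character(entries$allele)
  entries$residue <- as.character(entries$residue)
  pos <- entries$position
  if (any(is.na(pos)) || any(pos != round(pos)) || any(pos == 0))
    stop_hfm("positions must be non-zero integers (mature-protein numbering)",
             "hlafinemap_validation_error")
  entries$position <- as.integer(pos)
  ok_res <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")
  bad <- !entries$residue %in% ok_res
  if (any(bad))
    stop_hfm(paste0("invalid residue symbol(s): ",
                    paste(unique(entries$residue[bad]), collapse = ", ")),
             "hlafinemap_validation_error")
  if (anyDuplicated(entries[c("gene", "allele", "position")]))
    stop_hfm("duplicate (gene, allele, position) rows", "hlafinemap_validation_error")
  # aligned-protein invariant: within a gene all alleles cover the same positions
  for (g in unique(entries$gene)) {
    sub <- entries[entries$gene == g, ]
    sets <- tapply(sub$position, sub$allele, function(p) paste(sort(p), collapse = ","))
    if (length(unique(sets)) > 1L)
      stop_hfm(paste0("gene ", g, ": alleles cover inconsistent position sets"),
               "hlafinemap_validation_error")
  }
  entries <- entries[order(entries$gene, entries$allele, entries$position), ]
  rownames(entries) <- NULL
  class(entries) <- c("allele_dictionary", "data.frame")
  entries
}

#' Read an allele dictionary from a TSV file
#'
#' Expects a tab-separated file with header `gene allele position residue`
#' and one row per (allele, position), emulating an IMGT-derived protein
#' alignment export.
#'
#' @param path path to the TSV file.
#' @return An [allele_dictionary()].
#' @export
read_allele_dictionary <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  req <- c("gene", "allele", "position", "residue")
  if (!all(req %in% names(raw)))
    stop_hfm(paste0(path, ": expected header with columns ",
                    paste(req, collapse = ", ")), "hlafinemap_parse_error")
  pos <- suppressWarnings(as.numeric(raw$position))
  if (any(is.na(pos) | raw$residue == "" | raw$allele == "")) {
    bad <- which(is.na(pos) | raw$residue == "" | raw$allele == "")[1]
    stop_hfm(paste0(path, ": malformed row at line ", bad + 1L),
             "hlafinemap_parse_error")
  }
  raw$position <- pos
  allele_dictionary(raw)
}

#' @export
print.allele_dictionary <- function(x, ...) {
  genes <- unique(x$gene)
  cat("Allele dictionary:", length(genes), "gene(s)\n")
  for (g in genes) {
    sub <- x[x$gene == g, ]
    cat(sprintf("  %s: %d alleles x %d positions\n", g,
                length(unique(sub$allele)), length(unique(sub$position))))
  }
  invisible(x)
}

#' Look up the residue an allele carries at a position
#'
#' @param dict an [allele_dictionary()].
#' @param allele 4-digit classical allele name, e.g. `"B*27:05"`.
#' @param position integer amino-acid position (mature-protein numbering).
#' @return single-character residue code.
#' @export
residue_at <- function(dict, allele, position) {
  hit <- dict$allele == allele & dict$position == position
  if (!any(hit))
    stop_hfm(paste0("no dictionary entry for ", allele, " at position ", position),
             "hlafinemap_lookup_error")
  dict$residue[hit][1]
}

# genes present in the dictionary
dict_genes <- function(dict) unique(dict$gene)

# alleles of one gene
dict_alleles <- function(dict, gene) unique(dict$allele[dict$gene == gene])

# positions aligned for one gene
dict_positions <- function(dict, gene) sort(unique(dict$position[dict$gene == gene]))
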