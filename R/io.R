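#' Read a dosage matrix from a TSV or VCF file
#'
#' Two dialects are supported. The TSV dialect has a header row of marker IDs
#' with a leading `sample_id` column and one row per sample. The VCF dialect
#' carries one record per marker with a per-sample `DS` (dosage) FORMAT
#' field; marker IDs in either dialect are parsed with [parse_marker_id()]
#' (SNP2HLA-style names such as `HLA_C_0602` or `AA_B_67_S`), and IDs that do
#' not match any dialect are loaded as `kind = "SNP"` with a warning.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return a [dosage_matrix()].
#' @export
read_dosages <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE)
    if (names(tab)[1] != "sample_id")
      stop_hfm(paste0(path, ": first TSV column must be sample_id"),
               "hlafinemap_parse_error")
    ids <- as.character(tab$sample_id)
    D <- as.matrix(tab[-1])
    rownames(D) <- ids
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    D <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    rownames(D) <- vcfR::getID(v)
    D <- t(D)
  }
  if (anyDuplicated(rownames(D)))
    stop_hfm(paste0(path, ": duplicated sample IDs"), "hlafinemap_validation_error")
  bad <- which(apply(D, 2, function(x) any(is.na(x) | x < 0 | x > 2)))
  if (length(bad))
    stop_hfm(paste0(path, ": dosage outside [0,2] or missing in record(s) ",
                    paste(colnames(D)[utils::head(bad, 5)], collapse = ", ")),
             "hlafinemap_validation_error")
  variants <- do.call(rbind, lapply(colnames(D), parse_marker_id))
  n_unparsed <- sum(variants$kind == "SNP" &
                    !grepl("^rs[0-9]+$", variants$id))
  if (n_unparsed > 0)
    warning(n_unparsed, " marker ID(s) not in a recognised dialect; loaded as SNP",
            call. = FALSE)
  dosage_matrix(D, variants)
}

#' Write a dosage matrix to a TSV or VCF file
#'
#' The TSV dialect round-trips exactly through [read_dosages()]. The VCF
#' dialect writes a minimal VCF 4.2 with one record per marker and a
#' per-sample `DS` FORMAT field (REF/ALT are the conventional
#' absence/presence placeholders used for binary HLA markers).
#'
#' @param x a [dosage_matrix()].
#' @param path output file.
#' @param format `"tsv"` or `"vcf"`.
#' @param digits significant digits for dosages.
#' @export
write_dosages <- function(x, path, format = c("tsv", "vcf"), digits = 10) {
  format <- match.arg(format)
  D <- x$dosages
  if (format == "tsv") {
    tab <- data.frame(sample_id = rownames(D),
                      signif(D, digits), check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", rownames(D)), collapse = "\t")), con)
    info <- variant_info(x)
    for (j in seq_len(ncol(D))) {
      pos <- if (is.na(info$position[j])) j else info$position[j]
      writeLines(paste(c("6", pos, info$id[j], "A", "P", ".", "PASS", ".",
                         "DS", format(signif(D[, j], digits), trim = TRUE,
                                      scientific = FALSE)),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read best-guess classical-allele calls
#'
#' A best-guess call names the two most probable classical alleles per gene
#' per individual. Expected TSV columns: `sample_id`, `gene`, `allele1`,
#' `allele2` (4-digit names; 2-digit names are derived by truncation).
#'
#' @param path TSV file.
#' @return data.frame of calls.
#' @export
read_best_guess <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "gene", "allele1", "allele2")
  if (!all(req %in% names(tab)))
    stop_hfm(paste0(path, ": expected columns ", paste(req, collapse = ", ")),
             "hlafinemap_parse_error")
  if (anyDuplicated(tab[c("sample_id", "gene")]))
    stop_hfm(paste0(path, ": more than one call per sample per gene"),
             "hlafinemap_validation_error")
  tab
}

two_digit_name <- function(allele) sub("^([^*]+\\*[^:]+):.*$", "\\1", allele)

#' Imputation concordance between best-guess call sets
#'
#' Per sample per gene, the two allele slots of the imputed call are matched
#' against the typed call under the best order-insensitive pairing;
#' concordance is matched slots / total slots x 100. At 2-digit resolution
#' alleles are truncated to their first name field before comparison. The
#' measure is symmetric in its two arguments.
#'
#' @param imputed,typed best-guess call data.frames ([read_best_guess()]
#'   layout).
#' @param resolution `"4digit"` (default) or `"2digit"`.
#' @return concordance percentage in `[0, 100]`.
#' @export
concordance <- function(imputed, typed, resolution = c("4digit", "2digit")) {
  resolution <- match.arg(resolution)
  key <- function(t) paste(t$sample_id, t$gene, sep = "\r")
  common <- intersect(key(imputed), key(typed))
  if (!length(common))
    stop_hfm("no overlapping (sample, gene) calls", "hlafinemap_validation_error")
  a <- imputed[match(common, key(imputed)), ]
  b <- typed[match(common, key(typed)), ]
  trunc2 <- function(x) if (resolution == "2digit") two_digit_name(x) else x
  a1 <- trunc2(a$allele1); a2 <- trunc2(a$allele2)
  b1 <- trunc2(b$allele1); b2 <- trunc2(b$allele2)
  matched <- pmax((a1 == b1) + (a2 == b2), (a1 == b2) + (a2 == b1))
  100 * sum(matched) / (2 * length(common))
}

#' Write an analysis result table with a run manifest
#'
#' Serialises a result object (`hla_scan`, `hla_mvfit`, `hla_het`,
#' `hla_stepwise` or a plain data.frame) as a TSV with deterministic column
#' order and fixed float precision, plus a JSON sidecar manifest
#' (`<path>.manifest.json`) recording the package version, thresholds and
#' any caller-supplied configuration; reruns on identical inputs produce
#' byte-identical files.
#'
#' @param x result object.
#' @param path output TSV path.
#' @param manifest named list of extra manifest entries (e.g. config, seed).
#' @param digits significant digits for floats.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, manifest = list(), digits = 6) {
  tab <- result_table(x)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) signif(v, digits))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  man <- c(list(package = "hlafinemap",
                version = as.character(utils::packageVersion("hlafinemap")),
                result_class = class(x)[1], rows = nrow(tab)),
           manifest)
  jsonlite::write_json(man, paste0(path, ".manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

# flatten result objects to a data.frame for serialisation
result_table <- function(x) {
  if (inherits(x, "hla_mvfit")) return(x$table)
  if (inherits(x, "hla_stepwise")) return(x$trace)
  if (inherits(x, "hla_het"))
    return(data.frame(gene = x$gene, allele = x$alleles,
                      beta_psa = x$beta_psa, var_psa = x$var_psa,
                      beta_psc = x$beta_psc, var_psc = x$var_psc,
                      statistic = x$statistic, df = x$df, p = x$p,
                      threshold = x$threshold, stringsAsFactors = FALSE))
  if (is.data.frame(x)) return(as.data.frame(x))
  stop_hfm(paste0("cannot serialise object of class ", class(x)[1]),
           "hlafinemap_validation_error")
}

#' Read / write a simulation configuration as YAML
#'
#' Serialises a [sim_config()] to a structured YAML file and back, including
#' allele-frequency tables, coupling matrices, the allele dictionary and the
#' effect tables, so simulated studies can be described as plain text.
#'
#' @param config a [sim_config()].
#' @param path YAML file path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  ser_eff <- function(e) if (is.null(e)) NULL else as.list(as.data.frame(e))
  obj <- list(
    genes = lapply(config$genes, as.list),
    coupling = lapply(config$coupling, function(m)
      c(list(.parent_alleles = rownames(m), .child_alleles = colnames(m)),
        list(values = as.vector(t(m))))),
    dictionary = if (is.null(config$dictionary)) NULL
                 else as.list(as.data.frame(unclass(config$dictionary))),
    effects_disease = ser_eff(config$effects_disease),
    effects_subtype = ser_eff(config$effects_subtype),
    prevalence = config$prevalence, n_case = config$n_case,
    n_control = config$n_control, collections = config$collections,
    shift_sd = config$shift_sd, n_pcs = config$n_pcs,
    pc_shift = config$pc_shift, psa_fraction = config$psa_fraction,
    unknown_fraction = config$unknown_fraction)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  genes <- lapply(obj$genes, unlist)
  coupling <- lapply(obj$coupling, function(cp) {
    m <- matrix(unlist(cp$values), nrow = length(cp$.parent_alleles),
                byrow = TRUE,
                dimnames = list(cp$.parent_alleles, cp$.child_alleles))
    m
  })
  de_eff <- function(e) if (is.null(e)) NULL
            else as.data.frame(e, stringsAsFactors = FALSE)
  dict <- if (is.null(obj$dictionary)) NULL
          else allele_dictionary(as.data.frame(obj$dictionary,
                                               stringsAsFactors = FALSE))
  sim_config(genes = genes, coupling = coupling, dictionary = dict,
             effects_disease = de_eff(obj$effects_disease),
             effects_subtype = de_eff(obj$effects_subtype),
             prevalence = obj$prevalence, n_case = obj$n_case,
             n_control = obj$n_control, collections = obj$collections,
             shift_sd = obj$shift_sd, n_pcs = obj$n_pcs,
             pc_shift = obj$pc_shift, psa_fraction = obj$psa_fraction,
             unknown_fraction = obj$unknown_fraction)
}
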