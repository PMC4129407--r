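test_that("dictionary TSV reads back and validates the aligned-protein invariant", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(toy_dict_df(), path, sep = "\t", quote = FALSE, row.names = FALSE)
  d <- read_allele_dictionary(path)
  expect_s3_class(d, "allele_dictionary")
  expect_equal(length(unique(d$allele)), 2L)
  expect_equal(sort(unique(d$position)), c(9L, 45L, 67L))
  expect_equal(residue_at(d, "B*27:05", 45), "E")  # B*27:05 carries Glu at 45

  # inconsistent position coverage across alleles is rejected, naming the gene
  bad <- toy_dict_df()[-6, ]  # drop one B*07:02 position
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_allele_dictionary(path), "HLA-B",
               class = "hlafinemap_validation_error")

  # malformed row reported with its line number
  txt <- readLines(path)
  txt[3] <- "HLA-B\tB*27:05\tnot_a_number\tE"
  writeLines(txt, path)
  expect_error(read_allele_dictionary(path), "line 3",
               class = "hlafinemap_parse_error")
})

test_that("dictionary rejects bad residues, position zero, duplicates", {
  df <- toy_dict_df()
  df$residue[1] <- "Z"
  expect_error(allele_dictionary(df), class = "hlafinemap_validation_error")
  df <- toy_dict_df()
  df$position[1] <- 0
  expect_error(allele_dictionary(df), class = "hlafinemap_validation_error")
  df <- rbind(toy_dict_df(), toy_dict_df()[1, ])
  expect_error(allele_dictionary(df), class = "hlafinemap_validation_error")
  # gap symbol is a legal residue level
  df <- toy_dict_df(); df$residue[2] <- "-"
  expect_s3_class(allele_dictionary(df), "allele_dictionary")
})

test_that("residue expansion is linear, conserves dosage, handles fractions", {
  d <- toy_dict()
  # homozygous B*27:05: Glu45 dosage 2, the alternative Lys45 dosage 0
  hom <- classical_dm(cbind("B*27:05" = 2, "B*07:02" = 0))
  r <- expand_to_residue_dosages(hom, d)
  expect_equal(unname(r$dosages[1, "AA_B_45_E"]), 2)
  expect_equal(unname(r$dosages[1, "AA_B_45_K"]), 0)
  # fractional imputed dosages propagate linearly
  fr <- classical_dm(cbind("B*27:05" = 0.6, "B*07:02" = 1.4))
  rf <- expand_to_residue_dosages(fr, d)
  expect_equal(unname(rf$dosages[1, "AA_B_45_E"]), 0.6)
  expect_equal(unname(rf$dosages[1, "AA_B_45_K"]), 1.4)
  expect_equal(sum(rf$dosages[1, c("AA_B_45_E", "AA_B_45_K")]), 2)
  # allele absent from the dictionary is reported by name
  unknown <- classical_dm(cbind("B*15:01" = 2))
  expect_error(expand_to_residue_dosages(unknown, d), "B\\*15:01",
               class = "hlafinemap_lookup_error")
})

test_that("residue dosages match a brute-force per-individual oracle", {
  cfg <- psv_sim_config()
  cls <- random_classical(50, cfg$genes[["HLA-B"]], seed = 42)
  d <- cfg$dictionary
  r <- expand_to_residue_dosages(cls, d)
  info <- variant_info(r)
  cinfo <- variant_info(cls)
  # oracle: explicit loop over individuals, alleles and dictionary entries
  for (j in seq_len(ncol(r$dosages))) {
    carriers <- d$allele[d$gene == info$gene[j] & d$position == info$position[j] &
                         d$residue == info$label[j]]
    expected <- rowSums(cls$dosages[, cinfo$id[cinfo$label %in% carriers],
                                    drop = FALSE])
    expect_equal(unname(r$dosages[, j]), unname(expected))
  }
  # hard calls stay integral; per-position totals are 2
  expect_true(all(r$dosages %in% 0:2))
  for (pos in unique(info$position)) {
    tot <- rowSums(r$dosages[, info$position == pos, drop = FALSE])
    expect_equal(unname(tot), rep(2, 50))
  }
  # linearity of the expansion map
  cls2 <- random_classical(50, cfg$genes[["HLA-B"]], seed = 43)
  mix <- dosage_matrix(0.3 * cls$dosages + 0.7 * cls2$dosages, variant_info(cls))
  rmix <- expand_to_residue_dosages(mix, d)
  expect_equal(rmix$dosages,
               0.3 * r$dosages + 0.7 * expand_to_residue_dosages(cls2, d)$dosages)
})

test_that("multiallelic grouping orders members by frequency and drops monomorphs", {
  # residue frequencies 0.42 / 0.16 / 0.12 at one position (plus complement)
  n <- 500
  set.seed(9)
  h <- replicate(2, sample(c("S", "C", "M", "F"), n, TRUE,
                           prob = c(0.42, 0.16, 0.12, 0.30)))
  D <- sapply(c("S", "C", "M", "F"), function(r) (h[, 1] == r) + (h[, 2] == r))
  meta <- data.frame(id = paste0("AA_B_67_", colnames(D)), gene = "HLA-B",
                     kind = "aa_residue", position = 67L, label = colnames(D))
  colnames(D) <- meta$id
  resid <- dosage_matrix(D, meta)
  g <- group_multiallelic_positions(resid)
  expect_equal(nrow(g), 1L)
  expect_equal(g$label, "S")                       # reference = most frequent
  expect_equal(g$members[[1]][1], "AA_B_67_S")
  f <- allele_frequencies(resid)
  expect_equal(g$members[[1]], names(sort(-f)))    # descending frequency
  # a monomorphic position is omitted; m - 1 tested members for m = 3
  mono <- dosage_matrix(cbind(AA_B_9_Y = rep(2, n)),
                        data.frame(id = "AA_B_9_Y", gene = "HLA-B",
                                   kind = "aa_residue", position = 9L,
                                   label = "Y"))
  expect_equal(nrow(group_multiallelic_positions(mono)), 0L)
  three <- resid[, 1:3]
  g3 <- group_multiallelic_positions(three)
  expect_equal(length(g3$members[[1]]) - 1L, 2L)
})

test_that("two-digit collapse preserves per-gene totals and matches group sums", {
  cls <- classical_dm(cbind("B*27:05" = 1, "B*27:02" = 1, "B*07:02" = 0))
  two <- collapse_to_two_digit(cls)
  expect_equal(unname(two$dosages[1, "HLA_B_27"]), 2)
  expect_equal(unname(two$dosages[1, "HLA_B_07"]), 0)
  # 20-allele toy gene: collapse equals brute-force group sums
  set.seed(4)
  labs <- paste0("B*", rep(sprintf("%02d", 1:5), each = 4), ":",
                 sprintf("%02d", rep(1:4, 5)))
  f <- as.numeric(rmultinom(1, 1000, rep(1, 20))) / 1000
  names(f) <- labs
  big <- random_classical(100, f, seed = 5)
  two <- collapse_to_two_digit(big)
  info4 <- variant_info(big)
  for (grp in unique(sub(":.*", "", labs))) {
    sel <- startsWith(info4$label, paste0(grp, ":"))
    expect_equal(
      unname(two$dosages[, hlafinemap:::classical_marker_id(grp)]),
      unname(rowSums(big$dosages[, sel, drop = FALSE])))
  }
  expect_equal(rowSums(two$dosages), rowSums(big$dosages))
})

test_that("dosage matrix validates ranges, IDs and parses SNP2HLA names", {
  expect_error(dosage_matrix(matrix(c(0, 2.5), 1), data.frame(
    id = c("a", "b"), gene = NA, kind = "SNP", position = NA, label = NA)),
    class = "hlafinemap_validation_error")
  p <- parse_marker_id("AA_B_45_Glu")
  expect_equal(p$gene, "HLA-B")
  expect_equal(p$kind, "aa_residue")
  expect_equal(p$position, 45L)
  expect_equal(p$label, "Glu")
  expect_equal(parse_marker_id("HLA_C_0602")$label, "C*06:02")
  expect_equal(parse_marker_id("HLA_C_06")$kind, "classical_allele_2digit")
  expect_equal(parse_marker_id("MICA_00801")$label, "MICA*008:01")
  expect_equal(parse_marker_id("rs9264942")$kind, "SNP")
})
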