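# Builders for tiny in-code cohorts.

mk_ped <- function(n_trios = 1, n_singletons = 0, n_controls = 0) {
  rows <- list()
  for (t in seq_len(n_trios)) {
    p <- sprintf("P%d", t); f <- sprintf("FA%d", t); m <- sprintf("MO%d", t)
    fam <- sprintf("F%d", t)
    rows[[length(rows) + 1]] <- tibble::tibble(
      family_id = fam, sample_id = c(p, f, m),
      father_id = c(f, "0", "0"), mother_id = c(m, "0", "0"),
      sex = c(1L, 1L, 2L), phenotype = c(2L, 1L, 1L),
      role = c("proband", "father", "mother"))
  }
  for (s in seq_len(n_singletons)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      family_id = sprintf("FS%d", s), sample_id = sprintf("S%d", s),
      father_id = "0", mother_id = "0", sex = 1L, phenotype = 2L,
      role = "singleton")
  }
  for (c in seq_len(n_controls)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      family_id = sprintf("C%d", c), sample_id = sprintf("C%d", c),
      father_id = "0", mother_id = "0", sex = 0L, phenotype = 1L,
      role = "control")
  }
  dplyr::bind_rows(rows)
}

mk_variants <- function(n, chrom = "1", ref = "A", alt = "G") {
  tibble::tibble(chrom = chrom, pos = seq_len(n) * 100L,
                 ref = ref, alt = alt, filter = "PASS") |>
    dplyr::mutate(variant_id = paste(chrom, pos, ref, alt, sep = ":")) |>
    dplyr::select(variant_id, chrom, pos, ref, alt, filter)
}

# one genotype row; ad defaults consistent with the gt
mk_gt <- function(variant_id, sample_id, gt, gq = 99, dp = 40,
                  ad_alt = NULL, ad_ref = NULL) {
  if (is.null(ad_alt)) ad_alt <- switch(gt, hom_ref = 0, het = dp / 2,
                                        hom_alt = dp, missing = NA_real_)
  if (is.null(ad_ref)) ad_ref <- if (is.na(ad_alt)) NA_real_ else dp - ad_alt
  tibble::tibble(variant_id = variant_id, sample_id = sample_id, gt = gt,
                 gq = gq, dp = dp, ad_ref = ad_ref, ad_alt = ad_alt)
}

mk_cohort <- function(variants, genotypes, ped) {
  # fill unspecified genotypes as confident hom_ref so sites pass missingness
  full <- tidyr::expand_grid(variant_id = variants$variant_id,
                             sample_id = ped$sample_id) |>
    dplyr::anti_join(genotypes, by = c("variant_id", "sample_id")) |>
    dplyr::mutate(gt = "hom_ref", gq = 99, dp = 40, ad_ref = 40, ad_alt = 0)
  trioscreen:::new_cohort(variants = variants,
                          genotypes = dplyr::bind_rows(genotypes, full),
                          pedigree = ped, samples = ped$sample_id)
}

mk_ann <- function(variants, gene = "GENEA", consequence = "missense",
                   pop_af = 0, dann = 0.5, dann_rank = 0.5,
                   splice_ada = NA_real_, plp_label = NA_character_) {
  tibble::tibble(variant_id = variants$variant_id, chrom = variants$chrom,
                 pos = variants$pos, ref = variants$ref, alt = variants$alt,
                 gene = gene, consequence = consequence, pop_af = pop_af,
                 dann = dann, dann_rank = dann_rank, splice_ada = splice_ada,
                 plp_label = plp_label) |>
    classify_variants()
}

mk_gene_table <- function(genes, chrom = "1", pli = 0.99,
                          brain_expressed = TRUE, skeletal_expressed = TRUE) {
  tibble::tibble(gene = genes, chrom = chrom, pli = pli,
                 brain_expressed = brain_expressed,
                 skeletal_expressed = skeletal_expressed,
                 mu_syn = 1e-5, mu_mis = 2e-5, mu_lgd = 4e-6)
}

write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"GQ\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">")
  writeLines(c(header, lines), path)
  path
}

write_test_ped <- function(df, path = tempfile(fileext = ".ped")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# qualifying-variant row builder for screen-level tests
mk_qual <- function(sample_id, gene, vid, origin = "unknown", lgd = FALSE,
                    dann_rank = 0.9) {
  tibble::tibble(sample_id = sample_id, gene = gene, variant_id = vid,
                 chrom = "1", pos = 1L, ref = "A", alt = "G",
                 consequence = ifelse(lgd, "nonsense", "missense"),
                 dann = 0.99, dann_rank = dann_rank, splice_ada = NA_real_,
                 lgd = lgd, dmis = !lgd, origin = origin)
}
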