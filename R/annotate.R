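CONSEQUENCE_LEVELS <- c("synonymous", "missense", "inframe", "frameshift",
                        "splice_site", "nonsense", "other")

#' Load a per-variant annotation table
#'
#' The table stands in for an upstream annotation run (gene model,
#' consequence, population allele frequency, missense and splice
#' deleteriousness scores, optional curated P/LP labels). It is keyed exactly
#' on `chrom, pos, ref, alt`.
#'
#' @param path TSV with header columns `chrom, pos, ref, alt, gene,
#'   consequence, pop_af, dann, dann_rank, splice_ada, plp_label`.
#' @return a validated tibble with an added `variant_id` key column.
#' @export
load_annotations <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           pos = readr::col_integer(),
                           ref = readr::col_character(),
                           alt = readr::col_character(),
                           gene = readr::col_character(),
                           consequence = readr::col_character(),
                           pop_af = readr::col_double(),
                           dann = readr::col_double(),
                           dann_rank = readr::col_double(),
                           splice_ada = readr::col_double(),
                           plp_label = readr::col_character()))
  validate_annotations(ann)
}

#' @rdname load_annotations
#' @param ann an in-memory annotation tibble to validate.
#' @export
validate_annotations <- function(ann) {
  stopifnot_cols(ann, c("chrom", "pos", "ref", "alt", "gene", "consequence",
                        "pop_af", "dann", "dann_rank"), "annotation table")
  if (!"splice_ada" %in% names(ann)) ann$splice_ada <- NA_real_
  if (!"plp_label" %in% names(ann)) ann$plp_label <- NA_character_
  ann$variant_id <- variant_id(ann$chrom, ann$pos, ann$ref, ann$alt)
  dup <- duplicated(ann$variant_id)
  if (any(dup)) {
    stop("duplicate annotation rows for key(s): ",
         paste(head(unique(ann$variant_id[dup]), 5), collapse = ", "),
         call. = FALSE)
  }
  for (col in c("pop_af", "dann", "dann_rank", "splice_ada")) {
    bad <- which(!is.na(ann[[col]]) & (ann[[col]] < 0 | ann[[col]] > 1))
    if (length(bad) > 0) {
      stop(sprintf("malformed %s (outside [0,1]) at row %d (%s)",
                   col, bad[1], ann$variant_id[bad[1]]), call. = FALSE)
    }
  }
  bad_cons <- !ann$consequence %in% CONSEQUENCE_LEVELS
  if (any(bad_cons)) {
    stop("unknown consequence at row ", which(bad_cons)[1], ": ",
         ann$consequence[which(bad_cons)[1]], call. = FALSE)
  }
  tibble::as_tibble(ann)
}

#' Join cohort variants to their annotations
#'
#' Exact join on `chrom, pos, ref, alt`. Variants without an annotation row
#' are reported in the `unannotated` attribute and excluded from the returned
#' table (downstream analyses require annotation).
#'
#' @param variants the `variants` tibble of a `trio_cohort`.
#' @param ann annotation tibble from [load_annotations()].
#' @return annotated variants tibble with classification columns `lgd`,
#'   `dmis` added; attribute `unannotated` holds the unmatched variants.
#' @export
annotate_variants <- function(variants, ann) {
  joined <- dplyr::inner_join(
    variants, dplyr::select(ann, -dplyr::any_of(c("chrom", "pos", "ref", "alt"))),
    by = "variant_id")
  missed <- variants[!variants$variant_id %in% ann$variant_id, ]
  if (nrow(missed) > 0) {
    rlang::inform(sprintf("%d variant(s) had no annotation row and were excluded",
                          nrow(missed)))
  }
  joined <- classify_variants(joined)
  attr(joined, "unannotated") <- missed
  joined
}

#' Functional classification predicates
#'
#' `is_lgd()`: likely gene-disrupting — frameshift or nonsense consequences,
#' or splice-site variants whose splice deleteriousness (ADA) score exceeds
#' 0.9 (strict). A splice-site variant without an ADA score is not LGD.
#' `is_dmis()`: deleterious missense — missense with DANN score above 0.98
#' (strict). `is_rare()`: population allele frequency strictly below
#' `maf_max`; an absent frequency is treated as 0 (allele unseen in the
#' reference panel). The LGD and D-mis categories are disjoint by
#' construction.
#'
#' @param consequence character vector of consequence classes.
#' @param splice_ada,dann,pop_af numeric score vectors (NA allowed).
#' @param maf_max rarity threshold: 0.005 for the digenic screen, 0.001 for
#'   de novo calling.
#' @return logical vector.
#' @export
is_lgd <- function(consequence, splice_ada = NA_real_) {
  consequence %in% c("frameshift", "nonsense") |
    (consequence == "splice_site" & !is.na(splice_ada) & splice_ada > 0.9)
}

#' @rdname is_lgd
#' @export
is_dmis <- function(consequence, dann) {
  consequence == "missense" & !is.na(dann) & dann > 0.98
}

#' @rdname is_lgd
#' @export
is_rare <- function(pop_af, maf_max = 0.005) {
  is.na(pop_af) | pop_af < maf_max
}

#' Add `lgd` and `dmis` columns to an annotated variant table
#'
#' @param ann annotated variants (must carry `consequence`, `dann`,
#'   `splice_ada`).
#' @return the input with logical columns `lgd` and `dmis`.
#' @export
classify_variants <- function(ann) {
  ann$lgd <- is_lgd(ann$consequence, ann$splice_ada)
  ann$dmis <- is_dmis(ann$consequence, ann$dann)
  ann
}

#' Load the per-gene information table
#'
#' @param path TSV with columns `gene, chrom, pli, brain_expressed,
#'   skeletal_expressed, mu_syn, mu_mis, mu_lgd` (per-generation mutation
#'   rates by consequence class).
#' @return validated tibble; duplicate gene symbols on different chromosomes
#'   are a hard error.
#' @export
load_gene_table <- function(path) {
  genes <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             gene = readr::col_character(),
                             chrom = readr::col_character(),
                             pli = readr::col_double(),
                             brain_expressed = readr::col_logical(),
                             skeletal_expressed = readr::col_logical(),
                             mu_syn = readr::col_double(),
                             mu_mis = readr::col_double(),
                             mu_lgd = readr::col_double()))
  validate_gene_table(genes)
}

#' @rdname load_gene_table
#' @param genes in-memory gene tibble to validate.
#' @export
validate_gene_table <- function(genes) {
  stopifnot_cols(genes, c("gene", "chrom", "pli"), "gene table")
  genes$gene <- norm_gene(genes$gene)
  dup <- genes |>
    dplyr::distinct(.data$gene, .data$chrom) |>
    dplyr::count(.data$gene) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("gene symbol(s) on multiple chromosomes: ",
         paste(dup$gene, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(genes)
}
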