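#' Configuration for the digenic screen
#'
#' @param pli_min haploinsufficiency threshold; genes qualify with
#'   `pli > pli_min` (strict).
#' @param maf_max strict rarity ceiling for qualifying variants.
#' @param require_biparental restrict trio probands' pairs to variant couples
#'   drawn from both parental haplotypes (one allele from the father, one from
#'   the mother, a de novo allele counting as either). Proband-only samples
#'   are never restricted: origin is unknowable without parents.
#' @param zone_cutoffs three increasing score cutoffs delimiting the four
#'   confidence zones `neutral < candidate < zone99 < zone999`; the built-in
#'   stand-in scorer is calibrated to [0, 1].
#' @param expression_required drop pairs unless both genes have brain or
#'   skeletal expression.
#' @return a `screen_config` list.
#' @export
screen_config <- function(pli_min = 0.9, maf_max = 0.005,
                          require_biparental = TRUE,
                          zone_cutoffs = c(candidate = 0.5, zone99 = 0.7,
                                           zone999 = 0.85),
                          expression_required = TRUE) {
  stopifnot(length(zone_cutoffs) == 3, !is.unsorted(zone_cutoffs),
            maf_max > 0, maf_max < 1)
  structure(list(pli_min = pli_min, maf_max = maf_max,
                 require_biparental = require_biparental,
                 zone_cutoffs = zone_cutoffs,
                 expression_required = expression_required),
            class = "screen_config")
}

#' Select haploinsufficient autosomal genes
#'
#' @param gene_table tibble with `gene`, `chrom`, `pli`.
#' @param pli_min strict lower pLI bound (default 0.9).
#' @return character vector of qualifying gene symbols (autosomes 1-22 only;
#'   genes with missing pLI are skipped with a message).
#' @export
select_hi_genes <- function(gene_table, pli_min = 0.9) {
  gene_table <- validate_gene_table(gene_table)
  no_pli <- is.na(gene_table$pli)
  if (any(no_pli)) {
    rlang::inform(sprintf("%d gene(s) without pLI skipped", sum(no_pli)))
  }
  keep <- !no_pli & gene_table$pli > pli_min & is_autosome(gene_table$chrom)
  sort(gene_table$gene[keep])
}

#' Collect qualifying heterozygous variants for a set of samples
#'
#' A variant qualifies for the digenic model when it is heterozygous in the
#' carrier, rare (population frequency strictly below `maf_max`), LGD or
#' D-mis, and lies in a haploinsufficient autosomal gene. The digenic model is
#' additive haploinsufficiency, so homozygous-alt genotypes are excluded
#' (reported separately upstream if desired). For trio probands the parental
#' origin of each variant is inferred from the parents' genotypes: carried by
#' exactly one parent gives that parent, by neither gives `denovo`, by both
#' (or with no usable trio) gives `unknown`.
#'
#' @param cohort a QC-filtered `trio_cohort`.
#' @param ann annotated variants (with `lgd`/`dmis` columns, see
#'   [classify_variants()]).
#' @param gene_table gene info tibble.
#' @param samples sample IDs to collect for; default all probands and
#'   singletons.
#' @param config a [screen_config()].
#' @return tibble with one row per (carrier, qualifying variant): `sample_id`,
#'   `gene`, `variant_id`, coordinates, scores, `lgd`, `dmis`, `origin`.
#' @export
collect_qualifying <- function(cohort, ann, gene_table, samples = NULL,
                               config = screen_config()) {
  if (is.null(samples)) {
    samples <- cohort$pedigree$sample_id[
      cohort$pedigree$role %in% c("proband", "singleton")]
  }
  if (!"lgd" %in% names(ann)) ann <- classify_variants(ann)
  hi <- select_hi_genes(gene_table, config$pli_min)

  qual_var <- ann |>
    dplyr::mutate(gene = norm_gene(.data$gene)) |>
    dplyr::filter(is_rare(.data$pop_af, config$maf_max),
                  .data$lgd | .data$dmis,
                  .data$gene %in% hi)

  hets <- cohort$genotypes |>
    dplyr::filter(.data$sample_id %in% samples, .data$gt == "het") |>
    dplyr::inner_join(
      dplyr::select(qual_var, "variant_id", "gene", "chrom", "pos", "ref",
                    "alt", "consequence", "dann", "dann_rank", "splice_ada",
                    "lgd", "dmis"),
      by = "variant_id")

  # parental origin for trio probands
  trios <- ped_trios(cohort$pedigree)
  carrier_of <- function(parent_ids) {
    cohort$genotypes |>
      dplyr::filter(.data$sample_id %in% parent_ids) |>
      dplyr::transmute(.data$variant_id, parent = .data$sample_id,
                       carrier = .data$gt %in% c("het", "hom_alt"),
                       usable = .data$gt != "missing")
  }
  fa <- carrier_of(trios$father) |>
    dplyr::inner_join(dplyr::select(trios, "proband", parent = "father"),
                      by = "parent") |>
    dplyr::select("variant_id", sample_id = "proband",
                  f_carrier = "carrier", f_usable = "usable")
  mo <- carrier_of(trios$mother) |>
    dplyr::inner_join(dplyr::select(trios, "proband", parent = "mother"),
                      by = "parent") |>
    dplyr::select("variant_id", sample_id = "proband",
                  m_carrier = "carrier", m_usable = "usable")

  hets |>
    dplyr::left_join(fa, by = c("variant_id", "sample_id")) |>
    dplyr::left_join(mo, by = c("variant_id", "sample_id")) |>
    dplyr::mutate(origin = dplyr::case_when(
      is.na(.data$f_usable) | is.na(.data$m_usable) ~ "unknown",
      !.data$f_usable | !.data$m_usable ~ "unknown",
      .data$f_carrier & !.data$m_carrier ~ "paternal",
      !.data$f_carrier & .data$m_carrier ~ "maternal",
      !.data$f_carrier & !.data$m_carrier ~ "denovo",
      TRUE ~ "unknown")) |>
    dplyr::select("sample_id", "gene", "variant_id", "chrom", "pos", "ref",
                  "alt", "consequence", "dann", "dann_rank", "splice_ada",
                  "lgd", "dmis", "origin") |>
    dplyr::arrange(.data$sample_id, .data$gene, .data$chrom, .data$pos)
}

# a couple satisfies the biparental (two-haplotype) rule when its two origins
# cover both parental sides, a de novo allele counting as either side
biparental_ok <- function(origin_a, origin_b) {
  known <- origin_a != "unknown" & origin_b != "unknown"
  known &
    !(origin_a == "paternal" & origin_b == "paternal") &
    !(origin_a == "maternal" & origin_b == "maternal")
}

#' Enumerate per-proband digenic gene pairs
#'
#' Builds every unordered gene pair with at least one qualifying variant in
#' each gene, carrying all supporting variant couples as evidence. With the
#' biparental restriction, evidence couples must draw one allele from each
#' parental haplotype; pairs left without evidence are dropped.
#'
#' @param qualifying tibble from [collect_qualifying()].
#' @param biparental_samples sample IDs whose couples are origin-restricted
#'   (normally the trio probands); others pair without restriction.
#' @return tibble of evidence couples: `sample_id`, `gene_a < gene_b`,
#'   variant keys, origins and per-variant deleterious weights.
#' @export
enumerate_pairs <- function(qualifying, biparental_samples = character()) {
  if (nrow(qualifying) == 0) return(empty_couples())
  q <- qualifying |>
    dplyr::mutate(d = ifelse(.data$lgd, 1.0, .data$dann_rank))
  left <- dplyr::select(q, "sample_id", gene_a = "gene",
                        variant_a = "variant_id", origin_a = "origin",
                        d_a = "d")
  right <- dplyr::select(q, "sample_id", gene_b = "gene",
                         variant_b = "variant_id", origin_b = "origin",
                         d_b = "d")
  couples <- dplyr::inner_join(left, right, by = "sample_id",
                               relationship = "many-to-many") |>
    dplyr::filter(.data$gene_a < .data$gene_b)
  restricted <- couples$sample_id %in% biparental_samples
  keep <- !restricted | biparental_ok(couples$origin_a, couples$origin_b)
  couples[keep, ] |>
    dplyr::arrange(.data$sample_id, .data$gene_a, .data$gene_b,
                   .data$variant_a, .data$variant_b)
}

empty_couples <- function() {
  tibble::tibble(sample_id = character(), gene_a = character(),
                 gene_b = character(), variant_a = character(),
                 variant_b = character(), origin_a = character(),
                 origin_b = character(), d_a = double(), d_b = double())
}

#' Gene-level qualifying hits of unaffected individuals
#'
#' @param cohort a QC-filtered `trio_cohort`.
#' @param ann annotated variants.
#' @param gene_table gene info tibble.
#' @param config a [screen_config()].
#' @return distinct (`sample_id`, `gene`) tibble over parents and controls.
#' @export
unaffected_gene_hits <- function(cohort, ann, gene_table,
                                 config = screen_config()) {
  unaffected <- cohort$pedigree$sample_id[
    cohort$pedigree$role %in% c("father", "mother", "control")]
  collect_qualifying(cohort, ann, gene_table, samples = unaffected,
                     config = config) |>
    dplyr::distinct(.data$sample_id, .data$gene)
}

#' Exclude pairs observed in unaffected individuals
#'
#' A pair (A, B) is dropped when any single unaffected individual (parent or
#' population control) carries at least one qualifying variant in A *and* one
#' in B. Exclusion operates at the gene-pair level, the conservative reading
#' that minimizes false positives; it is anti-monotone in the control set.
#'
#' @param pairs tibble with `gene_a`, `gene_b` (one row per proband-pair).
#' @param unaffected_hits tibble from [unaffected_gene_hits()].
#' @return `pairs` with a logical column `excluded`.
#' @export
exclude_unaffected_pairs <- function(pairs, unaffected_hits) {
  if (nrow(pairs) == 0) {
    pairs$excluded <- logical(0)
    return(pairs)
  }
  hit_pairs <- unaffected_hits |>
    dplyr::distinct(.data$sample_id, .data$gene) |>
    dplyr::inner_join(dplyr::rename(unaffected_hits, gene2 = "gene"),
                      by = "sample_id", relationship = "many-to-many") |>
    dplyr::filter(.data$gene < .data$gene2) |>
    dplyr::distinct(gene_a = .data$gene, gene_b = .data$gene2)
  pairs$excluded <- paste(pairs$gene_a, pairs$gene_b) %in%
    paste(hit_pairs$gene_a, hit_pairs$gene_b)
  pairs
}

#' Score pairs and assign confidence zones
#'
#' The built-in stand-in scorer takes, for the best evidence couple, the mean
#' per-variant deleterious weight (1.0 for LGD, the DANN rank score for
#' D-mis) times the mean pLI of the two genes; it is a transparent
#' placeholder for an external combination-pathogenicity predictor, and an
#' externally supplied score overrides it verbatim.
#'
#' @param couples evidence couples from [enumerate_pairs()].
#' @param gene_table gene info tibble (for pLI).
#' @param config a [screen_config()] (zone cutoffs).
#' @param external_scores optional tibble (`sample_id`, `gene_a`, `gene_b`,
#'   `score`) overriding the stand-in.
#' @return pair-level tibble: `sample_id`, `gene_a`, `gene_b`, `n_couples`,
#'   `score`, `zone`, evidence strings `variants_a`/`variants_b`, `origins`.
#' @export
score_pairs <- function(couples, gene_table, config = screen_config(),
                        external_scores = NULL) {
  gene_table <- validate_gene_table(gene_table)
  pli <- setNames(gene_table$pli, gene_table$gene)
  if (nrow(couples) == 0) {
    return(tibble::tibble(sample_id = character(), gene_a = character(),
                          gene_b = character(), n_couples = integer(),
                          score = double(), zone = character(),
                          variants_a = character(), variants_b = character(),
                          origins = character()))
  }
  couples$couple_score <- 0.5 * (couples$d_a + couples$d_b) *
    0.5 * (pli[couples$gene_a] + pli[couples$gene_b])
  pairs <- couples |>
    dplyr::group_by(.data$sample_id, .data$gene_a, .data$gene_b) |>
    dplyr::summarise(
      n_couples = dplyr::n(),
      score = max(.data$couple_score),
      variants_a = paste(sort(unique(.data$variant_a)), collapse = ";"),
      variants_b = paste(sort(unique(.data$variant_b)), collapse = ";"),
      origins = paste(sort(unique(paste0(.data$origin_a, "+", .data$origin_b))),
                      collapse = ";"),
      .groups = "drop")
  if (!is.null(external_scores)) {
    stopifnot_cols(external_scores, c("sample_id", "gene_a", "gene_b", "score"),
                   "external score table")
    pairs <- pairs |>
      dplyr::left_join(external_scores,
                       by = c("sample_id", "gene_a", "gene_b"),
                       suffix = c("", ".ext")) |>
      dplyr::mutate(score = dplyr::coalesce(.data$score.ext, .data$score)) |>
      dplyr::select(-"score.ext")
  }
  cz <- config$zone_cutoffs
  pairs$zone <- dplyr::case_when(
    pairs$score >= cz[3] ~ "zone999",
    pairs$score >= cz[2] ~ "zone99",
    pairs$score >= cz[1] ~ "candidate",
    TRUE ~ "neutral")
  pairs
}

#' Tissue-expression filter for gene pairs
#'
#' @param pairs pair-level tibble with `gene_a`, `gene_b`.
#' @param gene_table gene info with `brain_expressed`, `skeletal_expressed`.
#' @return `pairs` with logical column `expressed` (both genes have brain or
#'   skeletal expression).
#' @export
expression_filter <- function(pairs, gene_table) {
  gene_table <- validate_gene_table(gene_table)
  expr <- setNames(
    gene_table$brain_expressed | gene_table$skeletal_expressed,
    gene_table$gene)
  pairs$expressed <- unname(expr[pairs$gene_a] & expr[pairs$gene_b])
  pairs$expressed[is.na(pairs$expressed)] <- FALSE
  pairs
}

#' Recurrence report over surviving pairs
#'
#' @param pairs surviving pair-level tibble (`sample_id`, `gene_a`, `gene_b`).
#' @return gene-pair-level tibble with `n_probands`, `probands` and `tier`
#'   (`recurrent` for pairs carried by >= 2 unrelated probands, otherwise
#'   `singleton`).
#' @export
recurrent_pairs <- function(pairs) {
  pairs |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(n_probands = dplyr::n_distinct(.data$sample_id),
                     probands = paste(sort(unique(.data$sample_id)),
                                      collapse = ";"),
                     .groups = "drop") |>
    dplyr::mutate(tier = ifelse(.data$n_probands >= 2, "recurrent",
                                "singleton")) |>
    dplyr::arrange(dplyr::desc(.data$n_probands), .data$gene_a, .data$gene_b)
}

#' Exome-wide digenic screen for case-specific pairs
#'
#' Runs the full pipeline: haploinsufficient-gene selection, qualifying
#' variant collection for probands, pair enumeration with biparental-origin
#' logic for trios, exclusion of pairs observed in unaffected parents or
#' population controls, stand-in pathogenicity scoring with confidence zones,
#' tissue-expression filtering, and recurrence across unrelated probands in
#' the top zone.
#'
#' @param cohort a QC-filtered `trio_cohort`.
#' @param ann annotated variant tibble.
#' @param gene_table gene info tibble.
#' @param config a [screen_config()].
#' @param external_scores optional external pair scores (see [score_pairs()]).
#' @return object of class `digenic_screen`: list with `pairs` (per-proband
#'   pair ledger with `excluded`, `zone`, `expressed`, `reported` flags),
#'   `recurrence` (gene-pair tier table over reported pairs), `qualifying`,
#'   `stage_counts`, and the `config`. Use [tidy()], [glance()],
#'   [autoplot()].
#' @export
digenic_screen <- function(cohort, ann, gene_table, config = screen_config(),
                           external_scores = NULL) {
  if (!"lgd" %in% names(ann)) ann <- classify_variants(ann)
  hi <- select_hi_genes(gene_table, config$pli_min)

  qualifying <- collect_qualifying(cohort, ann, gene_table, config = config)
  biparental <- if (config$require_biparental) {
    ped_trios(cohort$pedigree)$proband
  } else {
    character()
  }
  couples <- enumerate_pairs(qualifying, biparental_samples = biparental)
  pairs <- score_pairs(couples, gene_table, config,
                       external_scores = external_scores)
  hits <- unaffected_gene_hits(cohort, ann, gene_table, config = config)
  pairs <- exclude_unaffected_pairs(pairs, hits)
  pairs <- expression_filter(pairs, gene_table)

  pairs$reported <- !pairs$excluded & pairs$zone == "zone999" &
    (!config$expression_required | pairs$expressed)
  recurrence <- recurrent_pairs(pairs[pairs$reported, ])

  stage_counts <- tibble::tibble(
    stage = c("hi_genes", "qualifying_variants", "pairs_enumerated",
              "pairs_after_exclusion", "pairs_zone999",
              "pairs_after_expression", "pairs_reported",
              "gene_pairs_recurrent"),
    n = c(length(hi), nrow(qualifying), nrow(pairs),
          sum(!pairs$excluded),
          sum(!pairs$excluded & pairs$zone == "zone999"),
          sum(!pairs$excluded & pairs$zone == "zone999" & pairs$expressed),
          sum(pairs$reported),
          sum(recurrence$tier == "recurrent")))

  structure(list(pairs = pairs, recurrence = recurrence,
                 qualifying = qualifying, stage_counts = stage_counts,
                 config = config, n_hi_genes = length(hi)),
            class = "digenic_screen")
}

#' @exportS3Method base::print
print.digenic_screen <- function(x, ...) {
  cat("<digenic_screen>\n")
  print(x$stage_counts, n = nrow(x$stage_counts))
  invisible(x)
}

#' @export
tidy.digenic_screen <- function(x, ...) x$pairs

#' @export
glance.digenic_screen <- function(x, ...) {
  tidyr::pivot_wider(x$stage_counts, names_from = "stage", values_from = "n")
}

#' Write the digenic pair report
#'
#' @param screen a `digenic_screen` object.
#' @param tsv_path per-proband pair ledger TSV (with recurrence counts).
#' @param json_path optional JSON summary of the per-stage counts.
#' @return `tsv_path`, invisibly.
#' @export
write_pair_report <- function(screen, tsv_path, json_path = NULL) {
  out <- screen$pairs |>
    dplyr::left_join(
      dplyr::select(screen$recurrence, "gene_a", "gene_b", "n_probands", "tier"),
      by = c("gene_a", "gene_b"))
  readr::write_tsv(out, tsv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      as.list(setNames(screen$stage_counts$n, screen$stage_counts$stage)),
      json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(tsv_path)
}
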