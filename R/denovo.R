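#' De novo calling thresholds
#'
#' High-confidence trio criteria: the proband must be heterozygous with
#' GQ >= 60, DP >= 20 and allele balance in the closed interval [0.3, 0.7];
#' both parents must be homozygous reference with GQ >= 25, DP >= 20 and
#' allele balance below 0.03; and the variant's population allele frequency
#' must be below 0.1%. Note the proband AB window here is closed, unlike the
#' open cohort-QC heterozygote window.
#'
#' @param proband_gq_min,parent_gq_min minimum genotype qualities.
#' @param dp_min minimum depth for all three members.
#' @param proband_ab closed AB interval for the proband het call.
#' @param parent_ab_max strict upper AB bound for parental reference calls.
#' @param maf_max strict population-frequency ceiling.
#' @return a `denovo_thresholds` list.
#' @export
denovo_thresholds <- function(proband_gq_min = 60, parent_gq_min = 25,
                              dp_min = 20, proband_ab = c(0.3, 0.7),
                              parent_ab_max = 0.03, maf_max = 0.001) {
  structure(list(proband_gq_min = proband_gq_min, parent_gq_min = parent_gq_min,
                 dp_min = dp_min, proband_ab = proband_ab,
                 parent_ab_max = parent_ab_max, maf_max = maf_max),
            class = "denovo_thresholds")
}

#' Identify de novo variants in proband-parent trios
#'
#' Scans every complete trio in the cohort for sites where the proband is
#' heterozygous and both parents are homozygous reference, under the
#' high-confidence thresholds of [denovo_thresholds()]. Sites where any trio
#' member's genotype is missing are skipped for that trio. An optional
#' confirmation table models a second-caller / orthogonal-validation step;
#' by default every call is confirmed.
#'
#' @param cohort a QC-filtered `trio_cohort`.
#' @param ann annotated variants (provides `pop_af`, `gene`, `consequence`).
#' @param thresholds a [denovo_thresholds()] list.
#' @param confirmations optional tibble (`proband`, `variant_id`,
#'   `confirmed`); calls absent from the table keep `confirmed = TRUE`.
#' @return tibble of class `denovo_calls`: one row per (trio, variant) with
#'   key fields, annotation, trio QC metrics and a `confirmed` flag.
#' @export
call_denovo <- function(cohort, ann, thresholds = denovo_thresholds(),
                        confirmations = NULL) {
  trios <- ped_trios(cohort$pedigree)
  g <- cohort$genotypes |>
    dplyr::mutate(ab = allele_balance(.data$ad_ref, .data$ad_alt))

  member <- function(ids, prefix) {
    g |>
      dplyr::inner_join(ids, by = c(sample_id = "member")) |>
      dplyr::select("family_id", "variant_id",
                    !!paste0(prefix, "_gt") := "gt",
                    !!paste0(prefix, "_gq") := "gq",
                    !!paste0(prefix, "_dp") := "dp",
                    !!paste0(prefix, "_ab") := "ab")
  }
  pro <- member(dplyr::transmute(trios, member = .data$proband,
                                 family_id = .data$family_id), "p")
  fa <- member(dplyr::transmute(trios, member = .data$father,
                                family_id = .data$family_id), "f")
  mo <- member(dplyr::transmute(trios, member = .data$mother,
                                family_id = .data$family_id), "m")

  tg <- pro |>
    dplyr::inner_join(fa, by = c("family_id", "variant_id")) |>
    dplyr::inner_join(mo, by = c("family_id", "variant_id")) |>
    dplyr::filter(.data$p_gt != "missing", .data$f_gt != "missing",
                  .data$m_gt != "missing")

  th <- thresholds
  hits <- tg |>
    dplyr::filter(
      .data$p_gt == "het",
      .data$f_gt == "hom_ref", .data$m_gt == "hom_ref",
      .data$p_gq >= th$proband_gq_min, .data$p_dp >= th$dp_min,
      !is.na(.data$p_ab),
      .data$p_ab >= th$proband_ab[1], .data$p_ab <= th$proband_ab[2],
      .data$f_gq >= th$parent_gq_min, .data$f_dp >= th$dp_min,
      !is.na(.data$f_ab), .data$f_ab < th$parent_ab_max,
      .data$m_gq >= th$parent_gq_min, .data$m_dp >= th$dp_min,
      !is.na(.data$m_ab), .data$m_ab < th$parent_ab_max)

  ann_cols <- dplyr::select(ann, "variant_id", "chrom", "pos", "ref", "alt",
                            "gene", "consequence", "pop_af", "dann",
                            "dann_rank", "splice_ada",
                            dplyr::any_of("plp_label"))
  calls <- hits |>
    dplyr::inner_join(ann_cols, by = "variant_id") |>
    dplyr::filter(is_rare(.data$pop_af, th$maf_max)) |>
    dplyr::inner_join(dplyr::select(trios, "family_id", "proband"),
                      by = "family_id") |>
    dplyr::select("family_id", "proband", "variant_id", "chrom", "pos",
                  "ref", "alt", "gene", "consequence", "pop_af", "dann",
                  "dann_rank", "splice_ada", dplyr::any_of("plp_label"),
                  "p_gq", "p_dp", "p_ab", "f_ab", "m_ab") |>
    dplyr::arrange(.data$proband, .data$chrom, .data$pos, .data$alt)

  calls$confirmed <- TRUE
  if (!is.null(confirmations)) {
    stopifnot_cols(confirmations, c("proband", "variant_id", "confirmed"),
                   "confirmation table")
    calls <- calls |>
      dplyr::left_join(confirmations, by = c("proband", "variant_id"),
                       suffix = c("", ".ext")) |>
      dplyr::mutate(confirmed = dplyr::coalesce(.data$confirmed.ext,
                                                .data$confirmed)) |>
      dplyr::select(-"confirmed.ext")
  }
  class(calls) <- c("denovo_calls", class(calls))
  calls
}

#' Transition/transversion ratio of SNV calls
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine substitutions
#' (A<->G, C<->T); all other single-base substitutions are transversions.
#' Indels are ignored.
#'
#' @param calls a tibble with `ref` and `alt` columns.
#' @return the Ti/Tv ratio, or `NA` (with a message) when no transversion is
#'   present, in which case the ratio is undefined.
#' @export
#' @examples
#' titv_ratio(data.frame(ref = c(rep("A", 49), rep("A", 20)),
#'                       alt = c(rep("G", 49), rep("T", 20)))) # 2.45
titv_ratio <- function(calls) {
  snv <- nchar(calls$ref) == 1 & nchar(calls$alt) == 1 &
    calls$ref %in% c("A", "C", "G", "T") & calls$alt %in% c("A", "C", "G", "T") &
    calls$ref != calls$alt
  ref <- calls$ref[snv]; alt <- calls$alt[snv]
  ti <- (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
  n_tv <- sum(!ti)
  if (n_tv == 0) {
    rlang::inform("no transversions among SNV calls; Ti/Tv undefined")
    return(NA_real_)
  }
  sum(ti) / n_tv
}

#' De novo count vs parental age
#'
#' Simple nonparametric association report: Spearman rank correlation between
#' per-trio de novo counts and a parental-age covariate.
#'
#' @param counts integer vector of per-trio de novo counts.
#' @param ages numeric vector of parental ages, same order.
#' @return one-row tibble with `rho`, `p_value`, `n`.
#' @export
denovo_age_association <- function(counts, ages) {
  stopifnot(length(counts) == length(ages))
  ct <- suppressWarnings(cor.test(counts, ages, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(counts))
}
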