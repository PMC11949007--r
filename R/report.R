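#' Build a cohort summary from counts
#'
#' Container for the cohort-level counts everything else is recomputed from;
#' percentages are never stored, only derived (half-up to one decimal), so
#' the report can never drift from its counts.
#'
#' @param n_probands,n_trios,n_singletons cohort composition.
#' @param n_with_plp probands carrying at least one P/LP variant.
#' @param n_denovo_plp_probands trio probands with a de novo P/LP variant.
#' @param suture_counts named integer vector over
#'   `c("sagittal", "coronal", "lambdoid", "metopic", "multiple")`.
#' @param n_syndromic optional syndromic-case count.
#' @return a `cohort_summary` list.
#' @export
#' @examples
#' s <- cohort_summary(121, 52, 69, n_with_plp = 41, n_denovo_plp_probands = 15,
#'                     suture_counts = c(sagittal = 43, coronal = 34,
#'                                       lambdoid = 16, metopic = 9,
#'                                       multiple = 19))
#' diagnostic_yield(s)
cohort_summary <- function(n_probands, n_trios, n_singletons,
                           n_with_plp = NA_integer_,
                           n_denovo_plp_probands = NA_integer_,
                           suture_counts = NULL, n_syndromic = NA_integer_) {
  if (n_probands <= 0) stop("n_probands must be positive", call. = FALSE)
  if (!is.null(suture_counts)) {
    need <- c("sagittal", "coronal", "lambdoid", "metopic", "multiple")
    stopifnot(all(need %in% names(suture_counts)), all(suture_counts >= 0))
    if (sum(suture_counts[need]) != n_probands) {
      stop("suture counts (single + multiple) must sum to n_probands",
           call. = FALSE)
    }
  }
  structure(list(n_probands = n_probands, n_trios = n_trios,
                 n_singletons = n_singletons, n_with_plp = n_with_plp,
                 n_denovo_plp_probands = n_denovo_plp_probands,
                 suture_counts = suture_counts, n_syndromic = n_syndromic),
            class = "cohort_summary")
}

#' Percentage of a count, half-up to one decimal
#'
#' @param count,total non-negative counts, `total > 0`.
#' @return `100 * count / total` rounded half-up to one decimal.
#' @export
#' @examples
#' percent_of(41, 121) # 33.9
percent_of <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive", call. = FALSE)
  round_half_up(100 * count / total, 1)
}

#' Diagnostic yield of the cohort
#'
#' @param summary a [cohort_summary()].
#' @return one-row tibble: `yield` (% of probands with P/LP variants) and
#'   `trio_denovo_yield` (% of trios with a de novo P/LP variant).
#' @export
diagnostic_yield <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"))
  tibble::tibble(
    yield = percent_of(summary$n_with_plp, summary$n_probands),
    trio_denovo_yield = percent_of(summary$n_denovo_plp_probands,
                                   summary$n_trios))
}

#' Suture involvement distribution
#'
#' @param summary a [cohort_summary()] with `suture_counts`.
#' @return tibble with per-suture percentages and the single-suture total.
#' @export
suture_distribution <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"),
            !is.null(summary$suture_counts))
  sc <- summary$suture_counts
  single <- c("sagittal", "coronal", "lambdoid", "metopic")
  tibble::tibble(
    suture = c(single, "multiple", "single_total"),
    n = c(unname(sc[single]), unname(sc["multiple"]), sum(sc[single])),
    percent = percent_of(.data$n, summary$n_probands))
}

#' Detect multilocus pathogenic variation (MPV) carriers
#'
#' A proband carries MPV when it has P/LP variants in at least two distinct
#' genes. Duplicate variant records and variant order do not affect the
#' result.
#'
#' @param plp_calls tibble with `proband`, `gene` and `plp_label` (rows with
#'   label `"P"` or `"LP"` count; other rows are ignored).
#' @return tibble of carriers: `proband`, `n_genes`, `genes` (sorted,
#'   `;`-separated).
#' @export
detect_mpv <- function(plp_calls) {
  stopifnot_cols(plp_calls, c("proband", "gene", "plp_label"), "P/LP table")
  plp_calls |>
    dplyr::filter(.data$plp_label %in% c("P", "LP")) |>
    dplyr::distinct(.data$proband, gene = norm_gene(.data$gene)) |>
    dplyr::group_by(.data$proband) |>
    dplyr::summarise(n_genes = dplyr::n(),
                     genes = paste(sort(.data$gene), collapse = ";"),
                     .groups = "drop") |>
    dplyr::filter(.data$n_genes >= 2) |>
    dplyr::arrange(.data$proband)
}

#' @exportS3Method base::print
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d probands (%d trios, %d singletons)\n",
              x$n_probands, x$n_trios, x$n_singletons))
  if (!is.na(x$n_with_plp)) {
    cat(sprintf("  P/LP carriers: %d (%.1f%%)\n", x$n_with_plp,
                percent_of(x$n_with_plp, x$n_probands)))
  }
  invisible(x)
}
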