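# small shared helpers; not exported unless user-facing

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all reported percentages so that
#' e.g. 41/121 = 33.884...% prints as 33.9. Base `round()` uses banker's
#' rounding, which would disagree at exact .5 boundaries.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(33.85, 1) # 33.9, not 33.8
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# strip an optional "chr" prefix so "chr7" and "7" compare equal
norm_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom), ignore.case = TRUE)
}

is_autosome <- function(chrom) {
  norm_chrom(chrom) %in% as.character(1:22)
}

# canonical gene symbol: uppercase, whitespace stripped (pair identity contract)
norm_gene <- function(gene) {
  toupper(gsub("\\s+", "", as.character(gene)))
}

variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

GT_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
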