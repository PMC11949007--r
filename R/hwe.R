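#' Exact test of Hardy-Weinberg equilibrium from genotype counts
#'
#' Two-sided exact test conditional on the observed allele counts: all possible
#' heterozygote counts compatible with the minor-allele total are enumerated,
#' their conditional probabilities computed by the usual stable recurrence, and
#' the p-value is the summed probability of all configurations no more likely
#' than the observed one. Sites with extreme departures (the cohort QC default
#' drops p < 1e-12) are almost always genotyping artifacts such as collapsed
#' paralogs.
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative integer genotype counts
#'   (vectors are recycled to common length).
#' @return numeric vector of p-values in (0, 1].
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)   # most probable configuration, p = 1
#' hwe_exact_test(0, 100, 0)    # all-het excess, vanishingly small p
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- vctrs_recycle(n_hom_ref, n_het, n_hom_alt)
  mapply(hwe_exact1, n[[1]], n[[2]], n[[3]], USE.NAMES = FALSE)
}

# recycle three vectors to a common length (base implementation; keeps the
# exported surface vectorised without pulling in vctrs)
vctrs_recycle <- function(a, b, c) {
  len <- max(length(a), length(b), length(c))
  list(rep_len(a, len), rep_len(b, len), rep_len(c, len))
}

hwe_exact1 <- function(n_aa, n_ab, n_bb) {
  if (any(is.na(c(n_aa, n_ab, n_bb)))) return(NA_real_)
  if (n_aa < 0 || n_ab < 0 || n_bb < 0) {
    stop("genotype counts must be non-negative", call. = FALSE)
  }
  n <- n_aa + n_ab + n_bb
  if (n == 0) stop("no genotyped samples", call. = FALSE)

  rare <- min(2 * n_aa + n_ab, 2 * n_bb + n_ab) # minor allele copies
  if (rare == 0) return(1.0)                    # monomorphic: one configuration

  # valid het counts share the parity of the minor allele count
  het_vals <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(het_vals))

  # start at (approximately) the modal het count, walk the recurrence outward
  mid <- round(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2 != rare %% 2) mid <- mid + 1
  mid <- min(mid, rare)
  i_mid <- match(mid, het_vals)
  probs[i_mid] <- 1

  if (i_mid > 1) {
    for (i in seq(i_mid, 2L)) {
      h <- het_vals[i]
      haa <- (rare - h) / 2
      hbb <- n - haa - h
      # P(h-2) / P(h) = h (h-1) / (4 (haa+1) (hbb+1))
      probs[i - 1] <- probs[i] * h * (h - 1) / (4 * (haa + 1) * (hbb + 1))
    }
  }
  if (i_mid < length(het_vals)) {
    for (i in seq(i_mid, length(het_vals) - 1L)) {
      h <- het_vals[i]
      haa <- (rare - h) / 2
      hbb <- n - haa - h
      # P(h+2) / P(h) = 4 haa hbb / ((h+2) (h+1))
      probs[i + 1] <- probs[i] * 4 * haa * hbb / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)

  p_obs <- probs[match(n_ab, het_vals)]
  if (is.na(p_obs)) {
    stop(sprintf("heterozygote count %d is incompatible with allele counts", n_ab),
         call. = FALSE)
  }
  # tolerance factor guards against float ties at the observed probability
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}
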