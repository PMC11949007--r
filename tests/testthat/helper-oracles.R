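# Independent oracles used to cross-check the implementation.

# HWE exact test by closed-form log-gamma enumeration over all heterozygote
# counts compatible with the observed allele counts (independent of the
# package's recurrence-based computation).
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (n_a - h) / 2
    bb <- (n_b - h) / 2
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  }, double(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

# Upper-tail Poisson probability by direct pmf summation.
poisson_tail_oracle <- function(observed, lambda, kmax = 10000) {
  if (observed == 0) return(1)
  sum(dpois(observed:max(kmax, observed + 50 * ceiling(sqrt(lambda) + 1)),
            lambda))
}

# Naive per-site triple-loop de novo caller over a trio_cohort, mirroring the
# stated thresholds directly on wide genotype matrices.
denovo_oracle <- function(cohort, ann, th = denovo_thresholds()) {
  trios <- ped_trios(cohort$pedigree)
  g <- cohort$genotypes
  wide <- function(field) {
    m <- matrix(NA_real_, nrow(cohort$variants), length(cohort$samples),
                dimnames = list(cohort$variants$variant_id, cohort$samples))
    m[cbind(match(g$variant_id, rownames(m)), match(g$sample_id, colnames(m)))] <-
      if (field == "gt") match(g$gt, c("hom_ref", "het", "hom_alt", "missing"))
      else g[[field]]
    m
  }
  GT <- wide("gt"); GQ <- wide("gq"); DP <- wide("dp")
  AB <- wide("ad_alt") / (wide("ad_ref") + wide("ad_alt"))
  af <- setNames(ann$pop_af, ann$variant_id)

  hits <- list()
  for (t in seq_len(nrow(trios))) {
    p <- trios$proband[t]; f <- trios$father[t]; m <- trios$mother[t]
    for (v in rownames(GT)) {
      if (is.na(GT[v, p]) || is.na(GT[v, f]) || is.na(GT[v, m])) next
      if (GT[v, p] == 4 || GT[v, f] == 4 || GT[v, m] == 4) next
      if (!(v %in% names(af))) next
      a <- af[[v]]; if (is.na(a)) a <- 0
      ok <- GT[v, p] == 2 && GT[v, f] == 1 && GT[v, m] == 1 &&
        !is.na(GQ[v, p]) && GQ[v, p] >= th$proband_gq_min &&
        !is.na(DP[v, p]) && DP[v, p] >= th$dp_min &&
        !is.na(AB[v, p]) && AB[v, p] >= th$proband_ab[1] &&
        AB[v, p] <= th$proband_ab[2] &&
        !is.na(GQ[v, f]) && GQ[v, f] >= th$parent_gq_min &&
        !is.na(DP[v, f]) && DP[v, f] >= th$dp_min &&
        !is.na(AB[v, f]) && AB[v, f] < th$parent_ab_max &&
        !is.na(GQ[v, m]) && GQ[v, m] >= th$parent_gq_min &&
        !is.na(DP[v, m]) && DP[v, m] >= th$dp_min &&
        !is.na(AB[v, m]) && AB[v, m] < th$parent_ab_max &&
        a < th$maf_max
      if (ok) hits[[length(hits) + 1]] <- c(p, v)
    }
  }
  if (length(hits) == 0) return(character(0))
  sort(vapply(hits, function(h) paste(h[1], h[2]), character(1)))
}

# Brute-force unordered pair count for k genes.
pair_count_oracle <- function(k) {
  n <- 0L
  if (k >= 2) for (i in 1:(k - 1)) for (j in (i + 1):k) n <- n + 1L
  n
}
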