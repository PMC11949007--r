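#' Poisson mutation-rate burden test for de novo variants
#'
#' Compares an observed de novo count in one consequence class with its
#' expectation under a per-gene mutation-rate model: the expected count is
#' `2 * n_trios * sum(mu_class)` over the gene set under test (two transmitted
#' haplotypes per trio). The p-value is the upper-tail Poisson probability
#' `P(X >= observed)` at that expectation, so an observation of 0 always has
#' p = 1.
#'
#' @param observed observed de novo count in the class.
#' @param n_trios number of sequenced trios.
#' @param rates gene table carrying per-class mutation-rate columns
#'   (`mu_syn`, `mu_mis`, `mu_lgd`).
#' @param class one of `"synonymous"`, `"missense"`, `"lgd"`.
#' @param genes optional character vector restricting the gene set.
#' @return one-row tibble of class `burden_result`: `consequence_class`,
#'   `observed`, `expected`, `enrichment`, `p_value`. When `expected` is 0
#'   and `observed` > 0 the enrichment is `Inf` and the p-value 0 (below
#'   machine floor).
#' @export
#' @examples
#' rates <- data.frame(gene = "G1", mu_syn = 1e-5, mu_mis = 2e-5, mu_lgd = 5e-6)
#' burden_test(0, 52, rates, "synonymous")$p_value # 1
burden_test <- function(observed, n_trios, rates,
                        class = c("missense", "synonymous", "lgd"),
                        genes = NULL) {
  class <- match.arg(class)
  mu_col <- c(synonymous = "mu_syn", missense = "mu_mis", lgd = "mu_lgd")[class]
  stopifnot_cols(rates, mu_col, "rate table")
  if (!is.null(genes)) rates <- rates[norm_gene(rates$gene) %in% norm_gene(genes), ]
  expected <- 2 * n_trios * sum(rates[[mu_col]], na.rm = TRUE)

  if (expected == 0) {
    enrichment <- if (observed > 0) Inf else NA_real_
    p <- if (observed > 0) 0 else 1
  } else {
    enrichment <- observed / expected
    p <- ppois(observed - 1, lambda = expected, lower.tail = FALSE)
  }
  res <- tibble::tibble(consequence_class = class,
                        observed = as.integer(observed),
                        expected = expected, enrichment = enrichment,
                        p_value = p)
  class(res) <- c("burden_result", class(res))
  res
}

#' Burden table across consequence classes
#'
#' Runs [burden_test()] for each class, counting observed calls from a
#' `denovo_calls` tibble: `"lgd"` counts LGD calls, `"missense"` counts
#' non-LGD missense calls, `"synonymous"` counts synonymous calls. Only
#' confirmed calls are counted.
#'
#' @param calls a `denovo_calls` tibble.
#' @param n_trios number of trios.
#' @param rates gene table with mutation-rate columns.
#' @param genes optional gene-set restriction.
#' @return `burden_result` tibble with one row per class.
#' @export
burden_table <- function(calls, n_trios, rates, genes = NULL) {
  calls <- calls[calls$confirmed, ]
  lgd <- is_lgd(calls$consequence, calls$splice_ada)
  obs <- c(synonymous = sum(calls$consequence == "synonymous"),
           missense = sum(calls$consequence == "missense" & !lgd),
           lgd = sum(lgd))
  out <- dplyr::bind_rows(lapply(names(obs), function(cl) {
    burden_test(obs[[cl]], n_trios, rates, cl, genes = genes)
  }))
  class(out) <- c("burden_result", class(out))
  out
}

#' @export
tidy.burden_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "burden_result")
  out
}

#' @export
glance.burden_result <- function(x, ...) {
  tibble::tibble(n_classes = nrow(x),
                 min_p = min(x$p_value),
                 max_enrichment = max(x$enrichment, na.rm = TRUE))
}

#' Poisson goodness of fit for per-trio de novo counts
#'
#' Chi-square goodness-of-fit of the per-trio de novo count distribution
#' against a Poisson with rate equal to the sample mean. Count bins are pooled
#' from the upper tail (and lower end if needed) until every expected bin
#' count is at least 5; degrees of freedom are `bins - 2` (one for the total,
#' one for the estimated rate). With all counts zero the fit is perfect by
#' construction (`statistic = 0`, `p = 1`).
#'
#' @param counts integer vector of per-trio de novo counts (length >= 2).
#' @return object of class `poisson_gof` with fields `statistic`, `df`,
#'   `p_value`, `lambda`, `n`, `bins`.
#' @export
per_trio_gof <- function(counts) {
  stopifnot(length(counts) >= 2, all(counts >= 0))
  n <- length(counts)
  lambda <- mean(counts)
  if (lambda == 0) {
    return(new_poisson_gof(0, NA_integer_, 1, lambda, n,
                           tibble::tibble(bin = "0", observed = n, expected = n)))
  }
  kmax <- max(counts)
  probs <- dpois(0:kmax, lambda)
  probs <- c(probs, max(0, 1 - sum(probs)))       # tail bin k > kmax
  obs <- tabulate(counts + 1L, nbins = kmax + 1L)
  obs <- c(obs, 0L)
  expected <- n * probs

  # pool adjacent bins from the right, then from the left, until all >= 5
  labels <- c(as.character(0:kmax), paste0(">", kmax))
  while (length(expected) > 1 && expected[length(expected)] < 5) {
    k <- length(expected)
    expected[k - 1] <- expected[k - 1] + expected[k]
    obs[k - 1] <- obs[k - 1] + obs[k]
    labels[k - 1] <- paste0(sub("\\+.*", "", labels[k - 1]), "+")
    expected <- expected[-k]; obs <- obs[-k]; labels <- labels[-k]
  }
  while (length(expected) > 1 && expected[1] < 5) {
    expected[2] <- expected[2] + expected[1]
    obs[2] <- obs[2] + obs[1]
    labels[2] <- paste0("<=", sub(".*?(\\d+)", "\\1", labels[2]))
    expected <- expected[-1]; obs <- obs[-1]; labels <- labels[-1]
  }

  stat <- sum((obs - expected)^2 / expected)
  df <- length(expected) - 2L
  p <- if (df >= 1) pchisq(stat, df, lower.tail = FALSE) else NA_real_
  new_poisson_gof(stat, df, p, lambda, n,
                  tibble::tibble(bin = labels, observed = obs,
                                 expected = expected))
}

new_poisson_gof <- function(statistic, df, p_value, lambda, n, bins) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 lambda = lambda, n = n, bins = bins),
            class = "poisson_gof")
}

#' @exportS3Method base::print
print.poisson_gof <- function(x, ...) {
  cat(sprintf(
    "Poisson goodness of fit: X-squared = %.3f, df = %s, p = %s (rate %.3f, n = %d)\n",
    x$statistic, format(x$df), format.pval(x$p_value), x$lambda, x$n))
  invisible(x)
}

#' @export
tidy.poisson_gof <- function(x, ...) x$bins

#' @export
glance.poisson_gof <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 lambda = x$lambda, n = x$n)
}
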