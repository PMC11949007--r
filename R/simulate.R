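CHROM_ORDER <- c(as.character(1:22), "X")

#' Simulation configuration for a synthetic trio cohort
#'
#' Defaults emulate the study conditions the package targets: 52 trios, 69
#' proband-only samples and 1,048 unrelated population controls, with a mean
#' of 1.5 coding de novo variants per proband (about 78 expected over 52
#' trios) and SNV substitutions that are transitions with probability 0.71
#' (Ti/Tv ~ 2.45).
#'
#' @param seed integer; fully determines all output.
#' @param n_trios,n_singletons,n_controls cohort composition.
#' @param n_genes,fraction_hi,sites_per_gene gene panel size, fraction of
#'   genes with pLI > 0.9, and background variant sites per gene.
#' @param denovo_rate mean de novo coding variants per trio proband.
#' @param transition_prob probability a de novo SNV is a transition.
#' @param common_site_prob fraction of background sites drawn from the
#'   common-frequency stratum (the rest are rare, concentrated below 0.5%).
#' @param depth_mean mean sequencing depth for emitted genotypes.
#' @param gq_low_rate fraction of background genotypes emitted with a low GQ
#'   (5-19) to exercise genotype masking.
#' @param planted_pairs optional tibble (`gene_a`, `gene_b`,
#'   `n_case_probands`, `also_in_controls`); `NULL` selects a default of two
#'   case-specific pairs in 2 probands each plus one decoy pair planted into
#'   controls. Planted genes must have pLI > 0.9 on an autosome.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 0L, n_trios = 52L, n_singletons = 69L,
                       n_controls = 1048L, n_genes = 320L, fraction_hi = 0.2,
                       sites_per_gene = 2L, denovo_rate = 1.5,
                       transition_prob = 0.71, common_site_prob = 0.15,
                       depth_mean = 60, gq_low_rate = 0.02,
                       planted_pairs = NULL) {
  stopifnot(n_trios > 0, n_singletons >= 0, n_controls >= 0, n_genes > 0,
            fraction_hi >= 0, fraction_hi <= 1, sites_per_gene > 0,
            denovo_rate >= 0, transition_prob >= 0, transition_prob <= 1)
  structure(list(seed = as.integer(seed), n_trios = as.integer(n_trios),
                 n_singletons = as.integer(n_singletons),
                 n_controls = as.integer(n_controls),
                 n_genes = as.integer(n_genes), fraction_hi = fraction_hi,
                 sites_per_gene = as.integer(sites_per_gene),
                 denovo_rate = denovo_rate, transition_prob = transition_prob,
                 common_site_prob = common_site_prob, depth_mean = depth_mean,
                 gq_low_rate = gq_low_rate, planted_pairs = planted_pairs),
            class = "sim_config")
}

#' Simulate a gene panel
#'
#' Genes are placed on chromosomes 1-22 and X; pLI is drawn from a bimodal
#' mixture so that `fraction_hi` of genes exceed 0.9; per-class mutation
#' rates are log-uniform at exome-typical magnitudes with the usual ordering
#' missense > synonymous > LGD; tissue-expression flags are Bernoulli.
#'
#' @param config a [sim_config()].
#' @return gene info tibble (`gene`, `chrom`, `pli`, `brain_expressed`,
#'   `skeletal_expressed`, `mu_syn`, `mu_mis`, `mu_lgd`).
#' @export
simulate_gene_panel <- function(config) {
  withr::with_seed(config$seed, {
    n <- config$n_genes
    chrom <- sample(CHROM_ORDER, n, replace = TRUE,
                    prob = c(rep(1, 22), 0.8))
    hi <- runif(n) < config$fraction_hi
    pli <- ifelse(hi, runif(n, 0.905, 1), 0.9 * rbeta(n, 2, 8))
    mu_mis <- 10^runif(n, -5.5, -4.3)
    tibble::tibble(
      gene = sprintf("GENE%04d", seq_len(n)),
      chrom = chrom, pli = pli,
      brain_expressed = runif(n) < 0.6,
      skeletal_expressed = runif(n) < 0.5,
      mu_syn = mu_mis * runif(n, 0.3, 0.6),
      mu_mis = mu_mis,
      mu_lgd = mu_mis * runif(n, 0.05, 0.2))
  })
}

#' Draw random SNV substitutions
#'
#' @param n number of substitutions.
#' @param transition_prob probability of a transition (A<->G, C<->T).
#' @param seed optional seed for a self-contained deterministic draw.
#' @return tibble with `ref` and `alt` columns.
#' @export
simulate_substitutions <- function(n, transition_prob = 0.71, seed = NULL) {
  draw <- function() {
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    ti_partner <- c(A = "G", G = "A", C = "T", T = "C")
    is_ti <- runif(n) < transition_prob
    alt <- character(n)
    alt[is_ti] <- ti_partner[ref[is_ti]]
    # transversion: uniformly one of the two non-transition alternatives
    tv <- !is_ti
    if (any(tv)) {
      alt[tv] <- vapply(ref[tv], function(r) {
        sample(setdiff(c("A", "C", "G", "T"), c(r, ti_partner[[r]])), 1)
      }, character(1))
    }
    tibble::tibble(ref = ref, alt = alt)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a full trio cohort with planted truth
#'
#' Founder genotypes (parents, singletons, controls) are drawn per site from
#' the background allele frequency under Hardy-Weinberg equilibrium; trio
#' proband genotypes are Mendelian-transmitted from their parents. De novo
#' variants are added per trio proband with Poisson-distributed counts at new
#' sites where the proband is heterozygous and everyone else is reference;
#' planted digenic pairs are inserted as heterozygous deleterious-missense
#' qualifying variants with one paternally and one maternally transmitted
#' allele, and additionally into controls for decoy pairs. Genotype-level
#' emission (DP, AD, GQ) uses Poisson depth, binomial allelic depths and GQ
#' jitter, with every planted truth genotype emitted at high confidence so
#' that truth remains recoverable under the default hard filters. Background
#' sites in planted-pair genes are forced benign (synonymous) so the planted
#' pair is the only qualifying signal in those genes.
#'
#' @param config a [sim_config()].
#' @param panel optional gene panel; defaults to
#'   [simulate_gene_panel()]`(config)`.
#' @return object of class `trio_sim`: list with `config`, `panel`,
#'   `variants`, `samples`, `ped`, genotype/emission matrices (`gt_codes`,
#'   `gq`, `dp`, `ad_ref`, `ad_alt`), `annotations` and `truth`
#'   (`planted_denovo`, `planted_pairs` tibbles).
#' @export
simulate_cohort <- function(config, panel = NULL) {
  if (is.null(panel)) panel <- simulate_gene_panel(config)
  withr::with_seed(config$seed + 1L, sim_cohort_impl(config, panel))
}

sim_cohort_impl <- function(config, panel) {
  n_tr <- config$n_trios; n_sg <- config$n_singletons; n_ct <- config$n_controls
  probands <- sprintf("T%03d", seq_len(n_tr))
  fathers <- paste0(probands, "-FA")
  mothers <- paste0(probands, "-MO")
  singles <- sprintf("S%03d", seq_len(n_sg))
  controls <- sprintf("C%04d", seq_len(n_ct))
  samples <- c(probands, fathers, mothers, singles, controls)
  n_samp <- length(samples)

  ped <- dplyr::bind_rows(
    tibble::tibble(family_id = sprintf("F%03d", seq_len(n_tr)),
                   sample_id = probands, father_id = fathers,
                   mother_id = mothers, sex = 1L, phenotype = 2L),
    tibble::tibble(family_id = sprintf("F%03d", seq_len(n_tr)),
                   sample_id = fathers, father_id = "0", mother_id = "0",
                   sex = 1L, phenotype = 1L),
    tibble::tibble(family_id = sprintf("F%03d", seq_len(n_tr)),
                   sample_id = mothers, father_id = "0", mother_id = "0",
                   sex = 2L, phenotype = 1L),
    tibble::tibble(family_id = sprintf("FS%03d", seq_len(n_sg)),
                   sample_id = singles, father_id = "0", mother_id = "0",
                   sex = 1L, phenotype = 2L),
    tibble::tibble(family_id = controls, sample_id = controls,
                   father_id = "0", mother_id = "0", sex = 0L,
                   phenotype = 1L))

  # ---- planted pair plan -------------------------------------------------
  plan <- resolve_planted_pairs(config, panel, probands, controls)

  # ---- background sites --------------------------------------------------
  gene_idx <- rep(seq_len(config$n_genes), each = config$sites_per_gene)
  site_in_gene <- rep(seq_len(config$sites_per_gene), config$n_genes)
  n_bg <- length(gene_idx)
  common <- runif(n_bg) < config$common_site_prob
  af <- ifelse(common, runif(n_bg, 0.05, 0.5),
               pmin(rbeta(n_bg, 0.6, 800) + 1e-5, 0.0049))
  bg_sub <- simulate_substitutions(n_bg, transition_prob = 0.5)
  bg <- tibble::tibble(
    gene = panel$gene[gene_idx],
    chrom = panel$chrom[gene_idx],
    pos = gene_idx * 1000000L + site_in_gene * 1000L,
    ref = bg_sub$ref, alt = bg_sub$alt, af = af)
  bg <- dplyr::bind_cols(bg, sim_annotation_fields(bg$gene, forced = NULL,
                                                   n = n_bg))
  # frameshift / inframe background sites become indels
  ins1 <- bg$consequence == "frameshift"
  ins3 <- bg$consequence == "inframe"
  bg$alt[ins1] <- paste0(bg$ref[ins1], sample(c("A", "C", "G", "T"),
                                              sum(ins1), replace = TRUE))
  bg$alt[ins3] <- paste0(bg$ref[ins3],
                         vapply(seq_len(sum(ins3)), function(i) {
                           paste(sample(c("A", "C", "G", "T"), 3,
                                        replace = TRUE), collapse = "")
                         }, character(1)))
  # planted-pair genes carry no background signal: force benign
  if (nrow(plan$pairs) > 0) {
    benign <- bg$gene %in% unique(c(plan$pairs$gene_a, plan$pairs$gene_b))
    bg$consequence[benign] <- "synonymous"
    bg$dann[benign] <- runif(sum(benign), 0, 0.5)
    bg$splice_ada[benign] <- NA_real_
  }

  # founder genotypes in HWE; proband genotypes Mendelian-transmitted
  G_bg <- matrix(0L, n_bg, n_samp, dimnames = list(NULL, samples))
  founder_cols <- c(fathers, mothers, singles, controls)
  G_bg[, founder_cols] <- rbinom(n_bg * length(founder_cols), 2L, af)
  for (t in seq_len(n_tr)) {
    fg <- G_bg[, fathers[t]]; mg <- G_bg[, mothers[t]]
    tf <- (fg == 2L) + (fg == 1L) * rbinom(n_bg, 1L, 0.5)
    tm <- (mg == 2L) + (mg == 1L) * rbinom(n_bg, 1L, 0.5)
    G_bg[, probands[t]] <- as.integer(tf + tm)
  }

  # ---- de novo sites -----------------------------------------------------
  dn_counts <- rpois(n_tr, config$denovo_rate)
  n_dn <- sum(dn_counts)
  dn <- NULL
  if (n_dn > 0) {
    dn_gene <- sample(seq_len(config$n_genes), n_dn, replace = TRUE)
    is_snv <- runif(n_dn) < 0.95
    sub <- simulate_substitutions(n_dn, config$transition_prob)
    cons <- ifelse(is_snv,
                   sample(c("missense", "synonymous", "nonsense", "splice_site"),
                          n_dn, replace = TRUE, prob = c(0.55, 0.3, 0.1, 0.05)),
                   sample(c("frameshift", "inframe"), n_dn, replace = TRUE,
                          prob = c(0.6, 0.4)))
    alt <- sub$alt
    ind <- which(!is_snv)
    alt[ind] <- paste0(sub$ref[ind],
                       vapply(ind, function(i) {
                         k <- if (cons[i] == "inframe") 3 else 1
                         paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                               collapse = "")
                       }, character(1)))
    dn <- tibble::tibble(
      gene = panel$gene[dn_gene],
      chrom = panel$chrom[dn_gene],
      pos = dn_gene * 1000000L + 500000L + seq_len(n_dn) * 10L,
      ref = sub$ref, alt = alt, af = 0,
      proband = rep(probands, dn_counts))
    dn <- dplyr::bind_cols(
      dn, sim_annotation_fields(dn$gene, forced = cons, n = n_dn))
    dn$pop_af <- 0
  }

  # ---- planted digenic pair sites ---------------------------------------
  pp <- plan$sites # tibble: gene, carrier_parent (NA for controls), proband/carrier
  n_pp <- nrow(pp)
  if (n_pp > 0) {
    g_i <- match(pp$gene, panel$gene)
    pp$chrom <- panel$chrom[g_i]
    pp$pos <- g_i * 1000000L + 900000L + seq_len(n_pp) * 10L
    sub <- simulate_substitutions(n_pp, config$transition_prob)
    pp$ref <- sub$ref; pp$alt <- sub$alt
    pp$af <- 0
    ann_pp <- tibble::tibble(
      consequence = rep("missense", n_pp),
      pop_af = runif(n_pp, 1e-4, 5e-4),
      dann = runif(n_pp, 0.985, 0.999),
      dann_rank = runif(n_pp, 0.95, 0.995),
      splice_ada = NA_real_, plp_label = NA_character_)
    pp <- dplyr::bind_cols(pp, ann_pp)
  }

  # ---- assemble variant table & genotype matrix --------------------------
  all_sites <- dplyr::bind_rows(
    dplyr::mutate(bg, source = "background"),
    if (!is.null(dn)) dplyr::mutate(dn, source = "denovo"),
    if (n_pp > 0) dplyr::mutate(pp, source = "planted_pair"))
  n_sites <- nrow(all_sites)

  G <- matrix(0L, n_sites, n_samp, dimnames = list(NULL, samples))
  G[seq_len(n_bg), ] <- G_bg
  high_conf <- matrix(FALSE, n_sites, n_samp)

  trio_of <- setNames(seq_len(n_tr), probands)
  if (n_dn > 0) {
    rows <- n_bg + seq_len(n_dn)
    ci <- match(dn$proband, samples)
    G[cbind(rows, ci)] <- 1L
    t_i <- trio_of[dn$proband]
    high_conf[cbind(rows, ci)] <- TRUE
    high_conf[cbind(rows, match(fathers[t_i], samples))] <- TRUE
    high_conf[cbind(rows, match(mothers[t_i], samples))] <- TRUE
  }
  if (n_pp > 0) {
    rows <- n_bg + n_dn + seq_len(n_pp)
    for (i in seq_len(n_pp)) {
      r <- rows[i]
      carrier <- pp$carrier[i]
      if (carrier %in% probands) {
        t_i <- trio_of[carrier]
        parent <- if (pp$side[i] == "paternal") fathers[t_i] else mothers[t_i]
        G[r, carrier] <- 1L
        G[r, parent] <- 1L
        high_conf[r, match(c(carrier, fathers[t_i], mothers[t_i]), samples)] <- TRUE
      } else {
        G[r, carrier] <- 1L # singleton proband or control carrier
        high_conf[r, match(carrier, samples)] <- TRUE
      }
    }
  }

  # ---- emission: DP, AD, GQ ----------------------------------------------
  N <- n_sites * n_samp
  dp <- matrix(pmax(rpois(N, config$depth_mean), 1L), n_sites)
  p_alt <- matrix(0.002, n_sites, n_samp)
  p_alt[G == 1L] <- 0.5
  p_alt[G == 2L] <- 0.998
  ad_alt <- matrix(rbinom(N, as.vector(dp), as.vector(p_alt)), n_sites)
  gq <- matrix(sample(60:99, N, replace = TRUE), n_sites)
  low <- matrix(runif(N) < config$gq_low_rate, n_sites)
  gq[low] <- sample(5:19, sum(low), replace = TRUE)

  # planted truths are emitted at high confidence
  hc <- which(high_conf)
  dp[hc] <- 40L
  gq[hc] <- 85L
  ad_alt[hc] <- ifelse(G[hc] == 1L, 20L, ifelse(G[hc] == 2L, 40L, 0L))
  ad_ref <- dp - ad_alt

  variants <- tibble::tibble(
    chrom = all_sites$chrom, pos = all_sites$pos,
    ref = all_sites$ref, alt = all_sites$alt, filter = "PASS")
  ord <- order(match(norm_chrom(variants$chrom), CHROM_ORDER), variants$pos)
  variants <- variants[ord, ]
  variants$variant_id <- variant_id(variants$chrom, variants$pos,
                                    variants$ref, variants$alt)
  variants <- variants[, c("variant_id", "chrom", "pos", "ref", "alt", "filter")]
  all_sites <- all_sites[ord, ]
  G <- G[ord, , drop = FALSE]; gq <- gq[ord, , drop = FALSE]
  dp <- dp[ord, , drop = FALSE]
  ad_ref <- ad_ref[ord, , drop = FALSE]; ad_alt <- ad_alt[ord, , drop = FALSE]

  annotations <- tibble::tibble(
    chrom = all_sites$chrom, pos = all_sites$pos, ref = all_sites$ref,
    alt = all_sites$alt, gene = all_sites$gene,
    consequence = all_sites$consequence,
    pop_af = ifelse(all_sites$source == "background", all_sites$af,
                    all_sites$pop_af),
    dann = all_sites$dann, dann_rank = all_sites$dann_rank,
    splice_ada = all_sites$splice_ada,
    plp_label = ifelse(is.na(all_sites$plp_label), "none",
                       all_sites$plp_label))

  truth <- list(
    planted_denovo = if (is.null(dn)) {
      tibble::tibble(proband = character(), variant_id = character(),
                     consequence = character())
    } else {
      dn2 <- all_sites[all_sites$source == "denovo", ]
      tibble::tibble(
        proband = dn2$proband,
        variant_id = variant_id(dn2$chrom, dn2$pos, dn2$ref, dn2$alt),
        consequence = dn2$consequence)
    },
    planted_pairs = plan$pairs,
    pair_carriers = plan$carriers)

  structure(list(config = config, panel = panel, variants = variants,
                 samples = samples, ped = ped, gt_codes = G, gq = gq, dp = dp,
                 ad_ref = ad_ref, ad_alt = ad_alt, annotations = annotations,
                 truth = truth),
            class = "trio_sim")
}

# shared annotation-field generator for simulated sites; `forced` fixes the
# consequence vector (de novo sites), otherwise classes are sampled
sim_annotation_fields <- function(genes, forced, n) {
  consequence <- forced %||%
    sample(c("synonymous", "missense", "inframe", "frameshift", "splice_site",
             "nonsense", "other"), n, replace = TRUE,
           prob = c(0.28, 0.45, 0.04, 0.06, 0.08, 0.05, 0.04))
  dann <- runif(n)
  mis <- consequence == "missense"
  boost <- mis & runif(n) < 0.25
  dann[boost] <- runif(sum(boost), 0.981, 1)
  dann[mis & !boost] <- runif(sum(mis & !boost), 0, 0.98)
  dann_rank <- runif(n)
  dann_rank[dann > 0.98] <- runif(sum(dann > 0.98), 0.7, 1)
  splice_ada <- rep(NA_real_, n)
  spl <- consequence == "splice_site"
  hi_ada <- spl & runif(n) < 0.4
  splice_ada[hi_ada] <- runif(sum(hi_ada), 0.905, 1)
  splice_ada[spl & !hi_ada] <- runif(sum(spl & !hi_ada), 0, 0.9)
  tibble::tibble(consequence = consequence, dann = dann,
                 dann_rank = dann_rank, splice_ada = splice_ada,
                 plp_label = NA_character_)
}

# resolve the planted-pair plan: which genes, which case probands, which
# controls carry the decoy; one row per planted variant site in $sites
resolve_planted_pairs <- function(config, panel, probands, controls) {
  pairs <- config$planted_pairs
  if (is.null(pairs)) {
    cand <- panel$gene[panel$pli > 0.93 & is_autosome(panel$chrom) &
                         (panel$brain_expressed | panel$skeletal_expressed)]
    if (length(cand) < 6) {
      stop("gene panel too small to auto-place planted pairs", call. = FALSE)
    }
    g <- cand[1:6]
    pairs <- tibble::tibble(
      gene_a = pmin(g[c(1, 3, 5)], g[c(2, 4, 6)]),
      gene_b = pmax(g[c(1, 3, 5)], g[c(2, 4, 6)]),
      n_case_probands = 2L,
      also_in_controls = c(FALSE, FALSE, TRUE))
  }
  pli <- setNames(panel$pli, panel$gene)
  chrom <- setNames(panel$chrom, panel$gene)
  for (g in unique(c(pairs$gene_a, pairs$gene_b))) {
    if (!g %in% panel$gene) stop("planted gene not in panel: ", g, call. = FALSE)
    if (is.na(pli[g]) || pli[g] <= 0.9 || !is_autosome(chrom[g])) {
      stop("planted pair gene must be autosomal with pLI > 0.9: ", g,
           call. = FALSE)
    }
  }
  sites <- list(); carriers <- list()
  pro_cursor <- 0L; ctl_cursor <- 0L
  for (i in seq_len(nrow(pairs))) {
    k <- pairs$n_case_probands[i]
    if (pro_cursor + k > length(probands)) {
      stop("not enough trio probands for planted pairs", call. = FALSE)
    }
    cases <- probands[pro_cursor + seq_len(k)]
    pro_cursor <- pro_cursor + k
    sites[[length(sites) + 1]] <- tibble::tibble(
      gene = rep(c(pairs$gene_a[i], pairs$gene_b[i]), each = k),
      carrier = rep(cases, 2),
      side = rep(c("paternal", "maternal"), each = k))
    carriers[[length(carriers) + 1]] <- tibble::tibble(
      gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i], proband = cases,
      also_in_controls = pairs$also_in_controls[i])
    if (pairs$also_in_controls[i]) {
      if (ctl_cursor + 2 > length(controls)) {
        stop("not enough controls for decoy pairs", call. = FALSE)
      }
      ctl <- controls[ctl_cursor + 1:2]
      ctl_cursor <- ctl_cursor + 2L
      sites[[length(sites) + 1]] <- tibble::tibble(
        gene = rep(c(pairs$gene_a[i], pairs$gene_b[i]), each = 2),
        carrier = rep(ctl, 2),
        side = NA_character_)
    }
  }
  list(pairs = pairs,
       carriers = dplyr::bind_rows(carriers),
       sites = dplyr::bind_rows(sites))
}

#' Convert a simulation to an in-memory cohort
#'
#' Builds the `trio_cohort` directly from the simulated matrices, equivalent
#' to writing the fixture set and re-reading it with [read_cohort()].
#'
#' @param sim a `trio_sim` object.
#' @return a `trio_cohort`.
#' @export
as_cohort <- function(sim) {
  stopifnot(inherits(sim, "trio_sim"))
  n_var <- nrow(sim$variants)
  n_samp <- length(sim$samples)
  genotypes <- tibble::tibble(
    variant_id = rep(sim$variants$variant_id, times = n_samp),
    sample_id = rep(sim$samples, each = n_var),
    gt = GT_LEVELS[as.vector(sim$gt_codes) + 1L],
    gq = as.double(as.vector(sim$gq)),
    dp = as.double(as.vector(sim$dp)),
    ad_ref = as.double(as.vector(sim$ad_ref)),
    ad_alt = as.double(as.vector(sim$ad_alt)))
  ped <- sim$ped
  ped$role <- dplyr::case_when(
    ped$phenotype == 2L & ped$father_id != "0" ~ "proband",
    ped$phenotype == 2L ~ "singleton",
    ped$sample_id %in% ped$father_id ~ "father",
    ped$sample_id %in% ped$mother_id ~ "mother",
    TRUE ~ "control")
  new_cohort(variants = sim$variants, genotypes = genotypes,
             pedigree = ped, samples = sim$samples)
}

#' Write a complete fixture set to disk
#'
#' Emits `cohort.vcf`, `cohort.ped`, `annotations.tsv`, `genes.tsv`,
#' `truth.json` and a `manifest.tsv` of MD5 content hashes. All writers use
#' deterministic formatting, so identical configurations produce
#' byte-identical files.
#'
#' @param sim a `trio_sim` object.
#' @param out_dir output directory (created if needed).
#' @return tibble manifest (`file`, `md5`), invisibly.
#' @export
write_fixture_set <- function(sim, out_dir) {
  stopifnot(inherits(sim, "trio_sim"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)

  gt_str <- matrix(c("0/0", "0/1", "1/1")[sim$gt_codes + 1L],
                   nrow(sim$gt_codes))
  write_vcf_matrices(sim$variants, sim$samples, gt_str, sim$gq, sim$dp,
                     sim$ad_ref, sim$ad_alt, file.path(out_dir, "cohort.vcf"))
  utils::write.table(sim$ped[, c("family_id", "sample_id", "father_id",
                                 "mother_id", "sex", "phenotype")],
                     file.path(out_dir, "cohort.ped"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  readr::write_tsv(sim$annotations, file.path(out_dir, "annotations.tsv"))
  readr::write_tsv(sim$panel, file.path(out_dir, "genes.tsv"))
  jsonlite::write_json(
    list(planted_denovo = sim$truth$planted_denovo,
         planted_pairs = sim$truth$planted_pairs,
         pair_carriers = sim$truth$pair_carriers),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)

  files <- c("cohort.vcf", "cohort.ped", "annotations.tsv", "genes.tsv",
             "truth.json")
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}

#' @exportS3Method base::print
print.trio_sim <- function(x, ...) {
  cat(sprintf(
    "<trio_sim> seed %d: %d sites x %d samples (%d trios, %d singletons, %d controls)\n",
    x$config$seed, nrow(x$variants), length(x$samples), x$config$n_trios,
    x$config$n_singletons, x$config$n_controls))
  cat(sprintf("  planted: %d de novo, %d digenic pair(s)\n",
              nrow(x$truth$planted_denovo), nrow(x$truth$planted_pairs)))
  invisible(x)
}
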