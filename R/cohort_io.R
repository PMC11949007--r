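#' Read a 6-column pedigree file
#'
#' Standard PED columns: family, sample, father, mother, sex, phenotype
#' (1 = unaffected, 2 = affected, 0/-9 = unknown). Each sample is assigned a
#' cohort role: affected samples with both parents present form trios
#' (`proband`/`father`/`mother`); affected samples without parents are
#' `singleton` probands; unaffected samples with no family links that are not
#' anyone's parent are unrelated population `control`s. Controls may also be
#' supplied explicitly.
#'
#' @param path path to a whitespace-delimited PED file.
#' @param controls optional character vector of control sample IDs, or the path
#'   to a plain-text file with one sample ID per line. These are added as
#'   controls even if absent from the PED file.
#' @return a tibble with columns `family_id`, `sample_id`, `father_id`,
#'   `mother_id`, `sex`, `phenotype`, `role`.
#' @export
read_pedigree <- function(path, controls = NULL) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family_id", "sample_id", "father_id",
                                         "mother_id", "sex", "phenotype"),
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "integer"))
  ped <- tibble::as_tibble(ped)
  if (anyDuplicated(ped$sample_id)) {
    stop("duplicated sample IDs in PED: ",
         paste(unique(ped$sample_id[duplicated(ped$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  referenced <- setdiff(c(ped$father_id, ped$mother_id), c("0", ped$sample_id))
  if (length(referenced) > 0) {
    stop("PED references parent(s) with no row: ",
         paste(referenced, collapse = ", "), call. = FALSE)
  }

  is_father <- ped$sample_id %in% ped$father_id
  is_mother <- ped$sample_id %in% ped$mother_id
  has_parents <- ped$father_id != "0" & ped$mother_id != "0"
  affected <- ped$phenotype == 2L

  role <- dplyr::case_when(
    affected & has_parents ~ "proband",
    affected & !has_parents ~ "singleton",
    is_father ~ "father",
    is_mother ~ "mother",
    ped$phenotype == 1L & !has_parents ~ "control",
    TRUE ~ "other"
  )
  # a sample may not take two roles within one family (e.g. its own parent)
  bad <- ped$sample_id == ped$father_id | ped$sample_id == ped$mother_id
  if (any(bad)) {
    stop("sample(s) listed as their own parent: ",
         paste(ped$sample_id[bad], collapse = ", "), call. = FALSE)
  }
  ped$role <- role

  if (!is.null(controls)) {
    ids <- if (length(controls) == 1 && file.exists(controls)) {
      readLines(controls, warn = FALSE)
    } else {
      as.character(controls)
    }
    ids <- ids[nzchar(ids)]
    known <- ids %in% ped$sample_id
    ped$role[ped$sample_id %in% ids] <- "control"
    if (any(!known)) {
      ped <- dplyr::bind_rows(ped, tibble::tibble(
        family_id = ids[!known], sample_id = ids[!known],
        father_id = "0", mother_id = "0", sex = 0L, phenotype = 1L,
        role = "control"))
    }
  }
  ped
}

#' Trio table from a pedigree
#'
#' @param pedigree tibble from [read_pedigree()].
#' @return tibble with one row per complete trio: `family_id`, `proband`,
#'   `father`, `mother`.
#' @export
ped_trios <- function(pedigree) {
  pedigree |>
    dplyr::filter(.data$role == "proband") |>
    dplyr::transmute(family_id = .data$family_id, proband = .data$sample_id,
                     father = .data$father_id, mother = .data$mother_id)
}

#' Read a multi-sample cohort VCF plus pedigree
#'
#' Parses a VCF 4.x file with `GT`, `GQ`, `DP` and `AD` FORMAT fields into a
#' long per-genotype tibble. Multiallelic records are split into biallelic
#' variant keys (one ALT allele per key); a sample's genotype for a split key
#' counts only copies of that ALT allele, and its alt depth is the AD entry
#' for that allele. Every PED sample must be present in the VCF.
#'
#' @param vcf_path path to the VCF (plain text or bgzipped).
#' @param ped_path path to the 6-column PED file.
#' @param controls passed to [read_pedigree()].
#' @param missing_format what to do when a FORMAT field (GQ/DP/AD) is absent
#'   for a genotype: `"mask"` records `NA` (the genotype will then fail
#'   strict QC), `"error"` aborts.
#' @return an object of class `trio_cohort`: a list with tibbles `variants`
#'   (`variant_id`, `chrom`, `pos`, `ref`, `alt`, `filter`), `genotypes`
#'   (`variant_id`, `sample_id`, `gt`, `gq`, `dp`, `ad_ref`, `ad_alt`),
#'   `pedigree`, and the VCF `samples` in column order.
#' @export
read_cohort <- function(vcf_path, ped_path, controls = NULL,
                        missing_format = c("mask", "error")) {
  missing_format <- match.arg(missing_format)
  pedigree <- read_pedigree(ped_path, controls = controls)

  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]

  absent <- setdiff(pedigree$sample_id, samples)
  if (length(absent) > 0) {
    stop("PED sample(s) absent from VCF: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }

  if (nrow(vcf@fix) == 0) {
    return(new_cohort(
      variants = tibble::tibble(variant_id = character(), chrom = character(),
                                pos = integer(), ref = character(),
                                alt = character(), filter = character()),
      genotypes = tibble::tibble(variant_id = character(), sample_id = character(),
                                 gt = character(), gq = double(), dp = double(),
                                 ad_ref = double(), ad_alt = double()),
      pedigree = pedigree, samples = samples))
  }

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt_raw <- extract_format(vcf, "GT", missing_format)
  gq_raw <- extract_format(vcf, "GQ", missing_format)
  dp_raw <- extract_format(vcf, "DP", missing_format)
  ad_raw <- extract_format(vcf, "AD", missing_format)

  n_rec <- nrow(fix)
  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  rec_idx <- rep.int(seq_len(n_rec), n_alt)          # original record per key
  allele_idx <- unlist(lapply(n_alt, seq_len))       # ALT allele index per key

  variants <- tibble::tibble(
    chrom = fix$CHROM[rec_idx],
    pos = as.integer(fix$POS)[rec_idx],
    ref = fix$REF[rec_idx],
    alt = unlist(alt_list),
    filter = ifelse(is.na(fix$FILTER[rec_idx]), ".", fix$FILTER[rec_idx])
  )
  variants$variant_id <- variant_id(variants$chrom, variants$pos,
                                    variants$ref, variants$alt)
  if (anyDuplicated(variants$variant_id)) {
    stop("duplicate variant keys after multiallelic split", call. = FALSE)
  }
  variants <- variants[, c("variant_id", "chrom", "pos", "ref", "alt", "filter")]

  # parse GT strings once per unique value (few distinct genotypes in practice)
  gt_u <- unique(as.vector(gt_raw))
  gt_alleles <- strsplit(gsub("|", "/", gt_u, fixed = TRUE), "/", fixed = TRUE)
  names(gt_alleles) <- gt_u

  n_keys <- nrow(variants)
  out_gt <- matrix(NA_character_, n_keys, length(samples))
  out_adr <- matrix(NA_real_, n_keys, length(samples))
  out_ada <- matrix(NA_real_, n_keys, length(samples))

  ad_split <- split_ad(ad_raw)
  for (j in seq_len(max(n_alt))) {
    keys_j <- which(allele_idx == j)
    recs_j <- rec_idx[keys_j]
    al <- gt_alleles[gt_raw[recs_j, , drop = FALSE]]
    cnt <- vapply(al, function(a) {
      if (is.null(a) || length(a) == 0 || anyNA(a) || any(a == "."))
        return(NA_integer_)
      sum(a == as.character(j))
    }, integer(1))
    out_gt[keys_j, ] <- matrix(
      c("hom_ref", "het", "hom_alt")[cnt + 1L], length(keys_j))
    out_adr[keys_j, ] <- ad_split$ref[recs_j, , drop = FALSE]
    out_ada[keys_j, ] <- ad_split$alt[[j]][recs_j, , drop = FALSE]
  }
  out_gt[is.na(out_gt)] <- "missing"

  gq_num <- suppressWarnings(matrix(as.numeric(gq_raw), n_rec))
  dp_num <- suppressWarnings(matrix(as.numeric(dp_raw), n_rec))

  genotypes <- tibble::tibble(
    variant_id = rep(variants$variant_id, times = length(samples)),
    sample_id = rep(samples, each = n_keys),
    gt = as.vector(out_gt),
    gq = as.vector(gq_num[rec_idx, , drop = FALSE]),
    dp = as.vector(dp_num[rec_idx, , drop = FALSE]),
    ad_ref = as.vector(out_adr),
    ad_alt = as.vector(out_ada)
  )

  new_cohort(variants = variants, genotypes = genotypes,
             pedigree = pedigree, samples = samples)
}

new_cohort <- function(variants, genotypes, pedigree, samples,
                       site_qc = NULL, thresholds = NULL) {
  structure(list(variants = variants, genotypes = genotypes,
                 pedigree = pedigree, samples = samples,
                 site_qc = site_qc, thresholds = thresholds),
            class = "trio_cohort")
}

#' @exportS3Method base::print
print.trio_cohort <- function(x, ...) {
  cat(sprintf("<trio_cohort> %d variant(s) x %d sample(s); %s\n",
              nrow(x$variants), length(x$samples),
              if (is.null(x$site_qc)) "unfiltered" else "QC-filtered"))
  roles <- table(x$pedigree$role)
  cat("  roles:", paste(sprintf("%s=%d", names(roles), roles), collapse = " "), "\n")
  invisible(x)
}

extract_format <- function(vcf, element, missing_format) {
  fmt <- vcf@gt[, "FORMAT"]
  if (!any(grepl(element, fmt, fixed = TRUE))) {
    if (missing_format == "error") {
      stop(sprintf("FORMAT field %s absent from VCF", element), call. = FALSE)
    }
    return(matrix(NA_character_, nrow(vcf@fix), ncol(vcf@gt) - 1L,
                  dimnames = list(NULL, colnames(vcf@gt)[-1])))
  }
  m <- vcfR::extract.gt(vcf, element = element, as.numeric = FALSE)
  m[m == "."] <- NA_character_
  m
}

# split AD "ref,alt1[,alt2...]" matrices into numeric ref and per-allele alt
split_ad <- function(ad_raw) {
  u <- unique(as.vector(ad_raw))
  parts <- strsplit(u, ",", fixed = TRUE)
  max_alt <- max(1L, lengths(parts) - 1L)
  ref_u <- vapply(parts, function(p) suppressWarnings(as.numeric(p[1])), double(1))
  alt_u <- lapply(seq_len(max_alt), function(k) {
    vapply(parts, function(p) {
      if (length(p) < k + 1) return(NA_real_)
      suppressWarnings(as.numeric(p[k + 1]))
    }, double(1))
  })
  idx <- match(as.vector(ad_raw), u)
  dims <- dim(ad_raw)
  list(ref = matrix(ref_u[idx], dims[1], dims[2]),
       alt = lapply(alt_u, function(a) matrix(a[idx], dims[1], dims[2])))
}

#' Allele balance of a genotype call
#'
#' The fraction of reads supporting the alternate allele, computed from the
#' allelic depths (`AD`) rather than `DP`, since `DP` may include reads removed
#' by the caller's internal filters.
#'
#' @param ad_ref,ad_alt numeric vectors of reference / alternate read depths.
#' @return `ad_alt / (ad_ref + ad_alt)`, or `NA` where the summed depth is zero
#'   or either depth is missing (such genotypes fail AB-dependent filters under
#'   strict QC).
#' @export
#' @examples
#' allele_balance(5, 5)   # 0.5
#' allele_balance(0, 10)  # 1
allele_balance <- function(ad_ref, ad_alt) {
  tot <- ad_ref + ad_alt
  ifelse(!is.na(tot) & tot > 0, ad_alt / tot, NA_real_)
}

#' Cohort hard-filter thresholds
#'
#' Defaults follow the standard exome QC recipe this package implements:
#' genotypes with GQ < 20, DP < 20, or an allele balance outside the open
#' window (0.3, 0.7) for heterozygotes / not above 0.98 for alt homozygotes
#' are masked to missing; sites with a missing-genotype rate above 10%, an
#' exact Hardy-Weinberg p below 1e-12 (founders only), or a non-PASS FILTER
#' field are dropped.
#'
#' @param gq_min,dp_min per-genotype minimum GQ and DP.
#' @param missing_max maximum per-site missing genotype rate after masking.
#' @param hwe_min minimum exact HWE p-value.
#' @param het_ab open allele-balance window for heterozygotes.
#' @param hom_ab_min strict lower AB bound for alt homozygotes.
#' @param dp_min_controls optional DP override for control samples (genome
#'   controls are commonly held to a lower minimum depth, e.g. 10).
#' @param missing_ad `"strict"` masks a called genotype whose AB is
#'   uncomputable (absent or zero AD); `"lenient"` skips AB filters for it.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(gq_min = 20, dp_min = 20, missing_max = 0.10,
                          hwe_min = 1e-12, het_ab = c(0.3, 0.7),
                          hom_ab_min = 0.98, dp_min_controls = NULL,
                          missing_ad = c("strict", "lenient")) {
  structure(list(gq_min = gq_min, dp_min = dp_min, missing_max = missing_max,
                 hwe_min = hwe_min, het_ab = het_ab, hom_ab_min = hom_ab_min,
                 dp_min_controls = dp_min_controls,
                 missing_ad = match.arg(missing_ad)),
            class = "qc_thresholds")
}

#' Apply cohort hard filters
#'
#' Masks failing genotypes to missing, then drops failing sites. Masking
#' happens before the missing rate is computed, so a site can be lost purely
#' through low-quality genotypes. The operation is idempotent. The
#' Hardy-Weinberg test uses founders only (parents and unrelated controls);
#' probands are excluded because case genotypes can legitimately depart from
#' equilibrium at disease loci.
#'
#' @param cohort a `trio_cohort` from [read_cohort()].
#' @param thresholds a [qc_thresholds()] list.
#' @return the filtered `trio_cohort`, with a `site_qc` tibble (`chrom`,
#'   `pos`, `ref`, `alt`, `missing_rate`, `hwe_p`, `dropped`,
#'   `dropped_reason`) covering every input site.
#' @export
apply_filters <- function(cohort, thresholds = qc_thresholds()) {
  stopifnot(inherits(cohort, "trio_cohort"))
  g <- cohort$genotypes
  if (nrow(g) == 0) {
    cohort$site_qc <- tibble::tibble(
      chrom = character(), pos = integer(), ref = character(), alt = character(),
      missing_rate = double(), hwe_p = double(), dropped = logical(),
      dropped_reason = character())
    cohort$thresholds <- thresholds
    return(cohort)
  }

  role <- cohort$pedigree$role[match(g$sample_id, cohort$pedigree$sample_id)]
  role[is.na(role)] <- "other"
  dp_min <- rep(thresholds$dp_min, nrow(g))
  if (!is.null(thresholds$dp_min_controls)) {
    dp_min[role == "control"] <- thresholds$dp_min_controls
  }

  ab <- allele_balance(g$ad_ref, g$ad_alt)
  called <- g$gt != "missing"
  fail_gq <- is.na(g$gq) | g$gq < thresholds$gq_min
  fail_dp <- is.na(g$dp) | g$dp < dp_min
  ab_known <- !is.na(ab)
  lenient <- thresholds$missing_ad == "lenient"
  fail_ab <- dplyr::case_when(
    g$gt == "het" & ab_known ~
      !(ab > thresholds$het_ab[1] & ab < thresholds$het_ab[2]),
    g$gt == "hom_alt" & ab_known ~ !(ab > thresholds$hom_ab_min),
    g$gt %in% c("het", "hom_alt") & !ab_known ~ !lenient,
    TRUE ~ FALSE
  )
  masked <- called & (fail_gq | fail_dp | fail_ab)
  g$gt[masked] <- "missing"

  founder <- role %in% c("father", "mother", "control")
  site <- g |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(missing_rate = mean(.data$gt == "missing"),
                     .groups = "drop")
  # founder genotype counts for the HWE test
  fg <- g[founder & g$gt != "missing", c("variant_id", "gt")]
  counts <- fg |>
    dplyr::count(.data$variant_id, .data$gt) |>
    tidyr::pivot_wider(names_from = "gt", values_from = "n", values_fill = 0L)
  for (col in c("hom_ref", "het", "hom_alt")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  site <- site |>
    dplyr::select("variant_id", "missing_rate") |>
    dplyr::left_join(counts, by = "variant_id")
  for (col in c("hom_ref", "het", "hom_alt")) {
    site[[col]][is.na(site[[col]])] <- 0L
  }
  n_founder_gt <- site$hom_ref + site$het + site$hom_alt
  site$hwe_p <- NA_real_
  testable <- n_founder_gt > 0
  site$hwe_p[testable] <- hwe_exact_test(site$hom_ref[testable],
                                         site$het[testable],
                                         site$hom_alt[testable])

  v <- dplyr::left_join(cohort$variants, site, by = "variant_id")
  filter_pass <- v$filter %in% c("PASS", ".")
  fail_missing <- v$missing_rate > thresholds$missing_max
  fail_hwe <- !is.na(v$hwe_p) & v$hwe_p < thresholds$hwe_min
  dropped_reason <- dplyr::case_when(
    !filter_pass ~ "filter_field",
    fail_missing ~ "high_missing",
    fail_hwe ~ "hwe",
    TRUE ~ NA_character_
  )

  site_qc <- tibble::tibble(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    missing_rate = v$missing_rate, hwe_p = v$hwe_p,
    dropped = !is.na(dropped_reason), dropped_reason = dropped_reason)

  keep_ids <- v$variant_id[is.na(dropped_reason)]
  cohort$variants <- cohort$variants[cohort$variants$variant_id %in% keep_ids, ]
  cohort$genotypes <- g[g$variant_id %in% keep_ids, ]
  cohort$site_qc <- site_qc
  cohort$thresholds <- thresholds
  cohort
}

#' Write the per-site QC report
#'
#' @param cohort a filtered `trio_cohort`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_qc <- function(cohort, path) {
  stopifnot(!is.null(cohort$site_qc))
  readr::write_tsv(cohort$site_qc, path)
  invisible(path)
}

#' Write a cohort back to VCF
#'
#' Emits a minimal VCF 4.2 with `GT:GQ:DP:AD` genotypes, with deterministic
#' formatting (integers, fixed field order) so that identical cohorts produce
#' byte-identical files.
#'
#' @param cohort a `trio_cohort`.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  v <- cohort$variants
  samples <- cohort$samples
  n_var <- nrow(v)
  ri <- match(cohort$genotypes$variant_id, v$variant_id)
  ci <- match(cohort$genotypes$sample_id, samples)
  idx <- cbind(ri, ci)
  mk <- function(x, fill) {
    m <- matrix(fill, n_var, length(samples)); m[idx] <- x; m
  }
  gt_m <- mk(c("0/0", "0/1", "1/1", "./.")[
    match(cohort$genotypes$gt, GT_LEVELS)], "./.")
  gq_m <- mk(cohort$genotypes$gq, NA_real_)
  dp_m <- mk(cohort$genotypes$dp, NA_real_)
  adr_m <- mk(cohort$genotypes$ad_ref, NA_real_)
  ada_m <- mk(cohort$genotypes$ad_alt, NA_real_)
  write_vcf_matrices(v, samples, gt_m, gq_m, dp_m, adr_m, ada_m, path)
}

# shared deterministic VCF text writer; gt_m is a character genotype matrix
write_vcf_matrices <- function(variants, samples, gt_m, gq_m, dp_m,
                               adr_m, ada_m, path) {
  fmt_int <- function(m) {
    x <- ifelse(is.na(m), ".", format(as.integer(round(m)), trim = TRUE,
                                      scientific = FALSE))
    matrix(x, nrow(m))
  }
  gq_c <- fmt_int(gq_m); dp_c <- fmt_int(dp_m)
  ad_c <- matrix(paste(fmt_int(adr_m), fmt_int(ada_m), sep = ","), nrow(gq_c))
  ad_c[is.na(adr_m) & is.na(ada_m)] <- "."
  cell <- matrix(paste(gt_m, gq_c, dp_c, ad_c, sep = ":"), nrow(gq_c))

  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ".", variants$filter, ".", "GT:GQ:DP:AD", sep = "\t")
  for (j in seq_along(samples)) body <- paste(body, cell[, j], sep = "\t")

  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body), path, sep = "\n")
  invisible(path)
}
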