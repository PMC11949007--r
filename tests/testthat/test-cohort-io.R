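test_that("pedigree parsing assigns trio, singleton and control roles", {
  ped_df <- tibble::tibble(
    family_id = c("F1", "F1", "F1", "FS1", "K1"),
    sample_id = c("P1", "FA1", "MO1", "S1", "K1"),
    father_id = c("FA1", "0", "0", "0", "0"),
    mother_id = c("MO1", "0", "0", "0", "0"),
    sex = c(1L, 1L, 2L, 1L, 0L),
    phenotype = c(2L, 1L, 1L, 2L, 1L))
  ped <- read_pedigree(write_test_ped(ped_df))
  expect_equal(ped$role[match(c("P1", "FA1", "MO1", "S1", "K1"), ped$sample_id)],
               c("proband", "father", "mother", "singleton", "control"))
  trios <- ped_trios(ped)
  expect_equal(nrow(trios), 1)
  expect_equal(trios$father, "FA1")

  # explicit control list adds samples not present in the PED
  ped2 <- read_pedigree(write_test_ped(ped_df), controls = c("X9"))
  expect_true("X9" %in% ped2$sample_id)
  expect_equal(ped2$role[ped2$sample_id == "X9"], "control")

  # referenced parent with no row is a hard error
  bad <- ped_df[ped_df$sample_id != "MO1", ]
  expect_error(read_pedigree(write_test_ped(bad)), "MO1")
})

test_that("multiallelic records split into biallelic keys conserving carriers", {
  ped_df <- data.frame(f = c("F1", "F1", "F1"), s = c("P1", "FA1", "MO1"),
                       fa = c("FA1", "0", "0"), mo = c("MO1", "0", "0"),
                       sex = c(1, 1, 2), ph = c(2, 1, 1))
  vcf <- write_test_vcf(c(
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tP1\tFA1\tMO1"),
    "1\t100\t.\tC\tA,T\t.\tPASS\t.\tGT:GQ:DP:AD\t0/1:99:30:15,15,0\t0/2:99:30:14,0,16\t1/2:99:30:0,15,15",
    "1\t200\t.\tG\tA\t.\tPASS\t.\tGT:GQ:DP:AD\t0/1:80:40:20,20\t0/0:70:40:40,0\t./.:.:.:."))
  co <- read_cohort(vcf, write_test_ped(ped_df))

  expect_equal(nrow(co$variants), 3)
  split_keys <- co$variants[co$variants$pos == 100, ]
  expect_equal(sort(split_keys$alt), c("A", "T"))
  expect_equal(unique(split_keys$ref), "C")

  g <- co$genotypes
  gt_at <- function(vid, sid) g$gt[g$variant_id == vid & g$sample_id == sid]
  # P1 0/1 -> het for ALT A, hom_ref for ALT T
  expect_equal(gt_at("1:100:C:A", "P1"), "het")
  expect_equal(gt_at("1:100:C:T", "P1"), "hom_ref")
  # MO1 1/2 -> het for both split keys
  expect_equal(gt_at("1:100:C:A", "MO1"), "het")
  expect_equal(gt_at("1:100:C:T", "MO1"), "het")
  # carrier conservation: alt-carrying samples across split keys = original
  carriers_split <- unique(g$sample_id[g$variant_id %in% split_keys$variant_id &
                                         g$gt %in% c("het", "hom_alt")])
  expect_setequal(carriers_split, c("P1", "FA1", "MO1"))
  # per-allele AD extraction
  expect_equal(g$ad_alt[g$variant_id == "1:100:C:T" & g$sample_id == "FA1"], 16)
  expect_equal(g$ad_ref[g$variant_id == "1:100:C:T" & g$sample_id == "FA1"], 14)
  # missing genotype round-trips as missing with NA metrics
  expect_equal(gt_at("1:200:G:A", "MO1"), "missing")

  # PED sample absent from the VCF is a hard error naming the sample
  ped_extra <- rbind(ped_df, data.frame(f = "F2", s = "GHOST", fa = "0",
                                        mo = "0", sex = 1, ph = 2))
  expect_error(read_cohort(vcf, write_test_ped(ped_extra)), "GHOST")
})

test_that("empty VCF body yields an empty cohort with a valid pedigree", {
  ped_df <- data.frame(f = "F1", s = "P1", fa = "0", mo = "0", sex = 1, ph = 2)
  vcf <- write_test_vcf("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tP1")
  co <- read_cohort(vcf, write_test_ped(ped_df))
  expect_equal(nrow(co$variants), 0)
  expect_equal(nrow(co$genotypes), 0)
  expect_equal(nrow(co$pedigree), 1)
  # filtering a degenerate cohort is a no-op
  expect_equal(nrow(apply_filters(co)$site_qc), 0)
})

test_that("allele balance follows AD arithmetic with an undefined marker", {
  expect_equal(allele_balance(5, 5), 0.5)
  expect_equal(allele_balance(7, 3), 0.3)
  expect_equal(allele_balance(0, 10), 1.0)
  expect_true(is.na(allele_balance(0, 0)))
  expect_true(is.na(allele_balance(NA, 5)))
})

test_that("genotype masks and site drops follow the hard-filter rules", {
  ped <- mk_ped(n_trios = 1, n_controls = 7)
  v <- mk_variants(3)
  g <- dplyr::bind_rows(
    # site 1: het with GQ 19 -> masked despite good DP/AB
    mk_gt(v$variant_id[1], "P1", "het", gq = 19, dp = 30),
    # site 2: hom_alt with AB 0.99 -> retained
    mk_gt(v$variant_id[2], "P1", "hom_alt", gq = 60, dp = 40,
          ad_alt = 39.6, ad_ref = 0.4),
    # site 3: het at AB exactly 0.3 fails the open window
    mk_gt(v$variant_id[3], "P1", "het", gq = 99, dp = 40,
          ad_ref = 28, ad_alt = 12))
  co <- apply_filters(mk_cohort(v, g, ped))
  gt_of <- function(vid) co$genotypes$gt[co$genotypes$variant_id == vid &
                                           co$genotypes$sample_id == "P1"]
  expect_equal(gt_of(v$variant_id[1]), "missing")
  expect_equal(gt_of(v$variant_id[2]), "hom_alt")
  expect_equal(gt_of(v$variant_id[3]), "missing")
  # 1 masked genotype out of 10 samples = 10% missing, not > 10%: site kept
  expect_true(all(!co$site_qc$dropped))

  # with only 9 samples the masked genotype pushes missingness past 10%
  ped9 <- mk_ped(n_trios = 1, n_controls = 6)
  co9 <- apply_filters(mk_cohort(v, g, ped9))
  expect_equal(co9$site_qc$dropped_reason[1], "high_missing")
  expect_false(v$variant_id[1] %in% co9$variants$variant_id)

  # non-PASS FILTER drops the site regardless of genotypes
  v_fail <- v; v_fail$filter[2] <- "VQSRTrancheSNP99.80"
  cof <- apply_filters(mk_cohort(v_fail, g, ped))
  expect_equal(cof$site_qc$dropped_reason[2], "filter_field")
})

test_that("filtering is idempotent and monotone in the thresholds", {
  set.seed(11)
  ped <- mk_ped(n_trios = 2, n_controls = 10)
  v <- mk_variants(12)
  g <- tidyr::expand_grid(variant_id = v$variant_id,
                          sample_id = ped$sample_id) |>
    dplyr::mutate(gt = sample(c("hom_ref", "het", "hom_alt"), dplyr::n(),
                              replace = TRUE, prob = c(0.7, 0.25, 0.05)),
                  dp = rpois(dplyr::n(), 35),
                  gq = sample(5:99, dplyr::n(), replace = TRUE),
                  ad_alt = rbinom(dplyr::n(), dp,
                                  c(hom_ref = 0.01, het = 0.5,
                                    hom_alt = 0.99)[gt]),
                  ad_ref = dp - ad_alt)
  co <- trioscreen:::new_cohort(v, g, ped, ped$sample_id)

  once <- apply_filters(co)
  twice <- apply_filters(once)
  expect_equal(twice$variants, once$variants)
  expect_equal(twice$genotypes, once$genotypes)
  # site_qc covers the respective input sites; surviving sites keep their rates
  kept <- once$site_qc[!once$site_qc$dropped, ]
  expect_equal(twice$site_qc$missing_rate, kept$missing_rate)
  expect_false(any(twice$site_qc$dropped))

  # raising gq_min can only mask more genotypes and drop more sites
  strict <- apply_filters(co, qc_thresholds(gq_min = 40))
  loose_missing <- once$genotypes$variant_id[once$genotypes$gt == "missing"]
  strict_missing <- strict$genotypes |>
    dplyr::filter(.data$gt == "missing") |>
    dplyr::pull(variant_id)
  kept_both <- intersect(strict$variants$variant_id, once$variants$variant_id)
  loose_n <- sum(once$genotypes$gt == "missing" &
                   once$genotypes$variant_id %in% kept_both)
  strict_n <- sum(strict$genotypes$gt == "missing" &
                    strict$genotypes$variant_id %in% kept_both)
  expect_gte(strict_n, loose_n)
  expect_true(all(strict$variants$variant_id %in% once$variants$variant_id))
})

test_that("controls can run under a relaxed depth minimum", {
  ped <- mk_ped(n_trios = 1, n_controls = 9)
  v <- mk_variants(1)
  g <- dplyr::bind_rows(
    mk_gt(v$variant_id[1], "C1", "het", gq = 80, dp = 14),
    mk_gt(v$variant_id[1], "P1", "het", gq = 80, dp = 14))
  co <- apply_filters(mk_cohort(v, g, ped),
                      qc_thresholds(dp_min_controls = 10))
  g2 <- co$genotypes
  expect_equal(g2$gt[g2$sample_id == "C1"], "het")     # 14 >= 10
  expect_equal(g2$gt[g2$sample_id == "P1"], "missing") # 14 < 20
})

test_that("VCF round-trip preserves genotypes and metrics", {
  ped <- mk_ped(n_trios = 1, n_controls = 2)
  v <- mk_variants(4)
  g <- dplyr::bind_rows(
    mk_gt(v$variant_id[1], "P1", "het", gq = 61, dp = 33, ad_alt = 15),
    mk_gt(v$variant_id[2], "C1", "hom_alt", gq = 50, dp = 28),
    mk_gt(v$variant_id[3], "C2", "missing"))
  co <- mk_cohort(v, g, ped)
  path <- tempfile(fileext = ".vcf")
  write_cohort_vcf(co, path)
  back <- read_cohort(path, write_test_ped(
    co$pedigree[, c("family_id", "sample_id", "father_id", "mother_id",
                    "sex", "phenotype")]))
  key <- function(x) dplyr::arrange(x$genotypes, variant_id, sample_id)
  a <- key(co); b <- key(back)
  expect_equal(b$gt, a$gt)
  expect_equal(b$dp[b$gt != "missing"], a$dp[a$gt != "missing"])
  expect_equal(b$ad_alt[b$gt != "missing"], round(a$ad_alt[a$gt != "missing"]))
})
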