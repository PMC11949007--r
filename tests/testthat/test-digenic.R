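test_that("haploinsufficient gene selection is strict and autosomal", {
  gt <- mk_gene_table(c("A1", "A2", "A3", "A4"),
                      chrom = c("7", "7", "X", "12"),
                      pli = c(0.95, 0.90, 0.99, NA))
  hi <- suppressMessages(select_hi_genes(gt))
  expect_equal(hi, "A1")  # 0.90 excluded (strict), chrX excluded, NA skipped
})

test_that("qualifying variants obey zygosity, rarity, class and pLI gates", {
  genes <- mk_gene_table(c("HIA", "HIB", "LOW"), chrom = c("1", "2", "3"),
                         pli = c(0.97, 0.95, 0.5))
  v <- mk_variants(6)
  ann <- mk_ann(v, gene = c("HIA", "HIA", "HIB", "LOW", "HIB", "HIA"),
                consequence = c("missense", "missense", "nonsense",
                                "nonsense", "missense", "missense"),
                pop_af = c(0.001, 0.001, 0, 0, 0.005, 0.001),
                dann = c(0.99, 0.99, 0.5, 0.5, 0.99, 0.99),
                dann_rank = 0.9)
  ped <- mk_ped(1)
  g <- dplyr::bind_rows(
    mk_gt(v$variant_id[1], "P1", "het"),   # D-mis rare HIA -> qualifies
    mk_gt(v$variant_id[1], "FA1", "het"),  # father carries -> paternal
    mk_gt(v$variant_id[2], "P1", "hom_alt"),  # hom-alt excluded
    mk_gt(v$variant_id[3], "P1", "het"),   # LGD HIB, neither parent -> denovo
    mk_gt(v$variant_id[4], "P1", "het"),   # LGD but pLI 0.5 -> excluded
    mk_gt(v$variant_id[5], "P1", "het"),   # pop_af at 0.5% -> not rare
    mk_gt(v$variant_id[6], "P1", "het"),   # carried by both parents
    mk_gt(v$variant_id[6], "FA1", "het"),
    mk_gt(v$variant_id[6], "MO1", "het"))
  co <- mk_cohort(v, g, ped)
  q <- collect_qualifying(co, ann, genes)
  expect_setequal(q$variant_id, v$variant_id[c(1, 3, 6)])
  origin <- setNames(q$origin, q$variant_id)
  expect_equal(unname(origin[v$variant_id[1]]), "paternal")
  expect_equal(unname(origin[v$variant_id[3]]), "denovo")
  expect_equal(unname(origin[v$variant_id[6]]), "unknown")
})

test_that("pair enumeration yields C(k,2) pairs, matching brute force", {
  for (k in c(2, 3, 10, 60, 200)) {
    q <- mk_qual("P1", sprintf("G%04d", seq_len(k)),
                 sprintf("v%d", seq_len(k)))
    couples <- enumerate_pairs(q)
    pairs <- dplyr::distinct(couples, gene_a, gene_b)
    expect_equal(nrow(pairs), pair_count_oracle(k))
    expect_true(all(pairs$gene_a < pairs$gene_b))
  }
  expect_equal(nrow(enumerate_pairs(mk_qual("P1", "G1", "v1"))), 0)
})

test_that("biparental origin logic keeps only two-haplotype couples", {
  # both variants paternal: pair dies under the restriction
  q <- dplyr::bind_rows(mk_qual("P1", "GA", "v1", origin = "paternal"),
                        mk_qual("P1", "GB", "v2", origin = "paternal"))
  expect_equal(nrow(enumerate_pairs(q, biparental_samples = "P1")), 0)
  expect_equal(nrow(enumerate_pairs(q)), 1) # unrestricted keeps it

  # paternal + maternal, paternal + denovo, denovo + denovo all survive
  for (orig in list(c("paternal", "maternal"), c("paternal", "denovo"),
                    c("maternal", "denovo"), c("denovo", "denovo"))) {
    q2 <- dplyr::bind_rows(mk_qual("P1", "GA", "v1", origin = orig[1]),
                           mk_qual("P1", "GB", "v2", origin = orig[2]))
    expect_equal(nrow(enumerate_pairs(q2, biparental_samples = "P1")), 1,
                 info = paste(orig, collapse = "+"))
  }
  # unknown origin cannot certify biparental transmission
  q3 <- dplyr::bind_rows(mk_qual("P1", "GA", "v1", origin = "unknown"),
                         mk_qual("P1", "GB", "v2", origin = "maternal"))
  expect_equal(nrow(enumerate_pairs(q3, biparental_samples = "P1")), 0)

  # evidence couples: 2 variants in GA x 1 in GB -> 2 couples unrestricted
  q4 <- dplyr::bind_rows(mk_qual("P1", "GA", "v1"),
                         mk_qual("P1", "GA", "v2"),
                         mk_qual("P1", "GB", "v3"))
  expect_equal(nrow(enumerate_pairs(q4)), 2)
})

test_that("unaffected-pair exclusion is gene-pair-level and anti-monotone", {
  pairs <- tibble::tibble(sample_id = "P1",
                          gene_a = c("GA", "GA", "GC"),
                          gene_b = c("GB", "GC", "GD"))
  hits <- tibble::tibble(sample_id = c("C1", "C1", "C2"),
                         gene = c("GA", "GB", "GC"))
  out <- exclude_unaffected_pairs(pairs, hits)
  expect_equal(out$excluded, c(TRUE, FALSE, FALSE))
  # a control hitting only one gene of a pair never excludes it
  out1 <- exclude_unaffected_pairs(pairs,
                                   tibble::tibble(sample_id = "C9", gene = "GA"))
  expect_false(any(out1$excluded))
  # empty control set retains everything
  out0 <- exclude_unaffected_pairs(pairs,
                                   tibble::tibble(sample_id = character(),
                                                  gene = character()))
  expect_false(any(out0$excluded))

  # anti-monotone under randomly grown control sets: S subset T
  set.seed(8)
  genes <- sprintf("G%02d", 1:12)
  qp <- mk_qual("P1", genes, paste0("v", seq_along(genes)))
  allp <- dplyr::distinct(enumerate_pairs(qp), sample_id, gene_a, gene_b)
  small <- tibble::tibble(
    sample_id = sample(sprintf("C%d", 1:5), 14, replace = TRUE),
    gene = sample(genes, 14, replace = TRUE))
  for (rep in 1:5) {
    extra <- tibble::tibble(
      sample_id = sample(sprintf("C%d", 1:8), 10, replace = TRUE),
      gene = sample(genes, 10, replace = TRUE))
    big <- dplyr::bind_rows(small, extra)
    surv_small <- exclude_unaffected_pairs(allp, small)
    surv_big <- exclude_unaffected_pairs(allp, big)
    key <- function(x) paste(x$gene_a, x$gene_b)[!x$excluded]
    expect_true(all(key(surv_big) %in% key(surv_small)))
  }
})

test_that("stand-in pair score multiplies deleteriousness by pLI means", {
  genes <- mk_gene_table(c("GA", "GB"), chrom = c("1", "2"),
                         pli = c(0.95, 0.99))
  # D-mis with dann_rank 0.8 + LGD: 0.5*(0.8+1.0) * 0.5*(0.95+0.99) = 0.873
  q <- dplyr::bind_rows(mk_qual("P1", "GA", "v1", dann_rank = 0.8),
                        mk_qual("P1", "GB", "v2", lgd = TRUE))
  p <- score_pairs(enumerate_pairs(q), genes)
  expect_equal(p$score, 0.873)
  expect_equal(p$zone, "zone999")

  # two LGD variants in pLI-1.0 genes reach the maximal score 1
  genes1 <- mk_gene_table(c("GA", "GB"), chrom = c("1", "2"), pli = 1)
  q1 <- dplyr::bind_rows(mk_qual("P1", "GA", "v1", lgd = TRUE),
                         mk_qual("P1", "GB", "v2", lgd = TRUE))
  expect_equal(score_pairs(enumerate_pairs(q1), genes1)$score, 1)

  # best-couple selection: adding a weaker couple never lowers the score
  q2 <- dplyr::bind_rows(q, mk_qual("P1", "GA", "v3", dann_rank = 0.1))
  expect_equal(score_pairs(enumerate_pairs(q2), genes)$score, 0.873)

  # external score column overrides the stand-in verbatim
  ext <- tibble::tibble(sample_id = "P1", gene_a = "GA", gene_b = "GB",
                        score = 0.42)
  pe <- score_pairs(enumerate_pairs(q), genes, external_scores = ext)
  expect_equal(pe$score, 0.42)

  # zone assignment follows the ordered cutoffs
  cfg <- screen_config()
  sc <- function(s) score_pairs(
    dplyr::mutate(enumerate_pairs(q), d_a = s, d_b = s),
    mk_gene_table(c("GA", "GB"), chrom = c("1", "2"), pli = 1), cfg)$zone
  expect_equal(sc(0.3), "neutral")
  expect_equal(sc(0.6), "candidate")
  expect_equal(sc(0.75), "zone99")
  expect_equal(sc(0.9), "zone999")
})

test_that("expression filter needs brain or skeletal expression in both genes", {
  genes <- mk_gene_table(c("GA", "GB", "GC"), chrom = c("1", "2", "3"))
  genes$brain_expressed <- c(TRUE, FALSE, FALSE)
  genes$skeletal_expressed <- c(FALSE, TRUE, FALSE)
  pairs <- tibble::tibble(sample_id = "P1",
                          gene_a = c("GA", "GA"), gene_b = c("GB", "GC"))
  out <- expression_filter(pairs, genes)
  expect_equal(out$expressed, c(TRUE, FALSE))
  empty <- expression_filter(pairs[0, ], genes)
  expect_equal(nrow(empty), 0)
})

test_that("recurrence tiers pairs by the number of unrelated carriers", {
  pairs <- tibble::tibble(
    sample_id = c("P051", "P093", "P007"),
    gene_a = c("IL6ST", "IL6ST", "AAG1"),
    gene_b = c("TRPS1", "TRPS1", "ZZG2"))
  rec <- recurrent_pairs(pairs)
  expect_equal(rec$tier[rec$gene_a == "IL6ST"], "recurrent")
  expect_equal(rec$n_probands[rec$gene_a == "IL6ST"], 2)
  expect_equal(rec$tier[rec$gene_a == "AAG1"], "singleton")
  expect_equal(nrow(recurrent_pairs(pairs[0, ])), 0)
})

test_that("exclusion and expression filters commute in the pipeline", {
  set.seed(21)
  genes <- mk_gene_table(sprintf("G%02d", 1:10), chrom = as.character(1:10))
  genes$brain_expressed <- runif(10) < 0.5
  genes$skeletal_expressed <- runif(10) < 0.5
  q <- mk_qual("P1", genes$gene, paste0("v", 1:10))
  pairs <- dplyr::distinct(enumerate_pairs(q), sample_id, gene_a, gene_b)
  hits <- tibble::tibble(sample_id = sample(c("C1", "C2"), 8, replace = TRUE),
                         gene = sample(genes$gene, 8, replace = TRUE))
  a <- expression_filter(exclude_unaffected_pairs(pairs, hits), genes)
  b <- exclude_unaffected_pairs(expression_filter(pairs, genes), hits)
  surv <- function(x) paste(x$gene_a, x$gene_b)[!x$excluded & x$expressed]
  expect_setequal(surv(a), surv(b))
})

test_that("full screen recovers a case pair and honours control exclusion", {
  genes <- mk_gene_table(c("HIA", "HIB", "HIC"), chrom = c("1", "2", "3"),
                         pli = c(0.97, 0.96, 0.98))
  v <- mk_variants(8)
  ann <- mk_ann(v,
                gene = c("HIA", "HIB", "HIA", "HIB", "HIC", "HIA", "HIC", "HIB"),
                consequence = "missense", pop_af = 0.001, dann = 0.99,
                dann_rank = 0.97)
  ped <- mk_ped(n_trios = 1, n_singletons = 1, n_controls = 2)
  g <- dplyr::bind_rows(
    # trio proband: HIA paternal + HIB maternal
    mk_gt(v$variant_id[1], "P1", "het"), mk_gt(v$variant_id[1], "FA1", "het"),
    mk_gt(v$variant_id[2], "P1", "het"), mk_gt(v$variant_id[2], "MO1", "het"),
    # the same gene pair in the singleton proband (different variants)
    mk_gt(v$variant_id[3], "S1", "het"), mk_gt(v$variant_id[4], "S1", "het"),
    # trio proband also has HIC de novo -> pairs (HIA,HIC), (HIB,HIC)
    mk_gt(v$variant_id[5], "P1", "het"),
    # control C1 carries hits in both HIB and HIC -> that pair is excluded
    mk_gt(v$variant_id[7], "C1", "het"), mk_gt(v$variant_id[8], "C1", "het"))
  co <- mk_cohort(v, g, ped)
  scr <- digenic_screen(co, ann, genes)

  rep_pairs <- scr$pairs[scr$pairs$reported, ]
  expect_true(all(rep_pairs$gene_a < rep_pairs$gene_b))
  # (HIA,HIB) reported for both probands -> recurrent
  expect_equal(scr$recurrence$tier[scr$recurrence$gene_a == "HIA" &
                                     scr$recurrence$gene_b == "HIB"],
               "recurrent")
  # (HIB,HIC) present in the trio proband but excluded via control C1
  expect_true(any(scr$pairs$gene_a == "HIB" & scr$pairs$gene_b == "HIC" &
                    scr$pairs$excluded))
  expect_false(any(rep_pairs$gene_a == "HIB" & rep_pairs$gene_b == "HIC"))

  # results invariant under proband input order
  co2 <- co
  co2$genotypes <- co$genotypes[rev(seq_len(nrow(co$genotypes))), ]
  scr2 <- digenic_screen(co2, ann, genes)
  expect_equal(scr2$recurrence, scr$recurrence)
  expect_equal(glance(scr2), glance(scr))

  # report writer produces the ledger and the stage-count JSON
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_pair_report(scr, tsv, js)
  led <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_true(all(c("excluded", "zone", "expressed", "reported") %in% names(led)))
  counts <- jsonlite::read_json(js)
  expect_equal(counts$gene_pairs_recurrent, 1)
})
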