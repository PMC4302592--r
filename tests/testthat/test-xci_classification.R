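test_that("paternal fraction is reads over coverage", {
  expect_equal(paternal_fraction(0, 50), 0)
  expect_equal(paternal_fraction(3, 7), 0.30)
  expect_equal(paternal_fraction(5, 5), 0.5)
  expect_error(paternal_fraction(0, 0), "zero coverage")
})

test_that("the >10% minor-allele rule classifies SNPs with a strict boundary", {
  expect_equal(classify_snp(3, 7), "escaper")                 # 30/70
  expect_equal(classify_snp(0, 50), "paternal_inactivated")   # 0/100
  expect_equal(classify_snp(50, 0), "maternal_inactivated")
  # exactly 10% minor is NOT an escaper ("more than 10%")
  expect_equal(classify_snp(1, 9), "paternal_inactivated")
  expect_equal(classify_snp(9, 1), "maternal_inactivated")
  expect_equal(classify_snp(11, 89, escape_threshold = 0.10), "escaper")
})

test_that("classification is symmetric under parental label swap", {
  set.seed(11)
  for (i in 1:100) {
    p <- sample(0:40, 1); m <- sample(0:40, 1)
    if (p + m == 0) m <- 1
    a <- classify_snp(p, m)
    b <- classify_snp(m, p)
    swapped <- c(escaper = "escaper",
                 paternal_inactivated = "maternal_inactivated",
                 maternal_inactivated = "paternal_inactivated")
    expect_equal(b, unname(swapped[a]))
  }
})

test_that("intergenic SNPs ~1.3 kb apart form separate loci", {
  snps <- tibble::tibble(
    scaffold = "Scaffold28735",
    pos = c(1000L, 1100L, 2400L),   # third SNP 1.3 kb downstream
    maternal_reads = c(6L, 7L, 20L),
    paternal_reads = c(5L, 5L, 0L),
    status = c("escaper", "escaper", "paternal_inactivated")
  )
  loci <- aggregate_loci(snps, NULL, intergenic_cluster_bp = 1000)
  expect_equal(nrow(loci), 2)
  expect_equal(sort(loci$status),
               c("escaper", "paternal_inactivated"))
  expect_false(any(loci$conflict_flag))
})

test_that("locus status is unanimity, then majority, then tie-to-escaper", {
  ann <- tibble::tibble(gene_id = "g1", gene_name = "g1", scaffold = "S1",
                        start = 1L, end = 10000L,
                        exons = list(data.frame(start = 1, end = 10000)))
  un <- tibble::tibble(scaffold = "S1", pos = c(10L, 20L, 30L),
                       maternal_reads = 10L, paternal_reads = 0L,
                       status = "paternal_inactivated")
  l1 <- aggregate_loci(un, ann)
  expect_equal(nrow(l1), 1)
  expect_equal(l1$status, "paternal_inactivated")
  expect_false(l1$conflict_flag)
  expect_equal(l1$kind, "gene")

  tie <- tibble::tibble(scaffold = "S1", pos = c(10L, 20L),
                        maternal_reads = c(5L, 10L),
                        paternal_reads = c(5L, 0L),
                        status = c("escaper", "paternal_inactivated"))
  l2 <- aggregate_loci(tie, ann)
  expect_equal(l2$status, "escaper")
  expect_true(l2$conflict_flag)

  maj <- tibble::tibble(scaffold = "S1", pos = c(10L, 20L, 30L),
                        maternal_reads = c(10L, 10L, 5L),
                        paternal_reads = c(0L, 0L, 5L),
                        status = c("paternal_inactivated",
                                   "paternal_inactivated", "escaper"))
  l3 <- aggregate_loci(maj, ann)
  expect_equal(l3$status, "paternal_inactivated")
  expect_true(l3$conflict_flag)
  # read-weighted locus fraction
  expect_equal(l3$mean_paternal_fraction, 5 / 30)

  # ambiguous SNPs are retained but do not vote
  amb <- tibble::tibble(scaffold = "S1", pos = c(10L, 20L),
                        maternal_reads = c(10L, 4L),
                        paternal_reads = c(0L, 4L),
                        status = c("paternal_inactivated", "ambiguous"))
  l4 <- aggregate_loci(amb, ann)
  expect_equal(l4$status, "paternal_inactivated")
  expect_false(l4$conflict_flag)
  expect_equal(l4$n_snps, 2L)
})

test_that("loci partition the SNP set", {
  set.seed(3)
  snps <- tibble::tibble(
    scaffold = sample(c("S1", "S2"), 40, replace = TRUE),
    pos = sample(1:50000, 40),
    maternal_reads = sample(1:20, 40, replace = TRUE),
    paternal_reads = sample(0:20, 40, replace = TRUE),
    status = sample(c("escaper", "paternal_inactivated"), 40, replace = TRUE)
  )
  ann <- tibble::tibble(gene_id = "gA", gene_name = "gA", scaffold = "S1",
                        start = 1L, end = 20000L,
                        exons = list(data.frame(start = 1, end = 20000)))
  loci <- aggregate_loci(snps, ann)
  all_snps <- dplyr::bind_rows(loci$snps)
  expect_equal(nrow(all_snps), nrow(snps))
  expect_equal(sum(loci$n_snps), nrow(snps))
  key <- paste(all_snps$scaffold, all_snps$pos)
  expect_false(any(duplicated(key)))
})

test_that("escape summary counts reconcile and ignore locus order", {
  snps <- tibble::tibble(
    scaffold = "S1",
    pos = as.integer(seq(1000, by = 5000, length.out = 34)),
    maternal_reads = 10L,
    paternal_reads = as.integer(c(rep(0, 23), rep(8, 11))),
    status = c(rep("paternal_inactivated", 23), rep("escaper", 11))
  )
  loci <- aggregate_loci(snps, NULL)
  s <- summarize_escape(loci)
  expect_equal(s$n_loci, 34L)
  expect_equal(s$n_escaper, 11L)
  expect_equal(s$escape_fraction, 11 / 34)
  expect_equal(s$n_paternal_inactivated + s$n_maternal_inactivated +
                 s$n_escaper + s$n_ambiguous, s$n_loci)
  set.seed(2)
  s2 <- summarize_escape(loci[sample(nrow(loci)), ])
  expect_equal(s2, s)
  expect_error(summarize_escape(loci[0, ]), "no loci")
})

test_that("biallelic-only mode classifies by minor-allele fraction alone", {
  obs <- make_obs("mother", "transcriptome", "S1",
                  c(1000, 9000, 17000), "A", "G",
                  c(46, 95, 20), c(54, 5, 0))
  res <- classify_biallelic_only(obs, NULL)
  # 46/54 escapes; 95/5 is biallelic but below threshold; 20/0 never enters
  expect_equal(res$summary$n_loci, 2L)
  expect_equal(res$summary$n_escaper, 1L)
  expect_warning(
    out <- classify_biallelic_only(obs[obs$pos == 17000, ], NULL),
    "no biallelic")
  expect_equal(out$summary$n_loci, 0L)
})
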