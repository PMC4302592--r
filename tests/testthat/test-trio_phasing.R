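test_that("phasing matches the Mendelian enumeration oracle on the full truth table", {
  mothers <- c("hom_ref", "hom_alt", "het", "unknown")
  fathers <- c("ref", "alt", NA_character_)
  expressions <- list(ref_only = c(10L, 0L), alt_only = c(0L, 10L),
                      both = c(6L, 4L))
  for (m in mothers) for (f in fathers) for (e in names(expressions)) {
    reads <- expressions[[e]]
    site <- make_trio_site(m, f, reads[1], reads[2])
    got <- phase_trio_sites(site)
    expressed <- c("ref", "alt")[reads > 0]
    want <- oracle_phase(m, f, expressed)
    label <- paste(m, ifelse(is.na(f), "absent", f), e)
    expect_equal(got$phase == "phased", want$phase == "phased", info = label)
    if (want$phase == "phased") {
      allele <- function(x) ifelse(x == "ref", "A", "G")
      expect_equal(got$maternal_allele, allele(want$maternal), info = label)
      expect_equal(got$paternal_allele, allele(want$paternal), info = label)
    }
    # genotype classes agree whenever the evidence is Mendelian-consistent
    if (want$genotype != "unknown") {
      expect_equal(got$genotype, want$genotype, info = label)
    }
  }
})

test_that("monoallelic daughters with forcing parents are inferred heterozygous", {
  # daughter expresses only ref; mother hom ref; father carries alt
  s <- make_trio_site("hom_ref", "alt", 12, 0)
  p <- phase_trio_sites(s)
  expect_equal(p$genotype, "het_inferred")
  expect_equal(p$maternal_allele, "A")
  expect_equal(p$paternal_allele, "G")
  expect_equal(p$paternal_reads, 0L)
  expect_equal(p$maternal_reads, 12L)

  # both alleles expressed -> observed het
  expect_equal(infer_daughter_genotype(make_trio_site("unknown", "ref", 3, 3)),
               "het_observed")
  # mother het, father matching the only expressed allele: unresolved
  expect_equal(infer_daughter_genotype(make_trio_site("het", "ref", 10, 0)),
               "unknown")
  # expressed allele neither parent can donate: logged, not raised
  s2 <- make_trio_site("hom_ref", "ref", 0, 8)
  p2 <- phase_trio_sites(s2)
  expect_equal(p2$genotype, "unknown")
  expect_equal(p2$reason, "mendelian_inconsistent")
})

test_that("parent-of-origin assignment splits reads and respects exclusions", {
  # forced by hemizygosity: paternal ref with 0 reads, maternal alt with 50
  s <- make_trio_site("hom_alt", "ref", 0, 50)
  snp <- assign_parent_of_origin(s)
  expect_equal(nrow(snp), 1)
  expect_equal(snp$paternal_allele, "A")
  expect_equal(snp$paternal_reads, 0L)
  expect_equal(snp$maternal_reads, 50L)

  # mother hom for the father's allele cannot donate the other: ambiguous
  s2 <- make_trio_site("hom_alt", "alt", 5, 5)
  snp2 <- assign_parent_of_origin(s2)
  expect_equal(nrow(snp2), 0)
  expect_equal(attr(snp2, "unphased")$reason, "mendelian_inconsistent")

  # father-biallelic flag excludes the site outright
  s3 <- make_trio_site("hom_alt", "ref", 5, 5, biallelic = TRUE)
  snp3 <- assign_parent_of_origin(s3)
  expect_equal(nrow(snp3), 0)
  expect_equal(attr(snp3, "unphased")$reason, "father_biallelic")
})

test_that("read conservation: maternal + paternal reads equal coverage", {
  set.seed(7)
  for (i in 1:50) {
    m <- sample(c("hom_ref", "hom_alt", "het", "unknown"), 1)
    f <- sample(c("ref", "alt", NA), 1)
    reads <- sample(0:30, 2)
    if (sum(reads) == 0) reads[1] <- 1L
    s <- make_trio_site(m, f, reads[1], reads[2])
    snp <- assign_parent_of_origin(s)
    if (nrow(snp) == 1) {
      expect_equal(snp$maternal_reads + snp$paternal_reads, sum(reads))
    }
  }
})

test_that("trio assembly prefers genome evidence and attaches flags", {
  obs <- dplyr::bind_rows(
    make_obs("daughter", "transcriptome", "S1", c(1, 2, 3), "A", "G",
             c(5, 8, 4), c(5, 0, 4)),
    make_obs("mother", "genome", "S1", 1, "A", "G", 10, 10),
    make_obs("mother", "transcriptome", "S1", 1, "A", "G", 20, 0),
    make_obs("mother", "transcriptome", "S1", 2, "A", "G", 0, 15),
    make_obs("father", "genome", "S1", 1, "A", "G", 0, 12),
    make_obs("father", "transcriptome", "S1", 1, "A", "G", 9, 0)
  )
  sites <- assemble_trio_sites(obs, father_biallelic = "S1:3:A:G")
  sites <- sites[order(sites$pos), ]
  # genome het beats the XCI-shaped transcriptome hom; genome father allele
  # beats his transcriptome
  expect_equal(sites$mother_genotype[1], "het")
  expect_equal(sites$mother_source[1], "genome")
  expect_equal(sites$father_allele[1], "alt")
  expect_equal(sites$father_source[1], "genome")
  # site 2: only transcriptome evidence for the mother
  expect_equal(sites$mother_genotype[2], "hom_alt")
  expect_equal(sites$mother_source[2], "transcriptome")
  expect_true(is.na(sites$father_allele[2]))
  # site 3: no parental data at all, flag carried
  expect_equal(sites$mother_genotype[3], "unknown")
  expect_true(sites$father_biallelic[3])
  expect_equal(infer_daughter_genotype(sites[3, ]), "unknown")
})
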