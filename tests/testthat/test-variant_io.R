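test_that("TSV observations map fields directly and log multiallelic sites", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample_id\tsource\tscaffold\tpos\tref\talt\treads_ref\treads_alt",
    "daughter\ttranscriptome\tScaffoldX1\t1042\tA\tG\t12\t9",
    "daughter\ttranscriptome\tScaffoldX1\t2000\tA\tG,T\t5\t5",
    "mother\tgenome\tScaffoldX1\t3000\tC\tT\t8\t0"
  ), path)
  obs <- read_allele_observations(path, "tsv")
  expect_equal(nrow(obs), 2)
  expect_equal(obs$coverage[1], 21)
  expect_equal(obs$pos[1], 1042L)
  log <- attr(obs, "skip_log")
  expect_equal(nrow(log), 1)
  expect_equal(log$reason, "multiallelic")
  # retained + dropped = total input records
  expect_equal(nrow(obs) + nrow(log), 3)
})

test_that("TSV parse errors name the offending line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample_id\tsource\tscaffold\tpos\tref\talt\treads_ref\treads_alt",
    "daughter\ttranscriptome\tScaffoldX1\toops\tA\tG\t12\t9"
  ), path)
  expect_error(read_allele_observations(path, "tsv"), "line 1")
  expect_error(read_allele_observations(tempfile(), "tsv"), "no such file")
})

test_that("VCF allele depths populate ref/alt read counts", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tdaughter",
    "ScaffoldX1\t500\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/1:0,50",
    "ScaffoldX1\t900\t.\tC\tT,A\t.\tPASS\t.\tGT:AD\t1/2:0,3,4",
    "ScaffoldX1\t1200\t.\tG\tC\t.\tPASS\t.\tGT:AD\t0/1:7,3"
  ), path)
  obs <- read_allele_observations(path, "vcf", source = "transcriptome")
  expect_equal(nrow(obs), 2)
  expect_equal(obs$reads_ref[obs$pos == 500], 0L)
  expect_equal(obs$reads_alt[obs$pos == 500], 50L)
  expect_equal(obs$coverage[obs$pos == 500], 50L)
  expect_equal(attr(obs, "skip_log")$reason, "multiallelic")
})

test_that("BED intervals gain one and GFF3 exons nest under their gene", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("ScaffoldX1\t99\t200\tgeneA", bed)
  ann <- read_gene_annotation(bed, "bed")
  expect_equal(ann$start, 100L)
  expect_equal(ann$end, 200L)
  # interval length preserved by the coordinate change
  expect_equal(ann$end - ann$start + 1L, 200L - 99L)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "ScaffoldX1\tsrc\tgene\t100\t500\t.\t+\t.\tID=geneB;Name=GENEB",
    "ScaffoldX1\tsrc\texon\t100\t220\t.\t+\t.\tParent=geneB",
    "ScaffoldX1\tsrc\texon\t400\t500\t.\t+\t.\tParent=geneB"
  ), gff)
  ann2 <- read_gene_annotation(gff, "gff3")
  expect_equal(nrow(ann2), 1)
  expect_equal(nrow(ann2$exons[[1]]), 2)
  expect_equal(ann2$exons[[1]]$start, c(100L, 400L))

  empty <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_warning(out <- read_gene_annotation(empty, "gff3"), "empty")
  expect_equal(nrow(out), 0)
})

test_that("stratum map preserves order and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene\tscaffold\tposition\tstratum",
    "g3\tS1\t300\told",
    "g1\tS1\t100\told",
    "g2\tS1\t200\tnew"
  ), path)
  map <- read_stratum_map(path)
  expect_equal(map$gene, c("g1", "g2", "g3"))
  expect_s3_class(map, "stratum_map")

  expect_error(stratum_map(data.frame(
    gene = c("a", "a"), scaffold = "S1", position = c(1, 2), stratum = "old"
  )), "duplicate gene")
  expect_error(stratum_map(data.frame(
    gene = "a", scaffold = "S1", position = 1, stratum = "ancient"
  )), "ancient")
  # all-unknown labels are valid; assignment happens downstream
  m <- stratum_map(data.frame(gene = c("a", "b"), scaffold = "S1",
                              position = c(1, 2), stratum = "unknown"))
  expect_equal(nrow(m), 2)
})

test_that("orthology reader enforces human-field consistency", {
  ok <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("gene_id", "scaffold", "human_orthologue", "human_region",
          "opossum_orthologue", "opossum_chromosome", "is_one_to_one",
          sep = "\t"),
    "g1\tS1\tHSg1\tXCR\tMDg1\tX\tTRUE",
    "g2\tS1\tNA\tnone\tNA\tNA\tFALSE"
  ), ok)
  orth <- read_orthology(ok)
  expect_equal(nrow(orth), 2)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("gene_id", "scaffold", "human_orthologue", "human_region",
          "opossum_orthologue", "opossum_chromosome", "is_one_to_one",
          sep = "\t"),
    "g1\tS1\tNA\tXCR\tNA\tNA\tTRUE"
  ), bad)
  expect_error(read_orthology(bad), "g1")
})

test_that("report writing round-trips locus rows field for field", {
  snps <- tibble::tibble(
    scaffold = "S1", pos = c(100L, 1500L),
    maternal_reads = c(30L, 10L), paternal_reads = c(0L, 9L),
    status = c("paternal_inactivated", "escaper")
  )
  loci <- aggregate_loci(snps, NULL, 1000)
  loci$stratum <- c("old", "unassigned")
  loci$conflict_flag[1] <- TRUE
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(loci, summarize_escape(loci), path)
  back <- read_report(path)
  expect_equal(nrow(back), 2)
  expect_equal(back$locus, loci$locus_id)
  expect_equal(back$status, loci$status)
  expect_equal(back$stratum, loci$stratum)
  expect_equal(back$conflict_flag, loci$conflict_flag)
  expect_equal(back$maternal_reads, loci$maternal_reads)
  expect_equal(back$paternal_fraction,
               round(loci$mean_paternal_fraction, 6))
  # summary block survives as commented header lines
  expect_true(any(grepl("^# n_loci", readLines(path))))

  empty_path <- withr::local_tempfile(fileext = ".tsv")
  write_report(loci[0, ], NULL, empty_path)
  expect_equal(nrow(read_report(empty_path)), 0)
})
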