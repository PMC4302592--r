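#' Validate a table of per-sample allele observations
#'
#' The atomic input of the pipeline is one sample's read support for the two
#' alleles of a biallelic SNP. Observations are kept in a plain tibble with
#' one row per sample, source and site.
#'
#' @param x A data frame with columns `sample_id`, `source` (`"genome"` or
#'   `"transcriptome"`), `scaffold`, `pos` (1-based), `ref`, `alt`,
#'   `reads_ref`, `reads_alt`.
#' @return The validated tibble, with a `coverage` column added.
#' @export
allele_observations <- function(x) {
  needed <- c("sample_id", "source", "scaffold", "pos", "ref", "alt",
              "reads_ref", "reads_alt")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(paste0("allele observation table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x <- as_tibble(x)
  x$pos <- as.integer(x$pos)
  x$reads_ref <- as.integer(x$reads_ref)
  x$reads_alt <- as.integer(x$reads_alt)
  if (any(!x$source %in% c("genome", "transcriptome"))) {
    abort("source must be 'genome' or 'transcriptome'")
  }
  nt <- c("A", "C", "G", "T")
  if (any(!x$ref %in% nt) || any(!x$alt %in% nt)) {
    abort("ref and alt alleles must be single nucleotides (A/C/G/T)")
  }
  if (any(x$ref == x$alt)) abort("ref and alt alleles must differ")
  if (any(x$reads_ref < 0) || any(x$reads_alt < 0)) {
    abort("read counts must be non-negative")
  }
  x$coverage <- x$reads_ref + x$reads_alt
  x
}

empty_observations <- function() {
  allele_observations(tibble(
    sample_id = character(), source = character(), scaffold = character(),
    pos = integer(), ref = character(), alt = character(),
    reads_ref = integer(), reads_alt = integer()
  ))
}

skip_log_of <- function(x) {
  attr(x, "skip_log") %||%
    tibble(scaffold = character(), pos = integer(), reason = character())
}

with_skip_log <- function(x, log) {
  attr(x, "skip_log") <- log
  x
}

#' Read per-sample allele observations from TSV or VCF
#'
#' The canonical TSV dialect has a header line and the columns of
#' [allele_observations()] (tab-separated). The VCF dialect requires a
#' per-sample `AD` (allelic depth) FORMAT field; sample/source identity is
#' supplied by the caller since VCF does not carry a tissue tag.
#' Multiallelic sites (more than two observed alleles) are dropped and
#' recorded in the attached skip log (`attr(x, "skip_log")`).
#'
#' @param path File to read.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param source For the VCF dialect, the evidence source of every sample in
#'   the file: either a single value recycled to all samples or a named
#'   character vector `sample -> source`. Ignored for TSV.
#' @return A validated observation tibble with a `skip_log` attribute.
#' @export
read_allele_observations <- function(path, dialect = c("tsv", "vcf"),
                                     source = "transcriptome") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (dialect == "tsv") read_obs_tsv(path) else read_obs_vcf(path, source)
}

read_obs_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE)
  if (nrow(raw) == 0) {
    return(with_skip_log(empty_observations(), skip_log_of(NULL)))
  }
  bad_pos <- which(is.na(suppressWarnings(as.integer(raw$pos))))
  if (length(bad_pos) > 0) {
    abort(paste0("unparseable position at data line ", bad_pos[1],
                 " of ", path))
  }
  multi <- grepl(",", raw$alt, fixed = TRUE)
  log <- tibble(scaffold = raw$scaffold[multi],
                pos = as.integer(raw$pos[multi]),
                reason = rep("multiallelic", sum(multi)))
  bad_counts <- which(is.na(suppressWarnings(as.integer(raw$reads_ref))) |
                        is.na(suppressWarnings(as.integer(raw$reads_alt))))
  bad_counts <- setdiff(bad_counts, which(multi))
  if (length(bad_counts) > 0) {
    abort(paste0("unparseable read count at data line ", bad_counts[1],
                 " of ", path))
  }
  with_skip_log(allele_observations(raw[!multi, , drop = FALSE]), log)
}

read_obs_vcf <- function(path, source) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD"),
                 error = function(e) NULL)
  if (is.null(ad)) abort(paste0("VCF has no per-sample AD depths: ", path))
  samples <- colnames(ad)
  src <- if (length(source) == 1 && is.null(names(source))) {
    setNames(rep(source, length(samples)), samples)
  } else {
    source
  }
  if (any(!samples %in% names(src))) {
    abort("source must name every VCF sample")
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  log <- tibble(scaffold = fix$CHROM[multi], pos = as.integer(fix$POS[multi]),
                reason = rep("multiallelic", sum(multi)))
  keep <- which(!multi)
  rows <- lapply(samples, function(s) {
    depths <- ad[keep, s]
    if (any(is.na(depths))) {
      i <- keep[which(is.na(depths))[1]]
      abort(paste0("missing AD for sample ", s, " at ",
                   fix$CHROM[i], ":", fix$POS[i]))
    }
    parts <- strsplit(depths, ",", fixed = TRUE)
    tibble(
      sample_id = s, source = unname(src[s]),
      scaffold = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
      ref = fix$REF[keep], alt = fix$ALT[keep],
      reads_ref = as.integer(vapply(parts, `[`, "", 1)),
      reads_alt = as.integer(vapply(parts, function(p) {
        if (length(p) >= 2) p[2] else "0"
      }, ""))
    )
  })
  with_skip_log(allele_observations(bind_rows(rows)), log)
}

#' Read gene/exon annotation from GFF3 or BED
#'
#' Coordinates are normalized to the 1-based inclusive convention used
#' throughout the pipeline; BED's 0-based half-open starts are incremented
#' on ingest (delegated to rtracklayer, which applies the convention).
#' GFF3 `exon` features are attached to their parent gene; BED intervals
#' become single-exon genes.
#'
#' @param path File to read.
#' @param dialect `"gff3"` or `"bed"`.
#' @return A tibble with columns `gene_id`, `gene_name`, `scaffold`,
#'   `start`, `end` and a list-column `exons` of (start, end) data frames.
#' @export
read_gene_annotation <- function(path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  empty <- tibble(gene_id = character(), gene_name = character(),
                  scaffold = character(), start = integer(), end = integer(),
                  exons = list())
  info <- file.info(path)
  if (info$size == 0 ||
      all(grepl("^(#|$)", readLines(path, warn = FALSE)))) {
    warn(paste0("empty annotation file: ", path))
    return(empty)
  }
  gr <- rtracklayer::import(path, format = dialect)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warn(paste0("empty annotation file: ", path))
    return(empty)
  }
  if (dialect == "bed") {
    ann <- tibble(
      gene_id = as.character(df$name %||% paste0("region_", seq_len(nrow(df)))),
      gene_name = as.character(df$name %||% ""),
      scaffold = as.character(df$seqnames),
      start = as.integer(df$start), end = as.integer(df$end)
    )
    ann$exons <- lapply(seq_len(nrow(ann)), function(i) {
      data.frame(start = ann$start[i], end = ann$end[i])
    })
  } else {
    df$ID <- as.character(df$ID %||% NA_character_)
    genes <- df[df$type == "gene", , drop = FALSE]
    if (nrow(genes) == 0) abort(paste0("no gene features in ", path))
    ann <- tibble(
      gene_id = genes$ID,
      gene_name = as.character(genes$Name %||% genes$ID),
      scaffold = as.character(genes$seqnames),
      start = as.integer(genes$start), end = as.integer(genes$end)
    )
    exons <- df[df$type == "exon", , drop = FALSE]
    parent <- vapply(exons$Parent, function(p) as.character(p)[1], "")
    ann$exons <- lapply(ann$gene_id, function(g) {
      e <- exons[parent == g, , drop = FALSE]
      if (nrow(e) == 0) {
        gi <- ann[ann$gene_id == g, ]
        data.frame(start = gi$start, end = gi$end)
      } else {
        data.frame(start = as.integer(e$start), end = as.integer(e$end))
      }
    })
  }
  if (any(ann$end < ann$start)) {
    abort("annotation interval with end < start after normalization")
  }
  ann
}

#' Read an ordered X stratum map
#'
#' The map is a TSV of anchor genes with columns `gene`, `scaffold`,
#' `position` (map coordinate) and `stratum` (`old`, `new` or `unknown`),
#' optionally accompanied by a scaffold-offset TSV (`scaffold`,
#' `map_offset`) that places pipeline scaffolds on the same coordinate
#' system (the precomputed synteny lookup).
#'
#' @param path Anchor-gene TSV.
#' @param offsets_path Optional scaffold-offset TSV.
#' @return A `stratum_map` tibble ordered by map position, with the offset
#'   table in `attr(, "scaffold_offsets")`.
#' @export
read_stratum_map <- function(path, offsets_path = NULL) {
  genes <- readr::read_tsv(path, col_types = readr::cols(
    gene = "c", scaffold = "c", position = "d", stratum = "c"
  ), progress = FALSE)
  offsets <- NULL
  if (!is.null(offsets_path)) {
    offsets <- readr::read_tsv(offsets_path, col_types = readr::cols(
      scaffold = "c", map_offset = "d"
    ), progress = FALSE)
  }
  stratum_map(genes, offsets)
}

#' Construct a stratum map from data frames
#'
#' @param genes Data frame with `gene`, `scaffold`, `position`, `stratum`.
#' @param scaffold_offsets Optional data frame with `scaffold`, `map_offset`.
#' @return A `stratum_map` tibble.
#' @export
stratum_map <- function(genes, scaffold_offsets = NULL) {
  genes <- as_tibble(genes)
  bad <- setdiff(unique(genes$stratum), c("old", "new", "unknown"))
  if (length(bad) > 0) {
    abort(paste0("unknown stratum label: ", paste(bad, collapse = ", ")))
  }
  dup <- genes$gene[duplicated(genes$gene)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene in stratum map: ", dup[1]))
  }
  genes <- arrange(genes, .data$position)
  attr(genes, "scaffold_offsets") <- scaffold_offsets
  class(genes) <- c("stratum_map", class(genes))
  genes
}

#' Read a gene orthology table
#'
#' TSV with columns `gene_id`, `scaffold`, `human_orthologue`,
#' `human_region` (`XCR`, `X_other`, `autosome`, `none`),
#' `opossum_orthologue`, `opossum_chromosome`, `is_one_to_one`. Records
#' with no human orthologue must carry region `none`.
#'
#' @param path TSV to read.
#' @return A validated tibble.
#' @export
read_orthology <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", scaffold = "c", human_orthologue = "c",
    human_region = "c", opossum_orthologue = "c", opossum_chromosome = "c",
    is_one_to_one = "l"
  ), progress = FALSE, na = c("", "NA"))
  bad <- is.na(x$human_orthologue) & x$human_region != "none"
  if (any(bad)) {
    abort(paste0("orthology record without human orthologue must have ",
                 "region 'none': ", x$gene_id[which(bad)[1]]))
  }
  x
}

#' Write (and re-read) the locus-level XCI report
#'
#' A TSV with one row per locus and the escape summary as commented header
#' lines, the tabular analogue of a per-locus inactivation figure.
#'
#' @param loci Locus tibble from [aggregate_loci()] (optionally carrying a
#'   `stratum` column from [assign_strata()]).
#' @param summary An escape summary list from [summarize_escape()], or NULL.
#' @param path Output file.
#' @export
write_report <- function(loci, summary, path) {
  rows <- tibble(
    locus = loci$locus_id,
    scaffold = loci$scaffold,
    position = loci$position,
    n_snps = loci$n_snps,
    maternal_reads = loci$maternal_reads,
    paternal_reads = loci$paternal_reads,
    paternal_fraction = round(loci$mean_paternal_fraction, 6),
    status = loci$status,
    stratum = loci$stratum %||% rep("unassigned", nrow(loci)),
    conflict_flag = loci$conflict_flag
  )
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) abort(paste0("cannot write: ", path)))
  on.exit(close(con))
  if (!is.null(summary)) {
    for (k in names(summary)) {
      writeLines(sprintf("# %s: %s", k, format(summary[[k]], digits = 10)),
                 con)
    }
  }
  writeLines(paste(names(rows), collapse = "\t"), con)
  if (nrow(rows) > 0) {
    body <- do.call(paste, c(lapply(rows, as.character), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname write_report
#' @return `read_report()` returns the locus rows as a tibble.
#' @export
read_report <- function(path) {
  readr::read_tsv(path, comment = "#", col_types = readr::cols(
    locus = "c", scaffold = "c", position = "i", n_snps = "i",
    maternal_reads = "i", paternal_reads = "i", paternal_fraction = "d",
    status = "c", stratum = "c", conflict_flag = "l"
  ), progress = FALSE)
}
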