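#' Fraction of daughter reads from the paternal allele
#'
#' The allele-specific expression ratio: reads supporting the paternal
#' allele divided by total coverage at the site.
#'
#' @param paternal_reads,maternal_reads Read counts per allele.
#' @return Numeric vector of paternal fractions.
#' @export
paternal_fraction <- function(paternal_reads, maternal_reads) {
  cov <- paternal_reads + maternal_reads
  if (any(cov == 0)) abort("zero coverage: filter sites upstream")
  paternal_reads / cov
}

#' Classify a phased SNP's inactivation status
#'
#' A SNP escapes XCI when strictly more than `escape_threshold` of its
#' reads support the lowly expressed allele. Otherwise expression is
#' (effectively) monoallelic and the silenced parent is the one whose
#' allele is minor: paternal inactivation when the paternal allele is the
#' lowly expressed one, maternal inactivation in the mirror case.
#'
#' @param paternal_reads,maternal_reads Read counts per allele.
#' @param escape_threshold Minor-allele fraction above which a SNP is an
#'   escaper (default 0.10, strict inequality).
#' @return Character vector: `"escaper"`, `"paternal_inactivated"` or
#'   `"maternal_inactivated"`.
#' @export
classify_snp <- function(paternal_reads, maternal_reads,
                         escape_threshold = 0.10) {
  f <- paternal_fraction(paternal_reads, maternal_reads)
  minor <- pmin(f, 1 - f)
  ifelse(minor > escape_threshold, "escaper",
         ifelse(f <= 0.5, "paternal_inactivated", "maternal_inactivated"))
}

# Single-linkage clustering of sorted positions: a new cluster starts
# whenever the gap to the previous position exceeds max_gap.
cluster_positions <- function(pos, max_gap) {
  if (length(pos) == 0) return(integer())
  o <- order(pos)
  gaps <- c(0, diff(pos[o]))
  cl <- cumsum(gaps > max_gap) + 1L
  cl[order(o)]
}

#' Aggregate classified SNPs into loci
#'
#' SNPs inside the same annotated gene form one gene locus; intergenic
#' SNPs on the same scaffold are clustered by single linkage at
#' `intergenic_cluster_bp` and each cluster is one intergenic locus.
#' A locus's status is the unanimous SNP status when there is one;
#' otherwise the majority status with `conflict_flag` set, and a tie
#' resolves to `escaper` with the flag set (biallelic evidence at any SNP
#' demonstrates expression from both X chromosomes). Ambiguous SNPs are
#' excluded from the vote but retained in the locus. The locus paternal
#' fraction is read-weighted across its SNPs.
#'
#' @param snps Tibble of phased, classified SNPs: columns `scaffold`,
#'   `pos`, `maternal_reads`, `paternal_reads`, `status`.
#' @param annotation Gene annotation tibble (possibly empty).
#' @param intergenic_cluster_bp Maximum gap joining intergenic SNPs into
#'   one locus (default 1000 bp).
#' @return A locus tibble with one row per locus and a `snps` list-column.
#' @export
aggregate_loci <- function(snps, annotation = NULL,
                           intergenic_cluster_bp = 1000) {
  empty <- tibble(locus_id = character(), kind = character(),
                  gene_id = character(), scaffold = character(),
                  position = integer(), n_snps = integer(),
                  maternal_reads = integer(), paternal_reads = integer(),
                  mean_paternal_fraction = double(), status = character(),
                  conflict_flag = logical(), snps = list())
  if (nrow(snps) == 0) return(empty)
  snps <- as_tibble(snps)
  snps$gene_id <- gene_at(snps$scaffold, snps$pos, annotation)
  genic <- !is.na(snps$gene_id)
  snps$locus_id <- NA_character_
  snps$locus_id[genic] <- snps$gene_id[genic]
  ig <- snps[!genic, , drop = FALSE]
  if (nrow(ig) > 0) {
    ig_ids <- character(nrow(ig))
    counter <- 0L
    for (sc in unique(ig$scaffold)) {
      idx <- which(ig$scaffold == sc)
      cl <- cluster_positions(ig$pos[idx], intergenic_cluster_bp)
      for (c0 in sort(unique(cl))) {
        counter <- counter + 1L
        ig_ids[idx[cl == c0]] <- sprintf("X_Locus_%d", counter)
      }
    }
    snps$locus_id[!genic] <- ig_ids
  }

  one_locus <- function(g) {
    voting <- g$status[g$status != "ambiguous"]
    if (length(voting) == 0) {
      status <- "ambiguous"; conflict <- FALSE
    } else if (length(unique(voting)) == 1) {
      status <- voting[1]; conflict <- FALSE
    } else {
      tab <- sort(table(voting), decreasing = TRUE)
      conflict <- TRUE
      status <- if (sum(tab == max(tab)) > 1) "escaper" else names(tab)[1]
    }
    mr <- sum(g$maternal_reads); pr <- sum(g$paternal_reads)
    tibble(
      locus_id = g$locus_id[1],
      kind = if (is.na(g$gene_id[1])) "intergenic" else "gene",
      gene_id = g$gene_id[1],
      scaffold = g$scaffold[1],
      position = as.integer(min(g$pos)),
      n_snps = nrow(g),
      maternal_reads = as.integer(mr),
      paternal_reads = as.integer(pr),
      mean_paternal_fraction = if (mr + pr > 0) pr / (mr + pr) else NA_real_,
      status = status,
      conflict_flag = conflict,
      snps = list(g)
    )
  }
  parts <- split(snps, snps$locus_id)
  loci <- bind_rows(lapply(parts, one_locus))
  arrange(loci, .data$scaffold, .data$position)
}

#' Summarize escape from X inactivation over loci
#'
#' @param loci A locus tibble from [aggregate_loci()].
#' @return A list: locus counts by status, `escape_fraction` (escapers over
#'   decisively classified loci) and `mean_escaper_paternal_fraction`
#'   (read-weighted per escaper locus, averaged over escaper loci), plus
#'   `mean_escaper_paternal_fraction_snp` averaged over escaper SNPs.
#' @export
summarize_escape <- function(loci) {
  if (nrow(loci) == 0) abort("no loci to summarize")
  n <- nrow(loci)
  n_esc <- sum(loci$status == "escaper")
  n_pat <- sum(loci$status == "paternal_inactivated")
  n_mat <- sum(loci$status == "maternal_inactivated")
  n_amb <- sum(loci$status == "ambiguous")
  classified <- n - n_amb
  esc <- loci[loci$status == "escaper", , drop = FALSE]
  snp_frac <- NA_real_
  if (nrow(esc) > 0) {
    es <- bind_rows(esc$snps)
    es <- es[es$status == "escaper", , drop = FALSE]
    if (nrow(es) > 0) {
      snp_frac <- mean(es$paternal_reads /
                         (es$paternal_reads + es$maternal_reads))
    }
  }
  list(
    n_loci = n,
    n_paternal_inactivated = n_pat,
    n_maternal_inactivated = n_mat,
    n_escaper = n_esc,
    n_ambiguous = n_amb,
    escape_fraction = if (classified > 0) n_esc / classified else NA_real_,
    mean_escaper_paternal_fraction =
      if (nrow(esc) > 0) mean(esc$mean_paternal_fraction) else NA_real_,
    mean_escaper_paternal_fraction_snp = snp_frac
  )
}

#' Single-sample escape analysis over biallelically expressed SNPs
#'
#' The comparison mode that ignores parent of origin: only heterozygous,
#' biallelically expressed transcriptome SNPs enter, and a SNP escapes when
#' its minor-allele fraction exceeds the threshold. Useful for samples
#' without trio support (e.g. the mother's blood) and for contrasting with
#' the trio analysis, which also recovers monoallelically expressed
#' heterozygotes.
#'
#' @param observations One sample's transcriptome observation tibble.
#' @param annotation Gene annotation tibble.
#' @param escape_threshold Minor-allele fraction threshold (default 0.10).
#' @param intergenic_cluster_bp Intergenic clustering distance.
#' @return A list with the locus tibble (`loci`) and the escape `summary`;
#'   `summary$n_loci` is 0 (with a warning) when no biallelic site exists.
#' @export
classify_biallelic_only <- function(observations, annotation = NULL,
                                    escape_threshold = 0.10,
                                    intergenic_cluster_bp = 1000) {
  tx <- observations[observations$source == "transcriptome", , drop = FALSE]
  bi <- tx[tx$reads_ref > 0 & tx$reads_alt > 0, , drop = FALSE]
  if (nrow(bi) == 0) {
    warn("no biallelically expressed heterozygous sites")
    return(list(loci = aggregate_loci(tibble()), summary = list(
      n_loci = 0L, n_paternal_inactivated = 0L, n_maternal_inactivated = 0L,
      n_escaper = 0L, n_ambiguous = 0L, escape_fraction = NA_real_,
      mean_escaper_paternal_fraction = NA_real_,
      mean_escaper_paternal_fraction_snp = NA_real_
    )))
  }
  # Without parent of origin, orient by expression level: "paternal" slots
  # hold the minor allele so existing machinery classifies escape, and
  # monoallelic-leaning sites are labelled by the inactivated-minor
  # convention (reported as 'inactivated' rather than a parental status).
  minor <- pmin(bi$reads_ref, bi$reads_alt)
  major <- pmax(bi$reads_ref, bi$reads_alt)
  snps <- tibble(
    scaffold = bi$scaffold, pos = bi$pos,
    maternal_reads = major, paternal_reads = minor,
    status = ifelse(minor / (minor + major) > escape_threshold,
                    "escaper", "paternal_inactivated")
  )
  loci <- aggregate_loci(snps, annotation, intergenic_cluster_bp)
  list(loci = loci, summary = summarize_escape(loci))
}
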