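#' Site-level curation settings
#'
#' Defaults follow the study design the pipeline implements: a minimum read
#' depth of 5 at every SNP position in every sample, a ~20 kb total vicinity
#' window for intergenic SNPs, and at least three homozygous neighbours
#' required before a single-read heterozygote is discarded. The
#' father-biallelic thresholds separate X-Y homolog signal in the male
#' transcriptome from single-read sequencing noise.
#'
#' @param min_coverage Minimum coverage per sample per site (reads).
#' @param neighbor_window Total intergenic vicinity span in bp (the window
#'   extends half this distance either side of the SNP).
#' @param min_hom_neighbors Homozygous neighbours needed to discard a
#'   single-read heterozygote.
#' @param father_biallelic_min_reads Minimum reads on each allele before a
#'   father X site counts as biallelic.
#' @param father_biallelic_min_fraction Minimum minor-allele fraction for
#'   the same call.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_coverage = 5,
                          neighbor_window = 20000,
                          min_hom_neighbors = 3,
                          father_biallelic_min_reads = 2,
                          father_biallelic_min_fraction = 0.05) {
  stopifnot(min_coverage >= 1, neighbor_window > 0,
            father_biallelic_min_fraction >= 0,
            father_biallelic_min_fraction <= 1)
  structure(list(
    min_coverage = min_coverage,
    neighbor_window = neighbor_window,
    min_hom_neighbors = min_hom_neighbors,
    father_biallelic_min_reads = father_biallelic_min_reads,
    father_biallelic_min_fraction = father_biallelic_min_fraction
  ), class = "filter_config")
}

#' Drop sites below the per-sample coverage floor
#'
#' Retains exactly the observations with `reads_ref + reads_alt >=
#' min_coverage`, preserving input order; dropped sites are appended to the
#' skip log. Idempotent by construction.
#'
#' @param observations An observation tibble.
#' @param config A [filter_config()].
#' @return The filtered tibble with an updated `skip_log` attribute.
#' @export
filter_min_coverage <- function(observations, config = filter_config()) {
  keep <- observations$coverage >= config$min_coverage
  log <- bind_rows(skip_log_of(observations), tibble(
    scaffold = observations$scaffold[!keep],
    pos = observations$pos[!keep],
    reason = rep("low_coverage", sum(!keep))
  ))
  with_skip_log(observations[keep, , drop = FALSE], log)
}

# Which observations look heterozygous (both alleles supported)?
is_het_obs <- function(obs) obs$reads_ref > 0 & obs$reads_alt > 0

# Gene id containing each position, or NA when intergenic.
gene_at <- function(scaffold, pos, annotation) {
  out <- rep(NA_character_, length(pos))
  if (is.null(annotation) || nrow(annotation) == 0) return(out)
  for (i in seq_len(nrow(annotation))) {
    hit <- scaffold == annotation$scaffold[i] &
      pos >= annotation$start[i] & pos <= annotation$end[i]
    out[hit & is.na(out)] <- annotation$gene_id[i]
  }
  out
}

#' Curate single-read heterozygotes against their vicinity
#'
#' A heterozygous site whose minor allele carries exactly one read is a
#' likely sequencing error when its surroundings are uniformly homozygous.
#' Such a site is removed iff, within its vicinity (the same annotated gene
#' when genic, otherwise a window of `neighbor_window` bp centred on the
#' site), at least `min_hom_neighbors` sites are homozygous and no site is
#' heterozygous. Sites whose minor allele has two or more reads are never
#' touched.
#'
#' @param observations Observations from one sample/source.
#' @param annotation Gene annotation tibble (may be empty).
#' @param config A [filter_config()].
#' @return The curated tibble with an updated `skip_log` attribute.
#' @export
filter_singleton_het <- function(observations, annotation = NULL,
                                 config = filter_config()) {
  if (nrow(observations) == 0) return(observations)
  het <- is_het_obs(observations)
  singleton <- het & pmin(observations$reads_ref, observations$reads_alt) == 1
  if (!any(singleton)) return(observations)
  gene <- gene_at(observations$scaffold, observations$pos, annotation)
  half <- config$neighbor_window / 2
  drop <- rep(FALSE, nrow(observations))
  for (i in which(singleton)) {
    same_scaffold <- observations$scaffold == observations$scaffold[i]
    if (!is.na(gene[i])) {
      vicinity <- same_scaffold & !is.na(gene) & gene == gene[i]
    } else {
      vicinity <- same_scaffold &
        abs(observations$pos - observations$pos[i]) <= half
    }
    vicinity[i] <- FALSE
    n_hom <- sum(vicinity & !het)
    n_het <- sum(vicinity & het)
    drop[i] <- n_hom >= config$min_hom_neighbors && n_het == 0
  }
  log <- bind_rows(skip_log_of(observations), tibble(
    scaffold = observations$scaffold[drop],
    pos = observations$pos[drop],
    reason = rep("singleton_het", sum(drop))
  ))
  with_skip_log(observations[!drop, , drop = FALSE], log)
}

#' Flag father X sites with apparent biallelic expression
#'
#' A male is hemizygous on the X, so two well-supported alleles in his
#' transcriptome at an X site indicate reads from an X-Y homolog (or a
#' multicopy X gene) mismapped to the X; such sites are untrustworthy for
#' parent-of-origin work and are excluded downstream. A site is flagged
#' when both alleles have at least `father_biallelic_min_reads` reads and
#' the minor fraction is at least `father_biallelic_min_fraction`.
#'
#' @param father_obs The father's observation tibble (transcriptome rows
#'   are considered).
#' @param x_scaffolds Character vector of X-assigned scaffold names.
#' @param config A [filter_config()].
#' @return Character vector of flagged site keys (`scaffold:pos:ref:alt`).
#' @export
flag_father_biallelic_x <- function(father_obs, x_scaffolds,
                                    config = filter_config()) {
  tx <- father_obs[father_obs$source == "transcriptome", , drop = FALSE]
  on_x <- tx$scaffold %in% x_scaffolds
  minor <- pmin(tx$reads_ref, tx$reads_alt)
  frac <- ifelse(tx$coverage > 0, minor / tx$coverage, 0)
  hit <- on_x & minor >= config$father_biallelic_min_reads &
    frac >= config$father_biallelic_min_fraction
  unique(site_key(tx$scaffold[hit], tx$pos[hit], tx$ref[hit], tx$alt[hit]))
}

#' Is a trio site informative for parent-of-origin assignment?
#'
#' A daughter site is informative when her two alleles can each be uniquely
#' assigned to one parent: the genotype must resolve to heterozygous
#' (observed or Mendelian-forced) and the phase must be unambiguous given
#' the father's hemizygous allele and the mother's genotype.
#'
#' @param trio_sites A trio-site tibble from [assemble_trio_sites()].
#' @return Character vector, `"informative"` or `"non_informative"` per row.
#' @export
classify_informative <- function(trio_sites) {
  phased <- phase_trio_sites(trio_sites)
  ifelse(phased$phase == "phased", "informative", "non_informative")
}
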