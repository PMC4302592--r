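#' Parameters for the synthetic trio generator
#'
#' Defaults emulate the statistical structure of a wallaby-style trio ASE
#' study: ~34 X loci averaging ~1.25 SNPs each, negative-binomial read
#' depth with mean 20 (observed per-site coverages of roughly 5-50), 32%
#' of loci escaping XCI with escaper paternal expression centred on 46%,
#' complete silencing (zero leakage) at inactivated loci, 68% of called
#' SNPs shared/non-informative, and a small admixture of father-biallelic
#' X-Y homolog confounder sites.
#'
#' @param seed Integer seed governing all randomness.
#' @param n_loci Number of informative X loci.
#' @param snps_per_locus Mean SNPs per locus (1 + Poisson(mean - 1)).
#' @param x_scaffolds Number of X scaffolds to spread loci over.
#' @param escape_prob Probability a locus escapes XCI.
#' @param escaper_paternal_mean,escaper_paternal_concentration Mean and
#'   concentration of the Beta distribution of escaper paternal fractions.
#' @param inactivated_leakage Paternal read fraction at inactivated loci.
#' @param coverage_mean,coverage_dispersion Negative-binomial read-depth
#'   parameters (mean, size); draws are truncated at 1.
#' @param error_rate Symmetric per-read base miscall probability.
#' @param frac_shared_noninformative Fraction of all SNPs that are shared
#'   across the trio and hence non-informative.
#' @param frac_father_biallelic Father-biallelic confounder sites as a
#'   fraction of informative SNPs.
#' @param intergenic_fraction Fraction of loci lying outside annotated
#'   genes.
#' @param daughter_genome_mean Mean coverage of daughter genome
#'   observations; 0 (the default) omits daughter DNA evidence, as in a
#'   design where only the parents were genome-sequenced.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       n_loci = 34L,
                       snps_per_locus = 1.25,
                       x_scaffolds = 8L,
                       escape_prob = 0.32,
                       escaper_paternal_mean = 0.46,
                       escaper_paternal_concentration = 30,
                       inactivated_leakage = 0,
                       coverage_mean = 20,
                       coverage_dispersion = 5,
                       error_rate = 0,
                       frac_shared_noninformative = 0.68,
                       frac_father_biallelic = 0.05,
                       intergenic_fraction = 0.5,
                       daughter_genome_mean = 0) {
  p <- as.list(environment())
  fracs <- c(p$escape_prob, p$inactivated_leakage, p$error_rate,
             p$frac_shared_noninformative, p$frac_father_biallelic,
             p$intergenic_fraction, p$escaper_paternal_mean)
  stopifnot(all(fracs >= 0 & fracs <= 1), p$coverage_mean > 0,
            p$snps_per_locus >= 1)
  if (p$n_loci < 1) abort("n_loci must be >= 1")
  structure(p, class = "sim_params")
}

draw_coverage <- function(n, mean, size) {
  pmax(1L, rnbinom(n, mu = mean, size = size))
}

# Symmetric base error: each read flips to the other allele with prob e.
flip_counts <- function(n1, n2, e) {
  if (e == 0) return(list(n1 = n1, n2 = n2))
  f12 <- rbinom(length(n1), n1, e)
  f21 <- rbinom(length(n2), n2, e)
  list(n1 = n1 - f12 + f21, n2 = n2 - f21 + f12)
}

#' Simulate a mother-father-daughter allele-count dataset on the X
#'
#' Draws parental X haplotypes (heterozygous or homozygous mother sites, a
#' hemizygous father allele), passes one maternal allele and the paternal
#' allele to the daughter, silences the daughter's paternal copy locus by
#' locus except at escaper loci, and emits binomially split read counts at
#' negative-binomial depth for every sample and source. Shared
#' non-informative SNPs and father-biallelic confounder sites are injected
#' at the configured rates. Fully reproducible from `params$seed`.
#'
#' @param params A [sim_params()] list.
#' @return A list: `observations` (all samples/sources), `annotation`,
#'   `orthology`, `stratum_map`, `truth_loci`, `truth_snps`, `params`.
#' @export
simulate_trio <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  nts <- c("A", "C", "G", "T")
  scaffolds <- sprintf("ScaffoldX%d", seq_len(params$x_scaffolds))
  n <- params$n_loci

  locus_scaffold <- sort(sample(scaffolds, n, replace = TRUE))
  kind <- ifelse(runif(n) < params$intergenic_fraction, "intergenic", "gene")
  esc <- runif(n) < params$escape_prob
  sh1 <- params$escaper_paternal_mean * params$escaper_paternal_concentration
  sh2 <- (1 - params$escaper_paternal_mean) *
    params$escaper_paternal_concentration
  pat_frac <- ifelse(esc, rbeta(n, sh1, sh2), params$inactivated_leakage)
  n_snps <- 1L + stats::rpois(n, params$snps_per_locus - 1)
  # The mother has her own imprinted XCI; her silencing governs only her
  # transcriptome (used by the biallelic-only comparison mode).
  m_esc <- runif(n) < params$escape_prob
  m_frac <- ifelse(m_esc, rbeta(n, sh1, sh2), params$inactivated_leakage)
  m_silenced_transmitted <- runif(n) < 0.5

  gene_ctr <- 0L
  ig_ctr <- 0L
  locus_id <- character(n)
  for (i in seq_len(n)) {
    if (kind[i] == "gene") {
      gene_ctr <- gene_ctr + 1L
      locus_id[i] <- sprintf("GENE_%03d", gene_ctr)
    } else {
      ig_ctr <- ig_ctr + 1L
      locus_id[i] <- sprintf("IG_%03d", ig_ctr)
    }
  }

  # Sequential layout per scaffold: loci separated by wide gaps so
  # vicinity windows and intergenic clustering never bridge loci.
  cursor <- setNames(rep(10000, length(scaffolds)), scaffolds)
  snp_rows <- vector("list", n)
  locus_pos <- integer(n)
  for (i in seq_len(n)) {
    sc <- locus_scaffold[i]
    gaps <- sample(50:300, n_snps[i], replace = TRUE)
    pos <- as.integer(cursor[sc] + cumsum(gaps))
    cursor[sc] <- pos[length(pos)] + 30000
    locus_pos[i] <- pos[1]
    pair <- t(vapply(seq_along(pos), function(j) sample(nts, 2), nts[1:2]))
    snp_rows[[i]] <- tibble(
      locus_id = locus_id[i], scaffold = sc, pos = pos,
      ref = pair[, 1], alt = pair[, 2]
    )
  }
  snps <- bind_rows(snp_rows)
  li <- match(snps$locus_id, locus_id)

  # Per-SNP inheritance: paternal allele uniform, maternal the other
  # (daughter heterozygous), mother hom-for-maternal or het.
  pat_is_ref <- runif(nrow(snps)) < 0.5
  snps$father_nt <- ifelse(pat_is_ref, snps$ref, snps$alt)
  snps$maternal_nt <- ifelse(pat_is_ref, snps$alt, snps$ref)
  mother_het <- runif(nrow(snps)) < 0.4
  snps$mother_genotype <- ifelse(mother_het, "het", "hom_maternal")
  snps$class <- "informative"

  n_inf <- nrow(snps)
  f_sh <- params$frac_shared_noninformative
  n_shared <- round(n_inf * f_sh / max(1 - f_sh, 1e-9))
  n_fb <- round(n_inf * params$frac_father_biallelic)

  extra_site <- function(class, idx) {
    sc <- sample(scaffolds, 1)
    pos <- as.integer(cursor[sc] + 2000)
    cursor[sc] <<- pos
    pair <- sample(nts, 2)
    if (class == "shared_noninformative") {
      tibble(locus_id = NA_character_, scaffold = sc, pos = pos,
             ref = pair[1], alt = pair[2],
             father_nt = pair[1], maternal_nt = pair[1],
             mother_genotype = "hom_maternal", class = class)
    } else {
      tibble(locus_id = NA_character_, scaffold = sc, pos = pos,
             ref = pair[1], alt = pair[2],
             father_nt = pair[1], maternal_nt = pair[2],
             mother_genotype = "hom_maternal", class = class)
    }
  }
  extras <- bind_rows(
    lapply(seq_len(n_shared), function(j) extra_site("shared_noninformative", j)),
    lapply(seq_len(n_fb), function(j) extra_site("father_biallelic", j))
  )
  all_sites <- bind_rows(snps, extras)
  li <- match(all_sites$locus_id, locus_id)

  cov <- function(k) draw_coverage(k, params$coverage_mean,
                                   params$coverage_dispersion)
  m <- nrow(all_sites)
  e <- params$error_rate
  obs_rows <- list()
  add_obs <- function(sample_id, source, nt_a_reads, nt_b_reads) {
    # nt_a = maternal_nt column, nt_b = the other allele
    a_is_ref <- all_sites$maternal_nt == all_sites$ref
    flipped <- flip_counts(nt_a_reads, nt_b_reads, e)
    tibble(
      sample_id = sample_id, source = source,
      scaffold = all_sites$scaffold, pos = all_sites$pos,
      ref = all_sites$ref, alt = all_sites$alt,
      reads_ref = ifelse(a_is_ref, flipped$n1, flipped$n2),
      reads_alt = ifelse(a_is_ref, flipped$n2, flipped$n1)
    )
  }

  is_het <- all_sites$mother_genotype == "het"
  # Mother genome: het -> binomial 0.5 split; hom -> all maternal allele.
  mg_cov <- cov(m)
  mg_mat <- ifelse(is_het, rbinom(m, mg_cov, 0.5), mg_cov)
  obs_rows$mg <- add_obs("mother", "genome", mg_mat, mg_cov - mg_mat)
  # Mother transcriptome: her own silencing at het sites.
  mt_cov <- cov(m)
  m_low <- ifelse(is.na(li), 0, m_frac[ifelse(is.na(li), 1, li)])
  m_sil_tr <- ifelse(is.na(li), TRUE, m_silenced_transmitted[ifelse(is.na(li), 1, li)])
  p_mat_tx <- ifelse(is_het, ifelse(m_sil_tr, m_low, 1 - m_low), 1)
  mt_mat <- rbinom(m, mt_cov, p_mat_tx)
  obs_rows$mt <- add_obs("mother", "transcriptome", mt_mat, mt_cov - mt_mat)
  # Father: hemizygous; genome always his true allele, transcriptome too,
  # except X-Y homolog confounders where his transcriptome looks 50/50.
  father_is_mat <- all_sites$father_nt == all_sites$maternal_nt
  fg_cov <- cov(m)
  fg_mat <- ifelse(father_is_mat, fg_cov, 0L)
  obs_rows$fg <- add_obs("father", "genome", fg_mat, fg_cov - fg_mat)
  ft_cov <- cov(m)
  fb <- all_sites$class == "father_biallelic"
  ft_mat <- ifelse(fb, rbinom(m, ft_cov, 0.5),
                   ifelse(father_is_mat, ft_cov, 0L))
  obs_rows$ft <- add_obs("father", "transcriptome", ft_mat, ft_cov - ft_mat)
  # Daughter transcriptome: paternal copy silenced unless the locus
  # escapes; shared sites are homozygous maternal=paternal.
  dt_cov <- cov(m)
  p_pat <- ifelse(is.na(li), params$inactivated_leakage,
                  pat_frac[ifelse(is.na(li), 1, li)])
  d_hom <- all_sites$class == "shared_noninformative"
  dt_pat <- ifelse(d_hom, 0L, rbinom(m, dt_cov, p_pat))
  obs_rows$dt <- add_obs("daughter", "transcriptome",
                         dt_cov - dt_pat, dt_pat)
  if (params$daughter_genome_mean > 0) {
    dg_cov <- draw_coverage(m, params$daughter_genome_mean,
                            params$coverage_dispersion)
    dg_mat <- ifelse(d_hom, dg_cov, rbinom(m, dg_cov, 0.5))
    obs_rows$dg <- add_obs("daughter", "genome", dg_mat, dg_cov - dg_mat)
  } else {
    obs_rows$dg <- tibble(
      sample_id = character(), source = character(), scaffold = character(),
      pos = integer(), ref = character(), alt = character(),
      reads_ref = integer(), reads_alt = integer()
    )
  }
  observations <- allele_observations(bind_rows(obs_rows))

  # Annotation: gene loci become single-exon genes padded around their SNPs.
  gene_idx <- which(kind == "gene")
  annotation <- bind_rows(lapply(gene_idx, function(i) {
    g <- snps[snps$locus_id == locus_id[i], , drop = FALSE]
    tibble(gene_id = locus_id[i], gene_name = locus_id[i],
           scaffold = locus_scaffold[i],
           start = as.integer(min(g$pos) - 200L),
           end = as.integer(max(g$pos) + 200L),
           exons = list(data.frame(start = min(g$pos) - 200L,
                                   end = max(g$pos) + 200L)))
  }))
  if (length(gene_idx) == 0) {
    annotation <- tibble(gene_id = character(), gene_name = character(),
                         scaffold = character(), start = integer(),
                         end = integer(), exons = list())
  }

  # Map coordinates: scaffolds tiled end to end; two strata blocks with
  # the old/new boundary at 60% of the tiled length.
  sc_len <- vapply(scaffolds, function(s) unname(cursor[s]) + 10000, 0)
  offsets <- tibble(scaffold = scaffolds,
                    map_offset = cumsum(c(0, head(sc_len, -1))))
  total <- sum(sc_len)
  boundary <- 0.6 * total
  locus_map <- offsets$map_offset[match(locus_scaffold, offsets$scaffold)] +
    locus_pos
  region <- ifelse(locus_map < boundary, "old", "new")

  n_anchor <- 40L
  a_pos <- seq(total * 0.02, total * 0.98, length.out = n_anchor)
  a_lab <- ifelse(a_pos < boundary, "old", "new")
  a_lab[sample.int(n_anchor, max(1L, round(0.1 * n_anchor)))] <- "unknown"
  a_sc_idx <- findInterval(a_pos, cumsum(sc_len), left.open = TRUE) + 1L
  anchors <- tibble(
    gene = sprintf("ANCHOR_%02d", seq_len(n_anchor)),
    scaffold = scaffolds[a_sc_idx],
    position = a_pos, stratum = a_lab
  )
  in_map <- kind == "gene" & runif(n) < 0.2
  mapped_genes <- tibble(gene = locus_id[in_map],
                         scaffold = locus_scaffold[in_map],
                         position = locus_map[in_map],
                         stratum = region[in_map])
  map <- stratum_map(bind_rows(anchors, mapped_genes), offsets)

  orthology <- bind_rows(
    tibble(gene_id = locus_id[gene_idx], scaffold = locus_scaffold[gene_idx],
           human_orthologue = paste0("HS_", locus_id[gene_idx]),
           human_region = "XCR",
           opossum_orthologue = paste0("MD_", locus_id[gene_idx]),
           opossum_chromosome = "X", is_one_to_one = TRUE),
    tibble(gene_id = anchors$gene, scaffold = anchors$scaffold,
           human_orthologue = paste0("HS_", anchors$gene),
           human_region = "XCR",
           opossum_orthologue = paste0("MD_", anchors$gene),
           opossum_chromosome = "X", is_one_to_one = TRUE)
  )

  truth_loci <- tibble(
    locus_id = locus_id, kind = kind, scaffold = locus_scaffold,
    position = locus_pos, n_snps = n_snps,
    true_status = ifelse(esc, "escaper", "paternal_inactivated"),
    true_paternal_fraction = pat_frac,
    map_position = locus_map, stratum_region = region
  )
  truth_snps <- all_sites

  list(observations = observations, annotation = annotation,
       orthology = orthology, stratum_map = map,
       truth_loci = truth_loci, truth_snps = truth_snps, params = params)
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Emits the six observation TSVs (sample x source), a BED annotation, the
#' orthology, stratum-map, scaffold-offset and truth tables into a
#' directory (created if needed) without touching unrelated files.
#'
#' @param sim A [simulate_trio()] result.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  obs <- sim$observations
  for (s in c("mother", "father", "daughter")) {
    for (src in c("genome", "transcriptome")) {
      sel <- obs[obs$sample_id == s & obs$source == src,
                 c("sample_id", "source", "scaffold", "pos", "ref", "alt",
                   "reads_ref", "reads_alt")]
      readr::write_tsv(sel, file.path(dir, paste0(s, "_", src, ".tsv")))
    }
  }
  ann <- sim$annotation
  bed <- tibble(chrom = ann$scaffold, start = ann$start - 1L, end = ann$end,
                name = ann$gene_id)
  readr::write_tsv(bed, file.path(dir, "annotation.bed"), col_names = FALSE)
  readr::write_tsv(sim$orthology, file.path(dir, "orthology.tsv"))
  map <- sim$stratum_map
  readr::write_tsv(as_tibble(as.data.frame(map)),
                   file.path(dir, "stratum_map.tsv"))
  readr::write_tsv(attr(map, "scaffold_offsets"),
                   file.path(dir, "scaffold_offsets.tsv"))
  readr::write_tsv(sim$truth_loci, file.path(dir, "truth_loci.tsv"))
  readr::write_tsv(sim$truth_snps, file.path(dir, "truth_snps.tsv"))
  invisible(dir)
}
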