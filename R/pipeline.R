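#' Load pipeline inputs from a config file
#'
#' The config (YAML or JSON) names the input files: an `observations` map
#' of `sample: {genome: path, transcriptome: path}` TSVs, plus optional
#' `annotation` (`bed`/`gff3` chosen by extension), `orthology`,
#' `stratum_map` and `scaffold_offsets` paths, all relative to the config
#' file's directory unless absolute. Threshold overrides under `filter`,
#' `escape_threshold`, `intergenic_cluster_bp` and `mode` are carried
#' through to [run_pipeline()].
#'
#' @param path Config file.
#' @return A list of loaded inputs plus an `options` list of overrides.
#' @export
load_pipeline_inputs <- function(path) {
  if (!file.exists(path)) abort(paste0("no such config: ", path))
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(path)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  obs <- list()
  for (s in names(cfg$observations)) {
    for (src in names(cfg$observations[[s]])) {
      p <- resolve(cfg$observations[[s]][[src]])
      if (!file.exists(p)) abort(paste0("missing observation file: ", p))
      o <- read_allele_observations(p, dialect = "tsv")
      o$sample_id <- s
      o$source <- src
      obs[[paste(s, src)]] <- o
    }
  }
  annotation <- NULL
  if (!is.null(cfg$annotation)) {
    p <- resolve(cfg$annotation)
    if (!file.exists(p)) abort(paste0("missing annotation file: ", p))
    dialect <- if (grepl("\\.bed$", p)) "bed" else "gff3"
    annotation <- read_gene_annotation(p, dialect)
  }
  orthology <- if (!is.null(cfg$orthology)) {
    read_orthology(resolve(cfg$orthology))
  }
  map <- if (!is.null(cfg$stratum_map)) {
    read_stratum_map(resolve(cfg$stratum_map),
                     resolve(cfg$scaffold_offsets))
  }
  list(
    observations = allele_observations(bind_rows(obs)),
    annotation = annotation, orthology = orthology, stratum_map = map,
    options = cfg[intersect(names(cfg), c(
      "mode", "escape_threshold", "intergenic_cluster_bp", "filter",
      "out_dir", "biallelic_sample"
    ))]
  )
}

stage_entry <- function(stage, n_in, n_out) {
  tibble(stage = stage, n_in = as.integer(n_in), n_out = as.integer(n_out),
         n_skipped = as.integer(n_in - n_out))
}

#' Run the full trio XCI pipeline
#'
#' Stages, in order: site-level filters (coverage floor, singleton-het
#' curation), restriction to X-assigned scaffolds, father-biallelic
#' flagging, trio assembly and Mendelian phasing, SNP and locus
#' classification, stratum assignment and the escape-by-stratum exact
#' tests. Every excluded record lands in the skip log with a reason, and
#' each stage's in/out/skipped counts are retained, so record conservation
#' can be audited. The run is deterministic: identical inputs give
#' bit-identical reports.
#'
#' @param data A list with `observations` (all samples/sources) and
#'   optional `annotation`, `orthology`, `stratum_map` — e.g. a
#'   [simulate_trio()] result or [load_pipeline_inputs()] output.
#' @param mode `"trio"` (parent-of-origin analysis) or `"biallelic_only"`
#'   (single-sample minor-allele analysis).
#' @param filter A [filter_config()].
#' @param escape_threshold Minor-allele escape threshold (default 0.10).
#' @param intergenic_cluster_bp Intergenic locus clustering distance.
#' @param biallelic_sample Sample analysed in `biallelic_only` mode.
#' @param roles Optional `sample_id -> role` map for trio assembly.
#' @param out_dir If non-NULL, writes `report.tsv`, `summary.json`,
#'   `skip_log.tsv`, `stage_log.tsv` and `strata_tests.tsv` there.
#' @param quiet Suppress per-stage messages.
#' @return A list: `loci`, `summary`, `strata_tests`, `phased_snps`,
#'   `skip_log`, `stage_log` and (if written) `report_path`.
#' @export
run_pipeline <- function(data,
                         mode = c("trio", "biallelic_only"),
                         filter = filter_config(),
                         escape_threshold = 0.10,
                         intergenic_cluster_bp = 1000,
                         biallelic_sample = "daughter",
                         roles = NULL,
                         out_dir = NULL,
                         quiet = TRUE) {
  mode <- match.arg(mode)
  if (is.null(data$observations)) abort("data$observations is required")
  obs <- allele_observations(data$observations)
  annotation <- data$annotation
  stage_log <- list()
  skip <- skip_log_of(data$observations)
  say <- function(...) if (!quiet) inform(sprintf(...))

  note_stage <- function(stage, before, after) {
    stage_log[[length(stage_log) + 1L]] <<- stage_entry(stage,
                                                        nrow(before),
                                                        nrow(after))
    say("%s: %d in, %d out", stage, nrow(before), nrow(after))
  }

  # Coverage floor applies to every sample's evidence at a site.
  filtered <- filter_min_coverage(with_skip_log(obs, skip), filter)
  note_stage("min_coverage", obs, filtered)

  # Singleton-het curation runs per sample and source.
  parts <- split(filtered, paste(filtered$sample_id, filtered$source))
  cur_list <- lapply(parts, function(p) {
    filter_singleton_het(with_skip_log(p, NULL), annotation, filter)
  })
  curated <- bind_rows(cur_list)
  skip <- bind_rows(skip_log_of(filtered),
                    bind_rows(lapply(cur_list, skip_log_of)))
  note_stage("singleton_het", filtered, curated)

  # Restrict to X-assigned scaffolds (1:1 orthology evidence when given).
  x_sc <- if (!is.null(data$orthology)) {
    x_scaffolds_from_orthology(data$orthology)
  } else {
    unique(curated$scaffold)
  }
  on_x <- curated[curated$scaffold %in% x_sc, , drop = FALSE]
  skip <- bind_rows(skip, tibble(
    scaffold = curated$scaffold[!curated$scaffold %in% x_sc],
    pos = curated$pos[!curated$scaffold %in% x_sc],
    reason = rep("non_x_scaffold", sum(!curated$scaffold %in% x_sc))
  ))
  note_stage("x_restriction", curated, on_x)

  if (mode == "biallelic_only") {
    sample_obs <- on_x[on_x$sample_id == biallelic_sample, , drop = FALSE]
    res <- classify_biallelic_only(sample_obs, annotation,
                                   escape_threshold, intergenic_cluster_bp)
    loci <- res$loci
    if (!is.null(data$stratum_map) && nrow(loci) > 0) {
      loci <- assign_strata(loci, data$stratum_map)
    } else if (nrow(loci) > 0) {
      loci$stratum <- "unassigned"
    }
    out <- list(loci = loci, summary = res$summary,
                strata_tests = strata_escape_tests(loci),
                phased_snps = NULL, skip_log = skip,
                stage_log = bind_rows(stage_log))
    return(finalize_pipeline(out, out_dir))
  }

  father_id <- if (is.null(roles)) "father" else names(roles)[roles == "father"]
  father_obs <- on_x[on_x$sample_id %in% father_id, , drop = FALSE]
  flags <- flag_father_biallelic_x(father_obs, x_sc, filter)
  sites <- assemble_trio_sites(on_x, father_biallelic = flags, roles = roles)
  phased_all <- phase_trio_sites(sites)
  snps <- assign_parent_of_origin(sites)
  unphased <- attr(snps, "unphased")
  skip <- bind_rows(skip, tibble(
    scaffold = unphased$scaffold, pos = unphased$pos,
    reason = ifelse(unphased$reason == "", paste0("non_informative_",
                                                  unphased$genotype),
                    unphased$reason)
  ))
  note_stage("trio_phasing", sites, snps)

  snps$status <- classify_snp(snps$paternal_reads, snps$maternal_reads,
                              escape_threshold)
  loci <- aggregate_loci(snps, annotation, intergenic_cluster_bp)
  say("locus_aggregation: %d SNPs into %d loci", nrow(snps), nrow(loci))
  if (!is.null(data$stratum_map) && nrow(loci) > 0) {
    loci <- assign_strata(loci, data$stratum_map)
  } else if (nrow(loci) > 0) {
    loci$stratum <- "unassigned"
  }
  summary <- if (nrow(loci) > 0) summarize_escape(loci) else NULL
  out <- list(loci = loci, summary = summary,
              strata_tests = strata_escape_tests(loci),
              phased_snps = snps, skip_log = skip,
              stage_log = bind_rows(stage_log))
  finalize_pipeline(out, out_dir)
}

finalize_pipeline <- function(out, out_dir) {
  if (is.null(out_dir)) return(out)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  report <- file.path(out_dir, "report.tsv")
  write_report(out$loci, out$summary, report)
  readr::write_tsv(out$skip_log, file.path(out_dir, "skip_log.tsv"))
  readr::write_tsv(out$stage_log, file.path(out_dir, "stage_log.tsv"))
  readr::write_tsv(out$strata_tests, file.path(out_dir, "strata_tests.tsv"))
  if (!is.null(out$summary)) {
    jsonlite::write_json(out$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out$report_path <- report
  out
}
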