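#' Assemble per-site trio evidence for the daughter's covered sites
#'
#' Builds one row per site covered in the daughter, attaching the mother's
#' genotype (genome evidence outranking transcriptome, since transcriptome
#' homozygosity may be XCI-induced), the father's hemizygous X allele
#' (genome first, otherwise monoallelic transcriptome expression), and the
#' father-biallelic exclusion flag.
#'
#' @param observations A combined observation tibble for all samples and
#'   sources.
#' @param father_biallelic Character vector of flagged site keys from
#'   [flag_father_biallelic_x()].
#' @param roles Optional named vector mapping `sample_id` values to roles
#'   `"mother"`, `"father"`, `"daughter"`; by default sample ids are taken
#'   as the roles themselves.
#' @return A trio-site tibble (one row per daughter-covered site).
#' @export
assemble_trio_sites <- function(observations, father_biallelic = character(),
                                roles = NULL) {
  obs <- as_tibble(observations)
  obs$role <- if (is.null(roles)) obs$sample_id else unname(roles[obs$sample_id])
  obs <- obs[obs$role %in% c("mother", "father", "daughter"), , drop = FALSE]
  obs$key <- site_key(obs$scaffold, obs$pos, obs$ref, obs$alt)
  d <- obs[obs$role == "daughter", , drop = FALSE]
  if (nrow(d) == 0) {
    return(tibble(key = character(), scaffold = character(), pos = integer(),
                  ref = character(), alt = character(),
                  d_tx_ref = integer(), d_tx_alt = integer(),
                  d_gen_ref = integer(), d_gen_alt = integer(),
                  mother_genotype = character(), mother_source = character(),
                  father_allele = character(), father_source = character(),
                  father_biallelic = logical()))
  }
  base <- distinct(d[, c("key", "scaffold", "pos", "ref", "alt")])

  pick <- function(role, source, col) {
    sel <- obs[obs$role == role & obs$source == source, , drop = FALSE]
    v <- setNames(sel[[col]], sel$key)
    out <- unname(v[base$key])
    ifelse(is.na(out), NA_integer_, out)
  }
  base$d_tx_ref <- pick("daughter", "transcriptome", "reads_ref")
  base$d_tx_alt <- pick("daughter", "transcriptome", "reads_alt")
  base$d_gen_ref <- pick("daughter", "genome", "reads_ref")
  base$d_gen_alt <- pick("daughter", "genome", "reads_alt")

  geno_call <- function(rref, ralt) {
    dplyr::case_when(
      is.na(rref) | rref + ralt == 0 ~ "unknown",
      rref > 0 & ralt > 0 ~ "het",
      rref > 0 ~ "hom_ref",
      TRUE ~ "hom_alt"
    )
  }
  m_gen <- geno_call(pick("mother", "genome", "reads_ref"),
                     pick("mother", "genome", "reads_alt"))
  m_tx <- geno_call(pick("mother", "transcriptome", "reads_ref"),
                    pick("mother", "transcriptome", "reads_alt"))
  base$mother_genotype <- ifelse(m_gen != "unknown", m_gen, m_tx)
  base$mother_source <- dplyr::case_when(
    m_gen != "unknown" ~ "genome",
    m_tx != "unknown" ~ "transcriptome",
    TRUE ~ "none"
  )

  hemi_allele <- function(rref, ralt) {
    dplyr::case_when(
      is.na(rref) | rref + ralt == 0 ~ NA_character_,
      rref > 0 & ralt > 0 ~ "both",
      rref > 0 ~ "ref",
      TRUE ~ "alt"
    )
  }
  f_gen <- hemi_allele(pick("father", "genome", "reads_ref"),
                       pick("father", "genome", "reads_alt"))
  f_tx <- hemi_allele(pick("father", "transcriptome", "reads_ref"),
                      pick("father", "transcriptome", "reads_alt"))
  f_call <- ifelse(!is.na(f_gen), f_gen, f_tx)
  base$father_allele <- ifelse(f_call %in% c("ref", "alt"), f_call,
                               NA_character_)
  base$father_source <- dplyr::case_when(
    !is.na(f_gen) ~ "genome",
    !is.na(f_tx) ~ "transcriptome",
    TRUE ~ "none"
  )
  base$father_biallelic <- base$key %in% father_biallelic
  base
}

# Explicit decision table for one site. Alleles are "ref"/"alt".
# Returns genotype class, phase outcome, maternal/paternal allele and a
# reason string for excluded sites.
phase_one_site <- function(observed, mother, father, biallelic_flag) {
  res <- list(genotype = "unknown", phase = "unphased",
              maternal = NA_character_, paternal = NA_character_,
              reason = "")
  if (biallelic_flag) {
    res$reason <- "father_biallelic"
    return(res)
  }
  other <- function(a) if (a == "ref") "alt" else "ref"
  m_set <- switch(mother, hom_ref = "ref", hom_alt = "alt",
                  het = c("ref", "alt"), unknown = NULL)
  both_seen <- length(observed) == 2

  if (both_seen) {
    res$genotype <- "het_observed"
    if (!is.na(father)) {
      res$maternal <- other(father); res$paternal <- father
      if (!is.null(m_set) && !res$maternal %in% m_set) {
        res$genotype <- "het_observed"; res$phase <- "ambiguous"
        res$reason <- "mendelian_inconsistent"
      } else {
        res$phase <- "phased"
      }
    } else if (length(m_set) == 1) {
      res$maternal <- m_set; res$paternal <- other(m_set)
      res$phase <- "phased"
    } else {
      res$phase <- "ambiguous"; res$reason <- "no_father_allele"
    }
    return(res)
  }

  x <- observed  # single observed allele
  if (!is.na(father)) {
    p <- father
    if (is.null(m_set)) {
      if (x == p) {
        res$reason <- "genotype_unresolved"
      } else {
        res$genotype <- "het_inferred"
        res$maternal <- x; res$paternal <- p; res$phase <- "phased"
      }
    } else if (length(m_set) == 1) {
      m <- m_set
      if (m == p) {
        if (x == m) res$genotype <- "hom"
        else res$reason <- "mendelian_inconsistent"
      } else {
        if (x %in% c(m, p)) {
          res$genotype <- "het_inferred"
          res$maternal <- m; res$paternal <- p; res$phase <- "phased"
        } else {
          res$reason <- "mendelian_inconsistent"
        }
      }
    } else {  # mother het
      if (x == p) {
        res$reason <- "genotype_unresolved"
      } else {
        res$genotype <- "het_inferred"
        res$maternal <- x; res$paternal <- p; res$phase <- "phased"
      }
    }
  } else {  # father allele unavailable
    if (length(m_set) == 1) {
      m <- m_set
      if (x == m) {
        res$reason <- "genotype_unresolved"
      } else {
        res$genotype <- "het_inferred"
        res$maternal <- m; res$paternal <- x; res$phase <- "phased"
      }
    } else {
      res$reason <- "genotype_unresolved"
    }
  }
  res
}

observed_alleles <- function(row) {
  seen <- character()
  tx_ref <- row$d_tx_ref; tx_alt <- row$d_tx_alt
  gn_ref <- row$d_gen_ref; gn_alt <- row$d_gen_alt
  if (!is.na(tx_ref) && tx_ref > 0) seen <- c(seen, "ref")
  if (!is.na(tx_alt) && tx_alt > 0) seen <- c(seen, "alt")
  if (!is.na(gn_ref) && gn_ref > 0) seen <- c(seen, "ref")
  if (!is.na(gn_alt) && gn_alt > 0) seen <- c(seen, "alt")
  unique(seen)
}

#' Phase all trio sites
#'
#' Applies the Mendelian decision table to every assembled site: the
#' daughter's genotype is resolved (observed or inferred heterozygous,
#' homozygous, or unknown) and, where the phase is uniquely forced by the
#' parental evidence, her alleles are assigned to parents. Mendelian
#' impossibilities are logged via the `reason` column, never raised.
#'
#' @param trio_sites A tibble from [assemble_trio_sites()].
#' @return The input with columns `genotype`, `phase`, `maternal_allele`,
#'   `paternal_allele`, `maternal_reads`, `paternal_reads`, `reason` added.
#'   Read counts come from the daughter transcriptome and are `NA` for
#'   unphased sites.
#' @export
phase_trio_sites <- function(trio_sites) {
  n <- nrow(trio_sites)
  genotype <- character(n); phase <- character(n); reason <- character(n)
  mat_a <- character(n); pat_a <- character(n)
  mat_r <- rep(NA_integer_, n); pat_r <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    row <- trio_sites[i, ]
    obs <- observed_alleles(row)
    if (length(obs) == 0) {
      genotype[i] <- "unknown"; phase[i] <- "unphased"
      reason[i] <- "no_daughter_reads"
      mat_a[i] <- NA_character_; pat_a[i] <- NA_character_
      next
    }
    r <- phase_one_site(obs, row$mother_genotype, row$father_allele,
                        row$father_biallelic)
    genotype[i] <- r$genotype; phase[i] <- r$phase; reason[i] <- r$reason
    mat_a[i] <- r$maternal; pat_a[i] <- r$paternal
    if (identical(r$phase, "phased")) {
      tx_ref <- row$d_tx_ref %||% NA_integer_
      if (!is.na(tx_ref)) {
        mat_r[i] <- if (r$maternal == "ref") row$d_tx_ref else row$d_tx_alt
        pat_r[i] <- if (r$paternal == "ref") row$d_tx_ref else row$d_tx_alt
      }
    }
  }
  out <- trio_sites
  out$genotype <- genotype
  out$phase <- phase
  out$maternal_allele <- ifelse(mat_a == "ref", out$ref,
                                ifelse(mat_a == "alt", out$alt, NA))
  out$paternal_allele <- ifelse(pat_a == "ref", out$ref,
                                ifelse(pat_a == "alt", out$alt, NA))
  out$maternal_reads <- mat_r
  out$paternal_reads <- pat_r
  out$reason <- reason
  out
}

#' Infer the daughter's genotype at each trio site
#'
#' @param trio_sites A tibble from [assemble_trio_sites()].
#' @return Character vector: `"het_observed"`, `"het_inferred"`, `"hom"` or
#'   `"unknown"` per site.
#' @export
infer_daughter_genotype <- function(trio_sites) {
  phase_trio_sites(trio_sites)$genotype
}

#' Assign parent of origin to the daughter's alleles
#'
#' For sites with a (observed or inferred) heterozygous genotype and no
#' father-biallelic flag, returns the phased SNP table: maternal and
#' paternal alleles with their transcriptome read counts. Sites whose phase
#' is not uniquely forced are reported as ambiguous; Mendelian
#' inconsistencies are logged in `reason`.
#'
#' @param trio_sites A tibble from [assemble_trio_sites()].
#' @return A tibble of phased SNPs (only sites with daughter transcriptome
#'   coverage and a unique phase), with the ambiguous/excluded remainder in
#'   `attr(, "unphased")`.
#' @export
assign_parent_of_origin <- function(trio_sites) {
  phased <- phase_trio_sites(trio_sites)
  ok <- phased$phase == "phased" & !is.na(phased$maternal_reads) &
    (phased$maternal_reads + phased$paternal_reads) > 0
  snps <- phased[ok, c("key", "scaffold", "pos", "ref", "alt", "genotype",
                       "maternal_allele", "paternal_allele",
                       "maternal_reads", "paternal_reads")]
  attr(snps, "unphased") <- phased[!ok, , drop = FALSE]
  snps
}
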