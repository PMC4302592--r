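# Shared builders and independent oracles for the suite.

make_obs <- function(sample_id, source, scaffold, pos, ref, alt,
                     reads_ref, reads_alt) {
  allele_observations(tibble::tibble(
    sample_id = sample_id, source = source, scaffold = scaffold,
    pos = as.integer(pos), ref = ref, alt = alt,
    reads_ref = as.integer(reads_ref), reads_alt = as.integer(reads_alt)
  ))
}

make_trio_site <- function(mother = "unknown", father = NA_character_,
                           d_tx_ref = NA_integer_, d_tx_alt = NA_integer_,
                           d_gen_ref = NA_integer_, d_gen_alt = NA_integer_,
                           biallelic = FALSE, scaffold = "ScaffoldX1",
                           pos = 100L, ref = "A", alt = "G") {
  tibble::tibble(
    key = paste(scaffold, pos, ref, alt, sep = ":"),
    scaffold = scaffold, pos = as.integer(pos), ref = ref, alt = alt,
    d_tx_ref = as.integer(d_tx_ref), d_tx_alt = as.integer(d_tx_alt),
    d_gen_ref = as.integer(d_gen_ref), d_gen_alt = as.integer(d_gen_alt),
    mother_genotype = mother, mother_source = "genome",
    father_allele = father, father_source = "genome",
    father_biallelic = biallelic
  )
}

# Brute-force Mendelian oracle: enumerate every (maternal, paternal)
# allele assignment consistent with the evidence and report the genotype
# class and, when unique, the phase. Alleles are "ref"/"alt".
oracle_phase <- function(mother, father, expressed) {
  m_opts <- switch(mother, hom_ref = "ref", hom_alt = "alt",
                   het = c("ref", "alt"), unknown = c("ref", "alt"))
  p_opts <- if (is.na(father)) c("ref", "alt") else father
  pairs <- expand.grid(m = m_opts, p = p_opts, stringsAsFactors = FALSE)
  ok <- vapply(seq_len(nrow(pairs)), function(i) {
    all(expressed %in% c(pairs$m[i], pairs$p[i]))
  }, TRUE)
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(list(genotype = "unknown", phase = "unphased",
                maternal = NA, paternal = NA))
  }
  genos <- unique(vapply(seq_len(nrow(pairs)), function(i) {
    paste(sort(c(pairs$m[i], pairs$p[i])), collapse = "/")
  }, ""))
  if (length(genos) > 1) {
    return(list(genotype = "unknown", phase = "unphased",
                maternal = NA, paternal = NA))
  }
  g <- if (genos == "alt/ref") {
    if (length(expressed) == 2) "het_observed" else "het_inferred"
  } else {
    "hom"
  }
  phases <- unique(paste(pairs$m, pairs$p))
  if (g %in% c("het_observed", "het_inferred") && length(phases) == 1) {
    list(genotype = g, phase = "phased",
         maternal = pairs$m[1], paternal = pairs$p[1])
  } else {
    list(genotype = g, phase = if (g == "hom") "unphased" else "ambiguous",
         maternal = NA, paternal = NA)
  }
}

# Exhaustive two-sided Fisher oracle: enumerate all tables sharing the
# observed margins and sum the point probabilities (computed with choose())
# of tables no more likely than the observed one.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  prob <- function(x) {
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  }
  probs <- vapply(lo:hi, prob, 0)
  obs <- probs[(lo:hi) == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}
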