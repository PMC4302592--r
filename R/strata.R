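#' Assign genes or scaffolds to the X chromosome via 1:1 orthology
#'
#' A focal gene (and hence its scaffold) is X-linked when it has at least
#' one 1:1 orthologue on the human X conserved region (XCR) and/or the
#' opossum X; autosomal when its 1:1 orthologue lies on the remainder of
#' the human X or a human autosome; and unplaced (dropped downstream, with
#' a log entry) when it has no 1:1 orthologue.
#'
#' @param gene_ids Character vector of focal gene ids.
#' @param orthology Orthology tibble from [read_orthology()].
#' @return Character vector: `"X"`, `"autosome"` or `"unplaced"` per gene.
#' @export
assign_x_linkage <- function(gene_ids, orthology) {
  idx <- match(gene_ids, orthology$gene_id)
  out <- rep("unplaced", length(gene_ids))
  hit <- !is.na(idx)
  o <- orthology[idx[hit], , drop = FALSE]
  one <- o$is_one_to_one %in% TRUE
  on_x <- one & ((o$human_region %in% "XCR") |
                   (!is.na(o$opossum_chromosome) & o$opossum_chromosome == "X"))
  on_auto <- one & !on_x & o$human_region %in% c("X_other", "autosome")
  res <- ifelse(on_x, "X", ifelse(on_auto, "autosome", "unplaced"))
  out[hit] <- res
  out
}

#' X-assigned scaffolds implied by an orthology table
#'
#' @param orthology Orthology tibble with a `scaffold` column.
#' @return Character vector of scaffolds carrying at least one X-assigned
#'   gene.
#' @export
x_scaffolds_from_orthology <- function(orthology) {
  linkage <- assign_x_linkage(orthology$gene_id, orthology)
  unique(orthology$scaffold[linkage == "X"])
}

# Map position of loci on the stratum map's coordinate system via the
# scaffold-offset (synteny) table; NA when the scaffold is not placed.
locus_map_position <- function(loci, map) {
  offsets <- attr(map, "scaffold_offsets")
  if (is.null(offsets)) return(rep(NA_real_, nrow(loci)))
  off <- offsets$map_offset[match(loci$scaffold, offsets$scaffold)]
  off + loci$position
}

#' Assign loci to X evolutionary strata by the flanking-gene rule
#'
#' A locus that is itself a mapped gene with an old/new label takes its own
#' label. Any other locus is placed on the map coordinate (via the
#' scaffold-offset synteny lookup) and classified by its nearest flanking
#' mapped genes: both flanks old gives `old`, both new gives `new`, one of
#' each gives `excluded` (strata analysis cannot use it), and a missing or
#' unknown-labelled flank gives `unassigned`.
#'
#' @param loci Locus tibble from [aggregate_loci()].
#' @param map A [stratum_map()].
#' @return The locus tibble with a `stratum` column appended.
#' @export
assign_strata <- function(loci, map) {
  if (nrow(loci) == 0) {
    loci$stratum <- character()
    return(loci)
  }
  mpos <- locus_map_position(loci, map)
  self_idx <- match(loci$gene_id, map$gene)
  stratum <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    if (!is.na(self_idx[i]) && map$stratum[self_idx[i]] %in% c("old", "new")) {
      stratum[i] <- map$stratum[self_idx[i]]
      next
    }
    p <- mpos[i]
    if (is.na(p)) {
      stratum[i] <- "unassigned"
      next
    }
    below <- map[map$position <= p, , drop = FALSE]
    above <- map[map$position >= p, , drop = FALSE]
    left <- if (nrow(below) > 0) below$stratum[nrow(below)] else NA_character_
    right <- if (nrow(above) > 0) above$stratum[1] else NA_character_
    stratum[i] <- if (is.na(left) || is.na(right) ||
                      left == "unknown" || right == "unknown") {
      "unassigned"
    } else if (left == right) {
      left
    } else {
      "excluded"
    }
  }
  loci$stratum <- stratum
  loci
}
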