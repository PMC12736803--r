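# Cross-species ortholog comparison: direction concordance and
# stress-associated orthogroup flagging.

# Extract a gene -> regulation direction table from an integrated network,
# a selection data frame, or a named character vector.
regulation_table <- function(x) {
  if (inherits(x, "integrated_network")) {
    g <- x$nodes[x$nodes$type == "gene", , drop = FALSE]
    return(setNames(g$regulation, g$name))
  }
  if (is.data.frame(x) && all(c("gene", "direction") %in% names(x)))
    return(setNames(x$direction, x$gene))
  if (is.character(x) && !is.null(names(x))) return(x)
  sg_stop("cannot extract regulation directions", "solgrn_input_error")
}

#' Ortholog direction concordance between two networks
#'
#' Counts ortholog pairs with both ends present in the two networks (or
#' direction tables) and tallies same- versus opposite-direction pairs.
#' Many-to-many orthology is resolved pair-wise: each qualifying map record
#' is counted once. Pairs with a missing direction are excluded.
#'
#' @param net_A,net_B `integrated_network`s, selection data frames, or named
#'   direction vectors for species A and B.
#' @param map data frame with `gene_A`, `gene_B` (and optionally
#'   `orthogroup_id`).
#' @return list of class `concordance_report`: n_shared, n_same, n_opposite,
#'   concordance, `by_direction` (counts of up/up, down/down, discordant),
#'   and `pairs` (the per-pair table).
#' @export
concordance <- function(net_A, net_B, map) {
  dA <- regulation_table(net_A)
  dB <- regulation_table(net_B)
  sel <- map$gene_A %in% names(dA) & map$gene_B %in% names(dB)
  pairs <- map[sel, , drop = FALSE]
  pairs$dir_A <- unname(dA[pairs$gene_A])
  pairs$dir_B <- unname(dB[pairs$gene_B])
  ok <- pairs$dir_A %in% c("up", "down") & pairs$dir_B %in% c("up", "down")
  if (any(!ok))
    message("excluding ", sum(!ok), " pair(s) with missing direction")
  pairs <- pairs[ok, , drop = FALSE]
  pairs$same <- pairs$dir_A == pairs$dir_B
  n_shared <- nrow(pairs)
  n_same <- sum(pairs$same)
  out <- list(
    n_shared = n_shared, n_same = n_same, n_opposite = n_shared - n_same,
    concordance = if (n_shared > 0) n_same / n_shared else NA_real_,
    by_direction = c(up_up = sum(pairs$same & pairs$dir_A == "up"),
                     down_down = sum(pairs$same & pairs$dir_A == "down"),
                     opposite = n_shared - n_same),
    pairs = pairs)
  class(out) <- "concordance_report"
  out
}

#' Flag stress-associated orthogroups
#'
#' An orthogroup is flagged for a stress iff it contains at least one gene
#' in the stress DEG set of at least one species.
#'
#' @param map data frame with `gene_A`, `gene_B`, `orthogroup_id`.
#' @param deg_sets named list (per species: `A`, `B`) of gene-id vectors of
#'   stress DEGs.
#' @param stress stress label recorded in the output.
#' @return data frame orthogroup_id, stress, flagged, n_A, n_B (member DEG
#'   counts per species).
#' @export
flag_stress_orthogroups <- function(map, deg_sets, stress = "stress") {
  ogs <- sort(unique(map$orthogroup_id))
  rows <- lapply(ogs, function(og) {
    sub <- map[map$orthogroup_id == og, , drop = FALSE]
    nA <- sum(unique(sub$gene_A) %in% deg_sets$A)
    nB <- sum(unique(sub$gene_B) %in% deg_sets$B)
    data.frame(orthogroup_id = og, stress = stress,
               flagged = (nA + nB) > 0, n_A = nA, n_B = nB,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
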