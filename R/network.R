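# Tri-evidence gene regulatory network: merge co-expression, motif and PPI
# layers into a typed multigraph, cluster by evidence priority, call hubs.

#' Build an integrated gene regulatory network
#'
#' Nodes are the selected genes (carrying regulation direction), TFs among
#' them (flagged), and motif nodes for motifs retained by enrichment. Edges
#' are typed: `coexpression` (thresholded correlation), `motif` (motif ->
#' gene when the gene's promoter has >= 1 hit of a motif retained for the
#' gene's direction set, and motif -> TF per the association map), and `ppi`
#' (score >= `ppi_cut`). Parallel edges of different evidence are kept
#' distinct; duplicate same-evidence edges are deduplicated.
#'
#' @param selection [select_top()] output (gene, direction, ...).
#' @param coexpr data frame gene_a, gene_b, r from [correlation_edges()].
#' @param enrichment [enrich_motifs()] output; sets named `up` / `down`.
#' @param hits genes x motifs hit-count matrix.
#' @param motif_tf data frame `motif_id`, `tf_gene` associating motifs with
#'   TF genes (may be NULL).
#' @param ppi data frame gene_a, gene_b, score.
#' @param ppi_cut minimum PPI confidence (default 0.400).
#' @return list of class `integrated_network`: `graph` (igraph multigraph),
#'   `nodes`, `edges` data frames, `dropped` (edge records outside the
#'   selection universe).
#' @export
build_network <- function(selection, coexpr, enrichment, hits,
                          motif_tf = NULL, ppi = NULL, ppi_cut = 0.400) {
  if (nrow(selection) == 0)
    sg_stop("empty selection: no nodes to build", "solgrn_input_error")
  genes <- selection$gene
  dir <- setNames(selection$direction, genes)
  tf_genes <- if (!is.null(motif_tf)) intersect(motif_tf$tf_gene, genes)
              else character(0)
  retained <- enrichment[enrichment$retained, , drop = FALSE]
  motifs <- unique(retained$motif)

  edges <- list(); dropped <- list()
  add_edges <- function(a, b, evidence, weight) {
    data.frame(from = a, to = b, evidence = evidence, weight = weight,
               stringsAsFactors = FALSE)
  }
  if (!is.null(coexpr) && nrow(coexpr)) {
    ok <- coexpr$gene_a %in% genes & coexpr$gene_b %in% genes
    if (any(!ok)) dropped$coexpression <- coexpr[!ok, , drop = FALSE]
    edges$coexpression <- add_edges(coexpr$gene_a[ok], coexpr$gene_b[ok],
                                    "coexpression", coexpr$r[ok])
  }
  if (nrow(retained)) {
    for (i in seq_len(nrow(retained))) {
      m <- retained$motif[i]; set <- retained$set[i]
      members <- genes[dir[genes] == set]
      members <- members[members %in% rownames(hits)]
      with_hit <- members[hits[members, m] >= 1]
      if (length(with_hit))
        edges[[paste0("motif_", i)]] <- add_edges(
          rep(m, length(with_hit)), with_hit, "motif", retained$q[i])
    }
  }
  if (!is.null(motif_tf) && nrow(motif_tf)) {
    mt <- motif_tf[motif_tf$motif_id %in% motifs &
                     motif_tf$tf_gene %in% genes, , drop = FALSE]
    if (nrow(mt))
      edges$motif_tf <- add_edges(mt$motif_id, mt$tf_gene, "motif", 0)
  }
  if (!is.null(ppi) && nrow(ppi)) {
    keep <- ppi$score >= ppi_cut
    ppi <- ppi[keep, , drop = FALSE]
    ok <- ppi$gene_a %in% genes & ppi$gene_b %in% genes
    if (any(!ok)) {
      dropped$ppi <- ppi[!ok, , drop = FALSE]
      message("dropping ", sum(!ok), " PPI edge(s) outside the selection")
    }
    edges$ppi <- add_edges(ppi$gene_a[ok], ppi$gene_b[ok], "ppi",
                           ppi$score[ok])
  }
  ed <- do.call(rbind, edges)
  if (is.null(ed)) ed <- data.frame(from = character(0), to = character(0),
                                    evidence = character(0),
                                    weight = numeric(0))
  # deduplicate same-evidence duplicates (canonical order within evidence)
  key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to), ed$evidence)
  dup <- duplicated(key)
  n_dup <- sum(dup)
  ed <- ed[!dup, , drop = FALSE]
  rownames(ed) <- NULL

  used_motifs <- intersect(motifs, unique(c(ed$from, ed$to)))
  nodes <- rbind(
    data.frame(name = genes, type = "gene",
               is_tf = genes %in% tf_genes,
               regulation = unname(dir[genes]), stringsAsFactors = FALSE),
    if (length(used_motifs))
      data.frame(name = used_motifs, type = "motif", is_tf = FALSE,
                 regulation = NA_character_, stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nodes)
  out <- list(graph = g, nodes = nodes, edges = ed,
              dropped = dropped, n_deduplicated = n_dup)
  class(out) <- "integrated_network"
  out
}

#' Per-evidence and total edge counts of an integrated network
#'
#' @param net an `integrated_network`.
#' @return named integer vector with one entry per evidence type plus
#'   `total` (the per-evidence counts sum exactly to the total).
#' @export
edge_counts <- function(net) {
  tab <- table(net$edges$evidence)
  c(setNames(as.integer(tab), names(tab)), total = nrow(net$edges))
}

#' Assign clusters by evidence priority
#'
#' Stage 1: connected components of the co-expression-only subgraph (genes
#' with at least one co-expression edge) seed clusters. Stage 2: motif
#' nodes adopt the majority cluster of their already-clustered gene
#' neighbours (or seed a new cluster); unclustered genes with motif edges
#' join the cluster of their majority motif, ties resolved toward the
#' larger cluster then the smaller cluster label. Stage 3: remaining genes
#' cluster by connected components of the PPI-only subgraph among
#' themselves; singletons stay unclustered (label 0). Final labels are
#' renumbered 1..n by descending gene count, ties by ascending smallest
#' member id.
#'
#' @param net an `integrated_network`.
#' @return the network with `nodes$cluster` filled in and `graph` vertex
#'   attribute `cluster` set.
#' @export
assign_clusters <- function(net) {
  nodes <- net$nodes
  cl <- setNames(rep(0L, nrow(nodes)), nodes$name)
  ed <- net$edges
  next_cl <- 0L

  # stage 1: coexpression components
  ce <- ed[ed$evidence == "coexpression", , drop = FALSE]
  if (nrow(ce)) {
    gs <- igraph::graph_from_data_frame(ce[, c("from", "to")],
                                        directed = FALSE)
    comp <- igraph::components(gs)$membership
    cl[names(comp)] <- comp + next_cl
    next_cl <- next_cl + max(comp)
  }

  # stage 2: motif-mediated assignment
  me <- ed[ed$evidence == "motif", , drop = FALSE]
  motif_nodes <- nodes$name[nodes$type == "motif"]
  motif_cl <- setNames(rep(0L, length(motif_nodes)), motif_nodes)
  if (nrow(me)) {
    neigh <- function(m) {
      unique(c(me$to[me$from == m], me$from[me$to == m]))
    }
    for (m in motif_nodes) {
      nb <- setdiff(neigh(m), motif_nodes)
      cls <- cl[nb]; cls <- cls[cls > 0]
      if (length(cls)) {
        tab <- sort(table(cls), decreasing = TRUE)
        best <- as.integer(names(tab)[tab == tab[1]])
        motif_cl[m] <- min(best)
      } else {
        next_cl <- next_cl + 1L
        motif_cl[m] <- next_cl
      }
    }
    cl[motif_nodes] <- motif_cl
    unc <- nodes$name[nodes$type == "gene" & cl[nodes$name] == 0]
    for (g in unc) {
      ms <- intersect(neigh(g), motif_nodes)
      if (!length(ms)) next
      cand <- motif_cl[ms]
      tab <- sort(table(cand), decreasing = TRUE)
      best <- as.integer(names(tab)[tab == tab[1]])
      if (length(best) > 1) {
        sizes <- vapply(best, function(k) sum(cl == k), 0L)
        best <- best[order(-sizes, best)]
      }
      cl[g] <- best[1]
    }
  }

  # stage 3: PPI components among still-unclustered genes
  pe <- ed[ed$evidence == "ppi", , drop = FALSE]
  unc <- nodes$name[nodes$type == "gene" & cl[nodes$name] == 0]
  if (nrow(pe) && length(unc)) {
    pe <- pe[pe$from %in% unc & pe$to %in% unc, , drop = FALSE]
    if (nrow(pe)) {
      gs <- igraph::graph_from_data_frame(pe[, c("from", "to")],
                                          directed = FALSE)
      comp <- igraph::components(gs)$membership
      cl[names(comp)] <- comp + next_cl
      next_cl <- next_cl + max(comp)
    }
  }

  # renumber by descending gene count, ties by smallest member id
  is_gene <- setNames(nodes$type == "gene", nodes$name)
  live <- sort(unique(cl[cl > 0]))
  if (length(live)) {
    gene_n <- vapply(live, function(k) sum(cl == k & is_gene[names(cl)]), 0L)
    min_id <- vapply(live, function(k) min(names(cl)[cl == k]), "")
    ord <- live[order(-gene_n, min_id)]
    remap <- setNames(seq_along(ord), ord)
    cl[cl > 0] <- remap[as.character(cl[cl > 0])]
  }
  net$nodes$cluster <- as.integer(unname(cl[net$nodes$name]))
  igraph::V(net$graph)$cluster <-
    as.integer(unname(cl[igraph::V(net$graph)$name]))
  net
}

#' Call hub transcription factors
#'
#' TFs whose total degree (parallel edges of all evidence types counted
#' separately) exceeds `min_degree - 1` are flagged as hubs. High-degree
#' non-TF genes are reported separately, not as hubs.
#'
#' @param net an `integrated_network` (clusters assigned or not).
#' @param min_degree minimum hub degree; the default 41 encodes the
#'   "greater than 40 edges" rule.
#' @return list with `hubs` (data frame tf, degree, per-evidence counts,
#'   cluster) and `high_degree_genes` (non-TF genes over the same cutoff).
#' @export
call_hubs <- function(net, min_degree = 41) {
  deg <- igraph::degree(net$graph)
  nodes <- net$nodes
  per_ev <- function(v) {
    sel <- net$edges$from == v | net$edges$to == v
    tab <- table(factor(net$edges$evidence[sel],
                        levels = c("coexpression", "motif", "ppi")))
    as.integer(tab)
  }
  mk <- function(names) {
    if (!length(names))
      return(data.frame(node = character(0), degree = integer(0),
                        coexpression = integer(0), motif = integer(0),
                        ppi = integer(0), cluster = integer(0),
                        stringsAsFactors = FALSE))
    ev <- t(vapply(names, per_ev, integer(3)))
    data.frame(node = names, degree = as.integer(deg[names]),
               coexpression = ev[, 1], motif = ev[, 2], ppi = ev[, 3],
               cluster = if ("cluster" %in% names(nodes))
                 nodes$cluster[match(names, nodes$name)] else NA_integer_,
               stringsAsFactors = FALSE)
  }
  tfs <- nodes$name[nodes$is_tf]
  genes <- nodes$name[nodes$type == "gene" & !nodes$is_tf]
  hubs <- mk(tfs[deg[tfs] >= min_degree])
  high <- mk(genes[deg[genes] >= min_degree])
  list(hubs = hubs[order(-hubs$degree, hubs$node), , drop = FALSE],
       high_degree_genes = high[order(-high$degree, high$node), ,
                                drop = FALSE])
}

#' Summarize clusters of an integrated network
#'
#' @param net an `integrated_network` with clusters assigned.
#' @return data frame per cluster: n_genes, n_up, n_down, regulation class
#'   (`up`, `down`, `mixed`), member TFs, enriched motifs attached to the
#'   cluster, dominant evidence type by within-cluster edge count.
#' @export
summarize_clusters <- function(net) {
  stopifnot("cluster" %in% names(net$nodes))
  nodes <- net$nodes
  live <- sort(unique(nodes$cluster[nodes$cluster > 0]))
  rows <- lapply(live, function(k) {
    memb <- nodes[nodes$cluster == k, , drop = FALSE]
    gn <- memb[memb$type == "gene", , drop = FALSE]
    if (nrow(gn) == 0) return(NULL)
    n_up <- sum(gn$regulation == "up"); n_dn <- sum(gn$regulation == "down")
    reg <- if (n_dn == 0) "up" else if (n_up == 0) "down" else "mixed"
    inside <- net$edges$from %in% memb$name & net$edges$to %in% memb$name
    ev <- table(net$edges$evidence[inside])
    dom <- if (length(ev)) names(ev)[which.max(ev)] else NA_character_
    data.frame(cluster = k, n_genes = nrow(gn), n_up = n_up, n_down = n_dn,
               regulation = reg,
               tfs = paste(sort(gn$name[gn$is_tf]), collapse = ","),
               motifs = paste(sort(memb$name[memb$type == "motif"]),
                              collapse = ","),
               dominant_evidence = dom, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export an integrated network as SIF plus node/edge attribute tables
#'
#' @param net an `integrated_network`.
#' @param prefix output path prefix; writes `<prefix>.sif`,
#'   `<prefix>_nodes.tsv`, `<prefix>_edges.tsv`.
#' @export
write_network <- function(net, prefix) {
  sif <- sprintf("%s\t%s\t%s", net$edges$from, net$edges$evidence,
                 net$edges$to)
  writeLines(sif, paste0(prefix, ".sif"))
  write_tsv(net$nodes, paste0(prefix, "_nodes.tsv"))
  write_tsv(net$edges, paste0(prefix, "_edges.tsv"))
  invisible(prefix)
}
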