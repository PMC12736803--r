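# End-to-end orchestration: DE consensus -> promoter motifs -> coexpression
# -> integrated network -> cross-species/evolutionary comparison, with a
# provenance manifest.

#' Default pipeline parameters
#'
#' @param min_occurrence occurrence cutoff (NULL = majority rule, 5/6 of
#'   experiments).
#' @param k_per_direction top-set size per direction (default 500).
#' @param s_cut s-value cutoff (default 0.005).
#' @param lfc_cut absolute LFC cutoff / Wald threshold (default 0.32).
#' @param q_cut motif-enrichment q cutoff (default 0.05).
#' @param ppi_cut PPI confidence cutoff (default 0.400).
#' @param promoter_len promoter length (default 1000).
#' @param coexpr_threshold `"auto"` (adaptive by experiment count) or a
#'   numeric cutoff.
#' @param min_len,ks_band Ka/Ks pair filters.
#' @return parameter list.
#' @export
run_params <- function(min_occurrence = NULL, k_per_direction = 500,
                       s_cut = 0.005, lfc_cut = 0.32, q_cut = 0.05,
                       ppi_cut = 0.400, promoter_len = 1000,
                       coexpr_threshold = "auto",
                       min_len = 300, ks_band = c(0.01, 3)) {
  as.list(environment())
}

#' Run the full analysis for one species-stress condition
#'
#' Executes consensus DE selection, promoter extraction and motif
#' enrichment, batch-corrected co-expression, and tri-evidence network
#' assembly on a synthetic (or equivalently structured) input bundle.
#' Deterministic given the bundle. With an empty selection (null data) all
#' downstream artifacts are empty and the manifest records zero selected
#' genes.
#'
#' @param bundle a [simulate_bundle()] result (or a list with the same
#'   elements read from disk via [read_bundle()]).
#' @param params a [run_params()] list.
#' @param stress stress label carried through reports.
#' @param out_dir optional output directory; when given, all artifacts and
#'   `run_manifest.json` are written there.
#' @return list with `selection`, `consensus`, `combined`, `enrichment`,
#'   `hits`, `promoters`, `expr`, `coexpr_edges`, `network`, `clusters`,
#'   `hubs`, `kaks`, `stress`, `manifest`.
#' @export
run_condition <- function(bundle, params = run_params(), stress = "stress",
                          out_dir = NULL) {
  de <- consensus_select(bundle$counts, bundle$samples,
                         min_occurrence = params$min_occurrence,
                         k_per_direction = params$k_per_direction,
                         s_cut = params$s_cut, lfc_cut = params$lfc_cut)
  sel <- de$selection

  promoters <- extract_promoters(bundle$genome, bundle$gff,
                                 length = params$promoter_len)
  hits <- scan_pwm_set(promoters, bundle$pwms)

  enrichment <- NULL; coexpr <- NULL; net <- NULL
  clusters <- NULL; hubs <- NULL
  if (!is.null(sel) && nrow(sel) > 0) {
    sets <- split(sel$gene, sel$direction)
    enrichment <- enrich_motifs(sets, rownames(bundle$counts), hits,
                                q_cut = params$q_cut)
    expr <- normalize_log(bundle$counts)
    expr <- remove_batch(expr, bundle$samples$experiment_id,
                         bundle$samples$condition)
    thr <- if (identical(params$coexpr_threshold, "auto"))
      adaptive_threshold(length(unique(bundle$samples$experiment_id)))
    else params$coexpr_threshold
    universe <- unique(c(sel$gene,
                         if (!is.null(bundle$tf_motif))
                           bundle$tf_motif$tf_gene))
    coexpr <- correlation_edges(expr, universe, threshold = thr)
    tf_map <- if (!is.null(bundle$tf_motif))
      data.frame(motif_id = bundle$tf_motif$motif_id,
                 tf_gene = bundle$tf_motif$tf_gene,
                 stringsAsFactors = FALSE)
    net <- build_network(sel, coexpr, enrichment, hits, tf_map,
                         bundle$ppi, ppi_cut = params$ppi_cut)
    net <- assign_clusters(net)
    clusters <- summarize_clusters(net)
    hubs <- call_hubs(net)
  } else {
    expr <- normalize_log(bundle$counts)
  }

  kaks <- if (!is.null(bundle$cds_pairs) && length(bundle$cds_pairs))
    kaks_table(bundle$cds_pairs, min_len = params$min_len,
               ks_band = params$ks_band)

  res <- list(selection = sel, consensus = de$consensus,
              combined = de$combined, combined_degs = de$combined_degs,
              per_experiment = de$per_experiment,
              per_experiment_degs = de$per_experiment_degs,
              enrichment = enrichment, hits = hits, promoters = promoters,
              expr = expr, coexpr_edges = coexpr, network = net,
              clusters = clusters, hubs = hubs, kaks = kaks,
              stress = stress, params = params)
  if (!is.null(out_dir)) res$manifest <- write_run(res, out_dir)
  res
}

# Write all artifacts of a run and build the provenance manifest.
write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wf <- function(x, name) {
    if (is.null(x)) return(NULL)
    path <- file.path(out_dir, name)
    write_tsv(x, path)
    path
  }
  paths <- c(
    wf(res$combined[, c("gene", "base_mean", "lfc", "se", "wald_p",
                        "shrunk_lfc", "s_value")], "contrast_combined.tsv"),
    wf(res$consensus, "consensus.tsv"),
    wf(res$selection, "selection.tsv"),
    wf(res$enrichment, "enrichment.tsv"),
    wf(res$coexpr_edges, "coexpr_edges.tsv"),
    wf(res$clusters, "clusters.tsv"),
    wf(if (!is.null(res$hubs)) res$hubs$hubs, "hubs.tsv"),
    wf(res$kaks, "kaks.tsv"))
  if (!is.null(res$network)) {
    write_network(res$network, file.path(out_dir, "network"))
    paths <- c(paths, file.path(out_dir, c("network.sif",
                                           "network_nodes.tsv",
                                           "network_edges.tsv")))
  }
  files <- lapply(paths, function(p) {
    list(rows = length(readLines(p)) - 1L,
         md5 = unname(tools::md5sum(p)))
  })
  names(files) <- basename(paths)
  manifest <- list(
    stress = res$stress,
    params = res$params,
    n_selected = if (is.null(res$selection)) 0L else nrow(res$selection),
    n_selected_up = if (is.null(res$selection)) 0L else
      sum(res$selection$direction == "up"),
    n_selected_down = if (is.null(res$selection)) 0L else
      sum(res$selection$direction == "down"),
    edge_counts = if (!is.null(res$network))
      as.list(edge_counts(res$network)) else list(total = 0L),
    files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Read an input bundle from a directory written by [write_bundle()]
#'
#' @param dir directory containing counts.tsv, samples.tsv, genome.fa,
#'   genes.gff3, motifs.meme, ppi.tsv, tf_motif.tsv, orthologs.tsv,
#'   cds_pairs.fa.
#' @return list shaped like a [simulate_bundle()] result (without truth).
#' @export
read_bundle <- function(dir) {
  cdf <- read_tsv(file.path(dir, "counts.tsv"))
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf$gene_id
  storage.mode(counts) <- "integer"
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  genome <- setNames(as.character(genome), sub("\\s.*$", "", names(genome)))
  tfm_path <- file.path(dir, "tf_motif.tsv")
  cds <- Biostrings::readDNAStringSet(file.path(dir, "cds_pairs.fa"))
  n <- length(cds)
  pairs <- lapply(seq(1, n, 2), function(i)
    list(seq1 = as.character(cds[[i]]), seq2 = as.character(cds[[i + 1]])))
  names(pairs) <- sub("\\|1$", "", names(cds)[seq(1, n, 2)])
  list(counts = counts,
       samples = read_tsv(file.path(dir, "samples.tsv")),
       genome = genome,
       gff = file.path(dir, "genes.gff3"),
       pwms = read_meme(file.path(dir, "motifs.meme")),
       tf_motif = if (file.exists(tfm_path)) read_tsv(tfm_path),
       ppi = read_tsv(file.path(dir, "ppi.tsv")),
       orthologs = read_tsv(file.path(dir, "orthologs.tsv")),
       cds_pairs = pairs)
}

#' Cross-species comparison of two condition runs
#'
#' @param res_A,res_B [run_condition()] results for the same stress in two
#'   species.
#' @param map orthology map (gene_A, gene_B, orthogroup_id).
#' @return list with the `concordance_report` and per-direction breakdowns.
#' @export
compare_species <- function(res_A, res_B, map) {
  if (!identical(res_A$stress, res_B$stress))
    sg_stop("stress types differ between the two runs",
            "solgrn_input_error")
  dirs_A <- if (!is.null(res_A$network)) res_A$network else res_A$selection
  dirs_B <- if (!is.null(res_B$network)) res_B$network else res_B$selection
  if (is.null(dirs_A) || is.null(dirs_B) ||
      (is.data.frame(dirs_A) && nrow(dirs_A) == 0) ||
      (is.data.frame(dirs_B) && nrow(dirs_B) == 0)) {
    rep <- list(n_shared = 0L, n_same = 0L, n_opposite = 0L,
                concordance = NA_real_, by_direction = c(up_up = 0L,
                down_down = 0L, opposite = 0L), pairs = NULL)
    class(rep) <- "concordance_report"
    return(list(stress = res_A$stress, concordance = rep,
                non_overlapping = TRUE))
  }
  rep <- concordance(dirs_A, dirs_B, map)
  list(stress = res_A$stress, concordance = rep,
       non_overlapping = rep$n_shared == 0)
}
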