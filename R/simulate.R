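# Synthetic multi-experiment stress transcriptome generator.
#
# Emulates the statistical structure of a cross-experiment meta-analysis:
# negative-binomial counts with per-experiment batch shifts, a planted set of
# up/down stress-responsive genes, TF-driven co-expression modules, promoters
# with planted motif instances, PPI and TF-motif tables, ortholog pairs with
# a planted direction-concordance rate, and codon pairs evolved at given
# omega. Everything is deterministic given the seed, and ground truth is
# returned alongside the data.

#' Simulation configuration
#'
#' @param n_genes number of genes.
#' @param n_experiments number of independent experiments (batches).
#' @param samples_per_arm replicates per condition per experiment.
#' @param frac_up,frac_down fractions of genes planted as up/downregulated
#'   under stress (`frac_up + frac_down <= 1`).
#' @param lfc_magnitude absolute log2 fold change of every planted gene.
#' @param batch_sd standard deviation (log2 scale) of gene-specific
#'   per-experiment batch shifts.
#' @param dispersion NB dispersion alpha in Var = mu + alpha * mu^2.
#' @param promoter_len promoter length in bp.
#' @param gene_len gene-body length in bp (layout only).
#' @param planted_motifs data frame with columns `motif`, `target`
#'   (`"up"`/`"down"`), `rate` (planting probability per target-set gene).
#' @param n_background_motifs number of unplanted decoy PWMs.
#' @param motif_len length of generated PWMs.
#' @param n_tfs number of TF genes per direction (drawn from planted sets).
#' @param targets_per_tf planted targets per TF (same-direction genes).
#' @param module_sd log2-scale loading of the shared latent factor that
#'   co-expresses a TF with its targets.
#' @param ppi_edges number of PPI records (a fraction below the 0.400
#'   confidence cutoff to exercise filtering).
#' @param ortholog_pairs number of cross-species ortholog pairs.
#' @param concordance_rate probability an ortholog pair shares its planted
#'   regulation direction.
#' @param omega_grid omega values for codon-pair simulation.
#' @param n_codon_pairs codon pairs per omega value.
#' @param n_codons codons per simulated coding sequence (>= 100).
#' @param ks_target expected synonymous substitutions per synonymous site.
#' @param seed RNG seed; fixed seed gives byte-identical outputs.
#' @return validated configuration list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_experiments = 6, samples_per_arm = 3,
                       frac_up = 0.1, frac_down = 0.1, lfc_magnitude = 1.5,
                       batch_sd = 0.5, dispersion = 0.05,
                       promoter_len = 1000, gene_len = 300,
                       planted_motifs = data.frame(
                         motif = c("M_up1", "M_dn1"),
                         target = c("up", "down"),
                         rate = c(0.8, 0.8),
                         stringsAsFactors = FALSE),
                       n_background_motifs = 20, motif_len = 10,
                       n_tfs = 5, targets_per_tf = 10, module_sd = 0.4,
                       ppi_edges = 300, ortholog_pairs = 200,
                       concordance_rate = 0.9,
                       omega_grid = c(0.2, 1.0), n_codon_pairs = 50,
                       n_codons = 200, ks_target = 0.5, seed = 1) {
  cfg <- as.list(environment())
  if (n_genes < 1 || n_experiments < 1 || samples_per_arm < 1 ||
      promoter_len < 1)
    sg_stop("dimensions must be positive", "solgrn_config_error")
  if (frac_up < 0 || frac_down < 0 || frac_up + frac_down > 1)
    sg_stop("frac_up + frac_down must lie in [0,1]", "solgrn_config_error")
  if (nrow(planted_motifs) &&
      (any(planted_motifs$rate < 0) || any(planted_motifs$rate > 1)))
    sg_stop("planting rates must lie in [0,1]", "solgrn_config_error")
  if (concordance_rate < 0 || concordance_rate > 1)
    sg_stop("concordance_rate must lie in [0,1]", "solgrn_config_error")
  if (motif_len > promoter_len)
    sg_stop("motif longer than promoter", "solgrn_config_error")
  class(cfg) <- "sim_config"
  cfg
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Strongly informative random PWM: one dominant base per position.
random_pwm <- function(len, dominant_p = 0.88) {
  m <- matrix((1 - dominant_p) / 3, nrow = len, ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  dom <- sample.int(4, len, replace = TRUE)
  m[cbind(seq_len(len), dom)] <- dominant_p
  m
}

# Sample a motif instance from the PWM, conditioned on scoring at or above
# the default scan threshold (70% of max log-odds) so planted sites are
# detectable by construction; falls back to the consensus sequence.
sample_pwm_instance <- function(pwm) {
  lo <- pwm_logodds(pwm)
  thr <- 0.7 * attr(lo, "max_score")
  nt <- colnames(pwm)
  for (try in 1:50) {
    draw <- vapply(seq_len(nrow(pwm)), function(i)
      sample.int(4, 1, prob = pwm[i, ]), 0L)
    if (sum(lo[cbind(seq_len(nrow(pwm)), draw)]) >= thr)
      return(paste(nt[draw], collapse = ""))
  }
  paste(nt[apply(pwm, 1, which.max)], collapse = "")
}

#' Simulate multi-experiment NB counts with planted stress genes
#'
#' Counts are drawn NB(mean = baseline x sizefactor x 2^(batch + condition x
#' lfc + module latent), dispersion). The control arm carries no condition
#' term; batch shifts are gene-specific per experiment; TF modules share a
#' latent factor to create co-expression.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (gene x sample integer matrix), `samples`
#'   (data frame: sample_id, experiment_id, condition) and `truth`
#'   (planted sets, true LFCs, batch shifts, TF module membership, edges).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  ids <- gene_ids(n)
  n_up <- round(config$frac_up * n)
  n_dn <- round(config$frac_down * n)
  planted <- sample(ids, n_up + n_dn)
  planted_up <- sort(planted[seq_len(n_up)])
  planted_down <- sort(planted[n_up + seq_len(n_dn)])
  true_lfc <- setNames(numeric(n), ids)
  true_lfc[planted_up] <- config$lfc_magnitude
  true_lfc[planted_down] <- -config$lfc_magnitude

  # TF modules: TFs and their targets drawn from the same planted direction
  tfs <- character(0); edges <- NULL
  module_of <- setNames(rep(NA_integer_, n), ids)
  mod_id <- 0L
  for (dir in c("up", "down")) {
    pool <- if (dir == "up") planted_up else planted_down
    k <- min(config$n_tfs, max(0, floor(length(pool) / (config$targets_per_tf + 1))))
    if (k == 0) next
    picked <- sample(pool, k * (config$targets_per_tf + 1))
    for (i in seq_len(k)) {
      mod_id <- mod_id + 1L
      mem <- picked[((i - 1) * (config$targets_per_tf + 1) + 1):
                      (i * (config$targets_per_tf + 1))]
      tf <- mem[1]; tg <- mem[-1]
      tfs <- c(tfs, tf)
      edges <- rbind(edges, data.frame(tf = tf, target = tg,
                                       stringsAsFactors = FALSE))
      module_of[mem] <- mod_id
    }
  }

  E <- config$n_experiments
  exps <- sprintf("exp%d", seq_len(E))
  samples <- do.call(rbind, lapply(seq_len(E), function(e) {
    data.frame(
      sample_id = sprintf("%s_%s%d", exps[e],
                          rep(c("ctrl", "strs"), each = config$samples_per_arm),
                          rep(seq_len(config$samples_per_arm), 2)),
      experiment_id = exps[e],
      condition = rep(c("control", "stress"), each = config$samples_per_arm),
      stringsAsFactors = FALSE)
  }))
  ns <- nrow(samples)

  baseline <- 2 ^ rnorm(n, mean = 5, sd = 2)
  batch <- matrix(rnorm(n * E, 0, config$batch_sd), n, E,
                  dimnames = list(ids, exps))
  sf <- exp(rnorm(ns, 0, 0.2))
  n_mod <- mod_id
  latent <- if (n_mod > 0) matrix(rnorm(n_mod * ns), n_mod, ns) else NULL

  log2mu <- matrix(log2(baseline), n, ns, dimnames = list(ids, samples$sample_id))
  e_idx <- match(samples$experiment_id, exps)
  stress <- samples$condition == "stress"
  log2mu <- log2mu + batch[, e_idx]
  log2mu[, stress] <- log2mu[, stress] + true_lfc
  if (n_mod > 0) {
    in_mod <- which(!is.na(module_of))
    log2mu[in_mod, ] <- log2mu[in_mod, ] +
      config$module_sd * latent[module_of[in_mod], , drop = FALSE]
  }
  mu <- sweep(2 ^ log2mu, 2, sf, `*`)
  counts <- matrix(rnbinom(n * ns, mu = mu, size = 1 / config$dispersion),
                   n, ns, dimnames = dimnames(log2mu))
  storage.mode(counts) <- "integer"

  truth <- list(planted_up = planted_up, planted_down = planted_down,
                true_lfc = true_lfc, batch_shifts = batch,
                size_factors = setNames(sf, samples$sample_id),
                tfs = sort(tfs), true_edges = edges, module_of = module_of)
  list(counts = counts, samples = samples, truth = truth)
}

#' Simulate a synthetic genome with promoters carrying planted motifs
#'
#' Lays one gene model per gene on a single synthetic chromosome (random
#' strand), generates a PWM library (planted + decoy motifs), and plants
#' sampled motif instances into the promoters of the configured target sets
#' at the configured rate. Background sequence is 0-order random.
#'
#' @param truth the `truth` element from [simulate_counts()].
#' @param config a [sim_config()].
#' @return list with `genome` (named character, one chromosome), `gff`
#'   (data frame of 1-based inclusive gene features), `pwms` (PPM list),
#'   `promoters` (gene-oriented 5'->3' promoter sequences),
#'   `motif_plantings` (data frame motif/gene/pos) and `tf_motif`
#'   (TF gene <-> motif association table).
#' @export
simulate_promoters <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  ids <- names(truth$true_lfc)
  n <- length(ids)
  pm <- config$planted_motifs
  pwms <- list()
  if (nrow(pm))
    for (i in seq_len(nrow(pm)))
      pwms[[pm$motif[i]]] <- random_pwm(config$motif_len)
  for (i in seq_len(config$n_background_motifs))
    pwms[[sprintf("M_bg%02d", i)]] <- random_pwm(config$motif_len)

  promoters <- setNames(vapply(seq_len(n), function(i)
    rand_seq(config$promoter_len), ""), ids)
  plantings <- NULL
  if (nrow(pm)) {
    for (i in seq_len(nrow(pm))) {
      targets <- if (pm$target[i] == "up") truth$planted_up else truth$planted_down
      hit <- targets[runif(length(targets)) < pm$rate[i]]
      for (g in hit) {
        inst <- sample_pwm_instance(pwms[[pm$motif[i]]])
        pos <- sample.int(config$promoter_len - nchar(inst) + 1, 1)
        s <- promoters[[g]]
        substr(s, pos, pos + nchar(inst) - 1) <- inst
        promoters[[g]] <- s
        plantings <- rbind(plantings, data.frame(
          motif = pm$motif[i], gene = g, pos = pos, stringsAsFactors = FALSE))
      }
    }
  }

  strand <- sample(c("+", "-"), n, replace = TRUE)
  spacer <- 100L
  slot <- config$promoter_len + config$gene_len
  chunks <- character(2 * n)
  gff <- data.frame(gene_id = ids, chrom = "chr1", start = 0L, end = 0L,
                    strand = strand, stringsAsFactors = FALSE)
  pos <- 0L   # 0-based running coordinate
  for (i in seq_len(n)) {
    gene_seq <- rand_seq(config$gene_len)
    if (strand[i] == "+") {
      chunks[2 * i - 1] <- paste0(promoters[[i]], gene_seq)
      gff$start[i] <- pos + config$promoter_len      # 0-based gene start
    } else {
      chunks[2 * i - 1] <- paste0(
        gene_seq,
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(promoters[[i]]))))
      gff$start[i] <- pos
    }
    gff$end[i] <- gff$start[i] + config$gene_len     # 0-based half-open end
    chunks[2 * i] <- rand_seq(spacer)
    pos <- pos + slot + spacer
  }
  genome <- c(chr1 = paste(chunks, collapse = ""))

  # TF -> motif association: planted motifs mapped to TFs of their direction
  tf_motif <- NULL
  if (nrow(pm) && length(truth$tfs)) {
    dir_of <- ifelse(truth$true_lfc[truth$tfs] > 0, "up", "down")
    for (i in seq_len(nrow(pm))) {
      cand <- truth$tfs[dir_of == pm$target[i]]
      if (length(cand))
        tf_motif <- rbind(tf_motif, data.frame(
          tf_gene = utils::head(sort(cand), 2), motif_id = pm$motif[i],
          stringsAsFactors = FALSE))
    }
  }
  list(genome = genome, gff = gff, pwms = pwms, promoters = promoters,
       motif_plantings = plantings, tf_motif = tf_motif)
}

#' Simulate a scored PPI table over planted genes
#'
#' @param truth the `truth` element from [simulate_counts()].
#' @param config a [sim_config()].
#' @return data frame gene_a, gene_b, score in [0,1]; roughly 15% of records
#'   fall below the 0.400 medium-confidence cutoff.
#' @export
simulate_ppi <- function(truth, config) {
  set.seed(config$seed + 2L)
  pool <- c(truth$planted_up, truth$planted_down)
  if (length(pool) < 2 || config$ppi_edges < 1)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  k <- config$ppi_edges
  a <- sample(pool, k, replace = TRUE)
  b <- sample(pool, k, replace = TRUE)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi))
  lo <- lo[!dup]; hi <- hi[!dup]
  low <- runif(length(lo)) < 0.15
  score <- ifelse(low, runif(length(lo), 0, 0.399),
                  runif(length(lo), 0.4, 1))
  data.frame(gene_a = lo, gene_b = hi, score = round(score, 3),
             stringsAsFactors = FALSE)
}

#' Simulate cross-species ortholog pairs with planted direction concordance
#'
#' @param truth the `truth` element from [simulate_counts()].
#' @param config a [sim_config()].
#' @return list with `map` (gene_A, gene_B, orthogroup_id, pair_class) and
#'   `ortholog_truth` (per pair planted directions in both species).
#' @export
simulate_orthologs <- function(truth, config) {
  set.seed(config$seed + 3L)
  pool <- c(truth$planted_up, truth$planted_down)
  k <- min(config$ortholog_pairs, length(pool))
  if (k < 1)
    return(list(map = data.frame(gene_A = character(0),
                                 gene_B = character(0),
                                 orthogroup_id = character(0),
                                 pair_class = character(0),
                                 stringsAsFactors = FALSE),
                ortholog_truth = data.frame(gene_A = character(0),
                                            gene_B = character(0),
                                            dir_A = character(0),
                                            dir_B = character(0),
                                            stringsAsFactors = FALSE)))
  gene_A <- sample(pool, k)
  gene_B <- sprintf("spB_%s", gene_A)
  dir_A <- ifelse(truth$true_lfc[gene_A] > 0, "up", "down")
  same <- runif(k) < config$concordance_rate
  dir_B <- ifelse(same, dir_A, ifelse(dir_A == "up", "down", "up"))
  map <- data.frame(gene_A = gene_A, gene_B = gene_B,
                    orthogroup_id = sprintf("OG%04d", seq_len(k)),
                    pair_class = "ortholog", stringsAsFactors = FALSE)
  list(map = map,
       ortholog_truth = data.frame(gene_A = gene_A, gene_B = gene_B,
                                   dir_A = unname(dir_A), dir_B = unname(dir_B),
                                   stringsAsFactors = FALSE))
}

#' Simulate one aligned codon-sequence pair evolved at a given omega
#'
#' Synonymous and nonsynonymous substitutions are placed on a random coding
#' sequence at per-site event rates `ks_target` and `omega * ks_target`, so
#' that the NG86 estimator's expected (Ka, Ks) match
#' (omega x ks_target, ks_target). Stop codons are never introduced.
#'
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param ks_target synonymous substitutions per synonymous site.
#' @param n_codons codons in the sequence (>= 100).
#' @param seed RNG seed.
#' @return list with `seq1`, `seq2` (character) and `truth`
#'   (omega, ks_target, events placed).
#' @export
simulate_codon_pair <- function(omega, ks_target, n_codons = 200, seed = 1) {
  if (omega < 0 || ks_target < 0)
    sg_stop("omega and ks_target must be non-negative", "solgrn_config_error")
  if (n_codons < 100)
    sg_stop("n_codons must be >= 100", "solgrn_config_error")
  p_obs <- 3 / 4 * (1 - exp(-4 / 3 * ks_target))
  if (p_obs >= 3 / 4)
    sg_stop("requested divergence is saturated (pS >= 3/4)",
            "solgrn_saturation_error")
  set.seed(seed)
  tab <- codon_tables()
  anc <- sample(tab$sense, n_codons, replace = TRUE)
  S <- sum(tab$syn_frac[anc, ])
  N <- 3 * n_codons - S
  n_syn <- rpois(1, S * ks_target)
  n_non <- rpois(1, N * omega * ks_target)
  der <- anc
  place <- function(codons, n_events, lists, weights) {
    for (k in seq_len(n_events)) {
      w <- weights[codons]
      i <- sample.int(length(codons), 1, prob = w)
      df <- lists[[codons[i]]]
      codons[i] <- df$alt[sample.int(nrow(df), 1)]
    }
    codons
  }
  der <- place(der, n_syn, tab$syn_list, tab$syn_n)
  der <- place(der, n_non, tab$nonsyn_list, tab$nonsyn_n)
  list(seq1 = paste(anc, collapse = ""), seq2 = paste(der, collapse = ""),
       truth = list(omega = omega, ks_target = ks_target,
                    n_syn_events = n_syn, n_nonsyn_events = n_non))
}

#' Simulate a set of codon pairs over an omega grid
#'
#' @param config a [sim_config()]; uses `omega_grid`, `n_codon_pairs`,
#'   `n_codons`, `ks_target`, `seed`.
#' @return list with `pairs` (named list of seq1/seq2) and `omega_truth`
#'   (named numeric of planted omega per pair id).
#' @export
simulate_codon_pairs <- function(config) {
  pairs <- list(); omega_truth <- numeric(0)
  idx <- 0L
  for (om in config$omega_grid) {
    for (j in seq_len(config$n_codon_pairs)) {
      idx <- idx + 1L
      id <- sprintf("pair%04d_w%s", idx, gsub("\\.", "p", format(om)))
      cp <- simulate_codon_pair(om, config$ks_target, config$n_codons,
                                seed = config$seed * 100000L + idx)
      pairs[[id]] <- cp[c("seq1", "seq2")]
      omega_truth[id] <- om
    }
  }
  list(pairs = pairs, omega_truth = omega_truth)
}

#' Generate the full synthetic input bundle
#'
#' Runs every generator and assembles the complete set of pipeline inputs
#' plus ground truth.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_bundle`.
#' @export
simulate_bundle <- function(config) {
  cts <- simulate_counts(config)
  prom <- simulate_promoters(cts$truth, config)
  ppi <- simulate_ppi(cts$truth, config)
  orth <- simulate_orthologs(cts$truth, config)
  cod <- simulate_codon_pairs(config)
  truth <- c(cts$truth,
             list(motif_plantings = prom$motif_plantings,
                  promoters = prom$promoters,
                  ortholog_truth = orth$ortholog_truth,
                  omega_truth = cod$omega_truth))
  out <- list(config = config, counts = cts$counts, samples = cts$samples,
              genome = prom$genome, gff = prom$gff, pwms = prom$pwms,
              tf_motif = prom$tf_motif, ppi = ppi, orthologs = orth$map,
              cds_pairs = cod$pairs, truth = truth)
  class(out) <- "sim_bundle"
  out
}

#' Write a simulated bundle to disk in standard plain-text formats
#'
#' Writes counts.tsv, samples.tsv, genome.fa, genes.gff3 (1-based inclusive
#' coordinates), motifs.meme, ppi.tsv, tf_motif.tsv, orthologs.tsv,
#' cds_pairs.fa (interleaved pair records) and truth.json.
#'
#' @param bundle a [simulate_bundle()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cdf <- data.frame(gene_id = rownames(bundle$counts), bundle$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(cdf, file.path(dir, "counts.tsv"))
  write_tsv(bundle$samples, file.path(dir, "samples.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(bundle$genome), file.path(dir, "genome.fa"))
  gff <- bundle$gff
  lines <- c("##gff-version 3",
             sprintf("chr1\tsolgrn\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     gff$start + 1L, gff$end, gff$strand, gff$gene_id))
  writeLines(lines, file.path(dir, "genes.gff3"))
  write_meme(bundle$pwms, file.path(dir, "motifs.meme"))
  write_tsv(bundle$ppi, file.path(dir, "ppi.tsv"))
  if (!is.null(bundle$tf_motif))
    write_tsv(bundle$tf_motif, file.path(dir, "tf_motif.tsv"))
  write_tsv(bundle$orthologs, file.path(dir, "orthologs.tsv"))
  write_cds_pairs(bundle$cds_pairs, file.path(dir, "cds_pairs.fa"))
  truth <- bundle$truth
  truth$batch_shifts <- NULL   # large; regenerate from seed when needed
  # named atomic vectors serialize as JSON objects, not bare arrays
  truth <- lapply(truth, function(x)
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write aligned CDS pairs as an interleaved FASTA file
#'
#' @param pairs named list of `list(seq1=, seq2=)`.
#' @param path output FASTA path; records are named `<pair>|1`, `<pair>|2`.
#' @export
write_cds_pairs <- function(pairs, path) {
  if (!length(pairs)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(), path)
    return(invisible(path))
  }
  seqs <- unlist(lapply(names(pairs), function(id)
    setNames(c(pairs[[id]]$seq1, pairs[[id]]$seq2),
             paste0(id, "|", 1:2))))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
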