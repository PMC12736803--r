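# Shared fixtures and independent oracles. Everything is generated in code;
# expensive bundles are cached per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small fast bundle for structural tests.
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_genes = 200, n_experiments = 3, samples_per_arm = 3,
         ppi_edges = 60, ortholog_pairs = 40, n_codon_pairs = 2,
         n_codons = 110, n_tfs = 2, targets_per_tf = 6,
         n_background_motifs = 5, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# Default-scale bundle (the study conditions) shared by acceptance tests.
default_counts <- function() cached("default_counts", {
  simulate_counts(sim_config(seed = 1))
})

default_consensus <- function() cached("default_consensus", {
  b <- default_counts()
  consensus_select(b$counts, b$samples, min_occurrence = 5)
})

null_counts <- function() cached("null_counts", {
  simulate_counts(sim_config(frac_up = 0, frac_down = 0, n_tfs = 0, seed = 1))
})

# Rand index between two partitions (vectors over the same elements).
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  agree / choose(n, 2)
}

# Exact one-sided hypergeometric enrichment p-value by explicit summation:
# universe of size n_bg with k_bg hit genes; set of size n_set with a hits.
hyper_oracle <- function(a, n_set, k_bg, n_bg) {
  ks <- a:min(n_set, k_bg)
  sum(choose(k_bg, ks) * choose(n_bg - k_bg, n_set - ks)) /
    choose(n_bg, n_set)
}

# Brute-force NG86 difference counting for one codon pair: enumerates all
# substitution orders explicitly with the genetic code, skipping pathways
# through stops (falling back to all pathways if every one is blocked).
brute_codon_diffs <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  orders <- if (length(pos) == 1) matrix(pos, 1) else
    do.call(rbind, lapply(asplit(permute_all(pos), 1), identity))
  run <- function(ord, allow_stop) {
    cur <- c1; sd <- 0; nd <- 0
    for (p in ord) {
      nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stop && gc[nxt] == "*") return(NULL)
      if (gc[nxt] == gc[cur] && gc[nxt] != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null),
                apply(orders, 1, run, allow_stop = FALSE, simplify = FALSE))
  if (!length(res))
    res <- apply(orders, 1, run, allow_stop = TRUE, simplify = FALSE)
  m <- do.call(rbind, res)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

permute_all <- function(x) {
  if (length(x) == 1) return(matrix(x, 1))
  out <- NULL
  for (i in seq_along(x))
    out <- rbind(out, cbind(x[i], permute_all(x[-i])))
  out
}

# Brute-force NG86 synonymous site count of one sequence.
brute_syn_sites <- function(seq) {
  gc <- Biostrings::GENETIC_CODE
  total <- 0
  for (cd in solgrn:::split_codons(seq)) {
    for (p in 1:3) for (nt in setdiff(c("A", "C", "G", "T"),
                                      substr(cd, p, p))) {
      alt <- cd; substr(alt, p, p) <- nt
      if (gc[alt] == gc[cd] && gc[alt] != "*") total <- total + 1 / 3
    }
  }
  total
}

# Minimal hand-built network fixture for clustering/hub tests.
toy_selection <- function(genes, directions) {
  data.frame(gene = genes, direction = directions,
             occurrence = 3L, combined_lfc = ifelse(directions == "up", 1, -1),
             rank = seq_along(genes), selected = TRUE,
             stringsAsFactors = FALSE)
}
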