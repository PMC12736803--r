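# Normalized expression, batch removal, adaptive-threshold correlation
# edges, and topological-overlap module detection.

#' Log2 normalized expression
#'
#' `log2(count / sizefactor + 1)` per entry, using median-of-ratios size
#' factors.
#'
#' @param counts gene x sample integer matrix.
#' @param sf optional precomputed size factors.
#' @return gene x sample numeric matrix.
#' @export
normalize_log <- function(counts, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(counts)
  log2(sweep(counts, 2, sf, `/`) + 1)
}

#' Remove experiment batch structure from an expression matrix
#'
#' Fits, per gene, a linear model on condition and batch indicators and
#' subtracts the fitted batch terms only, so condition effects are
#' preserved (limma's removeBatchEffect behind this surface). Errors if any
#' batch lacks one of the conditions (confounded design).
#'
#' @param expr gene x sample log-scale expression matrix.
#' @param batch per-sample experiment labels.
#' @param condition per-sample condition labels (design to preserve).
#' @return corrected matrix, same dimensions.
#' @export
remove_batch <- function(expr, batch, condition) {
  batch <- factor(batch)
  condition <- factor(condition)
  if (nlevels(batch) == 1) return(expr)
  tab <- table(batch, condition)
  bad <- rownames(tab)[apply(tab, 1, function(r) any(r == 0))]
  if (length(bad))
    sg_stop(paste0("batch and condition are confounded in: ",
                   paste(bad, collapse = ", ")), "solgrn_design_error")
  design <- stats::model.matrix(~condition)
  limma::removeBatchEffect(expr, batch = batch, design = design)
}

#' Adaptive correlation threshold by experiment count
#'
#' Few-experiment conditions demand a stricter cutoff: 0.9 when the subset
#' has 3 or fewer experiments, 0.4 otherwise. Table-driven and overridable.
#'
#' @param n_experiments number of experiments in the subset.
#' @param table data frame `max_experiments`, `threshold`; rows tried in
#'   order, first with `n_experiments <= max_experiments` wins.
#' @return numeric threshold, with attribute `rule` recording the row used.
#' @export
adaptive_threshold <- function(n_experiments,
                               table = data.frame(
                                 max_experiments = c(3, Inf),
                                 threshold = c(0.9, 0.4))) {
  if (n_experiments < 1)
    sg_stop("n_experiments must be >= 1", "solgrn_config_error")
  row <- which(n_experiments <= table$max_experiments)[1]
  out <- table$threshold[row]
  attr(out, "rule") <- sprintf("n_experiments=%d -> threshold=%g",
                               n_experiments, out)
  out
}

#' Thresholded Pearson correlation edges
#'
#' Pearson correlation over all samples (after batch removal); an edge is
#' kept iff |r| >= threshold (unsigned network). Edges are canonically
#' ordered (gene_a < gene_b), self-edges excluded, zero-variance genes
#' dropped with a message.
#'
#' @param expr gene x sample expression matrix.
#' @param genes subset of genes to build edges over (default all).
#' @param threshold absolute-correlation cutoff.
#' @return data frame gene_a, gene_b, r.
#' @export
correlation_edges <- function(expr, genes = rownames(expr), threshold) {
  genes <- intersect(genes, rownames(expr))
  sub <- expr[genes, , drop = FALSE]
  v <- apply(sub, 1, var)
  if (any(v == 0)) {
    message("excluding ", sum(v == 0), " zero-variance gene(s) from edges")
    sub <- sub[v > 0, , drop = FALSE]
  }
  if (nrow(sub) < 2)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      r = numeric(0), stringsAsFactors = FALSE))
  cm <- cor(t(sub))
  cm[lower.tri(cm, diag = TRUE)] <- NA
  idx <- which(abs(cm) >= threshold, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      r = numeric(0), stringsAsFactors = FALSE))
  a <- rownames(cm)[idx[, 1]]; b <- colnames(cm)[idx[, 2]]
  lo <- pmin(a, b); hi <- pmax(a, b)
  out <- data.frame(gene_a = lo, gene_b = hi, r = cm[idx],
                    stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), ]
}

# Unsigned topological overlap matrix from an adjacency matrix.
tom_similarity <- function(adj) {
  diag(adj) <- 0
  k <- rowSums(adj)
  num <- adj %*% adj + adj
  den <- outer(k, k, pmin) + 1 - adj
  w <- num / den
  diag(w) <- 1
  w
}

# Scale-free fit R^2 of the degree distribution: log-log regression over
# 10 bins of connectivity.
scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(0)
  cuts <- cut(k, breaks = n_bins)
  dk <- tapply(k, cuts, mean)
  pk <- tapply(k, cuts, length) / length(k)
  ok <- !is.na(dk) & pk > 0
  if (sum(ok) < 3) return(0)
  fit <- lm(log10(pk[ok]) ~ log10(dk[ok]))
  summary(fit)$r.squared
}

#' Detect co-expression modules via topological overlap
#'
#' Builds an unsigned weighted network (adjacency |r|^beta with beta the
#' smallest power on the grid achieving scale-free fit R^2 >= 0.8, else the
#' argmax), computes the unsigned TOM, clusters genes by average-linkage on
#' 1 - TOM, cuts the tree statically at 0.995 x the maximum merge height,
#' discards clusters under `min_size` genes, and iteratively merges module
#' pairs whose eigengenes correlate above `merge_cor`. Module eigengenes are
#' first principal components with sign fixed to correlate positively with
#' mean module expression.
#'
#' @param expr gene x sample expression matrix (>= `min_size` genes,
#'   >= 8 samples).
#' @param power_grid candidate soft-threshold powers.
#' @param min_size minimum module size in genes (default 30).
#' @param merge_cor eigengene-correlation merge threshold (default 0.75).
#' @param cut_frac static cut height as a fraction of the maximum merge
#'   height (default 0.995).
#' @return list with `modules` (named integer vector, 0 = unassigned),
#'   `eigengenes` (samples x modules matrix), `power`, `r2`.
#' @export
detect_modules <- function(expr, power_grid = c(1:10, 12, 14, 16, 18, 20),
                           min_size = 30, merge_cor = 0.75,
                           cut_frac = 0.995) {
  if (nrow(expr) < min_size)
    sg_stop("need at least min_size genes", "solgrn_input_error")
  if (ncol(expr) < 8)
    sg_stop("need at least 8 samples", "solgrn_input_error")
  v <- apply(expr, 1, var)
  expr <- expr[v > 0, , drop = FALSE]
  r <- abs(cor(t(expr)))
  best <- NULL; best_r2 <- -Inf
  for (beta in sort(power_grid)) {
    adj <- r ^ beta
    diag(adj) <- 0
    r2 <- scale_free_r2(rowSums(adj))
    if (r2 >= 0.8) { best <- beta; best_r2 <- r2; break }
    if (r2 > best_r2) { best <- beta; best_r2 <- r2 }
  }
  if (best_r2 <= 0)
    warning("no power achieves a positive scale-free fit; using max power")
  adj <- r ^ best
  tom <- tom_similarity(adj)
  h <- hclust(as.dist(1 - tom), method = "average")
  cut_h <- cut_frac * max(h$height)
  cl <- cutree(h, h = cut_h)
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  modules <- setNames(rep(0L, nrow(expr)), rownames(expr))
  next_id <- 1L
  for (k in keep) {
    modules[cl == k] <- next_id
    next_id <- next_id + 1L
  }
  eig <- module_eigengenes(expr, modules)
  # iterative merge of the closest eligible pair
  repeat {
    ids <- colnames(eig)
    if (length(ids) < 2) break
    cm <- cor(eig)
    cm[lower.tri(cm, diag = TRUE)] <- NA
    mx <- which(cm == max(cm, na.rm = TRUE), arr.ind = TRUE)[1, , drop = FALSE]
    if (cm[mx] <= merge_cor) break
    a <- as.integer(ids[mx[1]]); b <- as.integer(ids[mx[2]])
    modules[modules == b] <- a
    eig <- module_eigengenes(expr, modules)
  }
  # renumber by decreasing size
  live <- sort(unique(modules[modules > 0]))
  sizes <- vapply(live, function(m) sum(modules == m), 0L)
  ord <- live[order(-sizes, live)]
  remap <- setNames(seq_along(ord), ord)
  modules[modules > 0] <- remap[as.character(modules[modules > 0])]
  eig <- module_eigengenes(expr, modules)
  list(modules = modules, eigengenes = eig, power = best, r2 = best_r2)
}

#' Module eigengenes (first principal components)
#'
#' @param expr gene x sample expression matrix.
#' @param modules named module assignment (0 = unassigned).
#' @return samples x modules matrix of unit-norm eigengenes, sign-fixed to
#'   correlate positively with mean module expression.
#' @export
module_eigengenes <- function(expr, modules) {
  live <- sort(unique(modules[modules > 0]))
  if (length(live) == 0)
    return(matrix(numeric(0), nrow = ncol(expr), ncol = 0,
                  dimnames = list(colnames(expr), NULL)))
  eig <- vapply(live, function(m) {
    sub <- expr[names(modules)[modules == m], , drop = FALSE]
    sub <- sub - rowMeans(sub)
    e <- svd(t(sub), nu = 1, nv = 0)$u[, 1]
    if (cor(e, colMeans(sub)) < 0) e <- -e
    e / sqrt(sum(e^2))
  }, numeric(ncol(expr)))
  colnames(eig) <- as.character(live)
  rownames(eig) <- colnames(expr)
  eig
}
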