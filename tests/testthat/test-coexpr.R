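test_that("log normalization has the pseudo-count and scaling identities", {
  counts <- matrix(c(0L, 4L, 10L, 0L, 8L, 20L), nrow = 3,
                   dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  sf <- c(1, 2)
  e <- normalize_log(counts, sf)
  expect_equal(e["a", ], c(s1 = 0, s2 = 0))
  # doubling a sample's counts and its size factor leaves it unchanged
  e2 <- normalize_log(cbind(s1 = counts[, 1], s2 = counts[, 2] * 2L),
                      c(1, 4))
  expect_equal(e, e2, ignore_attr = TRUE)
  # monotone within a sample
  expect_true(all(diff(e[, "s1"]) > 0))
})

test_that("batch removal centres batches, preserves condition effects,
           and is idempotent", {
  cfg <- small_config(seed = 3, frac_up = 0, frac_down = 0, n_tfs = 0)
  b <- simulate_counts(cfg)
  expr <- normalize_log(b$counts)
  fixed <- remove_batch(expr, b$samples$experiment_id, b$samples$condition)
  for (e in unique(b$samples$experiment_id)) {
    bm <- rowMeans(fixed[, b$samples$experiment_id == e])
    expect_lt(max(abs(bm - rowMeans(fixed))), 1e-8)
  }
  again <- remove_batch(fixed, b$samples$experiment_id, b$samples$condition)
  expect_lt(max(abs(again - fixed)), 1e-8)
  # single batch: a no-op
  one <- b$samples$experiment_id == "exp1"
  expect_identical(remove_batch(expr[, one], b$samples$experiment_id[one],
                                b$samples$condition[one]), expr[, one])
  # planted condition effect survives removal
  # balanced up/down planting so median-of-ratios normalization stays
  # centred (one-sided planting shifts the size factors by design)
  cfg2 <- small_config(seed = 5, n_genes = 300, frac_up = 0.15,
                       frac_down = 0.15, lfc_magnitude = 1.0, n_tfs = 0)
  b2 <- simulate_counts(cfg2)
  f2 <- remove_batch(normalize_log(b2$counts), b2$samples$experiment_id,
                     b2$samples$condition)
  up <- b2$truth$planted_up
  stress <- b2$samples$condition == "stress"
  diffs <- rowMeans(f2[up, stress]) - rowMeans(f2[up, !stress])
  # the +1 pseudo-count compresses fold changes at moderate expression, so
  # recovery is assessed where the transform is faithful
  keep <- rowMeans(sweep(b2$counts[up, ], 2,
                         size_factors(b2$counts), `/`)) >= 100
  se <- sd(diffs[keep]) / sqrt(sum(keep))
  expect_lt(abs(mean(diffs[keep]) - 1.0), 3 * se)
  # confounded design errors with the batch named
  samp <- b$samples
  samp$condition[samp$experiment_id == "exp2"] <- "control"
  expect_error(remove_batch(expr, samp$experiment_id, samp$condition),
               "exp2", class = "solgrn_design_error")
})

test_that("adaptive threshold follows the per-experiment-count table", {
  expect_equal(as.numeric(adaptive_threshold(3)), 0.9)
  expect_equal(as.numeric(adaptive_threshold(6)), 0.4)
  expect_equal(as.numeric(adaptive_threshold(2)), 0.9)
  # value not in the published table falls through to the default rule,
  # with a provenance note attached
  t4 <- adaptive_threshold(4)
  expect_equal(as.numeric(t4), 0.4)
  expect_match(attr(t4, "rule"), "n_experiments=4")
  expect_error(adaptive_threshold(0), class = "solgrn_config_error")
})

test_that("correlation edges respect threshold, sign and ordering", {
  set.seed(8)
  base <- matrix(rnorm(40 * 30), 40, 30,
                 dimnames = list(sprintf("g%02d", 1:40), NULL))
  base["g02", ] <- base["g01", ]                 # duplicate -> r = 1
  base["g03", ] <- -base["g01", ] + rnorm(30, sd = 0.2)  # anti-correlated
  ed <- correlation_edges(base, threshold = 0.9)
  expect_true(any(ed$gene_a == "g01" & ed$gene_b == "g02" & ed$r == 1))
  neg <- ed[ed$gene_a == "g01" & ed$gene_b == "g03", ]
  expect_identical(nrow(neg), 1L)
  expect_lt(neg$r, 0)
  expect_true(all(ed$gene_a < ed$gene_b))
  # monotone: raising the threshold never adds edges
  ed95 <- correlation_edges(base, threshold = 0.95)
  expect_true(all(paste(ed95$gene_a, ed95$gene_b) %in%
                    paste(ed$gene_a, ed$gene_b)))
  # permutation of samples leaves edges unchanged
  perm <- sample(ncol(base))
  edp <- correlation_edges(base[, perm], threshold = 0.9)
  expect_equal(ed, edp)
  # independent genes at threshold 0.9, n = 30: essentially no edges
  indep <- matrix(rnorm(60 * 30), 60, 30,
                  dimnames = list(sprintf("i%02d", 1:60), NULL))
  expect_lte(nrow(correlation_edges(indep, threshold = 0.9)), 1)
  # zero-variance gene excluded with a message
  base["g04", ] <- 5
  expect_message(correlation_edges(base, threshold = 0.9), "zero-variance")
})

test_that("TOM is symmetric, bounded and unit on the diagonal", {
  set.seed(4)
  a <- abs(cor(matrix(rnorm(20 * 15), 15)))^3
  w <- solgrn:::tom_similarity(a)
  expect_equal(w, t(w))
  expect_true(all(w >= 0 & w <= 1 + 1e-12))
  expect_true(all(diag(w) == 1))
})

two_block_expr <- function(seed = 1, n_samples = 30, block = 50, f = 0.9) {
  set.seed(seed)
  mk <- function(n) {
    z <- rnorm(n_samples)
    t(vapply(seq_len(n), function(i)
      f * z + rnorm(n_samples, sd = sqrt(1 - f^2)), numeric(n_samples)))
  }
  x <- rbind(mk(block), mk(block))
  rownames(x) <- sprintf("g%03d", seq_len(2 * block))
  x
}

test_that("module detection recovers planted blocks and rejects noise", {
  x <- two_block_expr()
  m <- detect_modules(x)
  truth <- rep(1:2, each = 50)
  expect_identical(length(unique(m$modules[m$modules > 0])), 2L)
  expect_gte(rand_index(truth, m$modules), 0.95)
  # pure noise: nothing of module size survives the cut
  set.seed(2)
  noise <- matrix(rnorm(100 * 30), 100, 30,
                  dimnames = list(sprintf("n%03d", 1:100), NULL))
  mn <- detect_modules(noise)
  expect_identical(sum(mn$modules > 0), 0L)
  expect_error(detect_modules(x[1:10, ]), class = "solgrn_input_error")
  expect_error(detect_modules(x[, 1:5]), class = "solgrn_input_error")
})

test_that("duplicated module genes are merged, not split", {
  x <- two_block_expr(seed = 3)
  dup <- x[1:50, ]
  rownames(dup) <- sprintf("d%03d", 1:50)
  m <- detect_modules(rbind(x, dup))
  # the duplicate block lands in the same module as the original
  expect_identical(unique(m$modules[rownames(dup)]),
                   unique(m$modules[rownames(x)[1:50]]))
})

test_that("eigengenes are unit-norm and aligned with module expression", {
  x <- two_block_expr(seed = 6)
  m <- detect_modules(x)
  eig <- m$eigengenes
  for (k in colnames(eig)) {
    expect_equal(sum(eig[, k]^2), 1, tolerance = 1e-9)
    memb <- names(m$modules)[m$modules == as.integer(k)]
    expect_gt(cor(eig[, k], colMeans(x[memb, ])), 0)
  }
})
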