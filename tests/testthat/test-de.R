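test_that("size factors follow the median-of-ratios formula", {
  m <- matrix(c(2, 4, 4, 8, 6, 12), nrow = 3, byrow = TRUE)
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # identical samples -> equal factors
  m2 <- cbind(a = c(5, 9, 2), b = c(5, 9, 2), c = c(5, 9, 2))
  expect_equal(unname(size_factors(m2)), rep(1, 3), tolerance = 1e-12)
  # scaling one sample by c scales its factor by c (up to shared rescale)
  m3 <- m; m3[, 2] <- m3[, 2] * 3
  sf3 <- size_factors(m3)
  expect_equal(sf3[2] / sf[2] / (sf3[1] / sf[1]), 3, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("size factors fall back when no gene is positive everywhere", {
  m <- matrix(c(0, 4, 6, 0, 8, 12), nrow = 3)
  expect_silent(sf <- size_factors(m))
  expect_true(all(sf > 0))
  expect_error(size_factors(matrix(0L, 3, 2)),
               class = "solgrn_normalization_error")
})

test_that("wald contrast handles no-signal and degenerate genes", {
  b <- cached("smallbundle", simulate_bundle(small_config()))
  sel <- b$samples$experiment_id == "exp1"
  counts <- b$counts[1:50, sel]
  # a gene with identical counts in both arms
  counts["g001", ] <- rep(c(40L, 50L, 45L), 2)
  counts["g002", ] <- 0L
  r <- nb_wald_contrast(counts, b$samples[sel, ])
  g1 <- r[r$gene == "g001", ]
  expect_lt(abs(g1$lfc), 0.25)
  expect_gt(g1$wald_p, 0.5)
  g2 <- r[r$gene == "g002", ]
  expect_identical(g2$status, "all_zero")
  expect_identical(g2$wald_p, 1)
  expect_identical(g2$lfc, 0)
  expect_error(nb_wald_contrast(counts, b$samples[sel, ], lfc_threshold = -1),
               class = "solgrn_config_error")
})

test_that("planted effects are recovered within 3 standard errors", {
  cfg <- small_config(seed = 11, lfc_magnitude = 2, n_experiments = 1,
                      samples_per_arm = 6)
  b <- simulate_counts(cfg)
  r <- nb_wald_contrast(b$counts, b$samples)
  up <- b$truth$planted_up
  ok <- r$gene %in% up & r$status == "ok" & r$se < 2
  cover <- abs(r$lfc[ok] - 2) <= 3 * r$se[ok]
  expect_gt(mean(cover), 0.95)
})

test_that("wald contrast agrees with an independent NB implementation", {
  b <- cached("smallbundle", simulate_bundle(small_config()))
  sel <- b$samples$experiment_id == "exp2"
  counts <- b$counts[, sel]
  r <- nb_wald_contrast(counts, b$samples[sel, ], lfc_threshold = 0)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      counts, S4Vectors::DataFrame(
        condition = factor(b$samples$condition[sel],
                           levels = c("control", "stress"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    dr <- DESeq2::results(dds)
  })
  both <- r$status == "ok" & !is.na(dr$log2FoldChange) & r$base_mean > 5
  expect_gt(cor(r$lfc[both], dr$log2FoldChange[both]), 0.95)
})

test_that("shrinkage pulls noisy effects and defines s-values sensibly", {
  df <- data.frame(gene = c("a", "b"), base_mean = 10,
                   lfc = c(0, 1), se = c(0.5, 1e-6),
                   wald_p = 0.5, status = "ok", stringsAsFactors = FALSE)
  # add spread so tau2 > 0
  df <- rbind(df, data.frame(gene = sprintf("x%d", 1:20), base_mean = 10,
                             lfc = rnorm(20, sd = 1), se = 0.5,
                             wald_p = 0.5, status = "ok",
                             stringsAsFactors = FALSE))
  s <- shrink_and_svalue(df)
  expect_equal(s$s_value[s$gene == "a"], 0.5, tolerance = 1e-9)
  expect_equal(s$shrunk_lfc[s$gene == "b"], 1, tolerance = 1e-4)
  expect_lt(s$s_value[s$gene == "b"], 1e-9)
  expect_true(all(s$s_value >= 0 & s$s_value <= 0.5, na.rm = TRUE))
})

test_that("empirical-Bayes shrinkage beats raw estimates in MSE", {
  set.seed(42)
  true <- rnorm(2000, 0, 1)
  se <- rep(0.5, 2000)
  obs <- true + rnorm(2000, 0, se)
  df <- data.frame(gene = sprintf("g%d", 1:2000), base_mean = 10,
                   lfc = obs, se = se, wald_p = 0.5, status = "ok",
                   stringsAsFactors = FALSE)
  s <- shrink_and_svalue(df)
  expect_false(attr(s, "degenerate"))
  expect_lt(mean((s$shrunk_lfc - true)^2), mean((obs - true)^2))
})

test_that("degenerate prior (tau2 = 0) is flagged with neutral output", {
  df <- data.frame(gene = sprintf("g%d", 1:50), base_mean = 10,
                   lfc = rnorm(50, sd = 0.01), se = 1,
                   wald_p = 0.5, status = "ok", stringsAsFactors = FALSE)
  s <- shrink_and_svalue(df)
  expect_true(attr(s, "degenerate"))
  expect_true(all(s$shrunk_lfc == 0))
  expect_true(all(s$s_value == 0.5))
})

test_that("DEG calls respect the strict s-value and inclusive LFC bounds", {
  df <- data.frame(gene = c("a", "b", "c", "d"),
                   shrunk_lfc = c(0.32, 0.32, 0.319, -0.5),
                   s_value = c(0.004, 0.005, 0.004, 0.0001),
                   stringsAsFactors = FALSE)
  d <- call_degs(df)
  expect_identical(d$gene, c("a", "d"))
  expect_identical(d$direction, c("up", "down"))
})

test_that("occurrence ranking counts comparisons and detects discordance", {
  mk <- function(genes, dir) data.frame(gene = genes, direction = dir,
                                        stringsAsFactors = FALSE)
  cmp <- c(replicate(13, mk("gA", "up"), simplify = FALSE),
           replicate(5, mk(character(0), character(0)), simplify = FALSE))
  cons <- occurrence_rank(cmp, min_occurrence = 13)
  expect_identical(cons$occurrence[cons$gene == "gA"], 13L)
  expect_true(cons$retained[cons$gene == "gA"])
  # 7 up + 6 down -> discordant
  cmp2 <- c(replicate(7, mk("gB", "up"), simplify = FALSE),
            replicate(6, mk("gB", "down"), simplify = FALSE))
  cons2 <- occurrence_rank(cmp2, min_occurrence = 5)
  expect_identical(cons2$direction[cons2$gene == "gB"], "discordant")
  expect_false(cons2$retained[cons2$gene == "gB"])
  # all-null input
  expect_identical(nrow(occurrence_rank(list(mk(character(0),
                                               character(0))), 1)), 0L)
  # monotone in min_occurrence
  mixed <- lapply(1:6, function(i)
    mk(sprintf("g%d", 1:i), rep("up", i)))
  n_ret <- vapply(1:6, function(k)
    sum(occurrence_rank(mixed, k)$retained), 0L)
  expect_true(all(diff(n_ret) <= 0))
  expect_error(occurrence_rank(mixed, 9), class = "solgrn_input_error")
})

test_that("top-set selection orders by occurrence group then |LFC|", {
  cons <- data.frame(gene = c("gA", "gB", "gC", "gD"),
                     occurrence = c(4L, 3L, 3L, 2L),
                     direction = "up", retained = TRUE,
                     stringsAsFactors = FALSE)
  degs <- data.frame(gene = c("gA", "gB", "gC", "gD"),
                     direction = "up",
                     shrunk_lfc = c(0.5, 1.0, 1.0, 3.0),
                     s_value = 1e-4, stringsAsFactors = FALSE)
  sel <- select_top(cons, degs, k_per_direction = 3)
  # occurrence beats |LFC|; ties by |LFC| then gene id; cap respected
  expect_identical(sel$gene, c("gA", "gB", "gC"))
  expect_identical(sel$rank, 1:3)
  # pool smaller than k: everything returned
  sel2 <- select_top(cons, degs, k_per_direction = 500)
  expect_identical(nrow(sel2), 4L)
  # direction mismatch between consensus and combined model excludes a gene
  degs$direction[1] <- "down"
  sel3 <- select_top(cons, degs, k_per_direction = 500)
  expect_false("gA" %in% sel3$gene)
})

test_that("selection invariants hold on a full consensus run", {
  de <- cached("small_consensus", {
    b <- cached("smallbundle", simulate_bundle(small_config()))
    consensus_select(b$counts, b$samples, min_occurrence = 2,
                     k_per_direction = 50)
  })
  sel <- de$selection
  expect_true(all(sel$gene %in% de$combined_degs$gene))
  expect_true(all(sel$occurrence >= 2))
  expect_true(all(sel$direction != "discordant"))
  for (d in unique(sel$direction)) {
    sub <- sel[sel$direction == d, ]
    expect_lte(nrow(sub), 50)
    expect_identical(sub$rank, seq_len(nrow(sub)))
    key <- order(-sub$occurrence, -abs(sub$combined_lfc), sub$gene)
    expect_identical(key, seq_len(nrow(sub)))
  }
})
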