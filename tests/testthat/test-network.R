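# Hand-built evidence layers exercising the integration, clustering,
# hub-calling and summary rules.

fixture_net <- function() {
  genes <- sprintf("g%02d", 1:12)
  dirs <- rep(c("up", "down"), each = 6)
  sel <- toy_selection(genes, dirs)
  coexpr <- data.frame(gene_a = c("g01", "g02", "g07"),
                       gene_b = c("g02", "g03", "g08"),
                       r = c(0.95, 0.9, -0.92), stringsAsFactors = FALSE)
  enr <- data.frame(motif = c("M1", "M2"), set = c("up", "down"),
                    a = 5, b = 1, c = 2, d = 50, odds_ratio = 10,
                    p = 1e-6, q = 1e-5, retained = TRUE,
                    stringsAsFactors = FALSE)
  hits <- matrix(0L, 12, 2, dimnames = list(genes, c("M1", "M2")))
  hits[c("g01", "g04", "g05"), "M1"] <- 1L   # up genes with M1 sites
  hits[c("g09", "g10"), "M2"] <- 2L          # down genes with M2 sites
  ppi <- data.frame(gene_a = c("g05", "g11", "g06", "zz9"),
                    gene_b = c("g06", "g12", "g12", "g01"),
                    score = c(0.8, 0.5, 0.399, 0.9),
                    stringsAsFactors = FALSE)
  tfm <- data.frame(motif_id = "M1", tf_gene = "g06",
                    stringsAsFactors = FALSE)
  list(sel = sel, coexpr = coexpr, enr = enr, hits = hits, ppi = ppi,
       tfm = tfm)
}

test_that("network merges layers with typed edges and hard cutoffs", {
  f <- fixture_net()
  expect_message(
    net <- build_network(f$sel, f$coexpr, f$enr, f$hits, f$tfm, f$ppi),
    "dropping 1 PPI")
  ec <- edge_counts(net)
  # additivity: per-evidence counts sum to the total
  expect_identical(unname(ec["total"]),
                   unname(ec["coexpression"] + ec["motif"] + ec["ppi"]))
  expect_identical(unname(ec["coexpression"]), 3L)
  # motif edges: 3 M1->gene + 2 M2->gene + 1 motif->TF
  expect_identical(unname(ec["motif"]), 6L)
  # ppi: scores 0.8, 0.5 kept; 0.399 below medium confidence; zz9 dropped
  expect_identical(unname(ec["ppi"]), 2L)
  expect_true(all(c("M1", "M2") %in% net$nodes$name))
  expect_true(net$nodes$is_tf[net$nodes$name == "g06"])
  expect_error(build_network(f$sel[0, ], f$coexpr, f$enr, f$hits),
               class = "solgrn_input_error")
})

test_that("duplicate same-evidence edges collapse; parallel evidence stays", {
  f <- fixture_net()
  co2 <- rbind(f$coexpr, data.frame(gene_a = "g02", gene_b = "g01",
                                    r = 0.95))        # same edge, reversed
  ppi2 <- rbind(f$ppi, data.frame(gene_a = "g01", gene_b = "g02",
                                  score = 0.9))       # parallel evidence
  net <- suppressMessages(
    build_network(f$sel, co2, f$enr, f$hits, f$tfm, ppi2))
  expect_identical(net$n_deduplicated, 1L)
  both <- net$edges[(net$edges$from == "g01" & net$edges$to == "g02") |
                      (net$edges$from == "g02" & net$edges$to == "g01"), ]
  expect_setequal(both$evidence, c("coexpression", "ppi"))
})

test_that("evidence priority: co-expression wins over motif membership", {
  # g01 has a co-expression edge into the g01-g02-g03 component AND motif
  # edges shared with g04/g05; it must stay with the co-expression cluster
  f <- fixture_net()
  net <- suppressMessages(
    build_network(f$sel, f$coexpr, f$enr, f$hits, f$tfm, f$ppi))
  net <- assign_clusters(net)
  cl <- setNames(net$nodes$cluster, net$nodes$name)
  expect_identical(cl[["g01"]], cl[["g02"]])
  expect_false(cl[["g01"]] == cl[["g04"]] && cl[["g04"]] != cl[["g02"]])
  # motif-only genes g04,g05 cluster via the shared motif node M1
  expect_identical(cl[["g04"]], cl[["M1"]])
  # PPI-only pair g11-g12 clusters at stage 3
  expect_identical(cl[["g11"]], cl[["g12"]])
  expect_gt(cl[["g11"]], 0)
})

test_that("clusters are numbered by descending gene count", {
  # three coexpression components with 4, 3 and 2 genes
  genes <- sprintf("h%02d", 1:9)
  sel <- toy_selection(genes, rep("up", 9))
  co <- data.frame(
    gene_a = c("h01", "h02", "h03", "h05", "h06", "h08"),
    gene_b = c("h02", "h03", "h04", "h06", "h07", "h09"),
    r = 0.95, stringsAsFactors = FALSE)
  enr <- data.frame(motif = character(0), set = character(0), a = integer(0),
                    b = integer(0), c = integer(0), d = integer(0),
                    odds_ratio = numeric(0), p = numeric(0), q = numeric(0),
                    retained = logical(0), stringsAsFactors = FALSE)
  hits <- matrix(0L, 9, 0, dimnames = list(genes, NULL))
  net <- assign_clusters(build_network(sel, co, enr, hits))
  cl <- setNames(net$nodes$cluster, net$nodes$name)
  expect_identical(unname(cl[c("h01", "h05", "h08")]), c(1L, 2L, 3L))
  sizes <- table(cl[cl > 0])
  expect_true(all(diff(as.integer(sizes)) <= 0))
})

test_that("cluster partition is invariant under node relabeling", {
  f <- fixture_net()
  net <- suppressMessages(
    build_network(f$sel, f$coexpr, f$enr, f$hits, f$tfm, f$ppi))
  net <- assign_clusters(net)
  # relabel genes with a stable (order-preserving) prefix change
  relab <- function(x) sub("^g", "x", x)
  f2 <- f
  f2$sel$gene <- relab(f2$sel$gene)
  f2$coexpr$gene_a <- relab(f2$coexpr$gene_a)
  f2$coexpr$gene_b <- relab(f2$coexpr$gene_b)
  rownames(f2$hits) <- relab(rownames(f2$hits))
  f2$ppi$gene_a <- relab(f2$ppi$gene_a)
  f2$ppi$gene_b <- relab(f2$ppi$gene_b)
  f2$tfm$tf_gene <- relab(f2$tfm$tf_gene)
  net2 <- suppressMessages(
    build_network(f2$sel, f2$coexpr, f2$enr, f2$hits, f2$tfm, f2$ppi))
  net2 <- assign_clusters(net2)
  cl1 <- setNames(net$nodes$cluster, net$nodes$name)
  cl2 <- setNames(net2$nodes$cluster, relab(net2$nodes$name))
  genes <- grep("^g", names(cl1), value = TRUE)
  expect_identical(cl1[genes], cl2[sub("^g", "x", genes)] |>
                     setNames(genes))
})

test_that("hub calling flips exactly at degree 41 and is TF-only", {
  hub_tf <- "t01"; near_tf <- "t02"; big_gene <- "b01"
  spokes41 <- sprintf("s%02d", 1:41)
  spokes40 <- sprintf("r%02d", 1:40)
  spokes50 <- sprintf("q%02d", 1:50)
  genes <- c(hub_tf, near_tf, big_gene, spokes41, spokes40, spokes50)
  sel <- toy_selection(genes, rep("up", length(genes)))
  co <- rbind(
    data.frame(gene_a = pmin(hub_tf, spokes41),
               gene_b = pmax(hub_tf, spokes41), r = 0.95),
    data.frame(gene_a = pmin(near_tf, spokes40),
               gene_b = pmax(near_tf, spokes40), r = 0.95),
    data.frame(gene_a = pmin(big_gene, spokes50),
               gene_b = pmax(big_gene, spokes50), r = 0.95))
  enr <- data.frame(motif = character(0), set = character(0), a = integer(0),
                    b = integer(0), c = integer(0), d = integer(0),
                    odds_ratio = numeric(0), p = numeric(0), q = numeric(0),
                    retained = logical(0), stringsAsFactors = FALSE)
  hits <- matrix(0L, length(genes), 0, dimnames = list(genes, NULL))
  tfm <- data.frame(motif_id = "M1", tf_gene = c(hub_tf, near_tf),
                    stringsAsFactors = FALSE)
  net <- assign_clusters(build_network(sel, co, enr, hits, tfm))
  h <- call_hubs(net)
  expect_identical(h$hubs$node, hub_tf)         # degree 41 -> hub
  expect_false(near_tf %in% h$hubs$node)        # degree 40 -> not a hub
  expect_identical(h$high_degree_genes$node, big_gene)  # not a TF
  # monotone in the cutoff
  h50 <- call_hubs(net, min_degree = 50)
  expect_true(all(h50$hubs$node %in% h$hubs$node))
})

test_that("cluster summaries count regulation and find member TFs", {
  f <- fixture_net()
  net <- assign_clusters(suppressMessages(
    build_network(f$sel, f$coexpr, f$enr, f$hits, f$tfm, f$ppi)))
  s <- summarize_clusters(net)
  expect_identical(s$n_genes, s$n_up + s$n_down)
  expect_identical(s$cluster, seq_len(nrow(s)))
  mixed <- s[s$n_up > 0 & s$n_down > 0, ]
  if (nrow(mixed)) expect_true(all(mixed$regulation == "mixed"))
  up_only <- s[s$n_down == 0, ]
  if (nrow(up_only)) expect_true(all(up_only$regulation == "up"))
  tf_row <- s[grepl("g06", s$tfs), ]
  expect_identical(nrow(tf_row), 1L)
})

test_that("network export writes SIF and attribute tables", {
  f <- fixture_net()
  net <- assign_clusters(suppressMessages(
    build_network(f$sel, f$coexpr, f$enr, f$hits, f$tfm, f$ppi)))
  d <- withr::local_tempdir()
  write_network(net, file.path(d, "net"))
  sif <- readLines(file.path(d, "net.sif"))
  expect_identical(length(sif), nrow(net$edges))
  expect_true(all(vapply(strsplit(sif, "\t"), length, 0L) == 3))
  nd <- read_tsv(file.path(d, "net_nodes.tsv"))
  expect_setequal(nd$name, net$nodes$name)
})
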