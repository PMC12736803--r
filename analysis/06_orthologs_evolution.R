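#!/usr/bin/env Rscript
# Stage 6: cross-species concordance, stress orthogroups, and Ka/Ks.
#
# Uses the species-A ortholog map (species-B partners carry planted
# directions with 90% concordance) to measure direction concordance of
# network genes; flags orthogroups containing at least one stress DEG;
# estimates NG86 Ka/Ks for the simulated codon pairs, applies the length
# (>= 300 nt) and Ks band filters, and contrasts the omega distributions of
# the planted rate classes with rank-sum tests.

suppressPackageStartupMessages(library(solgrn))

dir.create("results/evolution", recursive = TRUE, showWarnings = FALSE)

bundleA <- read_bundle("results/bundles/speciesA")
selA <- read_tsv("results/de/speciesA_selection.tsv")
truth <- jsonlite::read_json("results/bundles/speciesA/truth.json",
                             simplifyVector = TRUE)

## direction concordance of selected genes vs planted species-B directions
dirA <- setNames(selA$direction, selA$gene)
dirB <- setNames(truth$ortholog_truth$dir_B, truth$ortholog_truth$gene_B)
cc <- concordance(dirA, dirB, bundleA$orthologs)
message(sprintf(
  "concordance: %d shared ortholog pairs, %d same direction (%.3f)",
  cc$n_shared, cc$n_same, cc$concordance))
jsonlite::write_json(cc[c("n_shared", "n_same", "n_opposite",
                          "concordance")],
                     "results/evolution/concordance.json",
                     auto_unbox = TRUE, digits = NA)

## stress-associated orthogroups (at least one DEG member in any species)
degA <- selA$gene
flags <- flag_stress_orthogroups(bundleA$orthologs,
                                 list(A = degA, B = character(0)),
                                 stress = "stress")
message(sprintf("stress orthogroups: %d of %d flagged",
                sum(flags$flagged), nrow(flags)))
write_tsv(flags, "results/evolution/stress_orthogroups.tsv")

## NG86 Ka/Ks on the simulated codon pairs
kaks <- kaks_table(bundleA$cds_pairs)
kaks$planted_omega <- unlist(truth$omega_truth)[kaks$pair]
write_tsv(kaks, "results/evolution/kaks.tsv")
ok <- kaks$filters_passed
groups <- split(kaks$omega[ok], kaks$planted_omega[ok])
names(groups) <- sprintf("omega_%s", names(groups))
cmp <- compare_distributions(groups)
print(cmp$summary)
print(cmp$tests)
write_tsv(cmp$summary, "results/evolution/omega_summary.tsv")
write_tsv(cmp$tests, "results/evolution/ranksum.tsv")
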