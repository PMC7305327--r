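#!/usr/bin/env Rscript
# Stage 6: overlapping Cascade/Cas9 target-site selection.
#
# Builds an engineered genome in which one gene carries overlapping
# Cascade (32 nt, 5'-CC) and SpCas9 (20 nt, 3'-NGG) protospacers in its
# design window, and a second gene's promoter carries one decoy for each
# guide. The overlap search must include this engineered pair (shifted
# windows sharing sequence with the planted copies may also qualify) and
# returns nothing when the decoys are absent.

suppressMessages(library(crisprIF))

set.seed(20260930L)
genome <- generate_genome(1, 24000, gc = 0.41)
ds <- new_dataset(genome)
ds <- plant_gene(ds, "seq1", 6000L, "+", "geneA")
ds <- plant_gene(ds, "seq1", 18000L, "+", "geneB")

casc_sp <- paste0(sample(c("A", "C", "G", "T"), 32, TRUE), collapse = "")
ds <- plant_on_target(ds, "geneA", casc_sp, -150L)
# overlap: a 20-mer protospacer whose 3' NGG PAM we write 20 bp into the
# Cascade site
cas9_start <- ds$truth$start[1] + 20L
ds$genome[["seq1"]] <- crisprIF:::.replace_window(ds$genome[["seq1"]],
                                                  cas9_start + 20L, "AGG")
cas9_sp <- substr(ds$genome[["seq1"]], cas9_start + 1L, cas9_start + 20L)
ds <- plant_decoy(ds, casc_sp, c(1L, 9L), near_gene = "geneB",
                  tss_offset = -800L)
ds <- plant_decoy(ds, cas9_sp, c(2L, 10L), rule = spcas9_rule(),
                  near_gene = "geneB", tss_offset = 700L)

ov <- find_overlap_sites(ds$genome, ds$tss)
cat("Overlap regions with cross-promoter off-targets: ", nrow(ov), "\n",
    sep = "")
print(ov[, c("gene_id", "region_start", "region_end",
             "cascade_offtarget_gene", "cas9_offtarget_gene")],
      row.names = FALSE)
stopifnot(any(ov$cascade_spacer == casc_sp & ov$cas9_spacer == cas9_sp))

dir.create("results/overlap", recursive = TRUE, showWarnings = FALSE)
utils::write.table(ov, "results/overlap/overlap_sites.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("outputs in results/overlap/\n")
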