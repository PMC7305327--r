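test_that("genome generation is seed-reproducible with controlled GC", {
  g1 <- generate_genome(2, 1000, seed = 7)
  g2 <- generate_genome(2, 1000, seed = 7)
  expect_identical(g1, g2)
  g <- generate_genome(1, 10000, gc = 0.5, seed = 8)
  gc_frac <- mean(strsplit(g[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_frac - 0.5), 0.03)
  expect_error(generate_genome(1, 0), "length")
  expect_error(generate_genome(1, 100, gc = 1.2), "gc")
})

test_that("gene planting validates bounds, strand and uniqueness", {
  ds <- new_dataset(generate_genome(1, 1000, seed = 1))
  ds <- plant_gene(ds, "seq1", 500L, "+", "g1")
  expect_identical(ds$tss$gene_id, "g1")
  expect_error(plant_gene(ds, "seq1", 500L, "+", "g1"), "duplicate")
  expect_error(plant_gene(ds, "seq1", 2000L, "+", "g2"), "bounds")
  expect_error(plant_gene(ds, "seqX", 10L, "+", "g3"), "unknown")
})

test_that("planted on-targets round-trip through guide design on both strands", {
  for (strand in c("+", "-")) {
    set.seed(21)
    ds <- new_dataset(generate_genome(1, 4000, seed = 21))
    ds <- plant_gene(ds, "seq1", 2000L, strand, "g")
    sp <- random_spacer(32)
    ds <- plant_on_target(ds, "g", sp, -150L)
    cands <- extract_candidates(ds$genome, ds$tss)
    found <- cands[cands$spacer == sp, ]
    expect_identical(nrow(found), 1L)
    expect_identical(found$window_class, "optimal")
    expect_identical(found$start, ds$truth$start[1])
  }
})

test_that("two plants at the same locus collide", {
  set.seed(22)
  ds <- new_dataset(generate_genome(1, 4000, seed = 22))
  ds <- plant_gene(ds, "seq1", 2000L, "+", "g")
  ds <- plant_on_target(ds, "g", random_spacer(32), -150L)
  expect_error(plant_on_target(ds, "g", random_spacer(32), -150L),
               "collision")
})

test_that("decoy truth marks detectability under the rule's cap and mask", {
  set.seed(23)
  ds <- new_dataset(generate_genome(1, 6000, seed = 23))
  sp <- random_spacer(32)
  ds <- plant_decoy(ds, sp, c(6L, 12L, 24L))   # masked only
  ds <- plant_decoy(ds, sp, 1:5)               # five non-masked
  expect_identical(ds$truth$effective, c(0L, 5L))
  expect_identical(ds$truth$detectable, c(TRUE, FALSE))
  hits <- enumerate_offtargets(sp, ds$genome)
  expect_true(ds$truth$start[1] %in% hits$start)
  expect_false(ds$truth$start[2] %in% hits$start)
})

test_that("decoys planted beyond 2 kb of the TSS are filtered, nearer ones kept", {
  set.seed(24)
  ds <- new_dataset(generate_genome(1, 12000, seed = 24))
  ds <- plant_gene(ds, "seq1", 6000L, "+", "g")
  sp <- random_spacer(32)
  ds <- plant_decoy(ds, sp, c(1L, 9L), near_gene = "g", tss_offset = 1500L)
  ds <- plant_decoy(ds, sp, c(2L, 10L), near_gene = "g", tss_offset = 2500L)
  ds <- finalize_truth(ds)
  expect_identical(ds$truth$promoter_retained, c(TRUE, FALSE))
  truth <- evaluate_truth(ds)
  expect_true(all(truth$agrees))
})

test_that("dataset files round-trip and re-scan reproduces the truth", {
  ds <- simulate_dataset(seed = 99, n_genes = 2)
  dir <- tempfile()
  paths <- write_truth(ds, dir)
  expect_true(all(file.exists(paths)))
  genome <- read_fasta(paths[["fasta"]])
  expect_identical(genome, ds$genome)
  tss <- read_tss(paths[["bed"]], "bed", genome)
  expect_identical(tss, ds$tss)
  truth <- utils::read.delim(paths[["truth"]],
                             colClasses = c(mismatch_positions = "character"))
  expect_identical(nrow(truth), nrow(ds$truth))
  reloaded <- new_dataset(genome)
  reloaded$tss <- tss
  reloaded$truth <- ds$truth
  expect_true(all(evaluate_truth(reloaded)$agrees))
})
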