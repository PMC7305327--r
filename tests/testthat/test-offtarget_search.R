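test_that("both the Cascade and SpCas9 rules are expressible as rule sets", {
  rc <- cascade_rule()
  expect_identical(rc$pam, "CC")
  expect_identical(rc$pam_side, "5prime")
  expect_identical(rc$mask$masked, sort(c(6L, 12L, 18L, 24:32)))
  rk <- spcas9_rule()
  expect_identical(rk$pam, "NGG")
  expect_identical(rk$pam_side, "3prime")
  expect_identical(rk$mask$masked, integer(0))
  expect_error(rule_set("x", 32, "CC", "5prime", max_mismatches = -1), ">= 0")
  expect_error(rule_set("x", 32, "CJ"), "IUPAC")
})

test_that("a uniquely planted query is found exactly once with effective 0", {
  set.seed(31)
  ds <- new_dataset(generate_genome(1, 5000, seed = 31))
  sp <- random_spacer(32)
  ds <- plant_decoy(ds, sp, integer(0))
  hits <- enumerate_offtargets(sp, ds$genome)
  on <- hits[hits$is_exact, ]
  expect_identical(nrow(on), 1L)
  expect_identical(on$effective, 0L)
  expect_identical(on$start, ds$truth$start[1])
})

test_that("masked-position-only decoys score 0; 5 seed mismatches are rejected", {
  set.seed(32)
  ds <- new_dataset(generate_genome(1, 8000, seed = 32))
  sp <- random_spacer(32)
  ds <- plant_decoy(ds, sp, c(6L, 12L, 24L, 25L, 26L))
  ds <- plant_decoy(ds, sp, 1:5)
  hits <- enumerate_offtargets(sp, ds$genome)
  masked_only <- hits[hits$start == ds$truth$start[1], ]
  expect_identical(masked_only$effective, 0L)
  expect_identical(masked_only$n_mismatches, 5L)
  expect_false(ds$truth$start[2] %in% hits$start)
  expect_error(enumerate_offtargets(strrep("N", 32), ds$genome), "spacer")
  expect_error(enumerate_offtargets(random_spacer(32), character(0)), "empty genome")
})

test_that("enumerator agrees with the brute-force oracle on random genomes", {
  set.seed(33)
  for (i in 1:20) {
    genome <- generate_genome(1, 3000)
    ds <- new_dataset(genome)
    sp <- random_spacer(32)
    # plant a detectable and an undetectable decoy in half the genomes
    if (i %% 2 == 0) {
      ds <- plant_decoy(ds, sp, c(2L, 9L, 15L))
      ds <- plant_decoy(ds, sp, c(1:4, 7L, 9L))
    }
    for (rule in list(cascade_rule(), spcas9_rule(spacer_len = 32L))) {
      fast <- enumerate_offtargets(sp, ds$genome, rule)
      slow <- brute_force_oracle(sp, ds$genome, rule)
      expect_identical(fast, slow)
    }
  }
})

test_that("hit sets are strand-symmetric under genome reverse complement", {
  set.seed(34)
  ds <- new_dataset(generate_genome(1, 4000, seed = 34))
  sp <- random_spacer(32)
  ds <- plant_decoy(ds, sp, c(3L, 10L))
  hits <- enumerate_offtargets(sp, ds$genome)
  rc_hits <- enumerate_offtargets(sp, c(seq1 = revcomp(ds$genome[["seq1"]])))
  len <- nchar(ds$genome[["seq1"]])
  mapped <- data.frame(strand = ifelse(rc_hits$strand == "+", "-", "+"),
                       start = len - rc_hits$end, stringsAsFactors = FALSE)
  ord <- order(mapped$start, mapped$strand)
  expect_identical(hits$start, mapped$start[ord])
  expect_identical(hits$strand, mapped$strand[ord])
  expect_identical(hits$site_seq, rc_hits$site_seq[ord])
})

test_that("raising the cap only adds hits; shrinking the mask only removes them", {
  set.seed(35)
  ds <- new_dataset(generate_genome(1, 5000, seed = 35))
  sp <- random_spacer(32)
  ds <- plant_decoy(ds, sp, c(1L, 9L))
  ds <- plant_decoy(ds, sp, c(6L, 12L, 18L, 1L, 9L, 15L))
  key <- function(h) paste(h$seq_name, h$strand, h$start)
  h4 <- enumerate_offtargets(sp, ds$genome, cascade_rule(max_mismatches = 4))
  h6 <- enumerate_offtargets(sp, ds$genome, cascade_rule(max_mismatches = 6))
  expect_true(all(key(h4) %in% key(h6)))
  small_mask <- position_mask(32, masked = c(6L, 12L))
  hs <- enumerate_offtargets(sp, ds$genome, cascade_rule(mask = small_mask))
  expect_true(all(key(hs) %in% key(h4)))
  expect_identical(anyDuplicated(key(h6)), 0L)
})

test_that("promoter filter keeps <= 2 kb sites, annotates distance, breaks ties", {
  genome <- c(chrT = strrep("A", 20000))
  tss <- data.frame(gene_id = c("gB", "gA"), seq_name = "chrT",
                    tss = c(6000L, 10000L), strand = "+",
                    stringsAsFactors = FALSE)
  prom <- build_promoters(tss, genome)
  hit <- function(start) data.frame(
    seq_name = "chrT", strand = "+", start = start, end = start + 32L,
    site_seq = "x", site_display = "x", pam_observed = "CC",
    mismatch_positions = "", n_mismatches = 0L, effective = 0L,
    is_exact = TRUE, stringsAsFactors = FALSE)
  near <- promoter_filter(hit(10000L + 1500L), prom)
  expect_identical(nrow(near), 1L)
  expect_identical(near$tss_distance, 1500L)
  expect_identical(near$nearest_gene, "gA")
  far <- promoter_filter(hit(10000L + 2500L), prom)
  expect_identical(nrow(far), 0L)
  # equidistant between gB (6000) and gA (10000): lexicographically smaller
  mid <- promoter_filter(hit(8000L), prom)
  expect_identical(mid$nearest_gene, "gA")  # equidistant 2000 from both
  expect_identical(abs(mid$tss_distance), 2000L)
})

test_that("hit reports are deterministic TSV/BED with 0-based intervals", {
  set.seed(36)
  ds <- new_dataset(generate_genome(1, 4000, seed = 36))
  sp <- random_spacer(32)
  ds <- plant_decoy(ds, sp, c(2L, 9L))
  ds <- plant_decoy(ds, sp, integer(0))
  hits <- enumerate_offtargets(sp, ds$genome)
  expect_gte(nrow(hits), 2L)
  t1 <- tempfile(); b1 <- tempfile(); t2 <- tempfile()
  write_hits(hits, t1, b1)
  write_hits(hits, t2)
  expect_identical(readLines(t1), readLines(t2))
  tsv <- utils::read.delim(t1)
  expect_identical(nrow(tsv), nrow(hits))
  bed <- utils::read.delim(b1, header = FALSE)
  expect_identical(as.integer(bed$V3 - bed$V2), rep(32L, nrow(bed)))
  expect_identical(as.integer(bed$V2), hits$start)
  # mismatched bases are rendered lowercase
  mm_row <- which(hits$n_mismatches > 0)[1]
  expect_identical(toupper(hits$site_display[mm_row]), hits$site_seq[mm_row])
  expect_true(grepl("[acgt]", hits$site_display[mm_row]))
})

test_that("overlap-site search needs overlap plus cross-promoter off-targets", {
  # engineered genome: geneA with overlapping Cascade/Cas9 protospacers in
  # its design window, geneB promoter carrying a decoy for each guide
  set.seed(37)
  genome <- generate_genome(1, 24000, seed = 37)
  ds <- new_dataset(genome)
  ds <- plant_gene(ds, "seq1", 6000L, "+", "geneA")
  ds <- plant_gene(ds, "seq1", 18000L, "+", "geneB")
  casc_sp <- random_spacer(32)
  ds <- plant_on_target(ds, "geneA", casc_sp, -150L)
  # the Cas9 protospacer: the 20-mer ending 3 nt into the Cascade site,
  # planted as part of the genome already? instead plant an overlapping
  # NGG site explicitly and use its sequence as the gRNA
  cas9_start <- ds$truth$start[1] + 20L
  ds$genome[["seq1"]] <- crisprIF:::.replace_window(
    ds$genome[["seq1"]], cas9_start + 20L, "AGG")  # 3' NGG PAM
  cas9_sp <- substr(ds$genome[["seq1"]], cas9_start + 1L, cas9_start + 20L)
  # cross-promoter decoys near geneB
  ds <- plant_decoy(ds, casc_sp, c(1L, 9L), near_gene = "geneB",
                    tss_offset = -800L)
  ds <- plant_decoy(ds, cas9_sp, c(2L, 10L), rule = spcas9_rule(),
                    near_gene = "geneB", tss_offset = 700L)
  ov <- find_overlap_sites(ds$genome, ds$tss)
  expect_gte(nrow(ov), 1L)
  hit <- ov[ov$cascade_spacer == casc_sp & ov$cas9_spacer == cas9_sp, ]
  expect_identical(hit$gene_id, "geneA")
  expect_identical(hit$cascade_offtarget_gene, "geneB")
  expect_identical(hit$cas9_offtarget_gene, "geneB")

  # without the decoys there is no qualifying region
  ds0 <- new_dataset(genome)
  ds0 <- plant_gene(ds0, "seq1", 6000L, "+", "geneA")
  ds0 <- plant_gene(ds0, "seq1", 18000L, "+", "geneB")
  ds0 <- plant_on_target(ds0, "geneA", casc_sp, -150L)
  expect_identical(nrow(find_overlap_sites(ds0$genome, ds0$tss)), 0L)
})
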