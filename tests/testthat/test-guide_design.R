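test_that("scan_pam_sites finds CC-adjacent windows on both strands", {
  hits <- scan_pam_sites("AACCGTGTGT", 6)
  expect_identical(hits$strand, "+")
  expect_identical(hits$start, 4L)
  expect_identical(hits$spacer, "GTGTGT")

  # the same site seen from the reverse complement
  rc <- scan_pam_sites("ACACACGGTT", 6)
  expect_identical(rc$strand, "-")
  expect_identical(rc$start, 0L)
  expect_identical(rc$spacer, "GTGTGT")

  expect_identical(nrow(scan_pam_sites("AAAAAA", 3)), 0L)
  expect_error(scan_pam_sites("ACGT", 0), "spacer_len")
  expect_error(scan_pam_sites("", 6), "empty")
})

test_that("windows containing N are excluded by default", {
  hits <- scan_pam_sites("AACCGTNTGT", 6)
  expect_identical(nrow(hits), 0L)
  hits_n <- scan_pam_sites("AACCGTNTGT", 6, exclude_n = FALSE)
  expect_identical(hits_n$spacer, "GTNTGT")
})

test_that("candidate sets are strand-symmetric under reverse complement", {
  set.seed(42)
  for (rep in 1:25) {
    seq <- paste0(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
    fwd <- scan_pam_sites(seq, 32)
    rev <- scan_pam_sites(revcomp(seq), 32)
    # map rev coordinates back onto the forward axis of seq
    mapped <- data.frame(strand = ifelse(rev$strand == "+", "-", "+"),
                         start = nchar(seq) - rev$end,
                         spacer = rev$spacer, stringsAsFactors = FALSE)
    mapped <- mapped[order(mapped$start, mapped$strand), ]
    expect_identical(fwd$start, mapped$start)
    expect_identical(fwd$strand, mapped$strand)
    expect_identical(fwd$spacer, mapped$spacer)
  }
})

test_that("TSS window classification follows the upstream design windows", {
  expect_identical(classify_tss_window(-150L), "optimal")
  expect_identical(classify_tss_window(-100L), "optimal")
  expect_identical(classify_tss_window(-200L), "optimal")
  expect_identical(classify_tss_window(-500L), "in_range")
  expect_identical(classify_tss_window(-201L), "in_range")
  expect_identical(classify_tss_window(-50L), "out_of_range")
  expect_identical(classify_tss_window(50L), "out_of_range")
})

test_that("csy3_copies is ceil(L/6), non-decreasing, and rejects L < 6", {
  expect_identical(csy3_copies(32), 6L)
  expect_identical(csy3_copies(14), 3L)
  expect_identical(csy3_copies(50), 9L)
  expect_identical(csy3_copies(6), 1L)
  lens <- 6:120
  expect_identical(csy3_copies(lens), as.integer(ceiling(lens / 6)))
  expect_true(all(diff(csy3_copies(lens)) >= 0))
  expect_error(csy3_copies(5), "minimal length")
})

test_that("planted candidates are recovered with correct offsets on both gene strands", {
  set.seed(3)
  for (gene_strand in c("+", "-")) {
    ds <- new_dataset(generate_genome(1, 4000, seed = 100 + (gene_strand == "-")))
    ds <- plant_gene(ds, "seq1", 2000L, gene_strand, "g")
    sp <- random_spacer(32)
    ds <- plant_on_target(ds, "g", sp, -150L)
    cands <- extract_candidates(ds$genome, ds$tss)
    planted <- cands[cands$spacer == sp, ]
    expect_identical(nrow(planted), 1L)
    expect_identical(planted$tss_offset, -150L)
    expect_identical(planted$window_class, "optimal")
    expect_identical(planted$strand, gene_strand)
  }
})

test_that("sites outside the design range are excluded", {
  ds <- new_dataset(generate_genome(1, 4000, seed = 5))
  ds <- plant_gene(ds, "seq1", 2000L, "+", "g")
  sp_in <- random_spacer(32)
  sp_down <- random_spacer(32)
  ds <- plant_on_target(ds, "g", sp_in, -400L)
  ds <- plant_on_target(ds, "g", sp_down, 50L)  # downstream of the TSS
  cands <- extract_candidates(ds$genome, ds$tss)
  expect_identical(cands$window_class[cands$spacer == sp_in], "in_range")
  expect_false(sp_down %in% cands$spacer)
})

test_that("extend_spacer preserves the PAM-proximal 32 nt and round-trips", {
  set.seed(9)
  ds <- new_dataset(generate_genome(1, 4000, seed = 9))
  ds <- plant_gene(ds, "seq1", 2000L, "-", "g")
  sp <- random_spacer(32)
  ds <- plant_on_target(ds, "g", sp, -150L)
  cands <- extract_candidates(ds$genome, ds$tss)
  cand <- cands[cands$spacer == sp, ]
  ext <- extend_spacer(cand, ds$genome, 56L)
  expect_identical(nchar(ext$spacer), 56L)
  expect_identical(substr(ext$spacer, 1, 32), sp)
  expect_identical(ext$csy3_copies, 10L)
  expect_identical(ext$tss_offset, cand$tss_offset)
  # truncation back to 32 recovers the original candidate
  back <- extend_spacer(ext, ds$genome, 32L)
  expect_identical(back, cand)
  # identity and invalid lengths
  expect_identical(extend_spacer(cand, ds$genome, 32L), cand)
  expect_error(extend_spacer(cand, ds$genome, 40L), "32 \\+ 6k")
  expect_warning(extend_spacer(cand, ds$genome, 62L), "untested")
})

test_that("pair selection scores 50-75 bp spacing as optimal and sorts by it", {
  cands <- data.frame(
    gene_id = "g", seq_name = "s", strand = "+",
    start = c(100L, 160L, 127L), end = c(132L, 192L, 159L),
    pam = "CC", spacer = c("x", "y", "z"),
    tss_offset = c(-200L, -140L, -173L),
    window_class = "optimal", csy3_copies = 6L, stringsAsFactors = FALSE)
  pairs <- select_pairs(cands)
  expect_identical(nrow(pairs), 3L)
  expect_identical(pairs$spacing_class[1], "optimal")
  expect_identical(pairs$spacing[1], 60L)   # |100 - 160|
  # 27 bp (as for a real dual-crRNA design) is acceptable, not optimal
  expect_true(all(pairs$spacing_class[pairs$spacing == 27L] == "acceptable"))
  expect_identical(nrow(select_pairs(cands[1, , drop = FALSE])), 0L)
})

test_that("ranking is stable and prefers the optimal window", {
  cands <- data.frame(
    gene_id = "g", seq_name = "s", strand = "+",
    start = c(10L, 20L, 30L, 40L), end = c(42L, 52L, 62L, 72L),
    pam = "CC", spacer = letters[1:4],
    tss_offset = c(-400L, -150L, -150L, -120L),
    window_class = c("in_range", "optimal", "optimal", "optimal"),
    csy3_copies = 6L, stringsAsFactors = FALSE)
  ranked <- rank_candidates(cands)
  expect_identical(ranked$spacer, c("b", "c", "d", "a"))
  expect_identical(nrow(rank_candidates(cands[0, ])), 0L)
})
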