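test_that("default mask is {6,12,18,24-32} with seed {1-5,7,8} for 32-nt spacers", {
  mask <- position_mask(32)
  expect_identical(mask$masked, sort(c(6L, 12L, 18L, 24:32)))
  expect_identical(mask$seed, c(1:5, 7:8))
  expect_error(position_mask(32, masked = 33), "outside")
})

test_that("effective count ignores masked positions and counts N as mismatch", {
  ref <- strrep("ACGT", 8)  # 32 nt
  expect_identical(effective_mismatches(ref, ref)$effective, 0L)

  only_masked <- variant_at(ref, c(6, 12, 24, 30))
  r <- effective_mismatches(ref, only_masked)
  expect_identical(r$effective, 0L)
  expect_identical(r$positions, c(6L, 12L, 24L, 30L))

  unmasked <- variant_at(ref, c(1, 7))
  expect_identical(effective_mismatches(ref, unmasked)$effective, 2L)

  with_n <- ref; substr(with_n, 3, 3) <- "N"
  expect_identical(effective_mismatches(ref, with_n)$effective, 1L)
  expect_error(effective_mismatches(ref, substr(ref, 1, 30)), "lengths differ")
})

test_that("masked positions never change the effective count (property)", {
  set.seed(101)
  mask <- position_mask(32)
  for (i in 1:50) {
    ref <- random_spacer(32)
    site <- variant_at(ref, sample(32, sample(0:6, 1)))
    base <- effective_mismatches(ref, site, mask)$effective
    for (p in mask$masked) {
      site_p <- site
      substr(site_p, p, p) <- chartr("ACGT", "TGCA", substr(ref, p, p))
      expect_identical(effective_mismatches(ref, site_p, mask)$effective, base)
    }
  }
})

test_that("effective count <= Hamming distance, equal iff no masked mismatch", {
  set.seed(202)
  mask <- position_mask(32)
  for (i in 1:50) {
    ref <- random_spacer(32)
    pos <- sample(32, sample(1:8, 1))
    site <- variant_at(ref, pos)
    r <- effective_mismatches(ref, site, mask)
    expect_lte(r$effective, length(pos))
    expect_identical(r$effective == length(pos),
                     !any(pos %in% mask$masked))
  }
})

test_that("single-mismatch panel has one complement variant per position", {
  sp <- random_spacer(32)
  panel <- single_mismatch_panel(sp)
  expect_identical(nrow(panel), 32L)
  hamming <- vapply(panel$variant_spacer, function(v)
    sum(strsplit(v, "")[[1]] != strsplit(sp, "")[[1]]), integer(1))
  expect_true(all(hamming == 1L))
  # the panel scored against the reference reproduces the mask
  eff <- vapply(seq_len(32), function(i)
    effective_mismatches(sp, panel$variant_spacer[i])$effective, integer(1))
  expect_identical(which(eff == 0L), sort(c(6L, 12L, 18L, 24:32)))
  expect_true(all(eff[setdiff(1:32, c(6, 12, 18, 24:32))] == 1L))
  expect_error(single_mismatch_panel(""), "empty")
})

test_that("block panel covers positions 1-30 of a 32-nt spacer in five blocks", {
  sp <- random_spacer(32)
  panel <- block_mismatch_panel(sp)
  expect_identical(nrow(panel), 5L)
  expect_identical(panel$positions[1], paste(1:6, collapse = ","))
  expect_identical(panel$positions[5], paste(25:30, collapse = ","))
  # the PAM-distal block is mostly masked, the seed block is not
  eff <- vapply(panel$variant_spacer, function(v)
    effective_mismatches(sp, v)$effective, integer(1))
  expect_lt(eff[[5]], eff[[1]])
  expect_identical(nrow(block_mismatch_panel(random_spacer(12))), 2L)
  # panels are deterministic functions of the reference
  expect_identical(panel, block_mismatch_panel(sp))
})

test_that("position classes follow seed / periodic / distal architecture", {
  expect_identical(classify_position(3), "seed")
  expect_identical(classify_position(18), "periodic_tolerant")
  expect_identical(classify_position(27), "distal_tolerant")
  expect_identical(classify_position(10), "internal")
  expect_identical(classify_position(c(1, 6, 24, 25)),
                   c("seed", "periodic_tolerant", "periodic_tolerant",
                     "distal_tolerant"))
  expect_error(classify_position(0), "out of range")
  expect_error(classify_position(33), "out of range")
})
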