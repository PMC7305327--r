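# Shared fixtures: all test data is built in code.

random_spacer <- function(len = 32L) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# A complement-substituted variant of `spacer` at PAM-proximal positions.
variant_at <- function(spacer, positions) {
  for (i in positions)
    substr(spacer, i, i) <- chartr("ACGT", "TGCA", substr(spacer, i, i))
  spacer
}

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path)
  path
}

write_tmp_bed <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}
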