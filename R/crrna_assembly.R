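# CRISPR array assembly and in-silico Csy4 processing.
#
# A pre-crRNA is laid out DR-spacer1-DR-...-spacerN-DR (n spacers, n+1
# direct repeats). Csy4 cleaves within each 28-nt repeat after position 20,
# so each mature crRNA carries the last 8 nt of the preceding repeat as its
# 5' handle and the first 20 nt of the following repeat as its 3' hairpin:
# handle(8) + spacer + hairpin(20). The 20-nt leading fragment of the first
# repeat and the 8-nt trailing fragment of the last repeat are by-products.

#' Direct-repeat specification
#'
#' The 28-nt type I-F direct repeat, split into the 8-nt 5' handle
#' (bound by Csy1/Csy2) and the 20-nt 3' hairpin (bound by Csy4). The 20/8
#' cleavage register is the unique split consistent with those segment
#' lengths.
#'
#' @param repeat_seq 28-nt nucleotide string.
#' @param handle_len Handle length (8).
#' @param hairpin_len Hairpin length (20).
#' @return An object of class `repeat_spec`.
#' @export
repeat_spec <- function(repeat_seq, handle_len = 8L, hairpin_len = 20L) {
  repeat_seq <- toupper(repeat_seq)
  .check_alphabet(repeat_seq, allow_n = FALSE, what = "repeat")
  if (nchar(repeat_seq) != handle_len + hairpin_len)
    stop("repeat must be ", handle_len + hairpin_len, " nt (got ",
         nchar(repeat_seq), ")")
  structure(list(repeat_seq = repeat_seq,
                 handle_len = as.integer(handle_len),
                 hairpin_len = as.integer(hairpin_len)),
            class = "repeat_spec")
}

#' Placeholder direct repeat for examples and tests
#'
#' A synthetic 28-nt stand-in; it is **not** the biological
#' *P. aeruginosa* repeat, whose sequence must be supplied by the user for
#' production designs.
#'
#' @return A `repeat_spec`.
#' @export
example_repeat <- function() {
  # synthetic placeholder: 8-nt handle + 20-nt hairpin-length segment
  repeat_spec("GTTCACTGCCGTATAGGCAGCTAAGAAA")
}

#' Assemble a multi-spacer CRISPR array
#'
#' @param spacers Character vector of >= 1 spacer sequences (each >= 6 nt).
#' @param repeat_ A `repeat_spec`.
#' @return An object of class `crispr_array` with elements `spacers`,
#'   `repeat_` and `pre_crrna`.
#' @export
assemble_array <- function(spacers, repeat_ = example_repeat()) {
  if (length(spacers) < 1) stop("at least one spacer required")
  spacers <- toupper(spacers)
  .check_alphabet(spacers, allow_n = FALSE, what = "spacer")
  if (any(nchar(spacers) < 6)) stop("spacer(s) shorter than 6 nt")
  if (!inherits(repeat_, "repeat_spec")) stop("repeat_ must be a repeat_spec")
  dr <- repeat_$repeat_seq
  pre <- paste0(dr, paste0(vapply(spacers, function(s) paste0(s, dr),
                                  character(1)), collapse = ""))
  structure(list(spacers = unname(spacers), repeat_ = repeat_,
                 pre_crrna = pre),
            class = "crispr_array")
}

#' Simulate Csy4 processing of a pre-crRNA
#'
#' Cleaves within each direct repeat after its 20th nucleotide, yielding one
#' mature crRNA per spacer (8-nt handle + spacer + 20-nt hairpin) plus the
#' two terminal repeat fragments as by-products.
#'
#' @param array A `crispr_array`.
#' @return List with `crrnas` (a `data.frame` with columns `handle`,
#'   `spacer`, `hairpin`, `sequence`) and `fragments` (named character
#'   vector: `leading` 20-nt, `trailing` 8-nt).
#' @export
process_array <- function(array) {
  if (!inherits(array, "crispr_array")) stop("not a crispr_array")
  dr <- array$repeat_$repeat_seq
  hl <- array$repeat_$handle_len
  pl <- array$repeat_$hairpin_len
  n <- length(array$spacers)
  expected <- paste0(dr, paste0(vapply(array$spacers,
                                       function(s) paste0(s, dr),
                                       character(1)), collapse = ""))
  if (!identical(array$pre_crrna, expected))
    stop("malformed pre_crrna: does not match DR/spacer layout")
  handle <- substr(dr, pl + 1L, pl + hl)      # last 8 nt of the repeat
  hairpin <- substr(dr, 1L, pl)               # first 20 nt of the repeat
  crrnas <- data.frame(
    handle = rep(handle, n),
    spacer = array$spacers,
    hairpin = rep(hairpin, n),
    sequence = paste0(handle, array$spacers, hairpin),
    stringsAsFactors = FALSE
  )
  list(crrnas = crrnas,
       fragments = c(leading = hairpin, trailing = handle))
}

#' Sanity-check a CRISPR array
#'
#' Returns (rather than signals) warnings for duplicate spacers, spacers
#' embedding the full direct repeat (which would create spurious Csy4
#' processing sites), and spacer lengths outside the 32 + 6k design series
#' or beyond the tested 56 nt.
#'
#' @param array A `crispr_array`.
#' @return Character vector of warnings (empty if clean).
#' @export
validate_array <- function(array) {
  if (!inherits(array, "crispr_array")) stop("not a crispr_array")
  warnings <- character(0)
  sp <- array$spacers
  if (anyDuplicated(sp))
    warnings <- c(warnings, paste0("duplicate spacer(s): ",
                                   paste(unique(sp[duplicated(sp)]), collapse = ", ")))
  dr <- array$repeat_$repeat_seq
  embeds <- grepl(dr, sp, fixed = TRUE)
  if (any(embeds))
    warnings <- c(warnings,
                  paste0("spacer ", which(embeds), collapse = ", ") |>
                    paste("embeds the direct repeat (spurious processing site)"))
  lens <- nchar(sp)
  off_series <- lens < 32 | (lens - 32) %% 6 != 0
  if (any(off_series))
    warnings <- c(warnings, paste0("spacer length(s) outside the 32+6k series: ",
                                   paste(lens[off_series], collapse = ", ")))
  if (any(lens > 56))
    warnings <- c(warnings, paste0("spacer length(s) beyond the tested 56 nt: ",
                                   paste(lens[lens > 56], collapse = ", ")))
  warnings
}

#' Write an array and its processing manifest
#'
#' Emits the pre-crRNA as FASTA and a per-crRNA TSV manifest of segments.
#'
#' @param array A `crispr_array`.
#' @param fasta_path,manifest_path Output file paths.
#' @return Invisibly, the manifest `data.frame`.
#' @export
write_array <- function(array, fasta_path, manifest_path) {
  proc <- process_array(array)
  write_fasta(c(pre_crrna = array$pre_crrna), fasta_path)
  manifest <- cbind(crrna = seq_len(nrow(proc$crrnas)), proc$crrnas)
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}
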