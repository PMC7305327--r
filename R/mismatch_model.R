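# Positional mismatch-tolerance model for type I-F crRNA:DNA pairing.
#
# Positions are numbered 1-based from the PAM-proximal end of the spacer.
# Target binding tolerates mismatches at every sixth position (the base
# flipped out of the RNA:DNA duplex in the periodic 5+1 pairing pattern)
# and at the PAM-distal positions 24-32; the PAM-proximal seed
# (positions 1-5, 7, 8) is the least tolerant. Mismatches at tolerated
# ("masked") positions are excluded from the effective mismatch count used
# for off-target prediction.

#' Positional mask for effective mismatch counting
#'
#' The default mask for a 32-nt spacer is positions {6, 12, 18, 24-32};
#' for other lengths it generalises to every sixth position plus the eight
#' PAM-distal positions. The seed set defaults to positions 1-8 excluding 6.
#'
#' @param spacer_len Spacer length in nt.
#' @param masked Integer vector of 1-based PAM-proximal positions excluded
#'   from the effective count.
#' @param seed Integer vector of seed positions.
#' @return An object of class `position_mask`.
#' @export
position_mask <- function(spacer_len = 32L,
                          masked = default_masked_positions(spacer_len),
                          seed = setdiff(seq_len(min(8L, spacer_len)), 6L)) {
  masked <- sort(unique(as.integer(masked)))
  if (length(masked) > 0 && (min(masked) < 1 || max(masked) > spacer_len))
    stop("masked positions outside [1, spacer_len]")
  structure(list(spacer_len = as.integer(spacer_len), masked = masked,
                 seed = as.integer(seed)),
            class = "position_mask")
}

#' Default masked positions
#'
#' Every sixth position plus the last eight (PAM-distal) positions; for the
#' canonical 32-nt spacer this is {6, 12, 18, 24, 25, ..., 32}.
#'
#' @param spacer_len Spacer length in nt.
#' @return Sorted integer vector.
#' @export
default_masked_positions <- function(spacer_len = 32L) {
  spacer_len <- as.integer(spacer_len)
  every6 <- if (spacer_len >= 6L) seq.int(6L, spacer_len, by = 6L) else integer(0)
  as.integer(sort(unique(c(every6, seq.int(max(1L, spacer_len - 7L), spacer_len)))))
}

#' Effective mismatch count between a spacer and a genomic site
#'
#' Compares the two sequences position by position (1 = PAM-proximal) and
#' counts mismatches that fall outside the mask; N in the site counts as a
#' mismatch.
#'
#' @param spacer Reference spacer (A/C/G/T).
#' @param site_seq Genomic site of the same length (A/C/G/T/N), read on the
#'   protospacer strand in PAM-proximal-first orientation.
#' @param mask A `position_mask` matching the spacer length.
#' @return List with `effective` (integer) and `positions` (all mismatching
#'   positions, 1-based PAM-proximal).
#' @export
effective_mismatches <- function(spacer, site_seq, mask = position_mask(nchar(spacer))) {
  spacer <- toupper(spacer); site_seq <- toupper(site_seq)
  if (nchar(spacer) != nchar(site_seq))
    stop("spacer and site_seq lengths differ")
  if (nchar(spacer) != mask$spacer_len)
    stop("mask spacer_len does not match spacer")
  .check_alphabet(spacer, allow_n = FALSE, what = "spacer")
  .check_alphabet(site_seq, what = "site_seq")
  s <- strsplit(spacer, "")[[1]]
  t <- strsplit(site_seq, "")[[1]]
  mm <- s != t | t == "N"
  positions <- which(mm)
  list(effective = sum(!(positions %in% mask$masked)),
       positions = positions)
}

#' Single-nucleotide mismatch panel
#'
#' One variant per spacer position, substituting the Watson-Crick
#' complement of the reference base (a guaranteed mismatch); 32 variants for
#' the canonical 32-nt spacer.
#'
#' @param spacer Reference spacer (A/C/G/T, non-empty).
#' @return `data.frame` with `label`, `positions` (comma string),
#'   `variant_spacer`.
#' @export
single_mismatch_panel <- function(spacer) {
  spacer <- toupper(spacer)
  if (!nzchar(spacer)) stop("empty spacer")
  .check_alphabet(spacer, allow_n = FALSE, what = "spacer")
  n <- nchar(spacer)
  variants <- vapply(seq_len(n), function(i) {
    v <- spacer
    substr(v, i, i) <- .complement_chr(substr(spacer, i, i))
    v
  }, character(1))
  data.frame(label = sprintf("mm%02d", seq_len(n)),
             positions = as.character(seq_len(n)),
             variant_spacer = variants, stringsAsFactors = FALSE)
}

#' Six-nucleotide block mismatch panel
#'
#' Non-overlapping blocks starting at position 1, each fully complemented:
#' floor(L/6) variants, i.e. five blocks covering positions 1-30 of a 32-nt
#' spacer.
#'
#' @param spacer Reference spacer (A/C/G/T).
#' @param block_len Block length (default 6).
#' @return `data.frame` with `label`, `positions` (comma string),
#'   `variant_spacer`.
#' @export
block_mismatch_panel <- function(spacer, block_len = 6L) {
  spacer <- toupper(spacer)
  if (block_len < 1) stop("block_len must be >= 1")
  .check_alphabet(spacer, allow_n = FALSE, what = "spacer")
  n <- nchar(spacer)
  if (n < block_len) stop("spacer shorter than block_len")
  k <- n %/% block_len
  rows <- lapply(seq_len(k), function(j) {
    from <- (j - 1L) * block_len + 1L
    to <- from + block_len - 1L
    v <- spacer
    substr(v, from, to) <- .complement_chr(substr(spacer, from, to))
    data.frame(label = sprintf("block_%02d_%02d", from, to),
               positions = paste(from:to, collapse = ","),
               variant_spacer = v, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify a spacer position by mismatch tolerance
#'
#' Seed: 1-5, 7, 8 (PAM-proximal, least tolerant). Periodic-tolerant: every
#' sixth position (6, 12, 18, 24; flipped out of the duplex).
#' Distal-tolerant: 25-32. All others internal.
#'
#' @param pos Integer vector of 1-based positions in 1..32.
#' @return Character vector of classes.
#' @export
classify_position <- function(pos) {
  if (any(pos < 1 | pos > 32)) stop("position out of range 1..32")
  ifelse(pos %in% c(1:5, 7, 8), "seed",
         ifelse(pos %in% c(6, 12, 18, 24), "periodic_tolerant",
                ifelse(pos >= 25, "distal_tolerant", "internal")))
}

#' Write a mismatch panel as TSV and FASTA
#'
#' @param panel Panel `data.frame` from [single_mismatch_panel()] or
#'   [block_mismatch_panel()].
#' @param tsv_path,fasta_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the panel.
#' @export
write_panel <- function(panel, tsv_path = NULL, fasta_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(panel, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(fasta_path)) {
    seqs <- panel$variant_spacer
    names(seqs) <- panel$label
    write_fasta(seqs, fasta_path)
  }
  invisible(panel)
}
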