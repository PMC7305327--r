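#' Read genome or promoter sequences from FASTA
#'
#' Loads a FASTA file into a named character vector of uppercase nucleotide
#' sequences (alphabet A, C, G, T, N). Sequence names are the first
#' whitespace-delimited token of each header and must be unique. IUPAC
#' ambiguity codes other than N are collapsed to N with a warning; in strict
#' mode they raise an error instead.
#'
#' @param path Path to a FASTA file.
#' @param strict If `TRUE`, any character outside `{A,C,G,T,N}` is an error
#'   rather than being normalized to N.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  if (any(!nzchar(names(seqs)))) stop("empty sequence name in ", path)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence name(s) in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(!nzchar(seqs))) stop("empty sequence in ", path)
  nonstd <- grepl("[^ACGTN]", seqs)
  if (any(nonstd)) {
    if (strict)
      stop("sequence(s) contain non-ACGTN characters: ",
           paste(names(seqs)[nonstd], collapse = ", "))
    warning("non-ACGTN characters normalized to N in: ",
            paste(names(seqs)[nonstd], collapse = ", "))
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1))
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output file path.
#' @param width Line width for wrapping.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Reverse complement
#'
#' Reverse-complements one or more nucleotide strings over the alphabet
#' A, C, G, T, N (N maps to N). `revcomp(revcomp(s))` recovers `s`.
#'
#' @param seq Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  .check_alphabet(toupper(seq))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(seq))))
}

#' Read TSS records from BED6 or GFF3
#'
#' Extracts one transcription start site per feature. Internally all
#' coordinates are 0-based: for a `+` strand feature the TSS is the feature
#' start; for a `-` strand feature it is the last base (0-based end minus
#' one). GFF3 1-based closed coordinates are converted.
#'
#' @param path Path to a BED6 or GFF3 file.
#' @param format Either `"bed"` or `"gff3"`.
#' @param genome Optional named character vector of sequences; records whose
#'   TSS falls outside the sequence are dropped with a warning.
#' @return `data.frame` with columns `gene_id`, `seq_name`, `tss` (0-based),
#'   `strand`.
#' @export
read_tss <- function(path, format = c("bed", "gff3"), genome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("feature(s) without strand in ", path)
  ids <- if (format == "bed") {
    as.character(gr$name)
  } else {
    mc <- GenomicRanges::mcols(gr)
    id <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, length(gr))
    if ("Name" %in% names(mc)) id <- ifelse(is.na(id), as.character(mc$Name), id)
    if ("gene_id" %in% names(mc)) id <- ifelse(is.na(id), as.character(mc$gene_id), id)
    id
  }
  if (any(is.na(ids) | !nzchar(ids))) stop("feature(s) without identifier in ", path)
  tss <- ifelse(strand == "+",
                GenomicRanges::start(gr) - 1L,   # 0-based feature start
                GenomicRanges::end(gr) - 1L)     # 0-based feature end - 1
  out <- data.frame(
    gene_id = ids,
    seq_name = as.character(GenomicRanges::seqnames(gr)),
    tss = as.integer(tss),
    strand = strand,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$gene_id))
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(out$gene_id[duplicated(out$gene_id)]), collapse = ", "))
  if (!is.null(genome)) {
    len <- nchar(genome)[out$seq_name]
    bad <- is.na(len) | out$tss < 0L | out$tss >= len
    if (any(bad)) {
      warning("dropping ", sum(bad), " TSS record(s) outside sequence bounds: ",
              paste(out$gene_id[bad], collapse = ", "))
      out <- out[!bad, , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  out
}

#' Write TSS records as BED6
#'
#' @param tss_records `data.frame` from [read_tss()] or [plant_gene()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_tss_bed <- function(tss_records, path) {
  bed <- data.frame(
    tss_records$seq_name, tss_records$tss, tss_records$tss + 1L,
    tss_records$gene_id, 0L, tss_records$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build promoter intervals around TSSs
#'
#' A promoter is the window extending `half_width` bases either side of the
#' TSS (default 2 kb), as a 0-based half-open interval
#' `[tss - half_width, tss + half_width + 1)` clipped to the sequence.
#'
#' @param tss_records `data.frame` of TSS records.
#' @param genome Named character vector of sequences (needed for clipping and
#'   to reject unknown sequence names).
#' @param half_width Promoter half-width in bp; must be positive.
#' @return `data.frame` with `gene_id`, `seq_name`, `start`, `end` (0-based
#'   half-open), `tss`, `strand`.
#' @export
build_promoters <- function(tss_records, genome, half_width = 2000L) {
  if (length(half_width) != 1 || half_width <= 0)
    stop("half_width must be a single positive number")
  unknown <- setdiff(tss_records$seq_name, names(genome))
  if (length(unknown) > 0)
    stop("unknown seq_name(s): ", paste(unknown, collapse = ", "))
  len <- nchar(genome)[tss_records$seq_name]
  data.frame(
    gene_id = tss_records$gene_id,
    seq_name = tss_records$seq_name,
    start = pmax(0L, as.integer(tss_records$tss - half_width)),
    end = pmin(as.integer(len), as.integer(tss_records$tss + half_width + 1L)),
    tss = tss_records$tss,
    strand = tss_records$strand,
    stringsAsFactors = FALSE
  )
}
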