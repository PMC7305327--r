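# Guide design for type I-F Cascade CRISPRa: PAM scanning, TSS-window
# classification, Csy3 stoichiometry, spacer extension and pair selection.
#
# Conventions. The type I-F Cascade recognises a 5'-CC PAM immediately 5' of
# the protospacer, on the non-target strand; the crRNA spacer is taken
# identical in sequence to the protospacer on the PAM-carrying strand.
# Protospacer coordinates are 0-based half-open on the forward axis for both
# strands. TSS offsets are gene-strand-relative and anchored at the
# PAM-proximal protospacer base; negative means upstream of the TSS.

#' Scan a sequence for PAM-adjacent protospacer windows
#'
#' Finds every full-length protospacer window on either strand whose PAM
#' (default 5'-CC, as recognised by the type I-F Cascade) matches immediately
#' adjacent on the reported strand. Coordinates are reported on the forward
#' axis for both strands.
#'
#' @param seq A single nucleotide string.
#' @param spacer_len Protospacer length in nt (>= 1).
#' @param pam IUPAC PAM pattern (default `"CC"`).
#' @param pam_side `"5prime"` (PAM 5' of the protospacer, type I-F) or
#'   `"3prime"` (e.g. SpCas9 NGG).
#' @param exclude_n Drop windows whose protospacer contains N (default
#'   `TRUE`; off-target enumeration keeps them and counts N as mismatch).
#' @return `data.frame` with `strand`, `start`, `end` (0-based half-open,
#'   forward axis), `spacer` (protospacer-strand sequence) and `pam`.
#' @export
scan_pam_sites <- function(seq, spacer_len, pam = "CC", pam_side = "5prime",
                           exclude_n = TRUE) {
  stopifnot(length(seq) == 1)
  if (spacer_len < 1) stop("spacer_len must be >= 1")
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty sequence")
  .check_alphabet(seq)
  len <- nchar(seq)
  res <- lapply(c("+", "-"), function(strand) {
    S <- if (strand == "+") seq else revcomp(seq)
    starts <- .scan_strand_starts(S, spacer_len, pam, pam_side)
    if (length(starts) == 0) return(NULL)
    spacer <- substring(S, starts + 1L, starts + spacer_len)
    pam_obs <- .observed_pam(S, starts, spacer_len, nchar(pam), pam_side)
    if (exclude_n) {
      keep <- !grepl("N", spacer, fixed = TRUE)
      starts <- starts[keep]; spacer <- spacer[keep]; pam_obs <- pam_obs[keep]
    }
    if (length(starts) == 0) return(NULL)
    fwd_start <- if (strand == "+") starts else len - starts - spacer_len
    data.frame(strand = strand, start = as.integer(fwd_start),
               end = as.integer(fwd_start + spacer_len),
               spacer = spacer, pam = pam_obs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(strand = character(0), start = integer(0),
                      end = integer(0), spacer = character(0),
                      pam = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Protospacer start positions (0-based) on a single strand string.
.scan_strand_starts <- function(S, L, pam, pam_side) {
  len <- nchar(S)
  plen <- nchar(pam)
  pos1 <- .match_positions(S, .iupac_regex(pam))  # 1-based PAM starts
  if (pam_side == "5prime") {
    starts <- pos1 - 1L + plen
    starts[starts + L <= len]
  } else {
    starts <- pos1 - 1L - L
    starts[starts >= 0]
  }
}

.observed_pam <- function(S, starts, L, plen, pam_side) {
  if (pam_side == "5prime") substring(S, starts + 1L - plen, starts)
  else substring(S, starts + L + 1L, starts + L + plen)
}

#' Classify a TSS offset into the design windows
#'
#' Offsets are gene-strand-relative, negative upstream. The optimal window
#' (100-200 bp upstream of the TSS) and the wider design range (500-100 bp
#' upstream) reflect where Cascade-mediated activation works best.
#'
#' @param tss_offset Integer vector of signed offsets.
#' @param optimal_window Closed interval for `"optimal"` (default
#'   `c(-200, -100)`).
#' @param design_range Closed interval for `"in_range"` (default
#'   `c(-500, -100)`).
#' @return Character vector: `"optimal"`, `"in_range"` or `"out_of_range"`.
#' @export
classify_tss_window <- function(tss_offset, optimal_window = c(-200L, -100L),
                                design_range = c(-500L, -100L)) {
  ifelse(tss_offset >= optimal_window[1] & tss_offset <= optimal_window[2],
         "optimal",
         ifelse(tss_offset >= design_range[1] & tss_offset <= design_range[2],
                "in_range", "out_of_range"))
}

#' Csy3 copy number for a given spacer length
#'
#' Each Csy3 subunit binds 6 nt of the crRNA spacer; copy number is the
#' ceiling of length/6, giving 3 copies for a 14-nt spacer up to 9 for a
#' 50-nt spacer and 6 for the canonical 32-nt spacer.
#'
#' @param spacer_len Spacer length(s) in nt, each >= 6 (the minimal Csy3
#'   binding unit).
#' @return Integer vector of Csy3 copy numbers.
#' @export
csy3_copies <- function(spacer_len) {
  if (any(spacer_len < 6))
    stop("spacer_len below 6 nt, the minimal length for Csy3 binding")
  as.integer(ceiling(spacer_len / 6))
}

#' Extract guide candidates near annotated TSSs
#'
#' Scans each sequence for PAM-adjacent protospacers and keeps those whose
#' PAM-proximal base lies within the design range of a gene's TSS, measured
#' gene-strand-relative (negative upstream). Candidates on either genomic
#' strand are considered.
#'
#' @param genome Named character vector of sequences.
#' @param tss_records `data.frame` of TSS records.
#' @param spacer_len Protospacer length (default 32).
#' @param design_range Closed gene-strand-relative offset interval (default
#'   `c(-500, -100)`).
#' @param optimal_window Passed to [classify_tss_window()].
#' @param pam,pam_side PAM specification (default 5'-CC).
#' @return `data.frame` of candidates: `gene_id`, `seq_name`, `strand`,
#'   `start`, `end`, `pam`, `spacer`, `tss_offset`, `window_class`,
#'   `csy3_copies`.
#' @export
extract_candidates <- function(genome, tss_records, spacer_len = 32L,
                               design_range = c(-500L, -100L),
                               optimal_window = c(-200L, -100L),
                               pam = "CC", pam_side = "5prime") {
  if (nrow(tss_records) == 0) stop("no TSS records supplied")
  unknown <- setdiff(tss_records$seq_name, names(genome))
  if (length(unknown) > 0)
    stop("gene(s) on unknown sequence: ", paste(unknown, collapse = ", "))
  sites_by_seq <- lapply(unique(tss_records$seq_name), function(sn)
    scan_pam_sites(genome[[sn]], spacer_len, pam, pam_side))
  names(sites_by_seq) <- unique(tss_records$seq_name)
  rows <- lapply(seq_len(nrow(tss_records)), function(i) {
    g <- tss_records[i, ]
    sites <- sites_by_seq[[g$seq_name]]
    if (nrow(sites) == 0) return(NULL)
    anchor <- .pam_proximal_anchor(sites$strand, sites$start, sites$end, pam_side)
    offset <- if (g$strand == "+") anchor - g$tss else g$tss - anchor
    keep <- offset >= design_range[1] & offset <= design_range[2]
    if (!any(keep)) return(NULL)
    s <- sites[keep, , drop = FALSE]
    data.frame(
      gene_id = g$gene_id, seq_name = g$seq_name,
      strand = s$strand, start = s$start, end = s$end,
      pam = s$pam, spacer = s$spacer,
      tss_offset = as.integer(offset[keep]),
      window_class = classify_tss_window(offset[keep], optimal_window,
                                         design_range),
      csy3_copies = if (pam_side == "5prime") csy3_copies(spacer_len)
                    else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), seq_name = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), pam = character(0),
                      spacer = character(0), tss_offset = integer(0),
                      window_class = character(0), csy3_copies = integer(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Forward-axis position of the PAM-proximal protospacer base.
.pam_proximal_anchor <- function(strand, start, end, pam_side = "5prime") {
  if (pam_side == "5prime") ifelse(strand == "+", start, end - 1L)
  else ifelse(strand == "+", end - 1L, start)
}

#' Extend (or truncate) a candidate spacer at the PAM-distal end
#'
#' Spacer lengths vary by multiples of six from the canonical 32 nt
#' (32, 38, 44, 50, 56, ...), each step adding one Csy3 binding unit. The
#' PAM-proximal 32 nt are left unchanged; the extension is the genomic
#' continuation at the PAM-distal end. Lengths beyond 56 nt are accepted but
#' flagged with a warning as untested.
#'
#' @param candidate One-row candidate `data.frame` from
#'   [extract_candidates()].
#' @param genome Named character vector of sequences.
#' @param target_len Target spacer length, of the form 32 + 6k.
#' @return The modified candidate row.
#' @export
extend_spacer <- function(candidate, genome, target_len) {
  stopifnot(nrow(candidate) == 1)
  if (target_len < 32 || (target_len - 32) %% 6 != 0)
    stop("target_len must be of the form 32 + 6k (32, 38, 44, 50, 56, ...)")
  if (target_len > 56)
    warning("spacer lengths beyond 56 nt are untested; proceeding")
  seq <- genome[[candidate$seq_name]]
  if (is.null(seq)) stop("unknown seq_name: ", candidate$seq_name)
  if (candidate$strand == "+") {
    new_start <- candidate$start
    new_end <- candidate$start + target_len
  } else {
    new_start <- candidate$end - target_len
    new_end <- candidate$end
  }
  if (new_start < 0 || new_end > nchar(seq))
    stop("extension exceeds sequence bounds")
  window <- .seq_window(seq, new_start, new_end)
  spacer <- if (candidate$strand == "+") window else revcomp(window)
  if (grepl("N", spacer, fixed = TRUE)) stop("extension contains N")
  candidate$start <- as.integer(new_start)
  candidate$end <- as.integer(new_end)
  candidate$spacer <- spacer
  candidate$csy3_copies <- csy3_copies(target_len)
  candidate
}

#' Enumerate and classify crRNA pairs for a gene
#'
#' Dual crRNAs targeting the same promoter act synergistically, with an
#' inter-protospacer distance of about 50-75 bp optimal. Spacing is measured
#' between the 5'-most (forward-axis) positions of the two protospacers.
#' Pairs are ordered optimal-spacing first, then by distance from the
#' midpoint of the optimal interval.
#'
#' @param candidates Candidate `data.frame`; pairs are formed within each
#'   `gene_id`.
#' @param optimal_spacing Closed bp interval scored `"optimal"` (default
#'   `c(50, 75)`).
#' @return `data.frame` with index columns `first`, `second` (row indices
#'   into `candidates`), `gene_id`, `spacing`, `spacing_class`.
#' @export
select_pairs <- function(candidates, optimal_spacing = c(50L, 75L)) {
  empty <- data.frame(first = integer(0), second = integer(0),
                      gene_id = character(0), spacing = integer(0),
                      spacing_class = character(0), stringsAsFactors = FALSE)
  if (nrow(candidates) < 2) return(empty)
  mid <- mean(optimal_spacing)
  rows <- lapply(unique(candidates$gene_id), function(g) {
    idx <- which(candidates$gene_id == g)
    if (length(idx) < 2) return(NULL)
    cmb <- utils::combn(idx, 2)
    spacing <- abs(candidates$start[cmb[1, ]] - candidates$start[cmb[2, ]])
    data.frame(first = cmb[1, ], second = cmb[2, ], gene_id = g,
               spacing = as.integer(spacing),
               spacing_class = ifelse(spacing >= optimal_spacing[1] &
                                        spacing <= optimal_spacing[2],
                                      "optimal", "acceptable"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  ord <- order(out$spacing_class != "optimal", abs(out$spacing - mid),
               out$first, out$second)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank guide candidates
#'
#' Stable sort by window class (optimal, in-range, out-of-range), then by
#' distance of the TSS offset from -150 (the centre of the optimal window),
#' then by forward coordinate. Ties preserve input order.
#'
#' @param candidates Candidate `data.frame`.
#' @return The same `data.frame`, reordered.
#' @export
rank_candidates <- function(candidates) {
  if (nrow(candidates) == 0) return(candidates)
  class_rank <- match(candidates$window_class,
                      c("optimal", "in_range", "out_of_range"))
  ord <- order(class_rank, abs(candidates$tss_offset + 150L),
               candidates$start)
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write candidates as BED6
#'
#' Emits the 0-based half-open protospacer intervals; the score column holds
#' the Csy3 copy number.
#'
#' @param candidates Candidate `data.frame`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_candidates_bed <- function(candidates, path) {
  bed <- data.frame(
    candidates$seq_name, candidates$start, candidates$end,
    paste(candidates$gene_id, candidates$tss_offset, sep = "_"),
    ifelse(is.na(candidates$csy3_copies), 0L, candidates$csy3_copies),
    candidates$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
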