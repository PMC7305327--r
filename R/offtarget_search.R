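# Off-target enumeration under positional-mask rules.
#
# A rule set captures one matching specification: spacer length, PAM pattern
# and side, positional mask, and an effective-mismatch cap. The same
# machinery expresses the type I-F Cascade rule (32 nt, 5'-CC,
# mask {6,12,18,24-32}, <= 4 effective) and the SpCas9 comparator rule
# (20 nt, 3' NGG, no mask, <= 4 anywhere).
#
# The production enumerator scans PAM-anchored windows with vectorised
# per-position comparisons; brute_force_oracle() re-derives the same hit set
# by a plain position-by-position loop and exists purely as an independent
# correctness check.

#' Construct an off-target rule set
#'
#' @param name Rule-set name.
#' @param spacer_len Spacer/protospacer length in nt.
#' @param pam IUPAC PAM pattern.
#' @param pam_side `"5prime"` or `"3prime"` relative to the protospacer.
#' @param mask A `position_mask` of matching length.
#' @param max_mismatches Cap on effective (non-masked) mismatches.
#' @param require_pam Require the PAM on candidate off-target sites
#'   (default `TRUE`; PAM recognition is mechanistically required, but the
#'   flag allows a PAM-agnostic pure sequence-similarity search).
#' @return An object of class `rule_set`.
#' @export
rule_set <- function(name, spacer_len, pam, pam_side = c("5prime", "3prime"),
                     mask = position_mask(spacer_len, masked = integer(0)),
                     max_mismatches = 4L, require_pam = TRUE) {
  pam_side <- match.arg(pam_side)
  if (max_mismatches < 0) stop("max_mismatches must be >= 0")
  if (!nzchar(pam)) stop("empty PAM pattern")
  .iupac_regex(pam)  # validates
  if (!inherits(mask, "position_mask") || mask$spacer_len != spacer_len)
    stop("mask must be a position_mask of length spacer_len")
  structure(list(name = name, spacer_len = as.integer(spacer_len),
                 pam = toupper(pam), pam_side = pam_side, mask = mask,
                 max_mismatches = as.integer(max_mismatches),
                 require_pam = isTRUE(require_pam)),
            class = "rule_set")
}

#' Type I-F Cascade off-target rule
#'
#' 32-nt spacer, 5'-CC PAM, tolerated positions {6, 12, 18, 24-32} excluded
#' from the count, at most 4 effective mismatches.
#'
#' @param spacer_len Spacer length (default 32).
#' @param max_mismatches Effective-mismatch cap (default 4).
#' @param mask Positional mask (default [position_mask()] for the length).
#' @param require_pam Require 5'-CC on off-target sites (default `TRUE`).
#' @return A `rule_set`.
#' @export
cascade_rule <- function(spacer_len = 32L, max_mismatches = 4L,
                         mask = position_mask(spacer_len),
                         require_pam = TRUE) {
  rule_set("cascade_if", spacer_len, "CC", "5prime", mask,
           max_mismatches, require_pam)
}

#' SpCas9 comparator off-target rule
#'
#' 20-nt protospacer, 3' NGG PAM, no positional mask, at most 4 mismatches
#' anywhere.
#'
#' @param spacer_len Protospacer length (default 20).
#' @param max_mismatches Mismatch cap (default 4).
#' @param require_pam Require 3' NGG on off-target sites (default `TRUE`).
#' @return A `rule_set`.
#' @export
spcas9_rule <- function(spacer_len = 20L, max_mismatches = 4L,
                        require_pam = TRUE) {
  rule_set("spcas9", spacer_len, "NGG", "3prime",
           position_mask(spacer_len, masked = integer(0), seed = integer(0)),
           max_mismatches, require_pam)
}

# Mask positions mapped to 5'->3' spacer indices (PAM-proximal position 1 is
# the 5' end for a 5' PAM and the 3' end for a 3' PAM).
.mask53 <- function(rule) {
  m <- logical(rule$spacer_len)
  if (length(rule$mask$masked) > 0) {
    idx <- if (rule$pam_side == "5prime") rule$mask$masked
           else rule$spacer_len - rule$mask$masked + 1L
    m[idx] <- TRUE
  }
  m
}

# 5'->3' index -> PAM-proximal 1-based position.
.pp_positions <- function(idx, L, pam_side) {
  if (pam_side == "5prime") idx else L - idx + 1L
}

.lowercase_at <- function(site, idx53) {
  if (length(idx53) == 0) return(site)
  ch <- strsplit(site, "")[[1]]
  ch[idx53] <- tolower(ch[idx53])
  paste0(ch, collapse = "")
}

.validate_query <- function(spacer, rule) {
  spacer <- toupper(spacer)
  if (nchar(spacer) != rule$spacer_len)
    stop("query length ", nchar(spacer), " does not match rule spacer_len ",
         rule$spacer_len)
  .check_alphabet(spacer, allow_n = FALSE, what = "query spacer")
  spacer
}

#' Enumerate putative off-target sites
#'
#' Scans every window on both strands of every sequence; a window is
#' reported when its PAM matches the rule's pattern on the correct side (if
#' required) and its effective (non-masked) mismatch count against the
#' query does not exceed the cap. Exact on-target matches are included and
#' flagged. N in the genome counts as a mismatch and never satisfies a PAM
#' base.
#'
#' @param spacer Query spacer (A/C/G/T), length equal to the rule's.
#' @param genome Named character vector of sequences.
#' @param rule A `rule_set`.
#' @return `data.frame` of hits ordered by (`seq_name`, `start`, `strand`):
#'   `seq_name`, `strand`, `start`, `end` (0-based half-open protospacer),
#'   `site_seq` (protospacer strand, 5'->3'), `site_display` (mismatched
#'   bases lowercased), `pam_observed`, `mismatch_positions` (comma string,
#'   PAM-proximal 1-based), `n_mismatches`, `effective`, `is_exact`.
#' @export
enumerate_offtargets <- function(spacer, genome, rule = cascade_rule()) {
  spacer <- .validate_query(spacer, rule)
  if (length(genome) == 0 || all(!nzchar(genome))) stop("empty genome")
  L <- rule$spacer_len
  plen <- nchar(rule$pam)
  sc <- strsplit(spacer, "")[[1]]
  mask53 <- .mask53(rule)
  rows <- list()
  for (sn in names(genome)) {
    seq <- toupper(genome[[sn]])
    len <- nchar(seq)
    if (len < L) next
    for (strand in c("+", "-")) {
      S <- if (strand == "+") seq else revcomp(seq)
      starts <- if (rule$require_pam) {
        .scan_strand_starts(S, L, rule$pam, rule$pam_side)
      } else {
        0:(len - L)
      }
      if (length(starts) == 0) next
      n <- length(starts)
      mm <- matrix(FALSE, n, L)
      for (j in seq_len(L)) {
        b <- substring(S, starts + j, starts + j)
        mm[, j] <- b != sc[j] | b == "N"
      }
      eff <- rowSums(mm[, !mask53, drop = FALSE])
      keep <- which(eff <= rule$max_mismatches)
      if (length(keep) == 0) next
      starts_k <- starts[keep]
      site <- substring(S, starts_k + 1L, starts_k + L)
      pam_obs <- .observed_pam(S, starts_k, L, plen, rule$pam_side)
      total <- rowSums(mm[keep, , drop = FALSE])
      mmpos <- vapply(keep, function(i) {
        idx <- which(mm[i, ])
        paste(sort(.pp_positions(idx, L, rule$pam_side)), collapse = ",")
      }, character(1))
      disp <- vapply(seq_along(keep), function(k)
        .lowercase_at(site[k], which(mm[keep[k], ])), character(1))
      fwd_start <- if (strand == "+") starts_k else len - starts_k - L
      rows[[length(rows) + 1L]] <- data.frame(
        seq_name = sn, strand = strand,
        start = as.integer(fwd_start), end = as.integer(fwd_start + L),
        site_seq = site, site_display = disp, pam_observed = pam_obs,
        mismatch_positions = mmpos,
        n_mismatches = as.integer(total), effective = as.integer(eff[keep]),
        is_exact = total == 0L, stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else .empty_hits()
  out <- out[order(out$seq_name, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Brute-force off-target oracle
#'
#' Same contract as [enumerate_offtargets()], implemented as a plain
#' position-by-position exhaustive scan with no prefilter; serves as an
#' independent correctness oracle in tests.
#'
#' @inheritParams enumerate_offtargets
#' @return Same as [enumerate_offtargets()].
#' @export
brute_force_oracle <- function(spacer, genome, rule = cascade_rule()) {
  spacer <- .validate_query(spacer, rule)
  if (length(genome) == 0 || all(!nzchar(genome))) stop("empty genome")
  L <- rule$spacer_len
  plen <- nchar(rule$pam)
  sc <- strsplit(spacer, "")[[1]]
  pam_sets <- .IUPAC_SETS[strsplit(rule$pam, "")[[1]]]
  mask53 <- .mask53(rule)
  rows <- list()
  for (sn in names(genome)) {
    seq <- toupper(genome[[sn]])
    len <- nchar(seq)
    if (len < L) next
    for (strand in c("+", "-")) {
      S <- if (strand == "+") seq else revcomp(seq)
      ch <- strsplit(S, "")[[1]]
      for (s0 in 0:(len - L)) {
        if (rule$require_pam) {
          pam_pos <- if (rule$pam_side == "5prime") (s0 - plen + 1L):s0
                     else (s0 + L + 1L):(s0 + L + plen)
          if (pam_pos[1] < 1L || pam_pos[plen] > len) next
          pam_ok <- TRUE
          for (p in seq_len(plen)) {
            if (!(ch[pam_pos[p]] %in% pam_sets[[p]])) { pam_ok <- FALSE; break }
          }
          if (!pam_ok) next
        }
        site <- ch[(s0 + 1L):(s0 + L)]
        mmv <- site != sc | site == "N"
        eff <- sum(mmv & !mask53)
        if (eff > rule$max_mismatches) next
        idx <- which(mmv)
        fwd_start <- if (strand == "+") s0 else len - s0 - L
        rows[[length(rows) + 1L]] <- data.frame(
          seq_name = sn, strand = strand,
          start = as.integer(fwd_start), end = as.integer(fwd_start + L),
          site_seq = paste0(site, collapse = ""),
          site_display = .lowercase_at(paste0(site, collapse = ""), idx),
          pam_observed = if (rule$require_pam)
            paste0(ch[pam_pos], collapse = "") else
            .observed_pam(S, s0, L, plen, rule$pam_side),
          mismatch_positions = paste(sort(.pp_positions(idx, L, rule$pam_side)),
                                     collapse = ","),
          n_mismatches = length(idx), effective = as.integer(eff),
          is_exact = length(idx) == 0L, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else .empty_hits()
  out <- out[order(out$seq_name, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter off-target hits to promoter regions
#'
#' Retains hits whose protospacer overlaps at least one promoter interval
#' (any base within the interval) and annotates the nearest gene and the
#' signed, gene-strand-relative distance from the PAM-proximal protospacer
#' base to that gene's TSS (negative upstream). Ties between equidistant
#' genes go to the lexicographically smaller `gene_id`.
#'
#' @param hits Hit `data.frame` from [enumerate_offtargets()].
#' @param promoters Promoter `data.frame` from [build_promoters()].
#' @param pam_side PAM side of the generating rule (anchors the distance).
#' @return The retained hits with added `nearest_gene` and `tss_distance`.
#' @export
promoter_filter <- function(hits, promoters, pam_side = "5prime") {
  if (nrow(hits) == 0) {
    hits$nearest_gene <- character(0)
    hits$tss_distance <- integer(0)
    return(hits)
  }
  hg <- GenomicRanges::GRanges(hits$seq_name,
                               IRanges::IRanges(hits$start + 1L, hits$end))
  pg <- GenomicRanges::GRanges(promoters$seq_name,
                               IRanges::IRanges(promoters$start + 1L,
                                                promoters$end))
  ov <- GenomicRanges::findOverlaps(hg, pg)
  if (length(ov) == 0) {
    out <- hits[0, , drop = FALSE]
    out$nearest_gene <- character(0)
    out$tss_distance <- integer(0)
    return(out)
  }
  anchor <- .pam_proximal_anchor(hits$strand, hits$start, hits$end, pam_side)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  keep_idx <- sort(unique(qh))
  nearest_gene <- character(length(keep_idx))
  tss_distance <- integer(length(keep_idx))
  for (k in seq_along(keep_idx)) {
    i <- keep_idx[k]
    genes <- sh[qh == i]
    d <- ifelse(promoters$strand[genes] == "+",
                anchor[i] - promoters$tss[genes],
                promoters$tss[genes] - anchor[i])
    ord <- order(abs(d), promoters$gene_id[genes])
    nearest_gene[k] <- promoters$gene_id[genes][ord[1]]
    tss_distance[k] <- d[ord[1]]
  }
  out <- hits[keep_idx, , drop = FALSE]
  out$nearest_gene <- nearest_gene
  out$tss_distance <- as.integer(tss_distance)
  rownames(out) <- NULL
  out
}

#' Find overlapping Cascade/Cas9 target sites with cross-promoter off-targets
#'
#' Searches each gene's design window for a Cascade protospacer and a
#' SpCas9 protospacer that overlap by at least 1 bp, where each guide also
#' has at least one predicted off-target surviving the promoter filter in a
#' *different* gene's promoter — the site-selection procedure used to pick
#' targets for off-target analysis.
#'
#' @param genome Named character vector of sequences.
#' @param tss_records TSS `data.frame`.
#' @param cascade_rule_,cas9_rule_ The two `rule_set`s.
#' @param design_range Gene-strand-relative offset window for on-target
#'   candidates.
#' @param half_width Promoter half-width for the off-target filter.
#' @return `data.frame` of overlap regions: `gene_id`, `seq_name`,
#'   `region_start`, `region_end` (the overlapped interval),
#'   `cascade_start`, `cascade_strand`, `cascade_spacer`, `cas9_start`,
#'   `cas9_strand`, `cas9_spacer`, `cascade_offtarget_gene`,
#'   `cas9_offtarget_gene`.
#' @export
find_overlap_sites <- function(genome, tss_records,
                               cascade_rule_ = cascade_rule(),
                               cas9_rule_ = spcas9_rule(),
                               design_range = c(-500L, -100L),
                               half_width = 2000L) {
  empty <- data.frame(gene_id = character(0), seq_name = character(0),
                      region_start = integer(0), region_end = integer(0),
                      cascade_start = integer(0), cascade_strand = character(0),
                      cascade_spacer = character(0),
                      cas9_start = integer(0), cas9_strand = character(0),
                      cas9_spacer = character(0),
                      cascade_offtarget_gene = character(0),
                      cas9_offtarget_gene = character(0),
                      stringsAsFactors = FALSE)
  casc <- extract_candidates(genome, tss_records, cascade_rule_$spacer_len,
                             design_range, pam = cascade_rule_$pam,
                             pam_side = cascade_rule_$pam_side)
  cas9 <- extract_candidates(genome, tss_records, cas9_rule_$spacer_len,
                             design_range, pam = cas9_rule_$pam,
                             pam_side = cas9_rule_$pam_side)
  if (nrow(casc) == 0 || nrow(cas9) == 0) return(empty)
  promoters <- build_promoters(tss_records, genome, half_width)
  offt_cache <- new.env(parent = emptyenv())
  cross_offtarget <- function(spacer, rule, gene, own_start, own_strand,
                              seq_name, side) {
    key <- paste(rule$name, spacer, sep = ":")
    hits <- if (!is.null(offt_cache[[key]])) offt_cache[[key]] else {
      h <- promoter_filter(enumerate_offtargets(spacer, genome, rule),
                           promoters, side)
      offt_cache[[key]] <- h
      h
    }
    if (nrow(hits) == 0) return(NA_character_)
    other <- hits$nearest_gene != gene &
      !(hits$seq_name == seq_name & hits$start == own_start &
          hits$strand == own_strand)
    if (!any(other)) return(NA_character_)
    sort(hits$nearest_gene[other])[1]
  }
  rows <- list()
  for (g in unique(casc$gene_id)) {
    ci <- which(casc$gene_id == g)
    ki <- which(cas9$gene_id == g)
    for (i in ci) for (j in ki) {
      if (casc$seq_name[i] != cas9$seq_name[j]) next
      ov_start <- max(casc$start[i], cas9$start[j])
      ov_end <- min(casc$end[i], cas9$end[j])
      if (ov_end - ov_start < 1L) next
      cg <- cross_offtarget(casc$spacer[i], cascade_rule_, g, casc$start[i],
                            casc$strand[i], casc$seq_name[i],
                            cascade_rule_$pam_side)
      if (is.na(cg)) next
      kg <- cross_offtarget(cas9$spacer[j], cas9_rule_, g, cas9$start[j],
                            cas9$strand[j], cas9$seq_name[j],
                            cas9_rule_$pam_side)
      if (is.na(kg)) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, seq_name = casc$seq_name[i],
        region_start = as.integer(ov_start), region_end = as.integer(ov_end),
        cascade_start = casc$start[i], cascade_strand = casc$strand[i],
        cascade_spacer = casc$spacer[i],
        cas9_start = cas9$start[j], cas9_strand = cas9$strand[j],
        cas9_spacer = cas9$spacer[j],
        cascade_offtarget_gene = cg, cas9_offtarget_gene = kg,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  out
}

#' Write off-target hits as TSV and/or BED6
#'
#' Deterministic ordering (`seq_name`, `start`, `strand`); the TSV renders
#' mismatched bases in lowercase in `site_display`; BED rows use the
#' 0-based half-open protospacer interval with the effective mismatch count
#' as score.
#'
#' @param hits Hit `data.frame`.
#' @param tsv_path,bed_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the ordered hits.
#' @export
write_hits <- function(hits, tsv_path = NULL, bed_path = NULL) {
  hits <- hits[order(hits$seq_name, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  if (!is.null(tsv_path))
    utils::write.table(hits, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(bed_path)) {
    name <- sprintf("hit_%04d", seq_len(max(nrow(hits), 0L)))
    bed <- data.frame(hits$seq_name, hits$start, hits$end,
                      name[seq_len(nrow(hits))], hits$effective, hits$strand)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(hits)
}
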