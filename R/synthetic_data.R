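# Seeded synthetic genomes with planted protospacers and off-target decoys.
#
# A dataset bundles a genome, TSS annotations and a ground-truth manifest of
# every planted feature. Planting writes PAM + protospacer in gene-strand
# (or chosen-strand) orientation over the random background, tracks
# footprints to prevent collisions, and verifies that each planted
# PAM+protospacer string does not also occur by chance elsewhere.

#' Generate a random genome
#'
#' I.i.d. bases with `P(G) = P(C) = gc/2`; the same seed always yields the
#' same genome. The default GC fraction of 0.41 is human-like.
#'
#' @param n_seqs Number of sequences.
#' @param length Length of each sequence (>= 1).
#' @param gc GC fraction, strictly between 0 and 1.
#' @param seed Optional integer seed (set before sampling when supplied).
#' @return Named character vector (`seq1`, `seq2`, ...).
#' @export
generate_genome <- function(n_seqs = 1L, length = 10000L, gc = 0.41,
                            seed = NULL) {
  if (length < 1) stop("length must be >= 1")
  if (gc <= 0 || gc >= 1) stop("gc must be strictly between 0 and 1")
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n_seqs), function(i)
    paste0(sample(names(p), length, replace = TRUE, prob = p), collapse = ""),
    character(1))
  names(seqs) <- paste0("seq", seq_len(n_seqs))
  seqs
}

#' Create an empty synthetic dataset around a genome
#'
#' @param genome Named character vector of sequences.
#' @return An object of class `synthetic_dataset` with empty TSS and truth
#'   tables.
#' @export
new_dataset <- function(genome) {
  .check_alphabet(genome, what = "genome")
  structure(list(
    genome = genome,
    tss = data.frame(gene_id = character(0), seq_name = character(0),
                     tss = integer(0), strand = character(0),
                     stringsAsFactors = FALSE),
    truth = .empty_truth(),
    occupied = stats::setNames(
      rep(list(data.frame(start = integer(0), end = integer(0))),
          length(genome)), names(genome))
  ), class = "synthetic_dataset")
}

.empty_truth <- function() {
  data.frame(kind = character(0), gene_id = character(0),
             seq_name = character(0), strand = character(0),
             start = integer(0), end = integer(0),
             spacer_ref = character(0), variant = character(0),
             mismatch_positions = character(0), effective = integer(0),
             tss_offset = integer(0), detectable = logical(0),
             promoter_retained = logical(0), stringsAsFactors = FALSE)
}

#' Annotate a gene TSS in a dataset
#'
#' @param dataset A `synthetic_dataset`.
#' @param seq_name Sequence name.
#' @param tss 0-based TSS position.
#' @param strand `"+"` or `"-"`.
#' @param gene_id Unique gene identifier.
#' @return The updated dataset.
#' @export
plant_gene <- function(dataset, seq_name, tss, strand, gene_id) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!seq_name %in% names(dataset$genome))
    stop("unknown seq_name: ", seq_name)
  if (tss < 0 || tss >= nchar(dataset$genome[[seq_name]]))
    stop("tss outside sequence bounds")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (gene_id %in% dataset$tss$gene_id)
    stop("duplicate gene_id: ", gene_id)
  dataset$tss <- rbind(dataset$tss, data.frame(
    gene_id = gene_id, seq_name = seq_name, tss = as.integer(tss),
    strand = strand, stringsAsFactors = FALSE))
  dataset
}

# Footprint (PAM + protospacer) forward interval for a protospacer at
# [start, start + L) on the given strand under the given rule.
.footprint <- function(strand, start, L, plen, pam_side) {
  if ((pam_side == "5prime") == (strand == "+"))
    c(start - plen, start + L)   # PAM on the left of the forward interval
  else
    c(start, start + L + plen)   # PAM on the right
}

# Write pam+protospacer (protospacer-strand orientation) into the genome.
.plant_site <- function(dataset, seq_name, strand, start, variant, rule,
                        check_unique = TRUE) {
  L <- nchar(variant)
  plen <- nchar(rule$pam)
  pam_concrete <- .iupac_concrete(rule$pam)
  seq <- dataset$genome[[seq_name]]
  if (is.null(seq)) stop("unknown seq_name: ", seq_name)
  fp <- .footprint(strand, start, L, plen, rule$pam_side)
  if (fp[1] < 0 || fp[2] > nchar(seq))
    stop("planted site exceeds sequence bounds")
  occ <- dataset$occupied[[seq_name]]
  if (nrow(occ) > 0 && any(fp[1] < occ$end & occ$start < fp[2]))
    stop("collision with previously planted feature")
  strand_string <- if (rule$pam_side == "5prime")
    paste0(pam_concrete, variant) else paste0(variant, pam_concrete)
  fwd_string <- if (strand == "+") strand_string else revcomp(strand_string)
  seq <- .replace_window(seq, fp[1], fwd_string)
  if (check_unique) {
    n_occ <- .count_occurrences(seq, strand_string) +
      .count_occurrences(seq, revcomp(strand_string))
    # palindromic PAM+spacer would be double-counted; planted strings are
    # random 32-mers so treat > expected as a spurious duplicate
    if (n_occ > (1L + as.integer(strand_string == revcomp(strand_string))))
      stop("spurious duplicate: planted site occurs elsewhere in the genome")
  }
  dataset$genome[[seq_name]] <- seq
  dataset$occupied[[seq_name]] <- rbind(occ, data.frame(start = fp[1],
                                                        end = fp[2]))
  dataset
}

.count_occurrences <- function(seq, pattern) {
  m <- gregexpr(pattern, seq, fixed = TRUE)[[1]]
  if (length(m) == 1 && m[1] == -1) 0L else length(m)
}

# Protospacer forward start for a PAM-proximal anchor at gene-strand offset.
.start_for_offset <- function(tss, gene_strand, offset, L, pam_side) {
  anchor <- if (gene_strand == "+") tss + offset else tss - offset
  if (pam_side == "5prime") {
    if (gene_strand == "+") anchor else anchor - L + 1L
  } else {
    if (gene_strand == "+") anchor - L + 1L else anchor
  }
}

#' Plant an on-target protospacer upstream of a gene
#'
#' Writes PAM + spacer in gene-strand orientation so that the PAM-proximal
#' protospacer base sits at the requested gene-strand-relative TSS offset
#' (negative upstream), and records the ground truth.
#'
#' @param dataset A `synthetic_dataset`.
#' @param gene_id Gene (must be planted already).
#' @param spacer Spacer sequence (A/C/G/T).
#' @param tss_offset Signed gene-strand-relative offset of the PAM-proximal
#'   base.
#' @param rule The `rule_set` defining PAM and side (default Cascade).
#' @return The updated dataset.
#' @export
plant_on_target <- function(dataset, gene_id, spacer, tss_offset,
                            rule = cascade_rule()) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  spacer <- toupper(spacer)
  .check_alphabet(spacer, allow_n = FALSE, what = "spacer")
  g <- dataset$tss[dataset$tss$gene_id == gene_id, ]
  if (nrow(g) != 1) stop("unknown gene_id: ", gene_id)
  L <- nchar(spacer)
  start <- .start_for_offset(g$tss, g$strand, tss_offset, L, rule$pam_side)
  dataset <- .plant_site(dataset, g$seq_name, g$strand, start, spacer, rule)
  dataset$truth <- rbind(dataset$truth, data.frame(
    kind = "on_target", gene_id = gene_id, seq_name = g$seq_name,
    strand = g$strand, start = as.integer(start),
    end = as.integer(start + L), spacer_ref = spacer, variant = spacer,
    mismatch_positions = "", effective = 0L,
    tss_offset = as.integer(tss_offset), detectable = TRUE,
    promoter_retained = NA, stringsAsFactors = FALSE))
  dataset
}

#' Plant an off-target decoy
#'
#' Substitutes the Watson-Crick complement at each listed PAM-proximal
#' position of the reference spacer and plants PAM + variant either at a
#' stated TSS offset of a gene or at a random non-colliding locus (bounded
#' retries, deterministic given the RNG state). Truth records the effective
#' (non-masked) mismatch count and whether the site should be detected
#' under the rule's cap.
#'
#' @param dataset A `synthetic_dataset`.
#' @param spacer_ref Reference spacer (A/C/G/T).
#' @param mismatch_positions 1-based PAM-proximal positions to mutate.
#' @param rule The generating `rule_set` (default Cascade).
#' @param near_gene,tss_offset Plant at this gene-strand-relative offset of
#'   this gene; both `NULL` for random placement.
#' @param seq_name Sequence for random placement (default: first).
#' @param max_tries Retry budget for random placement (default 100).
#' @param check_unique Reject placements whose PAM+variant occurs elsewhere
#'   (default `TRUE`; disable to plant deliberate copies of one site).
#' @return The updated dataset.
#' @export
plant_decoy <- function(dataset, spacer_ref, mismatch_positions = integer(0),
                        rule = cascade_rule(), near_gene = NULL,
                        tss_offset = NULL, seq_name = NULL,
                        max_tries = 100L, check_unique = TRUE) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  spacer_ref <- toupper(spacer_ref)
  .check_alphabet(spacer_ref, allow_n = FALSE, what = "spacer_ref")
  L <- nchar(spacer_ref)
  mismatch_positions <- sort(unique(as.integer(mismatch_positions)))
  if (length(mismatch_positions) > 0 &&
      (min(mismatch_positions) < 1 || max(mismatch_positions) > L))
    stop("mismatch positions outside [1, spacer length]")
  # positions are PAM-proximal; map to 5'->3' string indices
  idx53 <- if (rule$pam_side == "5prime") mismatch_positions
           else L - mismatch_positions + 1L
  variant <- spacer_ref
  for (i in idx53)
    substr(variant, i, i) <- .complement_chr(substr(spacer_ref, i, i))
  effective <- sum(!(mismatch_positions %in% rule$mask$masked))
  detectable <- effective <= rule$max_mismatches
  plen <- nchar(rule$pam)
  if (!is.null(near_gene)) {
    if (is.null(tss_offset)) stop("tss_offset required with near_gene")
    g <- dataset$tss[dataset$tss$gene_id == near_gene, ]
    if (nrow(g) != 1) stop("unknown gene_id: ", near_gene)
    start <- .start_for_offset(g$tss, g$strand, tss_offset, L, rule$pam_side)
    strand <- g$strand
    sn <- g$seq_name
    dataset <- .plant_site(dataset, sn, strand, start, variant, rule,
                           check_unique)
  } else {
    sn <- if (is.null(seq_name)) names(dataset$genome)[1] else seq_name
    len <- nchar(dataset$genome[[sn]])
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      strand <- sample(c("+", "-"), 1)
      start <- sample.int(len - L - 2L * plen, 1) + plen - 1L
      ok <- tryCatch({
        dataset2 <- .plant_site(dataset, sn, strand, start, variant, rule,
                                check_unique)
        TRUE
      }, error = function(e) FALSE)
      if (ok) { dataset <- dataset2; placed <- TRUE; break }
    }
    if (!placed)
      stop("could not place decoy without collision after ", max_tries,
           " attempts")
    tss_offset <- NA_integer_
  }
  dataset$truth <- rbind(dataset$truth, data.frame(
    kind = "decoy",
    gene_id = if (is.null(near_gene)) NA_character_ else near_gene,
    seq_name = sn, strand = strand, start = as.integer(start),
    end = as.integer(start + L), spacer_ref = spacer_ref, variant = variant,
    mismatch_positions = paste(mismatch_positions, collapse = ","),
    effective = as.integer(effective),
    tss_offset = as.integer(tss_offset), detectable = detectable,
    promoter_retained = NA, stringsAsFactors = FALSE))
  dataset
}

#' Finalise truth annotations against the dataset's promoters
#'
#' Fills `promoter_retained` for every truth record: whether the planted
#' protospacer overlaps any ±`half_width` promoter interval (and is
#' detectable), computed from the actual planted coordinates.
#'
#' @param dataset A `synthetic_dataset`.
#' @param half_width Promoter half-width (default 2000).
#' @return The updated dataset.
#' @export
finalize_truth <- function(dataset, half_width = 2000L) {
  if (nrow(dataset$truth) == 0 || nrow(dataset$tss) == 0) return(dataset)
  prom <- build_promoters(dataset$tss, dataset$genome, half_width)
  tg <- GenomicRanges::GRanges(dataset$truth$seq_name,
                               IRanges::IRanges(dataset$truth$start + 1L,
                                                dataset$truth$end))
  pgr <- GenomicRanges::GRanges(prom$seq_name,
                                IRanges::IRanges(prom$start + 1L, prom$end))
  overlaps <- GenomicRanges::countOverlaps(tg, pgr) > 0
  dataset$truth$promoter_retained <- dataset$truth$detectable & overlaps
  dataset
}

#' Write a synthetic dataset to disk
#'
#' Emits `genome.fa`, `tss.bed` (BED6, one 1-bp feature per TSS) and
#' `truth.tsv`, deterministically.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_truth <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             bed = file.path(dir, "tss.bed"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(dataset$genome, paths[["fasta"]])
  write_tss_bed(dataset$tss, paths[["bed"]])
  utils::write.table(dataset$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Simulate a complete study dataset
#'
#' Builds a seeded genome with annotated genes on alternating strands, one
#' on-target protospacer per gene in the optimal window (offset -150), and
#' a panel of decoys per gene covering the interesting regimes:
#' masked-position-only mismatches (effective 0), moderate non-masked
#' mismatches (effective 2, at a random locus and at promoter-proximal and
#' promoter-distal planted offsets), and an undetectable decoy
#' (effective 5).
#'
#' @param seed Integer seed for all randomness.
#' @param n_genes Number of genes (default 2).
#' @param seq_length Genome length in bp (default 30000).
#' @param spacer_len Spacer length (default 32).
#' @param rule Generating `rule_set` (default Cascade).
#' @return A finalised `synthetic_dataset`.
#' @export
simulate_dataset <- function(seed, n_genes = 2L, seq_length = 30000L,
                             spacer_len = 32L, rule = cascade_rule()) {
  set.seed(seed)
  genome <- generate_genome(1L, seq_length, gc = 0.41)
  ds <- new_dataset(genome)
  tss_pos <- round(seq_length * seq_len(n_genes) / (n_genes + 1))
  strands <- rep(c("+", "-"), length.out = n_genes)
  for (i in seq_len(n_genes))
    ds <- plant_gene(ds, "seq1", tss_pos[i], strands[i],
                     sprintf("gene%02d", i))
  masked <- rule$mask$masked
  nonmasked <- setdiff(seq_len(spacer_len), masked)
  spacers <- vapply(seq_len(n_genes), function(i)
    paste0(sample(c("A", "C", "G", "T"), spacer_len, replace = TRUE),
           collapse = ""), character(1))
  # fixed-offset plants first for every gene, so that random loci can only
  # ever collide with an already-placed footprint and retry
  for (i in seq_len(n_genes)) {
    gid <- sprintf("gene%02d", i)
    ds <- plant_on_target(ds, gid, spacers[i], -150L, rule)
    ds <- plant_decoy(ds, spacers[i], nonmasked[c(2, 5)], rule,
                      near_gene = gid, tss_offset = -1500L)  # in promoter
    ds <- plant_decoy(ds, spacers[i], nonmasked[c(3, 6)], rule,
                      near_gene = gid, tss_offset = 2500L)   # outside
  }
  for (i in seq_len(n_genes)) {
    ds <- plant_decoy(ds, spacers[i], masked[seq_len(min(3, length(masked)))],
                      rule)                                      # effective 0
    ds <- plant_decoy(ds, spacers[i], nonmasked[c(1, 4)], rule)  # effective 2
    ds <- plant_decoy(ds, spacers[i], nonmasked[1:5], rule)      # effective 5
  }
  finalize_truth(ds)
}

#' Classify every planted truth record with the full pipeline
#'
#' Runs the off-target enumerator for each reference spacer, applies the
#' promoter filter, and compares the observed outcome of every planted
#' feature (detected / retained and its effective count) against the
#' ground-truth prediction.
#'
#' @param dataset A finalised `synthetic_dataset`.
#' @param rule The `rule_set` used when planting.
#' @param half_width Promoter half-width (default 2000).
#' @return The truth `data.frame` with `observed_detected`,
#'   `observed_effective`, `observed_retained` and `agrees` columns.
#' @export
evaluate_truth <- function(dataset, rule = cascade_rule(),
                           half_width = 2000L) {
  truth <- dataset$truth
  prom <- if (nrow(dataset$tss) > 0)
    build_promoters(dataset$tss, dataset$genome, half_width) else NULL
  truth$observed_detected <- FALSE
  truth$observed_effective <- NA_integer_
  truth$observed_retained <- FALSE
  for (sp in unique(truth$spacer_ref)) {
    hits <- enumerate_offtargets(sp, dataset$genome, rule)
    filt <- if (!is.null(prom)) promoter_filter(hits, prom, rule$pam_side)
            else hits
    rows <- which(truth$spacer_ref == sp)
    for (i in rows) {
      j <- which(hits$seq_name == truth$seq_name[i] &
                   hits$strand == truth$strand[i] &
                   hits$start == truth$start[i])
      if (length(j) == 1) {
        truth$observed_detected[i] <- TRUE
        truth$observed_effective[i] <- hits$effective[j]
      }
      truth$observed_retained[i] <- any(
        filt$seq_name == truth$seq_name[i] &
          filt$strand == truth$strand[i] & filt$start == truth$start[i])
    }
  }
  truth$agrees <- truth$observed_detected == truth$detectable &
    (!truth$observed_detected | truth$observed_effective == truth$effective) &
    (is.na(truth$promoter_retained) |
       truth$observed_retained == truth$promoter_retained)
  truth
}
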