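# Orchestration: validated run configuration and the design / off-target /
# simulate stages with deterministic file outputs. The numbered scripts
# under analysis/ are thin drivers over these functions.

#' Build and validate a run configuration
#'
#' Defaults are the type I-F study parameters: 5'-CC PAM, 32-nt spacer,
#' tolerated positions {6, 12, 18, 24-32}, at most 4 effective mismatches,
#' 2-kb promoter half-width, design range 500-100 bp upstream of the TSS,
#' optimal window 200-100 bp upstream, optimal pair spacing 50-75 bp.
#'
#' @param fasta,tss Optional input paths (FASTA; BED6/GFF3).
#' @param tss_format `"bed"` or `"gff3"`.
#' @param out_dir Output directory.
#' @param pam IUPAC PAM pattern.
#' @param spacer_len Spacer length in nt.
#' @param masked Masked (tolerated) positions; `NULL` for the default mask.
#' @param max_mismatches Effective-mismatch cap.
#' @param promoter_half_width Promoter half-width in bp.
#' @param design_range,optimal_window Gene-strand-relative offset intervals.
#' @param pair_spacing Optimal pair-spacing interval in bp.
#' @param seed Integer seed.
#' @return A validated object of class `run_config`.
#' @export
run_config <- function(fasta = NULL, tss = NULL, tss_format = "bed",
                       out_dir = ".", pam = "CC", spacer_len = 32L,
                       masked = NULL, max_mismatches = 4L,
                       promoter_half_width = 2000L,
                       design_range = c(-500L, -100L),
                       optimal_window = c(-200L, -100L),
                       pair_spacing = c(50L, 75L), seed = 1L) {
  cfg <- structure(list(
    fasta = fasta, tss = tss, tss_format = tss_format, out_dir = out_dir,
    pam = toupper(pam), spacer_len = as.integer(spacer_len),
    masked = if (is.null(masked)) default_masked_positions(spacer_len)
             else sort(unique(as.integer(masked))),
    max_mismatches = as.integer(max_mismatches),
    promoter_half_width = as.integer(promoter_half_width),
    design_range = as.integer(design_range),
    optimal_window = as.integer(optimal_window),
    pair_spacing = as.integer(pair_spacing),
    seed = as.integer(seed)), class = "run_config")
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' @param cfg A `run_config`.
#' @return The config, invisibly; stops with an informative message on the
#'   first invalid parameter.
#' @export
validate_config <- function(cfg) {
  if (!inherits(cfg, "run_config")) stop("not a run_config")
  .iupac_regex(cfg$pam)
  if (cfg$spacer_len < 6) stop("config: spacer_len must be >= 6")
  if (length(cfg$masked) > 0 &&
      (min(cfg$masked) < 1 || max(cfg$masked) > cfg$spacer_len))
    stop("config: masked positions outside [1, spacer_len]")
  if (cfg$max_mismatches < 0) stop("config: max_mismatches must be >= 0")
  if (cfg$promoter_half_width <= 0)
    stop("config: promoter_half_width must be positive")
  for (nm in c("design_range", "optimal_window", "pair_spacing")) {
    v <- cfg[[nm]]
    if (length(v) != 2 || v[1] > v[2])
      stop("config: ", nm, " must be an ordered interval")
  }
  if (!cfg$tss_format %in% c("bed", "gff3"))
    stop("config: tss_format must be 'bed' or 'gff3'")
  invisible(cfg)
}

#' Write a config as a plain-text key-value file and read it back
#'
#' @param cfg A `run_config`.
#' @param path File path.
#' @return `write_config`: the path invisibly. `read_config`: a
#'   `run_config`.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  fmt <- function(v) if (is.null(v)) "" else paste(v, collapse = ",")
  lines <- vapply(names(unclass(cfg)), function(nm)
    paste0(nm, " = ", fmt(cfg[[nm]])), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, function(x) if (length(x) > 1) x[2] else ""),
                          vapply(kv, `[`, character(1), 1))
  num <- function(x) as.integer(strsplit(x, ",")[[1]])
  chr <- function(x) if (nzchar(x)) x else NULL
  run_config(
    fasta = chr(vals$fasta), tss = chr(vals$tss),
    tss_format = vals$tss_format, out_dir = vals$out_dir, pam = vals$pam,
    spacer_len = num(vals$spacer_len), masked = num(vals$masked),
    max_mismatches = num(vals$max_mismatches),
    promoter_half_width = num(vals$promoter_half_width),
    design_range = num(vals$design_range),
    optimal_window = num(vals$optimal_window),
    pair_spacing = num(vals$pair_spacing), seed = num(vals$seed))
}

.cfg_rule <- function(cfg) {
  rule_set("cascade_if", cfg$spacer_len, cfg$pam, "5prime",
           position_mask(cfg$spacer_len, masked = cfg$masked),
           cfg$max_mismatches)
}

.load_inputs <- function(cfg, genome, tss_records) {
  if (is.null(genome)) {
    if (is.null(cfg$fasta)) stop("no genome: supply cfg$fasta or genome")
    genome <- read_fasta(cfg$fasta)
  }
  if (is.null(tss_records) && !is.null(cfg$tss))
    tss_records <- read_tss(cfg$tss, cfg$tss_format, genome)
  list(genome = genome, tss = tss_records)
}

#' Run the guide-design stage
#'
#' Extracts, ranks and pairs candidates and writes `candidates.tsv`,
#' `candidates.bed` and `pairs.tsv` under the config's output directory.
#' Re-running with identical inputs produces byte-identical outputs.
#'
#' @param cfg A `run_config`.
#' @param genome,tss_records In-memory inputs (override the config paths).
#' @return Invisibly, a list with `candidates` and `pairs`.
#' @export
run_design <- function(cfg, genome = NULL, tss_records = NULL) {
  validate_config(cfg)
  io <- .load_inputs(cfg, genome, tss_records)
  if (is.null(io$tss) || nrow(io$tss) == 0)
    stop("design stage: no TSS records supplied")
  cands <- extract_candidates(io$genome, io$tss, cfg$spacer_len,
                              cfg$design_range, cfg$optimal_window,
                              pam = cfg$pam)
  cands <- rank_candidates(cands)
  pairs <- select_pairs(cands, cfg$pair_spacing)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cands, file.path(cfg$out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_candidates_bed(cands, file.path(cfg$out_dir, "candidates.bed"))
  utils::write.table(pairs, file.path(cfg$out_dir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(candidates = cands, pairs = pairs))
}

#' Run the off-target stage
#'
#' Enumerates off-targets for each query spacer under the config's Cascade
#' rule, applies the promoter filter when TSS annotations are available
#' (otherwise warns and reports unfiltered hits), and writes one TSV per
#' spacer plus a merged BED.
#'
#' @param cfg A `run_config`.
#' @param spacers Named or unnamed character vector of query spacers.
#' @param genome,tss_records In-memory inputs (override the config paths).
#' @return Invisibly, a named list of hit `data.frame`s.
#' @export
run_offtarget <- function(cfg, spacers, genome = NULL, tss_records = NULL) {
  validate_config(cfg)
  if (length(spacers) == 0) stop("no spacers supplied")
  io <- .load_inputs(cfg, genome, tss_records)
  rule <- .cfg_rule(cfg)
  promoters <- if (!is.null(io$tss) && nrow(io$tss) > 0)
    build_promoters(io$tss, io$genome, cfg$promoter_half_width) else NULL
  if (is.null(promoters))
    warning("no TSS annotations: reporting unfiltered off-target hits")
  if (is.null(names(spacers)))
    names(spacers) <- sprintf("spacer%02d", seq_along(spacers))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  all_hits <- list()
  for (nm in names(spacers)) {
    hits <- enumerate_offtargets(spacers[[nm]], io$genome, rule)
    if (!is.null(promoters)) hits <- promoter_filter(hits, promoters)
    write_hits(hits, tsv_path = file.path(cfg$out_dir,
                                          paste0("offtargets_", nm, ".tsv")))
    all_hits[[nm]] <- hits
  }
  merged <- do.call(rbind, c(all_hits, make.row.names = FALSE))
  keep <- intersect(colnames(.empty_hits()), colnames(merged))
  write_hits(merged[, keep, drop = FALSE],
             bed_path = file.path(cfg$out_dir, "offtargets.bed"))
  invisible(all_hits)
}

#' Run the simulation stage
#'
#' Generates a seeded synthetic dataset and writes it (FASTA + BED6 + truth
#' TSV) under the config's output directory.
#'
#' @param cfg A `run_config`.
#' @param n_genes,seq_length Passed to [simulate_dataset()].
#' @return Invisibly, the `synthetic_dataset`.
#' @export
run_simulate <- function(cfg, n_genes = 2L, seq_length = 30000L) {
  validate_config(cfg)
  ds <- simulate_dataset(cfg$seed, n_genes = n_genes,
                         seq_length = seq_length,
                         spacer_len = cfg$spacer_len, rule = .cfg_rule(cfg))
  write_truth(ds, cfg$out_dir)
  invisible(ds)
}
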