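# Internal helpers shared across modules. All genomic coordinates inside the
# package are 0-based half-open on the forward axis; substr() below is the
# only place the 1-based shift happens.

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Genome N never matches any PAM letter, so every class excludes N.
.iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(.IUPAC_SETS))
  if (length(bad) > 0)
    stop("invalid IUPAC character(s) in PAM pattern: ", paste(bad, collapse = ", "))
  paste0(vapply(chars, function(ch) {
    set <- .IUPAC_SETS[[ch]]
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# Concrete instantiation of an IUPAC pattern (first base of each class),
# used when planting synthetic sites that must carry a valid PAM.
.iupac_concrete <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  paste0(vapply(chars, function(ch) .IUPAC_SETS[[ch]][1], character(1)),
         collapse = "")
}

# Extract [start, end) (0-based half-open) from a sequence string.
.seq_window <- function(seq, start, end) substr(seq, start + 1L, end)

# Replace [start, start + nchar(replacement)) in a sequence string.
.replace_window <- function(seq, start, replacement) {
  substr(seq, start + 1L, start + nchar(replacement)) <- replacement
  seq
}

.complement_chr <- function(x) chartr("ACGTN", "TGCAN", x)

.check_alphabet <- function(x, allow_n = TRUE, what = "sequence") {
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  if (any(grepl(pat, x)))
    stop(what, " contains characters outside ",
         if (allow_n) "{A,C,G,T,N}" else "{A,C,G,T}")
  invisible(x)
}

# All match positions (1-based) of a perl regex, overlapping allowed.
.match_positions <- function(string, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), string, perl = TRUE)[[1]]
  if (length(m) == 1 && m[1] == -1) integer(0) else as.integer(m)
}

.empty_hits <- function() {
  data.frame(
    seq_name = character(0), strand = character(0),
    start = integer(0), end = integer(0),
    site_seq = character(0), site_display = character(0),
    pam_observed = character(0), mismatch_positions = character(0),
    n_mismatches = integer(0), effective = integer(0),
    is_exact = logical(0), stringsAsFactors = FALSE
  )
}
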