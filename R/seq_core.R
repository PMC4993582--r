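# Nucleotide / codon primitives: coding sequences, complement arithmetic,
# translation, GC content.  Coordinates are 1-based inclusive; the reading
# frame is anchored at base 1, so codon i occupies bases 3*(i-1)+1 .. 3*i.

#' Construct a validated in-frame coding sequence
#'
#' A `coding_sequence` holds the sense-strand bases of an ORF (5'->3'),
#' uppercased and restricted to the alphabet A, C, G, T.  Residue index i on
#' the encoded protein maps 1:1 onto codon i, which occupies bases
#' `3*(i-1)+1 .. 3*i`.  The input must be the CDS itself, not a full plasmid:
#' protein numbering (e.g. K60, H61) only lines up when base 1 starts codon 1.
#'
#' @param bases Character scalar of nucleotides; lowercase accepted, `U`
#'   rejected (primers are DNA oligos).
#' @param id Label for the sequence.
#' @return An object of class `coding_sequence` with fields `id`, `bases`,
#'   `n_codons`.
#' @examples
#' cds <- coding_sequence("ATGAAACATGGC", id = "toy")
#' cds_codon(cds, 2)
#' @export
coding_sequence <- function(bases, id = "cds") {
  stopifnot(is.character(bases), length(bases) == 1L)
  bases <- toupper(bases)
  validate_nt(bases)
  if (nchar(bases) < 3L)
    stop("coding sequence must be at least one codon (3 bases) long", call. = FALSE)
  if (nchar(bases) %% 3L != 0L)
    warning(sprintf("sequence length %d is not a multiple of 3; trailing %d base(s) are ignored for codon arithmetic",
                    nchar(bases), nchar(bases) %% 3L))
  structure(
    list(id = as.character(id), bases = bases,
         n_codons = nchar(bases) %/% 3L),
    class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("coding_sequence '%s': %d nt, %d codons\n",
              x$id, nchar(x$bases), x$n_codons))
  invisible(x)
}

#' @export
length.coding_sequence <- function(x) nchar(x$bases)

# validation shared by all nucleotide-string entry points; names the first
# offending position, per the module error contract
validate_nt <- function(seq) {
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L)
    stop(sprintf("invalid nucleotide '%s' at position %d (alphabet is A/C/G/T)",
                 substr(seq, bad, bad), bad), call. = FALSE)
  invisible(seq)
}

#' Read a coding sequence from a FASTA file
#'
#' Single- or multi-record FASTA is accepted; the first record is used unless
#' `seq_id` selects another by name.
#'
#' @param path Path to a FASTA file.
#' @param seq_id Optional record name to select.
#' @return A [coding_sequence()].
#' @export
read_cds_fasta <- function(path, seq_id = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  idx <- 1L
  if (!is.null(seq_id)) {
    # FASTA headers often carry descriptions after the id token
    ids <- sub("\\s.*$", "", names(set))
    idx <- match(seq_id, ids)
    if (is.na(idx))
      stop("no FASTA record named '", seq_id, "' in ", path, call. = FALSE)
  }
  coding_sequence(as.character(set[[idx]]), id = sub("\\s.*$", "", names(set)[idx]))
}

#' Reverse complement of a DNA string
#'
#' Mutagenic forward and reverse primers are fully complementary, so the
#' reverse primer is always the reverse complement of the forward one.
#' Applying the operation twice returns the input.
#'
#' @param seq Character scalar over A/C/G/T (lowercase uppercased first).
#' @return The reverse complement, 5'->3'.
#' @examples
#' reverse_complement("ATGC")  # "GCAT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  validate_nt(seq)
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Extract codon i from a coding sequence
#'
#' @param cds A [coding_sequence()].
#' @param residue_index 1-based protein residue index.
#' @return Three-base codon string.
#' @export
cds_codon <- function(cds, residue_index) {
  stopifnot(inherits(cds, "coding_sequence"))
  i <- as.integer(residue_index)
  if (is.na(i) || i < 1L || i > cds$n_codons)
    stop(sprintf("residue index %s out of range (sequence has %d codons)",
                 as.character(residue_index), cds$n_codons), call. = FALSE)
  substr(cds$bases, 3L * (i - 1L) + 1L, 3L * i)
}

#' Translate one codon of a coding sequence
#'
#' Standard genetic code; stop is returned as `"*"`.
#'
#' @inheritParams cds_codon
#' @return Single-letter amino acid (or `"*"`).
#' @export
translate_residue <- function(cds, residue_index) {
  translate_codon(cds_codon(cds, residue_index))
}

#' Translate a codon string under the standard genetic code
#' @param codon Three-base string.
#' @return Single-letter amino acid or `"*"` for stop.
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L) stop("codon must be exactly 3 bases", call. = FALSE)
  validate_nt(codon)
  unname(Biostrings::GENETIC_CODE[[codon]])
}

# full translation, used by design invariants ("exactly one residue changes")
translate_cds <- function(bases) {
  n <- nchar(bases) %/% 3L
  starts <- 3L * (seq_len(n) - 1L) + 1L
  paste(vapply(starts, function(s) Biostrings::GENETIC_CODE[[substr(bases, s, s + 2L)]],
               character(1)), collapse = "")
}

#' GC content of a nucleotide string, in percent
#'
#' Returns the unrounded value `100 * (#G + #C) / length`.  Reports round to
#' the nearest integer, half away from zero, via [report_percent()].
#'
#' @param seq Character scalar over A/C/G/T.
#' @return Percentage in `[0, 100]`.
#' @examples
#' gc_percent("GGCC")  # 100
#' @export
gc_percent <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty sequence has no GC content", call. = FALSE)
  validate_nt(seq)
  n_gc <- nchar(gsub("[AT]", "", seq))
  100 * n_gc / nchar(seq)
}

#' Presentation rounding for percentages
#'
#' Nearest integer, half away from zero (so 51.5 -> 52), the convention used
#' for printed GC values in primer sheets.
#'
#' @param x Numeric vector of percentages.
#' @return Integer vector.
#' @export
report_percent <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' The standard codon table with usage weights
#'
#' Maps all 64 codons to single-letter amino acids (stop = `"*"`), keeps the
#' reverse amino-acid -> codon index, and carries positive per-codon usage
#' weights used only to break ties between equally distant candidate codons.
#' The default weights are human codon-usage frequencies (per 1000 codons).
#'
#' @param weights Named numeric vector of positive per-codon weights covering
#'   all 64 codons; defaults to the built-in human usage table.
#' @return An object of class `codon_table` with fields `aa` (codon -> aa),
#'   `codons` (aa -> codon vector) and `weights`.
#' @export
codon_table <- function(weights = human_codon_usage()) {
  aa <- Biostrings::GENETIC_CODE
  if (!all(names(aa) %in% names(weights)))
    stop("weights must cover all 64 codons", call. = FALSE)
  weights <- weights[names(aa)]
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("codon usage weights must be positive", call. = FALSE)
  structure(
    list(aa = aa,
         codons = split(names(aa), unname(aa)),
         weights = weights),
    class = "codon_table")
}

#' Human codon usage frequencies
#'
#' Standard human codon-usage table (occurrences per 1000 codons); used as the
#' default tie-break weighting in [choose_mutant_codon()].
#'
#' @return Named numeric vector of length 64.
#' @export
human_codon_usage <- function() {
  c(TTT = 17.6, TTC = 20.3, TTA = 7.7, TTG = 12.9,
    CTT = 13.2, CTC = 19.6, CTA = 7.2, CTG = 39.6,
    ATT = 16.0, ATC = 20.8, ATA = 7.5, ATG = 22.0,
    GTT = 11.0, GTC = 14.5, GTA = 7.1, GTG = 28.1,
    TCT = 15.2, TCC = 17.7, TCA = 12.2, TCG = 4.4,
    CCT = 17.5, CCC = 19.8, CCA = 16.9, CCG = 6.9,
    ACT = 13.1, ACC = 18.9, ACA = 15.1, ACG = 6.1,
    GCT = 18.4, GCC = 27.7, GCA = 15.8, GCG = 7.4,
    TAT = 12.2, TAC = 15.3, TAA = 1.0, TAG = 0.8,
    CAT = 10.9, CAC = 15.1, CAA = 12.3, CAG = 34.2,
    AAT = 17.0, AAC = 19.1, AAA = 24.4, AAG = 31.9,
    GAT = 21.8, GAC = 25.1, GAA = 29.0, GAG = 39.6,
    TGT = 10.6, TGC = 12.6, TGA = 1.6, TGG = 13.2,
    CGT = 4.5, CGC = 10.4, CGA = 6.2, CGG = 11.4,
    AGT = 12.1, AGC = 19.5, AGA = 12.2, AGG = 12.0,
    GGT = 10.8, GGC = 22.2, GGA = 16.5, GGG = 16.5)
}
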