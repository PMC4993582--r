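# Standardized n+3+n mutagenic primer design.  A primer of odd length N = 2n+3
# carries the mutant codon in the center flanked by n template-matching bases
# on each side; the reverse primer is the full reverse complement (the two
# oligos are fully complementary, as in whole-plasmid inverse-PCR mutagenesis).

hamming3 <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Choose a mutant codon with the minimal number of nucleotide changes
#'
#' Among all codons encoding `target_aa`, returns one at minimal Hamming
#' distance from the wild-type codon.  Ties are broken by the table's codon
#' usage weights (highest first), then lexicographically, so the choice is
#' deterministic.
#'
#' @param wt_codon Wild-type codon (3 bases).
#' @param target_aa Single-letter target amino acid; `"*"` (stop) only with
#'   `allow_stop = TRUE`.
#' @param table A [codon_table()].
#' @param tie_break `"usage"` (default: highest usage weight, then
#'   lexicographic) or `"lexicographic"`.
#' @param allow_stop Permit designing towards a stop codon.
#' @return List with `codon` and `mismatches` (Hamming distance, 0..3).
#' @examples
#' choose_mutant_codon("AAA", "R")  # AGA, 1 mismatch
#' @export
choose_mutant_codon <- function(wt_codon, target_aa, table = codon_table(),
                                tie_break = c("usage", "lexicographic"),
                                allow_stop = FALSE) {
  tie_break <- match.arg(tie_break)
  wt_codon <- toupper(wt_codon)
  if (nchar(wt_codon) != 3L) stop("wild-type codon must be 3 bases", call. = FALSE)
  validate_nt(wt_codon)
  target_aa <- toupper(target_aa)
  if (identical(target_aa, "*") && !allow_stop)
    stop("stop codon requested; set allow_stop = TRUE if intended", call. = FALSE)
  cands <- table$codons[[target_aa]]
  if (is.null(cands))
    stop("invalid amino acid letter '", target_aa, "'", call. = FALSE)
  d <- vapply(cands, hamming3, integer(1), a = wt_codon)
  cands <- cands[d == min(d)]
  if (length(cands) > 1L) {
    ord <- if (tie_break == "usage")
      order(-table$weights[cands], cands) else order(cands)
    cands <- cands[ord]
  }
  list(codon = cands[[1L]], mismatches = as.integer(min(d)))
}

# window of the N-mer primer for codon i: n bases left of the codon, n right
primer_window <- function(residue_index, length) {
  n <- (length - 3L) %/% 2L
  start <- 3L * (residue_index - 1L) + 1L - n
  c(start = start, end = 3L * residue_index + n)
}

check_primer_length <- function(length) {
  length <- as.integer(length)
  if (is.na(length) || length %% 2L == 0L || length < 15L)
    stop("primer length must be an odd integer >= 15 (n+3+n design)", call. = FALSE)
  if (length > 40L)
    warning("primers longer than 40 nt usually yield fewer colonies; consider the 29-mer standard")
  length
}

#' Design one standardized mutagenic primer pair
#'
#' Builds the forward primer by copying the template window centred on the
#' target codon and replacing that codon with the minimal-mismatch codon for
#' `target_aa`; the reverse primer is the full reverse complement.  GC% and
#' QuikChange Tm are annotated, as are 3'-terminal G/C flags for both strands.
#'
#' @param cds A [coding_sequence()].
#' @param residue_index Protein residue to mutate (1-based).
#' @param target_aa Single-letter target amino acid.
#' @param length Odd primer length `N = 2n+3`; default 29 (13+3+13), the
#'   standardized length.
#' @param table A [codon_table()] for codon choice.
#' @param allow_silent Allow a 0-mismatch design when `target_aa` equals the
#'   wild-type amino acid (rejected by default: no mutation introduced).
#' @param allow_stop Passed to [choose_mutant_codon()].
#' @return An object of class `primer_pair`: fields `target_id`,
#'   `residue_index`, `wt_aa`, `target_aa`, `wt_codon`, `mutant_codon`,
#'   `mismatches`, `length`, `forward`, `reverse`, `gc_percent`, `tm`,
#'   `fwd_3prime_GC`, `rev_3prime_GC`, `template_span` (c(start, end)).
#' @examples
#' cds <- coding_sequence(strrep("ATGAAACATGGC", 5), "toy")
#' design_primer_pair(cds, 6, "A")
#' @export
design_primer_pair <- function(cds, residue_index, target_aa, length = 29L,
                               table = codon_table(), allow_silent = FALSE,
                               allow_stop = FALSE) {
  stopifnot(inherits(cds, "coding_sequence"))
  length <- check_primer_length(length)
  n <- (length - 3L) %/% 2L
  residue_index <- as.integer(residue_index)
  if (residue_index < 1L || residue_index > cds$n_codons)
    stop(sprintf("residue index %d out of range (1..%d)", residue_index, cds$n_codons),
         call. = FALSE)
  win <- primer_window(residue_index, length)
  if (win["start"] < 1L || win["end"] > nchar(cds$bases)) {
    first_ok <- as.integer(ceiling(n / 3)) + 1L  # smallest i with 3(i-1)+1-n >= 1
    last_ok <- (nchar(cds$bases) - n) %/% 3L # largest i with 3i+n <= L
    stop(sprintf("flank out of range: residue %d needs bases %d..%d; designable residues are %d..%d",
                 residue_index, win["start"], win["end"], first_ok, last_ok),
         call. = FALSE)
  }
  wt_codon <- cds_codon(cds, residue_index)
  wt_aa <- translate_codon(wt_codon)
  target_aa <- toupper(target_aa)
  choice <- choose_mutant_codon(wt_codon, target_aa, table, allow_stop = allow_stop)
  if (choice$mismatches == 0L && !allow_silent)
    stop(sprintf("no mutation introduced: residue %d already encodes %s",
                 residue_index, wt_aa), call. = FALSE)
  tmpl <- substr(cds$bases, win["start"], win["end"])
  forward <- paste0(substr(tmpl, 1L, n), choice$codon,
                    substr(tmpl, n + 4L, length))
  gc <- gc_percent(forward)
  structure(
    list(target_id = paste0(wt_aa, residue_index, target_aa),
         residue_index = residue_index,
         wt_aa = wt_aa, target_aa = target_aa,
         wt_codon = wt_codon, mutant_codon = choice$codon,
         mismatches = choice$mismatches,
         length = length,
         forward = forward,
         reverse = reverse_complement(forward),
         gc_percent = gc,
         tm = tm_quikchange(gc, length, choice$mismatches),
         fwd_3prime_GC = substr(forward, length, length) %in% c("G", "C"),
         rev_3prime_GC = substr(forward, 1L, 1L) %in% c("G", "C"),
         template_span = c(start = unname(win["start"]), end = unname(win["end"]))),
    class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("%s  %d-mer (%d mismatch%s)  GC %d%%  Tm %.1f\n  F: %s\n  R: %s\n",
              x$target_id, x$length, x$mismatches,
              if (x$mismatches == 1L) "" else "es",
              report_percent(x$gc_percent), x$tm, x$forward, x$reverse))
  invisible(x)
}

#' Design an alanine-scanning primer series
#'
#' Starting from a user-chosen base position for the first primer, emits one
#' n+3+n primer pair per successive codon, each window shifted +3 bases from
#' the previous, until the window would overrun the sequence.  Codons already
#' encoding Ala are skipped with a notice; an out-of-frame start (one that
#' does not put the central triplet in frame) is advanced to the next in-frame
#' start, with a notice.
#'
#' @param cds A [coding_sequence()].
#' @param start_position 1-based base index where the first primer begins.
#' @param length Odd primer length; default 29.
#' @param table A [codon_table()].
#' @return List of [design_primer_pair()] objects (possibly empty, with a
#'   warning when nothing is designable).
#' @export
design_ala_scan <- function(cds, start_position, length = 29L,
                            table = codon_table()) {
  stopifnot(inherits(cds, "coding_sequence"))
  length <- check_primer_length(length)
  n <- (length - 3L) %/% 2L
  s <- as.integer(start_position)
  if (is.na(s) || s < 1L) stop("start position must be >= 1", call. = FALSE)
  # central codon starts at s + n; in frame iff (s + n) == 3k + 1
  shift <- (1L - (s + n)) %% 3L
  if (shift != 0L) {
    message(sprintf("start position %d is out of frame; advanced to %d", s, s + shift))
    s <- s + shift
  }
  first_codon <- (s + n - 1L) %/% 3L + 1L
  # nb: `length` (the primer length) shadows base::length() in this scope,
  # so the list is grown with c() and checked with seq_along()
  pairs <- list()
  i <- first_codon
  while (3L * i + n <= nchar(cds$bases)) {
    if (translate_residue(cds, i) == "A") {
      message(sprintf("codon %d already encodes Ala; skipped", i))
    } else {
      pairs <- c(pairs, list(
        design_primer_pair(cds, i, "A", length = length, table = table)))
    }
    i <- i + 1L
  }
  if (!any(seq_along(pairs) > 0L))
    warning("no designable non-Ala codon in range; empty primer list")
  pairs
}

#' Design a single-site multiple-substitution primer set
#'
#' One primer pair per distinct target amino acid, all sharing the identical
#' template window centred on `residue_index`.  Duplicate targets are removed;
#' a target equal to the wild-type residue is skipped with a notice.
#'
#' @inheritParams design_primer_pair
#' @param target_aas Character vector of single-letter targets.
#' @return List of `primer_pair` objects.
#' @examples
#' cds <- coding_sequence(strrep("ATGAAACATGGC", 5), "toy")
#' set <- design_multisite_set(cds, 6, c("R", "Y", "L", "P"))
#' @export
design_multisite_set <- function(cds, residue_index, target_aas, length = 29L,
                                 table = codon_table(), allow_stop = FALSE) {
  if (!any(nzchar(target_aas))) stop("target_aas must be non-empty", call. = FALSE)
  target_aas <- unique(toupper(target_aas))
  wt_aa <- translate_residue(cds, residue_index)
  pairs <- list()
  for (aa in target_aas) {
    if (aa == wt_aa) {
      message(sprintf("target %s equals the wild-type residue at %d; skipped",
                      aa, residue_index))
      next
    }
    pairs <- c(pairs, list(
      design_primer_pair(cds, residue_index, aa, length = length, table = table,
                         allow_stop = allow_stop)))
  }
  pairs
}

#' QuikChange-convention melting temperature
#'
#' `Tm = 81.5 + 0.41 * %GC - 675 / N - %mismatch`, with
#' `%mismatch = 100 * mismatches / N`.  Returned unrounded; presentation
#' rounding (nearest integer or nearest 0.5) is the caller's choice.
#'
#' @param gc_percent GC content in percent (0..100).
#' @param length Primer length N (> 0).
#' @param mismatches Number of mismatched bases (>= 0).
#' @return Tm in degrees Celsius (vectorized over the arguments).
#' @examples
#' tm_quikchange(52, 29, 1)  # 76.09
#' @export
tm_quikchange <- function(gc_percent, length, mismatches = 0L) {
  if (any(length <= 0)) stop("primer length must be positive", call. = FALSE)
  if (any(gc_percent < 0 | gc_percent > 100))
    stop("gc_percent must lie in [0, 100]", call. = FALSE)
  if (any(mismatches < 0)) stop("mismatches must be >= 0", call. = FALSE)
  81.5 + 0.41 * gc_percent - 675 / length - 100 * mismatches / length
}

#' Round a temperature to the nearest 0.5 degree
#' @param x Numeric vector.
#' @return Numeric vector on a 0.5 grid.
#' @export
round_half_degree <- function(x) round(x * 2) / 2

#' Built-in restriction enzyme recognition sites
#'
#' A small user-extendable dictionary of common 6-cutters used for diagnostic
#' digests of mutagenesis products.
#'
#' @return Named character vector (enzyme -> recognition site, 5'->3').
#' @export
default_enzymes <- function() {
  c(XbaI = "TCTAGA", BglII = "AGATCT", SalI = "GTCGAC", EcoRI = "GAATTC",
    BamHI = "GGATCC", HindIII = "AAGCTT", NheI = "GCTAGC", XhoI = "CTCGAG",
    PstI = "CTGCAG", KpnI = "GGTACC")
}

# all 1-based start positions of `site` in `seq`, scanning both strands;
# minus-strand hits are reported in plus-strand coordinates of the site start
site_positions <- function(seq, site) {
  find <- function(s, pat) {
    hits <- gregexpr(pat, s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) integer(0) else as.integer(hits)
  }
  fwd <- find(seq, site)
  rc <- reverse_complement(site)
  rev <- if (rc == site) integer(0) else find(seq, rc)
  sort(unique(c(fwd, rev)))
}

#' Restriction sites gained and lost by a substitution
#'
#' Scans equal-length wild-type and mutant regions (both strands) for each
#' enzyme's recognition site and reports sites present only in the mutant
#' (gained) or only in the wild type (lost), with 1-based start positions.
#' Classic use: confirming a designed mutation by diagnostic digest, e.g. a
#' substitution that introduces an XbaI site or destroys a BglII site.
#'
#' @param wt_region,mut_region Equal-length nucleotide strings.
#' @param enzymes Named character vector of recognition sites;
#'   defaults to [default_enzymes()].
#' @return List with `gained` and `lost`, each a named list of integer
#'   position vectors (only enzymes with changes are listed).
#' @export
restriction_site_diff <- function(wt_region, mut_region,
                                  enzymes = default_enzymes()) {
  wt_region <- toupper(wt_region); mut_region <- toupper(mut_region)
  if (nchar(wt_region) != nchar(mut_region))
    stop("wild-type and mutant regions must have equal length", call. = FALSE)
  validate_nt(wt_region); validate_nt(mut_region)
  if (is.null(names(enzymes)) || any(!nzchar(names(enzymes))))
    stop("enzymes must be a named vector of recognition sites", call. = FALSE)
  gained <- list(); lost <- list()
  for (enz in names(enzymes)) {
    w <- site_positions(wt_region, toupper(enzymes[[enz]]))
    m <- site_positions(mut_region, toupper(enzymes[[enz]]))
    g <- setdiff(m, w); l <- setdiff(w, m)
    if (length(g)) gained[[enz]] <- g
    if (length(l)) lost[[enz]] <- l
  }
  list(gained = gained, lost = lost)
}
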