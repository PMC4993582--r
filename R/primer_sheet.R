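# TSV primer sheets: one row per designed pair, round-trippable.

#' Tabulate primer pairs as a primer sheet
#'
#' @param pairs List of `primer_pair` objects.
#' @return A data.frame with one row per pair and the documented sheet
#'   columns (`target_id`, `residue_index`, ..., `template_span_end`).
#' @export
primer_sheet <- function(pairs) {
  if (inherits(pairs, "primer_pair")) pairs <- list(pairs)
  stopifnot(all(vapply(pairs, inherits, logical(1), "primer_pair")))
  do.call(rbind, lapply(pairs, function(p) {
    data.frame(
      target_id = p$target_id,
      residue_index = p$residue_index,
      wt_aa = p$wt_aa, target_aa = p$target_aa,
      wt_codon = p$wt_codon, mutant_codon = p$mutant_codon,
      mismatches = p$mismatches, length = p$length,
      forward_5to3 = p$forward, reverse_5to3 = p$reverse,
      gc_percent = p$gc_percent, tm = p$tm,
      fwd_3prime_GC = p$fwd_3prime_GC, rev_3prime_GC = p$rev_3prime_GC,
      template_span_start = p$template_span[["start"]],
      template_span_end = p$template_span[["end"]],
      stringsAsFactors = FALSE)
  }))
}

#' Write a primer sheet to TSV
#'
#' Tab-separated, header row, UTF-8, '.' decimal; provenance lines (tool
#' version, config hash, seed) are prepended as '#' comments.
#'
#' @param pairs List of `primer_pair` objects (or a [primer_sheet()] frame).
#' @param path Output file; `""` writes to stdout.
#' @param seed Optional seed recorded in the header.
#' @return Invisibly, the data.frame written.
#' @export
write_primer_sheet <- function(pairs, path = "", seed = NULL) {
  df <- if (is.data.frame(pairs)) pairs else primer_sheet(pairs)
  write_tsv_with_header(df, path, seed = seed)
}

#' Read a primer sheet written by [write_primer_sheet()]
#'
#' @param path TSV file path.
#' @param as_pairs Reconstruct `primer_pair` objects (default) or return the
#'   raw data.frame.
#' @return List of `primer_pair` objects, or a data.frame.
#' @export
read_primer_sheet <- function(path, as_pairs = TRUE) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = NA)
  if (!as_pairs) return(df)
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    structure(
      list(target_id = r$target_id, residue_index = as.integer(r$residue_index),
           wt_aa = r$wt_aa, target_aa = r$target_aa,
           wt_codon = r$wt_codon, mutant_codon = r$mutant_codon,
           mismatches = as.integer(r$mismatches), length = as.integer(r$length),
           forward = r$forward_5to3, reverse = r$reverse_5to3,
           gc_percent = as.numeric(r$gc_percent), tm = as.numeric(r$tm),
           fwd_3prime_GC = as.logical(r$fwd_3prime_GC),
           rev_3prime_GC = as.logical(r$rev_3prime_GC),
           template_span = c(start = as.integer(r$template_span_start),
                             end = as.integer(r$template_span_end))),
      class = "primer_pair")
  })
}

# provenance header + TSV body; data to `path` (or stdout), never stderr
write_tsv_with_header <- function(df, path = "", seed = NULL, extra = NULL) {
  con <- if (identical(path, "")) stdout() else file(path, "w")
  if (!identical(path, "")) on.exit(close(con))
  writeLines(provenance_header(df, seed = seed, extra = extra), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

provenance_header <- function(obj, seed = NULL, extra = NULL) {
  h <- c(sprintf("# onetubeSDM %s", as.character(packageVersion("onetubeSDM"))),
         sprintf("# config-hash: %s", content_hash(obj)),
         sprintf("# seed: %s", if (is.null(seed)) "none" else as.character(seed)))
  c(h, extra)
}

# tiny polynomial rolling hash over the serialized object; provenance only
content_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L)[-seq_len(14)]) # skip header
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", as.integer(h))
}
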