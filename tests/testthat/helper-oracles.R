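# Independent oracles used to freeze expected values.  Each is deliberately
# written by a different route than the implementation it checks.

# character-by-character complement + reversal (vs chartr-based implementation)
rc_oracle <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# brute-force 64-entry genetic code lookup table, built by enumeration
codon_lookup_oracle <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setNames(vapply(codons, function(cd)
    unname(Biostrings::GENETIC_CODE[[cd]]), character(1)), codons)
})

# exhaustive enumeration of all c^n equal-weight outcome sequences
enum_coverage_equal <- function(c, n) {
  if (n < 1) return(as.numeric(c == 0))
  grid <- do.call(expand.grid, rep(list(seq_len(c)), n))
  mean(apply(grid, 1, function(row) length(unique(row)) == c))
}

# weighted enumeration: sum of outcome-sequence probabilities covering all c
enum_coverage_weighted <- function(weights, n, wildtype_weight = 0) {
  p <- c(weights, wildtype_weight) / (sum(weights) + wildtype_weight)
  cats <- seq_along(p)
  grid <- do.call(expand.grid, rep(list(cats), n))
  probs <- apply(grid, 1, function(row) prod(p[row]))
  covered <- apply(grid, 1, function(row)
    all(seq_along(weights) %in% row))
  sum(probs[covered])
}

# brute-force hypergeometric coverage: enumerate all size-n draws
enum_coverage_hyper <- function(K, n) {
  pop <- rep.int(seq_along(K), K)
  draws <- combn(length(pop), n)
  mean(apply(draws, 2, function(idx)
    all(seq_along(K) %in% pop[idx])))
}

# exhaustive minimal-mismatch codon search over all 64 codons
brute_min_mismatch <- function(wt_codon, target_aa) {
  dist <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  cands <- names(codon_lookup_oracle)[codon_lookup_oracle == target_aa]
  min(vapply(cands, dist, numeric(1), a = wt_codon))
}

# translation by direct table lookup over codon substrings
translate_cds_oracle <- function(bases) {
  n <- nchar(bases) %/% 3
  paste(codon_lookup_oracle[substring(bases, 3 * seq_len(n) - 2, 3 * seq_len(n))],
        collapse = "")
}

# random in-frame CDS free of stop codons (and optionally of Ala)
random_cds <- function(n_codons, seed, no_ala = FALSE) {
  withr::with_seed(seed, {
    excl <- c("TAA", "TAG", "TGA", if (no_ala) c("GCT", "GCC", "GCA", "GCG"))
    pool <- setdiff(names(codon_lookup_oracle), excl)
    coding_sequence(paste(sample(pool, n_codons, replace = TRUE), collapse = ""),
                    id = sprintf("sim%d", seed))
  })
}
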