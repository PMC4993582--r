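# One-tube reaction pools: template mixes, scanning pools of consecutive
# primer pairs, and single-site multisite pools.  Two same-length primer
# windows shifted by d codons share max(0, N - 3d) bases; a pooled pair of
# primer pairs can yield a double mutant when that overlap fraction drops
# below the feasibility threshold (60% by default).

#' Fractional window overlap of two primer pairs
#'
#' For same-length pairs on the same template whose target residues are d
#' codons apart, the windows share `max(0, N - 3d)` bases, i.e. a fraction
#' `max(0, N - 3d) / N`.
#'
#' @param pair_a,pair_b `primer_pair` objects of equal length.
#' @return Overlap fraction in `[0, 1]`.
#' @examples
#' # 29-mers five residues apart: (29 - 15)/29 = 0.483
#' @export
overlap_fraction <- function(pair_a, pair_b) {
  stopifnot(inherits(pair_a, "primer_pair"), inherits(pair_b, "primer_pair"))
  if (pair_a$length != pair_b$length)
    stop("mixed-length pools are unsupported: primer lengths differ (",
         pair_a$length, " vs ", pair_b$length, ")", call. = FALSE)
  overlap_by_distance(pair_a$length, abs(pair_a$residue_index - pair_b$residue_index))
}

#' Overlap fraction from primer length and codon distance
#' @param length Primer length N.
#' @param d Non-negative residue (codon) distance.
#' @return `max(0, N - 3d) / N`.
#' @export
overlap_by_distance <- function(length, d) {
  stopifnot(length > 0, d >= 0)
  pmax(0, length - 3 * d) / length
}

#' Construct a one-tube reaction pool
#'
#' @param pairs List of `primer_pair` objects (>= 1), all the same length.
#' @param mode `"scanning"` (consecutive residues), `"multisite"` (one
#'   residue, several targets) or `"template-mix"`.
#' @param templates Character vector of template plasmid labels; template-mix
#'   pools need >= 2.
#' @param pool_id Identifier.
#' @param total_primer_uM Collective primer concentration recorded as
#'   metadata (primers are used equimolar; chemistry is not simulated).
#' @return Object of class `reaction_pool` with equimolar `per_pair_uM`.
#' @export
reaction_pool <- function(pairs, mode = c("scanning", "multisite", "template-mix"),
                          templates = "template", pool_id = "pool1",
                          total_primer_uM = 0.8) {
  mode <- match.arg(mode)
  if (inherits(pairs, "primer_pair")) pairs <- list(pairs)
  if (!length(pairs)) stop("a pool needs at least one primer pair", call. = FALSE)
  stopifnot(all(vapply(pairs, inherits, logical(1), "primer_pair")))
  lens <- vapply(pairs, `[[`, integer(1), "length")
  if (length(unique(lens)) > 1L)
    stop("mixed-length pools are unsupported", call. = FALSE)
  res <- vapply(pairs, `[[`, integer(1), "residue_index")
  if (mode == "scanning" && is.unsorted(res, strictly = TRUE))
    stop("scanning pools must target strictly increasing residue indices", call. = FALSE)
  if (mode == "multisite" && length(unique(res)) != 1L)
    stop("multisite pools must share a single residue index", call. = FALSE)
  if (mode == "template-mix" && length(templates) < 2L)
    stop("template-mix pools need at least two templates", call. = FALSE)
  structure(
    list(pool_id = pool_id, mode = mode, pairs = pairs,
         templates = as.character(templates),
         total_primer_uM = total_primer_uM,
         per_pair_uM = total_primer_uM / length(pairs)),
    class = "reaction_pool")
}

#' @export
print.reaction_pool <- function(x, ...) {
  ids <- vapply(x$pairs, `[[`, character(1), "target_id")
  cat(sprintf("reaction_pool '%s' [%s]: %d pair(s) (%s); templates: %s; %.3g uM each\n",
              x$pool_id, x$mode, length(x$pairs), paste(ids, collapse = ", "),
              paste(x$templates, collapse = "+"), x$per_pair_uM))
  invisible(x)
}

#' Predict feasible double mutants in a scanning pool
#'
#' Every unordered pair of primer pairs whose window overlap fraction is
#' strictly below `threshold` can recombine into a double mutant in the same
#' tube.  With 29-mers and the default 0.60 threshold, residues >= 4 codons
#' apart (overlap 58.6%) are feasible; 3 codons apart (69.0%) are not.
#' Singles are always feasible and are not listed.
#'
#' @param pool A `reaction_pool` (scanning mode).
#' @param threshold Overlap-fraction feasibility threshold, default 0.60.
#' @return data.frame with columns `target_a`, `target_b`, `residue_a`,
#'   `residue_b`, `distance`, `overlap` (possibly zero rows).
#' @export
predict_double_mutants <- function(pool, threshold = 0.60) {
  stopifnot(inherits(pool, "reaction_pool"))
  if (pool$mode != "scanning")
    stop("double-mutant prediction applies to scanning pools", call. = FALSE)
  out <- data.frame(target_a = character(0), target_b = character(0),
                    residue_a = integer(0), residue_b = integer(0),
                    distance = integer(0), overlap = numeric(0),
                    stringsAsFactors = FALSE)
  k <- length(pool$pairs)
  if (k < 2L) return(out)
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    a <- pool$pairs[[i]]; b <- pool$pairs[[j]]
    ov <- overlap_fraction(a, b)
    if (ov < threshold)
      out[nrow(out) + 1L, ] <- list(a$target_id, b$target_id,
                                    a$residue_index, b$residue_index,
                                    abs(a$residue_index - b$residue_index), ov)
  }
  out
}

#' Partition substitution targets into one-tube pools
#'
#' Scanning mode splits residue-sorted pairs into consecutive pools of at
#' most `max_plex` (default 4: larger scanning pools start yielding multi-site
#' products instead of clean singles).  Multisite mode groups pairs by
#' residue.  Template-mix mode puts each pair into one pool carrying all the
#' supplied templates (>= 2).
#'
#' @param pairs List of `primer_pair` objects.
#' @param mode `"scanning"`, `"multisite"` or `"template-mix"`.
#' @param max_plex Maximum primer pairs per pool (>= 1).
#' @param templates Template labels attached to each pool.
#' @param total_primer_uM Metadata passed to [reaction_pool()].
#' @return List of `reaction_pool` objects covering every input pair exactly
#'   once.
#' @export
plan_pools <- function(pairs, mode = c("scanning", "multisite", "template-mix"),
                       max_plex = 4L, templates = "template",
                       total_primer_uM = 0.8) {
  mode <- match.arg(mode)
  if (inherits(pairs, "primer_pair")) pairs <- list(pairs)
  max_plex <- as.integer(max_plex)
  if (is.na(max_plex) || max_plex < 1L) stop("max_plex must be >= 1", call. = FALSE)
  res <- vapply(pairs, `[[`, integer(1), "residue_index")
  pairs <- pairs[order(res, vapply(pairs, `[[`, character(1), "target_id"))]
  res <- sort(res)
  pools <- list()
  if (mode == "scanning") {
    chunks <- split(seq_along(pairs), ceiling(seq_along(pairs) / max_plex))
    for (ci in seq_along(chunks))
      pools[[ci]] <- reaction_pool(pairs[chunks[[ci]]], "scanning",
                                   templates = templates,
                                   pool_id = sprintf("scan%02d", ci),
                                   total_primer_uM = total_primer_uM)
  } else if (mode == "multisite") {
    groups <- split(seq_along(pairs), res)
    ci <- 0L
    for (g in groups) {
      ci <- ci + 1L
      pools[[ci]] <- reaction_pool(pairs[g], "multisite", templates = templates,
                                   pool_id = sprintf("site%02d", ci),
                                   total_primer_uM = total_primer_uM)
    }
  } else {
    for (ci in seq_along(pairs))
      pools[[ci]] <- reaction_pool(pairs[[ci]], "template-mix",
                                   templates = templates,
                                   pool_id = sprintf("tmix%02d", ci),
                                   total_primer_uM = total_primer_uM)
  }
  pools
}

#' Tabulate pools as a pool sheet
#'
#' @param pools List of `reaction_pool` objects.
#' @param double_threshold Threshold forwarded to [predict_double_mutants()]
#'   for scanning pools.
#' @return data.frame: `pool_id`, `mode`, `members`, `templates`,
#'   `predicted_doubles`, `per_pair_uM`.
#' @export
pool_sheet <- function(pools, double_threshold = 0.60) {
  do.call(rbind, lapply(pools, function(p) {
    doubles <- if (p$mode == "scanning" && length(p$pairs) > 1L) {
      d <- predict_double_mutants(p, double_threshold)
      paste(paste0(d$target_a, "+", d$target_b), collapse = ",")
    } else ""
    data.frame(pool_id = p$pool_id, mode = p$mode,
               members = paste(vapply(p$pairs, `[[`, character(1), "target_id"),
                               collapse = ","),
               templates = paste(p$templates, collapse = "+"),
               predicted_doubles = doubles,
               per_pair_uM = p$per_pair_uM,
               stringsAsFactors = FALSE)
  }))
}
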