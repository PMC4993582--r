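# Evaluation of colony-screening outcomes from one-tube reactions: per-
# experiment success, success rates, recovery frequency by mismatch class,
# and unions across iterative mutagenesis rounds.

#' Construct a screening experiment record
#'
#' Colony counts from sequencing/restriction screening of one one-tube
#' reaction.  The record must conserve colonies:
#' `sum(singles) + sum(doubles) + wildtype == colonies`.
#'
#' @param experiment_id Identifier.
#' @param targeted data.frame with columns `label` (mutation label, e.g.
#'   "I50A") and `mismatches` (1..3), in targeting order.
#' @param singles Named integer vector of single-mutant colony counts; names
#'   must match `targeted$label` (missing labels count 0).
#' @param doubles Named integer vector of double-mutant counts, names
#'   `"A+B"`; default none.
#' @param wildtype Wild-type colony count.
#' @param colonies Total colonies analyzed.
#' @param ... Extra metadata kept verbatim (e.g. `plex`, `template`,
#'   `residue`, `round`, `colonies_obtained`, `note`).
#' @return Object of class `screening_experiment`.
#' @export
screening_experiment <- function(experiment_id, targeted, singles,
                                 doubles = integer(0), wildtype = 0L,
                                 colonies, ...) {
  stopifnot(is.data.frame(targeted), all(c("label", "mismatches") %in% names(targeted)))
  if (anyDuplicated(targeted$label))
    stop("duplicated target labels in experiment ", experiment_id, call. = FALSE)
  full <- setNames(integer(nrow(targeted)), targeted$label)
  if (length(singles)) {
    unknown <- setdiff(names(singles), targeted$label)
    if (length(unknown))
      stop("single counts for untargeted labels in ", experiment_id, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    full[names(singles)] <- as.integer(singles)
  }
  doubles <- if (length(doubles)) setNames(as.integer(doubles), names(doubles)) else integer(0)
  wildtype <- as.integer(wildtype); colonies <- as.integer(colonies)
  if (any(full < 0) || any(doubles < 0) || wildtype < 0L)
    stop("counts must be non-negative in ", experiment_id, call. = FALSE)
  if (sum(full) + sum(doubles) + wildtype != colonies)
    stop(sprintf("colony counts do not conserve in %s: %d singles + %d doubles + %d wt != %d analyzed",
                 experiment_id, sum(full), sum(doubles), wildtype, colonies),
         call. = FALSE)
  structure(
    c(list(experiment_id = experiment_id, targeted = targeted, singles = full,
           doubles = doubles, wildtype = wildtype, colonies = colonies),
      list(...)),
    class = "screening_experiment")
}

#' @export
print.screening_experiment <- function(x, ...) {
  cat(sprintf("screening_experiment '%s': %d targets, %d colonies (%d wt, %d in doubles)\n",
              x$experiment_id, nrow(x$targeted), x$colonies, x$wildtype,
              sum(x$doubles)))
  invisible(x)
}

# labels recovered as singles; optionally credit doubles to both constituents
obtained_labels <- function(e, count_doubles = FALSE) {
  got <- names(e$singles)[e$singles >= 1L]
  if (count_doubles && length(e$doubles)) {
    halves <- unlist(strsplit(names(e$doubles)[e$doubles >= 1L], "+", fixed = TRUE))
    got <- union(got, intersect(halves, e$targeted$label))
  }
  got
}

#' Did an experiment recover all targeted mutations?
#'
#' TRUE iff every targeted mutation was recovered as a single mutant at least
#' once.  Double mutants are tabulated separately and by default do not count
#' towards their constituent singles; set `count_doubles = TRUE` to credit
#' them.
#'
#' @param e A [screening_experiment()].
#' @param count_doubles Credit double-mutant recoveries to each constituent.
#' @return Logical.
#' @export
experiment_success <- function(e, count_doubles = FALSE) {
  stopifnot(inherits(e, "screening_experiment"))
  all(e$targeted$label %in% obtained_labels(e, count_doubles))
}

#' Success rate over a set of experiments
#'
#' Percentage of experiments in which all targeted mutations were obtained.
#' Reported truncated (floor) to an integer, the convention used in screening
#' summaries, alongside the exact fraction.
#'
#' @param experiments List of [screening_experiment()] objects.
#' @param filter Optional predicate `function(e) TRUE/FALSE` applied first.
#' @param count_doubles Passed to [experiment_success()].
#' @return List: `percent` (truncated integer), `fraction`, `successes`,
#'   `total`.
#' @export
success_rate <- function(experiments, filter = NULL, count_doubles = FALSE) {
  if (!is.null(filter))
    experiments <- Filter(filter, experiments)
  if (!length(experiments))
    stop("no experiments left after filtering", call. = FALSE)
  ok <- vapply(experiments, experiment_success, logical(1),
               count_doubles = count_doubles)
  list(percent = as.integer(floor(100 * sum(ok) / length(ok))),
       fraction = sum(ok) / length(ok),
       successes = sum(ok), total = length(ok))
}

#' Recovery frequency by mismatch class
#'
#' For each mismatch count (1, 2, 3 nucleotide changes between wild-type and
#' mutant codon), tallies how many (experiment, target) instances were
#' targeted and how many of those were obtained as singles.
#'
#' @param experiments List of [screening_experiment()] objects; every target
#'   must carry a `mismatches` annotation.
#' @return data.frame with columns `mismatches`, `obtained`, `targeted`.
#' @export
mismatch_class_frequencies <- function(experiments) {
  rows <- lapply(experiments, function(e) {
    mm <- e$targeted$mismatches
    if (any(is.na(mm)))
      stop("missing mismatch annotation for target(s) ",
           paste(e$targeted$label[is.na(mm)], collapse = ", "),
           " in ", e$experiment_id, call. = FALSE)
    data.frame(mismatches = as.integer(mm),
               obtained = e$singles[e$targeted$label] >= 1L)
  })
  tab <- do.call(rbind, rows)
  out <- aggregate(cbind(obtained = tab$obtained, targeted = 1L),
                   by = list(mismatches = tab$mismatches), FUN = sum)
  out[order(out$mismatches), , drop = FALSE]
}

#' A series of iterative rounds on one residue
#'
#' @param residue Residue label shared by all rounds (e.g. "A126").
#' @param experiments Ordered list of [screening_experiment()] objects.
#' @return Object of class `round_series`.
#' @export
round_series <- function(residue, experiments) {
  stopifnot(all(vapply(experiments, inherits, logical(1), "screening_experiment")))
  labs <- unlist(lapply(experiments, function(e) e$residue))
  if (length(labs) && !all(labs == residue))
    stop("all experiments in a series must share the residue label ", residue,
         call. = FALSE)
  structure(list(residue = residue, experiments = experiments),
            class = "round_series")
}

#' Distinct substitutions recovered across iterative rounds
#'
#' Union of targets obtained as singles over all rounds of a series, together
#' with the total number of colonies analyzed.
#'
#' @param series A [round_series()].
#' @return List: `labels` (distinct substitutions), `distinct` (count),
#'   `colonies_analyzed` (total).
#' @export
distinct_obtained <- function(series) {
  stopifnot(inherits(series, "round_series"))
  got <- Reduce(union, lapply(series$experiments, obtained_labels), character(0))
  list(labels = got, distinct = length(got),
       colonies_analyzed = sum(vapply(series$experiments, `[[`, integer(1),
                                      "colonies")))
}

#' Targets still missing after the rounds run so far
#'
#' Set difference between a desired substitution list and the union of
#' substitutions already obtained, preserving the desired order — the
#' planning aid for the next iterative round.
#'
#' @param series A [round_series()] (may contain zero experiments).
#' @param desired Character vector of desired mutation labels (non-empty).
#' @return Character vector of labels not yet obtained.
#' @export
remaining_targets <- function(series, desired) {
  stopifnot(inherits(series, "round_series"))
  if (!length(desired)) stop("desired must be non-empty", call. = FALSE)
  got <- Reduce(union, lapply(series$experiments, obtained_labels), character(0))
  desired[!desired %in% got]
}

#' Read screening experiments from JSON
#'
#' Accepts a JSON array of experiment objects (or a single object) in the
#' documented schema: `experiment_id`, `targeted` (array of
#' `{label, mismatches}`), `singles` (label -> count), `doubles`
#' (`"A+B"` -> count), `wildtype`, `colonies`, plus free metadata fields.
#'
#' @param path JSON file path.
#' @return List of [screening_experiment()] objects.
#' @export
read_screening_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(raw$experiment_id)) raw <- list(raw)
  lapply(raw, function(x) {
    targeted <- data.frame(
      label = vapply(x$targeted, `[[`, character(1), "label"),
      mismatches = vapply(x$targeted, function(t)
        as.integer(t$mismatches %||% NA_integer_), integer(1)),
      stringsAsFactors = FALSE)
    extra <- x[setdiff(names(x), c("experiment_id", "targeted", "singles",
                                   "doubles", "wildtype", "colonies"))]
    do.call(screening_experiment, c(
      list(experiment_id = x$experiment_id, targeted = targeted,
           singles = unlist(x$singles) %||% integer(0),
           doubles = unlist(x$doubles) %||% integer(0),
           wildtype = x$wildtype %||% 0L, colonies = x$colonies),
      extra))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a bundled example screening dataset
#'
#' Three datasets from one-tube mutagenesis screens of the tumour suppressor
#' PTEN and the receptor phosphatase PTPRZ-B ship with the package:
#' \describe{
#'   \item{`"scanning"`}{17 scanning pools of 2-8 consecutive Ala
#'     substitutions (PTEN residues 50-69), singles, doubles and wild type.}
#'   \item{`"multisite"`}{32 single-site pools of 1-4 substitutions at PTEN
#'     H61 and L70, on two plasmid backgrounds.}
#'   \item{`"iterative"`}{Two sequential large multisite rounds each for PTEN
#'     A126 and G129 and PTPRZ-B L1454.}
#' }
#'
#' @param name One of `"scanning"`, `"multisite"`, `"iterative"`.
#' @return List of [screening_experiment()] objects.
#' @export
load_example_screen <- function(name = c("scanning", "multisite", "iterative")) {
  name <- match.arg(name)
  file <- c(scanning = "scan_pools.json", multisite = "single_site_pools.json",
            iterative = "iterative_rounds.json")[[name]]
  path <- system.file("extdata", file, package = "onetubeSDM", mustWork = TRUE)
  read_screening_json(path)
}
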