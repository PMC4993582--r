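# Coverage probability for colony screening of one-tube pools: the chance
# that n screened colonies contain at least one representative of each of c
# distinct mutations.  Two models:
#   * multinomial (default): unlimited population, draws with replacement;
#     the mutagenic mix has effectively unlimited primer copies;
#   * multivariate hypergeometric: finite population of size N partitioned
#     into groups of sizes K_i, draws without replacement.
# Both are solved exactly by inclusion-exclusion over the groups that are
# missed, and estimated by Monte Carlo simulation.

#' Exact multinomial coverage probability
#'
#' Probability that all `c` mutation groups appear among `n` independent
#' draws.  Equal weights use the closed form
#' `sum_{j=0..c} (-1)^j C(c,j) ((c-j)/c)^n`; unequal `weights` (and an
#' optional extra wild-type category via `wildtype_weight`) use
#' inclusion-exclusion over group subsets.
#'
#' @param c Number of distinct mutations (>= 1).
#' @param n Number of colonies screened (>= 0).
#' @param weights Optional positive per-group weights (length `c`); equal if
#'   `NULL`.
#' @param wildtype_weight Weight of an extra non-mutant category (default 0,
#'   i.e. 100% mutagenesis efficiency).
#' @return Probability in `[0, 1]`; 0 whenever `n < c`.
#' @examples
#' coverage_probability_multinomial(4, 13)  # 0.9056...
#' @export
coverage_probability_multinomial <- function(c, n, weights = NULL,
                                             wildtype_weight = 0) {
  c <- as.integer(c); n <- as.integer(n)
  stopifnot(c >= 1L, n >= 0L, wildtype_weight >= 0)
  if (n < c) return(0)
  if (is.null(weights) && wildtype_weight == 0) {
    j <- 0:c
    return(min(1, max(0, sum((-1)^j * choose(c, j) * ((c - j) / c)^n))))
  }
  if (is.null(weights)) weights <- rep(1, c)
  stopifnot(length(weights) == c, all(weights > 0))
  p <- weights / (sum(weights) + wildtype_weight)
  if (c > 25L)
    stop("inclusion-exclusion over 2^", c, " subsets is infeasible; use simulate_coverage()",
         call. = FALSE)
  # sum over subsets S of missed groups: (-1)^|S| (1 - p_S)^n
  total <- 0
  for (k in 0:c) {
    subs <- if (k == 0L) list(integer(0)) else
      utils::combn(c, k, simplify = FALSE)
    for (S in subs)
      total <- total + (-1)^k * (1 - sum(p[S]))^n
  }
  min(1, max(0, total))
}

#' Multivariate hypergeometric point probability
#'
#' Probability of drawing exactly `k[i]` colonies of group i when
#' `n = sum(k)` colonies are drawn without replacement from a population of
#' size `N = sum(K)` partitioned into groups of sizes `K[i]`:
#' `prod(choose(K, k)) / choose(N, n)`.  Model a wild-type remainder as its
#' own group.
#'
#' @param k Integer vector of observed per-group counts (`sum(k)` = draws).
#' @param K Integer vector of per-group population counts.
#' @return Probability.
#' @export
dmultihyper <- function(k, K) {
  stopifnot(length(k) == length(K), all(k >= 0), all(K >= k))
  exp(sum(lchoose(K, k)) - lchoose(sum(K), sum(k)))
}

# C(N - m, n) / C(N, n) as a stable exact-ratio product (no large binomials)
hyper_miss_ratio <- function(N, m, n) {
  if (N - m < n) return(0)
  if (n == 0L) return(1)
  j <- 0:(n - 1L)
  prod((N - m - j) / (N - j))
}

#' Exact hypergeometric coverage probability
#'
#' Probability that, drawing `n` colonies without replacement from a finite
#' population of size `N` with `K[i]` copies of mutation group i, every group
#' is seen at least once.  Inclusion-exclusion over missed-group subsets:
#' `sum_S (-1)^|S| C(N - K_S, n) / C(N, n)` with undefined binomials treated
#' as zero.  The subset count grows as `2^c`; above `max_groups` the function
#' refuses and points at [simulate_coverage()].
#'
#' @param K Integer vector of per-group population counts (length `c`).
#' @param n Colonies drawn (`<= N`).
#' @param N Population size; defaults to `sum(K)` (no wild-type remainder).
#' @param max_groups Cap on `c` before the exact sum is refused (default 20).
#' @return Probability in `[0, 1]`.
#' @examples
#' coverage_probability_hypergeometric(K = c(2, 2), n = 2)  # 2/3
#' @export
coverage_probability_hypergeometric <- function(K, n, N = sum(K),
                                                max_groups = 20L) {
  K <- as.integer(K); n <- as.integer(n); N <- as.integer(N)
  c <- length(K)
  stopifnot(c >= 1L, all(K >= 1L), n >= 0L)
  if (N < sum(K)) stop("population size N must be >= sum(K)", call. = FALSE)
  if (n > N) stop("cannot draw more colonies than the population size", call. = FALSE)
  if (c > max_groups)
    stop("exact inclusion-exclusion over 2^", c,
         " subsets exceeds the cap; use simulate_coverage()", call. = FALSE)
  if (n < c) return(0)
  total <- 0
  for (k in 0:c) {
    subs <- if (k == 0L) list(integer(0)) else utils::combn(c, k, simplify = FALSE)
    for (S in subs)
      total <- total + (-1)^k * hyper_miss_ratio(N, sum(K[S]), n)
  }
  min(1, max(0, total))
}

# seed handling: set the RNG deterministically without clobbering the
# caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Simulate coverage probability by Monte Carlo
#'
#' Draws `n` colonies per iteration (with replacement under the multinomial
#' model, without replacement from the finite population when `K`/`N` are
#' given) and reports the fraction of iterations in which all `c` groups
#' appeared, with its binomial standard error.  Identical seed and settings
#' give bit-identical output.
#'
#' @param c Number of mutation groups.
#' @param n Colonies drawn per iteration.
#' @param weights Optional per-group weights (multinomial model).
#' @param wildtype_weight Extra non-mutant category weight (multinomial).
#' @param K,N Optional finite-population group sizes / population size; when
#'   supplied, draws are without replacement.
#' @param iterations Number of iterations (default 50000).
#' @param seed Integer seed (required for reproducibility).
#' @return List with `estimate`, `se`, `iterations`, `seed`.
#' @examples
#' simulate_coverage(4, 13, iterations = 2000, seed = 1)
#' @export
simulate_coverage <- function(c, n, weights = NULL, wildtype_weight = 0,
                              K = NULL, N = NULL,
                              iterations = 50000L, seed = NULL) {
  c <- as.integer(c); n <- as.integer(n); iterations <- as.integer(iterations)
  stopifnot(c >= 1L, n >= 0L, iterations >= 1L)
  hit <- with_seed(seed, {
    if (n < c) {
      rep(FALSE, iterations)
    } else if (!is.null(K)) {
      K <- as.integer(K)
      stopifnot(length(K) == c)
      if (is.null(N)) N <- sum(K)
      if (n > N) stop("cannot draw more colonies than the population size", call. = FALSE)
      pop <- c(rep.int(seq_len(c), K), rep.int(0L, N - sum(K)))
      vapply(seq_len(iterations), function(i) {
        draw <- sample(pop, n, replace = FALSE)
        all(tabulate(draw, nbins = c) > 0L)
      }, logical(1))
    } else {
      prob <- if (is.null(weights) && wildtype_weight == 0) NULL else {
        w <- if (is.null(weights)) rep(1, c) else weights
        c(w, wildtype_weight) / (sum(w) + wildtype_weight)
      }
      ncat <- if (is.null(prob)) c else c + 1L
      m <- matrix(sample.int(ncat, n * iterations, replace = TRUE, prob = prob),
                  nrow = n)
      ok <- rep(TRUE, iterations)
      for (g in seq_len(c)) ok <- ok & (colSums(m == g) > 0L)
      ok
    }
  })
  est <- mean(hit)
  list(estimate = est, se = sqrt(est * (1 - est) / iterations),
       iterations = iterations, seed = seed)
}

#' Minimum colonies to reach a coverage-probability target
#'
#' Smallest `n` with coverage probability >= `prob_target` for `c` equally
#' weighted mutation groups.  `model = "exact"` uses the multinomial closed
#' form; `model = "simulate"` estimates each P(n) by Monte Carlo and returns
#' the first crossing.
#'
#' @param c Number of mutation groups (>= 1).
#' @param prob_target Target probability in (0, 1).
#' @param model `"exact"` or `"simulate"`.
#' @param weights Optional per-group weights.
#' @param wildtype_weight Extra non-mutant category weight.
#' @param iterations,seed Simulation settings (simulate mode).
#' @param n_max Safety cap on the search.
#' @return Integer number of colonies.
#' @examples
#' min_colonies(4, 0.90)  # 13
#' @export
min_colonies <- function(c, prob_target, model = c("exact", "simulate"),
                         weights = NULL, wildtype_weight = 0,
                         iterations = 50000L, seed = NULL, n_max = 10000L) {
  model <- match.arg(model)
  c <- as.integer(c)
  stopifnot(c >= 1L)
  if (!is.numeric(prob_target) || prob_target <= 0 || prob_target >= 1)
    stop("prob_target must lie strictly between 0 and 1", call. = FALSE)
  p_of_n <- if (model == "exact") {
    function(n) coverage_probability_multinomial(c, n, weights, wildtype_weight)
  } else {
    # one seed per n, derived from the master seed, keeps runs reproducible
    function(n) simulate_coverage(c, n, weights, wildtype_weight,
                                  iterations = iterations,
                                  seed = if (is.null(seed)) NULL else seed + n)$estimate
  }
  for (n in seq.int(c, n_max)) {
    if (p_of_n(n) >= prob_target) return(n)
  }
  stop("no n <= ", n_max, " reaches the target probability", call. = FALSE)
}

#' Coverage look-up table across pool sizes
#'
#' Minimum-colony counts for each pool size `c = 1..max_mutations` at one or
#' more probability targets; the classic screening-effort table.
#'
#' @param prob_targets Numeric vector of targets in (0, 1).
#' @param max_mutations Largest pool size tabulated.
#' @param model,iterations,seed Passed to [min_colonies()].
#' @return data.frame with `mutations` and one column per target.
#' @export
coverage_table <- function(prob_targets = c(0.85, 0.90, 0.95),
                           max_mutations = 15L, model = "exact",
                           iterations = 50000L, seed = NULL) {
  stopifnot(all(prob_targets > 0 & prob_targets < 1), max_mutations >= 1L)
  out <- data.frame(mutations = seq_len(max_mutations))
  for (p in prob_targets) {
    col <- vapply(out$mutations, function(cc)
      min_colonies(cc, p, model = model, iterations = iterations, seed = seed),
      integer(1))
    out[[sprintf("p%02d", round(100 * p))]] <- col
  }
  out
}
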