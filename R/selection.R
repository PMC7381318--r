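#' PAM k-medoids clustering on a distance matrix
#'
#' Partitioning around medoids with the classic two phases. BUILD greedily
#' grows the medoid set starting from the accession with minimum total
#' distance to all others, each step adding the accession that most reduces
#' the total cost `sum_i min_m d(i, m)`; it is skipped when
#' `initial_medoids` are supplied (e.g. randomly sampled medoids for a
#' stability experiment). SWAP repeatedly applies the best-improving
#' (medoid, non-medoid) exchange until none improves, ties broken by lowest
#' accession index, so the result is fully deterministic given its inputs.
#'
#' @param D a [gdist] (or square symmetric) distance matrix.
#' @param k number of medoids, `1 <= k <= N`.
#' @param initial_medoids optional character ids or integer indices of k
#'   distinct starting medoids (skips BUILD).
#' @param seed optional integer recorded in the provenance of the returned
#'   core (the algorithm itself is deterministic).
#' @return list with `core` (the medoids as a [core_set]), `assignment`
#'   (named vector: nearest medoid id per accession) and `cost` (total
#'   distance to nearest medoid).
#' @export
pam_kmedoids <- function(D, k, initial_medoids = NULL, seed = NA_integer_) {
  validate_gdist(D)
  ids <- rownames(D)
  if (k < 1 || k > nrow(D)) stop("`k` must be in [1, N]")
  init <- integer(0)
  if (!is.null(initial_medoids)) {
    init <- core_indices(initial_medoids, ids)
    if (length(init) != k) stop("`initial_medoids` must have length k")
  }
  res <- cpp_pam(unclass(D), as.integer(k), as.integer(init) - 1L)
  core <- core_set(ids[res$medoids], method = "kmedoids",
                   metric = attr(D, "metric") %||% NA_character_,
                   seed = seed)
  list(core = core,
       assignment = setNames(ids[res$assignment], ids),
       cost = res$cost)
}

#' Select a core set by stochastic local search
#'
#' Seeded random-descent subset search over one of five diversity
#' objectives: average entry-to-nearest-entry (`"ENE"`, maximized), average
#' accession-to-nearest-entry (`"ANE"`, minimized), Shannon diversity
#' (`"SD"`), expected heterozygosity (`"EH"`) and allele coverage (`"AC"`)
#' (all maximized). Starting from a random k-subset, single
#' selected-for-unselected swaps are proposed at random and accepted only
#' when strictly improving, with incremental objective updates; the search
#' stops when the evaluation budget is exhausted or no improvement has been
#' seen for `patience` evaluations. `restarts` independent starts share one
#' seeded random stream and the best subset found is returned.
#'
#' @param objective one of `"ENE"`, `"ANE"`, `"SD"`, `"EH"`, `"AC"`.
#' @param data a [gdist] matrix for `"ENE"`/`"ANE"`, a complete
#'   [genotypes] object for the allele-based objectives.
#' @param k core size (`k >= 2` for `"ENE"`).
#' @param seed integer seed; identical arguments give identical cores.
#' @param max_evaluations,patience search budget (candidate evaluations)
#'   and stop-early patience, per restart.
#' @param restarts number of independent restarts.
#' @param run optional replicate index recorded in the provenance.
#' @return a [core_set] with attributes `value` (the achieved objective on
#'   its natural scale) and `evaluations`.
#' @export
local_search_select <- function(objective = c("ENE", "ANE", "SD", "EH", "AC"),
                                data, k, seed = 1,
                                max_evaluations = 50000, patience = 5000,
                                restarts = 1, run = NA_integer_) {
  objective <- match.arg(objective)
  code <- match(objective, c("ENE", "ANE", "SD", "EH", "AC"))
  if (code <= 2) {
    validate_gdist(data)
    D <- unclass(data)
    X <- matrix(0, 0, 0)
    ids <- rownames(data)
    metric <- attr(data, "metric") %||% NA_character_
  } else {
    validate_genotypes(data)
    if (anyNA(data$calls)) stop("missing calls present; impute first")
    D <- matrix(0, 0, 0)
    X <- data$calls
    ids <- accession_ids(data)
    metric <- NA_character_
  }
  res <- cpp_local_search(code, D, X, as.integer(k),
                          as.integer(max_evaluations), as.integer(patience),
                          as.integer(restarts), as.numeric(seed))
  core <- core_set(ids[res$entries], method = objective, metric = metric,
                   seed = as.integer(seed), run = run)
  attr(core, "value") <- res$value
  attr(core, "evaluations") <- res$evaluations
  core
}

#' Random core set (uniform baseline)
#'
#' A uniform k-subset of accessions without replacement, the no-information
#' baseline of the method comparison.
#'
#' @param accession_ids character vector of the accession universe (or a
#'   [genotypes] / [gdist] object to take it from).
#' @param k core size.
#' @param seed integer seed.
#' @param run optional replicate index for the provenance.
#' @return a [core_set] with method `"random"`.
#' @export
random_core <- function(accession_ids, k, seed = 1, run = NA_integer_) {
  if (inherits(accession_ids, "genotypes"))
    accession_ids <- rownames(accession_ids$calls)
  if (is.matrix(accession_ids)) accession_ids <- rownames(accession_ids)
  n <- length(accession_ids)
  if (k < 1 || k > n) stop("`k` must be in [1, N]")
  picked <- with_seed(seed, sample(accession_ids, k))
  core_set(picked, method = "random", seed = as.integer(seed), run = run)
}
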