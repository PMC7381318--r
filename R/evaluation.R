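#' Parse a selection-method label
#'
#' The comparison harness names methods by label: the four distance-based
#' optimizer settings `"ENE-MRD"`, `"ENE-CSE"`, `"ANE-MRD"`, `"ANE-CSE"`,
#' the three allele-based settings `"SD"`, `"EH"`, `"AC"` (together the
#' seven optimizer settings), plus the `"kmedoids"` clustering and the
#' `"random"` baseline.
#'
#' @param label method label string.
#' @return list with `label`, `type` (`"objective"`, `"kmedoids"` or
#'   `"random"`), `objective` and `metric` (possibly `NA`).
#' @export
method_spec <- function(label) {
  if (label %in% c("kmedoids", "random"))
    return(list(label = label, type = label, objective = NA_character_,
                metric = if (label == "kmedoids") "MRD" else NA_character_))
  parts <- strsplit(label, "-", fixed = TRUE)[[1]]
  obj <- parts[1]
  if (!obj %in% c("ENE", "ANE", "SD", "EH", "AC"))
    stop("unknown method label: ", label)
  metric <- if (length(parts) > 1) parts[2] else NA_character_
  if (obj %in% c("ENE", "ANE")) {
    if (is.na(metric)) metric <- "MRD"
    if (!metric %in% c("MRD", "CSE")) stop("unknown metric in label: ", label)
  } else if (!is.na(metric)) stop("metric given for allele-based method: ",
                                  label)
  list(label = label, type = "objective", objective = obj, metric = metric)
}

# produce one core for a method spec at a given seed
run_one_core <- function(spec, k, seed, g = NULL, D_by_metric = list(),
                         budget = list(), run = NA_integer_) {
  if (spec$type == "random") {
    ids <- if (!is.null(g)) accession_ids(g) else rownames(D_by_metric[[1]])
    return(random_core(ids, k, seed = seed, run = run))
  }
  if (spec$type == "kmedoids") {
    D <- D_by_metric[[spec$metric]]
    ids <- rownames(D)
    init <- with_seed(seed, sample(ids, k))
    res <- pam_kmedoids(D, k, initial_medoids = init, seed = seed)
    core <- res$core
    attr(core, "run") <- run
    return(core)
  }
  data <- if (spec$objective %in% c("ENE", "ANE"))
    D_by_metric[[spec$metric]] else g
  core <- local_search_select(spec$objective, data, k, seed = seed,
                              max_evaluations = budget$max_evaluations %||% 50000,
                              patience = budget$patience %||% 5000,
                              restarts = budget$restarts %||% 1, run = run)
  attr(core, "method") <- spec$label  # full setting label incl. metric
  core
}

#' Replicated stability experiment for one method
#'
#' Runs a selection method `R` times with seeds `base_seed + 1` ...
#' `base_seed + R` (for k-medoids each run starts from freshly sampled
#' random initial medoids) and records, for every accession, the frequency
#' with which it was selected. Frequencies concentrated at 0 and 1 indicate
#' a stable method; frequencies near `k/N` indicate instability.
#'
#' @param method a method label (see [method_spec()]) or spec list.
#' @param k core size.
#' @param R number of replicate runs (default 1000).
#' @param base_seed integer; run r uses seed `base_seed + r`.
#' @param g complete [genotypes] object (needed for allele-based methods
#'   and for the accession universe).
#' @param D_by_metric named list of [gdist] matrices (`MRD`, `CSE`) for the
#'   distance-based methods.
#' @param budget list with `max_evaluations`, `patience`, `restarts` for
#'   the local-search methods.
#' @param keep_cores return the individual cores (needed for
#'   [quality_table()]).
#' @return object of class `"stability_result"`: list with `method`, `k`,
#'   `R`, `f` (named per-accession selection frequencies), `S` (stability
#'   index) and, if requested, `cores`.
#' @export
run_stability <- function(method, k, R = 1000, base_seed = 0, g = NULL,
                          D_by_metric = list(), budget = list(),
                          keep_cores = TRUE) {
  spec <- if (is.character(method)) method_spec(method) else method
  if (R < 1) stop("`R` must be >= 1")
  ids <- if (!is.null(g)) accession_ids(g) else rownames(D_by_metric[[1]])
  count <- setNames(numeric(length(ids)), ids)
  cores <- if (keep_cores) vector("list", R) else NULL
  for (r in seq_len(R)) {
    core <- run_one_core(spec, k, seed = base_seed + r, g = g,
                         D_by_metric = D_by_metric, budget = budget,
                         run = r)
    count[unclass(core)] <- count[unclass(core)] + 1
    if (keep_cores) cores[[r]] <- core
  }
  f <- count / R
  structure(list(method = spec$label, k = k, R = R, f = f,
                 S = stability_index(f), cores = cores),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("stability: %s, k = %d, R = %d, S = %.3f\n",
              x$method, x$k, x$R, x$S))
  invisible(x)
}

#' Empirical cumulative distribution of selection frequencies
#'
#' Returns the right-continuous step function
#' `F(x) = #\{i : f_i <= x\} / N`. For a stable method the mass of `f` sits
#' at 0 and 1, so the ecdf is flat in between (close to a horizontal line);
#' for an unstable method the mass sits near `k/N` and the ecdf jumps there
#' (close to a vertical line).
#'
#' @param f numeric vector of per-accession selection frequencies (or a
#'   `"stability_result"`).
#' @return a function of class `"ecdf"`.
#' @export
freq_ecdf <- function(f) {
  if (inherits(f, "stability_result")) f <- f$f
  if (length(f) == 0) stop("`f` must be non-empty")
  ecdf(f)
}

#' Stability index of a selection-frequency profile
#'
#' Quantifies the "never or always selected" notion on a 0-1 scale:
#' `S = 1 - mean(4 f (1 - f))`. `S = 1` exactly when every frequency is 0
#' or 1 (perfectly stable); `S = 0` when every accession is selected in
#' half the runs (maximal instability).
#'
#' @param f numeric vector of selection frequencies in [0, 1].
#' @return S in [0, 1].
#' @export
stability_index <- function(f) {
  if (inherits(f, "stability_result")) f <- f$f
  if (any(f < 0 | f > 1)) stop("frequencies must lie in [0, 1]")
  1 - mean(4 * f * (1 - f))
}

#' Quality table: average A-NE and E-NE per core
#'
#' Evaluates a list of cores under one common distance matrix (default
#' recommendation: MRD regardless of the metric used for selection), giving
#' the two quality measures per core. A theoretically ideal core has low
#' average A-NE (representation) and high average E-NE (spread).
#'
#' @param cores list of [core_set] objects.
#' @param D_common a [gdist] matrix covering all core entries.
#' @return data.frame with columns `method`, `run`, `seed`, `k`, `ane`,
#'   `ene`.
#' @export
quality_table <- function(cores, D_common) {
  validate_gdist(D_common)
  rows <- lapply(cores, function(core) {
    data.frame(
      method = attr(core, "method") %||% NA_character_,
      run = attr(core, "run") %||% NA_integer_,
      seed = attr(core, "seed") %||% NA_integer_,
      k = length(core),
      ane = avg_accession_nearest(core, D_common),
      ene = if (length(core) >= 2) avg_entry_nearest(core, D_common)
            else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Full method-comparison grid
#'
#' Runs every requested method at every core size for `R` replicates,
#' collecting selection-frequency stability (index and ecdf data) and the
#' A-NE / E-NE quality of every produced core under a common metric. This
#' is the harness behind the "two sizes x seven settings x R iterations"
#' accounting: `n_optimizer_cores` counts the cores produced by the seven
#' optimizer settings alone, excluding the k-medoids and random baselines.
#'
#' @param g complete [genotypes] object.
#' @param sizes integer vector of core sizes.
#' @param R replicates per method and size.
#' @param methods character vector of method labels (see [method_spec()]);
#'   the default is the seven optimizer settings plus both baselines.
#' @param base_seed integer master seed; every (method, size, run) triple
#'   derives a distinct seed from it.
#' @param budget local-search budget list (`max_evaluations`, `patience`,
#'   `restarts`).
#' @param common_metric metric used for the quality evaluation
#'   (`"MRD"` or `"CSE"`).
#' @return object of class `"method_comparison"`: list with `stability`
#'   (data.frame: method, size, S), `frequencies` (nested list of f
#'   vectors), `quality` (per-core data.frame with a `size` column),
#'   `quality_summary` (data.frame: method, size, mean_ane, mean_ene),
#'   `n_optimizer_cores`, `n_total_cores`, and `ranking` (methods by
#'   decreasing S).
#' @export
compare_methods <- function(g, sizes, R = 1000,
                            methods = c("ENE-MRD", "ENE-CSE", "ANE-MRD",
                                        "ANE-CSE", "SD", "EH", "AC",
                                        "kmedoids", "random"),
                            base_seed = 0, budget = list(),
                            common_metric = "MRD") {
  validate_genotypes(g)
  if (anyNA(g$calls)) stop("missing calls present; impute first")
  specs <- lapply(methods, method_spec)
  need_metrics <- unique(stats::na.omit(c(
    vapply(specs, function(s) s$metric, ""), common_metric)))
  D_by_metric <- list()
  for (mt in need_metrics)
    D_by_metric[[mt]] <- if (mt == "MRD") mrd_dist(g) else cse_dist(g)
  D_common <- D_by_metric[[common_metric]]

  optimizer <- vapply(specs, function(s) s$type == "objective", TRUE)
  stab_rows <- list(); qual_rows <- list(); freqs <- list()
  R <- as.integer(R)
  n_opt <- 0L; n_tot <- 0L
  for (si in seq_along(sizes)) {
    k <- sizes[si]
    for (mi in seq_along(specs)) {
      seed0 <- base_seed + ((mi - 1L) * length(sizes) + (si - 1L)) * R
      sr <- run_stability(specs[[mi]], k, R = R, base_seed = seed0, g = g,
                          D_by_metric = D_by_metric, budget = budget,
                          keep_cores = TRUE)
      qt <- quality_table(sr$cores, D_common)
      qt$size <- k
      key <- paste0(specs[[mi]]$label, ":", k)
      stab_rows[[key]] <- data.frame(method = specs[[mi]]$label, size = k,
                                     S = sr$S, stringsAsFactors = FALSE)
      qual_rows[[key]] <- qt
      freqs[[key]] <- sr$f
      n_tot <- n_tot + R
      if (optimizer[mi]) n_opt <- n_opt + R
    }
  }
  stability <- do.call(rbind, c(stab_rows, make.row.names = FALSE))
  quality <- do.call(rbind, c(qual_rows, make.row.names = FALSE))
  qs <- do.call(rbind, lapply(split(quality,
                                    list(quality$method, quality$size),
                                    drop = TRUE), function(d)
    data.frame(method = d$method[1], size = d$size[1],
               mean_ane = mean(d$ane), mean_ene = mean(d$ene),
               stringsAsFactors = FALSE)))
  rownames(qs) <- NULL
  agg <- vapply(split(stability$S, stability$method), mean, 0)
  structure(list(stability = stability, frequencies = freqs,
                 quality = quality, quality_summary = qs,
                 n_optimizer_cores = n_opt, n_total_cores = n_tot,
                 ranking = names(sort(agg, decreasing = TRUE))),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("method comparison: %d cores (%d from optimizer settings)\n",
              x$n_total_cores, x$n_optimizer_cores))
  cat("stability index by method and size:\n")
  print(x$stability, row.names = FALSE)
  cat("quality (mean average A-NE / E-NE) by method and size:\n")
  print(x$quality_summary, row.names = FALSE)
  invisible(x)
}
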