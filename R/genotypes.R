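#' Construct a genotype matrix object
#'
#' The central data container: an accessions x markers matrix of
#' reference-allele dosages. Each non-missing call is 0 (homozygous
#' alternate), 0.5 (heterozygous) or 1 (homozygous reference); missing calls
#' are `NA`. Optional per-accession collection labels and per-marker map
#' positions are carried alongside.
#'
#' @param calls numeric matrix, accessions in rows, markers in columns, with
#'   row and column names; values in \{0, 0.5, 1, NA\}.
#' @param collections optional character/factor vector of collection labels,
#'   one per accession.
#' @param chrom,pos optional per-marker chromosome labels and 1-based
#'   positions.
#' @param alleles optional two-column character matrix of (reference,
#'   alternate) alleles per marker.
#' @return An object of class `"genotypes"`: a list with elements `calls`,
#'   `accession_info` (data.frame: id, collection) and `marker_info`
#'   (data.frame: id, chrom, pos, ref, alt).
#' @examples
#' g <- genotypes(matrix(c(1, 0.5, 0, NA), 2, 2,
#'   dimnames = list(c("a1", "a2"), c("m1", "m2"))))
#' n_accessions(g)
#' @export
genotypes <- function(calls, collections = NULL, chrom = NULL, pos = NULL,
                      alleles = NULL) {
  if (!is.matrix(calls) || !is.numeric(calls))
    stop("`calls` must be a numeric matrix")
  if ((nrow(calls) > 0 && is.null(rownames(calls))) ||
      (ncol(calls) > 0 && is.null(colnames(calls))))
    stop("`calls` must have accession row names and marker column names")
  n <- nrow(calls); m <- ncol(calls)
  obj <- structure(list(
    calls = calls,
    accession_info = data.frame(
      id = rownames(calls) %||% character(0),
      collection = if (is.null(collections)) rep(NA_character_, n) else
        as.character(collections),
      stringsAsFactors = FALSE
    ),
    marker_info = data.frame(
      id = colnames(calls) %||% character(0),
      chrom = if (is.null(chrom)) rep(NA_character_, m) else
        as.character(chrom),
      pos = if (is.null(pos)) rep(NA_integer_, m) else as.integer(pos),
      ref = if (is.null(alleles)) rep(NA_character_, m) else alleles[, 1L],
      alt = if (is.null(alleles)) rep(NA_character_, m) else alleles[, 2L],
      stringsAsFactors = FALSE
    )
  ), class = "genotypes")
  validate_genotypes(obj)
}

#' Validate a genotypes object
#'
#' Checks id uniqueness, dimension agreement and the dosage domain
#' \{0, 0.5, 1, NA\}; errors on any violation rather than repairing.
#'
#' @param g a `"genotypes"` object.
#' @return `g`, invisibly unchanged, if valid.
#' @export
validate_genotypes <- function(g) {
  stopifnot(inherits(g, "genotypes"))
  ids <- rownames(g$calls)
  mids <- colnames(g$calls)
  if (anyDuplicated(ids)) stop("duplicate accession ids: ",
    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(mids)) stop("duplicate marker ids: ",
    paste(unique(mids[duplicated(mids)]), collapse = ", "))
  if (nrow(g$accession_info) != nrow(g$calls) ||
      nrow(g$marker_info) != ncol(g$calls))
    stop("metadata dimensions do not match the call matrix")
  v <- g$calls[!is.na(g$calls)]
  if (length(v) && !all(v %in% c(0, 0.5, 1)))
    stop("non-missing calls must be 0, 0.5 or 1")
  invisible(g)
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("genotypes: %d accessions x %d markers\n",
              nrow(x$calls), ncol(x$calls)))
  nmiss <- sum(is.na(x$calls))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nmiss,
              100 * nmiss / length(x$calls)))
  if (!all(is.na(x$accession_info$collection))) {
    tab <- table(x$accession_info$collection)
    cat("  collections: ",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname genotypes
#' @param g a `"genotypes"` object.
#' @export
n_accessions <- function(g) nrow(g$calls)

#' @rdname genotypes
#' @export
n_markers <- function(g) ncol(g$calls)

#' @rdname genotypes
#' @export
accession_ids <- function(g) rownames(g$calls)

#' @rdname genotypes
#' @export
marker_ids <- function(g) colnames(g$calls)

#' Subset a genotypes object
#'
#' @param x a `"genotypes"` object.
#' @param i accession index (ids, logical or integer).
#' @param j marker index.
#' @param ... unused.
#' @return the subsetted `"genotypes"` object.
#' @export
`[.genotypes` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  calls <- x$calls[i, j, drop = FALSE]
  ai <- x$accession_info[match(rownames(calls), x$accession_info$id), ,
                         drop = FALSE]
  mi <- x$marker_info[match(colnames(calls), x$marker_info$id), ,
                      drop = FALSE]
  rownames(ai) <- NULL; rownames(mi) <- NULL
  structure(list(calls = calls, accession_info = ai, marker_info = mi),
            class = "genotypes")
}

#' Construct a labelled genetic distance matrix
#'
#' A symmetric accession x accession dissimilarity matrix with zero diagonal
#' and values in [0, 1], tagged with the metric that produced it.
#'
#' @param values symmetric numeric matrix with matching dimnames.
#' @param metric metric label, e.g. `"MRD"`, `"CSE"` or `"other"`.
#' @return the matrix with class `"gdist"` and a `"metric"` attribute.
#' @export
gdist <- function(values, metric = "other") {
  validate_gdist(structure(values, metric = metric,
                           class = c("gdist", class(values))))
}

#' Validate a distance matrix
#'
#' @param D a square numeric matrix (ideally of class `"gdist"`).
#' @param tol numeric tolerance for symmetry and range checks.
#' @return `D` invisibly if valid; otherwise an error.
#' @export
validate_gdist <- function(D, tol = 1e-8) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("distance matrix must be square")
  if (is.null(rownames(D)) || !identical(rownames(D), colnames(D)))
    stop("distance matrix must have matching row/column accession ids")
  if (anyNA(D)) stop("distance matrix contains missing values")
  if (max(abs(D - t(D))) > tol) stop("distance matrix is not symmetric")
  if (max(abs(diag(D))) > tol) stop("distance matrix diagonal is not zero")
  if (min(D) < -tol || max(D) > 1 + tol)
    stop("distance values must lie in [0, 1]")
  invisible(D)
}

#' @export
print.gdist <- function(x, ...) {
  cat(sprintf("%s distance matrix: %d accessions, range [%.4f, %.4f]\n",
              attr(x, "metric"), nrow(x), min(x[upper.tri(x)]),
              max(x[upper.tri(x)])))
  invisible(x)
}

#' Construct a core set
#'
#' An ordered subset of accession ids of fixed size `k`, with provenance
#' (method, metric, seed, run index) recorded as attributes.
#'
#' @param entries character vector of accession ids (no duplicates).
#' @param method method label (e.g. "kmedoids", "ENE", "random").
#' @param metric distance metric used for selection, if any.
#' @param seed integer seed that produced the core.
#' @param run replicate index within a stability experiment, if any.
#' @return character vector of class `"core_set"` with provenance attributes.
#' @export
core_set <- function(entries, method = "manual", metric = NA_character_,
                     seed = NA_integer_, run = NA_integer_) {
  entries <- as.character(entries)
  if (anyDuplicated(entries)) stop("core set entries must be unique")
  if (length(entries) < 1L) stop("core set must contain at least one entry")
  structure(entries, class = "core_set", method = method, metric = metric,
            seed = seed, run = run)
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core set: k = %d, method = %s%s\n", length(x),
              attr(x, "method"),
              if (!is.na(attr(x, "metric")))
                paste0(" (", attr(x, "metric"), ")") else ""))
  cat("  ", paste(head(unclass(x), 8L), collapse = ", "),
      if (length(x) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# resolve a core (core_set / character ids / integer indices) to integer
# row indices of the accession universe given by `ids`; errors on foreign ids
core_indices <- function(core, ids) {
  if (is.numeric(core)) {
    idx <- as.integer(core)
    if (any(idx < 1L | idx > length(ids))) stop("core index out of range")
  } else {
    idx <- match(as.character(core), ids)
    if (anyNA(idx))
      stop("core contains accession ids not in the collection: ",
           paste(as.character(core)[is.na(idx)], collapse = ", "))
  }
  if (anyDuplicated(idx)) stop("core set entries must be unique")
  idx
}

# seeded evaluation helper: all package randomness flows through this
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
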