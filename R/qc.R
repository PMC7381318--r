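#' Pre-imputation marker filtering
#'
#' First stage of the QC cascade, applied before imputation: removes markers
#' with a missing-call fraction at or above `max_missing` (strictly-less is
#' kept), markers monomorphic over their non-missing calls (a marker whose
#' non-missing calls are all heterozygous still segregates and is kept),
#' and duplicate markers — identical call vectors including the missing
#' pattern — keeping the first in marker order.
#'
#' @param g a [genotypes] object.
#' @param max_missing missing-fraction threshold; markers with
#'   `missing >= max_missing` are removed (default 0.30).
#' @return list with `genotypes` (filtered) and `report` (a QC report, see
#'   [qc_report]).
#' @export
filter_pre_imputation <- function(g, max_missing = 0.30) {
  validate_genotypes(g)
  if (ncol(g$calls) == 0 || nrow(g$calls) == 0)
    stop("empty genotype matrix")
  calls <- g$calls
  reasons <- setNames(rep(NA_character_, ncol(calls)), colnames(calls))

  miss_frac <- colMeans(is.na(calls))
  reasons[miss_frac >= max_missing] <- "missing"

  mono <- apply(calls, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) == 0 || length(unique(v)) == 1 && v[1] != 0.5
  })
  reasons[is.na(reasons) & mono] <- "monomorphic"

  # duplicates judged among markers surviving the first two stages
  surv <- which(is.na(reasons))
  key <- apply(calls[, surv, drop = FALSE], 2, paste, collapse = ",")
  reasons[surv[duplicated(key)]] <- "duplicate"

  keep <- is.na(reasons)
  report <- qc_report(reasons,
                      thresholds = c(max_missing = max_missing),
                      stage_order = c("missing", "monomorphic", "duplicate"))
  list(genotypes = g[, keep], report = report)
}

#' Naive frequency-sampling imputation
#'
#' A deliberately simple, seeded stand-in for haplotype-based imputation:
#' each missing call is drawn from \{0, 0.5, 1\} with probabilities equal to
#' the marker's observed genotype frequencies. It preserves per-marker
#' genotype frequency spectra but ignores linkage; externally imputed
#' matrices can be supplied instead for fidelity runs.
#'
#' @param g a [genotypes] object with no fully missing marker.
#' @param seed integer seed (deterministic output).
#' @return a [genotypes] object with no missing calls.
#' @export
impute_naive <- function(g, seed = 1) {
  validate_genotypes(g)
  calls <- g$calls
  if (!anyNA(calls)) return(g)
  all_missing <- colSums(!is.na(calls)) == 0
  if (any(all_missing))
    stop("marker(s) fully missing (run filter_pre_imputation first): ",
         paste(colnames(calls)[all_missing][1:min(3, sum(all_missing))],
               collapse = ", "))
  lv <- c(0, 0.5, 1)
  calls <- with_seed(seed, {
    for (j in which(colSums(is.na(calls)) > 0)) {
      v <- calls[, j]
      obs <- v[!is.na(v)]
      freq <- vapply(lv, function(x) mean(obs == x), 0)
      v[is.na(v)] <- sample(lv, sum(is.na(v)), replace = TRUE, prob = freq)
      calls[, j] <- v
    }
    calls
  })
  g$calls <- calls
  g
}

#' Post-imputation marker filtering
#'
#' Final QC stage on complete data: keeps markers with minor allele
#' frequency at or above `maf_min` and heterozygous-call fraction at or
#' below `het_max` (both thresholds inclusive on the kept side). MAF is
#' `min(q, 1 - q)` with `q` the mean dosage; heterozygosity is the fraction
#' of calls equal to 0.5.
#'
#' @param g a [genotypes] object without missing calls.
#' @param maf_min minimum minor allele frequency kept (default 0.05).
#' @param het_max maximum heterozygous fraction kept (default 0.125).
#' @return list with `genotypes` and `report`.
#' @export
filter_post_imputation <- function(g, maf_min = 0.05, het_max = 0.125) {
  validate_genotypes(g)
  if (anyNA(g$calls))
    stop("missing calls present; impute or filter first")
  q <- colMeans(g$calls)
  maf <- pmin(q, 1 - q)
  het <- colMeans(g$calls == 0.5)
  reasons <- setNames(rep(NA_character_, ncol(g$calls)), colnames(g$calls))
  reasons[maf < maf_min] <- "maf"
  reasons[is.na(reasons) & het > het_max] <- "heterozygosity"
  report <- qc_report(reasons,
                      thresholds = c(maf_min = maf_min, het_max = het_max),
                      stage_order = c("maf", "heterozygosity"))
  list(genotypes = g[, is.na(reasons)], report = report)
}

#' Collapse perfect-LD haplotype blocks
#'
#' Markers in perfect linkage disequilibrium over all accessions — call
#' vectors identical, or exactly complementary (dosage `d` against `1 - d`
#' at every accession, i.e. the same marker with flipped allele coding) —
#' form one haplotype block. The first `keep` markers of each block (input
#' order) are retained as representatives.
#'
#' @param g a [genotypes] object without missing calls.
#' @param keep number of representatives retained per block (1 or 2).
#' @return list with `genotypes` (representatives only) and `blocks`
#'   (data.frame: marker_id, block, representative, retained).
#' @export
collapse_perfect_ld <- function(g, keep = 1) {
  validate_genotypes(g)
  if (anyNA(g$calls)) stop("missing calls present; impute or filter first")
  if (!keep %in% c(1, 2)) stop("`keep` must be 1 or 2")
  calls <- g$calls
  # canonical key: a vector and its complement share one representation
  keys <- apply(calls, 2, function(v) {
    a <- paste(v, collapse = ",")
    b <- paste(1 - v, collapse = ",")
    if (a <= b) a else b
  })
  block <- match(keys, unique(keys))
  retained <- logical(ncol(calls))
  for (b in unique(block)) {
    idx <- which(block == b)
    retained[idx[seq_len(min(keep, length(idx)))]] <- TRUE
  }
  rep_of <- vapply(block, function(b) colnames(calls)[block == b][1], "")
  blocks <- data.frame(marker_id = colnames(calls), block = block,
                       representative = rep_of, retained = retained,
                       stringsAsFactors = FALSE)
  list(genotypes = g[, retained], blocks = blocks)
}

#' QC report
#'
#' Per-stage accounting for a marker filtering step: counts of input,
#' removed and retained markers at each stage (balancing exactly), the
#' removal reason per marker, and the thresholds used.
#'
#' @param reasons named character vector (marker id -> removal reason, `NA`
#'   when retained).
#' @param thresholds named numeric vector of thresholds applied.
#' @param stage_order character vector giving the stage ordering.
#' @return an object of class `"qc_report"` with elements `stages`
#'   (data.frame: stage, input, removed, retained), `reasons`, `thresholds`.
#' @export
qc_report <- function(reasons, thresholds = numeric(),
                      stage_order = unique(stats::na.omit(reasons))) {
  n <- length(reasons)
  input <- n
  rows <- list()
  for (s in stage_order) {
    removed <- sum(reasons == s, na.rm = TRUE)
    rows[[s]] <- data.frame(stage = s, input = input, removed = removed,
                            retained = input - removed,
                            stringsAsFactors = FALSE)
    input <- input - removed
  }
  structure(list(stages = do.call(rbind, c(rows, make.row.names = FALSE)),
                 reasons = reasons, thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("marker QC report\n")
  print(x$stages, row.names = FALSE)
  if (length(x$thresholds))
    cat("thresholds:", paste(names(x$thresholds), x$thresholds,
                             sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Run the full QC cascade
#'
#' Convenience wrapper chaining [filter_pre_imputation()], [impute_naive()]
#' and [filter_post_imputation()] in the fixed order missing/monomorphic/
#' duplicate, imputation, MAF/heterozygosity.
#'
#' @param g a [genotypes] object.
#' @param max_missing,maf_min,het_max stage thresholds.
#' @param impute_seed seed for the naive imputation; `NULL` skips imputation
#'   (downstream distance computation must then use pairwise-complete mode).
#' @return list with `genotypes` and `reports` (list of stage reports).
#' @export
qc_cascade <- function(g, max_missing = 0.30, maf_min = 0.05,
                       het_max = 0.125, impute_seed = 1) {
  pre <- filter_pre_imputation(g, max_missing = max_missing)
  out <- pre$genotypes
  if (!is.null(impute_seed)) out <- impute_naive(out, seed = impute_seed)
  reports <- list(pre = pre$report)
  if (!anyNA(out$calls)) {
    post <- filter_post_imputation(out, maf_min = maf_min,
                                   het_max = het_max)
    out <- post$genotypes
    reports$post <- post$report
  }
  list(genotypes = out, reports = reports)
}
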