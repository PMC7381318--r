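#' Average entry-to-nearest-entry distance (E-NE)
#'
#' Mean, over the entries of a core set, of each entry's distance to its
#' closest other entry. Maximizing E-NE spreads entries apart and favors
#' cores that capture extreme genotypes (CC-X strategy).
#'
#' @param core a [core_set], character ids, or integer indices (k >= 2).
#' @param D a [gdist] distance matrix over the full collection.
#' @return the average E-NE, in [0, 1].
#' @export
avg_entry_nearest <- function(core, D) {
  idx <- core_indices(core, rownames(D))
  if (length(idx) < 2)
    stop("E-NE is undefined for cores with fewer than 2 entries")
  S <- D[idx, idx, drop = FALSE]
  diag(S) <- Inf
  mean(apply(S, 1, min))
}

#' Average accession-to-nearest-entry distance (A-NE)
#'
#' Mean, over every accession in the collection, of its distance to the
#' closest core entry (entries contribute zero). Minimizing A-NE yields
#' cores that uniformly represent the whole collection (CC-I strategy).
#'
#' @param core a [core_set], character ids, or integer indices (k >= 1).
#' @param D a [gdist] distance matrix over the full collection.
#' @return the average A-NE, in [0, 1].
#' @export
avg_accession_nearest <- function(core, D) {
  idx <- core_indices(core, rownames(D))
  mean(apply(D[, idx, drop = FALSE], 1, min))
}

# pooled reference-allele counts over core entries: 2 * k total per locus
pooled_counts <- function(core, g) {
  idx <- core_indices(core, accession_ids(g))
  X <- g$calls[idx, , drop = FALSE]
  if (anyNA(X)) stop("missing calls among core entries; impute first")
  k <- length(idx)
  cref <- 2 * colSums(X)
  cbind(ref = cref, alt = 2 * k - cref)
}

#' Shannon diversity index of a core set
#'
#' Entropy of the pooled allele-frequency distribution across all loci of
#' the core entries: with `f` the count of each allele divided by the total
#' allele count `2 * k * m`, `H = -sum(f * log(f))` over alleles with
#' nonzero count (natural logarithm). Heterozygotes contribute one count to
#' each allele. The index is maximal when the pooled allele counts are
#' uniform — i.e. when every allele is equally rare.
#'
#' @param core a [core_set], character ids, or integer indices.
#' @param g a [genotypes] object (complete over the entries).
#' @return Shannon index H >= 0.
#' @export
shannon_diversity <- function(core, g) {
  cc <- pooled_counts(core, g)
  f <- cc / sum(cc)
  f <- f[f > 0]
  -sum(f * log(f))
}

#' Expected heterozygosity of a core set
#'
#' Average over loci of `1 - sum(p_a^2)` with `p_a` the allele frequencies
#' among the core entries; for biallelic loci this is `2 p (1 - p)` with
#' maximum 0.5.
#'
#' @inheritParams shannon_diversity
#' @return expected heterozygosity in [0, 0.5].
#' @export
expected_het <- function(core, g) {
  cc <- pooled_counts(core, g)
  p <- cc[, "ref"] / rowSums(cc)
  mean(2 * p * (1 - p))
}

#' Allele coverage of a core set
#'
#' Fraction of the marker alleles observed anywhere in the full collection
#' that are also observed among the core entries.
#'
#' @inheritParams shannon_diversity
#' @return coverage proportion in [0, 1].
#' @export
allele_coverage <- function(core, g) {
  validate_genotypes(g)
  X <- g$calls
  if (anyNA(X)) stop("missing calls present; impute first")
  present_ref <- colSums(X) > 0
  present_alt <- colSums(1 - X) > 0
  cc <- pooled_counts(core, g)
  kept <- sum(cc[, "ref"] > 0 & present_ref) +
    sum(cc[, "alt"] > 0 & present_alt)
  kept / (sum(present_ref) + sum(present_alt))
}

#' Evaluate a core set under all five statistics
#'
#' @param core a [core_set].
#' @param g a [genotypes] object (for the allele-based statistics).
#' @param D a [gdist] matrix (for the distance-based statistics).
#' @return named numeric vector with elements `ene`, `ane`, `shannon`,
#'   `exp_het`, `coverage`.
#' @export
evaluate_core <- function(core, g = NULL, D = NULL) {
  out <- c(ene = NA_real_, ane = NA_real_, shannon = NA_real_,
           exp_het = NA_real_, coverage = NA_real_)
  if (!is.null(D)) {
    if (length(core) >= 2) out["ene"] <- avg_entry_nearest(core, D)
    out["ane"] <- avg_accession_nearest(core, D)
  }
  if (!is.null(g)) {
    out["shannon"] <- shannon_diversity(core, g)
    out["exp_het"] <- expected_het(core, g)
    out["coverage"] <- allele_coverage(core, g)
  }
  out
}
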