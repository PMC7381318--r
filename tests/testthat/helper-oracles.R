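# Independent oracles used across the suite. These deliberately avoid the
# package's optimized code paths: plain-R formulas, exhaustive enumeration
# and textbook estimators.

# Weir & Cockerham (1984) multilocus F_ST estimator from dosage calls and
# collection labels: variance components a (among collections), b (among
# individuals within), c (within individuals); theta = sum(a)/sum(a+b+c).
wc_fst <- function(g) {
  X <- g$calls
  groups <- split(seq_len(nrow(X)), g$accession_info$collection)
  r <- length(groups)
  ni <- lengths(groups)
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  A <- B <- C <- 0
  for (l in seq_len(ncol(X))) {
    p_i <- vapply(groups, function(ix) mean(X[ix, l]), 0)
    h_i <- vapply(groups, function(ix) mean(X[ix, l] == 0.5), 0)
    pbar <- sum(ni * p_i) / (r * nbar)
    s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * h_i) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    A <- A + a; B <- B + b; C <- C + hbar / 2
  }
  A / (A + B + C)
}

# random distance matrix from uniform points in [0,1]^3, scaled into [0, 0.9]
rand_gdist <- function(n, seed) {
  set.seed(seed)
  X <- matrix(runif(n * 3), n)
  D <- as.matrix(dist(X))
  D <- D / max(D) * 0.9
  dimnames(D) <- list(paste0("a", seq_len(n)), paste0("a", seq_len(n)))
  gdist(D)
}

# clustered instance: k well-separated groups of points (the geometry PAM
# is designed to recover); returns the distance matrix, n and k
clustered_instance <- function(seed) {
  set.seed(seed)
  k <- sample(1:3, 1)
  n <- sample(max(5, 2 * k):10, 1)
  centers <- matrix(runif(k * 3, 0, 10), k)
  grp <- sort(rep_len(seq_len(k), n))
  X <- centers[grp, , drop = FALSE] + matrix(runif(n * 3, 0, 0.5), n)
  D <- as.matrix(dist(X))
  D <- D / (max(D) + 1e-9)
  dimnames(D) <- list(paste0("a", seq_len(n)), paste0("a", seq_len(n)))
  list(D = gdist(D), n = n, k = k)
}

# exhaustive k-medoid cost optimum
exhaustive_pam_cost <- function(D, k) {
  min(apply(combn(nrow(D), k), 2, function(m)
    sum(apply(D[, m, drop = FALSE], 1, min))))
}

# exhaustive best objective value over all k-subsets
exhaustive_best <- function(objective, g = NULL, D = NULL, k) {
  n <- if (!is.null(D)) nrow(D) else n_accessions(g)
  f <- objective_fun(objective, g, D)
  max(apply(combn(n, k), 2, f))
}

# objective as a plain-R function of an index vector (sign: maximized)
objective_fun <- function(objective, g = NULL, D = NULL) {
  switch(objective,
    ENE = function(ix) avg_entry_nearest(ix, D),
    ANE = function(ix) -avg_accession_nearest(ix, D),
    SD  = function(ix) shannon_diversity(ix, g),
    EH  = function(ix) expected_het(ix, g),
    AC  = function(ix) allele_coverage(ix, g))
}

# seeded random id sample (for random initial medoids in tests)
with_seed_ids <- function(ids, k, seed) {
  set.seed(seed)
  sample(ids, k)
}

# independently written VCF export (used only to test the VCF reader)
write_vcf_helper <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", accession_ids(g)),
                     collapse = "\t")), con)
  gt_of <- function(d) {
    if (is.na(d)) "./." else if (d == 1) "0/0" else if (d == 0.5) "0/1"
    else "1/1"
  }
  for (j in seq_len(n_markers(g))) {
    gts <- vapply(g$calls[, j], gt_of, "")
    writeLines(paste(c("1", j, marker_ids(g)[j], "A", "G", ".", "PASS",
                       ".", "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}

# tiny deterministic genotypes object from a dosage matrix
geno_from <- function(calls, ...) {
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("a", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("m", seq_len(ncol(calls)))
  genotypes(calls, ...)
}
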