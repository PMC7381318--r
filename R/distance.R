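#' Modified Rogers distance matrix
#'
#' For accessions i and j genotyped at m biallelic loci, with per-individual
#' reference-allele frequencies p (0, 0.5 or 1, the dosage encoding),
#' \deqn{d(i,j) = \sqrt{\frac{1}{2m} \sum_{l} \sum_{a} (p_{ila} - p_{jla})^2}.}
#' For biallelic loci the inner sum equals twice the squared dosage
#' difference, so MRD reduces to the Euclidean distance between dosage
#' vectors divided by sqrt(m); values lie in [0, 1] with 1 attained by
#' opposite homozygotes at every locus.
#'
#' @param g a [genotypes] object. By default calls must be complete;
#'   `pairwise_complete = TRUE` computes each pair over its shared
#'   non-missing loci instead.
#' @param pairwise_complete allow missing calls via pairwise-complete loci.
#' @return a [gdist] matrix with metric `"MRD"`.
#' @export
mrd_dist <- function(g, pairwise_complete = FALSE) {
  validate_genotypes(g)
  X <- g$calls
  if (!anyNA(X)) {
    D <- as.matrix(dist(X)) / sqrt(ncol(X))
  } else {
    if (!pairwise_complete)
      stop("missing calls present; impute first or set pairwise_complete")
    D <- pairwise_sq_dist(X)
  }
  diag(D) <- 0
  D <- pmin(pmax((D + t(D)) / 2, 0), 1)
  gdist(D, metric = "MRD")
}

# pairwise-complete normalized Euclidean distance on dosages
pairwise_sq_dist <- function(X) {
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0
  Mn <- M * 1
  shared <- Mn %*% t(Mn)
  if (any(shared[upper.tri(shared)] == 0)) {
    bad <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)[1, ]
    stop("no shared loci between accessions ", rownames(X)[bad[1]],
         " and ", rownames(X)[bad[2]])
  }
  S <- X0^2
  ss <- S %*% t(Mn) + Mn %*% t(S) - 2 * X0 %*% t(X0)
  sqrt(pmax(ss, 0) / shared)
}

#' Cavalli-Sforza and Edwards chord distance matrix
#'
#' Normalized chord distance on square-root allele frequencies:
#' \deqn{d(i,j) = \sqrt{\frac{1}{m} \sum_l \left(1 - \sum_a
#'   \sqrt{p_{ila} p_{jla}}\right)},}
#' with per-individual allele frequencies as in [mrd_dist()]. Values lie in
#' [0, 1]; identical accessions give 0 and opposite homozygotes at every
#' locus give 1.
#'
#' @inheritParams mrd_dist
#' @return a [gdist] matrix with metric `"CSE"`.
#' @export
cse_dist <- function(g, pairwise_complete = FALSE) {
  validate_genotypes(g)
  X <- g$calls
  m <- ncol(X)
  if (!anyNA(X)) {
    A <- sqrt(X); B <- sqrt(1 - X)
    inner <- A %*% t(A) + B %*% t(B)   # sum over loci of sum_a sqrt(p q)
    D <- sqrt(pmax(m - inner, 0) / m)
  } else {
    if (!pairwise_complete)
      stop("missing calls present; impute first or set pairwise_complete")
    M <- !is.na(X)
    Mn <- M * 1
    shared <- Mn %*% t(Mn)
    if (any(shared[upper.tri(shared)] == 0)) {
      bad <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)[1, ]
      stop("no shared loci between accessions ", rownames(X)[bad[1]],
           " and ", rownames(X)[bad[2]])
    }
    A <- sqrt(X); B <- sqrt(1 - X)
    A[!M] <- 0; B[!M] <- 0
    inner <- A %*% t(A) + B %*% t(B)
    D <- sqrt(pmax(shared - inner, 0) / shared)
  }
  diag(D) <- 0
  D <- pmin(pmax((D + t(D)) / 2, 0), 1)
  gdist(D, metric = "CSE")
}

#' Principal coordinate analysis (classical scaling)
#'
#' Embeds a distance matrix into orthogonal axes by double-centering the
#' squared distances and eigendecomposing (Gower's classical scaling, as in
#' `stats::cmdscale`). Coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues; the variance explained by axis i
#' is reported as `100 * lambda_i / sum(positive lambda)`. Negative
#' eigenvalues (non-Euclidean input) are excluded from both coordinates and
#' the denominator; no correction is applied.
#'
#' @param D a [gdist] (or plain symmetric) distance matrix.
#' @param n_axes number of axes requested (at most N - 1); if fewer
#'   positive eigenvalues exist, fewer axes are returned with a warning.
#' @return an object of class `"pcoa_result"`: list with `coordinates`
#'   (N x axes matrix), `eigenvalues` (all, non-increasing), and
#'   `rel_variance` (percent per returned axis).
#' @export
pcoa_classic <- function(D, n_axes = 2) {
  validate_gdist(D)
  n <- nrow(D)
  if (n_axes > n - 1) stop("`n_axes` must be at most N - 1")
  # cmdscale warns when < k eigenvalues are positive; positivity is
  # handled explicitly below
  fit <- suppressWarnings(cmdscale(as.dist(D), k = n - 1, eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  tol <- 1e-9 * max(abs(eig))
  n_pos <- sum(eig > tol)
  if (n_pos < n_axes) {
    warning("only ", n_pos, " positive eigenvalue(s); returning ", n_pos,
            " axes")
    n_axes <- n_pos
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  rel <- 100 * eig[seq_len(n_axes)] / sum(eig[eig > tol])
  structure(list(coordinates = coords, eigenvalues = eig,
                 rel_variance = rel), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d accessions, %d axes\n", nrow(x$coordinates),
              ncol(x$coordinates)))
  cat("variance explained (%):",
      paste(sprintf("%.2f", x$rel_variance), collapse = ", "), "\n")
  invisible(x)
}
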