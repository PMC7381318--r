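#' Simulate a structured multi-collection genotype matrix
#'
#' Generates biallelic diploid SNP dosages for several diverged collections
#' under the Balding-Nichols model: each marker has an ancestral reference
#' allele frequency drawn uniformly from `ancestral_freq_range`; each
#' collection draws its own frequency from a Beta distribution with shape
#' parameters `p(1-F)/F` and `(1-p)(1-F)/F`, so that its mean is the
#' ancestral frequency and the differentiation among collections is `F`
#' (at `F = 0` the Beta degenerates to a point mass at `p`). Genotypes are
#' then drawn per accession with heterozygote probability scaled down by an
#' inbreeding coefficient (`P(het) = 2pq(1 - f)`), emulating a selfing crop
#' in which per-marker heterozygosity stays low.
#'
#' The defaults mirror a winter wheat panel of 890 accessions assembled from
#' five collections of sizes 92, 284, 40, 220 and 254.
#'
#' @param collection_sizes positive integer vector of accessions per
#'   collection.
#' @param n_markers number of biallelic markers.
#' @param fst differentiation parameter F in [0, 1).
#' @param ancestral_freq_range range (low < high, within (0,1)) for ancestral
#'   reference-allele frequencies.
#' @param inbreeding within-accession inbreeding coefficient f in [0, 1];
#'   the default 0.9 keeps heterozygous calls rare, as in a selfing crop.
#' @param missing_rate proportion of calls set to missing (MCAR), in [0, 1].
#' @param seed integer master seed; all draws flow from it in documented
#'   order (ancestral frequencies, collection frequencies, genotypes,
#'   missingness), so identical arguments give bit-identical output.
#' @return a [genotypes] object with collection labels.
#' @examples
#' g <- sim_genotypes(collection_sizes = c(20, 30), n_markers = 50, seed = 1)
#' table(g$accession_info$collection)
#' @export
sim_genotypes <- function(collection_sizes = c(92, 284, 40, 220, 254),
                          n_markers = 1000, fst = 0.1,
                          ancestral_freq_range = c(0.1, 0.9),
                          inbreeding = 0.9, missing_rate = 0, seed = 1) {
  if (any(collection_sizes < 1) || any(collection_sizes != round(collection_sizes)))
    stop("`collection_sizes` must be positive integers")
  if (sum(collection_sizes) < 2) stop("need at least 2 accessions in total")
  if (n_markers < 1) stop("`n_markers` must be >= 1")
  if (fst < 0 || fst >= 1) stop("`fst` must lie in [0, 1)")
  if (length(ancestral_freq_range) != 2 ||
      ancestral_freq_range[1] >= ancestral_freq_range[2] ||
      ancestral_freq_range[1] <= 0 || ancestral_freq_range[2] >= 1)
    stop("`ancestral_freq_range` must be (low, high) within (0, 1)")
  if (inbreeding < 0 || inbreeding > 1) stop("`inbreeding` must be in [0, 1]")
  if (missing_rate < 0 || missing_rate > 1)
    stop("`missing_rate` must be in [0, 1]")

  n_coll <- length(collection_sizes)
  n <- sum(collection_sizes)
  m <- as.integer(n_markers)
  coll_labels <- paste0("coll", seq_len(n_coll))
  coll_of <- rep(coll_labels, times = collection_sizes)

  g <- with_seed(seed, {
    p_anc <- runif(m, ancestral_freq_range[1], ancestral_freq_range[2])
    # collection-specific frequencies, one row per collection
    p_coll <- matrix(0, n_coll, m)
    for (c in seq_len(n_coll)) {
      if (fst == 0) {
        p_coll[c, ] <- p_anc
      } else {
        p_coll[c, ] <- rbeta(m, p_anc * (1 - fst) / fst,
                             (1 - p_anc) * (1 - fst) / fst)
      }
    }
    # genotype classes with inbreeding-adjusted Hardy-Weinberg proportions
    pm <- p_coll[rep(seq_len(n_coll), times = collection_sizes), , drop = FALSE]
    q <- 1 - pm
    p_hom_ref <- pm^2 + inbreeding * pm * q
    p_het <- 2 * pm * q * (1 - inbreeding)
    u <- matrix(runif(n * m), n, m)
    calls <- matrix(0, n, m)
    calls[u < p_hom_ref + p_het] <- 0.5
    calls[u < p_hom_ref] <- 1
    calls
  })
  dimnames(g) <- list(sprintf("acc%04d", seq_len(n)),
                      sprintf("mk%05d", seq_len(m)))
  out <- genotypes(g, collections = coll_of)
  if (missing_rate > 0)
    out <- inject_missingness(out, missing_rate, seed = seed + 1L)
  out
}

#' Set genotype calls to missing completely at random
#'
#' Each call is independently replaced by `NA` with probability `rate`.
#' The input object is not modified.
#'
#' @param g a [genotypes] object.
#' @param rate missingness probability in [0, 1].
#' @param seed integer seed.
#' @return a new [genotypes] object with missing calls injected.
#' @export
inject_missingness <- function(g, rate, seed = 1) {
  validate_genotypes(g)
  if (rate < 0 || rate > 1) stop("`rate` must be in [0, 1]")
  if (rate == 0) return(g)
  calls <- g$calls
  drop <- with_seed(seed, runif(length(calls)) < rate)
  calls[drop] <- NA_real_
  g$calls <- calls
  g
}

#' Simulate a probe-placement fixture with known truth
#'
#' Builds a small synthetic reference sequence, embeds SNP context sequences
#' (`left[X/Y]right`) at known positions, and emits the corresponding
#' paired "split read" alignment records together with a ground-truth table
#' saying which markers must survive the placement consistency filter.
#' A deterministic subset of markers is deliberately broken, one failure
#' mode each: a missing mate, a two-nucleotide inner gap, an `N` at the SNP
#' reference position, a sub-threshold MAPQ, a second marker duplicating an
#' existing position, a secondary alignment, an ambiguous double placement,
#' and a gapped (non full-match) CIGAR.
#'
#' @param n_markers number of markers (>= 1); broken cases are injected
#'   cyclically once `n_markers >= 2` (marker 2 gets the first failure mode,
#'   marker 3 the second, ... every third marker is clean).
#' @param flank_len flank length on each side of the SNP (>= 1).
#' @param seed integer seed.
#' @return a list with elements `manifest` (data.frame: marker_id,
#'   context_sequence), `reference` (named character vector of chromosome
#'   sequences), `alignments` (alignment record data.frame, see
#'   [filter_alignments()]), and `truth` (data.frame: marker_id, kept,
#'   reason, chrom, pos, ref_allele, alt_allele).
#' @export
sim_placement_fixture <- function(n_markers = 20, flank_len = 30, seed = 1) {
  if (flank_len < 1) stop("`flank_len` must be >= 1")
  if (n_markers < 1) stop("`n_markers` must be >= 1")
  bases <- c("A", "C", "G", "T")
  chroms <- c("1A", "3B", "5D")
  span <- 2L * flank_len + 1L  # reference bases consumed per marker

  with_seed(seed, {
    # lay markers on chromosomes with disjoint slots, 10 bp padding
    slot <- span + 10L
    chrom_of <- sample(chroms, n_markers, replace = TRUE)
    ref <- lapply(chroms, function(ch) {
      nslots <- sum(chrom_of == ch)
      len <- max(nslots, 1L) * slot + 2L * flank_len + 50L
      sample(bases, len, replace = TRUE)
    })
    names(ref) <- chroms
    slot_idx <- stats::ave(seq_len(n_markers), chrom_of, FUN = seq_along)
    snp_pos <- as.integer(25L + (slot_idx - 1L) * slot + flank_len + 1L)

    failure_modes <- c("mate", "gap", "N-site", "mapq", "dup",
                       "secondary", "ambiguous", "cigar")
    ids <- sprintf("mk%04d", seq_len(n_markers))
    manifest <- truth <- NULL
    aln <- list()
    mode_i <- 0L
    rows <- list(); tr <- list()
    for (i in seq_len(n_markers)) {
      mode <- "clean"
      if (n_markers >= 2 && i %% 3 != 1) {  # 2 of every 3 markers broken
        mode_i <- mode_i + 1L
        mode <- failure_modes[(mode_i - 1L) %% length(failure_modes) + 1L]
      }
      ch <- chrom_of[i]; pos <- snp_pos[i]
      if (mode == "dup") {
        # duplicate the position of the previous clean marker when possible:
        # both place cleanly, dedupe keeps the earlier one
        prev <- which(vapply(tr, function(t) t$kept, TRUE))
        if (length(prev)) {
          ch <- tr[[prev[length(prev)]]]$chrom
          pos <- tr[[prev[length(prev)]]]$pos
        } else mode <- "clean"
      }
      if (mode == "dup") {
        # reuse the existing reference base so the earlier marker's
        # context remains reconstructible
        alleles <- c(ref[[ch]][pos],
                     sample(setdiff(bases, ref[[ch]][pos]), 1L))
      } else {
        alleles <- sample(bases, 2L)
        ref[[ch]][pos] <- if (mode == "N-site") "N" else alleles[1L]
      }
      left <- paste(ref[[ch]][(pos - flank_len):(pos - 1L)], collapse = "")
      right <- paste(ref[[ch]][(pos + 1L):(pos + flank_len)], collapse = "")
      ctx <- sprintf("%s[%s/%s]%s", left, alleles[1L], alleles[2L], right)
      rows[[i]] <- data.frame(marker_id = ids[i], context_sequence = ctx,
                              origin = "synthetic", stringsAsFactors = FALSE)

      mk_rec <- function(mate, start, end, strand, mapq = 60L,
                         secondary = FALSE, mapped = TRUE,
                         cigar = paste0(flank_len, "M"))
        data.frame(read_id = paste0(ids[i], "_", mate),
                   chromosome = if (mapped) ch else NA_character_,
                   start = if (mapped) as.integer(start) else NA_integer_,
                   end = if (mapped) as.integer(end) else NA_integer_,
                   strand = if (mapped) strand else NA_character_,
                   mapq = mapq, is_secondary = secondary, is_mapped = mapped,
                   cigar = cigar, stringsAsFactors = FALSE)

      left_rec <- mk_rec(1L, pos - flank_len, pos - 1L, "+")
      right_rec <- mk_rec(2L, pos + 1L, pos + flank_len, "-")
      recs <- switch(mode,
        clean = , dup = , "N-site" = list(left_rec, right_rec),
        mate = list(left_rec, mk_rec(2L, NA, NA, NA, mapped = FALSE)),
        gap = list(left_rec, mk_rec(2L, pos + 2L, pos + flank_len + 1L, "-")),
        mapq = list(left_rec, mk_rec(2L, pos + 1L, pos + flank_len, "-",
                                     mapq = 5L)),
        secondary = list(left_rec, right_rec,
                         mk_rec(2L, pos + 1L, pos + flank_len, "-",
                                secondary = TRUE)),
        ambiguous = list(left_rec, right_rec,
                         mk_rec(2L, pos + flank_len + 5L,
                                pos + 2L * flank_len + 4L, "-")),
        # the 1-base deletion makes the reference span one base longer
        cigar = list(left_rec, mk_rec(2L, pos + 1L, pos + flank_len + 1L, "-",
                  cigar = sprintf("%dM1D%dM", flank_len %/% 2,
                                  flank_len - flank_len %/% 2)))
      )
      aln[[i]] <- do.call(rbind, recs)

      kept <- mode %in% c("clean")
      reason <- switch(mode,
        clean = NA_character_, dup = "duplicate-position",
        mate = "mate", gap = "gap", "N-site" = "N-site", mapq = "mate",
        secondary = NA_character_,  # secondary is discarded, pair still OK
        ambiguous = "ambiguous", cigar = "cigar")
      if (mode == "secondary") kept <- TRUE
      tr[[i]] <- list(marker_id = ids[i], kept = kept, reason = reason,
                      chrom = if (kept || mode == "dup") ch else NA_character_,
                      pos = if (kept || mode == "dup") pos else NA_integer_,
                      ref_allele = alleles[1L], alt_allele = alleles[2L])
    }
    manifest <- do.call(rbind, rows)
    truth <- do.call(rbind, lapply(tr, function(t)
      data.frame(t, stringsAsFactors = FALSE)))
    list(manifest = manifest,
         reference = vapply(ref, paste, "", collapse = ""),
         alignments = do.call(rbind, aln),
         truth = truth)
  })
}

#' Write a placement fixture to disk
#'
#' Serialises a [sim_placement_fixture()] result as a FASTA reference, a
#' tab-separated marker manifest and a SAM alignment file, the formats the
#' placement stage reads.
#'
#' @param fix fixture list from [sim_placement_fixture()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the file paths written.
#' @export
write_placement_fixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(reference = file.path(dir, "reference.fa"),
                manifest = file.path(dir, "manifest.tsv"),
                alignments = file.path(dir, "alignments.sam"),
                truth = file.path(dir, "truth.tsv"))
  writeLines(unlist(lapply(names(fix$reference), function(ch)
    c(paste0(">", ch), fix$reference[[ch]]))), paths$reference)
  write.table(fix$manifest, paths$manifest, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_sam(fix$alignments, fix$reference, paths$alignments)
  write.table(fix$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

# minimal SAM writer for fixture alignment records
write_sam <- function(records, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           vapply(names(reference), function(ch)
             sprintf("@SQ\tSN:%s\tLN:%d", ch, nchar(reference[[ch]])), ""))
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    flag <- 0L
    if (!r$is_mapped) flag <- bitwOr(flag, 4L)
    else if (r$strand == "-") flag <- bitwOr(flag, 16L)
    if (isTRUE(r$is_secondary)) flag <- bitwOr(flag, 256L)
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
            r$read_id, flag,
            if (r$is_mapped) r$chromosome else "*",
            if (r$is_mapped) r$start else 0L,
            r$mapq, if (r$is_mapped) r$cigar else "*")
  }, "")
  writeLines(c(hdr, lines), path)
}
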