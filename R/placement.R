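#' Split a SNP context sequence into pseudo paired-end reads
#'
#' A probe context sequence `LEFT[X/Y]RIGHT` is split at the polymorphic
#' site into two reads suitable for paired-end alignment: the left flank as
#' read 1 and the reverse complement of the right flank as read 2. After
#' alignment, a consistently mapped pair brackets the SNP position with an
#' inner gap of exactly one reference base.
#'
#' @param context_sequence character scalar in bracket notation.
#' @param marker_id marker id used in error messages and read ids.
#' @return list with `left_read`, `right_read` (reverse-complemented right
#'   flank) and `alleles` (character pair in written order).
#' @examples
#' split_context_sequence("AC[T/C]GA")  # right read "TC"
#' @export
split_context_sequence <- function(context_sequence, marker_id = "marker") {
  check_context_sequence(context_sequence, marker_id)
  left <- sub("\\[.*$", "", context_sequence)
  right <- sub("^.*\\]", "", context_sequence)
  al <- regmatches(context_sequence,
                   regexpr("\\[[ACGT]/[ACGT]\\]", context_sequence))
  al <- strsplit(gsub("[][]", "", al), "/", fixed = TRUE)[[1]]
  list(left_read = left, right_read = revcomp(right), alleles = al)
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""), "", USE.NAMES = FALSE))
}

#' Read alignment records from a SAM file
#'
#' Parses the mandatory SAM fields into the alignment record data.frame the
#' placement filters consume. Read ids are expected to end in `_1` (left
#' flank) or `_2` (right flank); the prefix is the marker id. Unmapped
#' records are retained (with `is_mapped = FALSE`) so that missing-mate
#' rejections can be diagnosed.
#'
#' @param path SAM file path.
#' @return data.frame with columns `read_id`, `chromosome`, `start`, `end`
#'   (1-based inclusive), `strand`, `mapq`, `is_secondary`, `is_mapped`,
#'   `cigar`.
#' @export
read_sam_records <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar", "strand"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !bitwAnd(x$flag, 4L)
  width <- rep(NA_integer_, length(x$qname))
  if (any(mapped))
    width[mapped] <- GenomicAlignments::cigarWidthAlongReferenceSpace(
      x$cigar[mapped])
  data.frame(
    read_id = x$qname,
    chromosome = ifelse(mapped, as.character(x$rname), NA_character_),
    start = ifelse(mapped, x$pos, NA_integer_),
    end = ifelse(mapped, x$pos + width - 1L, NA_integer_),
    strand = ifelse(mapped, as.character(x$strand), NA_character_),
    mapq = as.integer(x$mapq),
    is_secondary = bitwAnd(x$flag, 256L) > 0L,
    is_mapped = mapped,
    cigar = ifelse(mapped, x$cigar, NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Discard unmapped, secondary and low-quality alignments
#'
#' Keeps only primary mapped alignments with mapping quality at or above
#' `mapq_min` (inclusive threshold).
#'
#' @param records alignment record data.frame (see [read_sam_records()]).
#' @param mapq_min minimum mapping quality retained (default 20).
#' @return the filtered data.frame.
#' @export
filter_alignments <- function(records, mapq_min = 20) {
  records[records$is_mapped & !records$is_secondary &
            records$mapq >= mapq_min, , drop = FALSE]
}

#' Place markers by paired-alignment consistency
#'
#' Applies the placement consistency rule to quality-filtered alignments:
#' a marker is placed if and only if each of its two mates has exactly one
#' surviving ungapped (full-length match CIGAR) alignment, the mates lie on
#' the same chromosome in convergent orientation, the inner gap between
#' them is exactly one reference base, and the reference base in that gap
#' is not `N`. The gap coordinate becomes the SNP position. Markers placed
#' on the reference minus strand (left read aligned `-`) are accepted with
#' their alleles complemented and the strand recorded.
#'
#' Rejected markers carry exactly one primary reason, assigned in the fixed
#' order `mate` (a mate missing after filtering), `ambiguous` (a mate with
#' several surviving alignments), `cigar` (gapped flank alignment),
#' `orientation` (different chromosome or non-convergent strands), `gap`
#' (inner gap not exactly one base), `N-site`, `lookup` (reference lookup
#' failure).
#'
#' @param records filtered alignment records (after [filter_alignments()]).
#' @param reference_base_lookup function `(chromosome, position) -> base`;
#'   see [fasta_base_lookup()].
#' @param alleles optional named list mapping marker id to its allele pair
#'   (from the manifest); complemented for minus-strand placements.
#' @return list with `placed` (data.frame: marker_id, chromosome,
#'   snp_position, ref_allele, alt_allele, strand) and `rejected`
#'   (data.frame: marker_id, reason).
#' @export
consistency_filter <- function(records, reference_base_lookup,
                               alleles = NULL) {
  stopifnot(is.function(reference_base_lookup))
  mate <- sub("^.*_([12])$", "\\1", records$read_id)
  marker <- sub("_[12]$", "", records$read_id)
  if (any(!mate %in% c("1", "2")))
    stop("read ids must end in _1 or _2: ",
         records$read_id[!mate %in% c("1", "2")][1])

  placed <- list(); rejected <- list()
  for (mk in unique(marker)) {
    r <- records[marker == mk, , drop = FALSE]
    m1 <- r[mate[marker == mk] == "1", , drop = FALSE]
    m2 <- r[mate[marker == mk] == "2", , drop = FALSE]
    reject <- function(why) rejected[[mk]] <<- data.frame(
      marker_id = mk, reason = why, stringsAsFactors = FALSE)
    if (nrow(m1) == 0 || nrow(m2) == 0) { reject("mate"); next }
    if (nrow(m1) > 1 || nrow(m2) > 1) { reject("ambiguous"); next }
    if (!grepl("^[0-9]+M$", m1$cigar) || !grepl("^[0-9]+M$", m2$cigar)) {
      reject("cigar"); next
    }
    same_chr <- identical(m1$chromosome, m2$chromosome)
    fwd <- same_chr && m1$strand == "+" && m2$strand == "-" &&
      m1$end < m2$start
    rev <- same_chr && m1$strand == "-" && m2$strand == "+" &&
      m2$end < m1$start
    if (!fwd && !rev) { reject("orientation"); next }
    gap_lo <- as.integer(if (fwd) m1$end else m2$end)
    gap_hi <- as.integer(if (fwd) m2$start else m1$start)
    if (gap_hi - gap_lo != 2L) { reject("gap"); next }
    snp_pos <- gap_lo + 1L
    base <- tryCatch(reference_base_lookup(m1$chromosome, snp_pos),
                     error = function(e) NULL)
    if (is.null(base)) { reject("lookup"); next }
    if (toupper(base) == "N") { reject("N-site"); next }
    al <- if (!is.null(alleles) && !is.null(alleles[[mk]]))
      alleles[[mk]] else c(NA_character_, NA_character_)
    if (rev && !anyNA(al)) al <- chartr("ACGT", "TGCA", al)
    placed[[mk]] <- data.frame(
      marker_id = mk, chromosome = m1$chromosome, snp_position = snp_pos,
      ref_allele = al[1], alt_allele = al[2],
      strand = if (fwd) "+" else "-", stringsAsFactors = FALSE)
  }
  empty_placed <- data.frame(marker_id = character(), chromosome = character(),
                             snp_position = integer(), ref_allele = character(),
                             alt_allele = character(), strand = character(),
                             stringsAsFactors = FALSE)
  empty_rej <- data.frame(marker_id = character(), reason = character(),
                          stringsAsFactors = FALSE)
  list(placed = if (length(placed)) do.call(rbind, c(placed,
         make.row.names = FALSE)) else empty_placed,
       rejected = if (length(rejected)) do.call(rbind, c(rejected,
         make.row.names = FALSE)) else empty_rej)
}

#' Reference base lookup from sequences
#'
#' Builds the `(chromosome, position) -> base` closure that
#' [consistency_filter()] needs, from either a named character vector of
#' chromosome sequences or a `Biostrings::DNAStringSet` / FASTA path.
#'
#' @param reference named character vector, `DNAStringSet`, or path to a
#'   FASTA file.
#' @return a function of `(chromosome, position)` returning a single base;
#'   it errors on unknown chromosomes or out-of-range positions.
#' @export
fasta_base_lookup <- function(reference) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  if (methods::is(reference, "XStringSet")) {
    seqs <- reference
    function(chromosome, position) {
      if (!chromosome %in% names(seqs))
        stop("unknown chromosome: ", chromosome)
      if (position < 1 || position > Biostrings::width(seqs[chromosome]))
        stop("position out of range: ", chromosome, ":", position)
      as.character(Biostrings::subseq(seqs[[chromosome]], position, position))
    }
  } else {
    stopifnot(is.character(reference), !is.null(names(reference)))
    function(chromosome, position) {
      if (!chromosome %in% names(reference))
        stop("unknown chromosome: ", chromosome)
      if (position < 1 || position > nchar(reference[[chromosome]]))
        stop("position out of range: ", chromosome, ":", position)
      substr(reference[[chromosome]], position, position)
    }
  }
}

#' Remove markers mapping to the same physical position
#'
#' Among markers sharing a (chromosome, position), only the first in input
#' order is retained; the rest are reported with the id of the marker kept
#' in their place.
#'
#' @param placed placed-marker data.frame from [consistency_filter()].
#' @param input_order optional character vector of marker ids defining
#'   priority (defaults to the row order of `placed`).
#' @return list with `placed` (deduplicated) and `removed` (data.frame:
#'   marker_id, reason = "duplicate-position", kept_marker).
#' @export
dedupe_placements <- function(placed, input_order = NULL) {
  if (!is.null(input_order))
    placed <- placed[order(match(placed$marker_id, input_order)), ,
                     drop = FALSE]
  key <- paste(placed$chromosome, placed$snp_position)
  dup <- duplicated(key)
  removed <- placed[dup, c("marker_id", "chromosome", "snp_position"),
                    drop = FALSE]
  if (nrow(removed)) {
    first_of <- placed$marker_id[!dup][match(key[dup], key[!dup])]
    removed$reason <- "duplicate-position"
    removed$kept_marker <- first_of
  } else {
    removed$reason <- character(0)
    removed$kept_marker <- character(0)
  }
  rownames(removed) <- NULL
  out <- placed[!dup, , drop = FALSE]
  rownames(out) <- NULL
  list(placed = out, removed = removed)
}

#' Run the full placement stage
#'
#' Convenience wrapper: splits manifest context sequences (recording their
#' allele pairs), quality-filters the alignment records, applies the
#' consistency filter and positional deduplication, and returns placed
#' markers plus a full rejection report.
#'
#' @param manifest marker manifest data.frame (see [read_marker_manifest()]).
#' @param records alignment record data.frame.
#' @param reference reference accepted by [fasta_base_lookup()].
#' @param mapq_min minimum mapping quality (default 20).
#' @return list with `placed`, `rejected` (reason per rejected marker,
#'   including duplicate-position removals) and `n_input`.
#' @export
place_markers <- function(manifest, records, reference, mapq_min = 20) {
  alleles <- lapply(seq_len(nrow(manifest)), function(i)
    split_context_sequence(manifest$context_sequence[i],
                           manifest$marker_id[i])$alleles)
  names(alleles) <- manifest$marker_id
  kept <- filter_alignments(records, mapq_min = mapq_min)
  res <- consistency_filter(kept, fasta_base_lookup(reference),
                            alleles = alleles)
  # markers in the manifest with no surviving alignments at all
  absent <- setdiff(manifest$marker_id,
                    c(res$placed$marker_id, res$rejected$marker_id))
  if (length(absent))
    res$rejected <- rbind(res$rejected,
                          data.frame(marker_id = absent, reason = "mate",
                                     stringsAsFactors = FALSE))
  dd <- dedupe_placements(res$placed, input_order = manifest$marker_id)
  rejected <- rbind(res$rejected,
                    dd$removed[, c("marker_id", "reason"), drop = FALSE])
  rejected <- rejected[order(match(rejected$marker_id,
                                   manifest$marker_id)), , drop = FALSE]
  rownames(rejected) <- NULL
  list(placed = dd$placed, rejected = rejected, n_input = nrow(manifest))
}

#' Tally placed markers by chromosome and sub-genome
#'
#' Chromosome labels are expected in wheat style (`1A` ... `7D`); anything
#' unparseable is counted under `"unknown"` with a warning. Returns counts
#' per chromosome group and sub-genome, with totals and sub-genome
#' percentage shares.
#'
#' @param chrom character vector of chromosome labels, one per placed
#'   marker, or the `placed` data.frame from [place_markers()].
#' @param counts optional integer vector of pre-aggregated counts parallel
#'   to `chrom` (one label per chromosome).
#' @return list with `table` (chromosome-group x sub-genome count matrix
#'   with margins), `unknown` count, `total` grand total, and `share`
#'   (named percentages per sub-genome, of the assigned markers).
#' @export
tally_by_chromosome <- function(chrom, counts = NULL) {
  if (is.data.frame(chrom)) chrom <- chrom$chromosome
  if (is.null(counts)) counts <- rep(1L, length(chrom))
  counts <- as.integer(counts)
  stopifnot(length(chrom) == length(counts))
  ok <- grepl("^[1-7][ABD]$", chrom)
  if (any(!ok) && !all(chrom[!ok] == "unknown"))
    warning(sum(!ok & chrom != "unknown"),
            " unparseable chromosome label(s) counted as unknown")
  unknown <- sum(counts[!ok])
  grp <- substr(chrom[ok], 1, 1)
  sub <- substr(chrom[ok], 2, 2)
  tab <- matrix(0L, nrow = 7, ncol = 3,
                dimnames = list(as.character(1:7), c("A", "B", "D")))
  for (i in seq_along(grp))
    tab[grp[i], sub[i]] <- tab[grp[i], sub[i]] + counts[ok][i]
  tab <- cbind(tab, Total = rowSums(tab))
  tab <- rbind(tab, Total = colSums(tab))
  storage.mode(tab) <- "integer"
  assigned <- tab["Total", "Total"]
  share <- if (assigned > 0)
    100 * tab["Total", c("A", "B", "D")] / assigned else
      setNames(rep(NA_real_, 3), c("A", "B", "D"))
  list(table = tab, unknown = unknown, total = assigned + unknown,
       share = share)
}
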