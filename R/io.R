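#' Read a tabular genotype file
#'
#' Reads the package's tab-separated genotype dialect: one header row of
#' accession ids, one row per marker with the marker id in the first column.
#' Calls may be letter-coded (`AA`, `AB`, `BB`; `AA` maps to dosage 1,
#' `AB` to 0.5, `BB` to 0 — heterozygote phase is ignored) or numeric
#' (`0`, `0.5`, `1`). Optional reserved columns `chrom` and `pos`
#' immediately after the marker id carry map positions. A comment line
#' `#collection<TAB>...` carries collection labels.
#'
#' @param path file path.
#' @param missing_token token denoting a missing call (default `"--"`).
#' @return a [genotypes] object (accessions x markers).
#' @export
read_genotype_table <- function(path, missing_token = "--") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  coll_line <- grep("^#collection\t", lines, value = TRUE)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2) stop("genotype table needs a header and data rows: ",
                              path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1)
    stop(sprintf("ragged genotype table %s: row %d has %d fields, expected %d",
                 path, which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1]))
  header <- fields[[1]]
  meta_cols <- which(header %in% c("chrom", "pos"))
  acc_cols <- setdiff(seq_along(header)[-1], meta_cols)
  acc_ids <- header[acc_cols]
  if (anyDuplicated(acc_ids))
    stop("duplicate accession id in header: ",
         acc_ids[duplicated(acc_ids)][1])
  body <- fields[-1]
  marker_ids <- vapply(body, `[`, "", 1L)
  if (anyDuplicated(marker_ids))
    stop("duplicate marker id at row ",
         which(duplicated(marker_ids))[1] + 1L, ": ",
         marker_ids[duplicated(marker_ids)][1])
  tok <- t(vapply(body, function(f) f[acc_cols], character(length(acc_cols))))
  dos <- matrix(NA_real_, nrow = length(body), ncol = length(acc_cols))
  map <- c("AA" = 1, "AB" = 0.5, "BA" = 0.5, "BB" = 0,
           "0" = 0, "0.5" = 0.5, "1" = 1)
  known <- matrix(tok %in% c(names(map), missing_token), nrow = nrow(tok))
  if (!all(known)) {
    bad <- which(!known, arr.ind = TRUE)[1, ]
    stop(sprintf("unknown call token '%s' at marker %s, accession %s",
                 tok[!known][1], marker_ids[bad[1]], acc_ids[bad[2]]))
  }
  dos[] <- map[tok]
  calls <- t(dos)  # accessions x markers
  dimnames(calls) <- list(acc_ids, marker_ids)
  chrom <- pos <- NULL
  if (length(meta_cols)) {
    md <- t(vapply(body, function(f) f[meta_cols], character(length(meta_cols))))
    colnames(md) <- header[meta_cols]
    if ("chrom" %in% colnames(md)) chrom <- md[, "chrom"]
    if ("pos" %in% colnames(md)) pos <- as.integer(md[, "pos"])
  }
  collections <- NULL
  if (length(coll_line) == 1) {
    cf <- strsplit(coll_line, "\t", fixed = TRUE)[[1]][-1]
    if (length(cf) == length(acc_ids)) collections <- cf
  }
  genotypes(calls, collections = collections, chrom = chrom, pos = pos)
}

#' Write a genotype matrix to the tabular dialect
#'
#' Lossless counterpart of [read_genotype_table()]: dosages are written as
#' `0`/`0.5`/`1`, missing calls as `missing_token`; collection labels and
#' marker map positions are preserved.
#'
#' @param g a [genotypes] object.
#' @param path output file path.
#' @param missing_token missing-call token.
#' @return invisibly, `path`.
#' @export
write_genotype_table <- function(g, path, missing_token = "--") {
  validate_genotypes(g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coreselect genotype table", con)
  if (!all(is.na(g$accession_info$collection)))
    writeLines(paste(c("#collection", g$accession_info$collection),
                     collapse = "\t"), con)
  has_map <- !all(is.na(g$marker_info$chrom))
  header <- c("marker_id", if (has_map) c("chrom", "pos"),
              accession_ids(g))
  writeLines(paste(header, collapse = "\t"), con)
  tok <- t(g$calls)  # markers x accessions
  chr <- matrix(as.character(tok), nrow = nrow(tok))
  chr[is.na(tok)] <- missing_token
  body <- apply(chr, 1, paste, collapse = "\t")
  if (has_map)
    body <- paste(g$marker_info$chrom, g$marker_info$pos, body, sep = "\t")
  writeLines(paste(marker_ids(g), body, sep = "\t"), con)
  invisible(path)
}

#' Read biallelic records from a VCF file
#'
#' Diploid `GT` fields are mapped to reference-allele dosages:
#' `0/0` to 1, `0/1` or `1/0` to 0.5, `1/1` to 0 and `./.` to missing
#' (phased separators are treated alike). Records with more than one
#' alternate allele are skipped; the number skipped is reported as a message
#' and attached as attribute `"skipped_multiallelic"`. `CHROM`/`POS` and the
#' `REF`/`ALT` alleles are stored as marker metadata.
#'
#' @param path VCF file path (plain or bgzipped).
#' @return a [genotypes] object (possibly with zero markers).
#' @export
read_vcf_biallelic <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
    dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  bi <- !is.na(alt) & !grepl(",", alt, fixed = TRUE)
  n_skip <- sum(!bi)
  if (n_skip > 0) message(n_skip, " multi-allelic record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
    dimnames = list(rownames(gt), colnames(gt)))
  gt <- gt[bi, , drop = FALSE]
  fix <- fix[bi, , drop = FALSE]
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  if (nrow(gt) == 0) {
    calls <- matrix(numeric(0), ncol = 0, nrow = ncol(gt),
                    dimnames = list(colnames(gt), character(0)))
  } else {
    core <- gsub("|", "/", gt, fixed = TRUE)
    map <- c("0/0" = 1, "0/1" = 0.5, "1/0" = 0.5, "1/1" = 0)
    dos <- matrix(map[core], nrow = nrow(gt), dimnames = dimnames(gt))
    calls <- t(dos)
    colnames(calls) <- ids
  }
  out <- genotypes(calls,
                   chrom = if (nrow(fix)) fix[, "CHROM"] else NULL,
                   pos = if (nrow(fix)) as.integer(fix[, "POS"]) else NULL,
                   alleles = if (nrow(fix))
                     fix[, c("REF", "ALT"), drop = FALSE] else NULL)
  attr(out, "skipped_multiallelic") <- n_skip
  out
}

#' Write and read labelled distance matrices
#'
#' The on-disk format is a tab-separated square table with accession ids as
#' both header and first column, preceded by a `# metric:` comment line.
#' Values survive the round trip bit-exactly (17 significant digits).
#'
#' @param D a [gdist] matrix (validated before writing).
#' @param path file path.
#' @return `write_distance_matrix()`: invisibly `path`;
#'   `read_distance_matrix()`: a validated [gdist] matrix.
#' @export
write_distance_matrix <- function(D, path) {
  validate_gdist(D)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# metric: %s", attr(D, "metric") %||% "other"), con)
  writeLines(paste(c("id", rownames(D)), collapse = "\t"), con)
  vals <- format(D, digits = 17, trim = TRUE, scientific = FALSE)
  writeLines(paste(rownames(D), apply(vals, 1, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  metric <- "other"
  ml <- grep("^# metric:", lines, value = TRUE)
  if (length(ml)) metric <- trimws(sub("^# metric:", "", ml[1]))
  lines <- lines[!startsWith(lines, "#")]
  tab <- read.table(text = lines, header = TRUE, sep = "\t",
                    check.names = FALSE, row.names = 1)
  D <- as.matrix(tab)
  dimnames(D) <- list(rownames(tab), colnames(tab))
  gdist(D, metric = metric)
}

#' Read a marker manifest (context sequences)
#'
#' Accepts either a tab-separated table with columns `marker_id` and
#' `context_sequence` (optional `origin`), or a FASTA-style file whose
#' sequences contain the bracket site. Each context sequence must contain
#' exactly one `[X/Y]` site with distinct alleles in \{A,C,G,T\}, non-empty
#' flanks, and only A,C,G,T,N outside the bracket.
#'
#' @param path manifest file path.
#' @return data.frame with columns `marker_id`, `context_sequence`, `origin`.
#' @export
read_marker_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    ss <- Biostrings::readBStringSet(path)
    man <- data.frame(marker_id = names(ss),
                      context_sequence = as.character(ss),
                      origin = "fasta", stringsAsFactors = FALSE)
  } else {
    man <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    if (!all(c("marker_id", "context_sequence") %in% names(man)))
      stop("manifest must have columns marker_id and context_sequence: ",
           path)
    if (is.null(man$origin)) man$origin <- "table"
  }
  if (anyDuplicated(man$marker_id))
    stop("duplicate marker id in manifest: ",
         man$marker_id[duplicated(man$marker_id)][1])
  for (i in seq_len(nrow(man)))
    check_context_sequence(man$context_sequence[i], man$marker_id[i])
  man
}

check_context_sequence <- function(ctx, id) {
  n_open <- lengths(regmatches(ctx, gregexpr("\\[", ctx)))
  if (n_open != 1 ||
      !grepl("^[ACGTN]+\\[[ACGT]/[ACGT]\\][ACGTN]+$", ctx))
    stop("marker ", id, ": context sequence must be ",
         "FLANK[X/Y]FLANK with non-empty A/C/G/T/N flanks and one bracket")
  al <- regmatches(ctx, regexpr("\\[[ACGT]/[ACGT]\\]", ctx))
  al <- strsplit(gsub("[][]", "", al), "/", fixed = TRUE)[[1]]
  if (al[1] == al[2])
    stop("marker ", id, ": bracket alleles must differ")
  invisible(TRUE)
}

#' Write and read core set files
#'
#' A core file holds one accession id per line, preceded by `#`-comment
#' provenance lines (method, metric, seed, run).
#'
#' @param core a [core_set].
#' @param path file path.
#' @return `write_core()`: invisibly `path`; `read_core()`: a [core_set].
#' @export
write_core <- function(core, path) {
  stopifnot(inherits(core, "core_set"))
  hdr <- sprintf("# %s: %s", c("method", "metric", "seed", "run"),
                 c(attr(core, "method"), attr(core, "metric"),
                   attr(core, "seed"), attr(core, "run")))
  writeLines(c(hdr, unclass(core)), path)
  invisible(path)
}

#' @rdname write_core
#' @export
read_core <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    v <- sub(paste0("^# ", key, ": "), "", grep(paste0("^# ", key, ":"),
                                                hdr, value = TRUE))
    if (length(v) == 0 || v == "NA") NA_character_ else v
  }
  core_set(lines[!startsWith(lines, "#")], method = get("method"),
           metric = get("metric"),
           seed = suppressWarnings(as.integer(get("seed"))),
           run = suppressWarnings(as.integer(get("run"))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
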