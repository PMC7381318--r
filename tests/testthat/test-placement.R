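test_that("context sequences split into correct pseudo read pairs", {
  s <- split_context_sequence("AC[T/C]GA")
  expect_identical(s$left_read, "AC")
  expect_identical(s$right_read, "TC")  # reverse complement of GA
  expect_identical(s$alleles, c("T", "C"))
  # palindromic right flank is a reverse-complement fixed point
  s2 <- split_context_sequence("GGG[A/G]AT")
  expect_identical(s2$right_read, "AT")
  expect_error(split_context_sequence("[A/G]TT"), "non-empty")
  expect_error(split_context_sequence("AA[A/G]T[C/G]A"), "one bracket")
})

test_that("fixture context sequences re-embed into the reference", {
  fix <- sim_placement_fixture(30, 25, seed = 13)
  tr <- fix$truth[fix$truth$kept, ]
  for (i in seq_len(nrow(tr))) {
    m <- fix$manifest[fix$manifest$marker_id == tr$marker_id[i], ]
    s <- split_context_sequence(m$context_sequence)
    rebuilt <- paste0(s$left_read, s$alleles[1],
                      coreselect:::revcomp(s$right_read))
    ref <- fix$reference[[tr$chrom[i]]]
    span <- substr(ref, tr$pos[i] - nchar(s$left_read),
                   tr$pos[i] + nchar(s$right_read))
    expect_identical(rebuilt, span)
  }
})

test_that("alignment quality filter applies its thresholds inclusively", {
  rec <- data.frame(
    read_id = paste0("m", 1:4, "_1"),
    chromosome = "1A", start = 1L, end = 20L, strand = "+",
    mapq = c(20L, 19L, 60L, 60L),
    is_secondary = c(FALSE, FALSE, TRUE, FALSE),
    is_mapped = c(TRUE, TRUE, TRUE, FALSE),
    cigar = "20M", stringsAsFactors = FALSE)
  kept <- filter_alignments(rec, mapq_min = 20)
  expect_identical(kept$read_id, "m1_1")  # 20 kept, 19/secondary/unmapped out
})

test_that("consistency filter applies the one-nucleotide-gap rule", {
  lookup <- function(chrom, pos) if (pos == 120) "G" else "A"
  rec <- function(id, start, end, strand)
    data.frame(read_id = id, chromosome = "chr1", start = start, end = end,
               strand = strand, mapq = 60L, is_secondary = FALSE,
               is_mapped = TRUE, cigar = paste0(end - start + 1, "M"),
               stringsAsFactors = FALSE)
  good <- rbind(rec("mA_1", 100, 119, "+"), rec("mA_2", 121, 140, "-"))
  res <- consistency_filter(good, lookup)
  expect_identical(res$placed$snp_position, 120L)
  expect_identical(res$placed$chromosome, "chr1")

  gap2 <- rbind(rec("mB_1", 100, 119, "+"), rec("mB_2", 122, 141, "-"))
  expect_identical(consistency_filter(gap2, lookup)$rejected$reason, "gap")

  lone <- rec("mC_1", 100, 119, "+")
  expect_identical(consistency_filter(lone, lookup)$rejected$reason, "mate")

  n_lookup <- function(chrom, pos) "N"
  expect_identical(consistency_filter(good, n_lookup)$rejected$reason,
                   "N-site")

  ambig <- rbind(good[1, ], rec("mA_2", 121, 140, "-"),
                 rec("mA_2", 500, 519, "-"))
  expect_identical(consistency_filter(ambig, lookup)$rejected$reason,
                   "ambiguous")

  gapped_cigar <- good
  gapped_cigar$cigar[2] <- "10M2D10M"
  expect_identical(consistency_filter(gapped_cigar, lookup)$rejected$reason,
                   "cigar")

  disc <- good
  disc$strand[2] <- "+"
  expect_identical(consistency_filter(disc, lookup)$rejected$reason,
                   "orientation")
})

test_that("minus-strand placements are accepted with complemented alleles", {
  lookup <- function(chrom, pos) "C"
  rec <- function(id, start, end, strand)
    data.frame(read_id = id, chromosome = "chr2", start = start, end = end,
               strand = strand, mapq = 60L, is_secondary = FALSE,
               is_mapped = TRUE, cigar = paste0(end - start + 1, "M"),
               stringsAsFactors = FALSE)
  # read 1 on minus strand downstream, read 2 on plus upstream
  pair <- rbind(rec("mR_1", 221, 240, "-"), rec("mR_2", 200, 219, "+"))
  res <- consistency_filter(pair, lookup, alleles = list(mR = c("A", "G")))
  expect_identical(res$placed$snp_position, 220L)
  expect_identical(res$placed$strand, "-")
  expect_identical(c(res$placed$ref_allele, res$placed$alt_allele),
                   c("T", "C"))
})

test_that("positional dedup keeps the first marker in input order", {
  placed <- data.frame(
    marker_id = c("mA", "mB", "mC", "mD"),
    chromosome = c("2B", "2B", "2B", "1A"),
    snp_position = c(500L, 500L, 500L, 9L),
    ref_allele = "A", alt_allele = "G", strand = "+",
    stringsAsFactors = FALSE)
  dd <- dedupe_placements(placed)
  expect_identical(dd$placed$marker_id, c("mA", "mD"))
  expect_identical(dd$removed$marker_id, c("mB", "mC"))
  expect_identical(unique(dd$removed$kept_marker), "mA")
  # all-unique input is untouched
  uniq <- placed[3:4, ]
  expect_identical(dedupe_placements(uniq)$placed, local({
    u <- uniq; rownames(u) <- NULL; u
  }))
  # input_order overrides row order
  dd2 <- dedupe_placements(placed, input_order = c("mB", "mA", "mC", "mD"))
  expect_identical(dd2$placed$marker_id[1], "mB")
})

test_that("full placement stage reproduces the fixture truth exactly", {
  for (seed in c(3, 17, 29)) {
    fix <- sim_placement_fixture(36, 30, seed = seed)
    res <- place_markers(fix$manifest, fix$alignments, fix$reference)
    expect_setequal(res$placed$marker_id,
                    fix$truth$marker_id[fix$truth$kept])
    tr <- fix$truth[match(res$placed$marker_id, fix$truth$marker_id), ]
    expect_identical(res$placed$chromosome, tr$chrom)
    expect_identical(res$placed$snp_position, tr$pos)
    # each rejected marker carries exactly the constructed reason
    rej <- merge(res$rejected, fix$truth, by = "marker_id")
    expect_identical(rej$reason.x, rej$reason.y)
    # reasons partition the rejected set
    expect_identical(sort(c(res$placed$marker_id, res$rejected$marker_id)),
                     sort(fix$truth$marker_id))
    # counts monotone along the stages
    expect_lte(nrow(res$placed), res$n_input)
  }
})

test_that("SAM round trip preserves alignment records", {
  fix <- sim_placement_fixture(20, 30, seed = 8)
  dir <- withr::local_tempdir()
  paths <- write_placement_fixture(fix, dir)
  rec <- read_sam_records(paths$alignments)
  orig <- fix$alignments
  # order may differ after BAM conversion; compare per read id
  rec <- rec[order(rec$read_id), ]
  orig <- orig[order(orig$read_id), ]
  expect_identical(rec$read_id, orig$read_id)
  m <- orig$is_mapped
  expect_identical(rec$is_mapped, m)
  expect_identical(rec$start[m], orig$start[m])
  expect_identical(rec$end[m], orig$end[m])
  expect_identical(rec$strand[m], orig$strand[m])
  expect_identical(rec$cigar[m], orig$cigar[m])
  # and the placement result from the files matches the in-memory one
  man <- read_marker_manifest(paths$manifest)
  res_file <- place_markers(man, rec, paths$reference)
  res_mem <- place_markers(fix$manifest, fix$alignments, fix$reference)
  expect_identical(res_file$placed, res_mem$placed)
})

test_that("chromosome tally computes shares, totals and the unknown bin", {
  t1 <- tally_by_chromosome(c("1A", "1A", "1B", "1B", "1B"))
  expect_identical(unname(t1$table["Total", "Total"]), 5L)
  expect_equal(unname(t1$share), c(40, 60, 0))
  t0 <- tally_by_chromosome(character(0))
  expect_identical(unname(t0$table["Total", "Total"]), 0L)
  expect_warning(t2 <- tally_by_chromosome(c("1A", "chrX")), "unknown")
  expect_identical(t2$unknown, 1L)
})

test_that("tally aggregates an array-scale marker distribution", {
  # counts per chromosome of a wheat array placement (grand total 8,221)
  chroms <- as.vector(outer(1:7, c("A", "B", "D"), paste0))
  counts <- c(451, 480, 415, 287, 508, 485, 546,   # A
              580, 710, 556, 258, 595, 530, 485,   # B
              270, 289, 142, 62, 186, 169, 144)    # D
  t <- tally_by_chromosome(c(chroms, "unknown"), c(counts, 73))
  expect_identical(unname(t$table["Total", "Total"]), 8148L)
  expect_identical(t$total, 8221L)
  expect_identical(unname(t$table["Total", c("A", "B", "D")]),
                   c(3172L, 3714L, 1262L))
  expect_identical(unname(t$table["5", "B"]), 595L)
  expect_equal(unname(round(t$share)), c(39, 46, 15))
})
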