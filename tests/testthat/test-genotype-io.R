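test_that("letter-coded calls map to dosages", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("marker_id\tacc1\tacc2",
               "m1\tAA\tBB",
               "m2\tAB\t--"), path)
  g <- read_genotype_table(path)
  expect_identical(g$calls["acc1", c("m1", "m2")], c(m1 = 1, m2 = 0.5))
  expect_identical(g$calls["acc2", "m1"], 0)
  expect_true(is.na(g$calls["acc2", "m2"]))
})

test_that("genotype table round-trips losslessly", {
  g <- sim_genotypes(collection_sizes = c(8, 12), n_markers = 30,
                     missing_rate = 0.15, seed = 21)
  g$marker_info$chrom <- rep(c("1A", "2B", "3D"), 10)
  g$marker_info$pos <- seq_len(30) * 100L
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(g, path)
  g2 <- read_genotype_table(path)
  expect_identical(g2$calls, g$calls)
  expect_identical(g2$accession_info$collection, g$accession_info$collection)
  expect_identical(g2$marker_info$chrom, g$marker_info$chrom)
  expect_identical(g2$marker_info$pos, g$marker_info$pos)
})

test_that("format violations are rejected with location context", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("marker_id\ta1\ta2", "m1\tAA\tAB", "m1\tBB\tAA"), path)
  expect_error(read_genotype_table(path), "duplicate marker id")
  writeLines(c("marker_id\ta1\ta2", "m1\tAA"), path)
  expect_error(read_genotype_table(path), "ragged")
  writeLines(c("marker_id\ta1\ta2", "m1\tAA\tXY"), path)
  expect_error(read_genotype_table(path), "XY")
  writeLines(c("marker_id\ta1\ta1", "m1\tAA\tAB"), path)
  expect_error(read_genotype_table(path), "duplicate accession")
})

test_that("VCF reader maps genotypes and round-trips via an independent export", {
  g <- sim_genotypes(collection_sizes = c(6, 6), n_markers = 15,
                     missing_rate = 0.1, seed = 31)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_helper(g, path)
  g2 <- read_vcf_biallelic(path)
  expect_identical(unname(g2$calls[accession_ids(g), marker_ids(g)]),
                   unname(g$calls))
  expect_identical(attr(g2, "skipped_multiallelic"), 0L)
})

test_that("heterozygous and multi-allelic VCF records are handled", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
               "1\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/1\t1|0",
               "1\t200\tsnp2\tC\tG,T\t.\tPASS\t.\tGT\t0/1\t0/2"), path)
  expect_message(g <- read_vcf_biallelic(path), "1 multi-allelic")
  expect_identical(ncol(g$calls), 1L)
  expect_identical(unname(g$calls[, "snp1"]), c(0.5, 0.5))
  expect_identical(attr(g, "skipped_multiallelic"), 1L)
  # all records multi-allelic -> empty matrix, full skip count
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "1\t100\tsnp1\tA\tG,T\t.\tPASS\t.\tGT\t0/2",
               "1\t200\tsnp2\tC\tG,A\t.\tPASS\t.\tGT\t1/2"), path)
  expect_message(g0 <- read_vcf_biallelic(path), "2 multi-allelic")
  expect_identical(ncol(g0$calls), 0L)
  expect_identical(attr(g0, "skipped_multiallelic"), 2L)
})

test_that("distance matrices round-trip bit-exactly and are validated", {
  D <- rand_gdist(5, 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(D, path)
  D2 <- read_distance_matrix(path)
  expect_identical(unclass(D2)[, ], unclass(D)[, ])
  expect_identical(attr(D2, "metric"), attr(D, "metric"))

  bad <- unclass(D); bad[1, 2] <- bad[1, 2] + 0.1  # asymmetric
  expect_error(write_distance_matrix(
    structure(bad, class = class(D), metric = "MRD"), path), "symmetric")
  neg <- unclass(D); neg[1, 2] <- neg[2, 1] <- -0.2
  expect_error(write_distance_matrix(
    structure(neg, class = class(D), metric = "MRD"), path), "\\[0, 1\\]")
})

test_that("core files keep entries and provenance", {
  core <- core_set(c("a3", "a1", "a7"), method = "ANE", metric = "MRD",
                   seed = 42L, run = 7L)
  path <- withr::local_tempfile(fileext = ".txt")
  write_core(core, path)
  core2 <- read_core(path)
  expect_identical(unclass(core2), unclass(core))
  expect_identical(attr(core2, "method"), "ANE")
  expect_identical(attr(core2, "seed"), 42L)
})

test_that("marker manifests validate the bracket-site grammar", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("marker_id\tcontext_sequence",
               "m1\tACGT[A/G]TTAA"), path)
  man <- read_marker_manifest(path)
  expect_identical(man$marker_id, "m1")
  writeLines(c("marker_id\tcontext_sequence", "m1\tACGT[A/A]TT"), path)
  expect_error(read_marker_manifest(path), "differ")
  writeLines(c("marker_id\tcontext_sequence", "m1\t[A/G]TTAA"), path)
  expect_error(read_marker_manifest(path), "non-empty")
  writeLines(c("marker_id\tcontext_sequence", "m1\tAC[A/G]TT[C/T]AA"),
             path)
  expect_error(read_marker_manifest(path), "one bracket")
  # FASTA-style manifest
  writeLines(c(">m9", "ACGT[A/G]TTAA"), path)
  man2 <- read_marker_manifest(path)
  expect_identical(man2$marker_id, "m9")
  expect_identical(man2$context_sequence, "ACGT[A/G]TTAA")
})
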