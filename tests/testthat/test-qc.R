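test_that("pre-imputation filter applies boundary and reason semantics", {
  calls <- cbind(
    ok       = c(1, 0, 0.5, 1, 0, 1, 0, 1, 0, 1),
    miss30   = c(NA, NA, NA, 1, 0, 1, 0, 1, 0, 1),   # 30% missing: removed
    miss20   = c(NA, NA, 0.5, 1, 0, 1, 0, 1, 0, 1),  # 20% missing: kept
    mono     = rep(1, 10),                           # monomorphic: removed
    allhet   = rep(0.5, 10),                         # heterozygote-only: kept
    dup      = c(1, 0, 0.5, 1, 0, 1, 0, 1, 0, 1)     # duplicate of "ok"
  )
  g <- geno_from(calls)
  res <- filter_pre_imputation(g, max_missing = 0.30)
  expect_setequal(marker_ids(res$genotypes), c("ok", "miss20", "allhet"))
  r <- res$report$reasons
  expect_identical(unname(r[c("miss30", "mono", "dup")]),
                   c("missing", "monomorphic", "duplicate"))
  # stage accounting balances
  st <- res$report$stages
  expect_true(all(st$input == st$removed + st$retained))
  expect_identical(st$retained[nrow(st)], 3L)
  expect_error(filter_pre_imputation(g[, 0]), "empty")
})

test_that("duplicate removal keeps the first marker in order", {
  calls <- cbind(m1 = c(1, 0, 1), m2 = c(1, 0, 1), m3 = c(1, 0, 1))
  calls <- rbind(calls, c(0, 0, 0))  # make polymorphic
  g <- geno_from(calls)
  res <- filter_pre_imputation(g)
  expect_identical(marker_ids(res$genotypes), "m1")
})

test_that("naive imputation is seeded, degenerate-safe and frequency-matching", {
  g <- sim_genotypes(collection_sizes = c(10, 10), n_markers = 20, seed = 6)
  expect_identical(impute_naive(g, seed = 1)$calls, g$calls)  # no missing

  calls <- cbind(allone = c(rep(1, 9), NA), seg = c(rep(c(1, 0), 5)))
  gi <- impute_naive(geno_from(calls), seed = 2)
  expect_identical(unname(gi$calls[10, "allone"]), 1)

  # multinomial concentration at observed frequencies (1/4, 1/2, 1/4)
  obs <- c(rep(1, 10), rep(0.5, 20), rep(0, 10))
  calls2 <- matrix(c(obs, rep(NA_real_, 10000)), ncol = 1)
  gbig <- impute_naive(geno_from(calls2), seed = 3)
  imp <- gbig$calls[41:10040, 1]
  expect_lt(abs(mean(imp == 0.5) - 0.5), 0.02)
  expect_lt(abs(mean(imp == 1) - 0.25), 0.02)
  expect_lt(abs(mean(imp == 0) - 0.25), 0.02)
  expect_identical(impute_naive(geno_from(calls2), seed = 3)$calls,
                   gbig$calls)

  allmiss <- geno_from(cbind(bad = rep(NA_real_, 5), ok = c(1, 0, 1, 0, 1)))
  expect_error(impute_naive(allmiss), "filter_pre_imputation")
})

test_that("post-imputation filter applies inclusive MAF and heterozygosity bounds", {
  calls <- cbind(
    maf05  = c(rep(1, 950), rep(0, 50)),     # q = 0.95, MAF = 0.05: kept
    maf049 = c(rep(1, 951), rep(0, 49)),     # MAF = 0.049: removed
    het125 = c(rep(0.5, 125), rep(1, 437), rep(0, 438)),  # het 12.5%: kept
    het25  = c(rep(0.5, 250), rep(1, 375), rep(0, 375))   # het 25%: removed
  )
  g <- geno_from(calls)
  res <- filter_post_imputation(g, maf_min = 0.05, het_max = 0.125)
  expect_setequal(marker_ids(res$genotypes), c("maf05", "het125"))
  expect_identical(unname(res$report$reasons[c("maf049", "het25")]),
                   c("maf", "heterozygosity"))

  # hand arithmetic: 9 x dosage 1 + 1 x dosage 0 -> q = 0.9, MAF = 0.1, kept
  g2 <- geno_from(cbind(m = c(rep(1, 9), 0)))
  expect_identical(marker_ids(filter_post_imputation(g2)$genotypes), "m")

  gm <- geno_from(cbind(m = c(1, NA, 0)))
  expect_error(filter_post_imputation(gm), "missing")
})

test_that("post-imputation filtering is idempotent", {
  g <- sim_genotypes(collection_sizes = c(40, 40), n_markers = 300,
                     ancestral_freq_range = c(0.02, 0.98), seed = 44)
  r1 <- filter_post_imputation(g)
  r2 <- filter_post_imputation(r1$genotypes)
  expect_identical(r2$genotypes$calls, r1$genotypes$calls)
  expect_true(all(r2$report$stages$removed == 0))
})

test_that("perfect-LD collapse groups identical and complementary vectors", {
  calls <- cbind(
    a = c(1, 0.5, 0, 1), b = c(0, 0.5, 1, 0),    # complementary pair
    c = c(1, 1, 0, 0), d = c(1, 1, 0, 0), e = c(1, 1, 0, 0),
    f = c(1, 0, 0, 1)                             # its own block
  )
  g <- geno_from(calls)
  res1 <- collapse_perfect_ld(g, keep = 1)
  expect_setequal(marker_ids(res1$genotypes), c("a", "c", "f"))
  expect_identical(res1$blocks$block[res1$blocks$marker_id == "b"],
                   res1$blocks$block[res1$blocks$marker_id == "a"])
  # five identical vectors, keep two representatives
  calls5 <- calls[, c("c", "d", "e")]
  calls5 <- cbind(calls5, g2 = calls5[, 1], h2 = calls5[, 1])
  res2 <- collapse_perfect_ld(geno_from(calls5), keep = 2)
  expect_identical(n_markers(res2$genotypes), 2L)
  expect_identical(sum(!res2$blocks$retained), 3L)
  # pairwise distinct, non-complementary input passes through
  dist_in <- geno_from(cbind(x = c(1, 0, 0, 0), y = c(1, 1, 0, 0),
                             z = c(1, 1, 1, 0)))
  expect_identical(n_markers(collapse_perfect_ld(dist_in)$genotypes), 3L)
})

test_that("perfect-LD collapse is invariant to flipping a marker's allele coding", {
  g <- sim_genotypes(collection_sizes = c(10, 10), n_markers = 40, seed = 55)
  # duplicate some markers and flip others to create blocks
  calls <- g$calls
  calls[, 5] <- calls[, 1]
  calls[, 6] <- 1 - calls[, 2]
  colnames(calls) <- sprintf("m%02d", seq_len(ncol(calls)))
  b1 <- collapse_perfect_ld(geno_from(calls))$blocks
  flipped <- calls
  flipped[, 1] <- 1 - flipped[, 1]   # flip coding of a block member
  b2 <- collapse_perfect_ld(geno_from(flipped))$blocks
  expect_identical(b1$block, b2$block)
})

test_that("QC cascade is monotone and balances its accounting", {
  g <- sim_genotypes(collection_sizes = c(30, 30), n_markers = 400,
                     ancestral_freq_range = c(0.02, 0.98),
                     missing_rate = 0.1, seed = 66)
  res <- qc_cascade(g, impute_seed = 9)
  expect_false(anyNA(res$genotypes$calls))
  counts <- c(n_markers(g),
              res$reports$pre$stages$retained,
              res$reports$post$stages$retained)
  expect_true(all(diff(counts) <= 0))
  for (r in res$reports)
    expect_true(all(r$stages$input == r$stages$removed + r$stages$retained))
})
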