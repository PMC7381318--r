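test_that("PAM handles degenerate and well-separated cases exactly", {
  D <- rand_gdist(6, 3)
  # k = N: every accession is a medoid, zero cost
  res <- pam_kmedoids(D, 6)
  expect_equal(res$cost, 0)
  expect_setequal(unclass(res$core), rownames(D))

  # two well-separated triplets: one medoid per triplet, brute-force optimal
  ids <- paste0("a", 1:6)
  Dt <- matrix(0.9, 6, 6, dimnames = list(ids, ids))
  Dt[1:3, 1:3] <- 0.1; Dt[4:6, 4:6] <- 0.1; diag(Dt) <- 0
  Dt <- gdist(Dt)
  res2 <- pam_kmedoids(Dt, 2)
  expect_equal(res2$cost, exhaustive_pam_cost(Dt, 2))
  grp <- (match(unclass(res2$core), ids) - 1) %/% 3
  expect_setequal(grp, c(0, 1))
})

test_that("PAM is deterministic and validates its inputs", {
  D <- rand_gdist(12, 5)
  r1 <- pam_kmedoids(D, 3)
  r2 <- pam_kmedoids(D, 3)
  expect_identical(unclass(r1$core), unclass(r2$core))
  expect_identical(r1$cost, r2$cost)
  init <- c("a1", "a5", "a9")
  r3 <- pam_kmedoids(D, 3, initial_medoids = init)
  expect_identical(unclass(r3$core),
                   unclass(pam_kmedoids(D, 3, initial_medoids = init)$core))
  # swap phase never worsens the initial-medoid cost
  init_cost <- sum(apply(unclass(D)[, match(init, rownames(D))], 1, min))
  expect_lte(r3$cost, init_cost + 1e-12)
  expect_error(pam_kmedoids(D, 0), "k")
  expect_error(pam_kmedoids(D, 3, initial_medoids = c("a1", "a1", "a2")),
               "unique")
  expect_error(pam_kmedoids(D, 3, initial_medoids = c("a1", "a2")),
               "length k")
})

test_that("PAM agrees with the reference implementation on random geometry", {
  skip_if_not_installed("cluster")
  agree <- 0
  for (s in 1:40) {
    set.seed(s)
    n <- sample(8:14, 1); k <- sample(2:3, 1)
    D <- rand_gdist(n, s + 500)
    ours <- pam_kmedoids(D, k)$cost
    cp <- cluster::pam(stats::as.dist(unclass(D)), k)
    ref <- sum(apply(unclass(D)[, match(cp$medoids, rownames(D)),
                                drop = FALSE], 1, min))
    if (abs(ours - ref) < 1e-9) agree <- agree + 1
  }
  # both are local searches; they may settle in different basins rarely
  expect_gte(agree, 36)
})

test_that("local search is deterministic and respects its contracts", {
  g <- sim_genotypes(collection_sizes = c(10, 10), n_markers = 50, seed = 8)
  D <- mrd_dist(g)
  c1 <- local_search_select("ANE", D, 5, seed = 7, max_evaluations = 1000,
                            patience = 300)
  c2 <- local_search_select("ANE", D, 5, seed = 7, max_evaluations = 1000,
                            patience = 300)
  expect_identical(unclass(c1), unclass(c2))
  expect_identical(attr(c1, "value"), attr(c2, "value"))
  expect_equal(attr(c1, "value"), avg_accession_nearest(c1, D),
               tolerance = 1e-12)
  c3 <- local_search_select("SD", g, 5, seed = 7, max_evaluations = 1000,
                            patience = 300)
  expect_equal(attr(c3, "value"), shannon_diversity(c3, g),
               tolerance = 1e-9)
  expect_error(local_search_select("ENE", D, 1), "k >= 2")
  expect_error(local_search_select("ANE", D, 5, max_evaluations = 0),
               "positive")
})

test_that("incremental objective updates match full recomputation", {
  g <- sim_genotypes(collection_sizes = c(8, 8), n_markers = 40, seed = 15)
  D <- mrd_dist(g)
  for (obj in c("ENE", "ANE", "SD", "EH", "AC")) {
    f <- objective_fun(obj, g, D)
    for (s in 1:5) {
      core <- local_search_select(obj, if (obj %in% c("ENE", "ANE")) D
                                  else g, 4, seed = s,
                                  max_evaluations = 500, patience = 200)
      direct <- f(match(unclass(core), accession_ids(g)))
      reported <- attr(core, "value") * (if (obj == "ANE") -1 else 1)
      expect_equal(reported, direct, tolerance = 1e-9)
    }
  }
})

test_that("coverage objective attains a constructed optimum of 1", {
  # three complementary carriers jointly cover every allele
  base <- matrix(1, 10, 12)
  base[1, 1:4] <- 0; base[2, 5:8] <- 0; base[3, 9:12] <- 0
  rownames(base) <- paste0("a", 1:10)
  colnames(base) <- paste0("m", 1:12)
  g <- geno_from(base)
  core <- local_search_select("AC", g, 3, seed = 2,
                              max_evaluations = 3000, patience = 1000,
                              restarts = 5)
  expect_equal(allele_coverage(core, g), 1)
})

test_that("random cores are uniform, seeded and bounded", {
  ids <- paste0("a", 1:50)
  expect_setequal(unclass(random_core(ids, 50, seed = 1)), ids)
  expect_identical(unclass(random_core(ids, 10, seed = 5)),
                   unclass(random_core(ids, 10, seed = 5)))
  expect_error(random_core(ids, 51), "k")
  counts <- setNames(numeric(50), ids)
  for (s in 1:10000) {
    picked <- unclass(random_core(ids, 10, seed = s))
    counts[picked] <- counts[picked] + 1
  }
  f <- counts / 10000
  expect_true(all(abs(f - 0.2) < 0.02))
})

test_that("PAM cores represent the collection better than random cores", {
  g <- sim_genotypes(collection_sizes = c(25, 25), n_markers = 100,
                     seed = 19)
  D <- mrd_dist(g)
  diff <- vapply(1:50, function(s) {
    pam_core <- pam_kmedoids(D, 8,
      initial_medoids = with_seed_ids(rownames(D), 8, s))$core
    rnd <- random_core(rownames(D), 8, seed = s)
    avg_accession_nearest(rnd, D) - avg_accession_nearest(pam_core, D)
  }, 0)
  expect_gt(mean(diff), 0)
})
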