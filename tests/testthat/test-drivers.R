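test_that("mantel statistic matches vegan and saturates on identical input", {
  set.seed(6)
  t <- random_table(8, 20, seed = 6)
  bc <- bray_curtis(t)
  self <- mantel_test(bc, bc, n_permutations = 99, seed = 1)
  expect_equal(self$r, 1)
  env_d <- labelled_dm(as.matrix(dist(rnorm(8))), rownames(bc))
  ours <- mantel_test(bc, env_d, n_permutations = 99, seed = 2)
  veg <- vegan::mantel(stats::as.dist(bc), stats::as.dist(env_d),
                       permutations = 19)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-12)
  expect_gte(ours$p, 1 / 100)
  expect_error(mantel_test(bc, env_d[c(2:8, 1), c(2:8, 1)]), "label")
})

test_that("mantel permutation p approaches the exhaustive value at n = 5", {
  set.seed(3)
  d1 <- labelled_dm(as.matrix(dist(rnorm(5))), paste0("s", 1:5))
  d2 <- labelled_dm(as.matrix(dist(rnorm(5))), paste0("s", 1:5))
  lt <- lower.tri(d1)
  perms <- rbind(1:5)
  all_perm <- gtools_permutations <- NULL
  # enumerate all 120 permutations by recursion (no extra dependency)
  gen <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in gen(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  r_obs <- cor(d1[lt], d2[lt])
  r_all <- vapply(gen(1:5), function(p) cor(d1[lt], d2[p, p][lt]),
                  numeric(1))
  exact_p <- mean(r_all >= r_obs)
  est <- mantel_test(d1, d2, n_permutations = 999, seed = 8)
  se <- sqrt(exact_p * (1 - exact_p) / 999)
  expect_lt(abs(est$p - exact_p), 2 * se + 2 / 1000)
})

test_that("mantel r is invariant under common relabeling", {
  set.seed(4)
  d1 <- labelled_dm(as.matrix(dist(rnorm(6))), paste0("s", 1:6))
  d2 <- labelled_dm(as.matrix(dist(rnorm(6))), paste0("s", 1:6))
  r0 <- mantel_test(d1, d2, n_permutations = 49, seed = 1)$r
  o <- c(3, 1, 6, 2, 5, 4)
  r1 <- mantel_test(d1[o, o], d2[o, o], n_permutations = 49, seed = 1)$r
  expect_equal(r1, r0)
})

test_that("distance decay detects constructed monotone structure", {
  x <- seq(0, 100, length.out = 8)
  d <- labelled_dm(abs(outer(x, x, "-")) / 100, paste0("s", 1:8))
  res <- distance_decay(d, x, n_permutations = 199, seed = 2)
  expect_gt(res$r, 0.99)
  expect_lt(res$similarity_slope, 0)
  expect_equal(res$similarity_slope, -1 / 100, tolerance = 1e-9)
  expect_error(distance_decay(d, rep(1, 8)), "constant")
  # shuffled community: correlation collapses
  set.seed(5)
  perm <- sample(8)
  res0 <- distance_decay(labelled_dm(d[perm, perm], paste0("s", 1:8)), x,
                         n_permutations = 199, seed = 2)
  expect_lt(abs(res0$r), 0.5)
})

test_that("bioenv equals a brute-force reimplementation and vegan", {
  set.seed(11)
  t <- random_table(10, 25, seed = 11)
  bc <- bray_curtis(t)
  env <- tibble::tibble(v1 = rnorm(10), v2 = rnorm(10), v3 = rnorm(10),
                        v4 = rnorm(10))
  res <- bioenv_search(bc, env, max_subset_size = 4)
  # independent double-implementation of the subset loop
  z <- scale(as.matrix(env))
  lt <- lower.tri(bc)
  brute <- list()
  for (size in 1:4) {
    for (cb in utils::combn(4, size, simplify = FALSE)) {
      brute[[paste(colnames(env)[cb], collapse = " + ")]] <-
        cor(bc[lt], as.matrix(dist(z[, cb, drop = FALSE]))[lt],
            method = "spearman")
    }
  }
  got <- setNames(res$subsets$correlation, res$subsets$variables)
  expect_equal(got[names(brute)], unlist(brute)[names(brute)],
               tolerance = 1e-12)
  expect_equal(res$subsets$correlation, sort(res$subsets$correlation,
                                             decreasing = TRUE))
  expect_equal(res$best$correlation, max(res$subsets$correlation))
  # vegan agreement on the best subset's correlation
  veg <- vegan::bioenv(stats::as.dist(bc), as.data.frame(env),
                       index = "euclidean", upto = 4)
  veg_best <- veg$models[[veg$whichbest]]
  expect_equal(res$best$correlation, veg_best$est, tolerance = 1e-10)
  expect_error(bioenv_search(bc, as.data.frame(matrix(rnorm(160), 10))),
               "at most 15")
})

test_that("bioenv recovers a planted generating variable", {
  cfg <- sim_config(n_sites = 15, n_otus = 150, depth = 4000,
                    niche_strength = 5, env_noise_sd = 0.05, seed = 19)
  sim <- simulate_niche_metacommunity(cfg)
  bc <- bray_curtis(sim$table)
  env <- tibble::tibble(
    driver = sim$metadata$hails_true,
    noise1 = rnorm(15), noise2 = rnorm(15), noise3 = rnorm(15)
  )
  set.seed(23)
  env[2:4] <- lapply(env[2:4], function(x) rnorm(15))
  res <- bioenv_search(bc, env, max_subset_size = 2)
  expect_equal(res$best$variables, "driver")
  # all-noise env: best correlation stays near zero
  res0 <- bioenv_search(bc, env[2:4], max_subset_size = 2)
  expect_lt(res0$best$correlation, 0.45)
})

test_that("constrained ordination flags planted drivers and decomposes variance", {
  cfg <- sim_config(n_sites = 15, n_otus = 120, depth = 4000,
                    niche_strength = 5, seed = 29)
  sim <- simulate_niche_metacommunity(cfg)
  set.seed(31)
  env <- tibble::tibble(driver = sim$metadata$hails_true,
                        noise = rnorm(15))
  res <- constrained_ordination_significance(sim$table, env,
                                             n_permutations = 199, seed = 3)
  expect_lte(res$terms$p[res$terms$variable == "driver"], 0.01)
  # decomposition identity: constrained + unconstrained = total
  expect_equal(res$constrained_inertia / res$total_inertia,
               sum(res$axes$proportion), tolerance = 1e-9)
  expect_lte(sum(res$axes$proportion), 1 + 1e-9)
  # collinear columns dropped with a warning
  env2 <- dplyr::mutate(env, dup = driver * 2)
  expect_warning(constrained_ordination_significance(
    sim$table, env2, n_permutations = 99, seed = 3), "collinear")
})

test_that("varpart3 fractions sum to one and match vegan exactly", {
  set.seed(5)
  n <- 20
  t <- random_table(n, 30, lambda = 20, seed = 5)
  X1 <- tibble::tibble(a = rnorm(n), b = rnorm(n))
  X2 <- tibble::tibble(c = rnorm(n), d = rnorm(n))
  X3 <- tibble::tibble(e = rnorm(n))
  vp <- varpart3(t, X1, X2, X3)
  expect_equal(sum(vp$fractions), 1, tolerance = 1e-9)
  hel <- vegan::decostand(otu_counts(t), "hellinger")
  veg <- vegan::varpart(hel, as.data.frame(X1), as.data.frame(X2),
                        as.data.frame(X3))
  expect_equal(unname(vp$fractions),
               veg$part$indfract$Adj.R.square, tolerance = 1e-10)
  # identity holds across random draws
  for (s in 1:4) {
    set.seed(100 + s)
    vp_s <- varpart3(random_table(15, 20, seed = s),
                     tibble::tibble(a = rnorm(15)),
                     tibble::tibble(b = rnorm(15)),
                     tibble::tibble(c = rnorm(15)))
    expect_equal(sum(vp_s$fractions), 1, tolerance = 1e-9)
  }
})

test_that("varpart3 attributes planted and duplicated signal correctly", {
  cfg <- sim_config(n_sites = 15, n_otus = 120, depth = 4000,
                    niche_strength = 5, seed = 37)
  sim <- simulate_niche_metacommunity(cfg)
  set.seed(41)
  X1 <- tibble::tibble(driver = sim$metadata$hails_true)
  X2 <- tibble::tibble(n1 = rnorm(15))
  X3 <- tibble::tibble(n2 = rnorm(15))
  vp <- varpart3(sim$table, X1, X2, X3)
  f <- vp$fractions
  expect_gt(f[["a"]], 0.1)                       # pure planted driver
  # noise/shared fractions stay small relative to the planted one
  expect_lt(max(abs(f[c("b", "c", "d", "e", "f", "g")])), f[["a"]] / 2)
  # duplicated matrix: signal moves to the shared fraction
  vp2 <- varpart3(sim$table, X1, X1, X3)
  expect_lt(abs(vp2$fractions[["a"]]), 0.02)
  expect_lt(abs(vp2$fractions[["b"]]), 0.02)
  expect_gt(vp2$fractions[["d"]], 0.1)
})

test_that("topology_distance standardises the panel for network bioenv", {
  rec <- tibble::tibble(group = c("g1", "g2", "g3"),
                        TN = c(10, 20, 30), TL = c(20, 45, 80),
                        avgK = c(4, 4.5, 5.3), avgCC = c(0.5, 0.6, 0.7),
                        GD = c(0.4, 0.2, 0.2), NM = c(5, 4, 3),
                        M = c(0.8, 0.7, 0.6))
  dm <- topology_distance(rec)
  expect_equal(rownames(dm), rec$group)
  expect_equal(diag(dm), setNames(rep(0, 3), rec$group))
  expect_true(all(dm >= 0))
})
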