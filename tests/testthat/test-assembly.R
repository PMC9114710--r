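test_that("c_score matches an independent double-loop recomputation", {
  # perfect checkerboard: single pair contributes (2-0)(2-0) = 4
  cb <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(c_score(cb), 4)
  # identical site sets: S = r for the pair, term 0
  expect_equal(c_score(rbind(c(1, 0, 1), c(1, 0, 1))), 0)
  brute <- function(m) {
    vals <- c()
    for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
      s <- sum(m[i, ] & m[j, ])
      vals <- c(vals, (sum(m[i, ]) - s) * (sum(m[j, ]) - s))
    }
    mean(vals)
  }
  set.seed(10)
  for (rep in 1:10) {
    m <- matrix(rbinom(25, 1, 0.5), 5, 5)
    expect_equal(c_score(m), brute(m))
  }
  # invariance under row and column permutation
  m <- matrix(rbinom(42, 1, 0.4), 6, 7)
  expect_equal(c_score(m[sample(6), sample(7)]), c_score(m))
  expect_error(c_score(matrix(c(0, 2), 2, 2)), "binary")
})

test_that("sequential swap preserves margins at every sampled state", {
  set.seed(3)
  base <- matrix(rbinom(80, 1, 0.4), 10, 8)
  mats <- sample_null_matrices(base, 25, burn_in = 200, thin = 37, seed = 5)
  for (m in mats) {
    expect_equal(rowSums(m), rowSums(base))
    expect_equal(colSums(m), colSums(base))
    expect_true(all(m %in% c(0, 1)))
  }
  # chains actually move
  expect_gt(sum(vapply(mats, function(m) sum(m != base), numeric(1))), 0)
})

test_that("swap-chain null mean matches exhaustive fixed-margin enumeration", {
  base <- rbind(c(1, 1, 0, 0), c(1, 0, 1, 0), c(0, 1, 0, 1), c(0, 0, 1, 1))
  rs <- rowSums(base)
  cs <- colSums(base)
  vals <- c()
  for (code in 0:65535) {
    m <- matrix(bitwAnd(bitwShiftR(code, 0:15), 1L), 4, 4)
    if (all(rowSums(m) == rs) && all(colSums(m) == cs)) {
      vals <- c(vals, c_score(m))
    }
  }
  expect_gt(length(vals), 1)
  res <- null_model_ses(base, n_simulations = 2000, burn_in = 1000,
                        thin = 20, seed = 5)
  expect_lt(abs(res$null_mean - mean(vals)) / mean(vals), 0.02)
  expect_equal(res$ses, (res$observed_statistic - res$null_mean) / res$null_sd)
})

test_that("degenerate matrices without swaps yield a flagged sentinel", {
  frozen <- rbind(c(1, 1, 0), c(1, 1, 0))   # no 2x2 checkerboard exists
  expect_warning(res <- null_model_ses(frozen, n_simulations = 50,
                                       burn_in = 100, thin = 5, seed = 1),
                 "degenerate")
  expect_true(is.na(res$ses))
  expect_equal(res$null_sd, 0)
})

test_that("segregated matrices give positive SES beyond 2", {
  sim <- simulate_niche_metacommunity(
    sim_config(n_sites = 15, n_otus = 150, depth = 4000,
               niche_strength = 5, seed = 11))
  res <- null_model_ses(presence_matrix(sim$table), n_simulations = 300,
                        burn_in = 3000, thin = 20, seed = 3)
  expect_gt(res$ses, 2)
})

test_that("neutral model fit recovers the immigration rate", {
  t <- simulate_neutral_metacommunity(
    sim_config(n_sites = 15, n_otus = 300, depth = 8000,
               migration_m = 0.5, seed = 7))
  fit <- fit_ncm(t)
  expect_gt(fit$m, 0.4)
  expect_lt(fit$m, 0.6)
  expect_gt(fit$r_squared, 0.6)
  # contract checks on the per-OTU table
  otus <- tidy(fit)
  expect_true(all(otus$predicted_freq >= 0 & otus$predicted_freq <= 1))
  expect_true(all(otus$ci_low <= otus$predicted_freq + 1e-9))
  expect_true(all(otus$ci_high >= otus$predicted_freq - 1e-9))
  expect_true(all(otus$partition[otus$observed_freq > otus$ci_high] == "above"))
  expect_true(all(otus$partition[otus$observed_freq < otus$ci_low] == "below"))
  g <- glance(fit)
  expect_equal(g$m, fit$Nm / fit$N)
})

test_that("abundant ubiquitous OTUs saturate the neutral prediction", {
  set.seed(4)
  m <- matrix(rpois(10 * 40, 5), 10, 40)
  m[, 1] <- 5000                      # dominant OTU present everywhere
  t <- otu_tibble(m, sample_ids = sprintf("s%02d", 1:10))
  fit <- fit_ncm(t)
  row <- tidy(fit)[tidy(fit)$otu_id == "OTU0001", ]
  expect_gt(row$predicted_freq, 0.999)
  expect_equal(row$observed_freq, 1)
  expect_equal(row$partition, "within")
  expect_error(fit_ncm(t[1:4, ]), ">= 5 samples")
})

test_that("fit quality drops on niche-structured data at matched size", {
  r2 <- vapply(c(0, 5), function(ns) {
    sim <- simulate_niche_metacommunity(
      sim_config(n_sites = 15, n_otus = 150, depth = 4000,
                 niche_strength = ns, seed = 11))
    fit_ncm(sim$table)$r_squared
  }, numeric(1))
  expect_gt(r2[1], r2[2])
})

test_that("Levins' niche breadth matches hand-computed cases", {
  # uniform across N communities -> B = N; single community -> B = 1
  t <- otu_tibble(matrix(c(4, 4, 4,
                           9, 0, 0,
                           5, 5, 0), nrow = 3,
                         dimnames = list(NULL, c("u", "s", "h"))),
                  sample_ids = c("c1", "c2", "c3"))
  nb <- niche_breadth(t)
  expect_equal(nb$otus$B[nb$otus$otu_id == "u"], 3)
  expect_equal(nb$otus$B[nb$otus$otu_id == "s"], 1)
  expect_equal(nb$otus$B[nb$otus$otu_id == "h"], 2)   # P = (.5, .5, 0)
  expect_true(all(nb$otus$B >= 1 - 1e-12 &
                  nb$otus$B <= nb$otus$n_communities + 1e-12))
  # grouped: absent OTUs excluded and counted
  g <- niche_breadth(t, groups = c("g1", "g1", "g2"))
  # community c3 holds only OTU "u": the other two are excluded from g2
  expect_equal(g$summary$n_excluded[g$summary$group == "g2"], 2)
})

test_that("null SES calibration keeps false alarms rare", {
  set.seed(99)
  base <- matrix(rbinom(25 * 12, 1, 0.4), 25, 12)
  mats <- sample_null_matrices(base, 60, burn_in = 2000, thin = 2000,
                               seed = 17)
  ses <- vapply(seq_along(mats), function(i) {
    null_model_ses(mats[[i]], n_simulations = 200, burn_in = 2000,
                   thin = 50, seed = 1000 + i)$ses
  }, numeric(1))
  expect_gte(mean(abs(ses) < 2), 0.9)
})
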