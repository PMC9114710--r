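# planted correlation structure with constant sample totals, so the
# pattern survives conversion to relative abundance: A2 tracks A exactly,
# C mirrors it, noise pairs are complementary random fill
planted_corr_table <- function(n = 10, n_noise_pairs = 3, seed = 8) {
  set.seed(seed)
  x <- sort(sample(100:400, n))
  m <- cbind(A = x, A2 = x, C = 1000 - 2 * x)
  for (k in seq_len(n_noise_pairs)) {
    y <- sample(100:400, n)
    m <- cbind(m, y, 500 - y)
  }
  colnames(m)[-(1:3)] <- sprintf("N%02d", seq_len(2 * n_noise_pairs))
  otu_tibble(m, sample_ids = sprintf("s%02d", 1:n))
}

test_that("planted correlations become signed edges", {
  net <- build_network(planted_corr_table(), min_prevalence = 0,
                       threshold = 0.8, n_permutations = 500, seed = 2)
  ab <- net$edges[net$edges$u == "A" & net$edges$v == "A2", ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$weight, 1)          # monotone identical ranks
  expect_equal(ab$sign, "+")
  ac <- net$edges[net$edges$u == "A" & net$edges$v == "C", ]
  expect_equal(ac$weight, -1)
  expect_equal(ac$sign, "-")
  expect_true(all(abs(net$edges$weight) >= 0.8))
  expect_true(all(net$edges$q <= 0.05))
  expect_error(build_network(planted_corr_table()[1:3, ]), "samples")
})

test_that("independent noise passes FDR control", {
  set.seed(31)
  t <- otu_tibble(matrix(rpois(12 * 40, 30), 12,
                         dimnames = list(NULL, sprintf("o%02d", 1:40))),
                  sample_ids = sprintf("s%02d", 1:12))
  net <- build_network(t, min_prevalence = 0, threshold = 0,
                       n_permutations = 500, q_cutoff = 0.05, seed = 3)
  n_pairs <- choose(40, 2)
  expect_lte(nrow(net$edges) / n_pairs, 0.05 * 2)
})

test_that("topology identities hold on built networks and closed forms", {
  net <- build_network(planted_corr_table(n_noise_pairs = 5), min_prevalence = 0,
                       threshold = 0.5, n_permutations = 300,
                       q_cutoff = 0.3, seed = 4)
  tp <- topology(net)
  expect_equal(tp$TL, tp$NL + tp$PL)
  expect_equal(tp$avgK, 2 * tp$TL / tp$TN)
  expect_equal(tp$GD, 2 * tp$TL / (tp$TN * (tp$TN - 1)))
  if (tp$PL > 0) expect_equal(tp$NP, tp$NL / tp$PL)
  # complete graph on 5 nodes: avgCC = GD = APD = 1, CD = 0
  g5 <- igraph::make_full_graph(5)
  igraph::V(g5)$name <- letters[1:5]
  fake <- structure(list(graph = g5,
                         edges = tibble::tibble(sign = rep("+", 10))),
                    class = "conetwork")
  t5 <- topology(fake)
  expect_equal(t5$avgCC, 1)
  expect_equal(t5$GD, 1)
  expect_equal(t5$APD, 1)
  expect_equal(t5$CD, 0)
  expect_equal(t5$avgK, 4)
})

test_that("derived indices reproduce published-style panels from counts", {
  d <- derived_topology_indices(TN = c(100, 173), TL = c(184, 594),
                                NL = c(49, 267), PL = c(135, 327))
  expect_equal(round(d$avgK, 2), c(3.68, 6.87))
  expect_equal(round(d$NP, 2), c(0.36, 0.82))
  expect_equal(round(d$GD, 2), c(0.04, 0.04))
})

test_that("module detection maximises and reports Newman-Girvan modularity", {
  tri2 <- igraph::make_graph(~ a-b, b-c, c-a, d-e, e-f, f-d)
  dm <- detect_modules(tri2)
  expect_equal(dm$NM, 2)
  expect_equal(dm$M, 0.5)     # two equal components: Q = 2 (1/2 - 1/4^2 *4)
  clique <- igraph::make_full_graph(6)
  dmc <- detect_modules(clique)
  expect_equal(dmc$NM, 1)
  expect_equal(dmc$M, 0)
  # modularity equals definitional recomputation Q = sum(e_ss - a_s^2)
  set.seed(9)
  g <- igraph::sample_gnp(25, 0.15)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  res <- detect_modules(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  L <- nrow(el)
  mem <- res$membership
  e_ss <- vapply(sort(unique(mem)), function(s) {
    sum(mem[el[, 1]] == s & mem[el[, 2]] == s) / L
  }, numeric(1))
  a_s <- vapply(sort(unique(mem)), function(s) {
    sum((mem[el[, 1]] == s) + (mem[el[, 2]] == s)) / (2 * L)
  }, numeric(1))
  expect_equal(res$M, sum(e_ss - a_s^2), tolerance = 1e-12)
})

test_that("zi/pi roles match hand computation on the planted-module toy", {
  toy <- planted_module_graph()
  roles <- node_roles(toy$graph, toy$membership)
  r <- function(id) roles[roles$otu_id == id, ]
  # hub of the 8-node star: kin = 7 against module mean 1.75, sd sqrt(3.9375)
  expect_equal(r("a1")$zi, 5.25 / sqrt(3.9375), tolerance = 1e-12)
  expect_equal(r("a1")$pi, 0)
  expect_equal(r("a1")$category, "module hub")
  # bridge nodes split degree 2 evenly across the two modules
  expect_equal(r("a2")$pi, 0.5)
  expect_equal(r("b10")$pi, 0.5)
  expect_equal(r("b9")$zi, 1.5 / sqrt(0.75), tolerance = 1e-12)
  expect_equal(r("b9")$category, "peripheral")
  expect_true(all(roles$category[!roles$otu_id %in% "a1"] == "peripheral"))
  # categories partition all nodes and survive relabeling
  expect_equal(nrow(roles), 12)
  perm <- c(a1 = 2, a2 = 2, a3 = 2, a4 = 2, a5 = 2, a6 = 2, a7 = 2, a8 = 2,
            b9 = 7, b10 = 7, b11 = 7, b12 = 7)
  roles2 <- node_roles(toy$graph, perm)
  expect_equal(table(roles2$category), table(roles$category))
})

test_that("threshold role boundaries follow the zi/pi conventions", {
  # central node with degree 4 split over 4 triangle modules: pi = 0.75
  g <- igraph::make_graph(~ h-a1, h-b1, h-c1, h-d1,
                          a1-a2, a2-a3, a3-a1, b1-b2, b2-b3, b3-b1,
                          c1-c2, c2-c3, c3-c1, d1-d2, d2-d3, d3-d1)
  mem <- c(h = 5, a1 = 1, a2 = 1, a3 = 1, b1 = 2, b2 = 2, b3 = 2,
           c1 = 3, c2 = 3, c3 = 3, d1 = 4, d2 = 4, d3 = 4)
  roles <- node_roles(g, mem)
  h <- roles[roles$otu_id == "h", ]
  expect_equal(h$pi, 1 - 4 * (1 / 16))
  expect_equal(h$category, "connector")   # pi = 0.75 > 0.62, zi below 2.5
})

test_that("gradient schemes produce the expected network series", {
  cfg <- sim_config(n_sites = 15, n_otus = 120, depth = 3000,
                    niche_strength = 3, seed = 14)
  sim <- simulate_niche_metacommunity(cfg)
  nets <- networks_along_gradient(sim$table, sim$metadata,
                                  scheme = "per-reach-triplicate", seed = 2,
                                  min_prevalence = 0.5, threshold = 0.7,
                                  n_permutations = 100, q_cutoff = 0.5)
  expect_equal(nrow(nets), 9)
  expect_equal(sum(startsWith(nets$group, "upper")), 3)
  # subset HAILS means increase from upper to lower reaches
  expect_lt(mean(nets$hails[startsWith(nets$group, "upper")]),
            mean(nets$hails[startsWith(nets$group, "lower")]))
  nets3 <- networks_along_gradient(sim$table, sim$metadata,
                                   scheme = "per-reach", seed = 2,
                                   min_prevalence = 0.5, threshold = 0.7,
                                   n_permutations = 100, q_cutoff = 0.5)
  expect_equal(nrow(nets3), 3)
  # determinism: same seed, same subsets
  nets_b <- networks_along_gradient(sim$table, sim$metadata,
                                    scheme = "per-reach-triplicate", seed = 2,
                                    min_prevalence = 0.5, threshold = 0.7,
                                    n_permutations = 100, q_cutoff = 0.5)
  expect_identical(nets$subset, nets_b$subset)
  expect_equal(gradient_topology(nets)$TN, gradient_topology(nets_b)$TN)
})

test_that("stability regression reproduces hand least squares", {
  rec <- tibble::tibble(NM = c(50, 45, 40), M = c(0.9, 0.8, 0.7))
  h <- c(0, 10, 20)
  fit <- stability_decay(rec, h, response = "NM")
  expect_equal(fit$slope, -0.5)
  expect_equal(fit$percent_change_per_10, 10 * (-0.5) / 45 * 100)
  const <- stability_decay(tibble::tibble(NM = c(7, 7, 7), M = 1:3 / 3),
                           h, response = "NM")
  expect_equal(const$slope, 0)
  expect_equal(const$percent_change_per_10, 0)
  expect_error(stability_decay(rec[1:2, ], h[1:2]), ">= 3")
  expect_error(stability_decay(rec, c(5, 5, 5)), "all equal")
})
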