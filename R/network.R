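#' Build a signed co-occurrence network
#'
#' Pairwise correlations between OTU relative-abundance profiles across the
#' samples of a site group. An edge is kept iff `|r| >= threshold` and its
#' permutation-based BH-adjusted p (`q`) is `<= q_cutoff`. The permutation
#' null shuffles sample rows (`n_permutations` row permutations, each
#' applied to a copy of the matrix and correlated against the original, so
#' every pair receives the same-sized null). Edge sign is the sign of the
#' correlation.
#'
#' @param table A community tibble subset (one site group).
#' @param min_prevalence Drop OTUs present in fewer than this fraction of
#'   samples before testing.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param threshold Absolute-correlation cutoff for an edge.
#' @param n_permutations Row-shuffle permutations for edge p-values.
#' @param q_cutoff Benjamini-Hochberg FDR cutoff across all tested pairs.
#' @param min_samples Minimum samples required in the subset.
#' @param taxonomy Optional taxonomy tibble (`otu_id`, `taxonomy`) used to
#'   annotate nodes with a phylum.
#' @param seed Integer RNG seed.
#' @return An object of class `"conetwork"`: `graph` (igraph, absolute
#'   weights on edges plus signed attributes), `edges` and `nodes` tibbles,
#'   and `params`.
#' @export
build_network <- function(table, min_prevalence = 0.5,
                          method = c("spearman", "pearson"),
                          threshold = 0.6, n_permutations = 1000L,
                          q_cutoff = 0.05, min_samples = 5L,
                          taxonomy = otu_taxonomy(table), seed = 1L) {
  method <- match.arg(method)
  m <- otu_counts(table)
  if (nrow(m) < min_samples) {
    stop("network subset has ", nrow(m), " samples; need >= ", min_samples,
         call. = FALSE)
  }
  rel <- relative_abundance(table)
  prev <- colMeans(m > 0)
  keep <- prev >= min_prevalence
  zerovar <- apply(rel, 2, stats::sd) == 0
  if (any(keep & zerovar)) {
    warning("dropping ", sum(keep & zerovar), " zero-variance OTU column(s)",
            call. = FALSE)
  }
  keep <- keep & !zerovar
  x <- rel[, keep, drop = FALSE]
  p_otus <- ncol(x)
  if (p_otus < 2L) {
    stop("fewer than 2 OTUs pass the prevalence filter", call. = FALSE)
  }
  if (method == "spearman") x <- apply(x, 2, rank)
  xs <- scale(x)
  n <- nrow(xs)
  corr <- crossprod(xs) / (n - 1)
  withr_seed(seed, {
    exceed <- matrix(0L, p_otus, p_otus)
    for (b in seq_len(n_permutations)) {
      perm <- sample.int(n)
      null_corr <- crossprod(xs, xs[perm, , drop = FALSE]) / (n - 1)
      null_corr <- (null_corr + t(null_corr)) / 2
      exceed <- exceed + (abs(null_corr) >= abs(corr) - 1e-12)
    }
  })
  pmat <- (1 + exceed) / (1 + n_permutations)
  ut <- upper.tri(corr)
  idx <- which(ut, arr.ind = TRUE)
  edges <- tibble::tibble(
    u = colnames(x)[idx[, 1]],
    v = colnames(x)[idx[, 2]],
    weight = corr[ut],
    p = pmat[ut]
  )
  edges$q <- stats::p.adjust(edges$p, method = "BH")
  edges <- edges[abs(edges$weight) >= threshold & edges$q <= q_cutoff, ]
  edges$sign <- as.character(ifelse(edges$weight >= 0, "+", "-"))
  nodes <- tibble::tibble(otu_id = colnames(x))
  if (!is.null(taxonomy)) {
    nodes$phylum <- phylum_of(nodes$otu_id, taxonomy)
  } else {
    nodes$phylum <- NA_character_
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("u", "v")], directed = FALSE,
    vertices = nodes[nodes$otu_id %in% c(edges$u, edges$v), , drop = FALSE]
  )
  igraph::E(g)$weight <- abs(edges$weight)
  igraph::E(g)$correlation <- edges$weight
  igraph::E(g)$sign <- edges$sign
  structure(list(
    graph = g, edges = edges,
    nodes = nodes[nodes$otu_id %in% c(edges$u, edges$v), , drop = FALSE],
    params = list(method = method, threshold = threshold,
                  q_cutoff = q_cutoff, n_permutations = n_permutations,
                  min_prevalence = min_prevalence, seed = seed,
                  n_samples = n)
  ), class = "conetwork")
}

phylum_of <- function(otu_ids, taxonomy) {
  lin <- taxonomy$taxonomy[match(otu_ids, taxonomy$otu_id)]
  vapply(strsplit(ifelse(is.na(lin), "", lin), ";"), function(parts) {
    parts <- trimws(parts)
    if (length(parts) >= 2) parts[2] else NA_character_
  }, character(1))
}

#' @export
print.conetwork <- function(x, ...) {
  cat(sprintf("Co-occurrence network: %d nodes, %d edges (%d +, %d -)\n",
              igraph::vcount(x$graph), nrow(x$edges),
              sum(x$edges$sign == "+"), sum(x$edges$sign == "-")))
  cat(sprintf("  method %s, |r| >= %.2f, q <= %.2f, %d samples\n",
              x$params$method, x$params$threshold, x$params$q_cutoff,
              x$params$n_samples))
  invisible(x)
}

#' Topology panel of a co-occurrence network
#'
#' The standard index panel: total nodes (TN) and links (TL), negative and
#' positive link counts (NL, PL) and their ratio (NP), the R^2 of a
#' power-law fit to the degree distribution (R; log10 frequency vs log10
#' degree over distinct observed degrees), average degree
#' (`avgK = 2 TL / TN`), average clustering coefficient (avgCC; degree < 2
#' nodes contribute 0), average path distance over connected pairs (APD,
#' unweighted), Freeman degree centralization (CD), graph density
#' (`GD = 2 TL / (TN (TN - 1))`), and the module count (NM) and modularity
#' (M) from [detect_modules()].
#'
#' @param network A `"conetwork"` object.
#' @param seed Passed to [detect_modules()].
#' @return One-row tibble with columns
#'   `TN, TL, NL, PL, NP, R, avgK, avgCC, APD, CD, GD, NM, M`.
#' @export
topology <- function(network, seed = 1L) {
  stopifnot(inherits(network, "conetwork"))
  g <- network$graph
  tn <- igraph::vcount(g)
  if (tn < 2L) stop("topology needs >= 2 nodes", call. = FALSE)
  tl <- igraph::ecount(g)
  nl <- sum(network$edges$sign == "-")
  pl <- sum(network$edges$sign == "+")
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  apd <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE,
                               weights = NA)
  kmax <- max(deg)
  cd <- if (tn > 2) sum(kmax - deg) / ((tn - 1) * (tn - 2)) else 0
  mods <- detect_modules(network, seed = seed)
  tibble::tibble(
    TN = as.integer(tn), TL = as.integer(tl), NL = as.integer(nl),
    PL = as.integer(pl),
    NP = if (pl > 0) nl / pl else NA_real_,
    R = power_law_r2(deg),
    avgK = 2 * tl / tn,
    avgCC = mean(cc),
    APD = apd,
    CD = cd,
    GD = 2 * tl / (tn * (tn - 1)),
    NM = mods$NM,
    M = mods$M
  )
}

#' Derived topology indices from node/link counts
#'
#' The closed-form members of the topology panel, computed directly from
#' total nodes (TN), total links (TL) and the negative/positive link split
#' (NL, PL): `avgK = 2 TL / TN`, `NP = NL / PL`,
#' `GD = 2 TL / (TN (TN - 1))`. Useful for consistency-checking published
#' topology panels.
#'
#' @param TN,TL,NL,PL Integer vectors (recycled to a common length).
#' @return Tibble with `TN, TL, NL, PL, avgK, NP, GD`.
#' @export
derived_topology_indices <- function(TN, TL, NL = NA_integer_,
                                     PL = NA_integer_) {
  tibble::tibble(TN = TN, TL = TL, NL = NL, PL = PL) |>
    dplyr::mutate(
      avgK = 2 * .data$TL / .data$TN,
      NP = .data$NL / .data$PL,
      GD = 2 * .data$TL / (.data$TN * (.data$TN - 1))
    )
}

# R^2 of log10(frequency) ~ log10(degree) over distinct observed degrees >= 1
power_law_r2 <- function(deg) {
  deg <- deg[deg >= 1]
  if (length(unique(deg)) < 3L) return(NA_real_)
  tab <- table(deg)
  xf <- log10(as.numeric(names(tab)))
  yf <- log10(as.numeric(tab))
  summary(stats::lm(yf ~ xf))$r.squared
}

#' Detect modules by greedy modularity maximization
#'
#' Greedy agglomerative modularity optimisation on absolute edge weights
#' (isolated nodes, if any, become singleton modules). `M` is the
#' Newman-Girvan modularity `Q = sum_s (e_ss - a_s^2)` of the returned
#' partition on the whole graph.
#'
#' @param network A `"conetwork"` object (or bare igraph).
#' @param seed Kept for interface stability; the greedy algorithm is
#'   deterministic and ignores it.
#' @return List: `membership` (named integer vector), `NM`, `M`.
#' @export
detect_modules <- function(network, seed = 1L) {
  g <- if (inherits(network, "conetwork")) network$graph else network
  if (igraph::vcount(g) == 0L) stop("empty graph", call. = FALSE)
  if (igraph::ecount(g) == 0L) {
    mem <- seq_len(igraph::vcount(g))
    names(mem) <- igraph::V(g)$name
    return(list(membership = mem, NM = length(mem), M = 0))
  }
  w <- igraph::E(g)$weight
  w <- if (is.null(w)) rep(1, igraph::ecount(g)) else abs(w)
  fg <- igraph::cluster_fast_greedy(g, weights = w)
  # take the dendrogram cut with maximal modularity (ties -> fewest
  # modules); the library's own cut is occasionally off-optimum on
  # highly regular graphs
  n <- igraph::vcount(g)
  best <- igraph::membership(fg)
  best_q <- igraph::modularity(g, best, weights = w)
  for (k in seq_len(n)) {
    mem_k <- tryCatch(suppressWarnings(igraph::cut_at(fg, no = k)),
                      error = function(e) NULL)
    if (is.null(mem_k) || length(unique(mem_k)) != k) next
    q_k <- igraph::modularity(g, mem_k, weights = w)
    if (q_k > best_q + 1e-12 ||
        (abs(q_k - best_q) <= 1e-12 &&
         length(unique(mem_k)) < length(unique(best)))) {
      best <- mem_k
      best_q <- q_k
    }
  }
  mem <- best
  if (is.null(names(mem))) names(mem) <- igraph::V(g)$name
  list(membership = mem,
       NM = length(unique(mem)),
       M = best_q)
}

#' Classify node topological roles from zi and pi
#'
#' `zi` is the within-module degree z-score (a node's count of
#' within-module links, standardised over its module with the population
#' SD; modules with zero spread give `zi = 0`); `pi` is the participation
#' coefficient `1 - sum_s (k_is / k_i)^2` over modules `s`. Roles follow
#' the conventional thresholds: network hubs (`zi > 2.5`, `pi > 0.62`),
#' module hubs (`zi > 2.5`, `pi <= 0.62`), connectors (`zi <= 2.5`,
#' `pi > 0.62`), peripherals otherwise.
#'
#' @param network A `"conetwork"` object (or bare igraph).
#' @param modules Module membership as returned by [detect_modules()] (the
#'   list or the bare membership vector). `NULL` runs [detect_modules()].
#' @return Tibble with `otu_id`, `degree`, `within_module_degree`, `zi`,
#'   `pi`, `category`.
#' @export
node_roles <- function(network, modules = NULL) {
  g <- if (inherits(network, "conetwork")) network$graph else network
  if (is.null(igraph::V(g)$name)) {
    g <- igraph::set_vertex_attr(g, "name",
                                 value = as.character(seq_len(igraph::vcount(g))))
  }
  if (is.null(modules)) modules <- detect_modules(network)
  mem <- if (is.list(modules)) modules$membership else modules
  vnames <- igraph::V(g)$name
  if (is.null(names(mem))) names(mem) <- vnames
  if (!all(vnames %in% names(mem))) {
    stop("module assignment must cover all nodes", call. = FALSE)
  }
  mem <- mem[vnames]
  el <- igraph::as_edgelist(g, names = TRUE)
  k <- igraph::degree(g)
  n <- length(vnames)
  # within-module degree and per-module degree split
  kin <- stats::setNames(numeric(n), vnames)
  ksplit <- matrix(0, n, length(unique(mem)),
                   dimnames = list(vnames, sort(unique(mem))))
  for (e in seq_len(nrow(el))) {
    u <- el[e, 1]; v <- el[e, 2]
    ksplit[u, as.character(mem[v])] <- ksplit[u, as.character(mem[v])] + 1
    ksplit[v, as.character(mem[u])] <- ksplit[v, as.character(mem[u])] + 1
    if (mem[u] == mem[v]) {
      kin[u] <- kin[u] + 1
      kin[v] <- kin[v] + 1
    }
  }
  zi <- numeric(n)
  for (s in unique(mem)) {
    members <- names(mem)[mem == s]
    mu <- mean(kin[members])
    sdev <- sqrt(mean((kin[members] - mu)^2))   # population SD
    zi[match(members, vnames)] <- if (sdev > 0) {
      (kin[members] - mu) / sdev
    } else 0
  }
  pi <- ifelse(k > 0, 1 - rowSums((ksplit / pmax(k, 1))^2), 0)
  category <- dplyr::case_when(
    zi > 2.5 & pi > 0.62 ~ "network hub",
    zi > 2.5 ~ "module hub",
    pi > 0.62 ~ "connector",
    TRUE ~ "peripheral"
  )
  tibble::tibble(otu_id = vnames, degree = unname(k),
                 within_module_degree = unname(kin),
                 zi = zi, pi = unname(pi), category = category)
}

#' Networks along the HAILS gradient
#'
#' Builds one network per site group and pairs it with the group's mean
#' HAILS. `scheme = "per-reach"` builds one network per reach;
#' `"per-reach-triplicate"` builds three per reach from leave-one-site-out
#' subsets ordered by site position (nine networks for the canonical
#' 15-site design), the reconstruction of the study's nine networks per
#' season.
#'
#' @param table A community tibble (one season).
#' @param metadata Tibble with `sample_id`, `reach`, and land-use fractions
#'   (or a precomputed `hails` column).
#' @param scheme `"per-reach"` or `"per-reach-triplicate"`.
#' @param seed Integer RNG seed (per-network seeds derive from it).
#' @param min_samples Minimum subset size for a network; groups below it
#'   are skipped with a warning. Triplicate subsets of the 15-site design
#'   have 3-5 samples, hence the default 3.
#' @param ... Passed to [build_network()].
#' @return Tibble with `group`, `subset` (list of sample ids), `hails`,
#'   `network` (list column of `"conetwork"`).
#' @export
networks_along_gradient <- function(table, metadata,
                                    scheme = c("per-reach",
                                               "per-reach-triplicate"),
                                    seed = 1L, min_samples = 3L, ...) {
  scheme <- match.arg(scheme)
  stopifnot("reach" %in% names(metadata))
  md <- dplyr::semi_join(metadata, table, by = "sample_id")
  md <- md[match(table$sample_id, md$sample_id), ]
  if (!"hails" %in% names(md)) {
    md <- dplyr::left_join(md, hails_index(md), by = "sample_id")
  }
  md <- md[order(md$sample_id), ]
  subsets <- list()
  for (r in c("upper", "middle", "lower")) {
    ids <- md$sample_id[md$reach == r]
    if (!length(ids)) next
    if (scheme == "per-reach") {
      subsets[[r]] <- list(ids)
    } else {
      subsets[[r]] <- lapply(1:3, function(k) ids[-k])
    }
  }
  rows <- list()
  i <- 0L
  for (r in names(subsets)) {
    for (k in seq_along(subsets[[r]])) {
      ids <- subsets[[r]][[k]]
      label <- if (length(subsets[[r]]) > 1) paste0(r, "-", k) else r
      if (length(ids) < min_samples) {
        warning("skipping ", label, ": only ", length(ids), " samples",
                call. = FALSE)
        next
      }
      i <- i + 1L
      net <- build_network(table[table$sample_id %in% ids, ],
                           min_samples = min_samples,
                           seed = seed + i, ...)
      rows[[i]] <- tibble::tibble(
        group = label,
        subset = list(ids),
        hails = mean(md$hails[md$sample_id %in% ids]),
        network = list(net)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Regress a network-stability index on HAILS
#'
#' Ordinary least squares of a topology response (module count `NM` or
#' modularity `M`, the stability proxies) on group HAILS. The headline
#' summary `percent_change_per_10` expresses the fitted change over 10
#' HAILS percentage points as a percent of the gradient-mean response:
#' `10 * slope / mean(response) * 100`.
#'
#' @param records Data frame of topology records (rows align with `hails`),
#'   as from binding [topology()] rows.
#' @param hails Numeric group HAILS values.
#' @param response `"NM"` or `"M"`.
#' @return One-row tibble: `response`, `slope`, `intercept`, `p`,
#'   `r_squared`, `percent_change_per_10`, `n`.
#' @export
stability_decay <- function(records, hails, response = c("NM", "M")) {
  response <- match.arg(response)
  y <- records[[response]]
  if (length(y) != length(hails) || length(y) < 3L) {
    stop("need >= 3 aligned (record, hails) pairs", call. = FALSE)
  }
  if (stats::sd(hails) == 0) {
    stop("hails values are all equal", call. = FALSE)
  }
  fit <- stats::lm(y ~ hails)
  sm <- summary(fit)
  slope <- stats::coef(fit)[["hails"]]
  p <- if (nrow(sm$coefficients) > 1) sm$coefficients["hails", 4] else NA_real_
  tibble::tibble(
    response = response,
    slope = slope,
    intercept = stats::coef(fit)[["(Intercept)"]],
    p = p,
    r_squared = sm$r.squared,
    percent_change_per_10 = 10 * slope / mean(y) * 100,
    n = length(y)
  )
}

#' @rdname stability_decay
#' @param gradient_networks Output of [networks_along_gradient()].
#' @param seed Passed to [topology()].
#' @export
gradient_topology <- function(gradient_networks, seed = 1L) {
  ok <- vapply(gradient_networks$network,
               function(n) igraph::vcount(n$graph) >= 2, logical(1))
  if (any(!ok)) {
    warning("dropping ", sum(!ok),
            " network(s) with fewer than 2 connected nodes: ",
            paste(gradient_networks$group[!ok], collapse = ", "),
            call. = FALSE)
  }
  gn <- gradient_networks[ok, , drop = FALSE]
  recs <- purrr::map(gn$network, topology, seed = seed)
  dplyr::bind_cols(gn[, c("group", "hails")], dplyr::bind_rows(recs))
}

#' Plot network stability against the HAILS gradient
#'
#' @param topology_records Output of [gradient_topology()].
#' @param response `"NM"` or `"M"`.
#' @return A ggplot.
#' @export
plot_stability_decay <- function(topology_records, response = c("NM", "M")) {
  response <- match.arg(response)
  ggplot2::ggplot(topology_records,
                  ggplot2::aes(x = .data$hails, y = .data[[response]])) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "HAILS (%)", y = response,
                  title = "Network stability along the human-activity gradient") +
    ggplot2::theme_minimal()
}
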