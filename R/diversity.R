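#' Alpha diversity: bias-corrected Chao1 and Shannon
#'
#' Chao1 uses the bias-corrected form
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` (finite when no doubletons);
#' Shannon is `-sum(p_i log p_i)` over non-zero proportions.
#'
#' @param table A community tibble of integer counts.
#' @param base Logarithm base for Shannon: `"e"` or `"2"`.
#' @return Tibble with `sample_id`, `observed_richness`, `chao1`, `shannon`.
#' @export
alpha_diversity <- function(table, base = c("e", "2")) {
  base <- match.arg(base)
  m <- otu_counts(table)
  if (any(m != round(m))) {
    stop("alpha diversity needs integer counts", call. = FALSE)
  }
  if (any(rowSums(m) <= 0)) stop("empty sample(s)", call. = FALSE)
  logf <- if (base == "e") log else log2
  tibble::tibble(
    sample_id = rownames(m),
    observed_richness = rowSums(m > 0),
    chao1 = apply(m, 1, chao1_one),
    shannon = apply(m, 1, function(x) {
      p <- x[x > 0] / sum(x)
      -sum(p * logf(p))
    })
  )
}

chao1_one <- function(x) {
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' @rdname alpha_diversity
#' @param counts Integer count vector for a single sample.
#' @export
chao1 <- function(counts) {
  if (length(counts) == 0L || sum(counts) <= 0) {
    stop("empty sample", call. = FALSE)
  }
  if (any(counts != round(counts)) || any(counts < 0)) {
    stop("chao1 needs non-negative integer counts", call. = FALSE)
  }
  chao1_one(counts)
}

#' @rdname alpha_diversity
#' @export
shannon <- function(counts, base = c("e", "2")) {
  base <- match.arg(base)
  if (sum(counts) <= 0) stop("empty sample", call. = FALSE)
  p <- counts[counts > 0] / sum(counts)
  logf <- if (base == "e") log else log2
  -sum(p * logf(p))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(a, b) = sum|a_i - b_i| / sum(a_i + b_i)`; values in \[0, 1\].
#'
#' @param table A community tibble (counts or relative abundances).
#' @return A symmetric `dist`-like matrix with sample ids as dimnames.
#' @export
bray_curtis <- function(table) {
  m <- otu_counts(table)
  if (any(rowSums(m) <= 0)) {
    stop("all-zero sample(s) make Bray-Curtis undefined: ",
         paste(rownames(m)[rowSums(m) <= 0], collapse = ", "), call. = FALSE)
  }
  as.matrix(vegan::vegdist(m, method = "bray"))
}

validate_distance_matrix <- function(d, name = "distance matrix") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8 ||
      any(abs(diag(d)) > 1e-12) || any(d < -1e-12)) {
    stop(name, " must be symmetric, non-negative, with zero diagonal",
         call. = FALSE)
  }
  d
}

#' Principal coordinates analysis
#'
#' Gower-centred eigendecomposition of a distance matrix. Axes are built
#' from positive eigenvalues only; negative eigenvalues (possible for
#' semi-metric dissimilarities such as Bray-Curtis) are reported, not
#' corrected.
#'
#' @param dm Symmetric distance matrix with labelled rows.
#' @return List of class `"pcoa_ord"`: `coordinates` (tibble with
#'   `sample_id` and `Axis.k` columns), `eigenvalues` (all, sorted
#'   decreasing), `proportion_explained` (positive axes, relative to the
#'   positive-eigenvalue total), `negative_eigenvalues` flag.
#' @export
pcoa_ord <- function(dm) {
  d <- validate_distance_matrix(dm)
  n <- nrow(d)
  fit <- stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE)
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- which(fit$eig > 1e-8 * max(abs(fit$eig)))
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("Axis.", seq_along(pos))
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("s", seq_len(n))
  structure(list(
    coordinates = dplyr::bind_cols(tibble::tibble(sample_id = labels),
                                   tibble::as_tibble(coords)),
    eigenvalues = eig,
    proportion_explained = eig[eig > 0] / sum(eig[eig > 0]),
    negative_eigenvalues = any(fit$eig < -1e-8 * max(abs(fit$eig)))
  ), class = "pcoa_ord")
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of between-group vs within-group distances:
#' `R = (mean_between_rank - mean_within_rank) / (n(n-1)/4)`, with a
#' one-sided permutation p-value `(1 + #{R_perm >= R_obs}) / (1 + B)`.
#'
#' @param dm Symmetric distance matrix.
#' @param groups Group label per sample (>= 2 groups, each of size >= 2).
#' @param n_permutations Number of label permutations.
#' @param seed Integer RNG seed.
#' @return Tibble with `R`, `p`, `n_permutations`, `seed`.
#' @export
anosim_test <- function(dm, groups, n_permutations = 999L, seed = 1L) {
  d <- validate_distance_matrix(dm)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) {
    stop("one group label per sample required", call. = FALSE)
  }
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  }
  n <- nrow(d)
  lower <- lower.tri(d)
  rk <- rank(d[lower])
  denom <- n * (n - 1) / 4
  stat <- function(g) {
    within <- outer(g, g, "==")[lower]
    (mean(rk[!within]) - mean(rk[within])) / denom
  }
  r_obs <- stat(groups)
  withr_seed(seed, {
    r_null <- vapply(seq_len(n_permutations),
                     function(i) stat(sample(groups)), numeric(1))
  })
  tibble::tibble(
    R = r_obs,
    p = (1 + sum(r_null >= r_obs)) / (1 + n_permutations),
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed)
  )
}
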