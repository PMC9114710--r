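#' Mantel test between two distance matrices
#'
#' Correlation (Pearson or Spearman) of the lower-triangle vectors, with a
#' one-sided permutation p-value from random simultaneous row/column
#' permutations of the second matrix.
#'
#' @param dm1,dm2 Symmetric distance matrices over the same samples (same
#'   label order).
#' @param method `"pearson"` or `"spearman"`.
#' @param n_permutations Number of permutations.
#' @param seed Integer RNG seed.
#' @return One-row tibble: `r`, `p`, `n_permutations`, `method`, `seed`.
#' @export
mantel_test <- function(dm1, dm2, method = c("pearson", "spearman"),
                        n_permutations = 999L, seed = 1L) {
  method <- match.arg(method)
  d1 <- validate_distance_matrix(dm1, "dm1")
  d2 <- validate_distance_matrix(dm2, "dm2")
  if (nrow(d1) != nrow(d2)) stop("matrix sizes differ", call. = FALSE)
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2))) {
    stop("dm1 and dm2 label orders differ", call. = FALSE)
  }
  if (nrow(d1) < 4L) stop("need n >= 4 samples", call. = FALSE)
  lt <- lower.tri(d1)
  r_obs <- stats::cor(d1[lt], d2[lt], method = method)
  withr_seed(seed, {
    r_null <- vapply(seq_len(n_permutations), function(b) {
      perm <- sample.int(nrow(d2))
      stats::cor(d1[lt], d2[perm, perm][lt], method = method)
    }, numeric(1))
  })
  tibble::tibble(
    r = r_obs,
    p = (1 + sum(r_null >= r_obs)) / (1 + n_permutations),
    n_permutations = as.integer(n_permutations),
    method = method, seed = as.integer(seed)
  )
}

#' Distance-decay of community similarity
#'
#' Builds the geographic distance matrix `|g_i - g_j|` from a per-sample
#' scalar (e.g. river length), runs [mantel_test()] against the community
#' dissimilarities, and fits the OLS slope of similarity
#' (`1 - dissimilarity`) on distance: a negative slope is the distance-decay
#' pattern.
#'
#' @param community_dm Community dissimilarity matrix.
#' @param geo_values Non-negative per-sample scalar, in `community_dm`
#'   label order.
#' @inheritParams mantel_test
#' @return One-row tibble: Mantel columns plus `similarity_slope`.
#' @export
distance_decay <- function(community_dm, geo_values,
                           method = c("pearson", "spearman"),
                           n_permutations = 999L, seed = 1L) {
  method <- match.arg(method)
  d <- validate_distance_matrix(community_dm, "community_dm")
  if (length(geo_values) != nrow(d)) {
    stop("one geo value per sample required", call. = FALSE)
  }
  if (any(geo_values < 0)) stop("geo values must be >= 0", call. = FALSE)
  if (stats::sd(geo_values) == 0) {
    stop("constant geo values give a degenerate distance matrix",
         call. = FALSE)
  }
  gd <- abs(outer(geo_values, geo_values, "-"))
  dimnames(gd) <- dimnames(d)
  mt <- mantel_test(d, gd, method = method,
                    n_permutations = n_permutations, seed = seed)
  lt <- lower.tri(d)
  fit <- stats::lm(I(1 - d[lt]) ~ gd[lt])
  dplyr::mutate(mt, similarity_slope = stats::coef(fit)[[2]])
}

#' Bioenv: exhaustive best-subset search of environmental variables
#'
#' The classical BEST procedure: variables are z-scored; for every
#' non-empty subset up to `max_subset_size`, the Euclidean inter-sample
#' distance on the subset is rank-correlated (Spearman) with the community
#' dissimilarity; subsets are ranked by correlation. The same machinery
#' serves "network bioenv" by passing the Euclidean distance between
#' per-group topology-index vectors as `community_dm`.
#'
#' @param community_dm Community (or topology-vector) dissimilarity matrix.
#' @param env Data frame of candidate variables (an optional `sample_id`
#'   column is dropped; at most 15 variables, rows in `community_dm` label
#'   order).
#' @param max_subset_size Largest subset size searched.
#' @return List of class `"bioenv_result"`: `subsets` tibble
#'   (`variables`, `size`, `correlation`, sorted descending) and
#'   `best` (top row).
#' @export
bioenv_search <- function(community_dm, env, max_subset_size = NULL) {
  d <- validate_distance_matrix(community_dm, "community_dm")
  env <- tibble::as_tibble(env)
  env$sample_id <- NULL
  if (ncol(env) > 15L) {
    stop("bioenv searches at most 15 candidate variables (got ", ncol(env),
         "); pre-select variables first", call. = FALSE)
  }
  if (nrow(env) != nrow(d)) {
    stop("env rows must match community_dm samples", call. = FALSE)
  }
  if (is.null(max_subset_size)) max_subset_size <- ncol(env)
  max_subset_size <- min(max_subset_size, ncol(env))
  z <- scale(as.matrix(env))
  z[, apply(as.matrix(env), 2, stats::sd) == 0] <- 0   # constant columns
  lt <- lower.tri(d)
  dvec <- d[lt]
  vars <- colnames(env)
  rows <- list()
  i <- 0L
  for (size in seq_len(max_subset_size)) {
    combos <- utils::combn(length(vars), size, simplify = FALSE)
    for (cb in combos) {
      ed <- as.matrix(stats::dist(z[, cb, drop = FALSE]))
      i <- i + 1L
      rows[[i]] <- tibble::tibble(
        variables = paste(vars[cb], collapse = " + "),
        size = size,
        correlation = stats::cor(dvec, ed[lt], method = "spearman")
      )
    }
  }
  subsets <- dplyr::arrange(dplyr::bind_rows(rows),
                            dplyr::desc(.data$correlation))
  structure(list(subsets = subsets, best = subsets[1, ],
                 dissimilarity = "as supplied",
                 correlation_method = "spearman"),
            class = "bioenv_result")
}

#' @export
print.bioenv_result <- function(x, ...) {
  cat("Bioenv best-subset search (Spearman)\n")
  print(utils::head(x$subsets, 5))
  invisible(x)
}

#' @rdname bioenv_search
#' @param x A `"bioenv_result"`.
#' @param ... Unused.
#' @export
tidy.bioenv_result <- function(x, ...) x$subsets

#' Euclidean distance between per-group topology-index vectors
#'
#' Standardises the topology panel columns used for network bioenv
#' (`TN, TL, avgK, avgCC, GD, NM, M`) and returns the Euclidean distance
#' matrix between groups, the "community" side of a network-level bioenv.
#'
#' @param topology_records Data frame with the topology columns (one row
#'   per group; a `group` column provides labels).
#' @return Symmetric distance matrix.
#' @export
topology_distance <- function(topology_records) {
  cols <- c("TN", "TL", "avgK", "avgCC", "GD", "NM", "M")
  stopifnot(all(cols %in% names(topology_records)))
  z <- scale(as.matrix(topology_records[cols]))
  z[, apply(as.matrix(topology_records[cols]), 2, stats::sd) == 0] <- 0
  dm <- as.matrix(stats::dist(z))
  if ("group" %in% names(topology_records)) {
    dimnames(dm) <- list(topology_records$group, topology_records$group)
  }
  dm
}

#' Constrained-ordination significance of environmental variables
#'
#' Redundancy analysis of Hellinger-transformed abundances on the
#' environmental table, with marginal permutation tests per variable and
#' the constrained-axis eigenvalue proportions. Collinear (aliased)
#' columns are dropped with a warning before fitting.
#'
#' @param table A community tibble.
#' @param env Data frame of environmental variables (optional `sample_id`
#'   dropped; rows in table sample order).
#' @param n_permutations Permutations for the marginal tests.
#' @param seed Integer RNG seed.
#' @return List: `terms` tibble (`variable`, `variance`, `F`, `p`),
#'   `axes` tibble (`axis`, `eigenvalue`, `proportion`), `total_inertia`,
#'   `constrained_inertia`.
#' @export
constrained_ordination_significance <- function(table, env,
                                                n_permutations = 999L,
                                                seed = 1L) {
  env <- tibble::as_tibble(env)
  env$sample_id <- NULL
  m <- otu_counts(table)
  if (nrow(env) != nrow(m)) {
    stop("env rows must match community samples", call. = FALSE)
  }
  if (nrow(m) <= ncol(env)) {
    stop("need more samples than constrained variables", call. = FALSE)
  }
  hel <- vegan::decostand(m, method = "hellinger")
  qrx <- qr(scale(as.matrix(env)))
  if (qrx$rank < ncol(env)) {
    drop <- colnames(env)[-qrx$pivot[seq_len(qrx$rank)]]
    warning("dropping collinear column(s): ", paste(drop, collapse = ", "),
            call. = FALSE)
    env <- env[qrx$pivot[seq_len(qrx$rank)]]
  }
  df <- as.data.frame(env)
  mod <- vegan::rda(hel ~ ., data = df)
  withr_seed(seed, {
    an <- vegan::anova.cca(mod, by = "margin",
                           permutations = n_permutations)
  })
  terms <- tibble::tibble(
    variable = rownames(an)[rownames(an) != "Residual"],
    variance = an$Variance[rownames(an) != "Residual"],
    F = an$F[rownames(an) != "Residual"],
    p = an$`Pr(>F)`[rownames(an) != "Residual"]
  )
  eig <- mod$CCA$eig
  list(
    terms = terms,
    axes = tibble::tibble(axis = names(eig), eigenvalue = unname(eig),
                          proportion = unname(eig) / mod$tot.chi),
    total_inertia = mod$tot.chi,
    constrained_inertia = sum(eig)
  )
}

#' Three-matrix variation partitioning
#'
#' Partitions the variation of a community (Hellinger-transformed
#' abundances under RDA) among three explanatory matrices - canonically
#' land use (X1), water chemistry (X2) and geographic distance parameters
#' (X3) - into pure fractions `a, b, c`, pairwise shared `d` (X1&X2),
#' `e` (X2&X3), `f` (X1&X3), three-way shared `g`, and `unexplained`, via
#' Ezekiel-adjusted R-squared of the seven constrained models and
#' inclusion-exclusion. Fractions sum to 1 exactly; raw shared fractions
#' may be negative and are reported untruncated (`tidy()` adds a
#' display-floored column).
#'
#' @param community A community tibble (abundances) or a numeric matrix of
#'   responses (e.g. topology-index vectors per group, for the network
#'   variant; transformed with `transform = "none"`).
#' @param X1,X2,X3 Data frames of explanatory variables (optional
#'   `sample_id` columns dropped).
#' @param transform `"hellinger"` (community abundances) or `"none"`
#'   (z-scored response matrix used as-is).
#' @return Object of class `"varpart3_result"`: named `fractions` vector
#'   (`a`-`g`, `unexplained`), `adjusted = TRUE`, `r2` of the seven
#'   models.
#' @export
varpart3 <- function(community, X1, X2, X3,
                     transform = c("hellinger", "none")) {
  transform <- match.arg(transform)
  y <- if (is.data.frame(community) && "sample_id" %in% names(community)) {
    otu_counts(community)
  } else {
    as.matrix(community)
  }
  y <- switch(transform,
              hellinger = vegan::decostand(y, method = "hellinger"),
              none = scale(y))
  xs <- lapply(list(X1, X2, X3), function(x) {
    x <- tibble::as_tibble(x)
    x$sample_id <- NULL
    if (ncol(x) == 0L) stop("empty explanatory matrix", call. = FALSE)
    as.data.frame(x)
  })
  n <- nrow(y)
  p_tot <- sum(vapply(xs, ncol, integer(1)))
  if (n <= p_tot + 1L) {
    stop("need n > total predictors (+1) for the full model; n = ", n,
         ", predictors = ", p_tot, call. = FALSE)
  }
  adj_r2 <- function(cols) {
    df <- do.call(cbind, xs[cols])
    names(df) <- make.unique(names(df))
    mod <- vegan::rda(y ~ ., data = as.data.frame(df))
    vegan::RsquareAdj(mod)$adj.r.squared
  }
  A1 <- adj_r2(1); A2 <- adj_r2(2); A3 <- adj_r2(3)
  A12 <- adj_r2(c(1, 2)); A13 <- adj_r2(c(1, 3)); A23 <- adj_r2(c(2, 3))
  A123 <- adj_r2(c(1, 2, 3))
  a <- A123 - A23
  b <- A123 - A13
  c <- A123 - A12
  d <- A13 + A23 - A123 - A3      # shared X1 & X2 (not X3)
  e <- A12 + A13 - A123 - A1      # shared X2 & X3 (not X1)
  f <- A12 + A23 - A123 - A2      # shared X1 & X3 (not X2)
  g <- A123 - a - b - c - d - e - f
  fractions <- c(a = a, b = b, c = c, d = d, e = e, f = f, g = g,
                 unexplained = 1 - A123)
  structure(list(
    fractions = fractions,
    adjusted = TRUE,
    r2 = c(X1 = A1, X2 = A2, X3 = A3, X12 = A12, X13 = A13, X23 = A23,
           X123 = A123)
  ), class = "varpart3_result")
}

#' @export
print.varpart3_result <- function(x, ...) {
  cat("Variation partitioning (adjusted R^2), three explanatory matrices\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' @rdname varpart3
#' @param x A `"varpart3_result"`.
#' @param ... Unused.
#' @export
tidy.varpart3_result <- function(x, ...) {
  tibble::tibble(
    fraction = names(x$fractions),
    value = unname(x$fractions),
    display = pmax(unname(x$fractions), 0)
  )
}

#' @rdname varpart3
#' @export
glance.varpart3_result <- function(x, ...) {
  tibble::tibble(
    explained = 1 - x$fractions[["unexplained"]],
    unexplained = x$fractions[["unexplained"]],
    adjusted = x$adjusted
  )
}

#' @rdname varpart3
#' @param object A `"varpart3_result"`.
#' @export
autoplot.varpart3_result <- function(object, ...) {
  df <- tidy.varpart3_result(object)
  df$fraction <- factor(df$fraction, levels = df$fraction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$display)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fraction of variation",
                  title = "Variation partitioning (negative fractions floored at 0)") +
    ggplot2::theme_minimal()
}
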