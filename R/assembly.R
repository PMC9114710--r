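#' Fit the Sloan neutral community model
#'
#' Under purely stochastic dispersal, an OTU with mean relative abundance
#' `p` is detected (above a limit `d`) in a fraction
#' `1 - pbeta(d, Nm * p, Nm * (1 - p))` of local communities, where `N` is
#' the local community size (taken as the mean sample depth) and `m` the
#' immigration rate. `Nm` is estimated by least squares of predicted vs
#' observed occurrence frequency over OTUs (coarse log-grid start, then
#' golden-section refinement; `Nm` bounded in `(0, 10 N]`), `m = Nm / N`,
#' and fit quality is `R^2 = 1 - SSR/SST`. 95% prediction bands come from
#' the Clopper-Pearson beta quantiles of binomial sampling of the predicted
#' frequency across the `S` communities; OTUs are partitioned as `above` /
#' `within` / `below` the band.
#'
#' @param table A community tibble with >= 5 samples.
#' @param detection_limit Detection threshold on relative abundance;
#'   `NULL` (default) uses the half-read continuity correction
#'   `1 / (2 * mean(sample depth))`: a sampled count of at least 1 read
#'   corresponds to a relative abundance above the rounding midpoint, and
#'   this choice makes the fitted `m` nearly unbiased on data generated by
#'   [simulate_neutral_metacommunity()].
#' @return An object of class `"ncm_fit"`; see [tidy.ncm_fit()] and
#'   [glance.ncm_fit()].
#' @export
fit_ncm <- function(table, detection_limit = NULL) {
  m <- otu_counts(table)
  if (nrow(m) < 5L) {
    stop("fit_ncm needs >= 5 samples, got ", nrow(m), call. = FALSE)
  }
  depth <- mean(rowSums(m))
  d <- if (is.null(detection_limit)) 1 / (2 * depth) else detection_limit
  rel <- relative_abundance(table)
  keep <- colMeans(rel) > 0
  p_hat <- colMeans(rel)[keep]
  obs_freq <- colMeans(m[, keep, drop = FALSE] > 0)
  s <- nrow(m)

  pred_for <- function(nm) {
    stats::pbeta(d, nm * p_hat, nm * (1 - p_hat), lower.tail = FALSE)
  }
  ssr_for <- function(nm) sum((obs_freq - pred_for(nm))^2)
  # coarse log-spaced grid over (0, 10N], then 1-D refinement
  grid <- exp(seq(log(1), log(10 * depth), length.out = 80))
  ssr_grid <- vapply(grid, ssr_for, numeric(1))
  k <- which.min(ssr_grid)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(length(grid), k + 1)]
  opt <- stats::optimize(ssr_for, interval = c(lo, hi), tol = 1e-8)
  if (!is.finite(opt$objective)) {
    stop("neutral-model fit failed to converge; best Nm iterate ",
         signif(opt$minimum, 6), call. = FALSE)
  }
  nm <- opt$minimum
  pred <- pred_for(nm)
  ssr <- opt$objective
  sst <- sum((obs_freq - mean(obs_freq))^2)
  r2 <- 1 - ssr / sst

  ci_low <- ifelse(pred <= 0, 0, stats::qbeta(0.025, s * pred,
                                              s * (1 - pred) + 1))
  ci_high <- ifelse(pred >= 1, 1, stats::qbeta(0.975, s * pred + 1,
                                               pmax(s * (1 - pred), 1e-12)))
  partition <- ifelse(obs_freq > ci_high, "above",
                      ifelse(obs_freq < ci_low, "below", "within"))
  structure(list(
    m = nm / depth,
    Nm = nm,
    N = depth,
    r_squared = r2,
    detection_limit = d,
    n_samples = s,
    otus = tibble::tibble(
      otu_id = names(p_hat),
      mean_rel_abundance = unname(p_hat),
      observed_freq = unname(obs_freq),
      predicted_freq = unname(pred),
      ci_low = unname(ci_low),
      ci_high = unname(ci_high),
      partition = unname(partition)
    )
  ), class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  m = %.3f (Nm = %.1f, N = %.0f), R^2 = %.3f\n",
              x$m, x$Nm, x$N, x$r_squared))
  cat(sprintf("  %d OTUs over %d communities; detection limit %.2e\n",
              nrow(x$otus), x$n_samples, x$detection_limit))
  print(table(x$otus$partition))
  invisible(x)
}

#' Broom-style accessors for neutral-model fits
#'
#' `tidy()` returns the per-OTU table (observed vs predicted occurrence
#' frequency, prediction band and partition); `glance()` a one-row model
#' summary.
#'
#' @param x An `"ncm_fit"` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ncm_fit <- function(x, ...) x$otus

#' @rdname tidy.ncm_fit
#' @export
glance.ncm_fit <- function(x, ...) {
  tibble::tibble(m = x$m, Nm = x$Nm, N = x$N, r_squared = x$r_squared,
                 detection_limit = x$detection_limit,
                 n_otus = nrow(x$otus), n_samples = x$n_samples)
}

#' @rdname tidy.ncm_fit
#' @param object An `"ncm_fit"` object.
#' @export
autoplot.ncm_fit <- function(object, ...) {
  df <- object$otus
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$mean_rel_abundance))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted_freq),
                       colour = "blue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed_freq,
                                     colour = .data$partition), size = 0.8) +
    ggplot2::scale_colour_manual(values = c(above = "cyan3",
                                            within = "grey30",
                                            below = "red3")) +
    ggplot2::labs(
      x = "log10 mean relative abundance",
      y = "occurrence frequency",
      title = sprintf("Neutral model: m = %.3f, R² = %.3f",
                      object$m, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Checkerboard C-score of a presence/absence matrix
#'
#' Mean over OTU (row) pairs of `(r_i - S_ij)(r_j - S_ij)`, where `r` are
#' row totals and `S_ij` the number of sites where both OTUs occur: the
#' average number of checkerboard units per pair, a segregation statistic.
#'
#' @param presence Binary matrix, OTUs x sites, >= 2 rows.
#' @return Non-negative scalar.
#' @export
c_score <- function(presence) {
  m <- as.matrix(presence)
  if (nrow(m) < 2L) stop("need >= 2 OTU rows", call. = FALSE)
  if (!all(m %in% c(0, 1))) {
    stop("c_score needs a binary matrix (use presence_matrix())",
         call. = FALSE)
  }
  s <- tcrossprod(m)
  r <- rowSums(m)
  cb <- (r - s) * t(r - s)          # (r_i - S_ij)(r_j - S_ij)
  mean(cb[upper.tri(cb)])
}

#' Presence/absence matrix (OTUs x sites) from a community tibble
#'
#' @param table A community tibble.
#' @param min_prevalence Keep OTUs present in at least this fraction of
#'   samples (and drop OTUs present everywhere, which cannot contribute
#'   checkerboards, only when `drop_constant` is `TRUE`).
#' @param drop_constant Drop all-present and all-absent rows.
#' @return Binary integer matrix, OTUs x sites.
#' @export
presence_matrix <- function(table, min_prevalence = 0, drop_constant = TRUE) {
  m <- t(otu_counts(table) > 0) * 1L
  prev <- rowMeans(m)
  keep <- prev >= min_prevalence & prev > 0
  if (drop_constant) keep <- keep & prev < 1
  m[keep, , drop = FALSE]
}

# One sequential-swap chain step block: `attempts` random 2x2 checkerboard
# swap attempts (attempted, not successful, swaps are counted). Preserves
# row and column totals exactly.
swap_attempts <- function(m, attempts) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- sample.int(nr, attempts, replace = TRUE)
  rj <- sample.int(nr, attempts, replace = TRUE)
  ci <- sample.int(nc, attempts, replace = TRUE)
  cj <- sample.int(nc, attempts, replace = TRUE)
  for (k in seq_len(attempts)) {
    a <- ri[k]; b <- rj[k]
    if (a == b) next
    cc <- ci[k]; dd <- cj[k]
    if (cc == dd) next
    x <- m[a, cc]
    if (x != m[b, dd]) next
    y <- m[a, dd]
    if (y == x || y != m[b, cc]) next
    m[a, cc] <- y; m[b, dd] <- y; m[a, dd] <- x; m[b, cc] <- x
  }
  m
}

#' Sample fixed-margin null matrices by sequential swap
#'
#' Runs the sequential-swap chain (see [null_model_ses()]) and returns the
#' sampled matrices themselves, e.g. to seed calibration studies.
#'
#' @inheritParams null_model_ses
#' @param n Number of matrices to return.
#' @return List of binary matrices with the row and column totals of
#'   `presence`.
#' @export
sample_null_matrices <- function(presence, n, burn_in = 10000L,
                                 thin = 500L, seed = 1L) {
  m <- as.matrix(presence)
  if (!all(m %in% c(0, 1))) stop("presence must be binary", call. = FALSE)
  out <- vector("list", n)
  withr_seed(seed, {
    m <- swap_attempts(m, burn_in)
    for (i in seq_len(n)) {
      m <- swap_attempts(m, thin)
      out[[i]] <- m
    }
  })
  out
}

#' C-score null model by sequential-swap randomization
#'
#' Generates fixed-row, fixed-column null matrices with the sequential-swap
#' algorithm (random 2x2 checkerboard submatrices are swapped; attempted
#' swaps are counted), burns in, then samples the chain every `thin`
#' attempts until `n_simulations` null C-scores are collected. Reports the
#' standardized effect size `SES = (observed - null mean)/null sd` and a
#' two-sided empirical p (doubled one-sided tail, capped at 1). |SES| > 2
#' is read as non-random structure: segregation if positive, aggregation if
#' negative.
#'
#' @param presence Binary matrix, OTUs x sites.
#' @param n_simulations Number of null matrices (study default 30,000).
#' @param burn_in Attempted swaps before sampling starts.
#' @param thin Attempted swaps between successive samples.
#' @param seed Integer RNG seed.
#' @return One-row tibble: `observed_statistic`, `null_mean`, `null_sd`,
#'   `ses`, `p`, `n_simulations`, `algorithm`, `seed`. A matrix with no
#'   swappable submatrix yields `null_sd = 0`, `ses = NA` and a warning.
#' @export
null_model_ses <- function(presence, n_simulations = 30000L,
                           burn_in = 10000L, thin = 500L, seed = 1L) {
  m <- as.matrix(presence)
  if (!all(m %in% c(0, 1))) stop("presence must be binary", call. = FALSE)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least a 2x2 matrix", call. = FALSE)
  }
  obs <- c_score(m)
  nulls <- numeric(n_simulations)
  withr_seed(seed, {
    m <- swap_attempts(m, burn_in)
    for (i in seq_len(n_simulations)) {
      m <- swap_attempts(m, thin)
      nulls[i] <- c_score(m)
    }
  })
  mu <- mean(nulls)
  sdev <- stats::sd(nulls)
  if (!is.finite(sdev) || sdev == 0) {
    warning("degenerate null distribution (no swappable submatrix?): ",
            "SES undefined", call. = FALSE)
    ses <- NA_real_
    p <- NA_real_
  } else {
    ses <- (obs - mu) / sdev
    upper <- (1 + sum(nulls >= obs)) / (1 + n_simulations)
    lower <- (1 + sum(nulls <= obs)) / (1 + n_simulations)
    p <- min(1, 2 * min(upper, lower))
  }
  tibble::tibble(
    observed_statistic = obs, null_mean = mu, null_sd = sdev, ses = ses,
    p = p, n_simulations = as.integer(n_simulations),
    algorithm = "sequential swap", seed = as.integer(seed)
  )
}

#' Levins' niche breadth
#'
#' For OTU `j` across the `N` communities of a group,
#' `B_j = 1 / sum_i P_ij^2` with `P_ij` the proportion of OTU j's total
#' found in community i: the inverse Simpson concentration of its habitat
#' use. `B = 1` is a single-habitat specialist; `B = N` a uniform
#' generalist.
#'
#' @param table A community tibble.
#' @param groups Optional group label per sample (e.g. HAILS level); `NULL`
#'   treats all samples as one metacommunity.
#' @return List with `otus` (per group x OTU `B`) and `summary` (per-group
#'   mean `B` over OTUs present in the group, with the excluded-absent
#'   count).
#' @export
niche_breadth <- function(table, groups = NULL) {
  m <- otu_counts(table)
  if (is.null(groups)) groups <- rep("all", nrow(m))
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(m))
  per_group <- lapply(unique(groups), function(g) {
    sub <- m[groups == g, , drop = FALSE]
    tot <- colSums(sub)
    present <- tot > 0
    p <- sweep(sub[, present, drop = FALSE], 2, tot[present], "/")
    tibble::tibble(group = g, otu_id = colnames(sub)[present],
                   B = unname(1 / colSums(p^2)),
                   n_communities = nrow(sub))
  })
  otus <- dplyr::bind_rows(per_group)
  summary <- otus |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_B = mean(.data$B), n_otus = dplyr::n(),
                     n_communities = .data$n_communities[1],
                     .groups = "drop") |>
    dplyr::mutate(n_excluded = ncol(m) - .data$n_otus)
  list(otus = otus, summary = summary)
}
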