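#' Community count tables
#'
#' Throughout the package a community table is a wide tibble: a `sample_id`
#' character column followed by one non-negative integer column per OTU.
#' Taxonomy (semicolon-ranked lineages) travels alongside as an ordinary
#' two-column tibble (`otu_id`, `taxonomy`), attached to the table as the
#' `"taxonomy"` attribute by the readers and accessible with
#' [otu_taxonomy()].
#'
#' @param counts A matrix (samples x OTUs) or data frame of non-negative
#'   integer counts.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   row of `counts`.
#' @param taxonomy Optional tibble with columns `otu_id`, `taxonomy`.
#' @return A tibble with `sample_id` plus one column per OTU.
#' @examples
#' otu_tibble(matrix(1:4, 2, dimnames = list(NULL, c("OTU1", "OTU2"))),
#'            sample_ids = c("s1", "s2"))
#' @export
otu_tibble <- function(counts, sample_ids = rownames(counts), taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("OTU%04d", seq_len(ncol(counts)))
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("S%02d", seq_len(nrow(counts)))
  }
  out <- tibble::as_tibble(counts)
  out <- dplyr::mutate(out, sample_id = as.character(sample_ids),
                       .before = 1L)
  validate_otu_tibble(out)
  if (!is.null(taxonomy)) {
    stopifnot(all(c("otu_id", "taxonomy") %in% names(taxonomy)))
    if (!all(taxonomy$otu_id %in% colnames(counts))) {
      stop("taxonomy contains otu_ids absent from the count table",
           call. = FALSE)
    }
    attr(out, "taxonomy") <- tibble::as_tibble(taxonomy)
  }
  out
}

#' @rdname otu_tibble
#' @param table A community tibble.
#' @export
otu_taxonomy <- function(table) {
  attr(table, "taxonomy", exact = TRUE)
}

#' Extract the counts matrix from a community tibble
#'
#' @param table A community tibble (see [otu_tibble()]).
#' @return Numeric matrix, samples x OTUs, with sample ids as row names.
#' @export
otu_counts <- function(table) {
  validate_otu_tibble(table)
  m <- as.matrix(table[setdiff(names(table), "sample_id")])
  storage.mode(m) <- "double"
  rownames(m) <- table$sample_id
  m
}

validate_otu_tibble <- function(table) {
  if (!is.data.frame(table) || !"sample_id" %in% names(table)) {
    stop("community table must be a data frame with a 'sample_id' column",
         call. = FALSE)
  }
  if (anyDuplicated(table$sample_id)) {
    stop("duplicate sample_id values in community table", call. = FALSE)
  }
  otu_cols <- setdiff(names(table), "sample_id")
  if (anyDuplicated(otu_cols)) {
    stop("duplicate OTU ids in community table", call. = FALSE)
  }
  m <- as.matrix(table[otu_cols])
  if (!is.numeric(m)) stop("OTU columns must be numeric", call. = FALSE)
  if (any(m < 0, na.rm = TRUE) || anyNA(m)) {
    stop("counts must be non-negative and non-missing", call. = FALSE)
  }
  invisible(table)
}

#' Read a community table from TSV or dense BIOM-JSON
#'
#' TSV layout: first column `otu_id`, one column per sample, optional final
#' `taxonomy` column holding a semicolon-ranked lineage. Orientation is
#' auto-detected (a `sample_id` first column with OTU columns also parses)
#' and normalised to samples x OTUs.
#'
#' @param path File path.
#' @param format `"tsv"` or `"biom-json"`.
#' @return A community tibble with a `"taxonomy"` attribute when lineages
#'   are present.
#' @export
read_otu_table <- function(path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "biom-json") return(read_otu_biom(path))
  raw <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(), progress = FALSE),
    error = function(e) stop("malformed TSV '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("malformed community table '", path,
         "': need an id column and at least one data column", call. = FALSE)
  }
  id_col <- names(raw)[1]
  taxonomy <- NULL
  if (identical(id_col, "sample_id")) {
    out <- raw
  } else {
    if ("taxonomy" %in% names(raw)) {
      taxonomy <- tibble::tibble(otu_id = as.character(raw[[1]]),
                                 taxonomy = as.character(raw$taxonomy))
      raw$taxonomy <- NULL
    }
    otu_ids <- as.character(raw[[1]])
    if (anyDuplicated(otu_ids)) {
      stop("duplicate otu_id values in '", path, "'", call. = FALSE)
    }
    bad <- !vapply(raw[-1], is.numeric, logical(1))
    if (any(bad)) {
      stop("non-numeric count column(s) in '", path, "': ",
           paste(names(raw[-1])[bad], collapse = ", "), call. = FALSE)
    }
    m <- t(as.matrix(raw[-1]))
    colnames(m) <- otu_ids
    out <- otu_tibble(m, sample_ids = rownames(m))
  }
  bad <- vapply(out[setdiff(names(out), "sample_id")],
                function(x) !is.numeric(x), logical(1))
  if (any(bad)) {
    stop("non-numeric count column(s) in '", path, "': ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  }
  validate_otu_tibble(out)
  if (!is.null(taxonomy)) attr(out, "taxonomy") <- taxonomy
  out
}

read_otu_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("reading BIOM-JSON requires the 'biomformat' package", call. = FALSE)
  }
  b <- biomformat::read_biom(path)
  m <- t(as.matrix(biomformat::biom_data(b)))     # biom stores OTUs x samples
  out <- otu_tibble(m, sample_ids = rownames(m))
  md <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
  if (!is.null(md) && length(md)) {
    lin <- vapply(seq_len(nrow(as.data.frame(md))), function(i) {
      paste(unlist(as.data.frame(md)[i, ]), collapse = ";")
    }, character(1))
    attr(out, "taxonomy") <- tibble::tibble(otu_id = colnames(m),
                                            taxonomy = lin)
  }
  out
}

#' Write a community table as TSV (OTUs in rows)
#'
#' Inverse of [read_otu_table()]: first column `otu_id`, one column per
#' sample, and a final `taxonomy` column when lineages are attached.
#'
#' @param table A community tibble.
#' @param path Output path.
#' @param taxonomy Optional taxonomy tibble; defaults to the table's
#'   attached taxonomy.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, taxonomy = otu_taxonomy(table)) {
  m <- otu_counts(table)
  out <- tibble::as_tibble(t(m))
  out <- dplyr::mutate(out, otu_id = colnames(m), .before = 1L)
  if (!is.null(taxonomy)) {
    out <- dplyr::left_join(out, taxonomy, by = "otu_id")
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Rarefy every sample to a common depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric draw) to `depth`, the standard correction for unequal
#' sequencing effort. Samples are processed in sorted `sample_id` order so
#' the result depends only on `seed`, not input row order.
#'
#' @param table A community tibble of integer counts.
#' @param depth Target reads per sample (the source study used 24,343).
#' @param seed Integer RNG seed.
#' @param drop_shallow Drop (with a warning) samples whose total is below
#'   `depth` instead of erroring.
#' @return A rarefied community tibble; every retained sample sums to
#'   `depth`. OTUs that end up absent everywhere are kept as zero columns.
#' @export
rarefy <- function(table, depth, seed = 1L, drop_shallow = FALSE) {
  m <- otu_counts(table)
  if (any(m != round(m))) stop("rarefy needs integer counts", call. = FALSE)
  depth <- as.integer(depth)
  if (depth <= 0L) stop("depth must be positive", call. = FALSE)
  totals <- rowSums(m)
  shallow <- totals < depth
  if (all(shallow)) {
    stop("depth ", depth, " exceeds every sample total (max ", max(totals),
         "): no samples would remain", call. = FALSE)
  }
  if (any(shallow)) {
    if (!drop_shallow) {
      stop("samples below depth ", depth, ": ",
           paste(rownames(m)[shallow], collapse = ", "),
           " (set drop_shallow = TRUE to drop them)", call. = FALSE)
    }
    warning("dropping ", sum(shallow), " sample(s) below depth ", depth,
            call. = FALSE)
    m <- m[!shallow, , drop = FALSE]
  }
  ord <- order(rownames(m))
  m <- m[ord, , drop = FALSE]
  withr_seed(seed, {
    for (i in seq_len(nrow(m))) {
      x <- m[i, ]
      if (sum(x) == depth) next
      reads <- rep.int(seq_along(x), x)
      keep <- sample(reads, depth, replace = FALSE)
      m[i, ] <- tabulate(keep, nbins = length(x))
    }
  })
  otu_tibble(m, sample_ids = rownames(m), taxonomy = otu_taxonomy(table))
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Relative abundances
#'
#' @param table A community tibble with positive sample totals.
#' @return Numeric matrix (samples x OTUs) whose rows sum to 1.
#' @export
relative_abundance <- function(table) {
  m <- otu_counts(table)
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    stop("zero-total sample(s): ",
         paste(rownames(m)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  sweep(m, 1, totals, "/")
}

#' Good's coverage per sample
#'
#' `1 - F1/N` with `F1` the number of singleton OTUs and `N` the sample
#' total: the estimated probability that one more read belongs to an
#' already-seen OTU.
#'
#' @param table A community tibble of integer counts.
#' @return Tibble with `sample_id`, `coverage`.
#' @export
goods_coverage <- function(table) {
  m <- otu_counts(table)
  if (any(m != round(m))) {
    stop("goods_coverage needs integer counts", call. = FALSE)
  }
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    stop("zero-total sample(s): ",
         paste(rownames(m)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  f1 <- rowSums(m == 1)
  tibble::tibble(sample_id = rownames(m),
                 coverage = unname(1 - f1 / totals))
}

#' Fraction of reads from non-freshwater taxa
#'
#' Given a lookup classifying OTUs as `"freshwater"` / `"non-freshwater"`
#' (anything else, or an absent OTU, is unknown), returns the per-sample
#' fraction of classified reads assigned non-freshwater; unknowns are
#' excluded from the denominator.
#'
#' @param table A community tibble.
#' @param lookup Tibble with columns `otu_id`, `flag`.
#' @return Tibble with `sample_id`, `classified_reads`,
#'   `non_freshwater_fraction`.
#' @export
freshwater_fraction <- function(table, lookup) {
  if (is.null(lookup) || nrow(lookup) == 0L) {
    stop("empty freshwater lookup", call. = FALSE)
  }
  stopifnot(all(c("otu_id", "flag") %in% names(lookup)))
  m <- otu_counts(table)
  flag <- lookup$flag[match(colnames(m), lookup$otu_id)]
  fresh <- which(!is.na(flag) & flag == "freshwater")
  non <- which(!is.na(flag) & flag == "non-freshwater")
  if (length(fresh) + length(non) == 0L) {
    stop("lookup classifies no OTU present in the table", call. = FALSE)
  }
  classified <- rowSums(m[, c(fresh, non), drop = FALSE])
  nonreads <- rowSums(m[, non, drop = FALSE])
  tibble::tibble(
    sample_id = rownames(m),
    classified_reads = unname(classified),
    non_freshwater_fraction = unname(ifelse(classified > 0,
                                            nonreads / classified, NA_real_))
  )
}
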