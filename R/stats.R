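#' Default size-distribution bin edges
#'
#' 20 nm bins from 0 to 800 nm, covering the cluster size range typically
#' observed for internalized gold-nanoparticle aggregates.
#'
#' @param width bin width, nm.
#' @param max upper edge, nm.
#' @return numeric vector of strictly increasing edges.
#' @export
default_bins <- function(width = 20, max = 800) seq(0, max, by = width)

#' Histogram a set of cluster sizes
#'
#' Bins are left-closed (`[e_i, e_{i+1})`), with the last bin closed on both
#' sides. Sizes outside the edges are counted in `overflow`, never silently
#' dropped.
#'
#' @param sizes positive cluster sizes, nm (may be empty).
#' @param bin_edges strictly increasing edges, nm.
#' @param cell_id optional identifier carried into reports.
#' @param dimensionality `"2D"` or `"3D"` provenance tag.
#' @return object of class `size_distribution`: `bin_edges`, `counts`,
#'   `n_clusters` (= `sum(counts)`), `overflow`, `mode_nm`, `cell_id`,
#'   `dimensionality`.
#' @export
make_distribution <- function(sizes, bin_edges = default_bins(),
                              cell_id = NA_character_,
                              dimensionality = c("3D", "2D")) {
  dimensionality <- match.arg(dimensionality)
  if (any(diff(bin_edges) <= 0))
    stop_txq("txq_input_error", "bin edges must be strictly increasing")
  sizes <- as.numeric(sizes)
  if (any(sizes <= 0, na.rm = TRUE))
    stop_txq("txq_input_error", "sizes must be positive")
  nb <- length(bin_edges) - 1L
  lo <- bin_edges[1]
  hi <- bin_edges[length(bin_edges)]
  inside <- sizes >= lo & sizes <= hi
  idx <- findInterval(sizes[inside], bin_edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = nb)
  mode_nm <- if (length(sizes) > 0) estimate_mode(sizes, bin_edges) else NA_real_
  structure(list(
    bin_edges = bin_edges, counts = counts, n_clusters = sum(counts),
    overflow = sum(!inside), mode_nm = as.numeric(mode_nm),
    cell_id = cell_id, dimensionality = dimensionality
  ), class = "size_distribution")
}

#' Estimate the mode (peak) of a cluster size distribution
#'
#' For at least 5 raw sizes, the peak of a Gaussian kernel density estimate
#' (Silverman's rule-of-thumb bandwidth) evaluated on a dense grid; histogram
#' bin-center fallback otherwise (flagged `low_n`), and also when only a
#' binned [make_distribution()] object is available. Ties break toward the
#' smaller size.
#'
#' @param x numeric vector of raw sizes, or a `size_distribution`.
#' @param bin_edges edges used by the histogram fallback.
#' @return mode in nm, with attributes `method` (`"kde"` or `"histogram"`)
#'   and `low_n`.
#' @export
estimate_mode <- function(x, bin_edges = default_bins()) {
  if (inherits(x, "size_distribution")) {
    mids <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
    if (sum(x$counts) == 0)
      return(structure(NA_real_, method = "histogram", low_n = TRUE))
    return(structure(mids[which.max(x$counts)], method = "histogram",
                     low_n = sum(x$counts) < 5))
  }
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) == 0L)
    return(structure(NA_real_, method = "histogram", low_n = TRUE))
  if (diff(range(x)) == 0)
    return(structure(x[1], method = "kde", low_n = length(x) < 5))
  if (length(x) < 5L) {
    idx <- findInterval(x, bin_edges, rightmost.closed = TRUE)
    idx <- idx[idx >= 1 & idx <= length(bin_edges) - 1]
    mids <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
    counts <- tabulate(idx, nbins = length(bin_edges) - 1L)
    return(structure(mids[which.max(counts)], method = "histogram",
                     low_n = TRUE))
  }
  den <- density(x, bw = "nrd0", n = 2048)
  structure(den$x[which.max(den$y)], method = "kde", low_n = FALSE)
}

#' Compare two cluster size distributions
#'
#' Two-sample Kolmogorov-Smirnov test on raw sizes: the natural choice when
#' whole size distributions, not just their means, are being compared
#' between conditions or between 2D and 3D quantification of one specimen.
#' Small samples (product of sizes < 10000, no ties) use the exact
#' small-sample distribution and are flagged.
#'
#' @param sample_a,sample_b numeric size samples, each with n >= 5 for the
#'   asymptotic p-value to be meaningful (smaller samples are allowed and
#'   handled exactly).
#' @return list with `statistic` (D), `p_value`, `exact` (logical flag) and
#'   `method`.
#' @export
compare_distributions <- function(sample_a, sample_b) {
  a <- as.numeric(sample_a)
  b <- as.numeric(sample_b)
  if (length(a) < 1L || length(b) < 1L)
    stop_txq("txq_input_error", "both samples must be non-empty")
  ties <- any(duplicated(c(a, b)))
  kt <- suppressWarnings(ks.test(a, b))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       exact = (length(a) * length(b) < 10000) && !ties,
       method = "two-sample Kolmogorov-Smirnov")
}

#' Per-cell uptake summary table
#'
#' One row per cell with cluster count, size statistics and nucleus-relative
#' localization, plus a pooled row over all cells. For internalized gold
#' nanoparticles the expected fraction of clusters inside the nucleus is 0.
#'
#' @param records data frame of measured clusters with at least `cell_id`
#'   and `size_nm`; `nucleus_distance_nm` is used when present.
#' @return data frame with columns `cell_id, n_clusters, size_mean_nm,
#'   size_sd_nm, size_mode_nm, ndist_mean_nm, ndist_sd_nm,
#'   frac_in_nucleus`.
#' @export
uptake_report <- function(records) {
  if (is.null(records$cell_id)) records$cell_id <- "cell1"
  one <- function(df, id) {
    n <- nrow(df)
    nd <- df$nucleus_distance_nm %||% rep(NA_real_, n)
    data.frame(
      cell_id = id, n_clusters = n,
      size_mean_nm = if (n > 0) mean(df$size_nm) else NA_real_,
      size_sd_nm = if (n > 1) sd(df$size_nm) else NA_real_,
      size_mode_nm = if (n > 0) as.numeric(estimate_mode(df$size_nm)) else NA_real_,
      ndist_mean_nm = if (n > 0 && any(is.finite(nd))) mean(nd, na.rm = TRUE) else NA_real_,
      ndist_sd_nm = if (n > 1 && any(is.finite(nd))) sd(nd, na.rm = TRUE) else NA_real_,
      frac_in_nucleus = if (n > 0 && any(is.finite(nd))) mean(nd < 0, na.rm = TRUE) else NA_real_
    )
  }
  cells <- split(records, records$cell_id)
  per_cell <- do.call(rbind, lapply(names(cells), function(id) one(cells[[id]], id)))
  pooled <- one(records, "pooled")
  out <- rbind(per_cell, pooled)
  rownames(out) <- NULL
  out
}

#' @export
print.size_distribution <- function(x, ...) {
  cat("<size_distribution>\n")
  cat(sprintf("  %s, cell %s: %d cluster(s), %d overflow\n", x$dimensionality,
              x$cell_id, x$n_clusters, x$overflow))
  cat(sprintf("  bins: %g-%g nm (width %g); mode %.1f nm\n", min(x$bin_edges),
              max(x$bin_edges), x$bin_edges[2] - x$bin_edges[1], x$mode_nm))
  invisible(x)
}

#' @export
plot.size_distribution <- function(x, kde_sizes = NULL, ...) {
  mids <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  bp <- barplot(x$counts, names.arg = mids, xlab = "cluster size (nm)",
                ylab = "count",
                main = sprintf("%s cluster sizes (%s)", x$dimensionality,
                               x$cell_id), ...)
  if (!is.null(kde_sizes) && length(kde_sizes) >= 5) {
    den <- density(kde_sizes, bw = "nrd0")
    sc <- max(x$counts) / max(den$y)
    px <- approx(mids, bp[, 1], xout = den$x, rule = 2)$y
    lines(px, den$y * sc, col = "red3", lwd = 2)
  }
  invisible(x)
}
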