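# Outlier screening against an empirical background: percentile ranks of
# GC fraction and mean G/C-stretch length relative to a reference gene set,
# and a permutation two-sample test on the max-ECDF-difference statistic
# for comparing metric distributions between gene groups.

#' Build an empirical background model from reference metrics
#'
#' Sorts the background GC fractions and mean stretch lengths and bins the
#' stretch lengths into a fixed-width histogram (bin width `bin_width`,
#' starting at the stretch threshold `k`). Sequences with no qualifying
#' stretch (`mean_stretch_len` missing) are excluded from the stretch axis
#' and their count recorded.
#'
#' @param metrics Metrics tibble from [composition_metrics()] for the
#'   reference set (e.g. all RefSeq genes of a species).
#' @param min_n Minimum number of usable records (default 100); fewer is an
#'   error, because percentiles from a small reference are meaningless.
#' @param bin_width Histogram bin width on mean stretch length
#'   (default 0.1).
#' @param k Stretch threshold the metrics were computed with; the histogram
#'   starts here (default 3).
#' @param provenance Free-text description of the source recorded in the
#'   model (default "unspecified").
#' @return An object of class `gc_background` with fields `n`, `gc_values`
#'   (sorted), `stretch_values` (sorted, missing excluded), `n_missing_stretch`,
#'   `histogram` (tibble of bin edges and counts), `bin_width`, `k`,
#'   `provenance`.
#' @export
build_background <- function(metrics, min_n = 100, bin_width = 0.1, k = 3,
                             provenance = "unspecified") {
  usable <- !is.na(metrics$gc_fraction) & !is.na(metrics$mean_stretch_len)
  n_missing <- sum(is.na(metrics$mean_stretch_len))
  n <- sum(usable)
  if (n < min_n) {
    stop(sprintf(paste0("insufficient background: %d usable records ",
                        "(%d supplied, %d with no stretch), need >= %d"),
                 n, nrow(metrics), n_missing, min_n), call. = FALSE)
  }
  stretch <- sort(metrics$mean_stretch_len[usable])
  gc <- sort(metrics$gc_fraction[usable])
  # bins start at k (no qualifying stretch mean can fall below it for
  # metrics computed at threshold k); extend downward only if the data do
  lower <- min(k, floor(min(stretch)))
  breaks <- seq(lower, max(stretch) + 2 * bin_width, by = bin_width)
  counts <- graphics::hist(stretch, breaks = breaks, plot = FALSE,
                           right = FALSE)$counts
  histogram <- tibble::tibble(
    bin_start = breaks[-length(breaks)],
    bin_end = breaks[-1],
    count = counts
  )
  structure(
    list(n = n, gc_values = gc, stretch_values = stretch,
         n_missing_stretch = n_missing, histogram = histogram,
         bin_width = bin_width, k = k, provenance = provenance),
    class = "gc_background"
  )
}

#' @export
print.gc_background <- function(x, ...) {
  cat(sprintf("Empirical composition background (%d sequences)\n", x$n))
  cat(sprintf("  source: %s\n", x$provenance))
  cat(sprintf("  GC fraction: %.4f - %.4f (median %.4f)\n",
              min(x$gc_values), max(x$gc_values),
              stats::median(x$gc_values)))
  cat(sprintf("  mean stretch length: %.3f - %.3f (median %.3f)\n",
              min(x$stretch_values), max(x$stretch_values),
              stats::median(x$stretch_values)))
  if (x$n_missing_stretch > 0) {
    cat(sprintf("  excluded (no stretch >= %g nt): %d\n", x$k,
                x$n_missing_stretch))
  }
  invisible(x)
}

#' Percentile rank of a value within the background
#'
#' Inclusive counting rank: `100 * #{background values <= q} / n`. A query
#' below the background minimum ranks 0; at or above the maximum, 100.
#'
#' @param model A `gc_background` from [build_background()].
#' @param metric `"gc_fraction"` or `"mean_stretch_len"`.
#' @param q Query value(s); vectorized.
#' @return Percentile rank(s) in `[0, 100]`.
#' @export
percentile_rank <- function(model, metric, q) {
  stopifnot(inherits(model, "gc_background"))
  values <- switch(metric,
    gc_fraction = model$gc_values,
    mean_stretch_len = model$stretch_values,
    stop("unknown metric '", metric,
         "'; use 'gc_fraction' or 'mean_stretch_len'", call. = FALSE)
  )
  100 * findInterval(q, values) / length(values)
}

#' Flag compositional outliers against a background
#'
#' Computes each query's percentile rank on the GC axis and the stretch
#' axis and flags it when the rank reaches the threshold on both axes
#' (`mode = "both"`, the default surrogate for a visually "clear" outlier)
#' or on at least one (`mode = "either"`). Queries with a missing mean
#' stretch length can never be flagged on the stretch axis; they carry a
#' caveat note.
#'
#' @param queries Metrics tibble for the query genes.
#' @param model A `gc_background`.
#' @param gc_pct GC percentile threshold in `(0, 100]` (default 99).
#' @param stretch_pct Stretch percentile threshold in `(0, 100]`
#'   (default 99).
#' @param mode `"both"` or `"either"`.
#' @return Tibble with columns `id`, `gc_fraction`, `mean_stretch_len`,
#'   `gc_percentile`, `stretch_percentile`, `flagged`, `rule`, `caveat`.
#' @export
flag_outliers <- function(queries, model, gc_pct = 99, stretch_pct = 99,
                          mode = c("both", "either")) {
  mode <- match.arg(mode)
  stopifnot(gc_pct > 0, gc_pct <= 100, stretch_pct > 0, stretch_pct <= 100)
  rule <- sprintf("gc>=p%g & stretch>=p%g (mode=%s)", gc_pct, stretch_pct,
                  mode)
  if (nrow(queries) == 0) {
    return(tibble::tibble(id = character(), gc_fraction = numeric(),
                          mean_stretch_len = numeric(),
                          gc_percentile = numeric(),
                          stretch_percentile = numeric(),
                          flagged = logical(), rule = character(),
                          caveat = character()))
  }
  gc_p <- percentile_rank(model, "gc_fraction", queries$gc_fraction)
  has_stretch <- !is.na(queries$mean_stretch_len)
  st_p <- rep(NA_real_, nrow(queries))
  st_p[has_stretch] <- percentile_rank(model, "mean_stretch_len",
                                       queries$mean_stretch_len[has_stretch])
  gc_hit <- gc_p >= gc_pct
  st_hit <- has_stretch & !is.na(st_p) & st_p >= stretch_pct
  flagged <- if (mode == "both") gc_hit & st_hit else gc_hit | st_hit
  tibble::tibble(
    id = queries$id,
    gc_fraction = queries$gc_fraction,
    mean_stretch_len = queries$mean_stretch_len,
    gc_percentile = gc_p,
    stretch_percentile = st_p,
    flagged = flagged,
    rule = rule,
    caveat = ifelse(has_stretch, "",
                    "no stretch >= k; stretch axis not assessable")
  )
}

# Max absolute ECDF difference between samples x and y, evaluated exactly
# over the pooled support (tie blocks collapsed).
ecdf_max_diff <- function(x, y) {
  n_x <- length(x)
  n_y <- length(y)
  pooled <- c(x, y)
  ord <- order(pooled)
  w <- c(rep(1 / n_x, n_x), rep(-1 / n_y, n_y))[ord]
  cum <- cumsum(w)
  sorted <- pooled[ord]
  block_end <- c(sorted[-1] != sorted[-length(sorted)], TRUE)
  max(abs(cum[block_end]))
}

#' Compare a metric's distribution between two gene groups
#'
#' Two-sample comparison of `metric` between the records labeled `group_a`
#' and `group_b`, using the maximum absolute difference between the two
#' empirical CDFs (the Kolmogorov-Smirnov D statistic, computed exactly
#' over the pooled support) with a permutation null: group labels are
#' reshuffled `n_perm` times and the p-value is
#' `(1 + #{D* >= D_obs}) / (1 + n_perm)`, which is exact under label
#' exchangeability and never reports zero.
#'
#' @param metrics Metrics tibble with a `group` column.
#' @param group_a,group_b Group labels to compare.
#' @param metric `"gc_fraction"` or `"mean_stretch_len"`.
#' @param n_perm Number of label permutations (default 1000; minimum 99).
#' @param seed Integer seed for the permutation stream (required, recorded
#'   in the output).
#' @return One-row tibble: `group_a`, `group_b`, `metric`, `n_a`, `n_b`,
#'   `D`, `p_perm`, `n_perm`, `seed`.
#' @export
compare_groups <- function(metrics, group_a, group_b, metric = "gc_fraction",
                           n_perm = 1000, seed) {
  stopifnot(metric %in% c("gc_fraction", "mean_stretch_len"),
            n_perm >= 99, is.numeric(seed), length(seed) == 1)
  available <- unique(metrics$group[!is.na(metrics$group)])
  for (g in c(group_a, group_b)) {
    if (!g %in% available) {
      stop("unknown group label '", g, "'; available: ",
           paste(available, collapse = ", "), call. = FALSE)
    }
  }
  x <- metrics[[metric]][metrics$group %in% group_a]
  y <- metrics[[metric]][metrics$group %in% group_b]
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 5 || length(y) < 5) {
    stop(sprintf("need >= 5 non-missing values per group (got %d and %d)",
                 length(x), length(y)), call. = FALSE)
  }
  d_obs <- ecdf_max_diff(x, y)

  n_x <- length(x)
  n <- n_x + length(y)
  pooled <- c(x, y)
  ord <- order(pooled)
  sorted <- pooled[ord]
  block_end <- c(sorted[-1] != sorted[-length(sorted)], TRUE)
  w_a <- 1 / n_x
  w_b <- -1 / length(y)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  exceed <- 0L
  lab <- logical(n)
  for (b in seq_len(n_perm)) {
    lab[] <- FALSE
    lab[sample.int(n, n_x)] <- TRUE
    w <- ifelse(lab[ord], w_a, w_b)
    d_star <- max(abs(cumsum(w)[block_end]))
    if (d_star >= d_obs - 1e-12) exceed <- exceed + 1L
  }
  tibble::tibble(
    group_a = group_a, group_b = group_b, metric = metric,
    n_a = n_x, n_b = length(y), D = d_obs,
    p_perm = (1 + exceed) / (1 + n_perm),
    n_perm = as.integer(n_perm), seed = as.integer(seed)
  )
}

#' Per-group composition summary for one gene across clades
#'
#' Summarizes GC fraction and mean stretch length of a gene's orthologs
#' within each group (e.g. birds vs mammals vs reptiles), and runs the
#' pairwise permutation comparison for every group pair in which both
#' groups have at least 5 records; smaller pairs are reported as skipped.
#'
#' @param metrics Metrics tibble with `gene` and `group` columns.
#' @param gene Gene symbol to summarize.
#' @param n_perm,seed Passed to [compare_groups()] for the pairwise tests.
#' @return List with `summary` (per-group n, mean/min/max of both metrics)
#'   and `comparisons` (pairwise results or skip reasons).
#' @export
ortholog_contrast <- function(metrics, gene, n_perm = 1000, seed = 1) {
  sel <- metrics[!is.na(metrics$gene) & metrics$gene == gene &
                   !is.na(metrics$group), , drop = FALSE]
  if (nrow(sel) == 0) {
    stop("gene '", gene, "' not found in metrics", call. = FALSE)
  }
  summary <- dplyr::bind_rows(lapply(split(sel, sel$group), function(g) {
    tibble::tibble(
      group = g$group[1],
      n = nrow(g),
      gc_mean = mean(g$gc_fraction),
      gc_min = min(g$gc_fraction),
      gc_max = max(g$gc_fraction),
      stretch_mean = mean(g$mean_stretch_len, na.rm = TRUE),
      stretch_min = suppressWarnings(min(g$mean_stretch_len, na.rm = TRUE)),
      stretch_max = suppressWarnings(max(g$mean_stretch_len, na.rm = TRUE))
    )
  }))
  groups <- sort(unique(sel$group))
  comps <- list()
  if (length(groups) >= 2) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    for (pr in pairs) {
      n_a <- sum(sel$group == pr[1])
      n_b <- sum(sel$group == pr[2])
      if (n_a >= 5 && n_b >= 5) {
        cmp <- compare_groups(sel, pr[1], pr[2], metric = "gc_fraction",
                              n_perm = n_perm, seed = seed)
        cmp$skipped <- ""
        comps[[length(comps) + 1]] <- cmp
      } else {
        comps[[length(comps) + 1]] <- tibble::tibble(
          group_a = pr[1], group_b = pr[2], metric = "gc_fraction",
          n_a = n_a, n_b = n_b, D = NA_real_, p_perm = NA_real_,
          n_perm = NA_integer_, seed = NA_integer_,
          skipped = "fewer than 5 records in a group"
        )
      }
    }
  }
  comparisons <- if (length(comps) == 0) {
    tibble::tibble(group_a = character(), group_b = character(),
                   metric = character(), n_a = integer(), n_b = integer(),
                   D = numeric(), p_perm = numeric(), n_perm = integer(),
                   seed = integer(), skipped = character())
  } else {
    dplyr::bind_rows(comps)
  }
  list(gene = gene, summary = summary, comparisons = comparisons)
}
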