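# Pipeline stage drivers. Each run_* function chains the relevant module
# operations, logs progress to stderr via message(), and writes TSV outputs
# whose first lines are comment headers recording the package version and
# the full serialized configuration -- so any output file documents the run
# that produced it and identical runs are byte-identical.

pkg_version <- function() {
  as.character(utils::packageVersion("gcscreen"))
}

config_header <- function(stage, config) {
  cfg <- paste(sprintf("%s=%s", names(config),
                       vapply(config, function(v) paste(format(v), collapse = ","),
                              character(1))),
               collapse = " ")
  c(sprintf("gcscreen %s | stage=%s", pkg_version(), stage),
    sprintf("config: %s", cfg))
}

#' Compute and write composition metrics for a FASTA file
#'
#' Loads sequences (with optional metadata), applies the minimum-length
#' filter, computes composition metrics, and writes `metrics.tsv` into
#' `out_dir`. Counts in and out of the filter are logged to stderr.
#'
#' @param fasta Input FASTA path.
#' @param metadata Optional metadata TSV path (see [read_fasta()]).
#' @param out_dir Output directory, created if needed.
#' @param min_len Minimum CDS length in nt (default 300).
#' @param k Minimum G/C-stretch length (default 3).
#' @return The metrics tibble, invisibly.
#' @export
run_metrics <- function(fasta, metadata = NULL, out_dir, min_len = 300,
                        k = 3) {
  records <- read_fasta(fasta, metadata)
  kept <- filter_min_length(records, min_len)
  message(sprintf("%d records loaded; %d removed by length filter (< %d nt); %d analyzed",
                  nrow(records), nrow(records) - nrow(kept), min_len,
                  nrow(kept)))
  if (nrow(kept) == 0) {
    warning("no records pass the length filter; writing header-only table",
            call. = FALSE)
  }
  metrics <- composition_metrics(kept, k = k)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(fasta = fasta, metadata = if (is.null(metadata)) "none" else metadata,
              min_len = min_len, k = k)
  write_metrics_table(metrics, file.path(out_dir, "metrics.tsv"),
                      comments = config_header("metrics", cfg))
  invisible(metrics)
}

#' Screen query genes against a background set
#'
#' Builds the background model from one FASTA, computes query metrics from
#' another, flags outliers, and writes three tables into `out_dir`:
#' `outliers.tsv` (per-query calls), `plot_data.tsv` (x = GC fraction,
#' y = mean stretch length, series = background/query, the dot-plot data),
#' and `background_histogram.tsv` (binned mean stretch lengths of the
#' background).
#'
#' @param query_fasta FASTA of query genes.
#' @param background_fasta FASTA of the reference gene set.
#' @param out_dir Output directory.
#' @param min_len,k Filter and stretch parameters (defaults 300, 3).
#' @param gc_pct,stretch_pct,mode Outlier rule (defaults 99, 99, "both");
#'   see [flag_outliers()].
#' @param min_background_n Minimum usable background records (default 100).
#' @param bin_width Histogram bin width (default 0.1).
#' @return List with `calls`, `model`, `query_metrics`,
#'   `background_metrics`, invisibly.
#' @export
run_screen <- function(query_fasta, background_fasta, out_dir,
                       min_len = 300, k = 3, gc_pct = 99, stretch_pct = 99,
                       mode = "both", min_background_n = 100,
                       bin_width = 0.1) {
  bg_records <- filter_min_length(read_fasta(background_fasta), min_len)
  q_records <- filter_min_length(read_fasta(query_fasta), min_len)
  message(sprintf("background: %d records after filter; query: %d",
                  nrow(bg_records), nrow(q_records)))
  bg_metrics <- composition_metrics(bg_records, k = k)
  q_metrics <- composition_metrics(q_records, k = k)
  model <- build_background(bg_metrics, min_n = min_background_n,
                            bin_width = bin_width, k = k,
                            provenance = background_fasta)
  calls <- flag_outliers(q_metrics, model, gc_pct = gc_pct,
                         stretch_pct = stretch_pct, mode = mode)
  message(sprintf("flagged %d of %d query genes", sum(calls$flagged),
                  nrow(calls)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(query = query_fasta, background = background_fasta,
              min_len = min_len, k = k, gc_pct = gc_pct,
              stretch_pct = stretch_pct, mode = mode,
              bin_width = bin_width)
  hdr <- config_header("screen", cfg)

  out_calls <- calls
  out_calls$gc_fraction <- sprintf("%.6f", calls$gc_fraction)
  out_calls$mean_stretch_len <- ifelse(is.na(calls$mean_stretch_len), "NA",
                                       sprintf("%.6f", calls$mean_stretch_len))
  out_calls$gc_percentile <- sprintf("%.6f", calls$gc_percentile)
  out_calls$stretch_percentile <- ifelse(is.na(calls$stretch_percentile),
                                         "NA",
                                         sprintf("%.6f", calls$stretch_percentile))
  write_tsv_commented(out_calls, file.path(out_dir, "outliers.tsv"), hdr)

  plot_data <- tibble::tibble(
    id = c(bg_metrics$id, q_metrics$id),
    series = c(rep("background", nrow(bg_metrics)),
               rep("query", nrow(q_metrics))),
    gc_fraction = sprintf("%.6f", c(bg_metrics$gc_fraction,
                                    q_metrics$gc_fraction)),
    mean_stretch_len = ifelse(
      is.na(c(bg_metrics$mean_stretch_len, q_metrics$mean_stretch_len)),
      "NA",
      sprintf("%.6f", c(bg_metrics$mean_stretch_len,
                        q_metrics$mean_stretch_len)))
  )
  write_tsv_commented(plot_data, file.path(out_dir, "plot_data.tsv"), hdr)

  hist_out <- model$histogram
  hist_out$bin_start <- sprintf("%.6f", hist_out$bin_start)
  hist_out$bin_end <- sprintf("%.6f", hist_out$bin_end)
  write_tsv_commented(hist_out,
                      file.path(out_dir, "background_histogram.tsv"), hdr)
  invisible(list(calls = calls, model = model, query_metrics = q_metrics,
                 background_metrics = bg_metrics))
}

#' Compare a metric between two groups from a metrics table
#'
#' Reads a metrics TSV (as written by [run_metrics()]), runs the
#' permutation comparison, and writes `comparison.tsv` into `out_dir`.
#'
#' @param metrics_tsv Path to a metrics TSV, or a metrics tibble.
#' @param group_a,group_b Group labels.
#' @param metric `"gc_fraction"` or `"mean_stretch_len"`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed (required).
#' @param out_dir Output directory.
#' @return The one-row comparison tibble, invisibly.
#' @export
run_compare <- function(metrics_tsv, group_a, group_b,
                        metric = "gc_fraction", n_perm = 1000, seed,
                        out_dir) {
  metrics <- if (is.character(metrics_tsv)) {
    read_metrics_table(metrics_tsv)
  } else {
    metrics_tsv
  }
  res <- compare_groups(metrics, group_a, group_b, metric = metric,
                        n_perm = n_perm, seed = seed)
  message(sprintf("%s: %s vs %s -> D = %.4f, p_perm = %.4f (n_perm = %d)",
                  metric, group_a, group_b, res$D, res$p_perm, res$n_perm))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(metric = metric, group_a = group_a, group_b = group_b,
              n_perm = n_perm, seed = seed)
  out <- res
  out$D <- sprintf("%.6f", res$D)
  out$p_perm <- sprintf("%.6f", res$p_perm)
  write_tsv_commented(out, file.path(out_dir, "comparison.tsv"),
                      config_header("compare", cfg))
  invisible(res)
}

#' Simulate sequences (and optionally coverage) to files
#'
#' Generates a sequence set from a single spec and writes
#' `simulated.fasta` plus `simulated_meta.tsv` into `out_dir`; with
#' `coverage = TRUE` also writes `coverage.tsv` (BEDGRAPH-style) computed
#' under the GC-bias model.
#'
#' @param n,length_nt,gc,mean_run,seed Simulator parameters; see
#'   [synthetic_spec()].
#' @param out_dir Output directory.
#' @param group Group label stamped on the records (default "simulated").
#' @param coverage Whether to also emit expected-coverage profiles.
#' @param window,base_depth,beta,gc_ref Coverage-model parameters; see
#'   [simulate_coverage()].
#' @return The record tibble, invisibly.
#' @export
run_simulate <- function(n, length_nt, gc, mean_run, seed, out_dir,
                         group = "simulated", coverage = FALSE,
                         window = 50, base_depth = 30, beta = 10,
                         gc_ref = 0.5) {
  spec <- synthetic_spec(n_seqs = n, length_nt = length_nt, target_gc = gc,
                         mean_strong_run = mean_run, seed = seed,
                         group = group)
  records <- simulate_sequence(spec)
  message(sprintf("simulated %d sequences of %d nt (target GC %.2f, mean run %.2f)",
                  n, length_nt, gc, mean_run))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_sim <- list(n = n, length_nt = length_nt, gc = gc,
                  mean_run = mean_run, seed = seed, group = group)
  write_fasta(records, file.path(out_dir, "simulated.fasta"))
  write_tsv_commented(records[c("id", "gene", "species", "group")],
                      file.path(out_dir, "simulated_meta.tsv"),
                      config_header("simulate", cfg_sim))
  if (coverage) {
    profiles <- dplyr::bind_rows(lapply(seq_len(nrow(records)), function(i) {
      simulate_coverage(records[i, ], window = window,
                        base_depth = base_depth, beta = beta,
                        gc_ref = gc_ref)
    }))
    cfg <- list(n = n, length_nt = length_nt, gc = gc, mean_run = mean_run,
                seed = seed, window = window, base_depth = base_depth,
                beta = beta, gc_ref = gc_ref)
    write_coverage(profiles, file.path(out_dir, "coverage.tsv"),
                   config_header("simulate", cfg))
  }
  invisible(records)
}
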