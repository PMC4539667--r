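# Synthetic CDS-like sequence generator: a two-state (strong = G/C,
# weak = A/T) Markov chain with geometric run lengths, giving independent
# control over GC content and G/C-run structure -- the two axes the outlier
# screen operates on. Plus a window-level GC-biased coverage model that
# demonstrates how GC-rich stretches depress sequencing depth.

#' Parameter set for the two-state Markov sequence simulator
#'
#' Strong (G/C) runs have geometric lengths with mean `mean_strong_run`;
#' weak (A/T) runs have geometric mean
#' `mean_strong_run * (1 - target_gc) / target_gc`, which makes the
#' long-run expected GC fraction exactly `target_gc` (mean strong run over
#' the sum of the two means). Within a run, the two eligible bases are
#' chosen independently and equiprobably.
#'
#' @param n_seqs Number of sequences.
#' @param length_nt Length of each sequence in nt.
#' @param target_gc Long-run GC fraction, in (0, 1).
#' @param mean_strong_run Expected G/C run length, > 1.
#' @param seed Integer seed; each sequence uses the deterministic stream
#'   `seed + record index`, so output is independent of generation order.
#' @param prefix Record id prefix (ids are `<prefix>_0001`, ...).
#' @param gene,species,group Optional label templates applied to every
#'   record.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_seqs, length_nt, target_gc, mean_strong_run,
                           seed, prefix = "syn", gene = NA_character_,
                           species = NA_character_, group = NA_character_) {
  if (!is.numeric(target_gc) || target_gc <= 0 || target_gc >= 1) {
    stop("target_gc must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(mean_strong_run) || mean_strong_run <= 1) {
    stop("mean_strong_run must be > 1", call. = FALSE)
  }
  mean_weak_run <- mean_strong_run * (1 - target_gc) / target_gc
  if (mean_weak_run < 1) {
    stop(sprintf(paste0("implied mean weak-run length %.3f < 1; lower ",
                        "target_gc or raise mean_strong_run"),
                 mean_weak_run), call. = FALSE)
  }
  stopifnot(n_seqs >= 1, length_nt >= 1, is.numeric(seed))
  structure(
    list(n_seqs = as.integer(n_seqs), length_nt = as.integer(length_nt),
         target_gc = target_gc, mean_strong_run = mean_strong_run,
         mean_weak_run = mean_weak_run, seed = as.integer(seed),
         prefix = prefix, gene = gene, species = species, group = group),
    class = "synthetic_spec"
  )
}

# One sequence from its own seeded stream. Runs alternate strong/weak;
# run lengths are geometric on {1, 2, ...} with the spec'd means; the
# initial state is strong with probability target_gc (the stationary
# distribution over bases).
simulate_one_sequence <- function(spec, index) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed((spec$seed + index) %% .Machine$integer.max)
  p_s <- 1 / spec$mean_strong_run
  p_w <- 1 / spec$mean_weak_run
  len <- spec$length_nt
  first_strong <- stats::runif(1) < spec$target_gc
  mean_run <- (spec$mean_strong_run + spec$mean_weak_run) / 2
  # draw alternating run lengths in batches until the target length is met
  run_lens <- integer(0)
  run_strong <- logical(0)
  while (sum(run_lens) < len) {
    need <- ceiling((len - sum(run_lens)) / mean_run * 0.65) + 16L
    done <- length(run_lens)
    states <- xor(first_strong, (done + seq_len(2L * need)) %% 2 == 0)
    lens <- integer(2L * need)
    lens[states] <- stats::rgeom(sum(states), p_s) + 1L
    lens[!states] <- stats::rgeom(sum(!states), p_w) + 1L
    run_lens <- c(run_lens, lens)
    run_strong <- c(run_strong, states)
  }
  strong_pos <- rep(run_strong, run_lens)[seq_len(len)]
  coin <- stats::runif(len) < 0.5
  chars <- character(len)
  chars[strong_pos] <- ifelse(coin[strong_pos], "G", "C")
  chars[!strong_pos] <- ifelse(coin[!strong_pos], "A", "T")
  paste(chars, collapse = "")
}

#' Simulate CDS-like sequences from a synthetic spec
#'
#' @param spec A `synthetic_spec`.
#' @return Tibble of sequence records (`id`, `sequence`, `length`, `gene`,
#'   `species`, `group`), reproducible for a given spec and seed.
#' @export
simulate_sequence <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seqs <- vapply(seq_len(spec$n_seqs),
                 function(i) simulate_one_sequence(spec, i), character(1))
  tibble::tibble(
    id = sprintf("%s_%04d", spec$prefix, seq_len(spec$n_seqs)),
    sequence = seqs,
    length = nchar(seqs),
    gene = spec$gene,
    species = spec$species,
    group = spec$group
  )
}

#' Simulate a labeled background + outlier sequence panel
#'
#' Generates a large background set and a smaller outlier set from two
#' specs, labels them `group = "background"` / `"outlier"`, and gives them
#' disjoint id namespaces. This is the synthetic stand-in for a RefSeq-like
#' reference population spiked with GC-rich query genes.
#'
#' @param background_spec,outlier_spec `synthetic_spec` objects; their
#'   `prefix`/`group` fields are overridden to keep namespaces disjoint.
#' @param n_outliers Number of outlier records to generate (overrides
#'   `outlier_spec$n_seqs`).
#' @return Tibble of records, background first.
#' @export
simulate_panel <- function(background_spec, outlier_spec,
                           n_outliers = outlier_spec$n_seqs) {
  stopifnot(inherits(background_spec, "synthetic_spec"),
            inherits(outlier_spec, "synthetic_spec"))
  bg <- background_spec
  bg$prefix <- "bg"
  bg$group <- "background"
  out <- outlier_spec
  out$prefix <- "out"
  out$group <- "outlier"
  out$n_seqs <- as.integer(n_outliers)
  dplyr::bind_rows(simulate_sequence(bg), simulate_sequence(out))
}

#' Expected sequencing coverage along a sequence under GC bias
#'
#' Splits the sequence into fixed-width windows (final partial window
#' kept), computes each window's GC fraction, and applies the exponential
#' attenuation model
#' `coverage = base_depth * exp(-beta * max(0, window_gc - gc_ref))`.
#' With `beta = 0` coverage is uniform; with `beta > 0` windows above the
#' reference GC lose depth exponentially in their GC excess. This is a
#' deliberately simple demonstrator of PCR-driven GC dropout, not a fitted
#' model of any particular library protocol.
#'
#' @param record One-row tibble (or list) with `id` and `sequence`.
#' @param window Window width in nt (default 50).
#' @param base_depth Expected depth at or below `gc_ref` (> 0).
#' @param beta Bias strength, >= 0.
#' @param gc_ref Reference GC fraction above which attenuation starts
#'   (default 0.5).
#' @return Tibble with `id`, `start`, `end` (0-based half-open),
#'   `window_gc`, `expected_coverage`.
#' @export
simulate_coverage <- function(record, window = 50, base_depth, beta,
                              gc_ref = 0.5) {
  stopifnot(window >= 1, base_depth > 0, beta >= 0)
  sequence <- record$sequence[[1]]
  id <- record$id[[1]]
  len <- nchar(sequence)
  starts <- seq(0L, len - 1L, by = window)
  ends <- pmin(starts + window, len)
  gc <- vapply(seq_along(starts), function(i) {
    gc_fraction(substring(sequence, starts[i] + 1L, ends[i]))
  }, numeric(1))
  tibble::tibble(
    id = id,
    start = as.integer(starts),
    end = as.integer(ends),
    window_gc = gc,
    expected_coverage = base_depth * exp(-beta * pmax(0, gc - gc_ref))
  )
}

#' Write coverage profiles as a BEDGRAPH-style TSV
#'
#' @param profile Tibble from [simulate_coverage()] (rows from several
#'   records may be concatenated).
#' @param path Output path; columns chrom, start, end, value.
#' @param comments Optional comment lines written above the data.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(profile, path, comments = NULL) {
  out <- tibble::tibble(
    chrom = profile$id,
    start = profile$start,
    end = profile$end,
    value = sprintf("%.6f", profile$expected_coverage)
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(comments) && length(comments) > 0) {
    writeLines(paste0("# ", comments), con, sep = "\n")
  }
  if (nrow(out) > 0) {
    writeLines(do.call(paste, c(lapply(out, as.character), sep = "\t")),
               con, sep = "\n")
  }
  invisible(path)
}
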