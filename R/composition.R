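# Per-sequence compositional statistics: GC fraction, maximal G/C
# stretches (runs of >= k consecutive G or C), and G-quadruplex motif hits.
# These are the two axes of the background-vs-outlier dot plot: GC content
# and the average length of G/C stretches.

#' GC fraction of a nucleotide sequence
#'
#' Fraction of unambiguous bases that are G or C:
#' (G + C) / (A + C + G + T). IUPAC ambiguity codes (including S = G-or-C)
#' are excluded from both numerator and denominator, so the value reflects
#' only positively identified bases.
#'
#' @param sequence A single nucleotide string (uppercase A/C/G/T plus IUPAC
#'   ambiguity codes).
#' @return GC fraction in `[0, 1]`.
#' @export
gc_fraction <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  gc <- sum(chars == "G" | chars == "C")
  at <- sum(chars == "A" | chars == "T")
  if (gc + at == 0) {
    stop("GC fraction undefined: sequence has no unambiguous A/C/G/T bases",
         call. = FALSE)
  }
  gc / (gc + at)
}

#' Locate maximal G/C stretches
#'
#' Finds every maximal run of consecutive G or C bases of length at least
#' `k` (default 3, the conventional threshold for a G/C stretch). Runs are
#' maximal: they cannot be extended by a neighbouring G or C. Any other
#' character, including N and the ambiguity code S, breaks a run.
#'
#' @param sequence A single nucleotide string.
#' @param k Minimum run length to report (default 3).
#' @return Tibble with 0-based half-open columns `start`, `end` and
#'   `length`, sorted by position; zero rows when no run reaches `k`.
#' @export
find_gc_stretches <- function(sequence, k = 3) {
  stopifnot(is.character(sequence), length(sequence) == 1,
            is.numeric(k), length(k) == 1, k >= 1)
  if (nchar(sequence) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          length = integer()))
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  runs <- rle(chars == "G" | chars == "C")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  keep <- runs$values & runs$lengths >= k
  tibble::tibble(start = as.integer(starts[keep]),
                 end = as.integer(ends[keep]),
                 length = as.integer(runs$lengths[keep]))
}

#' Composition metrics for a set of sequence records
#'
#' Computes, per record: GC fraction, the number of G/C stretches of
#' length >= `k`, their mean, maximum and total length. The mean stretch
#' length is `NA` (not 0) for a sequence with no qualifying stretch, so
#' such sequences can be excluded from background fitting rather than
#' dragging its low tail down.
#'
#' @param records Tibble of sequence records from [read_fasta()] or
#'   [simulate_sequence()].
#' @param k Minimum stretch length (default 3).
#' @return Tibble with columns `id`, `gene`, `species`, `group`,
#'   `length_nt`, `gc_fraction`, `n_stretches`, `mean_stretch_len`,
#'   `max_stretch_len`, `total_stretch_nt`, one row per record in input
#'   order.
#' @export
composition_metrics <- function(records, k = 3) {
  n <- nrow(records)
  gc <- numeric(n)
  n_str <- integer(n)
  mean_str <- numeric(n)
  max_str <- integer(n)
  tot_str <- integer(n)
  for (i in seq_len(n)) {
    gc[i] <- gc_fraction(records$sequence[i])
    st <- find_gc_stretches(records$sequence[i], k = k)
    n_str[i] <- nrow(st)
    if (nrow(st) == 0) {
      mean_str[i] <- NA_real_
      max_str[i] <- 0L
      tot_str[i] <- 0L
    } else {
      mean_str[i] <- mean(st$length)
      max_str[i] <- max(st$length)
      tot_str[i] <- sum(st$length)
    }
  }
  tibble::tibble(
    id = records$id,
    gene = records$gene,
    species = records$species,
    group = records$group,
    length_nt = as.integer(records$length),
    gc_fraction = gc,
    n_stretches = n_str,
    mean_stretch_len = mean_str,
    max_stretch_len = max_str,
    total_stretch_nt = tot_str
  )
}

#' Scan for G-quadruplex-forming motifs
#'
#' Matches the canonical pattern-based quadruplex rule: `n_tracts` runs of
#' at least `tract_len` G, separated by loops of 1 to `max_loop` arbitrary
#' bases. Matches are left-greedy and non-overlapping. Minus-strand motifs
#' are found by applying the same rule to C-tracts and are reported in
#' plus-strand coordinates. This is a motif stand-in, not a thermodynamic
#' structure predictor.
#'
#' @param sequence A single nucleotide string.
#' @param tract_len Minimum G-tract length (default 3).
#' @param max_loop Maximum loop length between tracts (default 7).
#' @param n_tracts Number of tracts required (default 4).
#' @return Tibble with 0-based half-open `start`, `end`, `strand`
#'   (`"+"`/`"-"`) and `n_tracts` (tract count within the hit), sorted by
#'   `start`.
#' @export
scan_quadruplex <- function(sequence, tract_len = 3, max_loop = 7,
                            n_tracts = 4) {
  stopifnot(tract_len >= 2, max_loop >= 1, n_tracts >= 2)
  hits_for <- function(base) {
    pat <- sprintf("%s{%d,}(?:[A-Z]{1,%d}?%s{%d,}){%d}",
                   base, tract_len, max_loop, base, tract_len, n_tracts - 1)
    m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
    if (m[1] == -1) {
      return(tibble::tibble(start = integer(), end = integer(),
                            n_tracts = integer()))
    }
    starts <- as.integer(m) - 1L
    lens <- attr(m, "match.length")
    spans <- substring(sequence, starts + 1L, starts + lens)
    tract_pat <- sprintf("%s{%d,}", base, tract_len)
    counts <- vapply(spans, function(s) {
      t <- gregexpr(tract_pat, s, perl = TRUE)[[1]]
      if (t[1] == -1) 0L else length(t)
    }, integer(1), USE.NAMES = FALSE)
    tibble::tibble(start = starts, end = starts + as.integer(lens),
                   n_tracts = counts)
  }
  plus <- hits_for("G")
  minus <- hits_for("C")
  plus$strand <- rep("+", nrow(plus))
  minus$strand <- rep("-", nrow(minus))
  out <- rbind(plus, minus)
  out <- out[order(out$start, out$strand), c("start", "end", "strand",
                                             "n_tracts")]
  tibble::as_tibble(out)
}

#' Scan a record set for quadruplex motifs and write BED
#'
#' @param records Tibble of sequence records.
#' @param path Optional output BED path (0-based half-open, columns chrom,
#'   start, end, name, score, strand). `NULL` skips writing.
#' @inheritParams scan_quadruplex
#' @return Tibble of hits with an `id` column, invisibly returned after
#'   writing when `path` is given.
#' @export
scan_quadruplex_set <- function(records, path = NULL, tract_len = 3,
                                max_loop = 7, n_tracts = 4) {
  per <- lapply(seq_len(nrow(records)), function(i) {
    h <- scan_quadruplex(records$sequence[i], tract_len = tract_len,
                         max_loop = max_loop, n_tracts = n_tracts)
    if (nrow(h) > 0) h$id <- records$id[i]
    h
  })
  per <- per[vapply(per, nrow, integer(1)) > 0]
  hits <- if (length(per) == 0) {
    tibble::tibble(start = integer(), end = integer(),
                   strand = character(), n_tracts = integer(),
                   id = character())
  } else {
    dplyr::bind_rows(per)
  }
  hits <- hits[c("id", "start", "end", "strand", "n_tracts")]
  if (!is.null(path)) {
    bed <- tibble::tibble(
      chrom = hits$id, start = hits$start, end = hits$end,
      name = sprintf("G4_%d_tracts", hits$n_tracts),
      score = 0L, strand = hits$strand
    )
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (nrow(bed) > 0) {
      writeLines(do.call(paste, c(lapply(bed, as.character), sep = "\t")),
                 con, sep = "\n")
    }
  }
  invisible(hits)
}

#' Reverse complement of a nucleotide string
#'
#' @param sequence A single nucleotide string (IUPAC codes allowed).
#' @return The reverse complement.
#' @export
reverse_complement <- function(sequence) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sequence)))
}
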