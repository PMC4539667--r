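# Independent brute-force oracles and fixture builders shared by the suite.

# Quadratic stretch finder: tests every substring for being all-G/C and
# maximal. Deliberately naive so it cannot share a bug with the rle-based
# implementation.
brute_force_stretches <- function(sequence, k = 3) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  gc <- chars %in% c("G", "C")
  out <- list()
  for (start in seq_len(n)) {
    for (end in start:n) {
      if (!all(gc[start:end])) break
      left_ok <- start == 1 || !gc[start - 1]
      right_ok <- end == n || !gc[end + 1]
      if (left_ok && right_ok && (end - start + 1) >= k) {
        out[[length(out) + 1]] <- c(start - 1L, end)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          length = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
                 length = as.integer(m[, 2] - m[, 1]))
}

# Counting percentile oracle: 100 * #{values <= q} / n.
brute_force_percentile <- function(values, q) {
  100 * sum(values <= q) / length(values)
}

random_dna <- function(len, gc = 0.5) {
  paste(sample(c("G", "C", "A", "T"), len, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

# Minimal record tibble wrapper for raw sequences.
as_records <- function(seqs, ids = sprintf("s%03d", seq_along(seqs)),
                       group = NA_character_, gene = NA_character_) {
  tibble::tibble(id = ids, sequence = seqs, length = nchar(seqs),
                 gene = gene, species = NA_character_, group = group)
}

write_temp_fasta <- function(seqs, ids = sprintf("s%03d", seq_along(seqs)),
                             path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}
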