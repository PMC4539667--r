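# Sequence and table I/O: FASTA loading with normalization, the CDS length
# filter, and deterministic TSV writers used by every downstream stage.

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Read coding sequences from FASTA, with optional group metadata
#'
#' Loads a multi-record FASTA file into a tibble of sequence records.
#' Sequences are normalized on load: uppercased and with U mapped to T, so
#' RNA-derived CDS files (e.g. transcripts assembled from RNA-seq) are
#' accepted. Any character outside the IUPAC nucleotide alphabet is an
#' error. Record IDs are taken as the first whitespace-delimited token of
#' each FASTA header and must be unique.
#'
#' An optional tab-separated metadata file with columns `id`, `gene`,
#' `species`, `group` is joined on exact `id` match; FASTA records absent
#' from the metadata get `NA` labels, and metadata rows whose `id` matches
#' no FASTA record raise a warning (not an error).
#'
#' @param path Path to a FASTA file.
#' @param metadata Optional path to a tab-separated metadata file with a
#'   header row and columns `id`, `gene`, `species`, `group`.
#' @return A tibble with columns `id`, `sequence`, `length`, `gene`,
#'   `species`, `group`; one row per FASTA record, in file order.
#' @export
read_fasta <- function(path, metadata = NULL) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA record id(s): ", paste(dups, collapse = ", "),
         call. = FALSE)
  }
  seqs <- chartr("U", "T", unname(toupper(as.character(set))))
  bad <- grepl(sprintf("[^%s]", paste(IUPAC_CODES, collapse = "")), seqs)
  if (any(bad)) {
    stop("non-IUPAC characters in record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  records <- tibble::tibble(
    id = unname(ids),
    sequence = unname(seqs),
    length = nchar(seqs),
    gene = NA_character_,
    species = NA_character_,
    group = NA_character_
  )
  if (!is.null(metadata)) {
    meta <- read_metadata(metadata)
    missing_ids <- setdiff(meta$id, records$id)
    if (length(missing_ids) > 0) {
      warning("metadata id(s) not found in FASTA: ",
              paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    idx <- match(records$id, meta$id)
    hit <- !is.na(idx)
    records$gene[hit] <- meta$gene[idx[hit]]
    records$species[hit] <- meta$species[idx[hit]]
    records$group[hit] <- meta$group[idx[hit]]
  }
  records
}

read_metadata <- function(path) {
  if (!file.exists(path)) {
    stop("metadata file not found: ", path, call. = FALSE)
  }
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character",
                            comment.char = "#", quote = "")
  needed <- c("id", "gene", "species", "group")
  absent <- setdiff(needed, names(meta))
  if (length(absent) > 0) {
    stop("metadata is missing column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(meta[needed])
}

#' Keep only sequences long enough for compositional analysis
#'
#' Retains records whose length is at least `min_len` nucleotides. The
#' default of 300 nt implements the convention of analyzing only coding
#' sequences longer than 299 nt, below which GC and stretch statistics are
#' too noisy to compare against a gene-set background.
#'
#' @param records Tibble of sequence records from [read_fasta()].
#' @param min_len Minimum length in nt to keep (default 300).
#' @return The filtered tibble, original row order preserved.
#' @export
filter_min_length <- function(records, min_len = 300) {
  stopifnot(is.numeric(min_len), length(min_len) == 1, min_len >= 1)
  records[records$length >= min_len, , drop = FALSE]
}

#' Write per-sequence composition metrics to TSV
#'
#' Writes a tab-separated table with one header row and columns `id`,
#' `gene`, `species`, `group`, `length_nt`, `gc_fraction`, `n_stretches`,
#' `mean_stretch_len`, `max_stretch_len`, `total_stretch_nt`. Floats are
#' printed with 6 decimal places and rows appear in input order, so output
#' is byte-identical across runs. Optional comment lines (prefixed `# `)
#' are written above the header to record provenance.
#'
#' @param metrics Metrics tibble from [composition_metrics()].
#' @param path Output file path.
#' @param comments Optional character vector of comment lines (without the
#'   leading `# `).
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(metrics, path, comments = NULL) {
  cols <- c("id", "gene", "species", "group", "length_nt", "gc_fraction",
            "n_stretches", "mean_stretch_len", "max_stretch_len",
            "total_stretch_nt")
  stopifnot(all(cols %in% names(metrics)))
  out <- metrics[cols]
  out$gc_fraction <- sprintf("%.6f", out$gc_fraction)
  out$mean_stretch_len <- ifelse(is.na(metrics$mean_stretch_len), "NA",
                                 sprintf("%.6f", metrics$mean_stretch_len))
  write_tsv_commented(out, path, comments)
  invisible(path)
}

#' Read back a metrics table written by [write_metrics_table()]
#'
#' @param path Path to the TSV.
#' @return A metrics tibble with numeric columns restored.
#' @export
read_metrics_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", quote = "",
                           colClasses = c(id = "character",
                                          gene = "character",
                                          species = "character",
                                          group = "character"))
  tab$length_nt <- as.integer(tab$length_nt)
  tab$gc_fraction <- as.numeric(tab$gc_fraction)
  tab$n_stretches <- as.integer(tab$n_stretches)
  tab$mean_stretch_len <- as.numeric(tab$mean_stretch_len)
  tab$max_stretch_len <- as.integer(tab$max_stretch_len)
  tab$total_stretch_nt <- as.integer(tab$total_stretch_nt)
  tibble::as_tibble(tab)
}

#' Write sequence records as FASTA plus a metadata TSV
#'
#' @param records Tibble of sequence records.
#' @param fasta_path Output FASTA path.
#' @param metadata_path Optional output path for the id/gene/species/group
#'   TSV; skipped when `NULL`.
#' @return `fasta_path`, invisibly.
#' @export
write_fasta <- function(records, fasta_path, metadata_path = NULL) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, fasta_path, width = 70)
  if (!is.null(metadata_path)) {
    meta <- records[c("id", "gene", "species", "group")]
    write_tsv_commented(meta, metadata_path, NULL)
  }
  invisible(fasta_path)
}

# Deterministic TSV writer: LF endings, no quoting, NA printed as "NA".
write_tsv_commented <- function(df, path, comments) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(comments) && length(comments) > 0) {
    writeLines(paste0("# ", comments), con, sep = "\n")
  }
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df) > 0) {
    body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}
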