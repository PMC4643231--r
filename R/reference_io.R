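# Readers/writers and data model for 16S reference databases, taxonomy
# lineages, community profiles and frequency tables.

RANK_NAMES <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")

#' Parse a taxonomy lineage string
#'
#' Accepts both common dialects: plain semicolon-delimited paths
#' (`"Bacteria;Firmicutes;Clostridia"`) and rank-prefixed paths
#' (`"k__Bacteria; p__Firmicutes; c__Clostridia"`).  The dialect is
#' auto-detected from the presence of `"__"` prefixes.  Ranks are returned
#' in the fixed order domain, phylum, class, order, family, genus, species;
#' unassigned ranks (absent, or empty after a prefix) are the canonical
#' marker `NA`.
#'
#' @param x a single lineage string.
#' @return named character vector of length 7.
#' @export
#' @examples
#' parse_lineage("Bacteria;Firmicutes;Bacilli")
#' parse_lineage("k__Bacteria; p__Firmicutes; c__Bacilli; o__; f__; g__; s__")
parse_lineage <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  if (any(grepl("__", parts, fixed = TRUE))) {
    parts <- sub("^[kdpcofgs]__", "", parts)
  }
  parts <- parts[seq_len(min(length(parts), 7L))]
  parts[parts == ""] <- NA_character_
  out <- rep(NA_character_, 7L)
  out[seq_along(parts)] <- parts
  names(out) <- RANK_NAMES
  out
}

format_lineage <- function(ranks) {
  ranks <- ranks[RANK_NAMES]
  keep <- !is.na(ranks)
  # keep assigned ranks and any NA sandwiched before one (suffix-NA dropped)
  last <- if (any(keep)) max(which(keep)) else 0L
  vals <- ranks[seq_len(last)]
  vals[is.na(vals)] <- ""
  paste(vals, collapse = ";")
}

new_reference_db <- function(sequences, taxonomy) {
  stopifnot(is.character(sequences), !is.null(names(sequences)),
            is.data.frame(taxonomy))
  if (anyDuplicated(names(sequences)))
    stop("duplicate record_ids in reference database")
  if (!identical(taxonomy$record_id, names(sequences)))
    taxonomy <- taxonomy[match(names(sequences), taxonomy$record_id), ]
  structure(list(sequences = sequences, taxonomy = taxonomy),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db> %d records, %d phyla\n",
              length(x$sequences),
              length(unique(stats::na.omit(x$taxonomy$phylum)))))
  invisible(x)
}

#' Number of records in a reference database
#' @param x a `reference_db`.
#' @export
n_records <- function(x) length(x$sequences)

normalize_sequence <- function(seq, id = "") {
  s <- toupper(seq)
  s <- chartr("U", "T", s)
  ch <- unique(split_chars(s))
  bad <- setdiff(ch, IUPAC_CODES)
  if (length(bad) > 0)
    stop(sprintf("record '%s' contains non-IUPAC characters: %s",
                 id, paste(bad, collapse = ", ")))
  s
}

#' Read a 16S reference database (FASTA + taxonomy TSV)
#'
#' Sequences are normalized on read: uppercased, `U` mapped to `T`, and any
#' character outside the IUPAC nucleotide alphabet rejected.  Ambiguity
#' codes other than `N` are preserved (the primer matcher consumes them).
#' The taxonomy file must be a two-column TSV (`record_id <tab> lineage`);
#' both lineage dialects of [parse_lineage()] are accepted.
#'
#' @param path FASTA file of reference sequences.
#' @param taxonomy_path TSV of `record_id <tab> lineage string`.
#' @return a `reference_db`: list with `sequences` (named character) and
#'   `taxonomy` (data.frame of `record_id` plus the seven ranks).
#' @export
read_reference_fasta <- function(path, taxonomy_path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  sequences <- setNames(as.character(seqs), ids)
  if (any(nchar(sequences) == 0)) stop("zero-length sequence in ", path)
  sequences <- mapply(normalize_sequence, sequences, ids)

  tax_raw <- read.delim(taxonomy_path, header = FALSE, sep = "\t",
                        stringsAsFactors = FALSE, quote = "",
                        col.names = c("record_id", "lineage"))
  if (nrow(tax_raw) == 0) stop("empty taxonomy file: ", taxonomy_path)
  missing <- setdiff(ids, tax_raw$record_id)
  if (length(missing) > 0)
    stop("FASTA ids missing from taxonomy: ", paste(missing, collapse = ", "))
  tax_raw <- tax_raw[match(ids, tax_raw$record_id), ]
  ranks <- t(vapply(tax_raw$lineage, parse_lineage, character(7)))
  taxonomy <- data.frame(record_id = ids, ranks, row.names = NULL,
                         stringsAsFactors = FALSE)
  new_reference_db(sequences, taxonomy)
}

#' Write a reference database as FASTA + taxonomy TSV
#'
#' Lineages are written semicolon-delimited; a read/write cycle reproduces
#' sequences and lineages exactly.
#'
#' @param db a `reference_db`.
#' @param path output FASTA path.
#' @param taxonomy_path output taxonomy TSV path.
#' @export
write_reference_db <- function(db, path, taxonomy_path) {
  stopifnot(inherits(db, "reference_db"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(db$sequences), filepath = path)
  lineages <- apply(db$taxonomy[, RANK_NAMES], 1, function(r)
    format_lineage(setNames(r, RANK_NAMES)))
  writeLines(paste(db$taxonomy$record_id, lineages, sep = "\t"),
             taxonomy_path)
  invisible(NULL)
}

#' Normalize taxon weights into a community profile
#'
#' @param raw named non-negative numeric vector of taxon weights; at least
#'   one must be positive.
#' @return named numeric vector of relative frequencies summing to 1;
#'   zero-weight taxa are retained with frequency 0.
#' @export
#' @examples
#' normalize_profile(c(a = 2, b = 2))
normalize_profile <- function(raw) {
  if (!is.numeric(raw) || is.null(names(raw)) || any(names(raw) == ""))
    stop("profile must be a named numeric vector")
  if (any(raw < 0)) stop("negative taxon weight")
  total <- sum(raw)
  if (total <= 0) stop("all taxon weights are zero; cannot normalize")
  raw / total
}

#' Write a tabular report as TSV
#'
#' Writes with a header row, stable column order and full numeric precision
#' (at least 15 significant digits), so the matching reader round-trips
#' values within 1e-6.
#'
#' @param table a data.frame.
#' @param path output path.
#' @export
write_report <- function(table, path) {
  stopifnot(is.data.frame(table))
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a report written by [write_report()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_report <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, quote = "")
}

#' Write / read a samples-by-taxa frequency table
#'
#' Samples are rows (first column `sample`), taxa are columns.
#'
#' @param table data.frame with a `sample` column and numeric taxon columns.
#' @param path TSV path.
#' @export
write_frequency_table <- function(table, path) {
  stopifnot(is.data.frame(table), "sample" %in% names(table))
  num <- table[setdiff(names(table), "sample")]
  if (any(vapply(num, function(x) any(x < 0), logical(1))))
    stop("negative entries in frequency table")
  write_report(table, path)
}

#' @rdname write_frequency_table
#' @export
read_frequency_table <- function(path) read_report(path)
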