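# Primer and primer-pair objects.

#' Construct a primer
#'
#' @param name primer name, e.g. `"U341F"`.
#' @param sequence IUPAC nucleotide string given 5'->3'.
#' @param role `"forward"` or `"reverse"`.
#' @return a `primer` object.
#' @export
primer <- function(name, sequence, role = c("forward", "reverse")) {
  role <- match.arg(role)
  sequence <- toupper(sequence)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (nchar(sequence) < 6)
    stop("primer must be at least 6 nt (a 5-base 3' window plus one base)")
  seq_to_masks(sequence)  # validates alphabet
  structure(list(name = name, sequence = sequence, role = role),
            class = "primer")
}

#' Construct a primer pair
#'
#' Anchor coordinates are the conventional 1-based inclusive positions of the
#' amplicon (first base of the forward site through last base of the reverse
#' site) on the E. coli 16S reference numbering.
#'
#' @param name pair name, e.g. `"V3_U341F_534R"`.
#' @param forward,reverse primer sequences (IUPAC, 5'->3') or `primer`
#'   objects.
#' @param ecoli_start,ecoli_stop 1-based inclusive anchor coordinates;
#'   `ecoli_start < ecoli_stop`.
#' @return a `primer_pair` object.
#' @export
primer_pair <- function(name, forward, reverse, ecoli_start, ecoli_stop) {
  if (!inherits(forward, "primer"))
    forward <- primer(paste0(name, "_F"), forward, "forward")
  if (!inherits(reverse, "primer"))
    reverse <- primer(paste0(name, "_R"), reverse, "reverse")
  stopifnot(ecoli_start < ecoli_stop)
  structure(list(name = name, forward = forward, reverse = reverse,
                 ecoli_start = as.integer(ecoli_start),
                 ecoli_stop = as.integer(ecoli_stop)),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s: %s / %s (E. coli %d-%d)\n", x$name,
              x$forward$sequence, x$reverse$sequence,
              x$ecoli_start, x$ecoli_stop))
  invisible(x)
}

#' Read primer pairs from a TSV config
#'
#' Expected columns: `name`, `forward`, `reverse`, `ecoli_start`,
#' `ecoli_stop`.
#'
#' @param path TSV path.
#' @return named list of `primer_pair` objects.
#' @export
read_primer_pairs <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("name", "forward", "reverse", "ecoli_start", "ecoli_stop")
  if (!all(need %in% names(tab)))
    stop("primer table must have columns: ", paste(need, collapse = ", "))
  pairs <- lapply(seq_len(nrow(tab)), function(i)
    primer_pair(tab$name[i], tab$forward[i], tab$reverse[i],
                tab$ecoli_start[i], tab$ecoli_stop[i]))
  setNames(pairs, tab$name)
}

#' Packaged default primer pairs
#'
#' Literature-derived default sequences for the V3 (U341F/534R, E. coli
#' 341-534) and V4 (515F/806R, E. coli 515-806) universal primer pairs,
#' shipped as an editable TSV under `extdata`.  These are widely used
#' published sequences provided as defaults; substitute your own via
#' [read_primer_pairs()] if your protocol differs.
#'
#' @return named list of `primer_pair` objects.
#' @export
default_primer_pairs <- function() {
  read_primer_pairs(system.file("extdata", "primer_pairs.tsv",
                                package = "paleoamp", mustWork = TRUE))
}
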