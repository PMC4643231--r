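# IUPAC nucleotide code handling shared by the primer scanner and the
# synthetic database generator.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

IUPAC_CODES <- names(IUPAC_SETS)

# 4-bit base masks (A=1, C=2, G=4, T=8); two codes are compatible iff their
# masks intersect.
.base_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)
IUPAC_MASK <- vapply(IUPAC_SETS, function(b) sum(.base_bits[b]), integer(1))

.complement_map <- c(
  A = "T", C = "G", G = "C", T = "A",
  M = "K", R = "Y", W = "W", S = "S", Y = "R", K = "M",
  V = "B", H = "D", D = "H", B = "V", N = "N"
)

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Reverse complement of an IUPAC nucleotide string
#'
#' Ambiguity codes are complemented set-wise (e.g. `M` (A/C) maps to
#' `K` (T/G)).
#'
#' @param x a single nucleotide string over the IUPAC alphabet.
#' @return the reverse-complemented string.
#' @export
#' @examples
#' revcomp_iupac("CCTACGGGAGGCAGCAG")
revcomp_iupac <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  ch <- rev(split_chars(toupper(x)))
  bad <- setdiff(unique(ch), names(.complement_map))
  if (length(bad) > 0)
    stop("non-IUPAC characters in sequence: ", paste(bad, collapse = ", "))
  paste(.complement_map[ch], collapse = "")
}

# Convert a sequence to integer IUPAC masks.  In a search target, N is
# encoded as 0 so that it can never satisfy a primer base (an ambiguous
# reference base is treated as a mismatch rather than a free pass).
seq_to_masks <- function(x, target = FALSE) {
  ch <- split_chars(toupper(x))
  m <- IUPAC_MASK[ch]
  if (anyNA(m)) {
    bad <- unique(ch[is.na(m)])
    stop("non-IUPAC characters in sequence: ", paste(bad, collapse = ", "))
  }
  m <- unname(m)
  if (target) m[ch == "N"] <- 0L
  m
}

# TRUE where the IUPAC sets of two single characters intersect (target N
# never matches).
iupac_compatible <- function(primer_char, target_char) {
  p <- seq_to_masks(primer_char)
  t <- seq_to_masks(target_char, target = TRUE)
  bitwAnd(p, t) > 0L
}

# Local, restoring RNG scope: evaluates code with a fixed seed and puts the
# caller's RNG state back afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
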