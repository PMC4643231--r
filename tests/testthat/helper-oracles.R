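# Independent oracles used across the test suite, implemented separately
# from the package internals.

IUPAC_SET_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

# TRUE iff a primer character can bind a target character: IUPAC sets
# intersect, and a target N never matches.
oracle_base_match <- function(p, t) {
  if (t == "N") return(FALSE)
  length(intersect(IUPAC_SET_ORACLE[[p]], IUPAC_SET_ORACLE[[t]])) > 0
}

# Exhaustive enumeration of all <=1-gap alignments of a primer against a
# window, returning the minimum weighted penalty.  Written as plain nested
# loops, independent of the package's scanner.
oracle_score <- function(primer, window) {
  pc <- strsplit(primer, "")[[1]]
  wc <- strsplit(window, "")[[1]]
  L <- length(pc)
  m <- length(wc)
  mm_pen <- function(j) if (j == L) 3.0 else if (j >= L - 4) 1.0 else 0.4
  del_pen <- function(j) if (j >= L - 4) 3.0 else 1.0   # primer base vs gap
  ins_pen <- function(g) if (g >= L - 4) 3.0 else 1.0   # extra target base
  scores <- numeric(0)
  if (m == L) {
    s <- 0
    for (j in seq_len(L)) if (!oracle_base_match(pc[j], wc[j]))
      s <- s + mm_pen(j)
    scores <- c(scores, s)
  } else if (m == L - 1) {
    for (g in seq_len(L)) {
      s <- del_pen(g)
      for (j in setdiff(seq_len(L), g)) {
        wj <- if (j < g) j else j - 1
        if (!oracle_base_match(pc[j], wc[wj])) s <- s + mm_pen(j)
      }
      scores <- c(scores, s)
    }
  } else if (m == L + 1) {
    for (g in seq_len(L - 1)) {  # insertion between primer positions g, g+1
      s <- ins_pen(g)
      for (j in seq_len(L)) {
        wj <- if (j <= g) j else j + 1
        if (!oracle_base_match(pc[j], wc[wj])) s <- s + mm_pen(j)
      }
      scores <- c(scores, s)
    }
  } else stop("window length out of range")
  min(scores)
}

# Brute-force per-bond fragmenter: every internal bond of each template
# breaks independently with probability lambda (explicit rbinom draws).
# Returns fragment lengths after the min_len filter.
oracle_fragment_lengths <- function(n_templates, template_len, lambda,
                                    min_len = 1) {
  out <- integer(0)
  for (i in seq_len(n_templates)) {
    breaks <- which(stats::rbinom(template_len - 1, 1, lambda) == 1)
    bounds <- c(0, breaks, template_len)
    lens <- diff(bounds)
    out <- c(out, lens[lens >= min_len])
  }
  out
}

# Random IUPAC-free sequences
random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Small standard clade set used by several tests: the three-clade V3-like
# structure (archaeal clade shortest).
test_clades <- function(divergence = 0.02) {
  list(
    clade_spec(paste0("Archaea;Euryarchaeota;Methanobacteria;",
                      "Methanobacteriales;Methanobacteriaceae;",
                      "Methanobrevibacter"), 3, 151, divergence),
    clade_spec(paste0("Bacteria;Chloroflexi;Anaerolineae;Anaerolineales;",
                      "Anaerolineaceae;Anaerolinea"), 3, 169, divergence),
    clade_spec(paste0("Bacteria;Spirochaetes;Spirochaetia;Spirochaetales;",
                      "Spirochaetaceae;Treponema"), 3, 194, divergence))
}

test_v3_pair <- function() default_primer_pairs()$V3_U341F_534R

test_profile <- function() c(Methanobrevibacter = 1/3, Anaerolinea = 1/3,
                             Treponema = 1/3)

# Plant exact primer sites on a random background template: forward site
# starting at 1-based position fwd_start, reverse site ending at rev_end.
planted_template <- function(pair, fwd_start, rev_end, template_len = 1540,
                             seed = 42) {
  set.seed(seed)
  tpl <- random_seq(template_len)
  fseq <- pair$forward$sequence
  rseq <- revcomp_iupac(pair$reverse$sequence)
  # realize ambiguity codes as concrete bases (first of each set)
  realize <- function(x) paste(vapply(
    strsplit(x, "")[[1]], function(c) IUPAC_SET_ORACLE[[c]][1],
    character(1)), collapse = "")
  substr(tpl, fwd_start, fwd_start + nchar(fseq) - 1) <- realize(fseq)
  substr(tpl, rev_end - nchar(rseq) + 1, rev_end) <- realize(rseq)
  tpl
}
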