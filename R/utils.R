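# Internal helpers shared across modules.

# 20 canonical amino acids, alphabetical one-letter order (matrix column order
# used throughout the profile code).
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Robinson & Robinson background frequencies, renormalised over the 20
# canonical residues; used by the synthetic-fixture generator.
AA_BACKGROUND <- c(
  A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
  G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
  M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
  S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216
)

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_domex <- function(...) stop(sprintf(...), call. = FALSE)

#' @importFrom methods is
is_aa_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
}

# TRUE when the sequence uses only the 20 canonical residues plus X
valid_alphabet <- function(seq) {
  !grepl(paste0("[^", paste(c(AA20, "X"), collapse = ""), "]"), seq)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Cache: BLOSUM62 is used in tight loops (profiles, oracles).
.domex_cache <- new.env(parent = emptyenv())

# BLOSUM62 restricted to the 20 canonical residues, in AA20 order.
get_blosum62 <- function() {
  if (is.null(.domex_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .domex_cache$blosum62 <- e$BLOSUM62[AA20, AA20]
  }
  .domex_cache$blosum62
}

# split an amino-acid string into a character vector of residues
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Format a list of 1-based inclusive ranges as "a-b|c-d" (CATH-style).
format_ranges <- function(ranges) {
  paste(vapply(ranges, function(r) paste0(r[1], "-", r[2]), character(1)),
        collapse = "|")
}

# Parse "a-b|c-d" (also accepts en-dash and comma separators) into a list of
# length-2 integer vectors.
parse_ranges <- function(txt) {
  txt <- gsub("–", "-", txt)
  parts <- strsplit(txt, "[|,]")[[1]]
  lapply(parts, function(p) {
    m <- regmatches(p, regexec("^\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", p))[[1]]
    if (length(m) != 3L)
      stop_domex("cannot parse residue range '%s'", p)
    r <- as.integer(m[2:3])
    if (r[2] < r[1]) stop_domex("reversed residue range '%s'", p)
    r
  })
}
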