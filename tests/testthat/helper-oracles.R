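# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles are written as plain memoised recursions so they share
# no code with the package's alignment paths.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) paste(sample(AA, n, replace = TRUE),
                                    collapse = "")

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[AA, AA]
})

# Best local (Smith-Waterman) affine-gap alignment score between two
# sequences under BLOSUM62, gap cost open + k * ext. Direct evaluation of
# the three-state scoring recurrence; the empty alignment scores 0.
oracle_local_score <- function(a, b, open = 11, ext = 1) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m + 1)  # last column: ac[i] aligned to bc[j]
  X <- matrix(NEG, n + 1, m + 1)  # last column: ac[i] over a gap
  Y <- matrix(NEG, n + 1, m + 1)  # last column: gap over bc[j]
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- blosum62[ac[i], bc[j]] +
        max(0, M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Best global affine-gap profile-profile alignment score for a precomputed
# column-score matrix `sub` (n x m). Memoised recursion over (i, j, state).
oracle_global_score <- function(sub, open = 7, ext = 0.5) {
  n <- nrow(sub); m <- ncol(sub)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (i == 0 && j == 0) {
      if (state == 1) 0 else -Inf
    } else if (state == 1) {
      if (i == 0 || j == 0) -Inf
      else sub[i, j] + max(rec(i - 1, j - 1, 1), rec(i - 1, j - 1, 2),
                           rec(i - 1, j - 1, 3))
    } else if (state == 2) {   # column i of the first profile over a gap
      if (i == 0) -Inf
      else max(rec(i - 1, j, 1) - open - ext, rec(i - 1, j, 2) - ext)
    } else {                   # column j of the second profile over a gap
      if (j == 0) -Inf
      else max(rec(i, j - 1, 1) - open - ext, rec(i, j - 1, 3) - ext)
    }
    memo[[key]] <- val
    val
  }
  max(rec(n, m, 1), rec(n, m, 2), rec(n, m, 3))
}

# Build an assembled candidate from two explicit segment sequences by
# planting them as segments 1 and 3 of a synthetic chain.
candidate_from_segments <- function(seq_p, seq_q, middle = NULL,
                                    reversed = FALSE) {
  middle <- middle %||% random_protein(50)
  chain <- paste0(seq_p, middle, seq_q)
  segs <- segments_from_boundaries(chain,
                                   c(nchar(seq_p),
                                     nchar(seq_p) + nchar(middle)))
  assemble_candidate(segs[1, ], segs[3, ], reversed = reversed)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A minimal template_hit for unit tests of splitting/scoring.
toy_hit <- function(q_aln, t_aln, q_start = 1L, template_id = "t1",
                    source = "STRUCTURE", evalue = 1e-5, L_T = NULL,
                    template_seq = NULL) {
  stopifnot(nchar(q_aln) == nchar(t_aln))
  tseq <- gsub("-", "", t_aln, fixed = TRUE)
  structure(list(
    template_id = template_id, source = source, evalue = evalue,
    score = NA_real_, s = NA_real_, c = NA_real_,
    L_T = L_T %||% nchar(tseq),
    template_seq = template_seq %||% tseq,
    per_segment = NULL, q_aln = q_aln, t_aln = t_aln,
    q_start = q_start, t_start = 1L), class = "template_hit")
}

# Random gapped alignment pair over a query of length L_Q: returns aligned
# strings plus the query start, for the split-conservation properties.
random_alignment <- function(L_Q = 60) {
  q_start <- sample.int(max(1L, L_Q %/% 3L), 1L)
  span <- sample.int(L_Q - q_start + 1L, 1L)
  qres <- sample(AA, span, replace = TRUE)
  ncols <- span + sample(0:8, 1L)
  gap_cols <- if (ncols > span) sample(ncols, ncols - span) else integer(0)
  q_aln <- character(ncols)
  t_aln <- character(ncols)
  qi <- 0L
  for (k in seq_len(ncols)) {
    if (k %in% gap_cols) {
      q_aln[k] <- "-"
      t_aln[k] <- sample(AA, 1L)
    } else {
      qi <- qi + 1L
      q_aln[k] <- qres[qi]
      # template residue: gap, identical, or mismatch
      r <- stats::runif(1)
      t_aln[k] <- if (r < 0.15 && k > 1 && k < ncols) "-"
                  else if (r < 0.6) qres[qi]
                  else sample(AA, 1L)
    }
  }
  # avoid all-gap template columns pairing with query gaps
  list(q_aln = paste(q_aln, collapse = ""),
       t_aln = paste(t_aln, collapse = ""), q_start = q_start)
}

write_fasta <- function(named_seqs, path) {
  writeLines(unlist(lapply(names(named_seqs), function(n)
    c(paste0(">", n), named_seqs[[n]]))), path)
  path
}
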