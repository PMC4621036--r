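#' Build a sequence profile
#'
#' A profile holds one 20-component log-odds column per residue plus a
#' predicted secondary-structure state (\code{H}/\code{E}/\code{C}) with a
#' confidence. Columns come from a PSI-BLAST ASCII PSSM when one is
#' supplied; otherwise a single-sequence pseudo-profile is built from the
#' BLOSUM62 row of each residue (an \code{X} gets a zero column). Columns
#' are scaled to unit Euclidean norm, so a column dot-product is a cosine
#' similarity in \eqn{[-1, 1]}: aligning a column to itself scores exactly
#' 1, never less than any substitute. This is the scale on which the PPA
#' gap penalties and the score cutoff are defined (a perfect
#' ungapped self-alignment has PPA-score \eqn{-(1 + w_{ss})}).
#'
#' @param sequence amino-acid string.
#' @param pssm optional path to an NCBI ASCII PSSM (\code{psiblast
#'   -out_ascii_pssm}); row count must match the sequence length.
#' @param ss optional secondary structure: a path to a PSIPRED vertical
#'   (.ss2) file, or a character string of \code{H}/\code{E}/\code{C} of the
#'   same length as \code{sequence}. Default: all-coil with confidence 1.
#' @return An object of class \code{sequence_profile} with fields
#'   \code{length}, \code{mat} (length x 20, AA20 column order), \code{ss},
#'   \code{ss_conf}, \code{sequence}.
#' @export
build_profile <- function(sequence, pssm = NULL, ss = NULL) {
  if (!is_aa_string(sequence)) stop_domex("sequence must be a non-empty string")
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  chars <- seq_chars(sequence)

  if (is.null(pssm)) {
    bl <- get_blosum62()
    mat <- matrix(0, nrow = L, ncol = 20, dimnames = list(NULL, AA20))
    known <- chars %in% AA20
    mat[known, ] <- bl[chars[known], , drop = FALSE]
  } else {
    mat <- parse_ascii_pssm(pssm)
    if (nrow(mat) != L)
      stop_domex("PSSM has %d rows but the query has %d residues",
                 nrow(mat), L)
  }
  norms <- sqrt(rowSums(mat^2))
  mat <- mat / ifelse(norms > 0, norms, 1)

  if (is.null(ss)) {
    ss_states <- rep("C", L)
    ss_conf <- rep(1, L)
  } else if (length(ss) == 1L && file.exists(ss)) {
    parsed <- parse_ss2(ss)
    if (nrow(parsed) != L)
      stop_domex("secondary-structure file has %d positions for a %d-residue query",
                 nrow(parsed), L)
    ss_states <- parsed$ss
    ss_conf <- parsed$conf
  } else if (is.character(ss) && length(ss) == 1L) {
    if (nchar(ss) != L)
      stop_domex("secondary-structure string length %d != sequence length %d",
                 nchar(ss), L)
    ss_states <- seq_chars(toupper(ss))
    if (!all(ss_states %in% c("H", "E", "C")))
      stop_domex("secondary-structure states must be H, E or C")
    ss_conf <- rep(1, L)
  } else stop_domex("ss must be a file path or an H/E/C string")

  structure(list(length = L, mat = mat, ss = ss_states, ss_conf = ss_conf,
                 sequence = sequence),
            class = "sequence_profile")
}

# Parse an NCBI ASCII PSSM (psiblast -out_ascii_pssm): the first 20 numeric
# fields after the residue letter are the position-specific log-odds.
parse_ascii_pssm <- function(path) {
  if (!file.exists(path)) stop_domex("PSSM file not found: %s", path)
  lines <- readLines(path)
  rows <- grep("^\\s*\\d+\\s+[A-Zx*]", lines)
  if (!length(rows)) stop_domex("no PSSM rows found in %s", path)
  mat <- matrix(NA_real_, nrow = length(rows), ncol = 20,
                dimnames = list(NULL, AA20))
  # header line right above the first row gives the column residue order
  hdr <- strsplit(trimws(lines[rows[1] - 1L]), "\\s+")[[1]]
  cols <- hdr[seq_len(min(20L, length(hdr)))]
  if (!all(cols %in% AA20))
    stop_domex("unrecognised PSSM header line %d in %s", rows[1] - 1L, path)
  for (i in seq_along(rows)) {
    fields <- strsplit(trimws(lines[rows[i]]), "\\s+")[[1]]
    if (length(fields) < 22L)
      stop_domex("malformed PSSM line %d in %s", rows[i], path)
    vals <- suppressWarnings(as.numeric(fields[3:22]))
    if (anyNA(vals))
      stop_domex("non-numeric PSSM values on line %d in %s", rows[i], path)
    mat[i, cols] <- vals
  }
  mat
}

# Parse PSIPRED vertical (.ss2) output: columns index, residue, state,
# coil/helix/strand confidences.
parse_ss2 <- function(path) {
  lines <- readLines(path)
  lines <- lines[grepl("^\\s*\\d+\\s+[A-Zx]", lines)]
  if (!length(lines)) stop_domex("no data rows in %s", path)
  parts <- strsplit(trimws(lines), "\\s+")
  ss <- vapply(parts, `[[`, character(1), 3L)
  conf <- vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[4:6]))
    if (anyNA(v)) return(NA_real_)
    max(v)
  }, numeric(1))
  if (anyNA(conf)) stop_domex("non-numeric confidences in %s", path)
  data.frame(ss = ss, conf = conf, stringsAsFactors = FALSE)
}

#' Profile-profile alignment score
#'
#' Globally aligns two profiles by affine-gap dynamic programming. The score
#' of aligning query column \eqn{i} to template column \eqn{j} is the dot
#' product of the two log-odds columns plus \code{w_ss} when the predicted
#' secondary-structure states agree. The reported PPA-score is the negated,
#' alignment-length-normalised dynamic-programming optimum, so that a good
#' alignment has a low (typically negative) score.
#'
#' @param query,template [build_profile()] objects.
#' @param w_ss secondary-structure agreement bonus (default 1).
#' @param gap_open,gap_extend affine gap penalties on the column-score scale
#'   (a length-k gap costs \code{gap_open + k * gap_extend}; defaults 7 and
#'   0.5).
#' @return A list with \code{score} (the PPA-score), \code{raw_dp_score}
#'   (the DP optimum) and \code{alignment} (data frame of aligned column
#'   index pairs, \code{NA} at gaps).
#' @export
ppa_score <- function(query, template, w_ss = 1, gap_open = 7,
                      gap_extend = 0.5) {
  stopifnot(inherits(query, "sequence_profile"),
            inherits(template, "sequence_profile"))
  n <- query$length
  m <- template$length
  sub <- tcrossprod(query$mat, template$mat) +
    w_ss * outer(query$ss, template$ss, "==")

  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in template (query column unmatched)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in query
  M[1L, 1L] <- 0
  if (n >= 1L) X[2:(n + 1L), 1L] <- -(gap_open + seq_len(n) * gap_extend)
  if (m >= 1L) Y[1L, 2:(m + 1L)] <- -(gap_open + seq_len(m) * gap_extend)
  for (i in seq_len(n)) {
    ii <- i + 1L
    for (j in seq_len(m)) {
      jj <- j + 1L
      M[ii, jj] <- max(M[ii - 1L, jj - 1L], X[ii - 1L, jj - 1L],
                       Y[ii - 1L, jj - 1L]) + sub[i, j]
      X[ii, jj] <- max(M[ii - 1L, jj] - gap_open - gap_extend,
                       X[ii - 1L, jj] - gap_extend)
      Y[ii, jj] <- max(M[ii, jj - 1L] - gap_open - gap_extend,
                       Y[ii, jj - 1L] - gap_extend)
    }
  }
  raw <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])

  # traceback for the alignment columns
  qpos <- integer(0); tpos <- integer(0)
  i <- n; j <- m
  state <- which.max(c(M[n + 1L, m + 1L], X[n + 1L, m + 1L],
                       Y[n + 1L, m + 1L]))
  tol <- 1e-9
  while (i > 0L || j > 0L) {
    ii <- i + 1L; jj <- j + 1L
    if (state == 1L) {           # M: i aligned to j
      qpos <- c(i, qpos); tpos <- c(j, tpos)
      prev <- c(M[ii - 1L, jj - 1L], X[ii - 1L, jj - 1L], Y[ii - 1L, jj - 1L])
      state <- which(abs(prev - (M[ii, jj] - sub[i, j])) < tol)[1]
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {    # X: query column i over a gap
      qpos <- c(i, qpos); tpos <- c(NA_integer_, tpos)
      if (ii > 1L &&
          abs(M[ii - 1L, jj] - gap_open - gap_extend - X[ii, jj]) < tol)
        state <- 1L
      i <- i - 1L
    } else {                     # Y: template column j over a gap
      qpos <- c(NA_integer_, qpos); tpos <- c(j, tpos)
      if (jj > 1L &&
          abs(M[ii, jj - 1L] - gap_open - gap_extend - Y[ii, jj]) < tol)
        state <- 1L
      j <- j - 1L
    }
    if (i == 0L && state == 2L && j > 0L) state <- 3L
    if (j == 0L && state == 3L && i > 0L) state <- 2L
  }
  alen <- length(qpos)
  list(score = -(raw / alen), raw_dp_score = raw,
       alignment = data.frame(qpos = qpos, tpos = tpos))
}

#' Create a PPA scorer for the decision chain
#'
#' Returns a \code{function(candidate, hit)} that builds (and caches)
#' single-sequence profiles for the candidate and the hit's template and
#' returns their [ppa_score()]. Supply \code{query_ss} (an H/E/C string or
#' .ss2 path for the full chain is not meaningful here, so this is the
#' candidate-level structure string) to inject predicted secondary structure
#' for the query side.
#'
#' @param w_ss,gap_open,gap_extend passed to [ppa_score()].
#' @param query_ss optional secondary-structure source for candidates.
#' @return A scorer closure suitable for [decide()]'s \code{ppa_scorer}.
#' @export
make_ppa_scorer <- function(w_ss = 1, gap_open = 7, gap_extend = 0.5,
                            query_ss = NULL) {
  cache <- new.env(parent = emptyenv())
  profile_of <- function(seq, ss = NULL) {
    key <- paste0(seq, "|", ss %||% "")
    if (is.null(cache[[key]])) cache[[key]] <- build_profile(seq, ss = ss)
    cache[[key]]
  }
  function(candidate, hit) {
    qp <- profile_of(candidate$sequence, query_ss)
    tp <- profile_of(hit$template_seq)
    ppa_score(qp, tp, w_ss = w_ss, gap_open = gap_open,
              gap_extend = gap_extend)$score
  }
}
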