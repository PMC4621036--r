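#' Derive chain segments from predicted boundaries
#'
#' A boundary at position \eqn{B_i} breaks the chain after residue \eqn{B_i},
#' so \eqn{n} boundaries partition an \eqn{L}-residue chain into \eqn{n + 1}
#' contiguous segments covering every residue. All coordinates are 1-based
#' inclusive.
#'
#' @param sequence amino-acid string of the full chain.
#' @param boundaries integer vector of boundary positions, strictly
#'   increasing, each in \eqn{[1, L - 1]}. May be empty (one segment).
#'
#' @return A data frame with one row per segment and columns \code{index},
#'   \code{start}, \code{end}, \code{length}, \code{sequence}.
#' @export
segments_from_boundaries <- function(sequence, boundaries = integer(0)) {
  if (!is_aa_string(sequence)) stop_domex("sequence must be a non-empty string")
  L <- nchar(sequence)
  boundaries <- as.integer(boundaries)
  if (length(boundaries)) {
    if (is.unsorted(boundaries, strictly = TRUE))
      stop_domex("boundaries must be strictly increasing")
    if (min(boundaries) < 1L || max(boundaries) > L - 1L)
      stop_domex("boundary outside [1, %d]", L - 1L)
  }
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, L)
  data.frame(
    index = seq_along(starts),
    start = starts,
    end = ends,
    length = ends - starts + 1L,
    sequence = substring(sequence, starts, ends),
    stringsAsFactors = FALSE)
}

#' Assemble one candidate discontinuous domain
#'
#' Concatenates two segments into a putative domain \eqn{Q}. With
#' \code{reversed = FALSE} the segments are joined in chain (N- to C-terminal)
#' order; with \code{reversed = TRUE} the later segment is placed first while
#' the residue order inside each segment is preserved, modelling
#' segment-swapped domain homologs. The junction is the position of the last
#' residue of the first component within the concatenated sequence.
#'
#' @param first,second single-row segment data frames (rows of
#'   [segments_from_boundaries()]); \code{first$index < second$index} and the
#'   indices must differ by at least 2 (non-adjacent).
#' @param reversed logical; emit the second segment first.
#' @return An object of class \code{assembled_candidate}.
#' @export
assemble_candidate <- function(first, second, reversed = FALSE) {
  if (second$index - first$index < 2L)
    stop_domex("segments %d and %d are adjacent; candidates must skip >= 1 segment",
               first$index, second$index)
  a <- if (reversed) second else first
  b <- if (reversed) first else second
  structure(list(
    first = as.list(a[c("index", "start", "end", "length", "sequence")]),
    second = as.list(b[c("index", "start", "end", "length", "sequence")]),
    reversed = reversed,
    sequence = paste0(a$sequence, b$sequence),
    junction = nchar(a$sequence),
    id = sprintf("S%d+S%d%s", a$index, b$index, if (reversed) "(rev)" else "")
  ), class = "assembled_candidate")
}

#' @export
print.assembled_candidate <- function(x, ...) {
  cat(sprintf("Candidate %s: %d+%d = %d residues, junction after %d\n",
              x$id, x$first$length, x$second$length, nchar(x$sequence),
              x$junction))
  invisible(x)
}

#' Enumerate candidate discontinuous-domain assemblies
#'
#' Emits every pair of non-adjacent segments \eqn{(S_i, S_j)}, \eqn{j \ge
#' i + 2}, whose members both reach \code{min_len} residues, concatenated in
#' chain order. Adjacent pairs are not candidates (they would form a
#' continuous domain), and by default reversed (C- to N-terminal) assemblies
#' are skipped; \code{allow_reversed = TRUE} additionally emits each pair in
#' swapped order to catch segment-swapped domains.
#'
#' @param segments data frame from [segments_from_boundaries()].
#' @param min_len minimum segment length in residues (default 40, matching
#'   the +/-20-residue boundary-error tolerance of upstream predictors).
#' @param allow_reversed also emit swapped-order assemblies.
#' @return A list of [assemble_candidate()] objects (possibly empty).
#' @export
enumerate_candidates <- function(segments, min_len = 40L,
                                 allow_reversed = FALSE) {
  stopifnot(is.data.frame(segments))
  m <- nrow(segments)
  out <- list()
  if (m < 3L) return(out)
  for (i in seq_len(m - 2L)) {
    for (j in seq.int(i + 2L, m)) {
      if (segments$length[i] < min_len || segments$length[j] < min_len) next
      out[[length(out) + 1L]] <-
        assemble_candidate(segments[i, ], segments[j, ], reversed = FALSE)
      if (allow_reversed)
        out[[length(out) + 1L]] <-
          assemble_candidate(segments[i, ], segments[j, ], reversed = TRUE)
    }
  }
  out
}

#' Read predicted boundaries from TSV
#'
#' Expects a tab-separated file with columns \code{chain_id} and
#' \code{boundary} (1-based "break after residue" positions), one row per
#' boundary. A chain may appear with zero rows, meaning no boundaries.
#'
#' @param path TSV file path.
#' @return A data frame with columns \code{chain_id}, \code{boundary}.
#' @export
read_boundaries <- function(path) {
  if (!file.exists(path)) stop_domex("boundary file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chain_id", "boundary")
  if (!all(need %in% names(df)))
    stop_domex("boundary TSV must have columns: %s", paste(need, collapse = ", "))
  df$boundary <- as.integer(df$boundary)
  df[order(df$chain_id, df$boundary), need]
}

#' Write a boundary TSV
#' @param boundaries data frame with columns \code{chain_id}, \code{boundary}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_boundaries <- function(boundaries, path) {
  utils::write.table(boundaries[, c("chain_id", "boundary")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
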