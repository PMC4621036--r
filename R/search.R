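#' Search backends
#'
#' A search backend finds local alignments between an assembled candidate and
#' every record of a [domain_library()]. Two backends are provided:
#'
#' \describe{
#'   \item{\code{builtin_backend()}}{A deterministic in-process backend:
#'   BLOSUM62 log-odds scoring of the bare query with affine-gap local
#'   (Smith-Waterman) alignment against every library record, and a
#'   Karlin-Altschul E-value \eqn{E = K m n e^{-\lambda S}} where \eqn{m} is
#'   the query length and \eqn{n} the total residue count of the library. It
#'   makes the whole pipeline runnable with no external binaries.}
#'   \item{\code{psiblast_backend()}}{An adapter around the external
#'   \code{psiblast} binary implementing a two-stage profile alignment: stage
#'   one iterates PSI-BLAST against a background sequence set to build a
#'   query profile (PSSM), stage two searches the domain library with that
#'   profile. Stage counts and inclusion thresholds are configuration.}
#' }
#'
#' @param gap_opening,gap_extension affine gap penalties (cost of a length-k
#'   gap is \code{gap_opening + k * gap_extension}).
#' @param lambda,K Karlin-Altschul parameters; defaults are the standard
#'   gapped BLOSUM62/11/1 values.
#' @return A \code{search_backend} object.
#' @name search_backends
NULL

#' @rdname search_backends
#' @export
builtin_backend <- function(gap_opening = 11, gap_extension = 1,
                            lambda = 0.267, K = 0.041) {
  structure(list(name = "builtin", gap_opening = gap_opening,
                 gap_extension = gap_extension, lambda = lambda, K = K),
            class = c("builtin_backend", "search_backend"))
}

#' @rdname search_backends
#' @param iterations PSI-BLAST iterations for the profile-building stage; 1
#'   skips the profile stage and searches the library with the bare query.
#' @param inclusion_evalue inclusion threshold for profile iteration.
#' @param background_fasta FASTA of background sequences for stage one;
#'   defaults to the domain library itself.
#' @param exe,makeblastdb_exe binary names or paths.
#' @export
psiblast_backend <- function(iterations = 2, inclusion_evalue = 0.001,
                             background_fasta = NULL, exe = "psiblast",
                             makeblastdb_exe = "makeblastdb") {
  structure(list(name = "psiblast", iterations = as.integer(iterations),
                 inclusion_evalue = inclusion_evalue,
                 background_fasta = background_fasta, exe = exe,
                 makeblastdb_exe = makeblastdb_exe),
            class = c("psiblast_backend", "search_backend"))
}

#' Run a backend over a library
#'
#' Low-level generic behind [search_templates()]. Returns raw alignments, one
#' row per local alignment: \code{template_id}, \code{score},
#' \code{evalue}, \code{q_start}, \code{t_start}, and the aligned query and
#' template strings (with \code{-} gap characters) \code{q_aln},
#' \code{t_aln}. Deterministic given identical inputs and configuration.
#'
#' @param backend a \code{search_backend}.
#' @param query amino-acid string.
#' @param lib a [domain_library()].
#' @return A data frame of raw alignments (zero rows when nothing aligns).
#' @export
backend_search <- function(backend, query, lib) UseMethod("backend_search")

#' @export
backend_search.builtin_backend <- function(backend, query, lib) {
  stopifnot(inherits(lib, "domain_library"))
  if (!is_aa_string(query)) stop_domex("query must be a non-empty string")
  n_total <- sum(lib$length)
  m <- nchar(query)
  q <- Biostrings::AAString(query)
  rows <- lapply(seq_len(nrow(lib)), function(i) {
    al <- Biostrings::pairwiseAlignment(
      q, Biostrings::AAString(lib$sequence[i]), type = "local",
      substitutionMatrix = "BLOSUM62",
      gapOpening = backend$gap_opening, gapExtension = backend$gap_extension)
    S <- Biostrings::score(al)
    if (S <= 0) return(NULL)
    data.frame(
      template_id = lib$id[i],
      score = S,
      evalue = backend$K * m * n_total * exp(-backend$lambda * S),
      q_start = Biostrings::start(Biostrings::pattern(al)),
      t_start = Biostrings::start(Biostrings::subject(al)),
      q_aln = as.character(Biostrings::alignedPattern(al)),
      t_aln = as.character(Biostrings::alignedSubject(al)),
      stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(template_id = character(0), score = numeric(0),
                      evalue = numeric(0), q_start = integer(0),
                      t_start = integer(0), q_aln = character(0),
                      t_aln = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' @export
backend_search.psiblast_backend <- function(backend, query, lib) {
  stopifnot(inherits(lib, "domain_library"))
  if (Sys.which(backend$exe) == "" || Sys.which(backend$makeblastdb_exe) == "")
    stop_domex("psiblast backend requires '%s' and '%s' on PATH",
               backend$exe, backend$makeblastdb_exe)
  work <- tempfile("domex_psiblast_")
  dir.create(work)
  on.exit(unlink(work, recursive = TRUE), add = TRUE)

  qfa <- file.path(work, "query.fasta")
  writeLines(c(">query", query), qfa)
  libfa <- file.path(work, "library.fasta")
  seqs <- Biostrings::AAStringSet(lib$sequence)
  names(seqs) <- lib$id
  Biostrings::writeXStringSet(seqs, libfa)
  run <- function(args) {
    out <- suppressWarnings(system2(args[1], args[-1], stdout = TRUE,
                                    stderr = TRUE))
    status <- attr(out, "status") %||% 0L
    if (status != 0L)
      stop_domex("backend command failed (%s): %s", args[1],
                 paste(out, collapse = " | "))
    out
  }
  run(c(backend$makeblastdb_exe, "-in", libfa, "-dbtype", "prot",
        "-parse_seqids"))

  fmt <- "6 sseqid evalue score qstart sstart qseq sseq"
  tab <- file.path(work, "hits.tsv")
  if (backend$iterations > 1L) {
    bg <- backend$background_fasta %||% libfa
    if (!identical(bg, libfa))
      run(c(backend$makeblastdb_exe, "-in", bg, "-dbtype", "prot"))
    pssm <- file.path(work, "query.pssm")
    run(c(backend$exe, "-query", qfa, "-db", bg,
          "-num_iterations", backend$iterations,
          "-inclusion_ethresh", format(backend$inclusion_evalue),
          "-out_pssm", pssm, "-save_pssm_after_last_round",
          "-outfmt", "6", "-evalue", "10"))
    run(c(backend$exe, "-in_pssm", pssm, "-db", libfa, "-evalue", "1e6",
          "-outfmt", shQuote(fmt), "-out", tab))
  } else {
    run(c(backend$exe, "-query", qfa, "-db", libfa, "-evalue", "1e6",
          "-outfmt", shQuote(fmt), "-out", tab))
  }
  lines <- readLines(tab)
  lines <- lines[grepl("\t", lines, fixed = TRUE)]
  if (!length(lines))
    return(backend_search(builtin_backend(), "A",
                          domain_library("x", "A", "STRUCTURE"))[0, ])
  parts <- strsplit(lines, "\t", fixed = TRUE)
  parts <- parts[vapply(parts, length, integer(1)) == 7L]
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- c("template_id", "evalue", "score", "q_start", "t_start",
                 "q_aln", "t_aln")
  df$evalue <- as.numeric(df$evalue)
  df$evalue[df$evalue <= 0] <- 1e-180  # BLAST prints 0.0 below ~1e-180
  df$score <- as.numeric(df$score)
  df$q_start <- as.integer(df$q_start)
  df$t_start <- as.integer(df$t_start)
  # keep the best alignment per template
  df <- df[order(df$evalue, -df$score, df$template_id), ]
  df[!duplicated(df$template_id),
     c("template_id", "score", "evalue", "q_start", "t_start", "q_aln",
       "t_aln")]
}

# Identity/coverage statistics of an alignment, global and split at the
# candidate junction. Columns where both sequences have a residue are
# "aligned"; identity is counted over aligned columns only. A column that is
# a gap in the query is attributed to the part holding the nearest aligned
# query residue on its left (leading gaps go to the first part).
alignment_stats <- function(q_aln, t_aln, q_start, junction, len_p, len_q) {
  qc <- seq_chars(q_aln)
  tc <- seq_chars(t_aln)
  if (length(qc) != length(tc))
    stop_domex("aligned strings differ in length")
  aligned <- qc != "-" & tc != "-"
  ident <- aligned & qc == tc
  # query residue index carried by each column (last seen for gap columns)
  col_q <- q_start - 1L + cumsum(qc != "-")
  in_p <- col_q <= junction
  part <- function(sel, len_k) {
    ncols <- sum(aligned & sel)
    if (ncols == 0L) return(c(s = 0, c = 0))
    c(s = sum(ident & sel) / ncols, c = ncols / len_k)
  }
  list(
    s = if (sum(aligned)) sum(ident) / sum(aligned) else 0,
    n_aligned = sum(aligned),
    n_ident = sum(ident),
    p = part(in_p, len_p),
    q = part(!in_p, len_q))
}

#' Split a template hit at the candidate junction
#'
#' Partitions the alignment columns of a hit at the junction between the two
#' assembled segments and returns per-segment identity and coverage: for
#' segment \eqn{k}, \eqn{s_k} is the fraction of identical residues among the
#' aligned columns falling in that part and \eqn{c_k} the number of aligned
#' query residues in the part divided by the segment length. A part with no
#' aligned columns yields \eqn{(0, 0)}. These \eqn{(s_k, c_k)} vectors feed
#' the symmetry index.
#'
#' @param hit a \code{template_hit} from [search_templates()] (or any list
#'   with \code{q_aln}, \code{t_aln}, \code{q_start}).
#' @param junction position of the last residue of the first segment within
#'   the concatenated candidate.
#' @param len_p,len_q lengths of the two segments.
#' @return A list with elements \code{p} and \code{q}, each a named numeric
#'   vector \code{c(s =, c =)}.
#' @export
split_hit_at_junction <- function(hit, junction, len_p, len_q) {
  st <- alignment_stats(hit$q_aln, hit$t_aln, hit$q_start, junction,
                        len_p, len_q)
  list(p = st$p, q = st$q)
}

#' Search the domain library for templates of an assembled candidate
#'
#' Runs the backend over the library and converts raw alignments into
#' \code{template_hit} objects carrying the E-value, the global identity
#' \eqn{s} (identical residues / aligned columns), the global coverage
#' \eqn{c} (aligned residues / candidate length), the template length, and
#' the per-segment \eqn{(s_k, c_k)} statistics from
#' [split_hit_at_junction()].
#'
#' @param candidate an [assemble_candidate()] object.
#' @param lib a [domain_library()].
#' @param backend a \code{search_backend}; default [builtin_backend()].
#' @param max_evalue keep hits with E-value at or below this (default 10,
#'   the E-value normalisation constant, so the normalised term stays
#'   non-negative).
#' @return A list of \code{template_hit} objects, best E-value first.
#' @export
search_templates <- function(candidate, lib, backend = builtin_backend(),
                             max_evalue = 10) {
  stopifnot(inherits(candidate, "assembled_candidate"),
            inherits(lib, "domain_library"))
  raw <- backend_search(backend, candidate$sequence, lib)
  raw <- raw[raw$evalue <= max_evalue, , drop = FALSE]
  if (!nrow(raw)) return(list())
  raw <- raw[order(raw$evalue, -raw$score, raw$template_id), , drop = FALSE]
  L_Q <- nchar(candidate$sequence)
  hits <- lapply(seq_len(nrow(raw)), function(i) {
    r <- raw[i, ]
    k <- match(r$template_id, lib$id)
    if (is.na(k)) stop_domex("backend returned unknown template '%s'",
                             r$template_id)
    st <- alignment_stats(r$q_aln, r$t_aln, r$q_start, candidate$junction,
                          candidate$first$length, candidate$second$length)
    structure(list(
      template_id = r$template_id,
      source = lib$source[k],
      evalue = r$evalue,
      score = r$score,
      s = st$s,
      c = st$n_aligned / L_Q,
      L_T = lib$length[k],
      template_seq = lib$sequence[k],
      per_segment = list(p = st$p, q = st$q),
      q_aln = r$q_aln, t_aln = r$t_aln,
      q_start = r$q_start, t_start = r$t_start
    ), class = "template_hit")
  })
  hits
}
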