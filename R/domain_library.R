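#' Single-domain sequence library
#'
#' A domain library is the reference set of single-domain sequences that
#' assembled segment pairs are searched against. Each record carries a source
#' tag distinguishing structure-derived domain definitions (CATH/SCOP-like,
#' \code{"STRUCTURE"}) from sequence-derived ones (Pfam-like,
#' \code{"SEQUENCE"}); the tag decides whether the profile-profile alignment
#' filter applies to hits on that template.
#'
#' @param id character vector of unique record identifiers.
#' @param sequence character vector of amino-acid sequences (20 canonical
#'   letters plus \code{X}).
#' @param source character vector, each element \code{"STRUCTURE"} or
#'   \code{"SEQUENCE"}.
#' @param identity_cutoff redundancy cutoff recorded on the library once
#'   [dedup_library()] has been applied, or \code{NA} for an unfiltered
#'   library.
#'
#' @return An object of class \code{domain_library}: a data frame with columns
#'   \code{id}, \code{sequence}, \code{source}, \code{length}.
#' @seealso [read_domain_library()], [dedup_library()]
#' @export
domain_library <- function(id, sequence, source, identity_cutoff = NA_real_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  source <- as.character(source)
  if (length(id) != length(sequence) || length(id) != length(source))
    stop_domex("id, sequence and source must have equal length")
  if (anyDuplicated(id))
    stop_domex("duplicated record id: %s", id[duplicated(id)][1])
  if (!all(source %in% c("STRUCTURE", "SEQUENCE")))
    stop_domex("source must be STRUCTURE or SEQUENCE")
  if (any(!nzchar(sequence)))
    stop_domex("empty sequence for record %s", id[!nzchar(sequence)][1])
  bad <- !vapply(sequence, valid_alphabet, logical(1))
  if (any(bad))
    stop_domex("record %s contains non-amino-acid characters", id[bad][1])
  lib <- data.frame(id = id, sequence = sequence, source = source,
                    length = nchar(sequence), stringsAsFactors = FALSE)
  structure(lib, class = c("domain_library", "data.frame"),
            identity_cutoff = identity_cutoff)
}

#' @export
print.domain_library <- function(x, ...) {
  cat(sprintf("Domain library: %d records (%d STRUCTURE, %d SEQUENCE)\n",
              nrow(x), sum(x$source == "STRUCTURE"),
              sum(x$source == "SEQUENCE")))
  cutoff <- attr(x, "identity_cutoff")
  if (!is.na(cutoff))
    cat(sprintf("  redundancy-filtered at identity >= %.2f\n", cutoff))
  cat(sprintf("  lengths: %d-%d residues\n", min(x$length), max(x$length)))
  invisible(x)
}

#' Load a domain library from FASTA
#'
#' Reads a FASTA file of single-domain sequences and assigns each record a
#' source tag by matching its identifier against a set of regular-expression
#' rules (first match wins). Records containing characters outside the
#' amino-acid alphabet (20 canonical letters plus \code{X}) are dropped with a
#' warning. The returned library is unfiltered; apply [dedup_library()] to
#' impose the redundancy cutoff.
#'
#' @param fasta_path path to a FASTA file.
#' @param source_rules named character vector mapping regular expressions on
#'   record ids to \code{"STRUCTURE"}/\code{"SEQUENCE"}, e.g.
#'   \code{c("^cath\\\\|" = "STRUCTURE", "^pfam\\\\|" = "SEQUENCE")}. Every
#'   record must match at least one rule.
#'
#' @return A [domain_library()].
#' @export
read_domain_library <- function(fasta_path,
                                source_rules = c("^(cath|scop)[|_]" = "STRUCTURE",
                                                 "^pfam[|_]" = "SEQUENCE")) {
  if (!file.exists(fasta_path))
    stop_domex("FASTA file not found: %s", fasta_path)
  if (is.null(names(source_rules)) || !all(nzchar(names(source_rules))))
    stop_domex("source_rules must be a named character vector (pattern -> source)")
  seqs <- Biostrings::readAAStringSet(fasta_path)
  if (length(seqs) == 0L)
    stop_domex("FASTA file %s contains no records", fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  sequences <- toupper(as.character(seqs))

  keep <- vapply(sequences, valid_alphabet, logical(1), USE.NAMES = FALSE)
  if (any(!keep)) {
    warning(sprintf("dropping %d record(s) with non-amino-acid characters: %s",
                    sum(!keep), paste(ids[!keep], collapse = ", ")),
            call. = FALSE)
    ids <- ids[keep]
    sequences <- sequences[keep]
  }
  if (length(ids) == 0L)
    stop_domex("no valid records left in %s", fasta_path)

  source <- rep(NA_character_, length(ids))
  for (pat in names(source_rules)) {
    hit <- is.na(source) & grepl(pat, ids, ignore.case = TRUE)
    source[hit] <- source_rules[[pat]]
  }
  if (anyNA(source))
    stop_domex("no source rule matches record '%s'", ids[is.na(source)][1])
  domain_library(ids, sequences, source)
}

#' Pairwise global sequence identity
#'
#' Identity between two sequences, defined as the number of identical aligned
#' residues in a global (Needleman-Wunsch, BLOSUM62, affine-gap) alignment
#' divided by the length of the shorter sequence. This is the definition used
#' by the redundancy filter.
#'
#' @param a,b amino-acid strings.
#' @return identity fraction in \eqn{[0, 1]}.
#' @export
sequence_identity <- function(a, b) {
  if (!is_aa_string(a) || !is_aa_string(b))
    stop_domex("sequence_identity expects two non-empty sequence strings")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  Biostrings::nmatch(al) / min(nchar(a), nchar(b))
}

#' Remove redundant library records
#'
#' Greedy longest-first clustering in the style of CD-HIT: records are visited
#' in order of decreasing length (ties broken by id), and a record is
#' discarded exactly when its global-alignment identity (see
#' [sequence_identity()]) to an already-retained record reaches the cutoff.
#' The operation is idempotent and never alters retained sequences.
#'
#' @param lib a [domain_library()].
#' @param cutoff identity fraction in \eqn{(0, 1]}; records at or above this
#'   identity to a retained record are removed. Default 0.90.
#'
#' @return The filtered [domain_library()] with \code{identity_cutoff} set.
#' @export
dedup_library <- function(lib, cutoff = 0.90) {
  stopifnot(inherits(lib, "domain_library"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff > 1)
    stop_domex("cutoff must be a fraction in (0, 1]")
  if (nrow(lib) <= 1L) {
    attr(lib, "identity_cutoff") <- cutoff
    return(lib)
  }
  ord <- order(-lib$length, lib$id)
  retained <- integer(0)
  for (i in ord) {
    redundant <- FALSE
    for (j in retained) {
      if (sequence_identity(lib$sequence[i], lib$sequence[j]) >= cutoff) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) retained <- c(retained, i)
  }
  out <- lib[sort(retained), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("domain_library", "data.frame"),
            identity_cutoff = cutoff)
}

#' Persist a domain library
#'
#' Writes the library as \code{library.fasta} plus a \code{manifest.tsv}
#' sidecar (columns \code{id}, \code{source}, \code{length}) in \code{dir}.
#'
#' @param lib a [domain_library()].
#' @param dir output directory, created if needed.
#' @return \code{dir}, invisibly.
#' @export
write_domain_library <- function(lib, dir) {
  stopifnot(inherits(lib, "domain_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::AAStringSet(lib$sequence)
  names(seqs) <- lib$id
  Biostrings::writeXStringSet(seqs, file.path(dir, "library.fasta"))
  utils::write.table(
    lib[, c("id", "source", "length")],
    file.path(dir, "manifest.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load a persisted domain library
#'
#' Counterpart of [write_domain_library()]: reads \code{library.fasta} and
#' \code{manifest.tsv} from \code{dir}.
#'
#' @param dir directory written by [write_domain_library()].
#' @return A [domain_library()].
#' @export
load_domain_library <- function(dir) {
  fasta <- file.path(dir, "library.fasta")
  manifest <- file.path(dir, "manifest.tsv")
  if (!file.exists(fasta) || !file.exists(manifest))
    stop_domex("%s does not contain library.fasta + manifest.tsv", dir)
  man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  seqs <- Biostrings::readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  src <- man$source[match(ids, man$id)]
  if (anyNA(src))
    stop_domex("manifest.tsv is missing record '%s'", ids[is.na(src)][1])
  domain_library(ids, as.character(seqs), src)
}
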