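#' Specification for a synthetic benchmark
#'
#' The generator emulates the construction of the training benchmark:
#' multi-segment chains in which two non-adjacent segments jointly match a
#' single-domain library template (positive chains), chains whose segment
#' pairs have no joint template (negative chains), and random decoy library
#' records length-matched to candidate assemblies so the length-error filter
#' is exercised nontrivially. Templates for positive chains are the
#' concatenation of the two segments with independent point substitutions at
#' \code{mutation_rate}; a \code{reversed_fraction} of positives is built in
#' swapped (C- to N-terminal) segment order, emulating segment-swapped
#' domains.
#'
#' @param seed RNG seed; the full fixture set is a deterministic function of
#'   the spec.
#' @param n_chains number of query chains.
#' @param segments_per_chain segments per chain (>= 3).
#' @param segment_length length-2 integer range of segment lengths.
#' @param mutation_rate per-position substitution probability applied to
#'   positive templates.
#' @param fraction_discontinuous fraction of chains carrying one
#'   discontinuous domain.
#' @param library_decoys number of random decoy records.
#' @param reversed_fraction fraction of positive templates built in swapped
#'   segment order.
#' @param template_source source tag for positive templates
#'   (\code{"STRUCTURE"} or \code{"SEQUENCE"}).
#' @param indel_rate optional per-position indel probability on templates.
#' @return An object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(seed = 1L, n_chains = 20L, segments_per_chain = 4L,
                         segment_length = c(60L, 120L), mutation_rate = 0.1,
                         fraction_discontinuous = 0.5, library_decoys = 20L,
                         reversed_fraction = 0, template_source = "STRUCTURE",
                         indel_rate = 0) {
  stopifnot(n_chains >= 1, segments_per_chain >= 3,
            length(segment_length) == 2L, segment_length[1] >= 1,
            segment_length[2] >= segment_length[1],
            mutation_rate >= 0, mutation_rate <= 1,
            fraction_discontinuous >= 0, fraction_discontinuous <= 1,
            library_decoys >= 0, reversed_fraction >= 0,
            reversed_fraction <= 1, indel_rate >= 0, indel_rate < 1,
            template_source %in% c("STRUCTURE", "SEQUENCE"))
  structure(list(seed = as.integer(seed), n_chains = as.integer(n_chains),
                 segments_per_chain = as.integer(segments_per_chain),
                 segment_length = as.integer(segment_length),
                 mutation_rate = mutation_rate,
                 fraction_discontinuous = fraction_discontinuous,
                 library_decoys = as.integer(library_decoys),
                 reversed_fraction = reversed_fraction,
                 template_source = template_source,
                 indel_rate = indel_rate),
            class = "fixture_spec")
}

random_aa <- function(n) {
  paste(sample(names(AA_BACKGROUND), n, replace = TRUE,
               prob = AA_BACKGROUND), collapse = "")
}

# independent point substitutions (always to a different residue), plus
# optional indels
mutate_sequence <- function(seq, rate, indel_rate = 0) {
  chars <- seq_chars(seq)
  hit <- stats::runif(length(chars)) < rate
  for (i in which(hit)) {
    alt <- setdiff(names(AA_BACKGROUND), chars[i])
    chars[i] <- sample(alt, 1L, prob = AA_BACKGROUND[alt])
  }
  if (indel_rate > 0) {
    u <- stats::runif(length(chars))
    out <- character(0)
    for (i in seq_along(chars)) {
      if (u[i] < indel_rate / 2) next                       # deletion
      out <- c(out, chars[i])
      if (u[i] > 1 - indel_rate / 2) out <- c(out, random_aa(1L))  # insertion
    }
    chars <- out
  }
  paste(chars, collapse = "")
}

#' Generate a deterministic synthetic benchmark
#'
#' Builds the full set of inputs needed by every other module: a domain
#' library (positive templates plus decoys), query chains, predicted
#' boundaries, domain annotations and ground-truth labels. With a fixed
#' [fixture_spec()] the output is byte-identical across runs.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory; when given, writes
#'   \code{queries.fasta}, \code{boundaries.tsv}, \code{annotations.tsv},
#'   \code{truth.tsv} and the library (\code{library.fasta},
#'   \code{manifest.tsv}).
#' @return A list with \code{library} (a [domain_library()]),
#'   \code{queries} (named character vector), \code{boundaries} (data
#'   frame), \code{annotations} (data frame with CATH-style range strings),
#'   \code{truth} (data frame: chain, segment pair, label, template,
#'   reversed), and \code{chains} (the per-chain structures consumed by
#'   [generate_samples()]).
#' @export
generate_fixtures <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    n_pos <- round(spec$n_chains * spec$fraction_discontinuous)
    is_pos <- seq_len(spec$n_chains) <= n_pos
    n_rev <- round(n_pos * spec$reversed_fraction)

    queries <- character(0)
    boundaries <- list()
    annotations <- list()
    truth <- list()
    chains <- list()
    lib_id <- character(0); lib_seq <- character(0); lib_src <- character(0)

    src_prefix <- c(STRUCTURE = "cath", SEQUENCE = "pfam")

    for (ci in seq_len(spec$n_chains)) {
      chain_id <- sprintf("chain%03d", ci)
      m <- spec$segments_per_chain
      lens <- sample(seq.int(spec$segment_length[1], spec$segment_length[2]),
                     m, replace = TRUE)
      seg_seqs <- vapply(lens, random_aa, character(1))
      sequence <- paste(seg_seqs, collapse = "")
      ends <- cumsum(lens)
      starts <- c(1L, utils::head(ends, -1L) + 1L)
      queries[chain_id] <- sequence
      if (m > 1L)
        boundaries[[chain_id]] <- data.frame(
          chain_id = chain_id, boundary = utils::head(ends, -1L),
          stringsAsFactors = FALSE)

      if (is_pos[ci]) {
        # pick a non-adjacent segment pair for the discontinuous domain
        pairs <- which(outer(seq_len(m), seq_len(m),
                             function(i, j) j - i >= 2), arr.ind = TRUE)
        pick <- pairs[sample(nrow(pairs), 1L), ]
        i <- pick[1]; j <- pick[2]
        reversed <- ci <= n_rev
        tmpl_raw <- if (reversed) paste0(seg_seqs[j], seg_seqs[i])
                    else paste0(seg_seqs[i], seg_seqs[j])
        tmpl <- mutate_sequence(tmpl_raw, spec$mutation_rate,
                                spec$indel_rate)
        tid <- sprintf("%s|tmpl_%s", src_prefix[[spec$template_source]],
                       chain_id)
        lib_id <- c(lib_id, tid)
        lib_seq <- c(lib_seq, tmpl)
        lib_src <- c(lib_src, spec$template_source)

        doms <- list(lapply(c(i, j), function(k) c(starts[k], ends[k])))
        for (k in setdiff(seq_len(m), c(i, j)))
          doms[[length(doms) + 1L]] <- list(c(starts[k], ends[k]))
        truth[[length(truth) + 1L]] <- data.frame(
          chain_id = chain_id, first_index = i, second_index = j,
          label = "POSITIVE", template_id = tid, reversed = reversed,
          stringsAsFactors = FALSE)
      } else {
        doms <- lapply(seq_len(m), function(k) list(c(starts[k], ends[k])))
      }
      chains[[chain_id]] <- list(sequence = sequence, domains = doms)
      annotations[[chain_id]] <- data.frame(
        chain_id = chain_id,
        domain_id = sprintf("%s_d%d", chain_id, seq_along(doms)),
        ranges = vapply(doms, format_ranges, character(1)),
        stringsAsFactors = FALSE)
    }

    # decoys, length-matched to two-segment assemblies
    if (spec$library_decoys > 0L) {
      for (k in seq_len(spec$library_decoys)) {
        dl <- sum(sample(seq.int(spec$segment_length[1],
                                 spec$segment_length[2]), 2L,
                         replace = TRUE))
        src <- if (k %% 2L == 0L) "SEQUENCE" else "STRUCTURE"
        lib_id <- c(lib_id, sprintf("%s|decoy_%03d", src_prefix[[src]], k))
        lib_seq <- c(lib_seq, random_aa(dl))
        lib_src <- c(lib_src, src)
      }
    }

    out <- list(
      library = domain_library(lib_id, lib_seq, lib_src),
      queries = queries,
      boundaries = do.call(rbind, unname(boundaries)),
      annotations = do.call(rbind, unname(annotations)),
      truth = if (length(truth)) do.call(rbind, truth) else
        data.frame(chain_id = character(0), first_index = integer(0),
                   second_index = integer(0), label = character(0),
                   template_id = character(0), reversed = logical(0)),
      chains = chains)

    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      qs <- Biostrings::AAStringSet(out$queries)
      Biostrings::writeXStringSet(qs, file.path(dir, "queries.fasta"))
      write_boundaries(out$boundaries, file.path(dir, "boundaries.tsv"))
      utils::write.table(out$annotations, file.path(dir, "annotations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(out$truth, file.path(dir, "truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_domain_library(out$library, dir)
    }
    out
  })
}
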