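#' Pipeline configuration
#'
#' Collects everything a prediction run needs: the acceptance thresholds,
#' candidate enumeration settings, the search backend and its E-value
#' cutoff, and the PPA scoring parameters.
#'
#' @param thresholds a [domex_thresholds()] object.
#' @param min_len minimum segment length for candidate enumeration.
#' @param allow_reversed also try swapped-order (C- to N-terminal)
#'   assemblies; off by default, roughly doubling speed at the cost of
#'   missing segment-swapped domains.
#' @param backend a \code{search_backend}.
#' @param max_evalue search-stage E-value cutoff.
#' @param ppa list of [ppa_score()] parameters (\code{w_ss},
#'   \code{gap_open}, \code{gap_extend}) plus optional \code{query_ss}.
#' @return An object of class \code{domex_config}.
#' @export
domex_config <- function(thresholds = domex_thresholds(), min_len = 40L,
                         allow_reversed = FALSE,
                         backend = builtin_backend(), max_evalue = 10,
                         ppa = list(w_ss = 1, gap_open = 7,
                                    gap_extend = 0.5)) {
  stopifnot(inherits(thresholds, "domex_thresholds"),
            inherits(backend, "search_backend"))
  structure(list(thresholds = thresholds, min_len = as.integer(min_len),
                 allow_reversed = allow_reversed, backend = backend,
                 max_evalue = max_evalue, ppa = ppa),
            class = "domex_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the [domex_config()] arguments; threshold fields
#' (\code{b}, \code{e_max}, \code{t_ppa}, \code{ppa_applies_below_b},
#' \code{E0}, \code{strict}) sit under \code{thresholds}, backend choice
#' under \code{backend: \{name: builtin|psiblast, ...\}}.
#'
#' @param path YAML file.
#' @return A [domex_config()].
#' @export
read_domex_config <- function(path) {
  if (!file.exists(path)) stop_domex("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  th <- do.call(domex_thresholds, y$thresholds %||% list())
  bk <- y$backend %||% list(name = "builtin")
  backend <- switch(bk$name %||% "builtin",
    builtin = do.call(builtin_backend, bk[setdiff(names(bk), "name")]),
    psiblast = do.call(psiblast_backend, bk[setdiff(names(bk), "name")]),
    stop_domex("unknown backend '%s'", bk$name))
  domex_config(
    thresholds = th,
    min_len = y$min_len %||% 40L,
    allow_reversed = isTRUE(y$allow_reversed),
    backend = backend,
    max_evalue = y$max_evalue %||% 10,
    ppa = utils::modifyList(list(w_ss = 1, gap_open = 7, gap_extend = 0.5),
                            y$ppa %||% list()))
}

#' Domain partition of a chain
#'
#' Constructor and validator for a predicted (or reference) domain partition:
#' a list of domains, each one or two 1-based inclusive residue ranges, that
#' together cover every residue of the chain exactly once. Discontinuous
#' domains hold exactly two non-adjacent ranges.
#'
#' @param chain_id chain identifier.
#' @param chain_length residue count.
#' @param domains list; each element a list with \code{ranges} (list of
#'   \code{c(start, end)}), optional \code{discontinuous},
#'   \code{template_id}, \code{scores}.
#' @return An object of class \code{domain_prediction}.
#' @export
domain_prediction <- function(chain_id, chain_length, domains) {
  covered <- integer(0)
  domains <- lapply(domains, function(d) {
    d$ranges <- lapply(d$ranges, function(r) as.integer(r[1:2]))
    d$discontinuous <- isTRUE(d$discontinuous) || length(d$ranges) > 1L
    d
  })
  for (d in domains) {
    if (d$discontinuous && length(d$ranges) != 2L)
      stop_domex("a discontinuous domain must have exactly 2 ranges")
    for (r in d$ranges) covered <- c(covered, seq.int(r[1], r[2]))
  }
  if (anyDuplicated(covered) || !setequal(covered, seq_len(chain_length)))
    stop_domex("domains of %s do not partition residues 1..%d",
               chain_id, chain_length)
  structure(list(chain_id = chain_id, chain_length = as.integer(chain_length),
                 domains = domains),
            class = "domain_prediction")
}

#' @export
print.domain_prediction <- function(x, ...) {
  cat(sprintf("Chain %s (%d residues): %d domain(s)\n", x$chain_id,
              x$chain_length, length(x$domains)))
  for (k in seq_along(x$domains)) {
    d <- x$domains[[k]]
    cat(sprintf("  %d: %s%s%s\n", k, format_ranges(d$ranges),
                if (d$discontinuous) "  [discontinuous]" else "",
                if (!is.null(d$template_id) && !is.na(d$template_id %||% NA))
                  paste0("  template=", d$template_id) else ""))
  }
  invisible(x)
}

#' Resolve conflicts among accepted candidates
#'
#' Accepted assemblies may share a segment; each segment can belong to only
#' one discontinuous domain. Candidates are ranked by ascending PPA-score
#' (missing scores rank at 0), then descending TS-score, then input order,
#' and retained greedily while their segments are unused.
#'
#' @param decisions list of accepted \code{domex_decision}s.
#' @return The retained sub-list, in ranking order.
#' @export
resolve_conflicts <- function(decisions) {
  if (!length(decisions)) return(decisions)
  stopifnot(all(vapply(decisions, function(d) isTRUE(d$accepted), logical(1))))
  ppa <- vapply(decisions, function(d) {
    p <- d$scores$ppa_score
    if (is.null(p) || is.na(p)) 0 else p
  }, numeric(1))
  ts <- vapply(decisions, function(d) d$scores$ts_score, numeric(1))
  ord <- order(ppa, -ts, seq_along(decisions))
  used <- integer(0)
  keep <- list()
  for (i in ord) {
    segs <- c(decisions[[i]]$candidate$first$index,
              decisions[[i]]$candidate$second$index)
    if (any(segs %in% used)) next
    used <- c(used, segs)
    keep[[length(keep) + 1L]] <- decisions[[i]]
  }
  keep
}

#' Predict the domain partition of one chain
#'
#' Runs the full detection procedure: derive segments from the predicted
#' boundaries, enumerate non-adjacent candidate assemblies, search the
#' domain library for each, apply the TS-score / symmetry-index /
#' length-error / PPA decision chain, resolve segment conflicts keeping the
#' best-scoring assemblies, and report the resulting partition (unassembled
#' segments become continuous domains).
#'
#' @param sequence amino-acid string of the query chain.
#' @param boundaries integer vector of predicted boundary positions (break
#'   after residue).
#' @param lib a [domain_library()].
#' @param config a [domex_config()].
#' @param chain_id identifier used in reports.
#' @return A [domain_prediction()] with attributes \code{audit} (per
#'   candidate x template score table) and \code{decisions}.
#' @export
predict_domains <- function(sequence, boundaries, lib,
                            config = domex_config(), chain_id = "query") {
  stopifnot(inherits(config, "domex_config"))
  segs <- segments_from_boundaries(sequence, boundaries)
  candidates <- enumerate_candidates(segs, min_len = config$min_len,
                                     allow_reversed = config$allow_reversed)
  scorer <- do.call(make_ppa_scorer, config$ppa)
  decisions <- lapply(candidates, function(cand) {
    hits <- search_templates(cand, lib, backend = config$backend,
                             max_evalue = config$max_evalue)
    decide(cand, hits, th = config$thresholds, ppa_scorer = scorer)
  })
  audit_rows <- lapply(seq_along(decisions), function(i) {
    a <- decisions[[i]]$audit
    if (is.null(a) || !nrow(a)) return(NULL)
    cbind(chain_id = chain_id, candidate = decisions[[i]]$candidate$id, a,
          stringsAsFactors = FALSE)
  })
  audit <- do.call(rbind, audit_rows[!vapply(audit_rows, is.null, logical(1))])

  accepted <- decisions[vapply(decisions, `[[`, logical(1), "accepted")]
  winners <- resolve_conflicts(accepted)

  used <- integer(0)
  domains <- list()
  for (w in winners) {
    cand <- w$candidate
    segpair <- sort(c(cand$first$index, cand$second$index))
    used <- c(used, segpair)
    ranges <- lapply(segpair, function(k) c(segs$start[k], segs$end[k]))
    domains[[length(domains) + 1L]] <- list(
      ranges = ranges, discontinuous = TRUE,
      template_id = w$winning_hit$template_id,
      scores = w$scores, reversed = cand$reversed)
  }
  for (k in setdiff(segs$index, used))
    domains[[length(domains) + 1L]] <- list(
      ranges = list(c(segs$start[k], segs$end[k])), discontinuous = FALSE)

  first_res <- vapply(domains, function(d) min(vapply(d$ranges, `[`,
                                                      integer(1), 1L)),
                      integer(1))
  pred <- domain_prediction(chain_id, nchar(sequence),
                            domains[order(first_res)])
  attr(pred, "audit") <- audit
  attr(pred, "decisions") <- decisions
  pred
}

#' Run predictions for every chain of a FASTA + boundary TSV
#'
#' File-level driver: reads the query FASTA and boundary TSV (see
#' [read_boundaries()]), checks chain ids, runs [predict_domains()] per
#' chain, and optionally writes a prediction TSV, a JSON mirror and the
#' per-candidate audit TSV to \code{out_dir}.
#'
#' @param query_fasta FASTA of query chains.
#' @param boundary_tsv TSV with columns \code{chain_id}, \code{boundary}.
#' @param lib a [domain_library()].
#' @param config a [domex_config()].
#' @param out_dir optional output directory.
#' @return Named list of [domain_prediction()]s, invisibly when writing.
#' @export
run_domex <- function(query_fasta, boundary_tsv, lib,
                      config = domex_config(), out_dir = NULL) {
  seqs <- Biostrings::readAAStringSet(query_fasta)
  if (!length(seqs)) stop_domex("no query sequences in %s", query_fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  bnd <- read_boundaries(boundary_tsv)
  unknown <- setdiff(unique(bnd$chain_id), ids)
  if (length(unknown))
    stop_domex("boundary chain '%s' not present in %s", unknown[1],
               query_fasta)
  preds <- lapply(seq_along(ids), function(i) {
    predict_domains(as.character(seqs[[i]]),
                    bnd$boundary[bnd$chain_id == ids[i]], lib,
                    config = config, chain_id = ids[i])
  })
  names(preds) <- ids
  if (!is.null(out_dir)) {
    write_predictions(preds, out_dir)
    return(invisible(preds))
  }
  preds
}

#' Write predictions as TSV + JSON
#'
#' Emits \code{predictions.tsv} (chain_id, domain_index, ranges,
#' discontinuous flag, template and scores), \code{predictions.json} (the
#' same, nested) and \code{audit.tsv} (every candidate x template score
#' bundle) under \code{dir}.
#'
#' @param preds named list of [domain_prediction()]s.
#' @param dir output directory, created if needed.
#' @return \code{dir}, invisibly.
#' @export
write_predictions <- function(preds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (p in preds) {
    for (k in seq_along(p$domains)) {
      d <- p$domains[[k]]
      sc <- d$scores
      rows[[length(rows) + 1L]] <- data.frame(
        chain_id = p$chain_id, domain_index = k,
        ranges = format_ranges(d$ranges),
        discontinuous = d$discontinuous,
        template_id = d$template_id %||% NA_character_,
        ts_score = sc$ts_score %||% NA_real_,
        si = sc$si %||% NA_real_,
        e = sc$e %||% NA_real_,
        ppa_score = sc$ppa_score %||% NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, file.path(dir, "predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    lapply(preds, function(p) list(
      chain_id = p$chain_id, chain_length = p$chain_length,
      domains = lapply(p$domains, function(d) list(
        ranges = format_ranges(d$ranges),
        discontinuous = d$discontinuous,
        template_id = d$template_id %||% NA_character_)))),
    file.path(dir, "predictions.json"), auto_unbox = TRUE, pretty = TRUE)
  audits <- do.call(rbind, lapply(preds, function(p) attr(p, "audit")))
  if (!is.null(audits) && nrow(audits))
    utils::write.table(audits, file.path(dir, "audit.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read domain annotations
#'
#' Reads a TSV with columns \code{chain_id}, \code{domain_id},
#' \code{ranges}, where \code{ranges} is CATH-style \code{"1-156|342-393"}
#' (en-dashes and comma separators also accepted).
#'
#' @param path annotation TSV.
#' @return Data frame with columns \code{chain_id}, \code{domain_id},
#'   \code{ranges} (list column of integer pairs).
#' @export
read_domain_annotation <- function(path) {
  if (!file.exists(path)) stop_domex("annotation file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chain_id", "domain_id", "ranges")
  if (!all(need %in% names(df)))
    stop_domex("annotation TSV must have columns: %s",
               paste(need, collapse = ", "))
  df$ranges <- lapply(df$ranges, parse_ranges)
  df
}

#' Build a reference partition from annotations
#'
#' @param annotation data frame from [read_domain_annotation()] (or of the
#'   same shape).
#' @param chain_id chain to extract.
#' @param chain_length residue count of the chain.
#' @return A [domain_prediction()] acting as the reference partition.
#' @export
annotation_to_prediction <- function(annotation, chain_id, chain_length) {
  rows <- annotation[annotation$chain_id == chain_id, , drop = FALSE]
  if (!nrow(rows)) stop_domex("chain '%s' absent from annotation", chain_id)
  domains <- lapply(seq_len(nrow(rows)), function(i)
    list(ranges = rows$ranges[[i]],
         discontinuous = length(rows$ranges[[i]]) > 1L))
  domain_prediction(chain_id, chain_length, domains)
}
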