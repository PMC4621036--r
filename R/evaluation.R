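#' Construct labeled positive/negative samples from annotated chains
#'
#' For each annotated chain the domain ranges define the segments; every
#' non-adjacent segment pair whose members both reach \code{min_len}
#' becomes a sample, labeled \code{POSITIVE} when both segments belong to
#' the same annotated (discontinuous) domain and \code{NEGATIVE} otherwise.
#' Adjacent pairs are ignored (they would be continuous domains), and
#' swapped-order pairs only appear under \code{include_reversed}. Chains
#' with fewer than three segments are skipped with a warning.
#'
#' @param chains named list; each element a list with \code{sequence} (the
#'   chain) and \code{domains} (list of domains, each a list of
#'   \code{c(start, end)} ranges partitioning the chain).
#' @param min_len minimum segment length (default 40).
#' @param include_reversed also emit each pair in swapped order.
#' @return A data frame with columns \code{chain_id}, \code{first_index},
#'   \code{second_index}, \code{reversed}, \code{label}, \code{sample_id}
#'   and a list column \code{candidate} of [assemble_candidate()] objects.
#' @export
generate_samples <- function(chains, min_len = 40L,
                             include_reversed = FALSE) {
  rows <- list()
  for (chain_id in names(chains)) {
    ch <- chains[[chain_id]]
    ranges <- list()
    owner <- integer(0)
    for (d in seq_along(ch$domains)) {
      for (r in ch$domains[[d]]) {
        ranges[[length(ranges) + 1L]] <- as.integer(r[1:2])
        owner <- c(owner, d)
      }
    }
    ord <- order(vapply(ranges, `[`, integer(1), 1L))
    ranges <- ranges[ord]
    owner <- owner[ord]
    if (length(ranges) < 3L) {
      warning(sprintf("chain %s has %d segment(s); need >= 3, skipped",
                      chain_id, length(ranges)), call. = FALSE)
      next
    }
    boundaries <- vapply(ranges, `[`, integer(1), 2L)
    segs <- segments_from_boundaries(ch$sequence,
                                     boundaries[-length(boundaries)])
    cands <- enumerate_candidates(segs, min_len = min_len,
                                  allow_reversed = include_reversed)
    for (cand in cands) {
      i <- min(cand$first$index, cand$second$index)
      j <- max(cand$first$index, cand$second$index)
      rows[[length(rows) + 1L]] <- list(
        chain_id = chain_id, first_index = i, second_index = j,
        reversed = cand$reversed,
        label = if (owner[i] == owner[j]) "POSITIVE" else "NEGATIVE",
        candidate = cand)
    }
  }
  if (!length(rows))
    return(data.frame(chain_id = character(0), first_index = integer(0),
                      second_index = integer(0), reversed = logical(0),
                      label = character(0), sample_id = character(0)))
  out <- data.frame(
    chain_id = vapply(rows, `[[`, character(1), "chain_id"),
    first_index = vapply(rows, `[[`, integer(1), "first_index"),
    second_index = vapply(rows, `[[`, integer(1), "second_index"),
    reversed = vapply(rows, `[[`, logical(1), "reversed"),
    label = vapply(rows, `[[`, character(1), "label"),
    stringsAsFactors = FALSE)
  out$sample_id <- sprintf("%s:%d+%d%s", out$chain_id, out$first_index,
                           out$second_index,
                           ifelse(out$reversed, "r", ""))
  out$candidate <- I(lapply(rows, `[[`, "candidate"))
  out
}

#' Recall, precision and Matthews correlation coefficient
#'
#' Standard binary-classification metrics:
#' recall \eqn{= TP/(TP+FN)}, precision \eqn{= TP/(TP+FP)}, and
#' \eqn{MCC = (TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(FP+TN)(TN+FN)}}.
#' A metric whose denominator is zero is reported as \code{NaN} with a
#' warning rather than silently coerced to 0.
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return Named list with \code{recall}, \code{precision}, \code{mcc}.
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  # double precision: the MCC denominator overflows integer arithmetic
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("recall undefined: no positive samples", call. = FALSE)
    NaN
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("precision undefined: no predicted positives", call. = FALSE)
    NaN
  }
  denom <- (tp + fp) * (tp + fn) * (fp + tn) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else {
    warning("MCC undefined: zero marginal", call. = FALSE)
    NaN
  }
  list(recall = recall, precision = precision, mcc = mcc)
}

# exact maximum-weight one-to-one matching between the rows and columns of
# an overlap matrix, by bitmask dynamic programming over the smaller side
best_matching_weight <- function(O) {
  if (!length(O) || nrow(O) == 0L || ncol(O) == 0L) return(0)
  if (nrow(O) > ncol(O)) O <- t(O)
  n <- nrow(O); m <- ncol(O)
  if (m > 25L) stop_domex("too many domains for exact matching (%d)", m)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, mask) {
    if (i > n) return(0)
    key <- paste(i, mask)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    best <- rec(i + 1L, mask)  # row i unmatched
    for (j in seq_len(m)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0L)
        best <- max(best, O[i, j] + rec(i + 1L, bitwOr(mask, bit)))
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 0L)
}

#' Normalized domain-overlap (NDO) score
#'
#' Measures agreement between a predicted and a reference domain partition
#' of the same chain: residue overlaps are computed between every pair of
#' predicted and reference domains, the one-to-one domain matching
#' maximizing the summed overlap is found exactly, and the score is that
#' matched overlap divided by the chain length. Identical partitions score
#' 1; the score is symmetric in its arguments for full partitions.
#'
#' @param predicted,reference [domain_prediction()] objects on the same
#'   chain length.
#' @return score in \eqn{[0, 1]}.
#' @export
ndo_score <- function(predicted, reference) {
  stopifnot(inherits(predicted, "domain_prediction"),
            inherits(reference, "domain_prediction"))
  if (predicted$chain_length != reference$chain_length)
    stop_domex("chain lengths differ (%d vs %d)", predicted$chain_length,
               reference$chain_length)
  members <- function(d) unlist(lapply(d$ranges, function(r)
    seq.int(r[1], r[2])))
  pm <- lapply(predicted$domains, members)
  rm_ <- lapply(reference$domains, members)
  O <- matrix(0, length(pm), length(rm_))
  for (i in seq_along(pm))
    for (j in seq_along(rm_))
      O[i, j] <- length(intersect(pm[[i]], rm_[[j]]))
  best_matching_weight(O) / predicted$chain_length
}

#' Score labeled samples against a library
#'
#' Runs the search once per sample and records, for every template hit, the
#' TS-score, symmetry index, length error, template source and (optionally)
#' the PPA-score. Calibration sweeps ([calibrate_est()], [calibrate_ecv()],
#' [calibrate_pct()]) reuse this cache instead of re-searching.
#'
#' @param samples data frame from [generate_samples()].
#' @param lib a [domain_library()].
#' @param config a [domex_config()].
#' @param with_ppa compute the PPA-score for each hit (needed by
#'   [calibrate_pct()]).
#' @return A data frame with one row per sample-hit pair (samples without
#'   hits contribute one all-\code{NA} row), columns \code{sample_id},
#'   \code{label}, \code{template_id}, \code{source}, \code{ts}, \code{si},
#'   \code{e}, \code{ppa}.
#' @export
score_samples <- function(samples, lib, config = domex_config(),
                          with_ppa = FALSE) {
  scorer <- if (with_ppa) do.call(make_ppa_scorer, config$ppa) else NULL
  th <- config$thresholds
  rows <- list()
  for (i in seq_len(nrow(samples))) {
    cand <- samples$candidate[[i]]
    hits <- search_templates(cand, lib, backend = config$backend,
                             max_evalue = config$max_evalue)
    if (!length(hits)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = samples$sample_id[i], label = samples$label[i],
        template_id = NA_character_, source = NA_character_,
        ts = NA_real_, si = NA_real_, e = NA_real_, ppa = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    for (hit in hits) {
      sc <- score_hit(hit, nchar(cand$sequence), th)
      ppa <- if (with_ppa) scorer(cand, hit) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = samples$sample_id[i], label = samples$label[i],
        template_id = hit$template_id, source = hit$source,
        ts = sc$ts_score, si = sc$si, e = sc$e, ppa = ppa,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# counts of a cutoff rule applied to a scored-hit cache: a sample is
# predicted positive when any of its hits satisfies `pass`
sweep_counts <- function(scored, pass) {
  ok <- !is.na(scored$ts) & pass
  ok[is.na(ok)] <- FALSE
  pos_pred <- unique(scored$sample_id[ok])
  ids <- unique(scored$sample_id)
  labels <- scored$label[match(ids, scored$sample_id)]
  predicted <- ids %in% pos_pred
  c(tp = sum(predicted & labels == "POSITIVE"),
    fp = sum(predicted & labels == "NEGATIVE"),
    tn = sum(!predicted & labels == "NEGATIVE"),
    fn = sum(!predicted & labels == "POSITIVE"))
}

#' Exhaustive grid search of the TS-score and SI cutoffs
#'
#' Sweeps independent cutoffs \eqn{T_{TS}} and \eqn{T_{SI}} over a grid
#' (defaults: \eqn{[0.1, 1]} and \eqn{[0.05, 0.5]} in steps of 0.05, a
#' 19 x 10 grid), classifying each sample positive when any hit has
#' \code{e < e_max}, \code{ts >= T_TS} and \code{si <= T_SI}, and reports
#' recall, precision and MCC for every cell.
#'
#' @param scored data frame from [score_samples()].
#' @param t_ts_grid,t_si_grid cutoff grids.
#' @param e_max length-error cutoff applied throughout.
#' @return Data frame with one row per grid cell (\code{t_ts}, \code{t_si},
#'   counts and metrics), with the best cell (highest MCC; ties to the
#'   most permissive, i.e. lowest, cutoffs) in attribute \code{best}.
#' @export
calibrate_est <- function(scored, t_ts_grid = seq(0.1, 1, by = 0.05),
                          t_si_grid = seq(0.05, 0.5, by = 0.05),
                          e_max = 0.2) {
  grid <- expand.grid(t_ts = t_ts_grid, t_si = t_si_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    cnt <- sweep_counts(scored,
                        scored$e < e_max &
                          scored$ts >= grid$t_ts[k] - 1e-12 &
                          scored$si <= grid$t_si[k] + 1e-12)
    met <- suppressWarnings(classification_metrics(cnt["tp"], cnt["fp"],
                                                   cnt["tn"], cnt["fn"]))
    data.frame(t_ts = grid$t_ts[k], t_si = grid$t_si[k],
               tp = cnt["tp"], fp = cnt["fp"], tn = cnt["tn"],
               fn = cnt["fn"], recall = met$recall,
               precision = met$precision, mcc = met$mcc,
               row.names = NULL)
  })
  out <- do.call(rbind, res)
  finite <- which(is.finite(out$mcc))
  if (length(finite)) {
    ord <- finite[order(-out$mcc[finite], out$t_ts[finite],
                        out$t_si[finite])]
    attr(out, "best") <- out[ord[1], , drop = FALSE]
  }
  out
}

#' Validate the one-parameter cutoff constraint
#'
#' Runs the constrained decision rule — a hit passes when \code{e < e_max},
#' its TS-score exceeds \eqn{b/2} and its symmetry index does not exceed
#' [si_cutoff()] at that TS-score — for each value of the trade-off
#' parameter \code{b}, reusing the [score_samples()] cache.
#'
#' @param scored data frame from [score_samples()].
#' @param b_values trade-off parameter values (default 0.1 to 0.9).
#' @param e_max length-error cutoff.
#' @return Data frame with one row per \code{b}: counts and metrics.
#' @export
calibrate_ecv <- function(scored, b_values = seq(0.1, 0.9, by = 0.1),
                          e_max = 0.2) {
  res <- lapply(b_values, function(b) {
    cut <- si_cutoff(pmax(0, ifelse(is.na(scored$ts), 0, scored$ts)), b)
    cnt <- sweep_counts(scored,
                        scored$e < e_max & scored$ts > b / 2 &
                          scored$si <= cut)
    met <- suppressWarnings(classification_metrics(cnt["tp"], cnt["fp"],
                                                   cnt["tn"], cnt["fn"]))
    data.frame(b = b, tp = cnt["tp"], fp = cnt["fp"], tn = cnt["tn"],
               fn = cnt["fn"], recall = met$recall,
               precision = met$precision, mcc = met$mcc, row.names = NULL)
  })
  do.call(rbind, res)
}

#' Train the PPA-score cutoff per trade-off parameter
#'
#' For each value of \code{b}, sweeps the PPA-score cutoff from 0.0 to -5.0
#' in steps of -0.1 (51 values) over the constrained decision rule with the
#' PPA filter applied to sequence-database hits, and reports the cutoff
#' maximizing MCC (ties resolved to the most permissive cutoff).
#'
#' @param scored data frame from [score_samples()] with \code{with_ppa =
#'   TRUE}.
#' @param b_values trade-off parameter values.
#' @param ppa_grid PPA cutoffs to evaluate.
#' @param e_max length-error cutoff.
#' @param filter_sources template sources the PPA filter applies to
#'   (default \code{"SEQUENCE"}, i.e. Pfam-like templates only).
#' @return Data frame with one row per \code{b}: the selected \code{t_ppa}
#'   and its counts and metrics; full sweep in attribute \code{grid}.
#' @export
calibrate_pct <- function(scored, b_values = seq(0.9, 0.1, by = -0.1),
                          ppa_grid = seq(0, -5, by = -0.1), e_max = 0.2,
                          filter_sources = "SEQUENCE") {
  grid_rows <- list()
  best_rows <- list()
  for (b in b_values) {
    cut <- si_cutoff(pmax(0, ifelse(is.na(scored$ts), 0, scored$ts)), b)
    base_pass <- scored$e < e_max & scored$ts > b / 2 & scored$si <= cut
    filtered <- !is.na(scored$source) & scored$source %in% filter_sources
    cells <- lapply(ppa_grid, function(t_ppa) {
      pass <- base_pass &
        (!filtered | (!is.na(scored$ppa) & scored$ppa < t_ppa))
      cnt <- sweep_counts(scored, pass)
      met <- suppressWarnings(classification_metrics(cnt["tp"], cnt["fp"],
                                                     cnt["tn"], cnt["fn"]))
      data.frame(b = b, t_ppa = t_ppa, tp = cnt["tp"], fp = cnt["fp"],
                 tn = cnt["tn"], fn = cnt["fn"], recall = met$recall,
                 precision = met$precision, mcc = met$mcc,
                 row.names = NULL)
    })
    cells <- do.call(rbind, cells)
    grid_rows[[length(grid_rows) + 1L]] <- cells
    finite <- which(is.finite(cells$mcc))
    pick <- if (length(finite)) {
      finite[order(-cells$mcc[finite], -cells$t_ppa[finite])][1]
    } else 1L
    best_rows[[length(best_rows) + 1L]] <- cells[pick, , drop = FALSE]
  }
  out <- do.call(rbind, best_rows)
  rownames(out) <- NULL
  attr(out, "grid") <- do.call(rbind, grid_rows)
  out
}
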