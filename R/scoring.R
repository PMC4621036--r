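#' Normalised E-value term of the template-similarity score
#'
#' \eqn{h = \min(E_0, -\log_{10} E) / E_0} with normalisation parameter
#' \eqn{E_0 = 10}, clamped below at 0 (E-values above 1 would otherwise give
#' a negative term). \eqn{h = 0.3} at \eqn{E = 10^{-3}} and saturates at 1
#' for \eqn{E \le 10^{-10}}.
#'
#' @param E positive E-value (vectorised).
#' @param E0 normalisation parameter, default 10.
#' @return numeric in \eqn{[0, 1]}.
#' @export
normalized_evalue <- function(E, E0 = 10) {
  if (any(!is.finite(E) | E <= 0)) stop_domex("E-value must be positive")
  pmax(0, pmin(E0, -log10(E)) / E0)
}

#' Coverage factor of the template-similarity score
#'
#' A sigmoid in the alignment coverage \eqn{c} (aligned residues / candidate
#' length): 0 for \eqn{c \le 1/3}, and \eqn{1 / (1 + (1/(3c-1))^5)} above,
#' rising steeply around \eqn{c = 2/3} (where it equals 0.5) and approaching
#' \eqn{1/(1 + 2^{-5}) \approx 0.97} at full coverage. Alignments covering
#' less than a third of the candidate therefore contribute nothing.
#'
#' @param c coverage fraction in \eqn{[0, 1]} (vectorised).
#' @return numeric in \eqn{[0, 1)}.
#' @export
coverage_factor <- function(c) {
  if (any(!is.finite(c) | c < 0 | c > 1))
    stop_domex("coverage must be in [0, 1]")
  ifelse(c <= 1 / 3, 0, 1 / (1 + (1 / (3 * c - 1))^5))
}

#' Template-similarity score
#'
#' \code{TS = s * h * l}: global sequence identity times the normalised
#' E-value term ([normalized_evalue()]) times the coverage factor
#' ([coverage_factor()]). Monotone non-decreasing in each argument and
#' confined to \eqn{[0, 1]}.
#'
#' @param s identity fraction; @param h normalised E-value term;
#' @param l coverage factor.
#' @return numeric TS-score.
#' @export
ts_score <- function(s, h, l) {
  stopifnot(all(s >= 0 & s <= 1), all(h >= 0 & h <= 1), all(l >= 0 & l <= 1))
  s * h * l
}

#' Symmetric index of a split alignment
#'
#' Euclidean distance between the per-segment \eqn{(s_k, c_k)} vectors of
#' the two halves of a candidate's alignment to a template. A genuinely
#' homologous template aligns both segments with similar identity and
#' coverage, giving a small index; a template matching only one segment
#' scores near \eqn{\sqrt 2}.
#'
#' @param v_p,v_q numeric length-2 vectors \code{(s, c)} for the first and
#'   second segment.
#' @return non-negative distance, at most \eqn{\sqrt 2}.
#' @export
symmetric_index <- function(v_p, v_q) {
  v_p <- as.numeric(v_p); v_q <- as.numeric(v_q)
  stopifnot(length(v_p) == 2L, length(v_q) == 2L,
            all(v_p >= 0 & v_p <= 1), all(v_q >= 0 & v_q <= 1))
  sqrt(sum((v_p - v_q)^2))
}

#' Relative length variation between candidate and template
#'
#' \eqn{e = |L_T - L_Q| / L_Q}. Homologous domain pairs have similar
#' lengths, so candidates are only accepted when \eqn{e} stays below the
#' length-error cutoff (default 0.2).
#'
#' @param L_Q candidate (query) length, positive; @param L_T template length.
#' @return non-negative relative error.
#' @export
length_error <- function(L_Q, L_T) {
  if (any(L_Q <= 0)) stop_domex("candidate length must be positive")
  abs(L_T - L_Q) / L_Q
}

#' Symmetry-index cutoff as a function of the TS-score cutoff
#'
#' The two acceptance cutoffs are tied by a one-parameter piecewise-linear
#' constraint so a single parameter \code{b} trades recall against
#' precision:
#' \deqn{T_{SI} = f(T_{TS}, b) = \cases{0.3 & T_{TS} > 0.15 + b/2 \cr
#' 2 T_{TS} - b & 0.05 + b/2 < T_{TS} \le 0.15 + b/2 \cr
#' 0.1 & b/2 < T_{TS} \le 0.05 + b/2 \cr 0 & T_{TS} \le b/2}}
#' The function is continuous at the two inner breakpoints, non-decreasing
#' in \eqn{T_{TS}}, non-increasing in \eqn{b}, and its nonzero values lie in
#' \eqn{[0.1, 0.3]}. Boundary equalities are assigned to the lower piece.
#'
#' @param t_ts TS-score cutoff(s), non-negative (vectorised).
#' @param b trade-off parameter in \eqn{(0, 1)}.
#' @return the symmetry-index cutoff(s).
#' @export
si_cutoff <- function(t_ts, b) {
  if (!is.numeric(b) || length(b) != 1L || b <= 0 || b >= 1)
    stop_domex("b must be a single value in (0, 1)")
  if (any(t_ts < 0)) stop_domex("t_ts must be non-negative")
  ifelse(t_ts > 0.15 + b / 2, 0.3,
         ifelse(t_ts > 0.05 + b / 2, 2 * t_ts - b,
                ifelse(t_ts > b / 2, 0.1, 0)))
}

#' Acceptance thresholds
#'
#' Bundle of the tunable cutoffs used by [decide()]: the trade-off parameter
#' \code{b} of [si_cutoff()], the length-error cutoff \code{e_max}, the
#' profile-profile alignment score cutoff \code{t_ppa} applied to
#' sequence-database (Pfam-like) templates, and the \code{b} value below
#' which that filter is active. Defaults are the published operating point
#' (\code{b = 0.3}, \code{e_max = 0.2}, \code{t_ppa = -1.90}, filter active
#' for \code{b < 0.5}).
#'
#' @param b trade-off parameter in (0, 1).
#' @param e_max length-error cutoff (strict: accepted hits have
#'   \code{e < e_max}).
#' @param t_ppa PPA-score cutoff (strict: \code{ppa < t_ppa}).
#' @param ppa_applies_below_b apply the PPA filter when \code{b} is below
#'   this value.
#' @param E0 E-value normalisation parameter.
#' @param strict use strict inequalities for the TS/SI tests
#'   (\code{ts > cutoff}, \code{si < cutoff}) instead of the default
#'   \code{ts >= cutoff}, \code{si <= cutoff}.
#' @return An object of class \code{domex_thresholds}.
#' @export
domex_thresholds <- function(b = 0.3, e_max = 0.2, t_ppa = -1.90,
                             ppa_applies_below_b = 0.5, E0 = 10,
                             strict = FALSE) {
  if (b <= 0 || b >= 1) stop_domex("b must be in (0, 1)")
  if (e_max <= 0) stop_domex("e_max must be positive")
  structure(list(b = b, e_max = e_max, t_ppa = t_ppa,
                 ppa_applies_below_b = ppa_applies_below_b, E0 = E0,
                 strict = strict),
            class = "domex_thresholds")
}

# Score one hit against a candidate: TS-score components, symmetry index and
# length error, plus an optional PPA score.
score_hit <- function(hit, L_Q, th, ppa = NA_real_) {
  h <- normalized_evalue(hit$evalue, th$E0)
  l <- coverage_factor(hit$c)
  list(ts_score = ts_score(hit$s, h, l), h = h, l = l,
       si = symmetric_index(hit$per_segment$p, hit$per_segment$q),
       e = length_error(L_Q, hit$L_T),
       ppa_score = ppa)
}

# Single-hit filter chain; returns the failure reason or "ACCEPTED".
hit_verdict <- function(sc, source, th) {
  if (!(sc$e < th$e_max)) return("LENGTH_ERROR")
  cut <- si_cutoff(sc$ts_score, th$b)
  ts_ok <- sc$ts_score > th$b / 2
  si_ok <- if (th$strict) sc$si < cut else sc$si <= cut
  if (!(ts_ok && si_ok)) return("TS_SI_FAIL")
  if (source == "SEQUENCE" && th$b < th$ppa_applies_below_b) {
    if (is.na(sc$ppa_score) || !(sc$ppa_score < th$t_ppa))
      return("PPA_FAIL")
  }
  "ACCEPTED"
}

#' Accept or reject a candidate discontinuous domain
#'
#' Applies the decision chain to every template hit of a candidate. A hit
#' passes when (i) the length error is below \code{e_max}, (ii) the TS-score
#' exceeds \eqn{b/2} (the region where the symmetry-index cutoff is nonzero)
#' and the symmetry index does not exceed [si_cutoff()] evaluated at the
#' hit's TS-score, and (iii) for sequence-database templates with the PPA
#' filter active (\code{b < ppa_applies_below_b}), the profile-profile
#' alignment score is below \code{t_ppa}. Among passing hits the one with
#' the lowest PPA-score wins; hits without a computed PPA-score rank at 0
#' (PPA-scores of good alignments are negative), and remaining ties fall to
#' highest TS-score, then lowest E-value, then template id.
#'
#' @param candidate an [assemble_candidate()] object.
#' @param hits list of \code{template_hit}s from [search_templates()].
#' @param th a [domex_thresholds()] object.
#' @param ppa_scorer optional \code{function(candidate, hit)} returning a
#'   PPA score (see [make_ppa_scorer()]); evaluated lazily for hits that
#'   survive the length-error and TS/SI filters.
#' @return An object of class \code{domex_decision}: candidate, logical
#'   \code{accepted}, the winning hit and its score bundle (or \code{NULL}),
#'   and a \code{reason} in \code{NO_HIT}, \code{LENGTH_ERROR},
#'   \code{TS_SI_FAIL}, \code{PPA_FAIL}, \code{ACCEPTED}.
#' @export
decide <- function(candidate, hits, th = domex_thresholds(),
                   ppa_scorer = NULL) {
  stopifnot(inherits(candidate, "assembled_candidate"),
            inherits(th, "domex_thresholds"))
  mk <- function(accepted, reason, hit = NULL, scores = NULL, audit = NULL)
    structure(list(candidate = candidate, accepted = accepted,
                   winning_hit = hit, scores = scores, reason = reason,
                   audit = audit),
              class = "domex_decision")
  if (!length(hits)) return(mk(FALSE, "NO_HIT"))

  L_Q <- nchar(candidate$sequence)
  scored <- lapply(hits, function(hit) {
    sc <- score_hit(hit, L_Q, th)
    verdict <- hit_verdict(sc, hit$source, th)
    needs_ppa <- !is.null(ppa_scorer) &&
      verdict %in% c("ACCEPTED", "PPA_FAIL")
    if (needs_ppa && is.na(sc$ppa_score)) {
      sc$ppa_score <- ppa_scorer(candidate, hit)
      verdict <- hit_verdict(sc, hit$source, th)
    }
    list(hit = hit, scores = sc, verdict = verdict)
  })
  verdicts <- vapply(scored, function(x) x$verdict, character(1))
  audit <- data.frame(
    template_id = vapply(scored, function(x) x$hit$template_id, character(1)),
    source = vapply(scored, function(x) x$hit$source, character(1)),
    evalue = vapply(scored, function(x) x$hit$evalue, numeric(1)),
    ts_score = vapply(scored, function(x) x$scores$ts_score, numeric(1)),
    si = vapply(scored, function(x) x$scores$si, numeric(1)),
    e = vapply(scored, function(x) x$scores$e, numeric(1)),
    ppa_score = vapply(scored, function(x) x$scores$ppa_score, numeric(1)),
    verdict = verdicts,
    stringsAsFactors = FALSE)

  passing <- scored[verdicts == "ACCEPTED"]
  if (!length(passing)) {
    reason <- if ("PPA_FAIL" %in% verdicts) "PPA_FAIL"
      else if ("TS_SI_FAIL" %in% verdicts) "TS_SI_FAIL"
      else "LENGTH_ERROR"
    return(mk(FALSE, reason, audit = audit))
  }
  key <- vapply(passing, function(x) {
    p <- x$scores$ppa_score
    if (is.na(p)) 0 else p
  }, numeric(1))
  ord <- order(key,
               -vapply(passing, function(x) x$scores$ts_score, numeric(1)),
               vapply(passing, function(x) x$hit$evalue, numeric(1)),
               vapply(passing, function(x) x$hit$template_id, character(1)))
  best <- passing[[ord[1]]]
  mk(TRUE, "ACCEPTED", best$hit, best$scores, audit)
}

#' @export
print.domex_decision <- function(x, ...) {
  cat(sprintf("Candidate %s: %s (%s)\n", x$candidate$id,
              if (x$accepted) "discontinuous domain" else "rejected",
              x$reason))
  if (x$accepted)
    cat(sprintf("  template %s (%s): TS=%.3f SI=%.3f e=%.3f%s\n",
                x$winning_hit$template_id, x$winning_hit$source,
                x$scores$ts_score, x$scores$si, x$scores$e,
                if (is.na(x$scores$ppa_score)) ""
                else sprintf(" PPA=%.2f", x$scores$ppa_score)))
  invisible(x)
}
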