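test_that("the normalised E-value term matches its defining values", {
  expect_equal(normalized_evalue(0.001), 0.3)
  expect_equal(normalized_evalue(1e-10), 1.0)
  expect_equal(normalized_evalue(1e-12), 1.0)   # saturates below 1e-10
  expect_equal(normalized_evalue(1), 0.0)
  expect_equal(normalized_evalue(5), 0.0)       # clamped for E > 1
  expect_error(normalized_evalue(0), "positive")
  expect_error(normalized_evalue(-1), "positive")
})

test_that("the coverage factor is a floor-then-sigmoid in coverage", {
  expect_equal(coverage_factor(0.30), 0)
  expect_equal(coverage_factor(1 / 3), 0)
  expect_equal(coverage_factor(2 / 3), 0.5)
  expect_equal(coverage_factor(1.0), 1 / (1 + 0.5^5), tolerance = 1e-6)
  expect_equal(coverage_factor(1.0), 0.969697, tolerance = 1e-6)
  expect_error(coverage_factor(1.2), "coverage")
  # monotone over a grid
  grid <- seq(0, 1, by = 0.01)
  expect_true(all(diff(coverage_factor(grid)) >= 0))
})

test_that("the TS-score is the product of its three factors", {
  expect_equal(ts_score(1, 1, 1), 1.0)
  expect_equal(ts_score(0.5, 1.0, 0.969697), 0.484848, tolerance = 1e-5)
  expect_equal(ts_score(0.7, 0.4, 0), 0)
})

test_that("the symmetry index is the Euclidean distance of segment vectors", {
  expect_equal(symmetric_index(c(0.5, 0.8), c(0.5, 0.8)), 0)
  expect_equal(symmetric_index(c(1, 1), c(0, 0)), sqrt(2), tolerance = 1e-6)
  expect_equal(symmetric_index(c(0.4, 0.8), c(0.1, 0.4)), 0.5)
})

test_that("length variation is the relative length difference", {
  expect_equal(length_error(100, 100), 0)
  expect_equal(length_error(100, 115), 0.15)
  expect_equal(length_error(100, 125), 0.25)
  expect_error(length_error(0, 10), "positive")
})

test_that("the SI cutoff reproduces its worked values and piece structure", {
  expect_equal(si_cutoff(0.30, 0.4), 0.2)
  expect_equal(si_cutoff(0.10, 0.4), 0.0)
  expect_equal(si_cutoff(0.90, 0.4), 0.3)
  expect_error(si_cutoff(0.3, 0), "b must")
  expect_error(si_cutoff(0.3, 1), "b must")
})

test_that("the SI cutoff stays in {0} U [0.1, 0.3] and is monotone", {
  t_grid <- seq(0, 1.2, by = 0.005)
  for (b in seq(0.05, 0.95, by = 0.05)) {
    v <- si_cutoff(t_grid, b)
    expect_true(all(v == 0 | (v >= 0.1 - 1e-12 & v <= 0.3 + 1e-12)))
    expect_true(all(diff(v) >= -1e-12))  # non-decreasing in t_ts
  }
  # non-increasing in b at fixed t_ts
  b_grid <- seq(0.05, 0.95, by = 0.01)
  for (t in seq(0, 1, by = 0.05)) {
    v <- vapply(b_grid, function(b) si_cutoff(t, b), numeric(1))
    expect_true(all(diff(v) <= 1e-12))
  }
  # continuity at the two inner breakpoints
  for (b in c(0.2, 0.4, 0.6)) {
    expect_equal(si_cutoff(0.15 + b / 2, b),
                 si_cutoff(0.15 + b / 2 + 1e-9, b), tolerance = 1e-6)
    expect_equal(si_cutoff(0.05 + b / 2, b),
                 si_cutoff(0.05 + b / 2 + 1e-9, b), tolerance = 1e-6)
  }
})

# a hit whose scores land exactly at given (ts, si, e) values
planted_hit <- function(id = "cath|h", source = "STRUCTURE", s = 0.5,
                        evalue = 1e-10, c = 1.0, si_pair = NULL,
                        L_T = 100) {
  per <- si_pair %||% list(p = c(s = s, c = c), q = c(s = s, c = c))
  structure(list(template_id = id, source = source, evalue = evalue,
                 score = 100, s = s, c = c, L_T = L_T,
                 template_seq = random_protein(L_T),
                 per_segment = per, q_aln = "", t_aln = "",
                 q_start = 1L, t_start = 1L),
            class = "template_hit")
}

cand100 <- function() {
  set.seed(41)
  candidate_from_segments(random_protein(50), random_protein(50))
}

test_that("the worked acceptance example is accepted end to end", {
  # TS-score 0.30 (s=0.3093.., h=1, l=0.9697), SI 0.15, e = 0 at b = 0.4
  cand <- cand100()
  s_val <- 0.30 / (1.0 * coverage_factor(1.0))
  hit <- planted_hit(s = s_val, evalue = 1e-12, c = 1.0,
                     si_pair = list(p = c(s = s_val + 0.075, c = 1),
                                    q = c(s = s_val - 0.055, c = 0.9)),
                     L_T = 100)
  # engineered so si = sqrt(0.13^2 + 0.1^2) ... use exact pair instead
  hit$per_segment <- list(p = c(s = 0.5, c = 0.95),
                          q = c(s = 0.59, c = 0.83))  # si = 0.15
  d <- decide(cand, list(hit), domex_thresholds(b = 0.4))
  expect_equal(d$scores$ts_score, 0.30, tolerance = 1e-9)
  expect_equal(d$scores$si, 0.15, tolerance = 1e-9)
  expect_lt(d$scores$e, 0.2)
  expect_true(d$accepted)
  expect_equal(d$reason, "ACCEPTED")

  # same hit with a 25% length mismatch is rejected by the length filter
  hit2 <- hit
  hit2$L_T <- 125L
  d2 <- decide(cand, list(hit2), domex_thresholds(b = 0.4))
  expect_false(d2$accepted)
  expect_equal(d2$reason, "LENGTH_ERROR")
})

test_that("no hits yields a NO_HIT decision", {
  d <- decide(cand100(), list(), domex_thresholds())
  expect_false(d$accepted)
  expect_equal(d$reason, "NO_HIT")
  expect_null(d$winning_hit)
})

test_that("sequence-source hits need the PPA filter when b < 0.5", {
  cand <- cand100()
  hit <- planted_hit(id = "pfam|h", source = "SEQUENCE", s = 0.9,
                     evalue = 1e-12, L_T = 100)
  # no scorer available: cannot confirm, rejected
  d <- decide(cand, list(hit), domex_thresholds(b = 0.3))
  expect_false(d$accepted)
  expect_equal(d$reason, "PPA_FAIL")
  # a scorer returning a good (low) PPA-score lets it through
  d2 <- decide(cand, list(hit), domex_thresholds(b = 0.3),
               ppa_scorer = function(cand, hit) -2.5)
  expect_true(d2$accepted)
  expect_equal(d2$scores$ppa_score, -2.5)
  # the filter is inactive at high b
  d3 <- decide(cand, list(hit), domex_thresholds(b = 0.6))
  expect_true(d3$accepted)
  # structure-source hits bypass the filter entirely
  hit4 <- planted_hit(id = "cath|h", source = "STRUCTURE", s = 0.9,
                      evalue = 1e-12)
  expect_true(decide(cand, list(hit4), domex_thresholds(b = 0.3))$accepted)
})

test_that("the winning hit has the lowest PPA-score and ties break deterministically", {
  cand <- cand100()
  h1 <- planted_hit(id = "pfam|a", source = "SEQUENCE", s = 0.8,
                    evalue = 1e-12)
  h2 <- planted_hit(id = "pfam|b", source = "SEQUENCE", s = 0.95,
                    evalue = 1e-12)
  scorer <- function(cand, hit) if (hit$template_id == "pfam|a") -3 else -2
  d <- decide(cand, list(h1, h2), domex_thresholds(b = 0.3), scorer)
  expect_equal(d$winning_hit$template_id, "pfam|a")
  # without PPA, higher TS-score wins; then lower E-value; then id
  h3 <- planted_hit(id = "cath|c", source = "STRUCTURE", s = 0.9,
                    evalue = 1e-12)
  h4 <- planted_hit(id = "cath|d", source = "STRUCTURE", s = 0.8,
                    evalue = 1e-12)
  d2 <- decide(cand, list(h4, h3), domex_thresholds(b = 0.6))
  expect_equal(d2$winning_hit$template_id, "cath|c")
})

test_that("decisions are invariant to hit ordering", {
  set.seed(42)
  cand <- cand100()
  hits <- lapply(1:6, function(k)
    planted_hit(id = sprintf("cath|h%d", k), s = runif(1, 0.2, 1),
                evalue = 10^-runif(1, 2, 12), c = runif(1, 0.5, 1),
                L_T = sample(85:115, 1)))
  th <- domex_thresholds(b = 0.3)
  base <- decide(cand, hits, th)
  for (rep in 1:5) {
    perm <- decide(cand, sample(hits), th)
    expect_equal(perm$accepted, base$accepted)
    if (base$accepted)
      expect_equal(perm$winning_hit$template_id,
                   base$winning_hit$template_id)
  }
})

test_that("acceptance is monotone in hit quality", {
  set.seed(43)
  cand <- cand100()
  th <- domex_thresholds(b = 0.3)
  for (rep in 1:40) {
    s <- runif(1, 0.1, 1)
    ds <- runif(1, 0, 0.3)
    base_pair <- list(p = c(s = min(1, s + ds), c = 1),
                      q = c(s = max(0, s - ds), c = runif(1, 0.6, 1)))
    hit <- planted_hit(s = s, evalue = 10^-runif(1, 0, 12),
                       c = runif(1, 0.4, 1), si_pair = base_pair,
                       L_T = sample(80:130, 1))
    d <- decide(cand, list(hit), th)
    if (!d$accepted) next
    # improving the hit never flips accept -> reject
    better <- hit
    better$s <- min(1, hit$s + 0.05)
    better$evalue <- hit$evalue / 100
    better$L_T <- 100L
    better$per_segment <- list(p = c(s = 0.9, c = 1), q = c(s = 0.9, c = 1))
    expect_true(decide(cand, list(better), th)$accepted)
  }
})
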