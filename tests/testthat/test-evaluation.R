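test_that("sample construction labels the A1-B-A2-C layout like the schematic", {
  set.seed(71)
  lens <- c(60, 50, 70, 55)
  chain <- random_protein(sum(lens))
  ends <- cumsum(lens)
  starts <- c(1, head(ends, -1) + 1)
  rng <- function(k) c(starts[k], ends[k])
  chains <- list(ch1 = list(
    sequence = chain,
    domains = list(list(rng(1), rng(3)),  # A1 + A2 form one domain
                   list(rng(2)),          # B
                   list(rng(4)))))        # C
  samples <- generate_samples(chains, min_len = 40)
  expect_equal(nrow(samples), 3L)
  key <- paste(samples$first_index, samples$second_index)
  expect_equal(samples$label[key == "1 3"], "POSITIVE")
  expect_equal(samples$label[key == "1 4"], "NEGATIVE")
  expect_equal(samples$label[key == "2 4"], "NEGATIVE")

  # three continuous single-segment domains: exactly one negative pair (1,3)
  chains2 <- list(ch2 = list(
    sequence = chain[1],
    domains = list(list(c(1, 60)), list(c(61, 110)), list(c(111, 180)))))
  chains2$ch2$sequence <- random_protein(180)
  s2 <- generate_samples(chains2, min_len = 40)
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$label, "NEGATIVE")

  # short segments are excluded from pairing
  chains3 <- list(ch3 = list(
    sequence = random_protein(150),
    domains = list(list(c(1, 60)), list(c(61, 90)), list(c(91, 150)))))
  s3 <- generate_samples(chains3, min_len = 40)
  expect_equal(nrow(s3), 1L)  # only (1,3); the 30-residue middle never pairs

  # chains with fewer than three segments are skipped with a warning
  chains4 <- list(ch4 = list(sequence = random_protein(100),
                             domains = list(list(c(1, 50)), list(c(51, 100)))))
  expect_warning(s4 <- generate_samples(chains4), "skipped")
  expect_equal(nrow(s4), 0L)
})

test_that("recall, precision and MCC follow their definitions", {
  m <- classification_metrics(10, 0, 10, 0)
  expect_equal(unlist(m), c(recall = 1, precision = 1, mcc = 1))
  m2 <- classification_metrics(5, 5, 5, 5)
  expect_equal(unlist(m2), c(recall = 0.5, precision = 0.5, mcc = 0))
  w <- capture_warnings(m3 <- classification_metrics(0, 0, 10, 5))
  expect_match(w, "precision", all = FALSE)
  expect_true(is.nan(m3$precision))
  expect_true(is.nan(m3$mcc))
  # MCC stays in [-1, 1] over random counts
  set.seed(72)
  for (rep in 1:50) {
    cnt <- sample(0:30, 4, replace = TRUE)
    m <- suppressWarnings(classification_metrics(cnt[1], cnt[2], cnt[3],
                                                 cnt[4]))
    if (is.finite(m$mcc)) expect_true(abs(m$mcc) <= 1 + 1e-12)
    if (is.finite(m$recall)) expect_true(m$recall >= 0 && m$recall <= 1)
  }
})

test_that("the NDO score rewards matched residue overlap", {
  ref <- domain_prediction("c", 100, list(
    list(ranges = list(c(1, 50))), list(ranges = list(c(51, 100)))))
  expect_equal(ndo_score(ref, ref), 1.0)

  # single-domain reference vs a prediction splitting it in half
  one <- domain_prediction("c", 100, list(list(ranges = list(c(1, 100)))))
  half <- domain_prediction("c", 100, list(
    list(ranges = list(c(1, 50))), list(ranges = list(c(51, 100)))))
  expect_equal(ndo_score(half, one), 0.5)

  # partitions engineered so the best matching covers 80 of 100 residues
  pred <- domain_prediction("c", 100, list(
    list(ranges = list(c(1, 40))), list(ranges = list(c(41, 100)))))
  ref2 <- domain_prediction("c", 100, list(
    list(ranges = list(c(1, 20))), list(ranges = list(c(21, 100)))))
  expect_equal(ndo_score(pred, ref2), 0.8)
  # symmetry for full partitions
  expect_equal(ndo_score(ref2, pred), ndo_score(pred, ref2))

  # discontinuous domains count through both their ranges
  refd <- domain_prediction("c", 100, list(
    list(ranges = list(c(1, 30), c(71, 100))),
    list(ranges = list(c(31, 70)))))
  expect_equal(ndo_score(refd, refd), 1.0)
  expect_error(ndo_score(one, domain_prediction("c", 50,
                                                list(list(ranges = list(c(1, 50)))))),
               "lengths differ")
})

test_that("NDO matching agrees with exhaustive permutation search", {
  set.seed(73)
  for (rep in 1:20) {
    n <- sample(2:4, 1)
    cuts <- sort(sample(10:90, n - 1))
    mk <- function(cuts) {
      s <- c(1, cuts + 1); e <- c(cuts, 100)
      domain_prediction("c", 100, lapply(seq_along(s), function(k)
        list(ranges = list(c(s[k], e[k])))))
    }
    a <- mk(cuts)
    b <- mk(sort(sample(10:90, sample(1:4, 1))))
    got <- ndo_score(a, b)
    # brute force over all injective assignments
    am <- lapply(a$domains, function(d) seq(d$ranges[[1]][1],
                                            d$ranges[[1]][2]))
    bm <- lapply(b$domains, function(d) seq(d$ranges[[1]][1],
                                            d$ranges[[1]][2]))
    small <- if (length(am) <= length(bm)) am else bm
    big <- if (length(am) <= length(bm)) bm else am
    perms <- function(v) if (length(v) <= 1) list(v) else
      unlist(lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
    best <- 0
    for (p in perms(seq_along(big))) {
      tot <- sum(vapply(seq_along(small), function(i)
        length(intersect(small[[i]], big[[p[i]]])), numeric(1)))
      best <- max(best, tot)
    }
    expect_equal(got, best / 100)
  }
})

synthetic_scored <- function(n_pos, n_neg, ts_pos, si_pos, ts_neg, si_neg,
                             jitter = 0.01, seed = 74) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("s%04d", seq_len(n_pos + n_neg)),
    label = rep(c("POSITIVE", "NEGATIVE"), c(n_pos, n_neg)),
    template_id = "t", source = "STRUCTURE",
    ts = pmax(0, c(rnorm(n_pos, ts_pos, jitter), rnorm(n_neg, ts_neg,
                                                       jitter))),
    si = pmax(0, c(rnorm(n_pos, si_pos, jitter), rnorm(n_neg, si_neg,
                                                       jitter))),
    e = 0.05, ppa = NA_real_, stringsAsFactors = FALSE)
}

test_that("the TS/SI grid sweep has the stated shape and separates a clean design", {
  scored <- synthetic_scored(30, 60, ts_pos = 0.9, si_pos = 0.05,
                             ts_neg = 0.1, si_neg = 0.4)
  grid <- calibrate_est(scored)
  expect_equal(nrow(grid), 19L * 10L)
  expect_equal(length(unique(grid$t_ts)), 19L)
  expect_equal(length(unique(grid$t_si)), 10L)
  best <- attr(grid, "best")
  expect_equal(best$mcc, 1.0)
  cell <- grid[abs(grid$t_ts - 0.5) < 1e-9 & abs(grid$t_si - 0.2) < 1e-9, ]
  expect_equal(cell$mcc, 1.0)

  # degenerate cache: identical scores for every sample
  flat <- synthetic_scored(10, 10, 0.5, 0.2, 0.5, 0.2, jitter = 0)
  g2 <- calibrate_est(flat)
  expect_true(all(is.nan(g2$mcc) | abs(g2$mcc) < 1e-9))
})

test_that("the constrained (single-parameter) sweep reuses the score cache", {
  scored <- synthetic_scored(30, 60, ts_pos = 0.9, si_pos = 0.05,
                             ts_neg = 0.1, si_neg = 0.4)
  res <- calibrate_ecv(scored)
  expect_equal(nrow(res), 9L)
  expect_true(all(res$mcc == 1))  # fully separable at every b
  # samples with no hits count as predicted-negative
  scored2 <- rbind(scored,
                   data.frame(sample_id = "s9999", label = "POSITIVE",
                              template_id = NA, source = NA, ts = NA,
                              si = NA, e = NA, ppa = NA))
  res2 <- calibrate_ecv(scored2)
  expect_true(all(res2$fn == 1))
})

test_that("the PPA cutoff sweep picks a separating cutoff per b", {
  scored <- synthetic_scored(20, 20, ts_pos = 0.9, si_pos = 0.05,
                             ts_neg = 0.8, si_neg = 0.1)
  # negatives only distinguishable by PPA: give them poor (high) scores
  scored$source <- "SEQUENCE"
  scored$ppa <- ifelse(scored$label == "POSITIVE", -3.5, -0.5)
  res <- calibrate_pct(scored)
  expect_equal(nrow(res), 9L)
  grid <- attr(res, "grid")
  expect_equal(nrow(grid), 9L * 51L)
  # any cutoff in (-3.5, -0.5) separates; the most permissive is reported
  expect_true(all(res$t_ppa <= -0.5 & res$t_ppa >= -3.5))
  expect_true(all(res$mcc == 1))

  # without sequence-source hits the sweep is a no-op across cutoffs
  scored$source <- "STRUCTURE"
  res2 <- calibrate_pct(scored)
  g2 <- attr(res2, "grid")
  for (b in unique(g2$b))
    expect_equal(length(unique(g2$mcc[g2$b == b])), 1L)
  expect_equal(res2$t_ppa, rep(0, 9))
})
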