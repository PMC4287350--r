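test_that("theta matches its closed form and is antisymmetric", {
  expect_equal(compute_theta(30, 30), 0)
  expect_equal(compute_theta(25 * exp(1), 25, pseudocount = 0), 1)
  expect_equal(compute_theta(100, 0, pseudocount = 1), log(101))
  set.seed(1)
  a <- runif(50, 0, 500); b <- runif(50, 0, 500)
  expect_equal(compute_theta(a, b), -compute_theta(b, a))
  expect_error(compute_theta(0, 0, pseudocount = 0), "undefined")
  expect_error(compute_theta(-1, 5), ">= 0")
})

test_that("normalization rescales by the library total", {
  pc <- position_counts(pos = c(10, 20), strand = "+", count = c(10, 30),
                        genome_length = 100, total_nonrrna = 1e6)
  expect_equal(normalize_counts(pc, scale = 1e6)$count, c(10, 30))
  attr(pc, "total_nonrrna") <- 2e6
  expect_equal(normalize_counts(pc, scale = 1e6)$count, c(5, 15))
  # linearity: normalized sum = scale * (library sum / total)
  expect_equal(sum(normalize_counts(pc, 1e6)$count), 1e6 * 40 / 2e6)
  attr(pc, "total_nonrrna") <- 0
  expect_error(normalize_counts(pc, 1e6), "> 0")
})

test_that("threshold calibration reproduces the 2-sd rule and Welch test", {
  neg <- c(-0.9, -0.5, -0.1)   # mean -0.5, sd 0.4
  pos <- c(1.0, 1.5, 2.0, 2.5)
  cal <- calibrate_threshold(pos, neg)
  expect_equal(cal$mean_neg, -0.5)
  expect_equal(cal$sd_neg, 0.4)
  expect_equal(cal$threshold, -0.5 + 2 * 0.4)   # alpha = upper 2-sd tail
  wt <- t.test(pos, neg)                        # independent check
  expect_equal(cal$welch_t, unname(wt$statistic))
  expect_equal(cal$welch_df, unname(wt$parameter))
  # identical samples: t = 0, p = 1
  same <- c(0.1, 0.4, 0.9)
  cal0 <- calibrate_threshold(same, same)
  expect_equal(cal0$welch_t, 0)
  expect_equal(cal0$welch_p, 1)
  # the published operating point can be pinned while keeping the
  # calibrated value
  cal26 <- calibrate_threshold(pos, neg, override = 0.26)
  expect_equal(cal26$threshold, 0.26)
  expect_equal(cal26$calibrated, 0.3)
})

test_that("control matching respects the 5-bp rule and tie-breaks", {
  peaks <- data.frame(pos = c(103, 106, 98, 102),
                      strand = c("+", "+", "-", "-"),
                      count = c(50, 40, 60, 60),
                      theta = c(1.2, 0.9, 1.5, 2.0))
  known <- data.frame(pos = c(100, 100, 100), strand = c("+", "+", "-"))
  res <- match_controls(known[1, , drop = FALSE], peaks)
  expect_equal(res$theta, 1.2)                  # |103-100| = 3 <= 5
  res2 <- match_controls(data.frame(pos = 100, strand = "+"),
                         peaks[2, , drop = FALSE])
  expect_equal(res2$n_unmatched, 1)             # |106-100| = 6 > 5
  # equidistant peaks at 98 and 102 with equal counts: leftmost wins
  res3 <- match_controls(known[3, , drop = FALSE], peaks)
  expect_equal(res3$matched$peak_pos, 98)
  # the read floor removes weak peaks before matching
  res4 <- match_controls(known[1, , drop = FALSE], peaks, min_reads = 55)
  expect_equal(res4$n_unmatched, 1)
})

test_that("RNA-seq step filter compares downstream to upstream windows", {
  L <- 400
  cov <- list(plus = rep(10, L), minus = rep(10, L))
  cov$plus[200:L] <- 14
  expect_true(rna_seq_step_filter(cov, 200, "+"))    # 14 > 1.35 * 10
  cov$plus[200:L] <- 13.5
  expect_false(rna_seq_step_filter(cov, 200, "+"))   # not strictly greater
  cov2 <- list(plus = rep(0, L), minus = rep(0, L))
  cov2$plus[200:L] <- 5
  expect_true(rna_seq_step_filter(cov2, 200, "+"))   # zero-upstream rule
  # minus strand: transcription runs toward lower coordinates
  cov3 <- list(plus = rep(10, L), minus = rep(10, L))
  cov3$minus[1:200] <- 20
  expect_true(rna_seq_step_filter(cov3, 200, "-"))
  expect_false(rna_seq_step_filter(cov3, 300, "-"))
})

test_that("peak merging chains within 5 bp, sums reads, keeps max position", {
  cand <- data.frame(pos = c(100, 103, 104), plus = c(10, 5, 2))
  m <- merge_peaks(cand)
  expect_equal(nrow(m), 1)
  expect_equal(m$pos, 100)
  expect_equal(m$plus, 17)
  m2 <- merge_peaks(data.frame(pos = c(100, 106), plus = c(5, 5)))
  expect_equal(nrow(m2), 2)                          # gap 6 > 5
  m3 <- merge_peaks(data.frame(pos = c(100, 102), plus = c(5, 5)))
  expect_equal(m3$pos, 100)                          # tie -> leftmost
  expect_equal(m3$plus, 10)
})

test_that("merging conserves reads and never moves peaks beyond the span", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:30, 1)
    cand <- data.frame(pos = sort(sample.int(200, n)),
                       plus = rpois(n, 20) + 1, minus = rpois(n, 10))
    m <- merge_peaks(cand)
    expect_equal(sum(m$plus), sum(cand$plus))
    expect_equal(sum(m$minus), sum(cand$minus))
    expect_true(all(m$pos %in% cand$pos))
    expect_true(all(diff(m$pos) > 5))
  }
})

make_tracks <- function(pos, strand, plus, minus, L = 1000,
                        total_p = sum(plus), total_m = sum(minus)) {
  list(plus = position_counts(pos, strand, plus, "p", L, total_p),
       minus = position_counts(pos, strand, minus, "m", L, total_m))
}

test_that("calling requires the read floor, strict threshold, and step", {
  flat <- list(plus = rep(10, 1000), minus = rep(10, 1000))
  step <- list(plus = rep(10, 1000), minus = rep(10, 1000))
  step$plus[500:1000] <- 50
  tr <- make_tracks(500, "+", 24, 1)
  res <- call_tss(tr$plus, tr$minus, step, 0.26)
  expect_false(any(res$called))                      # +TAP 24 < 25
  # fix both library totals so normalization leaves counts unchanged
  tr2 <- make_tracks(500, "+", 100, 10, total_p = 1000, total_m = 1000)
  # theta is exactly compute_theta(100, 10); threshold == theta is
  # rejected by the strict >
  res2 <- call_tss(tr2$plus, tr2$minus, step, compute_theta(100, 10))
  expect_false(any(res2$called))
  res3 <- call_tss(tr2$plus, tr2$minus, step, 0.26)
  expect_true(res3$called[1])
  res4 <- call_tss(tr2$plus, tr2$minus, flat, 0.26)
  expect_false(any(res4$called))                     # step filter fails
})

test_that("calling decisions are invariant under a common scale factor", {
  set.seed(3)
  pos <- sort(sample(100:900, 30))
  plus <- rpois(30, 60) + 1; minus <- rpois(30, 20) + 1
  cov <- list(plus = rep(1, 1000), minus = rep(1, 1000))
  for (p in pos) cov$plus[p:min(1000, p + 100)] <-
    cov$plus[p:min(1000, p + 100)] + 5
  # background-dominated library totals, scaled with the counts; with no
  # pseudocount theta is exactly scale-invariant
  tr <- make_tracks(pos, "+", plus, minus, total_p = 5000, total_m = 5000)
  r1 <- call_tss(tr$plus, tr$minus, cov, 0.26, pseudocount = 0)
  tr2 <- make_tracks(pos, "+", plus * 7, minus * 7,
                     total_p = 35000, total_m = 35000)
  r2 <- call_tss(tr2$plus, tr2$minus, cov, 0.26, pseudocount = 0)
  expect_equal(r1$called, r2$called)
  expect_equal(r1$theta, r2$theta, tolerance = 1e-12)
  expect_true(any(r1$called) && !all(r1$called))
})

test_that("noise-free separation: perfect sensitivity and no false calls", {
  # wide theta separation, no Poisson layer: every true site called,
  # every processing-like site rejected
  L <- 5000
  true_pos <- seq(200, 2000, by = 200)
  proc_pos <- seq(2600, 4400, by = 200)
  pos <- c(true_pos, proc_pos)
  plus <- c(rep(200 * exp(1.71), length(true_pos)),
            rep(200 * exp(-0.52), length(proc_pos)))
  minus <- rep(200, length(pos))
  cov <- list(plus = rep(10, L), minus = rep(10, L))
  # short transcripts so each TSS keeps a clean upstream/downstream step
  for (p in true_pos) cov$plus[p:(p + 150)] <- 60
  tr <- list(plus = position_counts(pos, "+", plus, "p", L),
             minus = position_counts(pos, "+", minus, "m", L))
  # equalize library totals so normalization is composition-neutral
  tot <- max(sum(plus), sum(minus))
  attr(tr$plus, "total_nonrrna") <- tot
  attr(tr$minus, "total_nonrrna") <- tot
  res <- call_tss(tr$plus, tr$minus, cov, 0.26)
  called <- res$pos[res$called]
  expect_setequal(called, true_pos)
})
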