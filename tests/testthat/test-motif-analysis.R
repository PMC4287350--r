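test_that("gapped IUPAC consensus matching follows IUPAC semantics", {
  ccrm <- motif_model("CcrM", consensus = "GANTC", window = c(-50, -1))
  prom <- paste0(strrep("T", 40), "GACTC", "TTTTT")   # hit at offset -10
  h <- scan_consensus(prom, ccrm)
  expect_equal(h$offset, -10)
  expect_equal(h$seq, "GACTC")
  prom2 <- paste0(strrep("T", 40), "GACTA", "TTTTT")  # 5th base mismatch
  expect_equal(nrow(scan_consensus(prom2, ccrm)), 0)
  full <- motif_model("CtrA_full", consensus = "TTAA-N7-TTAA")
  spacer <- "GCGCGCG"
  prom3 <- paste0(strrep("C", 50), "TTAA", spacer, "TTAA", strrep("C", 35))
  h3 <- scan_consensus(prom3, full)   # first T at index 51 of 100 -> -50
  expect_equal(h3$offset, -50)
  expect_error(motif_model("bad", consensus = "TTAX"), "non-IUPAC")
})

test_that("palindromic consensus hits mirror under reverse complement", {
  full <- motif_model("CtrA_full", consensus = "TTAA-N7-TTAA")
  prom <- paste0(strrep("C", 30), "TTAAGCGCGCGTTAA", strrep("C", 55))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(prom)))
  h_fwd <- scan_consensus(prom, full)
  h_rc <- scan_consensus(rc, full)
  # the pattern is its own reverse complement, so a hit at offset o on one
  # strand mirrors to offset -(100 + 15) - o on the other (promoter length
  # 100, motif width 15)
  expect_setequal(h_rc$offset, -115 - h_fwd$offset)
  expect_gt(nrow(h_fwd) + nrow(h_rc), 0)
})

test_that("PWMs are built with pseudocounts and score words additively", {
  m0 <- build_pwm(c("ACGT", "ACGT"), pseudocount = 0)
  expect_equal(m0$pwm[, 1], c(A = 1, C = 0, G = 0, T = 0))
  m <- build_pwm(c("ACGT", "ACGT"), pseudocount = 0.5)
  expect_equal(max(m$pwm), 2.5 / 4)
  expect_equal(colSums(m$pwm), rep(1, 4), ignore_attr = TRUE)
  expect_equal(pwm_score(m0, "ACGT"),
               sum(log2(1 / 0.25) * 4) / 1, tolerance = 1e-12)
})

test_that("uniform PWM equals background: all words score 0 with p = 1", {
  m <- motif_model("unif", pwm = matrix(0.25, 4, 3))
  expect_equal(pwm_score(m, "ACG"), 0)
  expect_equal(pwm_pvalue(m, 0), 1)
})

test_that("DP p-values equal exhaustive enumeration for widths 1 to 8", {
  for (w in 1:8) {
    m <- random_pwm(w, seed = 100 + w)
    dist <- pwm_score_distribution(m)
    expect_equal(sum(dist$prob), 1, tolerance = 1e-12)
    # probe at every achievable word score of a few random words plus the
    # extremes of the distribution
    set.seed(w)
    words <- replicate(5, paste(sample(c("A", "C", "G", "T"), w, TRUE),
                                collapse = ""))
    probes <- c(vapply(words, function(x) pwm_score(m, x), numeric(1)),
                min(dist$score), max(dist$score))
    expect_equal(pwm_pvalue(m, probes, dist = dist),
                 enumerate_pwm_pvalue(m, probes), tolerance = 1e-12)
  }
})

test_that("the maximal score has p equal to the best-letter probability", {
  m <- random_pwm(4, seed = 77)
  lo <- log2(m$pwm / m$background[rownames(m$pwm)])
  best <- apply(lo, 2, which.max)
  max_score <- sum(lo[cbind(best, 1:4)])
  expect_equal(pwm_pvalue(m, max_score),
               prod(m$background[best]), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("p-values are monotone non-increasing in the score", {
  m <- random_pwm(5, seed = 13)
  dist <- pwm_score_distribution(m)
  grid <- seq(min(dist$score) - 1, max(dist$score) + 1, length.out = 200)
  p <- pwm_pvalue(m, grid, dist = dist)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("PWM scanning finds planted sites and respects alpha", {
  dnaa <- build_pwm(c("CTCCACA", "ATCCACA", "GTCCACA"), name = "DnaA",
                    background = c(A = .165, C = .335, G = .335, T = .165))
  set.seed(21)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE,
                                 prob = c(.165, .335, .335, .165)),
                          collapse = "")
  prom <- paste0(bg(41), "CTCCACA", bg(52))           # plant at -59
  h <- scan_pwm(prom, dnaa, alpha = 0.001)
  expect_true(-59 %in% h$offset)
  expect_true(all(h$p_value < 0.001))
  # random background: false hits are rare at alpha = 0.001
  nhits <- vapply(1:60, function(i) nrow(scan_pwm(bg(100), dnaa,
                                                  alpha = 0.001)),
                  numeric(1))
  expect_lt(mean(nhits), 0.2)
  # alpha = 1 reports every scored offset
  h_all <- scan_pwm(bg(100), dnaa, alpha = 1)
  expect_equal(nrow(h_all), 100 - 7 + 1)
})

test_that("CtrA binding modes map to offset bands", {
  expect_equal(classify_ctra_mode("CtrA_half", -14), "half_repressor")
  expect_equal(classify_ctra_mode("CtrA_full", -39), "full")
  expect_equal(classify_ctra_mode("CtrA_half", -60), "unclassified")
  expect_equal(classify_ctra_mode(c("CtrA_half", "CtrA_half"), c(-30, -10)),
               c("half_activator", "half_repressor"))
})

test_that("offset histograms and co-occurrence counts are exact", {
  h <- positions_histogram(c(-35, -35, -34))
  expect_equal(h$count[h$offset == -35], 2)
  expect_equal(h$count[h$offset == -34], 1)
  expect_equal(nrow(positions_histogram(numeric(0))), 0)
  co <- cooccurrence(list(t1 = "A", t2 = c("A", "B"), t3 = "B"))
  expect_equal(co$matrix["A", "B"], 1)
  expect_equal(co$matrix["A", "A"], 1)
  expect_equal(co$matrix["B", "B"], 1)
  expect_equal(unname(co$combination_counts[c("1", "2")]), c(2L, 1L))
  expect_equal(dim(cooccurrence(list())$matrix), c(0, 0))
})

test_that("ChIP fold enrichment is window mean over genome mean", {
  track <- rep(10, 2000)
  track[450:499] <- 30
  ce <- chip_enrichment(track, 500, "+")
  expect_equal(ce$fold, 30 / mean(track), tolerance = 1e-12)
  # the >= 3 flag boundary is inclusive: exactly 3-fold is enriched
  expect_true(chip_enrichment(track, 500, "+",
                              min_fold = 30 / mean(track))$enriched)
  track2 <- rep(10, 2000); track2[450:499] <- 29.9
  expect_false(chip_enrichment(track2, 500, "+",
                               min_fold = 30 / mean(track))$enriched)
  flat <- rep(7, 2000)
  expect_equal(chip_enrichment(flat, c(500, 1500), c("+", "-"))$fold,
               c(1, 1))
  expect_error(chip_enrichment(rep(0, 100), 50, "+"), "> 0")
})
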