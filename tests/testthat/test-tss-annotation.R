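test_that("genomic-context categories follow the positional rules", {
  ann <- toy_annotation()
  tss <- data.frame(
    pos = c(2100, 950, 1900, 1000, 1400, 5500, 6100, 8000),
    strand = c("+", "+", "+", "+", "+", "+", "-", "-"),
    stringsAsFactors = FALSE)
  ct <- categorize_tss(tss, ann)
  expect_equal(ct$category,
               c("AP",  # 50 bp upstream of cdsB, inside opposite cdsC
                 "P",   # 50 bp upstream of cdsA, intergenic
                 "IP",  # in cdsA's last 30%, 250 bp before cdsB start
                 "P",   # leaderless: first base of cdsA's start codon
                 "I",   # mid-cdsA, > 300 bp from the next start
                 "A",   # inside opposite-strand cdsD, no nearby start
                 "P",   # 100 bp upstream of minus-strand cdsD
                 "N"))  # intergenic, far from everything
  expect_equal(ct$assigned_cds[1:4], c("cdsB", "cdsA", "cdsB", "cdsA"))
  expect_equal(ct$assigned_cds[7], "cdsD")
  expect_true(all(nzchar(ct$category)))
})

test_that("N TSSs within 1 kb upstream of a CDS are flagged for review", {
  ann <- toy_annotation()
  ct <- categorize_tss(data.frame(pos = c(550, 8000), strand = "+"), ann)
  expect_equal(ct$category, c("N", "N"))
  expect_equal(ct$needs_review, c(TRUE, FALSE))
})

test_that("contribution filters apply share and level floors", {
  rec <- data.frame(
    id = c("a", "b", "c", "d", "e"),
    pos = c(100, 110, 300, 400, 500), strand = "+",
    plus = c(90, 9, 20, 80, 50),
    category = c("P", "P", "I", "I", "P"),
    assigned_cds = c("g1", "g1", "g2", "g2", "g3"),
    stringsAsFactors = FALSE)
  lv <- matrix(30, nrow = 5, ncol = 8,
               dimnames = list(NULL, paste0("t", seq(0, 140, 20))))
  lv[5, ] <- 1.5                     # P TSS whose best time point is 1.5
  rec <- cbind(rec, as.data.frame(lv))
  kept <- contribution_filter(rec)
  expect_setequal(kept$id, c("a", "d"))
  # b: 9/99 < 10%; c: 20% < 25%; e: max level 1.5 < 2
  expect_true(all(kept$share >
                    ifelse(kept$category == "P", 0.10, 0.25)))
  # shares within a CDS/strand group sum to <= 1 before filtering
  pre <- contribution_filter(rec, upstream_share = -1, internal_share = -1,
                             min_level_primary = 0, min_level_other = 0)
  expect_lte(max(tapply(pre$share, paste(pre$assigned_cds, pre$strand),
                        sum)), 1 + 1e-12)
})

test_that("multi-promoter genes are collected and ordered", {
  rec <- data.frame(
    id = c("p1", "p2", "p3", "q1"),
    pos = c(880, 978, 930, 2100), strand = "+",
    category = c("P", "P", "P", "P"),
    assigned_cds = c("cdsA", "cdsA", "cdsA", "cdsB"),
    stringsAsFactors = FALSE)
  mp <- find_multi_promoter_genes(rec)
  expect_equal(names(mp), "cdsA")           # cdsB has a single promoter
  expect_equal(nrow(mp$cdsA), 3)            # all three planted recovered
  expect_equal(mp$cdsA$id, c("p1", "p3", "p2"))
})

test_that("operon-internal TSSs serve downstream members only", {
  ann <- toy_annotation()                   # operon cdsA (1000-) -> cdsB
  rec <- data.frame(
    id = c("up", "mid"), pos = c(950, 2100), strand = "+",
    category = c("P", "P"), assigned_cds = c("cdsA", "cdsB"),
    regulated = c(TRUE, TRUE), stringsAsFactors = FALSE)
  oi <- find_operon_internal_tss(rec, ann)
  expect_equal(nrow(oi), 1)
  expect_equal(oi$assigned_cds, "cdsB")     # 'up' precedes the operon
  expect_equal(oi$downstream_members, "cdsB")
  expect_true(oi$regulated)
})

test_that("antisense pairing labels peak-time relationships", {
  ann <- toy_annotation()
  lv <- function(peak) { x <- rep(1, 8); x[peak / 20 + 1] <- 50; x }
  mk <- function(id, pos, strand, cat, cds, peak) {
    out <- data.frame(id = id, pos = pos, strand = strand, category = cat,
                      assigned_cds = cds, plus = 100,
                      stringsAsFactors = FALSE)
    out[paste0("t", seq(0, 140, 20))] <- as.list(lv(peak))
    out
  }
  rec <- rbind(
    mk("sense", 950, "+", "P", "cdsA", 40),
    mk("anti", 1500, "-", "A", "cdsA", 100),   # inside cdsA, opposite
    mk("anti2", 5500, "+", "A", "cdsD", 40))   # host cdsD has no primary
  pairs <- pair_antisense(rec, ann)
  a1 <- pairs[pairs$antisense_pos == 1500, ]
  expect_equal(a1$relationship, "anticorrelated")   # |100 - 40| = 60
  expect_equal(a1$delta_peak, 60)
  a2 <- pairs[pairs$antisense_pos == 5500, ]
  expect_true(is.na(a2$relationship))               # unpaired
  rec2 <- rbind(mk("sense", 950, "+", "P", "cdsA", 40),
                mk("anti", 1500, "-", "A", "cdsA", 40))
  expect_equal(pair_antisense(rec2, ann)$relationship, "correlated")
})

test_that("direction bias splits strands by replichore", {
  L <- 1000
  # ori at 1, ter at 501: plus strand on 1..501 is co-directional
  rec <- data.frame(pos = c(250, 250, 750, 750),
                    strand = c("+", "-", "-", "+"))
  db <- direction_bias(rec, ori = 1, ter = 501, genome_length = L)
  expect_equal(db$n_codirectional, 2)
  expect_equal(db$n_opposing, 2)
  # strand-symmetric random fixture: each side near half (binomial oracle)
  set.seed(4)
  n <- 4000
  rec2 <- data.frame(pos = sample.int(L, n, TRUE),
                     strand = sample(c("+", "-"), n, TRUE))
  db2 <- direction_bias(rec2, 1, 501, L)
  expect_lt(abs(db2$n_codirectional - n / 2), 3 * sqrt(n * 0.25))
})

test_that("density profile is circular and counts single TSSs exactly", {
  L <- 50000
  expect_true(all(density_profile(
    data.frame(pos = integer(), strand = character()), L)$plus == 0))
  one <- density_profile(data.frame(pos = 100, strand = "+"), L,
                         window = 10000, step = 1000)
  circ <- pmin(abs(one$center - 100), L - abs(one$center - 100))
  expect_equal(one$plus, as.numeric(circ <= 5000))
  expect_true(all(one$minus == 0))
  # uniform fixture: flat within 3 sqrt(expected)
  set.seed(10)
  recs <- data.frame(pos = sample.int(L, 2000, TRUE), strand = "+")
  dp <- density_profile(recs, L, window = 10000, step = 5000)
  expected <- 2000 * 10000 / L
  expect_true(all(abs(dp$plus - expected) <= 3 * sqrt(expected)))
})
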