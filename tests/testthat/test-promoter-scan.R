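neutral <- function(n) strrep("C", n)

test_that("hexamer matching counts identical bases, no gaps, N mismatches", {
  expect_equal(hexamer_match("TTGACA", "TTGACA"), 6L)
  expect_equal(hexamer_match("TTAACG", "TTGACA"), 4L)
  expect_equal(hexamer_match("AATAAT", "TATAAT"), 5L)
  expect_equal(hexamer_match("NNNNNN", "TTGACA"), 0L)
  expect_equal(hexamer_match("TTGACN", "TTGACA"), 5L)
  expect_error(hexamer_match("TTGAC", "TTGACA"), "length-6")
})

test_that("spacer bonus is 3/2/1 at 17/16,18/15,19 bp and 0 elsewhere", {
  expect_equal(spacer_length_score(17), 3L)
  expect_equal(spacer_length_score(16), 2L)
  expect_equal(spacer_length_score(18), 2L)
  expect_equal(spacer_length_score(15), 1L)
  expect_equal(spacer_length_score(19), 1L)
  expect_equal(spacer_length_score(14), 0L)
  expect_equal(spacer_length_score(c(20, 17, 0)), c(0L, 3L, 0L))
})

test_that("a perfect consensus construct scores the 15-point maximum", {
  seq <- paste0(neutral(10), "TTGACA", strrep("G", 17), "TATAAT", neutral(10))
  hits <- scan_sequence(seq, strand_mode = "forward")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$total, 15L)
  expect_equal(hits$pos35, 10L)
  expect_equal(hits$m35, 6L)
  expect_equal(hits$m10, 6L)
  expect_equal(hits$spacer_score, 3L)

  rc <- revcomp(seq)
  rhits <- scan_sequence(rc)
  minus <- rhits[rhits$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  expect_equal(minus$total, 15L)
  expect_equal(minus$seq35, "TTGACA")   # as read on the promoter strand
})

test_that("sequences below the 27-bp minimum footprint yield no hits", {
  expect_equal(nrow(scan_sequence(neutral(26))), 0L)
  expect_error(scan_sequence("TTGACAXX"), "alphabet")
})

test_that("retained hits satisfy the threshold predicate and score bounds", {
  set.seed(42)
  for (rep in 1:10) {
    g <- generate_genome(800, 0.45, seed = 100 + rep)
    hits <- scan_sequence(g)
    if (nrow(hits) == 0L) next
    expect_true(all(hits$total >= 0 & hits$total <= 15))
    expect_true(all(hits$m35 >= 4 & hits$m10 >= 4 & hits$m35 + hits$m10 >= 8))
    expect_true(all(hits$spacer_len %in% 15:19))
    expect_equal(hits$total, hits$m35 + hits$m10 + hits$spacer_score)
  }
  # strict thresholds exclude boundary hits
  g <- generate_genome(2000, 0.5, seed = 200)
  loose <- scan_sequence(g, scoring_scheme())
  strict <- scan_sequence(g, scoring_scheme(strict = TRUE))
  expect_true(all(strict$m35 > 4 & strict$m10 > 4))
  expect_lte(nrow(strict), nrow(loose))
})

test_that("scanning is involutive under reverse complement", {
  for (rep in 1:5) {
    g <- generate_genome(600, 0.5, seed = 300 + rep)
    fwd <- scan_sequence(g)
    rev <- scan_sequence(revcomp(g$seq))
    # mirror rev hits back: strand flips, pos35 maps through L - pos - 6
    L <- genome_length(g)
    rev$strand <- ifelse(rev$strand == "+", "-", "+")
    rev$pos35 <- L - rev$pos35 - 6L
    expect_setequal(hit_key(fwd), hit_key(rev))
  }
})

test_that("the scan agrees hit-for-hit with brute-force triple enumeration", {
  for (rep in 1:5) {
    g <- generate_genome(500, 0.5, seed = 400 + rep)
    fast <- scan_sequence(g)
    slow <- brute_scan(g$seq)
    expect_setequal(hit_key(fast), hit_key(slow))
  }
})

test_that("best-hit selection applies the documented tie-breaks", {
  h <- function(total, spacer, m10, pos) data.frame(
    strand = "+", pos35 = pos, seq35 = "TTGACA", spacer_len = spacer,
    seq10 = "TATAAT", m35 = 6L, m10 = m10, spacer_score = 0L, total = total)

  hits <- rbind(h(9, 17, 6, 0), h(14, 17, 6, 5), h(11, 17, 6, 9))
  expect_equal(best_hit(hits)$total, 14)

  tie1 <- rbind(h(12, 16, 6, 0), h(12, 17, 6, 5))
  expect_equal(best_hit(tie1)$spacer_len, 17)

  tie2 <- rbind(h(12, 17, 4, 0), h(12, 17, 6, 5))
  expect_equal(best_hit(tie2)$m10, 6L)

  tie3 <- rbind(h(12, 17, 6, 9), h(12, 17, 6, 2))
  expect_equal(best_hit(tie3)$pos35, 2)

  expect_null(best_hit(hits[0, ]))
  expect_null(best_hit(NULL))
})

test_that("compact table notation scores by the same scheme", {
  expect_equal(score_promoter_string("TTGACA-17-TATAAT"), 15L)
  expect_equal(score_promoter_string("TTGACA-18-TATAAT"), 14L)
  expect_equal(score_promoter_string("CCAGGG-17-CGCGGC"), 3L)  # 0 + 0 + 3
  expect_equal(score_promoter_string("AAAAAA-17-GGGGGG"), 5L)  # A matches at 4,6
  expect_error(score_promoter_string("TTGACA~17~TATAAT"), "malformed")
})

test_that("region scanning reports genome-wide coordinates with flank rescue", {
  g <- generate_genome(2000, 0.0, seed = 500)  # AT-only: no chance TTGACA
  pl <- plant_promoter(g, 510, "+", 6, 6, 17, seed = 501)
  # region starts downstream of the -35 box; the 20-bp flank recovers it
  regions <- data.frame(start = 520L, end = 700L)
  hits <- scan_regions(pl$genome, regions)
  best <- best_hit(hits[hits$total == 15, ])
  expect_equal(best$pos35, 510L)
  expect_equal(best$region, 1L)
})
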