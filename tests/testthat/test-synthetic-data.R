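test_that("genome generation is seed-deterministic and respects GC content", {
  g1 <- generate_genome(1000, 0.5, seed = 1)
  g2 <- generate_genome(1000, 0.5, seed = 1)
  expect_identical(g1$seq, g2$seq)
  expect_equal(genome_length(g1), 1000L)

  at_only <- generate_genome(1000, 0.0, seed = 2)
  expect_false(grepl("[GC]", at_only$seq))

  g <- generate_genome(100000, 0.5, seed = 3)
  gc <- (nchar(g$seq) - nchar(gsub("[GC]", "", g$seq))) / nchar(g$seq)
  # binomial bound: 3 sd of a proportion at n = 1e5, p = 0.5
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 1e5))

  expect_error(generate_genome(0, 0.5), "positive")
  expect_error(generate_genome(1000, 1.5), "gc_fraction")
})

test_that("gene layouts realize the requested spacer orientation classes", {
  g <- generate_genome(20000, 0.5, seed = 4)

  la <- plant_gene_layout(g, data.frame(type = "A", spacer_len = 500))
  expect_equal(nrow(la$genes), 2L)
  expect_equal(la$genes$strand, c("-", "+"))
  expect_equal(la$truth$end - la$truth$start, 500L)
  expect_equal(la$genes$start[2] - la$genes$end[1], 500L)

  lc <- plant_gene_layout(g, data.frame(type = "C", spacer_len = 200))
  expect_equal(lc$genes$strand, c("+", "-"))   # both point into the gap

  le <- plant_gene_layout(g, list())
  expect_equal(nrow(le$genes), 0L)
  expect_equal(nrow(le$truth), 0L)

  # every planted spacer classifies back to its requested type
  layout <- data.frame(type = c("A", "B", "C", "B", "A"),
                       spacer_len = c(300, 150, 200, 400, 250))
  big <- plant_gene_layout(g, layout)
  sp <- extract_spacers(big$genes)
  for (i in seq_len(nrow(big$truth))) {
    m <- sp[sp$start == big$truth$start[i] & sp$end == big$truth$end[i], ]
    expect_equal(m$type, big$truth$type[i])
  }

  tiny <- generate_genome(1000, 0.5, seed = 5)
  expect_error(plant_gene_layout(tiny, data.frame(type = "A", spacer_len = 500)),
               "exceeds genome length")
})

test_that("planted promoters have exactly the requested consensus agreement", {
  g <- generate_genome(2000, 0.5, seed = 6)

  perfect <- plant_promoter(g, 10, "+", 6, 6, 17, seed = 7)
  expect_equal(substr(perfect$genome$seq, 11, 16), "TTGACA")
  expect_equal(substr(perfect$genome$seq, 34, 39), "TATAAT")

  # recount round trip over the full grid of match counts and spacers
  for (m35 in 0:6) for (m10 in c(0L, 3L, 6L)) {
    pl <- plant_promoter(g, 50, "+", m35, m10, 16, seed = m35 * 10 + m10)
    box35 <- substr(pl$genome$seq, 51, 56)
    box10 <- substr(pl$genome$seq, 51 + 6 + 16, 56 + 6 + 16)
    expect_equal(hexamer_match(box35, "TTGACA"), m35)
    expect_equal(hexamer_match(box10, "TATAAT"), m10)
  }

  expect_error(plant_promoter(g, 1995, "+", 6, 6, 17), "footprint")
  expect_error(plant_promoter(g, 10, "+", 7, 6, 17), "match counts")
})

test_that("minus-strand plants are recovered by the scanner at mirrored coordinates", {
  g <- generate_genome(500, 0.5, seed = 8)
  pl <- plant_promoter(g, 100, "-", 6, 6, 17, seed = 9)
  hits <- scan_sequence(pl$genome)
  rec <- hits[hits$strand == "-" & hits$pos35 == pl$truth$pos35, ]
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$total, 15L)
  expect_equal(rec$seq35, "TTGACA")
  expect_equal(rec$seq10, "TATAAT")
})

test_that("array signal simulation matches its kernel arithmetic", {
  flat <- simulate_array_signal(5000, peaks = NULL, noise_sd = 0)
  expect_true(all(flat$cy5 / flat$cy3 == 1))
  expect_equal(flat$probe_start[1:3], c(0L, 105L, 210L))

  one <- simulate_array_signal(10000,
                               data.frame(center = 2100, amplitude = 99),
                               noise_sd = 0)
  r <- one$cy5 / one$cy3
  expect_equal(max(r), 100)
  expect_equal(one$probe_start[which.max(r)], 2100L)
  # triangular kernel half-width 150 > 105-bp spacing: neighbours elevated
  runs <- rle(r > 2)
  expect_gte(max(runs$lengths[runs$values]), 2L)

  two <- simulate_array_signal(10000,
                               data.frame(center = c(3150, 3550),
                                          amplitude = c(50, 50)),
                               noise_sd = 0)
  r2 <- two$cy5 / two$cy3
  elevated <- rle(r2 > 1.5)
  expect_equal(sum(elevated$values), 2L)   # two disjoint elevated runs

  expect_error(simulate_array_signal(1000, data.frame(center = 5000,
                                                      amplitude = 10)),
               "within the genome")
})

test_that("time-course simulation follows the saturating exponential", {
  expect_equal(simulate_time_course(100, 0.5, times = 0)$signal, 0)
  expect_equal(simulate_time_course(100, 0.5, times = 1e6)$signal, 100)
  expect_equal(simulate_time_course(100, 0.5, times = log(2) / 0.5)$signal,
               50, tolerance = 1e-12)
  expect_equal(simulate_time_course(1, 1)$time, c(0.5, 1, 2.5, 5, 7.5, 10, 15))
  expect_error(simulate_time_course(-1, 0.5), "amplitude")
  expect_error(simulate_time_course(1, 0), "rate_k")
})

test_that("silencer-site generator yields in-bounds AT-rich intervals", {
  g <- generate_genome(20000, 0.5, seed = 11)
  sites <- generate_hns_sites(g, 5, width = 120, seed = 12)
  expect_equal(nrow(sites), 5L)
  expect_true(all(sites$start >= 0 & sites$end <= genome_length(g)))
  at <- vapply(seq_len(nrow(sites)), function(i) {
    w <- genome_subseq(g, sites$start[i], sites$end[i])
    (nchar(w) - nchar(gsub("[AT]", "", w))) / nchar(w)
  }, 0)
  expect_true(all(at > 0.5))   # selected windows are AT-enriched
})

test_that("synthetic outputs survive FASTA/GFF3/BED round trips", {
  g <- generate_genome(5000, 0.5, seed = 13)
  fa <- tempfile(fileext = ".fa")
  write_genome_fasta(g, fa)
  g2 <- read_genome_fasta(fa)
  expect_equal(g2$seq, g$seq)

  lay <- plant_gene_layout(g, data.frame(type = c("A", "B"),
                                         spacer_len = c(300, 200)))
  lay$genes$operon <- c(NA, NA, "op1", "op1")
  gff <- tempfile(fileext = ".gff3")
  write_genes_gff3(lay$genes, gff)
  genes2 <- read_genes_gff3(gff)
  expect_equal(genes2$start, lay$genes$start)
  expect_equal(genes2$end, lay$genes$end)
  expect_equal(genes2$strand, lay$genes$strand)
  expect_equal(genes2$operon, lay$genes$operon)

  bed <- tempfile(fileext = ".bed")
  sites <- data.frame(start = c(10L, 400L), end = c(130L, 520L))
  write_bed(sites, bed)
  sites2 <- read_bed(bed)
  expect_equal(sites2$start, sites$start)
  expect_equal(sites2$end, sites$end)
})
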