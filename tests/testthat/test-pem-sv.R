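make_fr_pairs <- function(inserts, pos1 = NULL, chrom = "chr1",
                          sample_id = "S") {
  n <- length(inserts)
  if (is.null(pos1)) pos1 <- seq(1e5, by = 5000, length.out = n)
  as_pair_table(data.frame(
    sample_id = rep(sample_id, n), chrom1 = rep(chrom, n), pos1 = pos1,
    strand1 = rep("+", n), chrom2 = rep(chrom, n),
    pos2 = pos1 + inserts - 50, strand2 = rep("-", n),
    insert = inserts, stringsAsFactors = FALSE))
}

test_that("library stats are trim-robust and unbiased", {
  set.seed(7)
  ins <- round(rnorm(1e5, 2554, 719))
  st <- estimate_library_stats(make_fr_pairs(ins))
  expect_lt(abs(st$insert_mean - 2554) / 2554, 0.01)
  expect_lt(abs(st$insert_sd - 719) / 719, 0.05)
  st0 <- estimate_library_stats(make_fr_pairs(rep(2000, 2000)))
  expect_equal(st0$insert_mean, 2000)
  expect_equal(st0$insert_sd, 0)
  # 0.5% contamination at 50 kb falls in the trimmed tail
  contaminated <- make_fr_pairs(c(ins, rep(5e4, 500)))
  stc <- estimate_library_stats(contaminated)
  expect_lt(abs(stc$insert_mean - st$insert_mean) / st$insert_mean, 0.005)
  expect_error(estimate_library_stats(make_fr_pairs(rep(2000, 10))),
               "too few")
})

test_that("signature classification applies the 4 SD / order / strand rules", {
  st <- list(insert_mean = 2500, insert_sd = 700)
  p <- make_fr_pairs(c(2500, 5301, 5300, 100))
  expect_equal(classify_pairs(p, st),
               c("concordant", "deletion", "concordant", "concordant"))
  # short insert is only an insertion when mean - 4 sd is positive
  st2 <- list(insert_mean = 2500, insert_sd = 300)
  expect_equal(classify_pairs(p, st2)[4], "insertion")
  inter <- p; inter$chrom2 <- "chr2"; inter$insert <- -1
  expect_true(all(classify_pairs(inter, st) == "translocation"))
  ff <- p; ff$strand2 <- "+"
  expect_true(all(classify_pairs(ff, st) == "inversion"))
  rf <- p; rf$strand1 <- "-"; rf$strand2 <- "+"
  expect_true(all(classify_pairs(rf, st) == "duplication"))
})

test_that("clustering equals the connected-components oracle and honors support", {
  st <- list(insert_mean = 2500, insert_sd = 700)
  d_max <- 2500 + 4 * 700
  del <- function(n, at) make_fr_pairs(rep(5e4, n),
                                       pos1 = at + seq_len(n) * 100)
  # 2 linked pairs at support 3 -> nothing; 3 pairs -> one call
  expect_equal(nrow(cluster_anomalies(del(2, 1e5), st, 3)), 0)
  c3 <- cluster_anomalies(del(3, 1e5), st, 3)
  expect_equal(nrow(c3), 1)
  expect_equal(c3$support, 3)
  expect_equal(nrow(cluster_anomalies(del(0, 1e5), st, 1)), 0)
  # two loci far apart -> two calls
  two <- rbind(del(3, 1e5), del(3, 1e5 + 10 * d_max))
  expect_equal(nrow(cluster_anomalies(two, st, 3)), 2)
  # randomized oracle equivalence on <= 50 pairs
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:50, 1)
    pos1 <- sort(sample.int(3e5, n))
    p <- make_fr_pairs(rep(5e4, n), pos1 = pos1)
    calls <- cluster_anomalies(p, st, 1)
    oracle <- brute_components(p$pos1, p$pos2, d_max)
    expect_equal(nrow(calls), length(unique(oracle)))
    expect_equal(sort(calls$support), sort(as.vector(table(oracle))))
  }
})

test_that("strand/order filter drops internally inconsistent calls", {
  ok <- make_call("chr1", 1000, 1400, "chr1", 60000, 60400)
  expect_equal(nrow(filter_strand_order(ok)$retained), 1)
  mixed <- make_call("chr1", 1000, 1400, "chr1", 60000, 60400,
                     sv_type = "inversion", strand1 = "+", strand2 = "-")
  fs <- filter_strand_order(mixed)
  expect_equal(nrow(fs$retained), 0)
  expect_match(fs$removed$reason, "strand")
  overlapping <- make_call("chr1", 1000, 5000, "chr1", 2000, 3000)
  fo <- filter_strand_order(overlapping)
  expect_equal(nrow(fo$retained), 0)
  expect_match(fo$removed$reason, "order")
})

test_that("matched-control subtraction requires same-type overlap on both links", {
  tum <- make_call("chr1", 1000, 1400, "chr1", 60000, 60400)
  same <- tum; same$sample_id <- "C"; same$call_id <- "cc1"
  expect_equal(nrow(subtract_matched_control(tum, same)$retained), 0)
  # abutting but disjoint on one side (gap >= 1 bp) -> retained
  shifted <- same; shifted$start2 <- 60400; shifted$end2 <- 60800
  expect_equal(nrow(subtract_matched_control(tum, shifted)$retained), 1)
  other_type <- same; other_type$sv_type <- "duplication"
  other_type$strand1 <- "-"; other_type$strand2 <- "+"
  expect_equal(nrow(subtract_matched_control(tum, other_type)$retained), 1)
  expect_equal(nrow(subtract_matched_control(tum, same[0, ])$retained), 1)
})

test_that("implanted SVs of every class are recovered with correct type", {
  g <- test_genome()
  svs <- rbind(
    sv_event("deletion", "chr1", 2e6, pos2 = 2.05e6, zygosity = "homozygous"),
    sv_event("duplication", "chr1", 5e6, pos2 = 5.08e6, zygosity = "homozygous"),
    sv_event("inversion", "chr2", 3e6, pos2 = 3.1e6, zygosity = "homozygous"),
    sv_event("insertion", "chr3", 4e6, size = 1200, zygosity = "homozygous"),
    sv_event("translocation", "chr4", 6e6, chrom2 = "chr5", pos2 = 2e6,
             zygosity = "homozygous"))
  p <- simulate_read_pairs(g, tight_plan(166667, seed = 77), svs = svs)
  calls <- detect_svs(p, min_support = 3)
  st <- estimate_library_stats(p)
  slack <- st$insert_mean + 4 * st$insert_sd
  for (i in seq_len(nrow(svs))) {
    ev <- svs[i, ]
    hit <- calls$sv_type == ev$sv_type & calls$chrom1 == ev$chrom1 &
      abs((calls$start1 + calls$end1) / 2 - ev$pos1) < slack
    expect_true(any(hit), info = ev$sv_type)
  }
  # breakpoint accuracy: inner edge of the deletion call's left link
  del <- calls[calls$sv_type == "deletion", ][1, ]
  expect_lt(abs(del$end1 - 2e6), slack)
  expect_lt(abs(del$start2 - 2.05e6), slack)
})
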