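test_that("minimum window size matches the exhaustive scan and scales with depth", {
  w <- minimum_window_size(1e6, 1e6, 5e7, 1e-4, 0.6)
  # independent oracle: 1-bp scan of the same criterion
  z <- qnorm(1 - 1e-4 / 2)
  crit <- function(w) {
    mu_x <- 1e6 * w / 5e7; mu_y <- mu_x; T <- 2^0.6
    abs((mu_y * T - mu_x) / sqrt(mu_y * T^2 + mu_x)) >= z
  }
  scan <- which(vapply(1:20000, crit, logical(1)))[1]
  expect_equal(w, scan)
  # doubling both read totals halves the window (N*w invariant)
  w2 <- minimum_window_size(2e6, 2e6, 5e7, 1e-4, 0.6)
  expect_lte(abs(w2 - w / 2), 1)
  # monotonicity: shallower ratio needs a larger window
  expect_gt(minimum_window_size(1e6, 1e6, 5e7, 1e-4, 0.3), w)
  expect_error(minimum_window_size(100, 100, 5e7, 1e-12, 0.001),
               "did not converge")
})

test_that("window counting conserves totals and respects the partial-window rule", {
  g <- genome_spec("chrA", 10000)
  mk <- function(pos) as_pair_table(data.frame(
    sample_id = "S", chrom1 = "chrA", pos1 = pos, strand1 = "+",
    chrom2 = "chrA", pos2 = pos + 200, strand2 = "-", insert = 250))
  p <- mk(rep(0, 10))
  w <- count_windows(p, mk(5), g, window = 1000, step = 500)
  expect_equal(w$count_t[1], 10)
  expect_equal(w$count_t[2], 0)
  # non-overlapping tiling: counts sum to the number of fragments
  p2 <- mk(sort(sample.int(9999, 500)) - 1)
  w2 <- count_windows(p2, p2, g, window = 1000, step = 1000)
  expect_equal(sum(w2$count_t), 500)
  # 10 kb genome, window 3 kb step 1.5 kb: last start 9000 gives a 1 kb
  # partial window < step, dropped; start 7500 gives 2.5 kb, kept
  w3 <- count_windows(p, p, g, window = 3000, step = 1500)
  expect_equal(max(w3$start), 7500)
  expect_equal(w3$end[w3$start == 7500], 10000)
  expect_error(count_windows(mk(1), mk(1),
                             genome_spec("chrB", 1000), 100, 50),
               "unknown chromosome.*chrA")
})

test_that("ratio p-values match hand computation and are calibrated under the null", {
  win <- data.frame(chrom = "c", start = 0, end = 1, count_t = 150,
                    count_c = 100)
  r <- compute_ratios(win, 1e7, 1e7)
  expect_equal(r$log2_ratio, log2(1.5), tolerance = 1e-6)
  expect_equal(r$p_value, 0.00193, tolerance = 2e-3)
  r0 <- compute_ratios(data.frame(chrom = "c", start = 0, end = 1,
                                  count_t = 120, count_c = 120), 1e7, 1e7)
  expect_equal(r0$log2_ratio, 0)
  expect_equal(r0$p_value, 1)
  # zero control count -> excluded (NA)
  rz <- compute_ratios(data.frame(chrom = "c", start = 0, end = 1,
                                  count_t = 5, count_c = 0), 1e7, 1e7)
  expect_true(is.na(rz$log2_ratio) && is.na(rz$p_value))
  # null calibration: paired Poisson counts give ~uniform p-values
  set.seed(42)
  n <- 5000
  win <- data.frame(chrom = "c", start = seq_len(n), end = seq_len(n) + 1,
                    count_t = rpois(n, 500), count_c = rpois(n, 500))
  p <- compute_ratios(win, 1e7, 1e7)$p_value
  # counts are discrete so tied p-values are expected; KS is approximate
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("kernel smoothing reproduces the closed form and its limits", {
  win <- data.frame(chrom = "c", start = c(0, 1000, 2000),
                    end = c(1000, 2000, 3000),
                    count_t = 1, count_c = 1, p_value = 1,
                    log2_ratio = c(0, 1, 0))
  s <- smooth_ratios(win, bandwidth = 1)
  expect_equal(s$smoothed_ratio[2], 1 / (1 + 2 * exp(-0.5)),
               tolerance = 1e-6)
  # constant track is a fixed point
  win$log2_ratio <- 0.7
  expect_equal(smooth_ratios(win, 2)$smoothed_ratio, rep(0.7, 3))
  # bandwidth -> 0 recovers the raw track
  win$log2_ratio <- c(-1, 2, 0.3)
  s0 <- smooth_ratios(win, bandwidth = 1e-3)
  expect_lt(max(abs(s0$smoothed_ratio - win$log2_ratio)), 1e-6)
  # smoothing never crosses chromosome boundaries
  win2 <- win
  win2$chrom <- c("c1", "c1", "c2")
  s2 <- smooth_ratios(win2, 2)
  expect_equal(s2$smoothed_ratio[3], 0.3)
})

test_that("per-chromosome BH limits follow the step-up rule", {
  win <- data.frame(chrom = "c", start = 0:3 * 1000, end = 1:4 * 1000,
                    count_t = 1, count_c = 1,
                    log2_ratio = c(0.9, 0.6, 0.5, 0.2),
                    p_value = c(1e-6, 5e-5, 2e-4, 0.1),
                    smoothed_ratio = c(0.8, 0.5, 0.4, 0.1))
  sl <- significance_limits(win, bh_alpha = 1e-4)
  # BH at alpha 1e-4, m = 4 keeps the two smallest p-values
  expect_equal(sum(sl$windows$bh_significant), 2)
  expect_equal(sl$limits$limit, 0.5)
  expect_equal(sl$windows$significant, c("gain", "gain", "none", "none"))
  win$p_value <- 1
  sl1 <- significance_limits(win, 1e-4)
  expect_true(is.na(sl1$limits$limit))
  expect_true(all(sl1$windows$significant == "none"))
})

test_that("region merging matches a run-length oracle on the window flags", {
  mk <- function(flags) data.frame(
    chrom = "c", start = seq_along(flags) * 1000 - 1000,
    end = seq_along(flags) * 1000, smoothed_ratio = 0.5,
    significant = flags, stringsAsFactors = FALSE)
  expect_equal(nrow(call_regions(mk(rep("none", 6)))), 0)
  flags <- c("gain", "gain", "none", "none", "gain", "gain")
  reg <- call_regions(mk(flags))
  expect_equal(nrow(reg), 2)
  rle_oracle <- sum(rle(flags)$values != "none")
  expect_equal(nrow(reg), rle_oracle)
  # adjacent runs of opposite sign stay separate regions
  flags2 <- c("gain", "gain", "loss", "loss")
  expect_equal(call_regions(mk(flags2))$direction, c("gain", "loss"))
})

test_that("implanted copy-number segments are recovered with sign and size", {
  g <- test_genome()
  cn <- rbind(cn_segment("chr2", 2e6, 7e6, 1),  # single-copy loss
              cn_segment("chr4", 3e6, 8e6, 3))  # single-copy gain
  tum <- simulate_read_pairs(g, wide_plan(1e5, seed = 61), cn = cn,
                             sample_id = "T")
  ctl <- simulate_read_pairs(g, wide_plan(1e5, seed = 62), sample_id = "C")
  doc <- run_doc_cnv(tum, ctl, g)
  loss <- doc$regions[doc$regions$direction == "loss", ]
  gain <- doc$regions[doc$regions$direction == "gain", ]
  expect_equal(nrow(loss), 1)
  expect_equal(loss$chrom, "chr2")
  recip <- function(reg, s, e) {
    ov <- min(reg$end, e) - max(reg$start, s)
    min(ov / (e - s), ov / (reg$end - reg$start))
  }
  expect_gt(recip(loss, 2e6, 7e6), 0.9)
  main_gain <- gain[which.max(gain$end - gain$start), ]
  expect_equal(main_gain$chrom, "chr4")
  expect_gt(recip(main_gain, 3e6, 8e6), 0.9)
  # plateau accuracy: windows interior to the implanted segment, clear of
  # the smoothing ramp (one kernel bandwidth at each edge)
  plateau_mean <- function(chrom, s, e) {
    margin <- 2 * doc$window
    w <- doc$windows
    mid <- (w$start + w$end) / 2
    mean(w$smoothed_ratio[w$chrom == chrom & mid >= s + margin &
                            mid <= e - margin], na.rm = TRUE)
  }
  expect_lt(abs(plateau_mean("chr2", 2e6, 7e6) - log2(1 / 2)), 0.15)
  expect_lt(abs(plateau_mean("chr4", 3e6, 8e6) - log2(3 / 2)), 0.15)
})
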