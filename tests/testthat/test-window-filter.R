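test_that("link distances and the both-links rule follow the +/-3 kb window", {
  expect_equal(link_distance("c", 100, 200, "c", 150, 300), 0)
  expect_equal(link_distance("c", 100, 200, "c", 500, 600), 300)
  expect_equal(link_distance("c1", 100, 200, "c2", 100, 200), Inf)
  tum <- make_call("chr1", 10000, 10400, "chr5", 20000, 20400,
                   sv_type = "translocation")
  ctl_hit <- make_call("chr1", 12500, 12900, "chr5", 18200, 18600,
                       sv_type = "inversion", strand1 = "+", strand2 = "+",
                       sample_id = "C", call_id = "g1")
  # gaps 2100 and 1400, both <= 3000; type mismatch is irrelevant
  wf <- window_filter(tum, ctl_hit, 3000)
  expect_equal(nrow(wf$retained), 0)
  expect_equal(wf$removal_log$control_call_id, "g1")
  expect_equal(wf$removal_log$dist_link1, 2100)
  expect_equal(wf$removal_log$dist_link2, 1400)
  # one link out of range (gap 3600) -> retained: both links must match
  ctl_miss <- ctl_hit
  ctl_miss$start2 <- 24000; ctl_miss$end2 <- 24400
  expect_equal(nrow(window_filter(tum, ctl_miss, 3000)$retained), 1)
  # link pairing is tried in both orders
  swapped <- make_call("chr5", 18200, 18600, "chr1", 12500, 12900,
                       sample_id = "C", call_id = "g2")
  expect_equal(nrow(window_filter(tum, swapped, 3000)$retained), 0)
  expect_equal(nrow(window_filter(tum, ctl_hit[0, ], 3000)$retained), 1)
})

test_that("cascade counts are monotone and panel idempotence holds", {
  set.seed(9)
  n <- 40
  mk_rand <- function(m, sample_id, seed) {
    set.seed(seed)
    do.call(rbind, lapply(seq_len(m), function(i)
      make_call("chr1", p1 <- sample.int(9e6, 1), p1 + 400,
                "chr1", p2 <- p1 + 5e5 + sample.int(1e5, 1), p2 + 400,
                sample_id = sample_id, call_id = paste0(sample_id, "_", i))))
  }
  tum <- mk_rand(n, "T", 1)
  ctl <- mk_rand(15, "C", 2)    # some will fall near tumor calls
  panel <- list(ctl, mk_rand(15, "P1", 3), mk_rand(15, "P2", 4))
  res <- filter_cascade(tum, ctl, panel, window = 3000)
  expect_lte(res$n_after_wf2, res$n_after_wf1)
  expect_lte(res$n_after_wf1, res$n_input)
  expect_equal(nrow(res$retained), res$n_after_wf2)
  # panel = matched control only: stage 2 removes nothing further
  res2 <- filter_cascade(tum, ctl, list(ctl), window = 3000)
  expect_equal(res2$n_after_wf2, res2$n_after_wf1)
  # a larger panel never increases retained calls
  expect_lte(res$n_after_wf2, res2$n_after_wf2)
})

test_that("soundness: calls with no control within the window survive", {
  tum <- rbind(make_call("chr1", 1e6, 1e6 + 400, "chr1", 2e6, 2e6 + 400),
               make_call("chr2", 5e6, 5e6 + 400, "chr3", 6e6, 6e6 + 400,
                         sv_type = "translocation", call_id = "c2"))
  far <- make_call("chr1", 1e6 + 5000, 1e6 + 5400, "chr1", 2e6 + 5000,
                   2e6 + 5400, sample_id = "C", call_id = "far")
  res <- filter_cascade(tum, far, list(far), window = 3000)
  expect_equal(res$n_after_wf2, 2)
  expect_equal(nrow(res$removal_log), 0)
})

test_that("removal decisions equal the brute-force all-pairs oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    mk <- function(m, id) do.call(rbind, lapply(seq_len(m), function(i) {
      c1 <- sample(paste0("chr", 1:3), 1)
      p1 <- sample.int(1e6, 1); p2 <- sample.int(1e6, 1)
      make_call(c1, p1, p1 + 300, sample(paste0("chr", 1:3), 1), p2,
                p2 + 300, sample_id = id, call_id = paste0(id, i))
    }))
    tum <- mk(50, "T"); ctl <- mk(50, "C")
    got <- window_filter(tum, ctl, 3000)
    dist1 <- function(ca, sa, ea, cb, sb, eb)
      if (ca != cb) Inf else max(0, max(sa, sb) - min(ea, eb))
    oracle_removed <- vapply(seq_len(nrow(tum)), function(i) {
      any(vapply(seq_len(nrow(ctl)), function(j) {
        straight <-
          dist1(tum$chrom1[i], tum$start1[i], tum$end1[i],
                ctl$chrom1[j], ctl$start1[j], ctl$end1[j]) <= 3000 &&
          dist1(tum$chrom2[i], tum$start2[i], tum$end2[i],
                ctl$chrom2[j], ctl$start2[j], ctl$end2[j]) <= 3000
        crossed <-
          dist1(tum$chrom1[i], tum$start1[i], tum$end1[i],
                ctl$chrom2[j], ctl$start2[j], ctl$end2[j]) <= 3000 &&
          dist1(tum$chrom2[i], tum$start2[i], tum$end2[i],
                ctl$chrom1[j], ctl$start1[j], ctl$end1[j]) <= 3000
        straight || crossed
      }, logical(1)))
    }, logical(1))
    expect_equal(got$removed$call_id, tum$call_id[oracle_removed])
  }
})

test_that("retention percentages use half-up one-decimal rounding", {
  expect_equal(retention_pct(200, 553), 36.2)
  expect_equal(retention_pct(35, 553), 6.3)
  expect_equal(retention_pct(445, 625), 71.2)
  expect_equal(retention_pct(7, 625), 1.1)
  expect_equal(retention_pct(1, 16), 6.3)   # 6.25 rounds half-up
  expect_true(is.na(retention_pct(0, 0)))
})
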