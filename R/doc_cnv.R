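#' Depth-of-coverage CNV configuration
#'
#' Parameters of the windowed tumor/control copy-number ratio analysis.
#'
#' @param p_prime Confidence level used to derive the minimum window size
#'   (default 1e-4).
#' @param r_prime Log2 ratio the minimum window must resolve (default 0.6).
#' @param window_multiplier The analysis window is this multiple of the
#'   minimum window (default 4).
#' @param step_fraction Sliding step as a fraction of the window (default
#'   0.5, the usual half-overlap convention).
#' @param kernel_bandwidth Gaussian smoothing bandwidth in window widths
#'   (default 2).
#' @param bh_alpha Per-chromosome Benjamini-Hochberg FDR level (default
#'   1e-4).
#' @return A `doc_config` list.
#' @export
doc_config <- function(p_prime = 1e-4, r_prime = 0.6, window_multiplier = 4,
                       step_fraction = 0.5, kernel_bandwidth = 2,
                       bh_alpha = 1e-4) {
  stopifnot(p_prime > 0, r_prime != 0, window_multiplier > 0,
            step_fraction > 0, step_fraction <= 1, kernel_bandwidth > 0,
            bh_alpha > 0)
  structure(list(p_prime = p_prime, r_prime = r_prime,
                 window_multiplier = window_multiplier,
                 step_fraction = step_fraction,
                 kernel_bandwidth = kernel_bandwidth, bh_alpha = bh_alpha),
            class = "doc_config")
}

# Geary-Hinkley t statistic for an observed count ratio T = x/y against
# null expectations mu_x, mu_y (ratio-of-Poissons normal approximation)
gh_t <- function(T, mu_x, mu_y) {
  (mu_y * T - mu_x) / sqrt(mu_y * T^2 + mu_x)
}

#' Minimum window size resolving a given log2 ratio
#'
#' Smallest window (bp) at which a window whose true tumor/control density
#' ratio is `2^r_prime` reaches two-sided significance `p_prime` under the
#' Geary-Hinkley ratio test, given total read counts and genome length. The
#' analysis window used downstream is `window_multiplier` times this value.
#' The criterion: with null expectations `mu_x = n_reads_t*w/G`,
#' `mu_y = n_reads_c*w/G` and alternative ratio `T = 2^r_prime *
#' n_reads_t/n_reads_c`, the statistic `t = (mu_y*T - mu_x)/sqrt(mu_y*T^2 +
#' mu_x)` must satisfy `|t| >= qnorm(1 - p_prime/2)`. `|t|` grows as
#' `sqrt(w)`, so the boundary is found by bisection on integers.
#'
#' @param n_reads_t,n_reads_c Total mapped reads in tumor and control.
#' @param genome_length Genome length G in bp.
#' @param p_prime,r_prime See [doc_config()]; `r_prime` may be negative to
#'   size for a loss.
#' @return Minimum window size in bp (integer).
#' @export
minimum_window_size <- function(n_reads_t, n_reads_c, genome_length,
                                p_prime = 1e-4, r_prime = 0.6) {
  stopifnot(n_reads_t > 0, n_reads_c > 0, genome_length > 0, p_prime > 0,
            r_prime != 0)
  z <- stats::qnorm(1 - p_prime / 2)
  crit <- function(w) {
    mu_x <- n_reads_t * w / genome_length
    mu_y <- n_reads_c * w / genome_length
    T <- 2^r_prime * n_reads_t / n_reads_c
    abs(gh_t(T, mu_x, mu_y)) >= z
  }
  if (crit(1)) return(1L)
  lo <- 1
  hi <- 100
  while (!crit(hi)) {
    lo <- hi
    hi <- hi * 2
    if (hi > genome_length)
      stop("minimum window size did not converge within the genome length")
  }
  while (hi - lo > 1) {             # invariant: !crit(lo), crit(hi)
    mid <- (lo + hi) %/% 2
    if (crit(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Count fragment starts in sliding windows
#'
#' Counts the leftmost read start of each pair (one count per fragment).
#' The two reads of a pair are not independent depth observations — they
#' sit one insert apart on the same fragment — so counting both would
#' double the variance of window counts and break the Poisson calibration
#' of the ratio p-values; fragment starts are counted instead.
#'
#' @param tumor_pairs,control_pairs Pair tables.
#' @param genome A [genome_spec()].
#' @param window Window width in bp.
#' @param step Sliding step in bp (`step <= window`). The final partial
#'   window of a chromosome is kept if it is at least `step` long.
#' @return data.frame of `RatioWindow` rows: `chrom`, `start`, `end`,
#'   `count_t`, `count_c`.
#' @export
count_windows <- function(tumor_pairs, control_pairs, genome, window, step) {
  stopifnot(window >= step, step > 0)
  reads_t <- data.frame(chrom = tumor_pairs$chrom1, pos = tumor_pairs$pos1)
  reads_c <- data.frame(chrom = control_pairs$chrom1,
                        pos = control_pairs$pos1)
  for (rd in list(reads_t, reads_c)) {
    unk <- setdiff(unique(rd$chrom), genome$chrom)
    if (length(unk))
      stop("unknown chromosome(s) in pairs: ", paste(unk, collapse = ", "))
  }
  res <- lapply(seq_len(nrow(genome)), function(i) {
    chrom <- genome$chrom[i]; len <- genome$length[i]
    starts <- seq(0, max(len - step, 0), by = step)
    ends <- pmin(starts + window, len)
    keep <- ends - starts >= step
    starts <- starts[keep]; ends <- ends[keep]
    pt <- sort(reads_t$pos[reads_t$chrom == chrom])
    pc <- sort(reads_c$pos[reads_c$chrom == chrom])
    count_in <- function(pos, s, e) {
      if (!length(pos)) return(rep(0L, length(s)))
      findInterval(e - 0.5, pos) - findInterval(s - 0.5, pos)
    }
    data.frame(chrom = chrom, start = starts, end = ends,
               count_t = count_in(pt, starts, ends),
               count_c = count_in(pc, starts, ends),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Log2 ratios and Geary-Hinkley p-values per window
#'
#' The log2 ratio is the globally normalized density ratio
#' `log2((x/N_x)/(y/N_y))`. The two-sided p-value treats the window's
#' tumor/control counts as a ratio of Poisson variables with a pooled null
#' density `lambda = (x+y)/(N_x+N_y)`: `mu_x = lambda*N_x`,
#' `mu_y = lambda*N_y`, `T = x/y`, `t = (mu_y*T - mu_x)/sqrt(mu_y*T^2 +
#' mu_x)`, `p = 2*(1 - pnorm(|t|))`. Windows with zero control count get
#' `NA` ratio and p-value and are excluded from downstream significance.
#'
#' @param windows Output of [count_windows()].
#' @param n_reads_t,n_reads_c Total mapped reads per sample (globally, not
#'   per window).
#' @return `windows` with added columns `log2_ratio`, `p_value`.
#' @export
compute_ratios <- function(windows, n_reads_t, n_reads_c) {
  stopifnot(n_reads_t > 0, n_reads_c > 0)
  x <- windows$count_t; y <- windows$count_c
  ok <- y > 0
  log2_ratio <- rep(NA_real_, nrow(windows))
  p_value <- rep(NA_real_, nrow(windows))
  log2_ratio[ok] <- log2((x[ok] / n_reads_t) / (y[ok] / n_reads_c))
  lambda <- (x + y) / (n_reads_t + n_reads_c)
  mu_x <- lambda * n_reads_t
  mu_y <- lambda * n_reads_c
  t_stat <- gh_t(x[ok] / y[ok], mu_x[ok], mu_y[ok])
  p_value[ok] <- 2 * (1 - stats::pnorm(abs(t_stat)))
  windows$log2_ratio <- log2_ratio
  windows$p_value <- p_value
  windows
}

#' Parzen-Rosenblatt smoothing of the ratio track
#'
#' Nadaraya-Watson kernel regression of the log2 ratios over window
#' midpoints with a Gaussian kernel `K(u) = exp(-u^2/2)`, where `u` is
#' genomic distance in units of `bandwidth * window width`. Smoothing never
#' crosses chromosome boundaries; windows with undefined ratio contribute
#' nothing and keep an `NA` smoothed value.
#'
#' @param windows Output of [compute_ratios()].
#' @param bandwidth Kernel bandwidth in window widths.
#' @return `windows` with added column `smoothed_ratio`.
#' @export
smooth_ratios <- function(windows, bandwidth = 2) {
  stopifnot(bandwidth > 0)
  windows$smoothed_ratio <- NA_real_
  for (chrom in unique(windows$chrom)) {
    idx <- which(windows$chrom == chrom)
    sub <- windows[idx, ]
    ok <- !is.na(sub$log2_ratio)
    if (!any(ok)) next
    mid <- (sub$start + sub$end) / 2
    width <- stats::median(sub$end - sub$start)
    h <- bandwidth * width
    m_ok <- mid[ok]; r_ok <- sub$log2_ratio[ok]
    sm <- vapply(seq_along(mid), function(j) {
      if (!ok[j]) return(NA_real_)
      w <- exp(-((mid[j] - m_ok) / h)^2 / 2)
      sum(w * r_ok) / sum(w)
    }, numeric(1))
    windows$smoothed_ratio[idx] <- sm
  }
  windows
}

#' Per-chromosome Benjamini-Hochberg significance limits
#'
#' Applies BH step-up at level `bh_alpha` to each chromosome's window
#' p-values; the chromosome's symmetric significance limit is the smallest
#' `|smoothed_ratio|` among its BH-significant windows (reported as a
#' `+/-limit` band), `NA` when nothing passes. Each window is flagged
#' `gain`, `loss` or `none`: significant windows are BH-significant with
#' `|smoothed_ratio|` at or beyond the chromosome limit, signed by the
#' smoothed ratio.
#'
#' @param windows Output of [smooth_ratios()].
#' @param bh_alpha FDR level.
#' @return List with `limits` (data.frame `chrom`, `limit`) and `windows`
#'   (input with added columns `bh_significant`, `significant`).
#' @export
significance_limits <- function(windows, bh_alpha = 1e-4) {
  windows$bh_significant <- FALSE
  windows$significant <- "none"
  lims <- data.frame(chrom = unique(windows$chrom), limit = NA_real_,
                     stringsAsFactors = FALSE)
  for (k in seq_len(nrow(lims))) {
    chrom <- lims$chrom[k]
    idx <- which(windows$chrom == chrom & !is.na(windows$p_value))
    if (!length(idx)) next
    adj <- stats::p.adjust(windows$p_value[idx], method = "BH")
    sig <- adj <= bh_alpha
    windows$bh_significant[idx[sig]] <- TRUE
    if (any(sig)) {
      lim <- min(abs(windows$smoothed_ratio[idx[sig]]), na.rm = TRUE)
      lims$limit[k] <- lim
      pass <- idx[sig][!is.na(windows$smoothed_ratio[idx[sig]]) &
                         abs(windows$smoothed_ratio[idx[sig]]) >= lim]
      windows$significant[pass] <-
        ifelse(windows$smoothed_ratio[pass] > 0, "gain", "loss")
    }
  }
  list(limits = lims, windows = windows)
}

#' Merge significant windows into copy-number regions
#'
#' Maximal runs of consecutive windows on one chromosome that are flagged
#' significant with the same sign are merged (sliding overlap included)
#' into regions reporting span, mean smoothed ratio and direction.
#'
#' @param windows `windows` element of [significance_limits()] output.
#' @return data.frame with `chrom`, `start`, `end`, `n_windows`,
#'   `mean_smoothed_ratio`, `direction` (`gain`/`loss`).
#' @export
call_regions <- function(windows) {
  out <- list()
  for (chrom in unique(windows$chrom)) {
    sub <- windows[windows$chrom == chrom, ]
    sub <- sub[order(sub$start), ]
    state <- sub$significant
    n <- nrow(sub)
    if (!n) next
    run_id <- cumsum(c(TRUE, state[-1] != state[-n]))
    for (r in unique(run_id)) {
      rows <- sub[run_id == r, ]
      dir <- rows$significant[1]
      if (dir == "none") next
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = min(rows$start), end = max(rows$end),
        n_windows = nrow(rows),
        mean_smoothed_ratio = mean(rows$smoothed_ratio),
        direction = dir, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      mean_smoothed_ratio = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Full depth-of-coverage CNV analysis of one tumor/control sample pair
#'
#' Derives the window size from the read totals (unless `window` is given),
#' counts sliding windows, computes ratios and p-values, smooths, applies
#' per-chromosome BH limits and merges significant regions.
#'
#' @param tumor_pairs,control_pairs Pair tables.
#' @param genome A [genome_spec()].
#' @param config A [doc_config()].
#' @param window Optional explicit window size (bp) overriding the derived
#'   `window_multiplier * minimum` size.
#' @return List: `window`, `min_window`, `windows`, `limits`, `regions`.
#' @export
run_doc_cnv <- function(tumor_pairs, control_pairs, genome,
                        config = doc_config(), window = NULL) {
  n_t <- nrow(tumor_pairs)
  n_c <- nrow(control_pairs)
  G <- genome_length(genome)
  min_w <- minimum_window_size(n_t, n_c, G, config$p_prime, config$r_prime)
  if (is.null(window)) window <- config$window_multiplier * min_w
  step <- max(1, round(window * config$step_fraction))
  w <- count_windows(tumor_pairs, control_pairs, genome, window, step)
  w <- compute_ratios(w, n_t, n_c)
  w <- smooth_ratios(w, config$kernel_bandwidth)
  sl <- significance_limits(w, config$bh_alpha)
  regions <- call_regions(sl$windows)
  list(window = window, min_window = min_w, windows = sl$windows,
       limits = sl$limits, regions = regions)
}
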