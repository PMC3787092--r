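#' Count read starts in fixed genomic tiles
#'
#' Non-overlapping tiling of each chromosome (default 5 Mbp; the last tile
#' of a chromosome may be short). Both reads of each pair are counted at
#' their start positions.
#'
#' @param pairs A pair table.
#' @param genome A [genome_spec()].
#' @param tile Tile width in bp (default 5e6).
#' @return data.frame `chrom`, `start`, `end`, `raw`.
#' @export
tile_counts <- function(pairs, genome, tile = 5e6) {
  stopifnot(tile > 0)
  reads <- pairs_to_reads(pairs)
  unk <- setdiff(unique(reads$chrom), genome$chrom)
  if (length(unk))
    stop("unknown chromosome(s) in pairs: ", paste(unk, collapse = ", "))
  res <- lapply(seq_len(nrow(genome)), function(i) {
    chrom <- genome$chrom[i]; len <- genome$length[i]
    starts <- seq(0, len - 1, by = tile)
    ends <- pmin(starts + tile, len)
    pos <- sort(reads$pos[reads$chrom == chrom])
    cnt <- if (length(pos))
      findInterval(ends - 0.5, pos) - findInterval(starts - 0.5, pos)
    else rep(0L, length(starts))
    data.frame(chrom = chrom, start = starts, end = ends, raw = cnt,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Normalize tile counts to 10 million reads per sample
#'
#' @param tiles Output of [tile_counts()].
#' @param target Total to scale to (default 1e7).
#' @return `tiles` with added column `normalized`.
#' @export
normalize_counts <- function(tiles, target = 1e7) {
  total <- sum(tiles$raw)
  if (total <= 0) stop("sample has zero reads: cannot normalize")
  tiles$normalized <- tiles$raw * (target / total)
  tiles
}

#' Z-scores of a sample against a control panel
#'
#' Per tile, `z = (c - mean(controls)) / sd(controls)` where `c` is the
#' sample's normalized count and mean/SD (denominator n-1) are taken over
#' the control panel's normalized counts for that tile. Tiles where the
#' control SD is zero get `NA`. The reference analysis uses a panel of 5
#' control genomes; at least 2 are required.
#'
#' @param sample_tiles Normalized tile table for the sample
#'   ([normalize_counts()] output).
#' @param control_tiles List of normalized tile tables for the controls,
#'   all on the identical tiling.
#' @return `sample_tiles` with added column `z`.
#' @export
zscores <- function(sample_tiles, control_tiles) {
  if (length(control_tiles) < 2)
    stop("need at least 2 control tracks")
  key <- paste(sample_tiles$chrom, sample_tiles$start)
  mat <- vapply(control_tiles, function(ct) {
    if (!identical(paste(ct$chrom, ct$start), key))
      stop("control tiling does not match sample tiling")
    ct$normalized
  }, numeric(nrow(sample_tiles)))
  mat <- matrix(mat, nrow = nrow(sample_tiles))
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  z <- (sample_tiles$normalized - mu) / sdv
  z[sdv == 0] <- NA_real_
  sample_tiles$z <- z
  sample_tiles
}

#' Tumor-cfDNA Z-score concordance restricted to aberrant regions
#'
#' Restricts both Z-score tracks to tiles overlapping copy-number regions
#' of the requested class (a tile overlaps if at least `min_overlap_frac`
#' of the tile lies within regions of that class), then computes the
#' Pearson correlation between the tumor and cfDNA Z-scores and the
#' F-statistic `F = r^2 (n-2) / (1 - r^2)` with p from `F(1, n-2)`.
#'
#' @param tumor_track,cfdna_track [zscores()] outputs on the same tiling.
#' @param regions Region table from [call_regions()] (columns `chrom`,
#'   `start`, `end`, `direction`).
#' @param region_class `"amplified"` (gain regions) or `"deleted"` (loss).
#' @param min_overlap_frac Minimum fraction of a tile covered by class
#'   regions (default 0.5).
#' @return List: `region_class`, `n_tiles`, `r`, `F`, `p`. Perfect
#'   correlation reports `F = Inf`, `p = 0`.
#' @export
region_restricted_correlation <- function(tumor_track, cfdna_track, regions,
                                          region_class = c("amplified",
                                                           "deleted"),
                                          min_overlap_frac = 0.5) {
  region_class <- match.arg(region_class)
  dir <- if (region_class == "amplified") "gain" else "loss"
  reg <- regions[regions$direction == dir, , drop = FALSE]
  ov <- vapply(seq_len(nrow(tumor_track)), function(i) {
    tl <- tumor_track[i, ]
    r <- reg[reg$chrom == tl$chrom, , drop = FALSE]
    if (!nrow(r)) return(0)
    sum(pmax(0, pmin(r$end, tl$end) - pmax(r$start, tl$start))) /
      (tl$end - tl$start)
  }, numeric(1))
  sel <- ov >= min_overlap_frac & !is.na(tumor_track$z) &
    !is.na(cfdna_track$z)
  n <- sum(sel)
  if (n < 3)
    stop("fewer than 3 tiles overlap ", region_class, " regions")
  r <- stats::cor(tumor_track$z[sel], cfdna_track$z[sel])
  if (abs(r) >= 1 - 1e-12) {
    f <- Inf; p <- 0
  } else {
    f <- r^2 * (n - 2) / (1 - r^2)
    p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  }
  list(region_class = region_class, n_tiles = n, r = r, F = f, p = p)
}
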