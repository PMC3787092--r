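#' Structural-variant event description
#'
#' One implanted rearrangement. Deletions, duplications and inversions span
#' `[pos1, pos2)` on one chromosome; insertions are novel sequence of `size`
#' bp entering at `pos1` (`pos2 == pos1`); translocations join two breakends
#' on different chromosomes (`size = 0`).
#'
#' @param sv_type One of `"deletion"`, `"duplication"`, `"insertion"`,
#'   `"inversion"`, `"translocation"`.
#' @param chrom1,pos1 First breakend (0-based).
#' @param chrom2,pos2 Second breakend. Defaults to the first chromosome.
#' @param size Event size in bp; derived from the breakends for
#'   deletion/duplication/inversion, required for insertion, 0 for
#'   translocation.
#' @param zygosity `"heterozygous"` or `"homozygous"`.
#' @param origin `"germline"` or `"somatic"`.
#' @return One-row data.frame; rbind rows to form an event set.
#' @export
sv_event <- function(sv_type, chrom1, pos1, chrom2 = chrom1, pos2 = pos1,
                     size = NA, zygosity = "heterozygous",
                     origin = "somatic") {
  sv_type <- match.arg(sv_type, c("deletion", "duplication", "insertion",
                                  "inversion", "translocation"))
  zygosity <- match.arg(zygosity, c("heterozygous", "homozygous"))
  origin <- match.arg(origin, c("germline", "somatic"))
  if (sv_type %in% c("deletion", "duplication", "inversion")) {
    if (!identical(chrom1, chrom2) || !(pos1 < pos2))
      stop(sv_type, " requires both breakends on one chromosome with pos1 < pos2")
    size <- pos2 - pos1
  } else if (sv_type == "translocation") {
    if (identical(chrom1, chrom2))
      stop("translocation breakends must be on different chromosomes")
    size <- 0
  } else { # insertion
    if (is.na(size) || size <= 0)
      stop("insertion requires a positive size")
    pos2 <- pos1
  }
  data.frame(sv_type = sv_type, chrom1 = as.character(chrom1), pos1 = pos1,
             chrom2 = as.character(chrom2), pos2 = pos2, size = size,
             zygosity = zygosity, origin = origin, stringsAsFactors = FALSE)
}

#' Copy-number segment
#'
#' @param chrom,start,end Interval (0-based half-open).
#' @param copy_number Non-negative real total copy number (2 = diploid).
#' @return One-row data.frame; rbind rows to form a copy-number plan.
#' @export
cn_segment <- function(chrom, start, end, copy_number) {
  if (start >= end) stop("start must be < end")
  if (copy_number < 0) stop("copy_number must be >= 0")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             copy_number = copy_number, stringsAsFactors = FALSE)
}

#' Sequencing library plan
#'
#' Parameters of a simulated library: insert-size distribution, read length,
#' number of pairs, tumor purity and seed. Mate-pair libraries in this
#' problem domain have inserts around 2.3-2.6 kb (SD 600-780) and paired-end
#' libraries around 90-145 bp; the default emulates a mate-pair library.
#'
#' @param insert_mean,insert_sd Insert-size mean and SD in bp. When the mean
#'   is below 4 SD the lower concordance bound `mean - 4*sd` is negative and
#'   no insertion signature is classifiable — true of wide mate-pair
#'   libraries, which accordingly yield almost no insertion calls.
#' @param read_length Read length in bp.
#' @param n_pairs Number of pairs to emit.
#' @param purity Tumor cell content in `[0, 1]`; attenuates somatic events.
#' @param seed Integer seed.
#' @return A `library_plan` list.
#' @export
library_plan <- function(insert_mean = 2554, insert_sd = 719,
                         read_length = 50, n_pairs = 1e5, purity = 1,
                         seed = 1) {
  if (insert_sd < 0 || insert_mean <= insert_sd)
    stop("require insert_mean > insert_sd >= 0")
  if (insert_mean < 2 * read_length)
    stop("insert_mean must be at least twice the read length")
  if (n_pairs <= 0) stop("n_pairs must be positive")
  if (purity < 0 || purity > 1) stop("purity must be in [0, 1]")
  structure(list(insert_mean = insert_mean, insert_sd = insert_sd,
                 read_length = read_length, n_pairs = as.integer(n_pairs),
                 purity = purity, seed = as.integer(seed)),
            class = "library_plan")
}

#' Digital-PCR droplet plan
#'
#' @param n_partitions Droplets per reaction (the instrument emulated here
#'   reads about 14,000 droplets of the ~20,000 generated).
#' @param lambda_target,lambda_ref Mean template copies per partition.
#' @param seed Integer seed.
#' @return A `droplet_plan` list.
#' @export
droplet_plan <- function(n_partitions = 14121, lambda_target = 0.5,
                         lambda_ref = 0.5, seed = 1) {
  if (n_partitions <= 0) stop("n_partitions must be positive")
  if (lambda_target < 0 || lambda_ref < 0) stop("lambda must be >= 0")
  structure(list(n_partitions = as.integer(n_partitions),
                 lambda_target = lambda_target, lambda_ref = lambda_ref,
                 seed = as.integer(seed)),
            class = "droplet_plan")
}

# check all events fall inside the genome; error names the offender
validate_events <- function(genome, svs) {
  if (is.null(svs) || !nrow(svs)) return(invisible(NULL))
  for (i in seq_len(nrow(svs))) {
    ev <- svs[i, ]
    l1 <- chrom_length(genome, ev$chrom1)
    l2 <- chrom_length(genome, ev$chrom2)
    if (ev$pos1 < 0 || ev$pos1 > l1 || ev$pos2 < 0 || ev$pos2 > l2)
      stop(sprintf("event outside genome bounds: %s %s:%d-%s:%d",
                   ev$sv_type, ev$chrom1, ev$pos1, ev$chrom2, ev$pos2))
  }
  invisible(NULL)
}

# piecewise-constant sampling weights from a copy-number plan:
# weight = (purity*CN + (1-purity)*2) / 2, i.e. expected depth relative to
# diploid in a tumor/normal cell mixture
weight_segments <- function(genome, cn, purity) {
  segs <- lapply(seq_len(nrow(genome)), function(i) {
    chrom <- genome$chrom[i]; len <- genome$length[i]
    cuts <- c(0, len)
    cni <- if (!is.null(cn) && nrow(cn)) cn[cn$chrom == chrom, , drop = FALSE]
           else NULL
    if (!is.null(cni) && nrow(cni))
      cuts <- c(cuts, cni$start, cni$end)
    cuts <- sort(unique(pmin(pmax(cuts, 0), len)))
    start <- cuts[-length(cuts)]; end <- cuts[-1]
    mid <- (start + end) / 2
    copy <- rep(2, length(mid))
    if (!is.null(cni) && nrow(cni)) {
      for (j in seq_len(nrow(cni)))
        copy[mid >= cni$start[j] & mid < cni$end[j]] <- cni$copy_number[j]
    }
    data.frame(chrom = chrom, start = start, end = end,
               weight = (purity * copy + (1 - purity) * 2) / 2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, segs)
}

#' Simulate mapped read pairs from a rearranged tumor/normal genome
#'
#' Emits mapped pairs directly (no sequence, no alignment step): positions
#' are sampled along the genome with density proportional to the
#' purity-mixed copy number, insert sizes are Normal(`insert_mean`,
#' `insert_sd`) truncated at twice the read length, and fragments spanning
#' an implanted rearrangement junction are emitted with the corresponding
#' anomalous mapping signature:
#'
#' * deletion of size d: apparent insert grows by d;
#' * novel insertion of size d: apparent insert shrinks by d (only
#'   fragments longer than d + 2 read lengths can span);
#' * inversion: same-strand pairs (FF at the left junction, RR at the right);
#' * tandem duplication: everted (RF) pairs across the copy junction;
#' * translocation: inter-chromosomal pairs.
#'
#' A fragment spans a junction only if both reads map cleanly on either
#' side; junction signatures are applied with probability equal to the
#' variant allele presence (1 for homozygous, 0.5 for heterozygous,
#' multiplied by `purity` for somatic events). Copy-number segments shape
#' depth only; to give a deletion both a depth and a pair signature, supply
#' a matching [cn_segment()].
#'
#' @param genome A [genome_spec()].
#' @param plan A [library_plan()].
#' @param cn Optional data.frame of [cn_segment()] rows (tumor copy number).
#' @param svs Optional data.frame of [sv_event()] rows.
#' @param sample_id Sample label written into the pair table.
#' @return A pair table (see [as_pair_table()]).
#' @export
simulate_read_pairs <- function(genome, plan, cn = NULL, svs = NULL,
                                sample_id = "S1") {
  stopifnot(inherits(plan, "library_plan"))
  validate_events(genome, svs)
  set.seed(plan$seed)
  rl <- plan$read_length
  n <- plan$n_pairs

  segs <- weight_segments(genome, cn, plan$purity)
  seg_w <- segs$weight * (segs$end - segs$start)
  idx <- sample.int(nrow(segs), n, replace = TRUE, prob = seg_w)
  s <- floor(segs$start[idx] + stats::runif(n) * (segs$end[idx] - segs$start[idx]))
  chrom <- segs$chrom[idx]
  clen <- chrom_length(genome, chrom)

  L <- round(stats::rnorm(n, plan$insert_mean, plan$insert_sd))
  L <- pmax(L, 2 * rl)
  s <- pmin(s, clen - L)          # keep the fragment inside the chromosome
  s <- pmax(s, 0)

  out <- data.frame(sample_id = sample_id,
                    chrom1 = chrom, pos1 = s, strand1 = "+",
                    chrom2 = chrom, pos2 = s + L - rl, strand2 = "-",
                    insert = L, stringsAsFactors = FALSE)
  free <- rep(TRUE, n)            # not yet consumed by an event signature
  e <- s + L                      # fragment end

  if (!is.null(svs) && nrow(svs)) {
    for (i in seq_len(nrow(svs))) {
      ev <- svs[i, ]
      p_allele <- (if (ev$zygosity == "homozygous") 1 else 0.5) *
                  (if (ev$origin == "somatic") plan$purity else 1)
      if (p_allele <= 0) next
      b1 <- ev$pos1; b2 <- ev$pos2; d <- ev$size
      on_c1 <- free & chrom == ev$chrom1
      take <- function(cand) {
        w <- which(cand)
        w[stats::runif(length(w)) < p_allele]
      }
      if (ev$sv_type == "deletion") {
        k <- take(on_c1 & s + rl <= b1 & e - rl >= b1 &
                    e + d <= chrom_length(genome, ev$chrom1))
        out$pos2[k] <- s[k] + L[k] + d - rl
        out$insert[k] <- L[k] + d
        free[k] <- FALSE
      } else if (ev$sv_type == "insertion") {
        k <- take(on_c1 & s + rl <= b1 & e - d - rl >= b1)
        out$pos2[k] <- s[k] + L[k] - d - rl
        out$insert[k] <- L[k] - d
        free[k] <- FALSE
      } else if (ev$sv_type == "inversion") {
        # left junction: mate falls inside the inverted block -> FF
        k <- take(on_c1 & s + rl <= b1 & e - rl >= b1 & e <= b2)
        out$pos2[k] <- b1 + b2 - e[k]
        out$strand2[k] <- "+"
        out$insert[k] <- out$pos2[k] - out$pos1[k] + rl
        free[k] <- FALSE
        # right junction: leading read inside the block -> RR
        k <- take(on_c1 & s >= b1 & s + rl <= b2 & e - rl >= b2)
        out$pos1[k] <- b1 + b2 - s[k] - rl
        out$strand1[k] <- "-"
        out$pos2[k] <- e[k] - rl
        out$strand2[k] <- "-"
        out$insert[k] <- out$pos2[k] - out$pos1[k] + rl
        free[k] <- FALSE
      } else if (ev$sv_type == "duplication") {
        # fragment runs off the end of the first copy into the second
        k <- take(on_c1 & s + rl <= b2 & e - rl >= b2 & e <= b2 + d &
                    b1 + (e - b2) - rl < s)
        out$pos1[k] <- b1 + (e[k] - b2) - rl
        out$strand1[k] <- "-"
        out$pos2[k] <- s[k]
        out$strand2[k] <- "+"
        out$insert[k] <- out$pos2[k] - out$pos1[k] + rl
        free[k] <- FALSE
      } else if (ev$sv_type == "translocation") {
        k <- take(on_c1 & s + rl <= b1 & e - rl >= b1 &
                    b2 + plan$insert_mean + 4 * plan$insert_sd <=
                      chrom_length(genome, ev$chrom2))
        m2 <- b2 + (e[k] - b1) - rl
        i1 <- match(ev$chrom1, genome$chrom); i2 <- match(ev$chrom2, genome$chrom)
        if (i1 <= i2) {
          out$chrom2[k] <- ev$chrom2; out$pos2[k] <- m2; out$strand2[k] <- "-"
        } else {
          out$chrom1[k] <- ev$chrom2; out$pos1[k] <- m2; out$strand1[k] <- "-"
          out$chrom2[k] <- ev$chrom1; out$pos2[k] <- s[k]; out$strand2[k] <- "+"
        }
        out$insert[k] <- -1
        free[k] <- FALSE
      }
    }
  }
  as_pair_table(out)
}

#' Mix tumor and normal pairs into a cfDNA sample
#'
#' Each emitted pair is drawn (with replacement) from the tumor pool with
#' probability `tumor_fraction`, otherwise from the normal pool — the plasma
#' cell-free DNA model: a tumor/normal fragment mixture at a set fraction.
#'
#' @param tumor_pairs,normal_pairs Pair tables to draw from.
#' @param tumor_fraction Fraction of tumor-derived pairs in `[0, 1]`.
#' @param n_pairs Number of pairs to emit.
#' @param seed Integer seed.
#' @param sample_id Sample label for the output.
#' @return A pair table with an extra logical column `from_tumor`.
#' @export
mix_cfdna <- function(tumor_pairs, normal_pairs, tumor_fraction, n_pairs,
                      seed = 1, sample_id = "cfDNA") {
  if (tumor_fraction < 0 || tumor_fraction > 1)
    stop("tumor_fraction must be in [0, 1]")
  if (tumor_fraction > 0 && nrow(tumor_pairs) == 0)
    stop("tumor pair collection is empty")
  if (tumor_fraction < 1 && nrow(normal_pairs) == 0)
    stop("normal pair collection is empty")
  set.seed(seed)
  from_tumor <- stats::runif(n_pairs) < tumor_fraction
  n_t <- sum(from_tumor)
  rows <- list()
  if (n_t > 0)
    rows$t <- tumor_pairs[sample.int(nrow(tumor_pairs), n_t,
                                     replace = TRUE), PAIR_COLS]
  if (n_pairs - n_t > 0)
    rows$n <- normal_pairs[sample.int(nrow(normal_pairs), n_pairs - n_t,
                                      replace = TRUE), PAIR_COLS]
  out <- do.call(rbind, rows)
  out$sample_id <- sample_id
  rownames(out) <- NULL
  out <- as_pair_table(out)
  out$from_tumor <- c(rep(TRUE, n_t), rep(FALSE, n_pairs - n_t))
  out
}

#' Simulate a two-channel droplet digital-PCR reaction
#'
#' Positive droplets per channel are Binomial(n, 1 - exp(-lambda)): the
#' partition-occupancy model digital PCR quantification inverts.
#'
#' @param plan A [droplet_plan()].
#' @param assay_id,sample_id Labels for the output rows.
#' @return data.frame with one row per channel (`target`, `reference`) and
#'   columns `assay_id`, `sample_id`, `channel`, `n_total`, `n_positive`.
#' @export
simulate_droplets <- function(plan, assay_id = "assay", sample_id = "S1") {
  stopifnot(inherits(plan, "droplet_plan"))
  set.seed(plan$seed)
  n <- plan$n_partitions
  k_t <- stats::rbinom(1, n, 1 - exp(-plan$lambda_target))
  k_r <- stats::rbinom(1, n, 1 - exp(-plan$lambda_ref))
  data.frame(assay_id = assay_id, sample_id = sample_id,
             channel = c("target", "reference"),
             n_total = n, n_positive = c(k_t, k_r),
             stringsAsFactors = FALSE)
}

#' Simulate a split 384-well breakpoint/reference plate assay
#'
#' Wells are digital-PCR partitions loaded at `genome_equivalents_per_well`
#' haploid genome equivalents. Reference wells turn positive with
#' probability 1 - exp(-g); breakpoint wells with probability
#' 1 - exp(-g * f) where `f` is the fraction of template molecules carrying
#' the tumor-specific breakpoint.
#'
#' @param breakpoint_fraction Fraction `f` in `[0, 1]`.
#' @param wells_per_assay Wells per primer set (half a 384-well plate = 192).
#' @param genome_equivalents_per_well Mean haploid genome equivalents per
#'   well (`g`); the bench protocol emulated uses 0.5.
#' @param seed Integer seed.
#' @return List with `breakpoint` and `reference`, each `(positive, total)`.
#' @export
simulate_well_plate <- function(breakpoint_fraction, wells_per_assay = 192,
                                genome_equivalents_per_well = 0.5, seed = 1) {
  if (breakpoint_fraction < 0 || breakpoint_fraction > 1)
    stop("breakpoint_fraction must be in [0, 1]")
  if (wells_per_assay <= 0) stop("wells_per_assay must be positive")
  set.seed(seed)
  g <- genome_equivalents_per_well
  k_ref <- stats::rbinom(1, wells_per_assay, 1 - exp(-g))
  k_bp <- stats::rbinom(1, wells_per_assay,
                        1 - exp(-g * breakpoint_fraction))
  list(breakpoint = c(positive = k_bp, total = wells_per_assay),
       reference = c(positive = k_ref, total = wells_per_assay))
}

#' Write implanted truth to plain-text files
#'
#' SV events are written as BEDPE and copy-number segments as BED with a
#' copy-number column, both 0-based half-open.
#'
#' @param svs,cn Event / segment data.frames.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_truth_bedpe <- function(svs, path) {
  df <- data.frame(chrom1 = svs$chrom1, start1 = svs$pos1, end1 = svs$pos1 + 1,
                   chrom2 = svs$chrom2, start2 = svs$pos2, end2 = svs$pos2 + 1,
                   name = paste0(svs$sv_type, "_", seq_len(nrow(svs))),
                   score = ".", strand1 = ".", strand2 = ".",
                   type = svs$sv_type, origin = svs$origin,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_bedpe
#' @export
write_truth_bed <- function(cn, path) {
  utils::write.table(cn[, c("chrom", "start", "end", "copy_number")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
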