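#' Estimate library insert-size statistics from mapped pairs
#'
#' Uses intra-chromosomal pairs in the expected ("innie" FR) orientation
#' only, and trims the extreme 1% of inserts (0.5% per tail) before taking
#' the mean and SD, so a small admixture of discordant pairs cannot shift
#' the estimates.
#'
#' @param pairs A pair table.
#' @param min_pairs Minimum number of usable pairs (default 1000).
#' @return List `insert_mean`, `insert_sd`, `n_concordant_used`.
#' @export
estimate_library_stats <- function(pairs, min_pairs = 1000) {
  pairs <- as_pair_table(pairs)
  ok <- pairs$chrom1 == pairs$chrom2 & pairs$strand1 == "+" &
    pairs$strand2 == "-" & pairs$insert >= 0
  ins <- pairs$insert[ok]
  if (length(ins) < min_pairs)
    stop("too few expected-orientation intra-chromosomal pairs (",
         length(ins), " < ", min_pairs, ")")
  q <- stats::quantile(ins, c(0.005, 0.995), names = FALSE, type = 1)
  keep <- ins >= q[1] & ins <= q[2]
  list(insert_mean = mean(ins[keep]),
       insert_sd = stats::sd(ins[keep]),
       n_concordant_used = sum(keep))
}

#' Classify read pairs by PEM signature
#'
#' A pair's (distance, order, orientation) signature, at a `k_sd` SD insert
#' threshold:
#'
#' * different chromosomes — `translocation`;
#' * same strand — `inversion`;
#' * everted order (leftmost read on the reverse strand) — `duplication`;
#' * expected orientation with insert beyond `mean + k_sd*sd` — `deletion`;
#' * below `mean - k_sd*sd` — `insertion`;
#' * otherwise `concordant`.
#'
#' @param pairs A pair table.
#' @param stats Output of [estimate_library_stats()] (or a list with
#'   `insert_mean`, `insert_sd`).
#' @param k_sd SD multiplier (default 4).
#' @return Character vector of signatures, one per pair.
#' @export
classify_pairs <- function(pairs, stats, k_sd = 4) {
  pairs <- as_pair_table(pairs)
  hi <- stats$insert_mean + k_sd * stats$insert_sd
  lo <- stats$insert_mean - k_sd * stats$insert_sd
  sig <- rep("concordant", nrow(pairs))
  inter <- pairs$chrom1 != pairs$chrom2
  same_strand <- !inter & pairs$strand1 == pairs$strand2
  everted <- !inter & !same_strand & pairs$strand1 == "-"
  fr <- !inter & pairs$strand1 == "+" & pairs$strand2 == "-"
  sig[fr & pairs$insert > hi] <- "deletion"
  sig[fr & pairs$insert < lo] <- "insertion"
  sig[everted] <- "duplication"
  sig[same_strand] <- "inversion"
  sig[inter] <- "translocation"
  sig
}

# empty SV call table
empty_calls <- function() {
  data.frame(sample_id = character(), sv_type = character(),
             chrom1 = character(), start1 = numeric(), end1 = numeric(),
             strand1 = character(),
             chrom2 = character(), start2 = numeric(), end2 = numeric(),
             strand2 = character(),
             support = integer(), call_id = character(),
             stringsAsFactors = FALSE)
}

#' Cluster anomalous pairs into structural-variant calls
#'
#' Single-linkage clustering of same-signature pairs: two pairs belong to
#' one cluster if both their end positions lie within `mean + 4*sd` of each
#' other (and they share the signature, strand pattern and chromosome
#' pair). Each cluster becomes one call whose two links are the min/max
#' envelopes of the member read ends on each side; clusters with fewer than
#' `min_support` members are dropped. Detection practice in this package:
#' tumor samples are called at `min_support = 3`, control samples at 1 so
#' the germline filters see every control cluster.
#'
#' @param pairs A pair table (only anomalous pairs are used).
#' @param stats Library stats, as in [classify_pairs()].
#' @param min_support Minimum member pairs per retained call.
#' @param k_sd SD multiplier for both classification and the linkage
#'   distance (default 4).
#' @param read_length Read length used to close link intervals (default 50).
#' @return SV call table: one row per call with typed links
#'   (`chrom1`, `start1`, `end1`, `strand1`, same for side 2), `support`,
#'   `sample_id` and `call_id`. Links are ordered canonically (lower
#'   chromosome/coordinate first).
#' @export
cluster_anomalies <- function(pairs, stats, min_support = 3, k_sd = 4,
                              read_length = 50) {
  stopifnot(min_support >= 1)
  pairs <- as_pair_table(pairs)
  if (!nrow(pairs)) return(empty_calls())
  sig <- classify_pairs(pairs, stats, k_sd)
  anom <- pairs[sig != "concordant", , drop = FALSE]
  sig <- sig[sig != "concordant"]
  if (!nrow(anom)) return(empty_calls())
  d_max <- stats$insert_mean + k_sd * stats$insert_sd
  key <- paste(anom$sample_id, sig, anom$chrom1, anom$chrom2,
               anom$strand1, anom$strand2, sep = "\r")
  calls <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    sub <- anom[idx, ]
    # deterministic order, then single linkage = connected components of
    # the "both ends within d_max" graph, found by a union-find sweep
    o <- order(sub$pos1, sub$pos2)
    sub <- sub[o, ]
    n <- nrow(sub)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) {
      j <- i - 1
      while (j >= 1 && sub$pos1[i] - sub$pos1[j] <= d_max) {
        if (abs(sub$pos2[i] - sub$pos2[j]) <= d_max) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
        j <- j - 1
      }
    }
    comp <- vapply(seq_len(n), find, numeric(1))
    for (cid in unique(comp)) {
      members <- sub[comp == cid, ]
      if (nrow(members) < min_support) next
      calls[[length(calls) + 1]] <- data.frame(
        sample_id = members$sample_id[1],
        sv_type = sig[idx[1]],
        chrom1 = members$chrom1[1],
        start1 = min(members$pos1), end1 = max(members$pos1) + read_length,
        strand1 = members$strand1[1],
        chrom2 = members$chrom2[1],
        start2 = min(members$pos2), end2 = max(members$pos2) + read_length,
        strand2 = members$strand2[1],
        support = nrow(members), call_id = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(empty_calls())
  out <- do.call(rbind, calls)
  out <- out[order(out$chrom1, out$start1, out$chrom2, out$start2,
                   out$sv_type), ]
  rownames(out) <- NULL
  out$call_id <- sprintf("%s_call_%04d", out$sample_id, seq_len(nrow(out)))
  out
}

#' Strand and order filtering of clustered calls
#'
#' Removes calls that are internally inconsistent: links on different
#' chromosomes for an intra-chromosomal type, mismatched strand pattern for
#' the declared type (deletions/insertions must be `+/-`, duplications
#' `-/+`, inversions same-strand), and deletion/insertion calls whose two
#' link intervals overlap (the read clusters must be ordered apart for a
#' distance signature to make sense). Retained calls are unchanged.
#'
#' @param calls An SV call table.
#' @return List with `retained` and `removed` call tables; `removed` gains
#'   a `reason` column.
#' @export
filter_strand_order <- function(calls) {
  if (!nrow(calls))
    return(list(retained = calls, removed = cbind(calls, reason = character())))
  reason <- rep(NA_character_, nrow(calls))
  intra <- calls$sv_type != "translocation"
  bad_chrom <- intra & calls$chrom1 != calls$chrom2
  reason[bad_chrom] <- "links on different chromosomes"
  fr_types <- calls$sv_type %in% c("deletion", "insertion")
  bad_strand <- is.na(reason) & (
    (fr_types & !(calls$strand1 == "+" & calls$strand2 == "-")) |
    (calls$sv_type == "duplication" &
       !(calls$strand1 == "-" & calls$strand2 == "+")) |
    (calls$sv_type == "inversion" & calls$strand1 != calls$strand2))
  reason[bad_strand] <- "strand pattern contradicts type"
  overlap <- is.na(reason) & fr_types &
    calls$start2 < calls$end1 & calls$start1 < calls$end2
  reason[overlap] <- "link order contradicts type"
  removed <- calls[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  list(retained = calls[is.na(reason), , drop = FALSE], removed = removed)
}

# gap between two intervals on one chromosome: 0 if they overlap
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

#' Subtract matched-control calls overlapping a tumor call
#'
#' A tumor call is removed if a control call of the same type overlaps it
#' by at least `min_overlap` bp on both links.
#'
#' @param tumor_calls,control_calls SV call tables; control calls should
#'   come from `min_support = 1` detection.
#' @param min_overlap Minimum overlap per link in bp (default 1).
#' @return List with `retained` and `removed` (with `matched_control_id`).
#' @export
subtract_matched_control <- function(tumor_calls, control_calls,
                                     min_overlap = 1) {
  if (!nrow(tumor_calls) || !nrow(control_calls))
    return(list(retained = tumor_calls,
                removed = cbind(tumor_calls[0, ],
                                matched_control_id = character())))
  hit <- rep(NA_character_, nrow(tumor_calls))
  for (i in seq_len(nrow(tumor_calls))) {
    tc <- tumor_calls[i, ]
    cand <- control_calls[control_calls$sv_type == tc$sv_type, ]
    if (!nrow(cand)) next
    ov1 <- cand$chrom1 == tc$chrom1 &
      pmin(cand$end1, tc$end1) - pmax(cand$start1, tc$start1) >= min_overlap
    ov2 <- cand$chrom2 == tc$chrom2 &
      pmin(cand$end2, tc$end2) - pmax(cand$start2, tc$start2) >= min_overlap
    m <- which(ov1 & ov2)
    if (length(m)) hit[i] <- cand$call_id[m[1]]
  }
  removed <- tumor_calls[!is.na(hit), , drop = FALSE]
  if (nrow(removed)) removed$matched_control_id <- hit[!is.na(hit)]
  else removed <- cbind(removed, matched_control_id = character())
  list(retained = tumor_calls[is.na(hit), , drop = FALSE], removed = removed)
}

#' Detect structural variants in one sample
#'
#' Convenience wrapper: estimate library stats, classify, cluster at
#' `min_support` and apply the strand/order filter.
#'
#' @inheritParams cluster_anomalies
#' @param min_support 3 for tumor samples, 1 for control samples by
#'   convention.
#' @return Filtered SV call table.
#' @export
detect_svs <- function(pairs, min_support = 3, k_sd = 4, read_length = 50,
                       stats = NULL) {
  if (is.null(stats)) stats <- estimate_library_stats(pairs)
  calls <- cluster_anomalies(pairs, stats, min_support, k_sd, read_length)
  filter_strand_order(calls)$retained
}

#' Read / write SV calls as BEDPE
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, name, score
#' (= support), strand1, strand2, type, sample. 0-based half-open.
#'
#' @param calls An SV call table.
#' @param path File path.
#' @export
write_bedpe <- function(calls, path) {
  df <- data.frame(chrom1 = calls$chrom1, start1 = calls$start1,
                   end1 = calls$end1, chrom2 = calls$chrom2,
                   start2 = calls$start2, end2 = calls$end2,
                   name = calls$call_id, score = calls$support,
                   strand1 = calls$strand1, strand2 = calls$strand2,
                   type = calls$sv_type, sample = calls$sample_id,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedpe
#' @export
read_bedpe <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df) <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                 "name", "score", "strand1", "strand2", "type", "sample")
  data.frame(sample_id = df$sample, sv_type = df$type,
             chrom1 = df$chrom1, start1 = df$start1, end1 = df$end1,
             strand1 = df$strand1,
             chrom2 = df$chrom2, start2 = df$start2, end2 = df$end2,
             strand2 = df$strand2,
             support = df$score, call_id = df$name,
             stringsAsFactors = FALSE)
}
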