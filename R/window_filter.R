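#' Distance between two links
#'
#' Gap in bp between two link intervals: 0 if they overlap, the gap length
#' otherwise, infinite across chromosomes.
#'
#' @param chrom_a,start_a,end_a,chrom_b,start_b,end_b Link coordinates
#'   (vectors recycle).
#' @return Numeric distances.
#' @export
link_distance <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  d <- interval_gap(start_a, end_a, start_b, end_b)
  d[chrom_a != chrom_b] <- Inf
  d
}

#' Germline window filter against one control call set
#'
#' A tumor call is removed if a single control structural variation has
#' both of its links within `+/-window` bp of the tumor call's two links
#' (link distance 0 when intervals overlap; link pairing is tried in both
#' orders; type match is NOT required). This is the panel-of-normals
#' subtraction for clustered read-pair calls: control detection at minimum
#' support 1 makes even weakly covered germline variants available for
#' matching.
#'
#' @param tumor_calls,control_calls SV call tables.
#' @param window Match window in bp (default 3000).
#' @param stage Label written into the removal log.
#' @return List: `retained`, `removed`, and `removal_log` (data.frame of
#'   call id, stage, matching control call id and the two link distances).
#' @export
window_filter <- function(tumor_calls, control_calls, window = 3000,
                          stage = "window_filter") {
  stopifnot(window >= 0)
  log_empty <- data.frame(call_id = character(), stage = character(),
                          control_call_id = character(),
                          dist_link1 = numeric(), dist_link2 = numeric(),
                          stringsAsFactors = FALSE)
  if (!nrow(tumor_calls) || !nrow(control_calls))
    return(list(retained = tumor_calls,
                removed = tumor_calls[0, , drop = FALSE],
                removal_log = log_empty))
  removed <- rep(FALSE, nrow(tumor_calls))
  logs <- list()
  for (i in seq_len(nrow(tumor_calls))) {
    tc <- tumor_calls[i, ]
    # straight pairing: tumor link1 ~ control link1, link2 ~ link2
    d11 <- link_distance(tc$chrom1, tc$start1, tc$end1,
                         control_calls$chrom1, control_calls$start1,
                         control_calls$end1)
    d22 <- link_distance(tc$chrom2, tc$start2, tc$end2,
                         control_calls$chrom2, control_calls$start2,
                         control_calls$end2)
    # crossed pairing
    d12 <- link_distance(tc$chrom1, tc$start1, tc$end1,
                         control_calls$chrom2, control_calls$start2,
                         control_calls$end2)
    d21 <- link_distance(tc$chrom2, tc$start2, tc$end2,
                         control_calls$chrom1, control_calls$start1,
                         control_calls$end1)
    straight <- d11 <= window & d22 <= window
    crossed <- d12 <= window & d21 <= window
    m <- which(straight | crossed)
    if (length(m)) {
      removed[i] <- TRUE
      j <- m[1]                       # first match wins in the log
      logs[[length(logs) + 1]] <- data.frame(
        call_id = tc$call_id, stage = stage,
        control_call_id = control_calls$call_id[j],
        dist_link1 = if (straight[j]) d11[j] else d12[j],
        dist_link2 = if (straight[j]) d22[j] else d21[j],
        stringsAsFactors = FALSE)
    }
  }
  list(retained = tumor_calls[!removed, , drop = FALSE],
       removed = tumor_calls[removed, , drop = FALSE],
       removal_log = if (length(logs)) do.call(rbind, logs) else log_empty)
}

#' Two-stage germline filter cascade
#'
#' Stage 1: exact-overlap subtraction against the matched control
#' ([subtract_matched_control()]) followed by the `+/-window` filter
#' against the matched control's calls (WindowFilter1). Stage 2: the same
#' window filter against the pooled panel of control call sets
#' (WindowFilter2). Retention percentages are relative to the input count,
#' rounded half-up to one decimal.
#'
#' @param tumor_calls SV call table for the tumor.
#' @param matched_control_calls Calls from the same animal's control sample
#'   (min support 1).
#' @param panel_control_calls List of call tables for the control panel
#'   (may or may not include the matched control; both work).
#' @param window Match window in bp (default 3000).
#' @return List of class `filter_cascade_result`: `n_input`, `n_after_wf1`,
#'   `n_after_wf2`, `pct_after_wf1`, `pct_after_wf2`, `retained`,
#'   `removal_log`.
#' @export
filter_cascade <- function(tumor_calls, matched_control_calls,
                           panel_control_calls, window = 3000) {
  n_input <- nrow(tumor_calls)
  s0 <- subtract_matched_control(tumor_calls, matched_control_calls)
  wf1 <- window_filter(s0$retained, matched_control_calls, window,
                       stage = "window_filter_1")
  panel <- do.call(rbind, panel_control_calls)
  wf2 <- window_filter(wf1$retained, panel, window,
                       stage = "window_filter_2")
  n1 <- nrow(wf1$retained)
  n2 <- nrow(wf2$retained)
  structure(list(
    n_input = n_input, n_after_wf1 = n1, n_after_wf2 = n2,
    pct_after_wf1 = retention_pct(n1, n_input),
    pct_after_wf2 = retention_pct(n2, n_input),
    retained = wf2$retained,
    removal_log = rbind(wf1$removal_log, wf2$removal_log)),
    class = "filter_cascade_result")
}

#' Retention percentage, one decimal, half-up
#'
#' @param n Retained count.
#' @param n_input Input count.
#' @return Percentage rounded half-up to one decimal.
#' @export
retention_pct <- function(n, n_input) {
  if (n_input == 0) return(NA_real_)
  round_half_up(100 * n / n_input, 1)
}
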