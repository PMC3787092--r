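#' Poisson copies-per-partition from digital-PCR counts
#'
#' With `k` of `n` partitions positive, the mean template copies per
#' partition is `lambda = -ln(1 - k/n)`; the delta-method standard error is
#' `sqrt(p / ((1 - p) * n))` with `p = k/n`.
#'
#' @param k Positive partitions.
#' @param n Total partitions.
#' @return List `lambda`, `se`.
#' @export
poisson_lambda <- function(k, n) {
  if (n <= 0) stop("n must be positive")
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n")
  if (k == n)
    stop("all partitions positive: reaction saturated, dilute the sample")
  p <- k / n
  list(lambda = -log(1 - p), se = sqrt(p / ((1 - p) * n)))
}

#' Target/reference copy ratio with 95% confidence interval
#'
#' Computes per-channel lambdas and their ratio; the CI propagates the
#' relative errors on the log scale:
#' `exp(log(ratio) +/- 1.96 * sqrt((se_t/lambda_t)^2 + (se_r/lambda_r)^2))`.
#'
#' @param target,reference One-row slices (or lists) with `n_positive` and
#'   `n_total`, e.g. rows of [simulate_droplets()] output.
#' @return List of class `quant_result`: `lambda_target`, `se_target`,
#'   `lambda_ref`, `se_ref`, `ratio`, `ci_low`, `ci_high`.
#' @export
copy_ratio <- function(target, reference) {
  qt <- poisson_lambda(target$n_positive, target$n_total)
  qr <- poisson_lambda(reference$n_positive, reference$n_total)
  if (qr$lambda == 0)
    stop("reference lambda is zero: ratio undefined")
  ratio <- qt$lambda / qr$lambda
  if (qt$lambda == 0) {
    ci <- c(0, 0)
  } else {
    rel <- sqrt((qt$se / qt$lambda)^2 + (qr$se / qr$lambda)^2)
    ci <- exp(log(ratio) + c(-1, 1) * 1.96 * rel)
  }
  structure(list(lambda_target = qt$lambda, se_target = qt$se,
                 lambda_ref = qr$lambda, se_ref = qr$se,
                 ratio = ratio, ci_low = ci[1], ci_high = ci[2]),
            class = "quant_result")
}

#' Call a deletion from tumor vs matched-normal copy ratios
#'
#' `deleted` when the tumor ratio's CI lies entirely below the normal
#' ratio's CI; `not_deleted` when the CIs overlap and the tumor point ratio
#' is at least 90% of the normal ratio; `indeterminate` otherwise (CI
#' separation rule; configurable via the margin).
#'
#' @param tumor,matched_normal `quant_result` objects from [copy_ratio()].
#' @param margin Fraction of the normal ratio the tumor ratio must reach to
#'   be called `not_deleted` when CIs overlap (default 0.9).
#' @return `"deleted"`, `"not_deleted"` or `"indeterminate"`.
#' @export
call_deletion <- function(tumor, matched_normal, margin = 0.9) {
  if (tumor$ci_high < matched_normal$ci_low) return("deleted")
  overlap <- tumor$ci_high >= matched_normal$ci_low &&
    matched_normal$ci_high >= tumor$ci_low
  if (overlap && tumor$ratio >= margin * matched_normal$ratio)
    return("not_deleted")
  "indeterminate"
}

#' Call gene amplification from a fixed copy-number-difference rule
#'
#' Amplified when the tumor ratio exceeds the matched-normal ratio by
#' strictly more than `threshold` (default 0.02, the largest
#' tumor-vs-normal difference observed among amplification-free genomes in
#' the calibration this rule descends from).
#'
#' @param tumor,matched_normal `quant_result` objects.
#' @param threshold Copy-number-difference cutoff (strict inequality).
#' @return `"amplified"` or `"not_amplified"`.
#' @export
call_her2_amplification <- function(tumor, matched_normal,
                                    threshold = 0.02) {
  diff <- tumor$ratio - matched_normal$ratio
  if (diff > threshold + 1e-9) "amplified" else "not_amplified"
}

#' Breakpoint fraction in cfDNA from split well-plate counts
#'
#' The tumor-burden marker: concentration of a tumor-specific rearrangement
#' junction relative to a reference locus, in percent. Each channel's
#' lambda is `-ln(1 - k/n)`; the CI propagates as in [copy_ratio()].
#'
#' @param bp_wells,ref_wells Numeric vectors `c(positive, total)` for the
#'   breakpoint and reference primer sets (e.g. from
#'   [simulate_well_plate()]).
#' @return List: `fraction_pct`, `ci_low_pct`, `ci_high_pct`, `lambda_bp`,
#'   `lambda_ref`.
#' @export
breakpoint_fraction <- function(bp_wells, ref_wells) {
  qb <- poisson_lambda(bp_wells[["positive"]], bp_wells[["total"]])
  qr <- poisson_lambda(ref_wells[["positive"]], ref_wells[["total"]])
  if (qr$lambda == 0)
    stop("no positive reference wells: fraction undefined")
  frac <- qb$lambda / qr$lambda
  if (qb$lambda == 0) {
    ci <- c(0, 0)
  } else {
    rel <- sqrt((qb$se / qb$lambda)^2 + (qr$se / qr$lambda)^2)
    ci <- exp(log(frac) + c(-1, 1) * 1.96 * rel)
  }
  list(fraction_pct = 100 * frac, ci_low_pct = 100 * ci[1],
       ci_high_pct = 100 * ci[2], lambda_bp = qb$lambda,
       lambda_ref = qr$lambda)
}

#' Quantify a table of digital-PCR counts
#'
#' Convenience wrapper over [copy_ratio()] for a long-format count table
#' (columns `assay_id`, `sample_id`, `channel`, `n_total`, `n_positive`;
#' one `target` and one `reference` row per assay/sample).
#'
#' @param counts Count table.
#' @return data.frame with one row per assay/sample: lambdas, ratio, CI.
#' @export
quantify_ddpcr <- function(counts) {
  keys <- unique(counts[, c("assay_id", "sample_id")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- counts[counts$assay_id == keys$assay_id[i] &
                    counts$sample_id == keys$sample_id[i], ]
    q <- copy_ratio(sub[sub$channel == "target", ],
                    sub[sub$channel == "reference", ])
    data.frame(assay_id = keys$assay_id[i], sample_id = keys$sample_id[i],
               lambda_target = q$lambda_target, se_target = q$se_target,
               lambda_ref = q$lambda_ref, se_ref = q$se_ref,
               ratio = q$ratio, ci_low = q$ci_low, ci_high = q$ci_high,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
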