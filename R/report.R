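SV_TYPES <- c("duplication", "insertion", "deletion", "translocation",
              "inversion")

#' Round half-up
#'
#' Decimal rounding where exact halves round away from zero toward the
#' larger magnitude (the table-formatting convention used throughout the
#' cohort summaries), unlike base `round()`'s round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal digits.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Tabulate validated structural-variant counts per sample and type
#'
#' @param calls An SV call table with `sample_id` and `sv_type`, or a list
#'   of such tables.
#' @param samples Optional character vector fixing the sample order (and
#'   including samples with zero calls).
#' @return data.frame: one row per sample, one column per SV type, plus
#'   `total`; attribute `grand_total` carries the cohort-wide sum.
#' @export
tabulate_sv_counts <- function(calls, samples = NULL) {
  if (is.data.frame(calls)) calls <- list(calls)
  df <- do.call(rbind, lapply(calls, function(x)
    x[, c("sample_id", "sv_type"), drop = FALSE]))
  if (is.null(df)) df <- data.frame(sample_id = character(),
                                    sv_type = character())
  if (is.null(samples)) samples <- unique(df$sample_id)
  if (!length(samples)) {
    out <- data.frame(sample_id = character(), stringsAsFactors = FALSE)
    for (tp in c(SV_TYPES, "total")) out[[tp]] <- numeric(0)
    attr(out, "grand_total") <- 0
    return(out)
  }
  tab <- sapply(SV_TYPES, function(tp) {
    vapply(samples, function(s)
      sum(df$sample_id == s & df$sv_type == tp), numeric(1))
  })
  tab <- matrix(tab, nrow = length(samples),
                dimnames = list(samples, SV_TYPES))
  out <- data.frame(sample_id = samples, tab, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$total <- rowSums(tab)
  attr(out, "grand_total") <- sum(out$total)
  out
}

#' Cohort prevalence summary of rearrangement counts
#'
#' Per SV type (and the total), the mean occurrence per tumor with the
#' reporting convention: means above 1 are rounded half-up to integers,
#' means of 1 or below to one decimal; min and max are reported unrounded.
#'
#' @param table Output of [tabulate_sv_counts()].
#' @return data.frame: `type`, `mean` (unrounded), `mean_reported`, `min`,
#'   `max`.
#' @export
summarize_prevalence <- function(table) {
  stopifnot(nrow(table) >= 1)
  types <- c(SV_TYPES, "total")
  rows <- lapply(types, function(tp) {
    v <- table[[tp]]
    m <- mean(v)
    rep_m <- if (m > 1) round_half_up(m, 0) else round_half_up(m, 1)
    data.frame(type = tp, mean = m, mean_reported = rep_m,
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gene copy-number status from significant regions
#'
#' A gene is `gain`/`loss` when it overlaps a significant region of that
#' direction by at least 1 bp; `neutral` otherwise. A gene overlapping
#' regions of both signs reports both, comma-separated.
#'
#' @param regions Region table ([call_regions()] output).
#' @param genes data.frame with `chrom`, `start`, `end`, `name`.
#' @return data.frame `name`, `status`.
#' @export
annotate_genes <- function(regions, genes) {
  status <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    hit <- regions$chrom == g$chrom &
      pmin(regions$end, g$end) - pmax(regions$start, g$start) >= 1
    dirs <- unique(regions$direction[hit])
    if (!length(dirs)) return("neutral")
    paste(sort(ifelse(dirs == "gain", "gain", "loss")), collapse = ",")
  }, character(1))
  data.frame(name = genes$name, status = status, stringsAsFactors = FALSE)
}

#' Count gene-fusion candidate calls
#'
#' Number of calls whose two links fall inside two distinct annotated genes
#' (interval arithmetic only; no ORF reasoning).
#'
#' @param calls An SV call table.
#' @param genes data.frame with `chrom`, `start`, `end`, `name`.
#' @return Integer count.
#' @export
count_gene_fusions <- function(calls, genes) {
  if (!nrow(calls)) return(0L)
  hit_gene <- function(chrom, start, end) {
    m <- which(genes$chrom == chrom &
                 pmin(genes$end, end) - pmax(genes$start, start) >= 1)
    if (length(m)) genes$name[m[1]] else NA_character_
  }
  n <- 0L
  for (i in seq_len(nrow(calls))) {
    g1 <- hit_gene(calls$chrom1[i], calls$start1[i], calls$end1[i])
    g2 <- hit_gene(calls$chrom2[i], calls$start2[i], calls$end2[i])
    if (!is.na(g1) && !is.na(g2) && g1 != g2) n <- n + 1L
  }
  n
}

#' Mann-Whitney rank-sum association test with midranks
#'
#' Two-sided Mann-Whitney U test. Ties are handled by midranks. For
#' combined sample sizes up to `exact_max` the p-value is computed by full
#' enumeration of all group assignments of the observed (tied) ranks:
#' `p = P(|U - n_a n_b / 2| >= |U_obs - n_a n_b / 2|)`. Larger samples use
#' the normal approximation with tie correction and continuity correction.
#' Missing values are dropped listwise.
#'
#' @param values_a,values_b Numeric vectors (NAs dropped).
#' @param exact_max Largest combined n for exact enumeration (default 20).
#' @return List: `U` (the smaller of U_a, U_b), `U_a`, `U_b`, `p`,
#'   `method`.
#' @export
ranksum_association <- function(values_a, values_b, exact_max = 20) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 non-missing values")
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)                      # midranks
  u_from_ranks <- function(ra) sum(ra) - n_a * (n_a + 1) / 2
  U_a <- u_from_ranks(rk[seq_len(n_a)])
  U_b <- n_a * n_b - U_a
  U <- min(U_a, U_b)
  mu <- n_a * n_b / 2
  if (n_a + n_b <= exact_max) {
    combos <- utils::combn(n_a + n_b, n_a)
    dev_obs <- abs(U_a - mu)
    devs <- abs(apply(combos, 2, function(ix) u_from_ranks(rk[ix])) - mu)
    p <- mean(devs >= dev_obs - 1e-9)
    method <- "exact enumeration"
  } else {
    n <- n_a + n_b
    ties <- table(rk)
    sigma2 <- n_a * n_b / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(U_a - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    method <- "normal approximation with tie correction"
  }
  list(U = U, U_a = U_a, U_b = U_b, p = min(p, 1), method = method)
}

#' Reference cohort tables shipped with the package
#'
#' Small plain-text reference tables from the published canine mammary
#' carcinoma cohort this package's methods were built for:
#'
#' * `"validated_sv_counts"` — validated rearrangement counts per tumor and
#'   SV type for the five sequenced tumors;
#' * `"sv_filter_counts"` — predicted aberration counts after initial
#'   detection and the two window-filter stages, per tumor;
#' * `"cfa27_cohort"` — CFA27 proximal-deletion status, Ki-67 score, ER and
#'   HER2 status for the 20-tumor screening cohort (ND = not determined).
#'
#' @param name One of the table names above.
#' @return data.frame.
#' @export
cohort_table <- function(name = c("validated_sv_counts",
                                  "sv_filter_counts", "cfa27_cohort")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "svcnv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
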