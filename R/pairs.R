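#' Mapped read-pair tables
#'
#' All sequencing input is represented as a table of mapped read pairs, one
#' row per pair, in a fixed TSV dialect:
#'
#' * `sample_id` — sample the pair belongs to
#' * `chrom1`, `pos1`, `strand1` — chromosome, 0-based leftmost position and
#'   strand (`+`/`-`) of the leftmost read (for intra-chromosomal pairs) or
#'   the read on the lower-sorting chromosome
#' * `chrom2`, `pos2`, `strand2` — same for the other read
#' * `insert` — apparent fragment length in bp (outer distance spanned by the
#'   pair); `-1` for inter-chromosomal pairs
#'
#' The concordant orientation convention is "innie" FR: opposite strands with
#' the leftmost read on the forward strand. The simulator emits this
#' convention and the signature classifier assumes it.
#'
#' @name pair-table
#' @keywords internal
NULL

PAIR_COLS <- c("sample_id", "chrom1", "pos1", "strand1",
               "chrom2", "pos2", "strand2", "insert")

#' Validate a mapped-pair table
#'
#' @param pairs A data.frame in the pair-table dialect.
#' @return The validated data.frame (invisibly classed `pair_table`).
#' @export
as_pair_table <- function(pairs) {
  miss <- setdiff(PAIR_COLS, names(pairs))
  if (length(miss))
    stop("pair table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(pairs) && any(!pairs$strand1 %in% c("+", "-")))
    stop("strand1 must be '+' or '-'")
  if (nrow(pairs) && any(!pairs$strand2 %in% c("+", "-")))
    stop("strand2 must be '+' or '-'")
  pairs <- pairs[, PAIR_COLS]
  class(pairs) <- unique(c("pair_table", class(pairs)))
  pairs
}

#' Read / write mapped pairs in the package TSV dialect
#'
#' @param path File path.
#' @return `read_pairs()` returns a validated pair table.
#' @export
read_pairs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(sample_id = "character",
                                         chrom1 = "character",
                                         chrom2 = "character",
                                         strand1 = "character",
                                         strand2 = "character"))
  as_pair_table(df)
}

#' @rdname read_pairs
#' @param pairs A pair table.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(as_pair_table(pairs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expand a pair table to individual read start positions
#'
#' Each pair contributes two read records, one per end, each on its own
#' chromosome. Used by the depth-of-coverage and Z-score counters, which
#' count read starts rather than pairs.
#'
#' @param pairs A pair table.
#' @return data.frame with columns `chrom`, `pos`.
#' @export
pairs_to_reads <- function(pairs) {
  pairs <- as_pair_table(pairs)
  data.frame(chrom = c(pairs$chrom1, pairs$chrom2),
             pos = c(pairs$pos1, pairs$pos2),
             stringsAsFactors = FALSE)
}
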