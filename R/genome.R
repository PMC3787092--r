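#' Define a genome as an ordered set of chromosomes
#'
#' A genome specification is the coordinate frame shared by the simulator and
#' every analysis stage: an ordered table of chromosome names and lengths.
#' All coordinates in the package are 0-based half-open.
#'
#' @param chromosomes Character vector of unique chromosome names.
#' @param lengths Integer-ish vector of chromosome lengths in base pairs,
#'   parallel to `chromosomes`; all must be positive.
#' @return A `genome_spec` object: a data.frame with columns `chrom` and
#'   `length`, ordered as given.
#' @examples
#' genome_spec(paste0("chr", 1:5), rep(10e6, 5))
#' @export
genome_spec <- function(chromosomes, lengths) {
  chromosomes <- as.character(chromosomes)
  lengths <- as.numeric(lengths)
  if (length(chromosomes) != length(lengths))
    stop("chromosomes and lengths must have equal length")
  if (anyDuplicated(chromosomes))
    stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  out <- data.frame(chrom = chromosomes, length = lengths,
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_spec", "data.frame")
  out
}

#' Total genome length
#' @param genome A [genome_spec()].
#' @return Total length G in base pairs.
#' @export
genome_length <- function(genome) sum(genome$length)

# length lookup by chromosome name; errors on unknown names
chrom_length <- function(genome, chrom) {
  idx <- match(chrom, genome$chrom)
  if (anyNA(idx)) {
    bad <- unique(chrom[is.na(idx)])
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  }
  genome$length[idx]
}
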