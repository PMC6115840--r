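#' N50 of a length set
#'
#' The smallest length L such that pieces of length >= L together contain
#' at least half of the total bases.
#'
#' @param lengths Positive numeric vector of contig or read lengths (bp).
#' @return N50 in bp (an element of `lengths`).
#' @export
#' @examples
#' n50(c(rep(1, 10), 91))  # 91
n50 <- function(lengths) {
  if (!length(lengths)) stop("empty length set", call. = FALSE)
  if (any(lengths <= 0) || anyNA(lengths))
    stop("lengths must be positive", call. = FALSE)
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Read-set summary after a minimum-length filter
#'
#' Removes reads strictly shorter than `min_len` and summarises the kept
#' reads.  The mean length is truncated to an integer number of bp
#' (floor), the convention under which 128,622,819,749 bp over 9,859,413
#' reads reports as 13,045 bp.
#'
#' @param lengths Read lengths in bp.
#' @param min_len Minimum length kept (default 500 bp).
#' @return List: `n_input`, `n_kept`, `frac_reads_removed`,
#'   `frac_bases_removed`, `mean_bp` (floored), `max_bp`, `sd_bp`,
#'   `n50_bp`.
#' @export
read_stats <- function(lengths, min_len = 500) {
  if (!length(lengths)) stop("empty length set", call. = FALSE)
  lengths <- as.numeric(lengths)
  if (any(lengths <= 0) || anyNA(lengths))
    stop("lengths must be positive", call. = FALSE)
  kept <- lengths[lengths >= min_len]
  if (!length(kept))
    stop("all reads removed by the ", min_len, " bp filter", call. = FALSE)
  total <- sum(lengths)
  total_kept <- sum(kept)
  list(n_input = length(lengths),
       n_kept = length(kept),
       frac_reads_removed = 1 - length(kept) / length(lengths),
       frac_bases_removed = 1 - total_kept / total,
       mean_bp = floor(total_kept / length(kept)),
       max_bp = max(kept),
       sd_bp = stats::sd(kept),
       n50_bp = n50(kept))
}

#' Phased (heterozygous) genome fraction
#'
#' In a phased diploid assembly the secondary (haplotig) contigs cover
#' the regions heterozygous enough to be separated into two haplotypes,
#' so the secondary/primary total-size ratio estimates the phased genome
#' fraction.
#'
#' @param primary_total_bp Total size of the primary assembly (> 0).
#' @param secondary_total_bp Total size of the secondary haplotype
#'   assembly (>= 0).
#' @return Fraction (may exceed 1 for fully phased genomes).
#' @export
#' @examples
#' phased_fraction(1064991496, 432637353)  # ~0.406
phased_fraction <- function(primary_total_bp, secondary_total_bp) {
  if (!is.numeric(primary_total_bp) || primary_total_bp <= 0)
    stop("primary assembly size must be positive", call. = FALSE)
  if (!is.numeric(secondary_total_bp) || secondary_total_bp < 0)
    stop("secondary assembly size must be non-negative", call. = FALSE)
  secondary_total_bp / primary_total_bp
}

#' Contig-set summary
#'
#' @param lengths Contig lengths in bp.
#' @return List: `n`, `total_bp`, `n50_bp`, `mean_bp`, `max_bp`.
#' @export
contig_stats <- function(lengths) {
  if (!length(lengths)) stop("empty length set", call. = FALSE)
  lengths <- as.numeric(lengths)
  list(n = length(lengths), total_bp = sum(lengths), n50_bp = n50(lengths),
       mean_bp = mean(lengths), max_bp = max(lengths))
}

# Lengths from a FASTA/FASTA.gz or a one-column list file.
read_length_set <- function(path) {
  check_file_exists(path, "length input")
  first <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path,
                     n = 1L, warn = FALSE)
  if (startsWith(first, ">")) {
    ss <- Biostrings::readDNAStringSet(path)
    as.numeric(Biostrings::width(ss))
  } else {
    v <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#")
    v
  }
}
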