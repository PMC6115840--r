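STOP_CODONS <- c("TAA", "TAG", "TGA")

# Complete reading frame: starts with ATG, length divisible by 3, ends in
# a stop codon, no internal stop.  A codon containing N is neither start,
# stop, nor internal stop, so any N disqualifies the start/stop tests it
# falls in but never creates a false internal stop.
is_complete_orf <- function(seq) {
  n <- nchar(seq)
  if (n < 6L || n %% 3L != 0L) return(FALSE)
  if (substr(seq, 1L, 3L) != "ATG") return(FALSE)
  codons <- substring(seq, seq.int(1L, n - 2L, 3L), seq.int(3L, n, 3L))
  if (!(codons[length(codons)] %in% STOP_CODONS)) return(FALSE)
  !any(codons[-length(codons)][-1L] %in% STOP_CODONS)
}

# Longest ORF fraction used to describe fragmentary sequences: from the
# first ATG in the first `scan` nt to the next in-frame stop (or the end).
orf_fraction <- function(seq, scan = 30L) {
  n <- nchar(seq)
  m <- regexpr("ATG", substr(seq, 1L, min(n, scan + 2L)), fixed = TRUE)
  if (m < 0L) return(0)
  starts <- seq.int(m, n - 2L, 3L)
  codons <- substring(seq, starts, starts + 2L)
  stop_at <- which(codons %in% STOP_CODONS)
  orf_codons <- if (length(stop_at)) stop_at[1] else length(codons)
  (orf_codons * 3L) / n
}

#' Classify a coding prediction by reading-frame integrity
#'
#' A sequence with a complete reading frame (ATG start, terminal stop,
#' length divisible by three, no internal stop) is `functional`.  A
#' sequence that is not functional but can be made so by deleting one
#' nucleotide or inserting one nucleotide anywhere - the signature of a
#' single sequencing error - is `ambiguous`; the first recovering edit
#' found (deletions scanned left to right, then insertions) is reported
#' as evidence.  Everything else is a `pseudogene`.  Non-recoverable
#' sequences are described as fragmentary when no ATG falls within the
#' first `max_start_scan` nt or the longest open frame covers less than
#' `min_orf_frac` of the sequence, and as frame-disrupted otherwise.
#'
#' @param seq Nucleotide string over A, C, G, T, N, length >= 6.
#' @param max_start_scan Window (nt) in which a start codon must occur
#'   (default 30).
#' @param min_orf_frac Minimum ORF fraction of the sequence below which a
#'   non-recoverable sequence is described as fragmentary (default 0.5).
#' @return A `gene_status` list: `status` (one of `functional`,
#'   `ambiguous`, `pseudogene`) and `evidence` (text).
#' @export
#' @examples
#' classify_orf("ATGAAATAA")$status     # functional
#' classify_orf("ATGAAAATAA")$status    # ambiguous (one extra base)
classify_orf <- function(seq, max_start_scan = 30L, min_orf_frac = 0.5) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    stop("non-nucleotide character in sequence: '",
         regmatches(seq, regexpr("[^ACGTN]", seq)), "'", call. = FALSE)
  n <- nchar(seq)
  if (n < 6L) stop("sequence shorter than 6 nt", call. = FALSE)
  if (is_complete_orf(seq))
    return(structure(list(status = "functional",
                          evidence = "complete reading frame"),
                     class = "gene_status"))
  for (i in seq_len(n)) {
    cand <- paste0(substr(seq, 1L, i - 1L), substr(seq, i + 1L, n))
    if (is_complete_orf(cand))
      return(structure(list(
        status = "ambiguous",
        evidence = sprintf("deleting 1 nt at position %d recovers a complete frame", i)),
        class = "gene_status"))
  }
  for (i in 0:n) {
    for (b in c("A", "C", "G", "T")) {
      cand <- paste0(substr(seq, 1L, i), b, substr(seq, i + 1L, n))
      if (is_complete_orf(cand))
        return(structure(list(
          status = "ambiguous",
          evidence = sprintf("inserting %s after position %d recovers a complete frame",
                             b, i)),
          class = "gene_status"))
    }
  }
  no_start <- regexpr("ATG", substr(seq, 1L, min(n, max_start_scan + 2L)),
                      fixed = TRUE) < 0L
  frac <- orf_fraction(seq, max_start_scan)
  structure(list(
    status = "pseudogene",
    evidence = if (no_start)
      sprintf("no start codon within the first %d nt", max_start_scan)
    else if (frac < min_orf_frac)
      sprintf("fragmentary reading frame (open for %.0f%% of the sequence)",
              100 * frac)
    else "disrupted frame; no single-nucleotide edit recovers it"),
    class = "gene_status")
}

#' @export
print.gene_status <- function(x, ...) {
  cat(sprintf("%s (%s)\n", x$status, x$evidence))
  invisible(x)
}

#' Screen a FASTA of coding predictions
#'
#' Applies [classify_orf()] to every sequence of a nucleotide FASTA.
#'
#' @param fasta Path to a FASTA file, or a named character vector of
#'   sequences.
#' @param out Optional path; when given, the result is written as TSV
#'   (`seq_id`, `status`, `evidence`).
#' @param ... Passed to [classify_orf()].
#' @return `data.frame` with columns `seq_id`, `status`, `evidence`.
#' @export
gene_screen <- function(fasta, out = NULL, ...) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    stats::setNames(as.character(ss), sub("\\s.*", "", names(ss)))
  } else fasta
  if (!length(seqs)) stop("no sequences to screen", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  res <- lapply(seqs, classify_orf, ...)
  df <- data.frame(seq_id = names(seqs),
                   status = vapply(res, `[[`, character(1), "status"),
                   evidence = vapply(res, `[[`, character(1), "evidence"),
                   stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(out)) write_tsv(df, out)
  df
}
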