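#' Windowed ROH scan of a genome
#'
#' High-level driver for the ROH stage: reads filtered SNPs from a VCF,
#' tiles contigs into fixed windows, counts SNPs per window, calls ROH
#' segments under each requested heterozygosity threshold and computes
#' genome-wide and per-contig fROH.
#'
#' @param vcf Path to a VCF of SNP calls (plain or gzipped).
#' @param contigs Contig table (`contig`, `length`), path to a 2-column
#'   TSV, or `NULL` to take lengths from the VCF `##contig` header lines.
#' @param window_size Window size in bp (default 100 kb).
#' @param min_contig_len Minimum contig length retained (default 500 kb).
#' @param thresholds Character or numeric vector of thresholds understood
#'   by [threshold_spec()].  Defaults to perfect autozygosity plus the
#'   four standard presets.
#' @return An object of class `roh_scan` with components `windows` (the
#'   populated window table), `results` (per threshold: `threshold`,
#'   `segments`, `froh`), `per_contig` (per-contig fROH summary under the
#'   first threshold), `n_snps`, `total_contig_bp` and `encounter_rate_bp`
#'   (bp per SNP over retained contigs).
#' @seealso [call_roh()], [froh()], [per_contig_froh()]
#' @export
roh_scan <- function(vcf, contigs = NULL, window_size = 100000L,
                     min_contig_len = 500000L,
                     thresholds = c("perfect", "0.01", "0.02", "0.04", "0.1")) {
  if (is.character(contigs) && length(contigs) == 1L)
    contigs <- read_contig_lengths(contigs)
  if (is.null(contigs)) contigs <- contigs_from_vcf(vcf)
  snps <- read_snps(vcf, contigs)
  wt <- tile_windows(contigs, window_size, min_contig_len)
  wt <- count_snps_per_window(snps, wt)
  specs <- lapply(thresholds, threshold_spec)
  results <- lapply(specs, function(th) {
    seg <- call_roh(wt, th)
    list(threshold = th, segments = seg, froh = froh(wt, seg, th))
  })
  names(results) <- vapply(specs, `[[`, character(1), "label")
  n_snps <- sum(wt$snp_count)
  total_bp <- sum(attr(wt, "contig_lengths")$length)
  structure(list(
    windows = wt,
    results = results,
    per_contig = per_contig_froh(wt, results[[1]]$segments),
    n_snps = n_snps,
    total_contig_bp = total_bp,
    encounter_rate_bp = if (n_snps > 0) snp_encounter_rate(n_snps, total_bp) else NA_real_,
    window_size = window_size_of(wt)),
    class = "roh_scan")
}

#' @export
print.roh_scan <- function(x, ...) {
  cat("Windowed ROH scan\n")
  cat(sprintf("  %d contigs retained (%.3g bp), %d windows of %g bp, %d SNPs\n",
              nrow(x$per_contig$per_contig), x$total_contig_bp,
              nrow(x$windows), x$window_size, x$n_snps))
  if (is.finite(x$encounter_rate_bp))
    cat(sprintf("  SNP encounter rate: 1 per %.0f bp\n", x$encounter_rate_bp))
  for (r in x$results)
    cat(sprintf("  fROH [%s]: %d/%d windows = %.1f%%\n",
                r$threshold$label, r$froh$n_roh_windows,
                r$froh$total_windows, r$froh$froh_percent))
  invisible(x)
}

#' @export
summary.roh_scan <- function(object, ...) {
  df <- do.call(rbind, lapply(object$results, function(r) {
    data.frame(threshold = r$threshold$label,
               max_snps_per_kb = r$threshold$max_snps_per_kb,
               n_segments = nrow(r$segments),
               n_roh_windows = r$froh$n_roh_windows,
               total_windows = r$froh$total_windows,
               froh = r$froh$froh,
               froh_percent = r$froh$froh_percent,
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

#' @export
plot.roh_scan <- function(x, ...) {
  s <- summary(x)
  graphics::barplot(s$froh_percent, names.arg = s$threshold,
                    ylab = "fROH (%)", xlab = "heterozygosity threshold (SNP/kb)",
                    main = "Autozygous genome fraction by threshold", ...)
  invisible(x)
}
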