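#' Read a contig-length table
#'
#' Reads a two-column tab-separated file of contig identifiers and lengths
#' in base pairs.  A header line is optional and detected automatically.
#'
#' @param path Path to a 2-column TSV (`contig_id`, `length`).
#' @return A `data.frame` with columns `contig` (character) and `length`
#'   (numeric, bp).
#' @export
read_contig_lengths <- function(path) {
  check_file_exists(path, "contig length table")
  first <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "character", nrows = 1L)
  has_header <- ncol(first) >= 2L && is.na(suppressWarnings(as.numeric(first[[2]])))
  df <- if (has_header)
    utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  else
    utils::read.table(path, sep = "\t", header = FALSE,
                      col.names = c("contig", "length"),
                      stringsAsFactors = FALSE)
  names(df)[1:2] <- c("contig", "length")
  df$contig <- as.character(df$contig)
  df$length <- as.numeric(df$length)
  validate_contig_lengths(df[, c("contig", "length")])
}

validate_contig_lengths <- function(df) {
  if (!all(c("contig", "length") %in% names(df)))
    stop("contig table needs columns 'contig' and 'length'", call. = FALSE)
  if (anyNA(df$length) || any(df$length <= 0))
    stop("contig lengths must be positive", call. = FALSE)
  if (anyDuplicated(df$contig))
    stop("duplicate contig ids: ",
         paste(unique(df$contig[duplicated(df$contig)]), collapse = ", "),
         call. = FALSE)
  df
}

#' Extract contig lengths from VCF header lines
#'
#' Parses `##contig=<ID=...,length=...>` lines from a VCF header so that a
#' separate contig-length table is not required.
#'
#' @param vcf_path Path to a VCF file (plain or gzipped).
#' @return A `data.frame` with columns `contig` and `length`.
#' @export
contigs_from_vcf <- function(vcf_path) {
  check_file_exists(vcf_path, "VCF")
  con <- if (grepl("\\.gz$", vcf_path)) gzfile(vcf_path, "rt") else file(vcf_path, "rt")
  on.exit(close(con))
  hdr <- character()
  repeat {
    chunk <- readLines(con, n = 512L, warn = FALSE)
    if (!length(chunk)) break
    meta <- grepl("^##", chunk)
    hdr <- c(hdr, chunk[meta])
    if (!all(meta)) break
  }
  lines <- grep("^##contig=<", hdr, value = TRUE)
  if (!length(lines))
    stop("no ##contig lines in VCF header: ", vcf_path, call. = FALSE)
  id <- sub(".*[<,]ID=([^,>]+).*", "\\1", lines)
  len <- suppressWarnings(as.numeric(sub(".*[<,]length=([0-9]+).*", "\\1", lines)))
  if (anyNA(len))
    stop("##contig lines without a length= field in ", vcf_path, call. = FALSE)
  validate_contig_lengths(data.frame(contig = id, length = len,
                                     stringsAsFactors = FALSE))
}

#' Read filtered SNP positions from a VCF
#'
#' Loads a VCF and keeps only biallelic SNP records (single-base REF and
#' ALT) whose FILTER field is `PASS` or `.` and whose genotypes, when
#' present, are fully called.  Indels, multi-allelic sites and records
#' with missing genotypes are dropped.  Positions are converted from the
#' 1-based VCF convention to 0-based coordinates.
#'
#' @param vcf_path Path to a VCF file (plain or bgzipped).
#' @param contigs Optional contig table (see [read_contig_lengths()]).
#'   When supplied, a VCF record on a contig absent from the table is an
#'   error.
#' @return Named list of sorted 0-based integer position vectors, one per
#'   contig present in the VCF after filtering.
#' @export
read_snps <- function(vcf_path, contigs = NULL) {
  check_file_exists(vcf_path, "VCF")
  v <- tryCatch(
    vcfR::read.vcfR(vcf_path, verbose = FALSE),
    error = function(e) {
      stop("malformed or unreadable VCF ", vcf_path, ": ",
           locate_vcf_defect(vcf_path, conditionMessage(e)), call. = FALSE)
    })
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    res <- list()
  } else {
    ref <- fix[, "REF"]
    alt <- fix[, "ALT"]
    filt <- fix[, "FILTER"]
    keep <- !is.na(ref) & !is.na(alt) &
      ref %in% c("A", "C", "G", "T") &
      alt %in% c("A", "C", "G", "T") &
      (is.na(filt) | filt %in% c("PASS", "."))
    gt <- v@gt
    if (!is.null(gt) && ncol(gt) >= 2L) {
      fmt1 <- strsplit(gt[, 1L], ":", fixed = TRUE)
      gt_idx <- vapply(fmt1, function(f) match("GT", f), integer(1))
      smp <- gt[, -1L, drop = FALSE]
      miss <- rep(FALSE, nrow(gt))
      gt_first <- !anyNA(gt_idx) && all(gt_idx == 1L)
      for (j in seq_len(ncol(smp))) {
        val <- if (gt_first) sub(":.*", "", smp[, j]) else
          vapply(seq_len(nrow(smp)), function(i) {
            if (is.na(gt_idx[i]) || is.na(smp[i, j])) return(NA_character_)
            strsplit(smp[i, j], ":", fixed = TRUE)[[1]][gt_idx[i]]
          }, character(1))
        miss <- miss | is.na(val) | grepl(".", val, fixed = TRUE)
      }
      keep <- keep & !miss
    }
    chrom <- fix[keep, "CHROM"]
    pos0 <- as.integer(fix[keep, "POS"]) - 1L
    res <- lapply(split(pos0, chrom), function(p) sort(unique(p)))
  }
  if (!is.null(contigs)) {
    contigs <- validate_contig_lengths(contigs)
    unknown <- setdiff(names(res), contigs$contig)
    if (length(unknown))
      stop("VCF contigs absent from the contig table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  res
}

# Best-effort line diagnosis for a VCF that the reader rejected.
locate_vcf_defect <- function(path, fallback) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) NULL)
  if (!is.null(lines)) {
    body <- which(!startsWith(lines, "#"))
    for (i in body) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 8L || is.na(suppressWarnings(as.integer(f[2]))))
        return(paste0("line ", i, " is not a valid VCF record"))
    }
  }
  fallback
}

#' Tile contigs into fixed-size windows
#'
#' Builds the non-overlapping window grid over which SNP densities and ROH
#' are assessed.  Contigs shorter than `min_contig_len` are dropped.  Each
#' retained contig is covered by `ceiling(length / window_size)` windows;
#' the final window may be shorter than `window_size` on the sequence, but
#' it still counts as one full window of the denominator, so the
#' cumulative window length can exceed the summed contig lengths.
#'
#' @param contigs Contig table (`contig`, `length`) or named numeric
#'   vector of lengths.
#' @param window_size Window size in bp (default 100 kb).
#' @param min_contig_len Minimum contig length retained (default 500 kb,
#'   i.e. at least five consecutive windows).  Must be at least
#'   `window_size`.
#' @return A `window_table`: a `data.frame` with columns `contig`,
#'   `window_index` (0-based), `start`, `end` (0-based half-open bp) and
#'   `snp_count` (zeroed), with the window size kept as an attribute.
#' @export
tile_windows <- function(contigs, window_size = 100000L, min_contig_len = 500000L) {
  if (is.numeric(contigs) && !is.null(names(contigs)))
    contigs <- data.frame(contig = names(contigs), length = as.numeric(contigs),
                          stringsAsFactors = FALSE)
  contigs <- validate_contig_lengths(contigs)
  window_size <- as.numeric(window_size)
  if (window_size <= 0) stop("window_size must be positive", call. = FALSE)
  if (min_contig_len < window_size)
    stop("min_contig_len (", min_contig_len, ") smaller than window_size (",
         window_size, "): every retained contig must hold at least one window",
         call. = FALSE)
  if (min_contig_len < 5 * window_size)
    warning("min_contig_len below five windows; short contigs cannot hold ",
            "the minimum run of five consecutive windows", call. = FALSE)
  keep <- contigs[contigs$length >= min_contig_len, , drop = FALSE]
  if (nrow(keep) == 0L)
    stop("no contigs of length >= ", min_contig_len, call. = FALSE)
  parts <- lapply(seq_len(nrow(keep)), function(i) {
    len <- keep$length[i]
    n <- as.integer(ceiling(len / window_size))
    idx <- seq_len(n) - 1L
    start <- idx * window_size
    data.frame(contig = keep$contig[i], window_index = idx, start = start,
               end = pmin(start + window_size, len), snp_count = 0L,
               stringsAsFactors = FALSE)
  })
  wt <- do.call(rbind, parts)
  rownames(wt) <- NULL
  attr(wt, "window_size") <- window_size
  attr(wt, "contig_lengths") <- keep
  class(wt) <- c("window_table", "data.frame")
  wt
}

window_size_of <- function(table) {
  ws <- attr(table, "window_size")
  if (is.null(ws)) stop("not a window table (missing window_size attribute)",
                        call. = FALSE)
  ws
}

#' Count SNPs per window
#'
#' Assigns each 0-based SNP position to the unique window containing it
#' and fills the `snp_count` column.  Positions on contigs that were
#' dropped at the tiling stage are ignored; a position at or beyond the
#' contig end is an error.
#'
#' @param positions Named list of 0-based position vectors, as returned by
#'   [read_snps()].
#' @param table A `window_table` from [tile_windows()].
#' @return The window table with `snp_count` populated.
#' @export
count_snps_per_window <- function(positions, table) {
  ws <- window_size_of(table)
  counts <- table$snp_count
  counts[] <- 0L
  for (ctg in intersect(names(positions), unique(table$contig))) {
    rows <- which(table$contig == ctg)
    len <- max(table$end[rows])
    pos <- positions[[ctg]]
    bad <- pos < 0 | pos >= len
    if (any(bad))
      stop("SNP position ", pos[which(bad)[1]], " outside contig ", ctg,
           " (length ", len, ")", call. = FALSE)
    idx <- floor(pos / ws) + 1L
    counts[rows] <- tabulate(idx, nbins = length(rows))
  }
  table$snp_count <- counts
  table
}

#' Heterozygosity threshold for ROH window qualification
#'
#' A window qualifies as part of a run of homozygosity when its SNP count
#' is at most `max_snps_per_kb` times the window size in kb (inclusive
#' comparison).  `"perfect"` (0 SNP/kb) encodes perfect autozygosity; the
#' four standard non-zero presets are 0.01, 0.02, 0.04 and 0.1 SNP/kb,
#' i.e. at most 1 SNP per 100, 50, 25 and 10 kb.
#'
#' @param x `"perfect"`, a numeric rate in SNP/kb, or a string holding one
#'   (e.g. `"0.02"`).
#' @param label Optional label used in reports; defaults to `"perfect"` or
#'   the rate itself.
#' @return A `threshold_spec` list with fields `max_snps_per_kb`, `label`.
#' @export
threshold_spec <- function(x, label = NULL) {
  if (inherits(x, "threshold_spec")) return(x)
  if (is.character(x) && length(x) == 1L && tolower(x) == "perfect") {
    rate <- 0
    if (is.null(label)) label <- "perfect"
  } else {
    rate <- suppressWarnings(as.numeric(x))
    if (length(rate) != 1L || is.na(rate) || rate < 0)
      stop("threshold must be 'perfect' or a non-negative SNP/kb rate",
           call. = FALSE)
    if (is.null(label)) label <- if (rate == 0) "perfect" else format(rate)
  }
  structure(list(max_snps_per_kb = rate, label = label),
            class = "threshold_spec")
}

#' Call ROH segments on a window table
#'
#' A run of homozygosity is a maximal run of consecutive qualifying
#' windows within one contig; a single non-qualifying window terminates a
#' run, and runs never span contigs.  Segment length is counted in whole
#' windows (`n_windows * window_size`), matching the denominator
#' convention of [froh()].
#'
#' @param table A populated `window_table`.
#' @param threshold A [threshold_spec()] (or something coercible to one).
#' @return `data.frame` of segments: `contig`, `first_window`,
#'   `last_window` (inclusive 0-based window indices), `n_windows`,
#'   `length_bp`.
#' @export
call_roh <- function(table, threshold) {
  threshold <- threshold_spec(threshold)
  ws <- window_size_of(table)
  limit <- threshold$max_snps_per_kb * ws / 1000
  out <- list()
  for (ctg in unique(table$contig)) {
    rows <- which(table$contig == ctg)
    qual <- table$snp_count[rows] <= limit
    r <- rle(qual)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values)
    if (length(hit))
      out[[ctg]] <- data.frame(
        contig = ctg,
        first_window = table$window_index[rows][starts[hit]],
        last_window = table$window_index[rows][ends[hit]],
        n_windows = r$lengths[hit],
        stringsAsFactors = FALSE)
  }
  seg <- if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(), first_window = integer(),
               last_window = integer(), n_windows = integer(),
               stringsAsFactors = FALSE)
  rownames(seg) <- NULL
  seg$length_bp <- seg$n_windows * ws
  attr(seg, "threshold") <- threshold
  attr(seg, "window_size") <- ws
  seg
}

#' Genome-wide autozygosity fraction (fROH)
#'
#' fROH is the summed ROH segment length divided by the cumulative length
#' of all windows.  Because segments and the denominator are both counted
#' in whole windows, this equals the fraction of windows inside ROH.
#'
#' @param table The `window_table` the segments were called from.
#' @param segments Segment table from [call_roh()].
#' @param threshold Optional [threshold_spec()]; defaults to the one
#'   recorded on `segments`.
#' @return A `froh_result` list: `threshold_label`, `n_roh_windows`,
#'   `total_windows`, `cumulative_window_bp`, `froh` (fraction) and
#'   `froh_percent` (one decimal, half-up).
#' @export
froh <- function(table, segments, threshold = NULL) {
  ws <- window_size_of(table)
  if (nrow(table) == 0L)
    stop("empty window table: fROH denominator undefined", call. = FALSE)
  if (is.null(threshold)) threshold <- attr(segments, "threshold")
  n_roh <- sum(segments$n_windows)
  total <- nrow(table)
  frac <- (n_roh * ws) / (total * ws)
  structure(list(
    threshold_label = if (is.null(threshold)) NA_character_ else threshold$label,
    n_roh_windows = n_roh,
    total_windows = total,
    cumulative_window_bp = total * ws,
    froh = frac,
    froh_percent = percent_one_decimal(frac)),
    class = "froh_result")
}

#' @export
print.froh_result <- function(x, ...) {
  cat(sprintf("fROH [%s]: %d of %d windows in ROH = %.4f (%.1f%%)\n",
              x$threshold_label, x$n_roh_windows, x$total_windows,
              x$froh, x$froh_percent))
  invisible(x)
}

#' Per-contig autozygosity fractions
#'
#' Computes, for every contig, the fraction of its own windows lying in
#' ROH, plus the minimum, maximum, median and mean over contigs (median of
#' an even-length set is the mean of the two middle values).
#'
#' @inheritParams froh
#' @return A `contig_froh` list: `per_contig` data.frame (`contig`,
#'   `n_windows`, `n_roh_windows`, `froh`) and scalar `min`, `max`,
#'   `median`, `mean`.
#' @export
per_contig_froh <- function(table, segments) {
  ctgs <- unique(table$contig)
  tot <- vapply(ctgs, function(c) sum(table$contig == c), numeric(1))
  roh <- vapply(ctgs, function(c) sum(segments$n_windows[segments$contig == c]),
                numeric(1))
  per <- data.frame(contig = ctgs, n_windows = as.integer(tot),
                    n_roh_windows = as.integer(roh), froh = roh / tot,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(per_contig = per,
                 min = min(per$froh), max = max(per$froh),
                 median = stats::median(per$froh), mean = mean(per$froh)),
            class = "contig_froh")
}

#' @export
print.contig_froh <- function(x, ...) {
  cat(sprintf(
    "per-contig fROH over %d contigs: min %.1f%%, max %.1f%%, median %.1f%%, mean %.1f%%\n",
    nrow(x$per_contig), 100 * x$min, 100 * x$max, 100 * x$median, 100 * x$mean))
  invisible(x)
}

#' SNP encounter rate
#'
#' Average spacing between SNPs if they were evenly distributed: total
#' sequence length divided by the number of SNPs, in bp per SNP.
#'
#' @param n_snps Number of SNPs (> 0).
#' @param total_bp Total sequence length in bp (> 0).
#' @return bp per SNP (numeric).
#' @export
snp_encounter_rate <- function(n_snps, total_bp) {
  if (!is.numeric(n_snps) || n_snps <= 0)
    stop("n_snps must be positive: encounter rate undefined", call. = FALSE)
  if (!is.numeric(total_bp) || total_bp <= 0)
    stop("total_bp must be positive", call. = FALSE)
  total_bp / n_snps
}
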