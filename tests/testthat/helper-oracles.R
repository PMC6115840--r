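# Independent oracles and small generators used across the test files.
# Oracles are deliberately written with different primitives than the
# implementation they check.

# Brute-force run-length ROH scanner: walk windows one by one.
oracle_roh <- function(counts_by_contig, window_size, max_snps_per_kb) {
  limit <- max_snps_per_kb * window_size / 1000
  out <- data.frame(contig = character(), first_window = integer(),
                    last_window = integer(), n_windows = integer(),
                    stringsAsFactors = FALSE)
  for (ctg in names(counts_by_contig)) {
    counts <- counts_by_contig[[ctg]]
    run_start <- NA_integer_
    for (i in seq_along(counts)) {
      if (counts[i] <= limit) {
        if (is.na(run_start)) run_start <- i
      } else if (!is.na(run_start)) {
        out <- rbind(out, data.frame(contig = ctg,
                                     first_window = run_start - 1L,
                                     last_window = i - 2L,
                                     n_windows = i - run_start))
        run_start <- NA_integer_
      }
    }
    if (!is.na(run_start))
      out <- rbind(out, data.frame(contig = ctg,
                                   first_window = run_start - 1L,
                                   last_window = length(counts) - 1L,
                                   n_windows = length(counts) - run_start + 1L))
  }
  out$length_bp <- out$n_windows * window_size
  rownames(out) <- NULL
  out
}

# Cumulative-sum N50 oracle on the ascending sort.
oracle_n50 <- function(lengths) {
  s <- sort(lengths)
  half <- sum(lengths) / 2
  acc <- 0
  for (i in seq(length(s), 1)) {
    acc <- acc + s[i]
    if (acc >= half) return(s[i])
  }
}

# Exhaustive single-edit ORF oracle built on Biostrings translation.
oracle_is_orf <- function(seq) {
  n <- nchar(seq)
  if (n < 6 || n %% 3 != 0 || grepl("N", seq, fixed = TRUE)) {
    if (grepl("N", seq, fixed = TRUE)) return(FALSE)
    if (n < 6 || n %% 3 != 0) return(FALSE)
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(seq)))
  startsWith(aa, "M") && endsWith(aa, "*") &&
    !grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE)
}

oracle_classify <- function(seq) {
  if (oracle_is_orf(seq)) return("functional")
  n <- nchar(seq)
  cands <- character()
  for (i in seq_len(n))
    cands <- c(cands, paste0(substr(seq, 1, i - 1), substr(seq, i + 1, n)))
  for (i in 0:n)
    for (b in c("A", "C", "G", "T"))
      cands <- c(cands, paste0(substr(seq, 1, i), b, substr(seq, i + 1, n)))
  if (any(vapply(cands, oracle_is_orf, logical(1)))) "ambiguous" else "pseudogene"
}

# Random window table over a few contigs, counts in 0..max_count.
random_window_table <- function(n_contigs = 3, max_windows = 12,
                                max_count = 3, window_size = 1e5) {
  lens <- sample(5:max_windows, n_contigs, replace = TRUE) * window_size
  names(lens) <- paste0("c", seq_len(n_contigs))
  wt <- tile_windows(lens, window_size, min_contig_len = 5 * window_size)
  wt$snp_count <- sample(0:max_count, nrow(wt), replace = TRUE)
  wt
}

counts_by_contig <- function(wt) {
  lapply(split(wt$snp_count, wt$contig), as.integer)
}

# Random complete ORF: ATG + random non-stop codons + stop.
random_orf <- function(n_codons = NULL) {
  if (is.null(n_codons)) n_codons <- sample(3:40, 1)
  gc <- Biostrings::GENETIC_CODE
  safe <- names(gc)[gc != "*" & gc != "M"]
  paste0(c("ATG", sample(safe, n_codons - 2, replace = TRUE),
           sample(c("TAA", "TAG", "TGA"), 1)), collapse = "")
}

# Plain mean silhouette on Euclidean distances.
mean_silhouette <- function(x, labels) {
  d <- as.matrix(dist(x))
  sil <- vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(x)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    if (is.nan(a)) a <- 0
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

# Minimal VCF writer for hand-made fixtures.
write_tiny_vcf <- function(path, contigs, records) {
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                      as.integer(contigs)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
  writeLines(c(header, records), path)
  path
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "consgen")
}
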