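#' Specification of a simulated diploid SNP landscape
#'
#' Describes a mosaic genome: autozygous tracts (rate `rate_in_tract`,
#' usually 0 SNP/kb) alternating with background sequence whose SNP rate
#' is either uniform or drawn per 100-kb window from a mixture of gamma
#' distributions.  Tract and gap lengths are exponential; the expected
#' autozygous fraction of each contig is `autozygous_fraction`.
#'
#' @param contig_lengths Named numeric vector or `data.frame`
#'   (`contig`, `length`) of contig sizes in bp.
#' @param autozygous_fraction Expected fraction of each contig inside
#'   autozygous tracts; a scalar or one value per contig.
#' @param tract_length_mean Mean autozygous tract length in bp
#'   (exponential draws).
#' @param rate_in_tract SNP rate inside tracts, SNP/kb.
#' @param background Either `list(model = "uniform", rate_per_kb = r)` or
#'   `list(model = "gamma_mixture", weights = w, shapes = a,
#'   means_per_kb = m)`, the latter drawing each window's background rate
#'   from component i with probability `w[i]` and
#'   `Gamma(shape = a[i], mean = m[i])`.
#' @param seed Integer seed; every output of [simulate_genome()] is a
#'   pure function of the spec including this seed.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(contig_lengths,
                        autozygous_fraction = 0,
                        tract_length_mean = 1e6,
                        rate_in_tract = 0,
                        background = list(model = "uniform", rate_per_kb = 1),
                        seed = 1L) {
  if (is.numeric(contig_lengths) && !is.null(names(contig_lengths)))
    contig_lengths <- data.frame(contig = names(contig_lengths),
                                 length = as.numeric(contig_lengths),
                                 stringsAsFactors = FALSE)
  contig_lengths <- validate_contig_lengths(contig_lengths)
  f <- rep_len(autozygous_fraction, nrow(contig_lengths))
  if (any(f < 0 | f > 1))
    stop("autozygous_fraction must lie in [0, 1]", call. = FALSE)
  if (rate_in_tract < 0) stop("rate_in_tract must be >= 0", call. = FALSE)
  if (!background$model %in% c("uniform", "gamma_mixture"))
    stop("background model must be 'uniform' or 'gamma_mixture'", call. = FALSE)
  structure(list(contig_lengths = contig_lengths,
                 autozygous_fraction = f,
                 tract_length_mean = tract_length_mean,
                 rate_in_tract = rate_in_tract,
                 background = background,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Inbred-genome simulation profile
#'
#' Emulates the SNP landscape of a severely inbred bird genome: a small
#' fraction of perfectly autozygous tracts in a background whose
#' per-window SNP density is strongly right-skewed (target window median
#' about 0.05 and mean about 0.40 SNP/kb).  The skew comes from a
#' two-component gamma mixture: most windows sit near the median rate
#' while a minority of highly variable windows carries most of the SNPs.
#' Autozygous tracts are numerous and short (250 kb mean), the pattern
#' expected when shared ancestry is old enough for recombination to have
#' broken long identical-by-descent segments apart.
#'
#' @param n_contigs,contig_length Genome layout (default 10 x 100 Mb, i.e.
#'   10,000 windows of 100 kb).
#' @param seed Integer seed.
#' @return A `genome_spec`.
#' @export
inbred_profile <- function(n_contigs = 10, contig_length = 1e8, seed = 1L) {
  genome_spec(
    stats::setNames(rep(contig_length, n_contigs),
                    sprintf("ctg%02d", seq_len(n_contigs))),
    autozygous_fraction = 0.02,
    tract_length_mean = 2.5e5,
    rate_in_tract = 0,
    background = list(model = "gamma_mixture",
                      weights = c(0.88, 0.12),
                      shapes = c(15, 3),
                      means_per_kb = c(0.045, 3.07)),
    seed = seed)
}

#' Outbred-genome simulation profile
#'
#' Emulates an outbred genome sequenced the same way: a uniform
#' background of about 1.95 SNP/kb with a small autozygous fraction, so
#' that relaxing the ROH heterozygosity threshold barely changes fROH.
#'
#' @inheritParams inbred_profile
#' @return A `genome_spec`.
#' @export
outbred_profile <- function(n_contigs = 10, contig_length = 1e8, seed = 1L) {
  genome_spec(
    stats::setNames(rep(contig_length, n_contigs),
                    sprintf("ctg%02d", seq_len(n_contigs))),
    autozygous_fraction = 0.044,
    tract_length_mean = 1e6,
    rate_in_tract = 0,
    background = list(model = "uniform", rate_per_kb = 1.95),
    seed = seed)
}

# Alternating exponential on/off process until the contig is covered.
# Returns a data.frame of 0-based half-open tract intervals.
draw_tracts <- function(len, f, tract_mean) {
  if (f <= 0) return(data.frame(start = numeric(), end = numeric()))
  if (f >= 1) return(data.frame(start = 0, end = len))
  gap_mean <- tract_mean * (1 - f) / f
  pos <- 0
  in_tract <- stats::runif(1) < f
  starts <- ends <- numeric()
  while (pos < len) {
    span <- stats::rexp(1, 1 / (if (in_tract) tract_mean else gap_mean))
    if (in_tract) {
      starts <- c(starts, pos)
      ends <- c(ends, min(pos + span, len))
    }
    pos <- pos + span
    in_tract <- !in_tract
  }
  data.frame(start = floor(starts), end = floor(ends))
}

# Background SNP positions for one contig: per 100-kb window, draw a rate
# (uniform or gamma-mixture), a Poisson count, then uniform positions.
draw_background <- function(len, background, window = 1e5) {
  n_win <- ceiling(len / window)
  starts <- (seq_len(n_win) - 1) * window
  wlen <- pmin(starts + window, len) - starts
  rate_kb <- if (background$model == "uniform") {
    rep(background$rate_per_kb, n_win)
  } else {
    comp <- sample.int(length(background$weights), n_win, replace = TRUE,
                       prob = background$weights)
    stats::rgamma(n_win, shape = background$shapes[comp],
                  scale = background$means_per_kb[comp] /
                    background$shapes[comp])
  }
  counts <- stats::rpois(n_win, rate_kb * wlen / 1000)
  tot <- sum(counts)
  if (tot == 0) return(numeric())
  floor(rep(starts, counts) + stats::runif(tot) * rep(wlen, counts))
}

#' Simulate a diploid SNP landscape and write VCF + truth files
#'
#' Plants autozygous tracts by alternating exponential draws, lays down
#' SNPs as a Poisson process (`rate_in_tract` inside tracts, the
#' background model outside), and writes a VCF v4.2 of biallelic
#' heterozygous SNPs, a contig-length TSV and a BED of the true tract
#' coordinates.  Byte-identical output for identical specs.
#'
#' @param spec A [genome_spec()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"sim"`).
#' @return Invisibly, a list with paths (`vcf`, `contigs`, `bed`), the
#'   tract table and `n_snps`.
#' @export
simulate_genome <- function(spec, dir, prefix = "sim") {
  stopifnot(inherits(spec, "genome_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cl <- spec$contig_lengths
  with_local_seed(spec$seed, {
    all_tracts <- list()
    chrom <- list()
    pos <- list()
    for (i in seq_len(nrow(cl))) {
      len <- cl$length[i]
      tr <- draw_tracts(len, spec$autozygous_fraction[i], spec$tract_length_mean)
      bg <- draw_background(len, spec$background)
      if (nrow(tr)) {
        bounds <- as.vector(rbind(tr$start, tr$end))
        bg <- bg[findInterval(bg, bounds) %% 2 == 0]
        tract_counts <- stats::rpois(nrow(tr),
                                     spec$rate_in_tract * (tr$end - tr$start) / 1000)
        inside <- floor(rep(tr$start, tract_counts) +
                          stats::runif(sum(tract_counts)) *
                          rep(tr$end - tr$start, tract_counts))
      } else inside <- numeric()
      p <- sort(unique(c(bg, inside)))
      chrom[[i]] <- rep(cl$contig[i], length(p))
      pos[[i]] <- p
      if (nrow(tr)) {
        tr$contig <- cl$contig[i]
        all_tracts[[i]] <- tr[, c("contig", "start", "end")]
      }
    }
    pos <- unlist(pos)
    chrom <- unlist(chrom)
    n <- length(pos)
    bases <- c("A", "C", "G", "T")
    ref_i <- sample.int(4L, n, replace = TRUE)
    alt_i <- ((ref_i - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L
    vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=consgen simulate_genome",
      sprintf("##contig=<ID=%s,length=%d>", cl$contig, as.integer(cl$length)),
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSIM")
    records <- if (n) sprintf("%s\t%d\t.\t%s\t%s\t60\tPASS\t.\tGT\t0/1",
                              chrom, as.integer(pos) + 1L,
                              bases[ref_i], bases[alt_i]) else character()
    writeLines(c(header, records), vcf_path)
    contig_path <- file.path(dir, paste0(prefix, "_contigs.tsv"))
    write_tsv(data.frame(contig = cl$contig, length = as.integer(cl$length)),
              contig_path)
    tracts <- if (length(all_tracts)) do.call(rbind, all_tracts) else
      data.frame(contig = character(), start = numeric(), end = numeric())
    bed_path <- file.path(dir, paste0(prefix, "_truth_tracts.bed"))
    writeLines(sprintf("%s\t%d\t%d", tracts$contig, as.integer(tracts$start),
                       as.integer(tracts$end)), bed_path)
    invisible(list(vcf = vcf_path, contigs = contig_path, bed = bed_path,
                   tracts = tracts, n_snps = n))
  })
}

#' Specification of a supertype-structured peptide set
#'
#' @param k Number of planted clusters.
#' @param n_positions Peptide length (= number of selected codons).
#' @param n_per_species_per_cluster Sequences generated per species and
#'   cluster.
#' @param species Character vector of species codes.
#' @param mutation_rate Per-residue probability that a member deviates
#'   from its cluster centroid.  Deviations are conservative: the residue
#'   is replaced by its nearest amino acid in z-descriptor space, so
#'   members stay physiochemically close to their centroid - the defining
#'   property of a supertype.  Centroid residues are drawn from the amino
#'   acids whose nearest z-space neighbour lies at a moderate distance,
#'   which keeps the within-cluster spread homogeneous across clusters.
#' @param min_z_separation Minimum pairwise Euclidean distance between
#'   centroid peptides in z-descriptor space.
#' @param alignment_codons Total codons in the emitted alignment; codons
#'   off the selected positions are conserved across sequences.
#' @param pss 1-based selected codon indices within the alignment
#'   (default: the shipped nine-position preset layout).
#' @param seed Integer seed.
#' @return A `supertype_spec` list.
#' @export
supertype_spec <- function(k = 8, n_positions = 9,
                           n_per_species_per_cluster = 4,
                           species = c("spA", "spB", "spC", "spD"),
                           mutation_rate = 0.05, min_z_separation = 10,
                           alignment_codons = 30, pss = NULL, seed = 1L) {
  if (is.null(pss)) pss <- default_pss(alignment_codons, n_positions)
  pss <- sort(unique(as.integer(pss)))
  if (length(pss) != n_positions || max(pss) > alignment_codons)
    stop("pss must hold n_positions indices within the alignment",
         call. = FALSE)
  stopifnot(k >= 1, n_per_species_per_cluster >= 1, mutation_rate >= 0,
            mutation_rate <= 1)
  structure(list(k = k, n_positions = n_positions,
                 n_per_species_per_cluster = n_per_species_per_cluster,
                 species = species, mutation_rate = mutation_rate,
                 min_z_separation = min_z_separation,
                 alignment_codons = alignment_codons, pss = pss,
                 seed = as.integer(seed)),
            class = "supertype_spec")
}

default_pss <- function(alignment_codons = 30, n_positions = 9) {
  as.integer(round(seq(3, alignment_codons - 2, length.out = n_positions)))
}

# Nearest z-space neighbour of every amino acid (conservative
# substitution target), and the "core" alphabet whose nearest neighbour
# sits at a moderate distance (centroids drawn from it have homogeneous
# within-cluster spread under nearest-neighbour substitution).
z_neighbourhood <- function() {
  z <- z_scales()
  d <- as.matrix(stats::dist(z))
  diag(d) <- Inf
  nn_dist <- apply(d, 1L, min)
  list(nearest = apply(d, 1L, function(row) names(which.min(row))),
       core = names(which(nn_dist >= 2 & nn_dist <= 3.2)))
}

# Codons per amino acid from the standard genetic code (stops excluded).
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(names(gc), unname(gc))
}

back_translate <- function(peptide, codon_table) {
  res <- strsplit(peptide, "")[[1]]
  paste0(vapply(res, function(a) {
    cs <- codon_table[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1)), collapse = "")
}

#' Simulate a supertype-structured codon alignment
#'
#' Draws `k` centroid peptides mutually separated by at least
#' `min_z_separation` in z-descriptor space, generates member peptides by
#' mutating centroid residues at `mutation_rate`, back-translates each
#' with random synonymous codons, embeds the selected codons in an
#' alignment padded with conserved codons, and writes the aligned FASTA,
#' a species map TSV and a truth-label TSV (`seq_id`, `species`,
#' `cluster`).  Byte-identical output for identical specs.
#'
#' @param spec A [supertype_spec()].
#' @param dir Output directory.
#' @param prefix File-name prefix (default `"sim"`).
#' @return Invisibly, a list with paths (`fasta`, `species`, `truth`,
#'   `pss`), the truth data.frame and the centroid peptides.
#' @export
simulate_supertype_alignment <- function(spec, dir, prefix = "sim") {
  stopifnot(inherits(spec, "supertype_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ct <- codons_by_aa()
  nb <- z_neighbourhood()
  with_local_seed(spec$seed, {
    centroids <- character()
    for (i in seq_len(spec$k)) {
      placed <- FALSE
      for (try in seq_len(1000L)) {
        cand <- paste0(sample(nb$core, spec$n_positions, replace = TRUE),
                       collapse = "")
        ok <- if (!length(centroids)) TRUE else {
          zs <- encode_z(c(centroids, cand))
          d <- sqrt(rowSums(sweep(zs[seq_along(centroids), , drop = FALSE],
                                  2L, zs[nrow(zs), ])^2))
          all(d >= spec$min_z_separation)
        }
        if (ok) { centroids[i] <- cand; placed <- TRUE; break }
      }
      if (!placed)
        stop("could not draw ", spec$k, " centroids with z-separation >= ",
             spec$min_z_separation, " after 1000 attempts; lower ",
             "min_z_separation", call. = FALSE)
    }
    conserved <- vapply(seq_len(spec$alignment_codons), function(i) {
      cs <- unlist(ct, use.names = FALSE)
      cs[sample.int(length(cs), 1L)]
    }, character(1))
    rows <- list()
    idx <- 0L
    for (cl in seq_len(spec$k)) {
      cen <- strsplit(centroids[cl], "")[[1]]
      for (sp in spec$species) {
        for (j in seq_len(spec$n_per_species_per_cluster)) {
          idx <- idx + 1L
          pep <- cen
          mut <- stats::runif(spec$n_positions) < spec$mutation_rate
          pep[mut] <- nb$nearest[pep[mut]]
          codons <- conserved
          codons[spec$pss] <- substring(
            back_translate(paste0(pep, collapse = ""), ct),
            3 * (seq_len(spec$n_positions) - 1L) + 1L,
            3 * seq_len(spec$n_positions))
          rows[[idx]] <- list(
            seq_id = sprintf("%s_c%02d_%03d", sp, cl, j),
            species = sp, cluster = cl,
            peptide = paste0(pep, collapse = ""),
            seq = paste0(codons, collapse = ""))
        }
      }
    }
    ids <- vapply(rows, `[[`, character(1), "seq_id")
    seqs <- vapply(rows, `[[`, character(1), "seq")
    truth <- data.frame(
      seq_id = ids,
      species = vapply(rows, `[[`, character(1), "species"),
      cluster = vapply(rows, `[[`, integer(1), "cluster"),
      peptide = vapply(rows, `[[`, character(1), "peptide"),
      stringsAsFactors = FALSE)
    fasta_path <- file.path(dir, paste0(prefix, "_alignment.fasta"))
    writeLines(paste0(">", ids, "\n", seqs), fasta_path)
    species_path <- file.path(dir, paste0(prefix, "_species.tsv"))
    utils::write.table(truth[, c("seq_id", "species")], species_path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    truth_path <- file.path(dir, paste0(prefix, "_truth_labels.tsv"))
    write_tsv(truth, truth_path)
    pss_path <- file.path(dir, paste0(prefix, "_pss.txt"))
    writeLines(as.character(spec$pss), pss_path)
    invisible(list(fasta = fasta_path, species = species_path,
                   truth = truth_path, pss = pss_path, truth_df = truth,
                   centroids = centroids))
  })
}
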