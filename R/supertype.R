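#' Read an in-frame codon alignment with species labels
#'
#' @param fasta Path to an aligned nucleotide FASTA.  All sequences must
#'   have equal length divisible by 3, over the alphabet A, C, G, T, N, -.
#' @param species Optional species map: a 2-column TSV path or data.frame
#'   (`seq_id`, `species_code`).  Sequences without a mapping get species
#'   `NA`.
#' @return A `data.frame` with columns `seq_id`, `species`, `seq`;
#'   the alignment length (nt) is stored in attribute `aln_length`.
#' @export
read_codon_alignment <- function(fasta, species = NULL) {
  check_file_exists(fasta, "alignment FASTA")
  ss <- Biostrings::readDNAStringSet(fasta)
  if (!length(ss)) stop("empty alignment: ", fasta, call. = FALSE)
  seqs <- toupper(as.character(ss))
  ids <- sub("\\s.*", "", names(ss))
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("alignment sequences differ in length", call. = FALSE)
  if (len %% 3L != 0L)
    stop("alignment length ", len, " is not divisible by 3", call. = FALSE)
  if (any(grepl("[^ACGTN-]", seqs)))
    stop("alignment contains characters outside {A,C,G,T,N,-}", call. = FALSE)
  sp <- rep(NA_character_, length(ids))
  if (!is.null(species)) {
    if (is.character(species) && length(species) == 1L) {
      check_file_exists(species, "species map")
      species <- utils::read.table(species, sep = "\t", header = FALSE,
                                   col.names = c("seq_id", "species_code"),
                                   stringsAsFactors = FALSE)
      if (identical(species$seq_id[1], "seq_id")) species <- species[-1, ]
    }
    sp <- species$species_code[match(ids, species$seq_id)]
  }
  out <- data.frame(seq_id = ids, species = sp, seq = unname(seqs),
                    stringsAsFactors = FALSE)
  attr(out, "aln_length") <- len
  out
}

#' Read positively-selected codon positions
#'
#' One 1-based codon index per line; blank lines and `#` comments are
#' skipped.  The package default preset (nine antigen-binding positions)
#' is in `system.file("extdata", "pss_default.txt", package = "consgen")`.
#'
#' @param path Path to the positions file.
#' @return Sorted unique integer vector of 1-based codon indices.
#' @export
read_pss <- function(path) {
  check_file_exists(path, "PSS positions file")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  idx <- suppressWarnings(as.integer(lines))
  if (!length(idx) || anyNA(idx) || any(idx < 1L))
    stop("PSS file must hold positive 1-based codon indices", call. = FALSE)
  sort(unique(idx))
}

#' Trim to selected codons, translate and deduplicate
#'
#' Reduces every aligned sequence to the codons at the positively selected
#' sites, translates them with the standard genetic code, drops sequences
#' whose selected codons contain an alignment gap, a stop, or an
#' unresolvable ambiguity (with a warning naming them), and collapses
#' identical peptides into unique variants that keep back-references to
#' their member sequences and species.
#'
#' @param aln Codon alignment from [read_codon_alignment()] (or a
#'   data.frame with columns `seq_id`, `species`, `seq`).
#' @param pss Integer vector of 1-based codon indices (see [read_pss()]).
#' @return A `peptide_variants` data.frame: `peptide`, `n_members`, and
#'   list-columns `members` (seq ids) and `species`.  Attribute
#'   `n_positions` records the peptide length; attribute `dropped` the ids
#'   of discarded sequences.
#' @export
trim_translate_dedupe <- function(aln, pss) {
  pss <- sort(unique(as.integer(pss)))
  n_codons <- nchar(aln$seq[1]) %/% 3L
  if (any(pss < 1L) || any(pss > n_codons))
    stop("PSS indices outside the alignment (1..", n_codons, ")", call. = FALSE)
  codon_mat <- vapply(pss, function(p)
    substring(aln$seq, (p - 1L) * 3L + 1L, p * 3L), character(nrow(aln)))
  trimmed <- apply(matrix(codon_mat, nrow = nrow(aln)), 1L, paste0, collapse = "")
  gap <- grepl("-", trimmed, fixed = TRUE)
  pep <- rep(NA_character_, nrow(aln))
  if (any(!gap)) {
    pep[!gap] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(trimmed[!gap]), if.fuzzy.codon = "solve"))
  }
  bad_res <- !gap & grepl("[*X]", pep)
  drop <- gap | bad_res
  if (any(drop)) {
    reason <- ifelse(gap[drop], "gap at a selected codon",
                     "stop or ambiguous residue at a selected position")
    warning("dropped ", sum(drop), " sequence(s): ",
            paste0(aln$seq_id[drop], " (", reason, ")", collapse = "; "),
            call. = FALSE)
  }
  if (all(drop))
    stop("all sequences dropped at the selected codons", call. = FALSE)
  keep <- which(!drop)
  groups <- split(keep, pep[keep])
  out <- data.frame(peptide = names(groups),
                    n_members = lengths(groups),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$members <- lapply(groups, function(i) aln$seq_id[i])
  out$species <- lapply(groups, function(i) aln$species[i])
  attr(out, "n_positions") <- length(pss)
  attr(out, "dropped") <- aln$seq_id[drop]
  class(out) <- c("peptide_variants", "data.frame")
  out
}

#' Encode peptides as a z-descriptor matrix
#'
#' Each residue contributes the five z-scale values of its amino acid, so
#' a peptide of length p becomes a row of 5p numbers.  Columns are
#' position-major, descriptor-minor: `p1_z1..p1_z5, p2_z1..`.
#'
#' @param variants `peptide_variants` from [trim_translate_dedupe()], or a
#'   character vector of peptides.
#' @param ztable Descriptor table, by default [z_scales()].
#' @return Numeric matrix, one row per peptide (rownames = peptides).
#' @export
encode_z <- function(variants, ztable = z_scales()) {
  peps <- if (is.data.frame(variants)) variants$peptide else as.character(variants)
  if (!length(peps)) stop("no peptides to encode", call. = FALSE)
  plen <- unique(nchar(peps))
  if (length(plen) != 1L)
    stop("peptides differ in length", call. = FALSE)
  res <- matrix(unlist(strsplit(peps, "")), nrow = length(peps), byrow = TRUE)
  unknown <- which(!(res %in% rownames(ztable)))
  if (length(unknown)) {
    row <- (unknown[1] - 1L) %% nrow(res) + 1L
    col <- (unknown[1] - 1L) %/% nrow(res) + 1L
    stop("unknown residue '", res[row, col], "' in peptide ", peps[row],
         call. = FALSE)
  }
  z <- matrix(0, nrow = length(peps), ncol = 5L * plen,
              dimnames = list(peps, paste0(
                rep(paste0("p", seq_len(plen)), each = 5L), "_",
                rep(colnames(ztable), plen))))
  for (p in seq_len(plen))
    z[, (p - 1L) * 5L + 1:5] <- ztable[res[, p], , drop = FALSE]
  z
}

# k-means++ seeding: first centre uniform, later centres drawn with
# probability proportional to squared distance to the nearest chosen one.
kmeanspp_init <- function(z, k) {
  n <- nrow(z)
  centers <- matrix(NA_real_, k, ncol(z))
  i <- sample.int(n, 1L)
  centers[1L, ] <- z[i, ]
  if (k > 1L) {
    d2 <- rowSums(sweep(z, 2L, centers[1L, ])^2)
    for (j in 2:k) {
      i <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2) else sample.int(n, 1L)
      centers[j, ] <- z[i, ]
      d2 <- pmin(d2, rowSums(sweep(z, 2L, centers[j, ])^2))
    }
  }
  centers
}

kmeans_once <- function(z, k, n_starts, max_iter) {
  best <- NULL
  failures <- 0L
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(z, centers = kmeanspp_init(z, k),
                                     iter.max = max_iter, algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(fit)) { failures <- failures + 1L; next }
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best))
    stop("k-means failed for k = ", k, " after ", failures,
         " restarts (empty clusters)", call. = FALSE)
  best
}

#' Cluster peptide variants by k-means with BIC model selection
#'
#' Lloyd's algorithm with k-means++ initialisation and `n_starts` random
#' restarts (best total within-cluster sum of squares kept).  In automatic
#' mode the number of clusters minimises
#' `BIC(k) = n * log(W_k / n) + k * log(n)` over `k_range`, where `W_k` is
#' the total within-cluster sum of squares; a fixed `k` bypasses
#' selection.  Optionally the data are first reduced to their leading
#' principal components.
#'
#' The BIC curve around its minimum is often flat to well under the
#' conventional "worth a bare mention" evidence threshold of 2 (Kass &
#' Raftery 1995), so the smallest candidate within `bic_tol` of the
#' minimum is reported rather than the literal argmin, a parsimony
#' tie-break that keeps the selection stable.
#'
#' @param z z-descriptor matrix from [encode_z()].
#' @param k Fixed number of clusters, or `NULL` (default) for automatic
#'   selection.
#' @param k_range Candidate cluster numbers for automatic mode.
#' @param n_starts Random restarts per candidate k (default 25).
#' @param seed Optional integer seed; the fit is fully reproducible given
#'   the seed.
#' @param pca_pcs Optionally, number of principal components to reduce to
#'   before clustering (`NULL` = cluster the raw z-columns).
#' @param max_iter Lloyd iteration cap per start.
#' @param bic_tol Evidence tolerance for the parsimony tie-break on the
#'   BIC curve (default 2).
#' @return A `supertype_clustering` list: `k`, `assignments` (named
#'   integer vector, one per row of `z`), `centroids`, `tot_withinss`,
#'   `bic_curve` (data.frame `k`, `bic`; `NULL` in fixed-k mode) and
#'   `pca_pcs`.
#' @export
cluster_kmeans <- function(z, k = NULL, k_range = 2:15, n_starts = 25,
                           seed = NULL, pca_pcs = NULL, max_iter = 300L,
                           bic_tol = 2) {
  stopifnot(is.matrix(z), nrow(z) >= 2L)
  zc <- z
  if (!is.null(pca_pcs)) {
    pca_pcs <- min(pca_pcs, nrow(z) - 1L, ncol(z))
    zc <- stats::prcomp(z, center = TRUE)$x[, seq_len(pca_pcs), drop = FALSE]
  }
  n <- nrow(zc)
  with_local_seed(seed, {
    if (!is.null(k)) {
      if (k >= n) stop("k must be smaller than the number of variants (",
                       n, ")", call. = FALSE)
      if (k < 1L) stop("k must be at least 1", call. = FALSE)
      fit <- kmeans_once(zc, k, n_starts, max_iter)
      bic_curve <- NULL
    } else {
      ks <- k_range[k_range < n & k_range >= 1L]
      if (!length(ks)) stop("no feasible k in k_range", call. = FALSE)
      fits <- lapply(ks, kmeans_once, z = zc, n_starts = n_starts,
                     max_iter = max_iter)
      w <- vapply(fits, `[[`, numeric(1), "tot.withinss")
      bic <- n * log(pmax(w, .Machine$double.eps) / n) + ks * log(n)
      best <- which(bic <= min(bic) + bic_tol)[1]
      fit <- fits[[best]]
      k <- ks[best]
      bic_curve <- data.frame(k = ks, bic = bic)
    }
    structure(list(
      k = k,
      assignments = stats::setNames(fit$cluster, rownames(z)),
      centroids = fit$centers,
      tot_withinss = fit$tot.withinss,
      bic_curve = bic_curve,
      pca_pcs = pca_pcs),
      class = "supertype_clustering")
  })
}

#' Discriminant analysis of principal components
#'
#' Centres the columns of `z`, projects onto the leading `n_pcs`
#' principal components, then finds linear discriminant axes maximising
#' the between- over within-cluster variance of the retained components.
#' At most `k - 1` axes carry discrimination, so `min(n_da, k - 1)` axes
#' are kept.  If the within-cluster scatter is singular a ridge `ridge *
#' I` is added with a warning.  Each axis is oriented so that its
#' largest-magnitude coefficient is positive, making coordinates
#' reproducible across row orderings.
#'
#' @param z z-descriptor matrix.
#' @param assignments Cluster assignment vector (one per row of `z`).
#' @param n_pcs Principal components retained (default 10); must not
#'   exceed `min(nrow(z) - 1, ncol(z))`.
#' @param n_da Discriminant axes requested (default 3).
#' @param ridge Ridge added to a singular within-cluster scatter.
#' @return A `dapc` list: `n_pcs`, `n_da`, `eigenvalues` (non-negative,
#'   non-increasing), `coords` (per-variant discriminant coordinates),
#'   `groups`, plus the PCA rotation/centre and discriminant vectors
#'   needed to project new data.
#' @export
dapc_fit <- function(z, assignments, n_pcs = 10, n_da = 3, ridge = 1e-8) {
  groups <- factor(assignments)
  k <- nlevels(groups)
  if (k < 2L) stop("DAPC needs at least two clusters", call. = FALSE)
  if (length(assignments) != nrow(z))
    stop("assignments and z disagree in length", call. = FALSE)
  max_pcs <- min(nrow(z) - 1L, ncol(z))
  if (n_pcs > max_pcs)
    stop("n_pcs must be at most min(n - 1, n_columns) = ", max_pcs,
         call. = FALSE)
  pc <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  mu <- colMeans(scores)
  B <- matrix(0, n_pcs, n_pcs)
  W <- matrix(0, n_pcs, n_pcs)
  for (g in levels(groups)) {
    xg <- scores[groups == g, , drop = FALSE]
    mg <- colMeans(xg)
    B <- B + nrow(xg) * tcrossprod(mg - mu)
    xc <- sweep(xg, 2L, mg)
    W <- W + crossprod(xc)
  }
  R <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(R)) {
    warning("within-cluster scatter singular; adding ridge ", ridge,
            call. = FALSE)
    R <- chol(W + ridge * diag(n_pcs))
  }
  C <- backsolve(R, B, transpose = TRUE)          # R'^-1 B
  A <- t(backsolve(R, t(C), transpose = TRUE))    # R'^-1 B R^-1
  A <- (A + t(A)) / 2
  eig <- eigen(A, symmetric = TRUE)
  r <- min(n_da, k - 1L)
  evals <- pmax(eig$values, 0)
  V <- backsolve(R, eig$vectors[, seq_len(r), drop = FALSE])
  V <- sweep(V, 2L, sqrt(colSums(V^2)), "/")
  # orient axes by their loadings on the original variables, which are
  # invariant to input row order (PC sign flips cancel out)
  loadings <- pc$rotation[, seq_len(n_pcs), drop = FALSE] %*% V
  for (j in seq_len(r)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) V[, j] <- -V[, j]
  }
  coords <- scores %*% V
  colnames(coords) <- paste0("LD", seq_len(r))
  rownames(coords) <- rownames(z)
  structure(list(
    n_pcs = n_pcs,
    n_da = r,
    eigenvalues = evals[seq_len(r)],
    all_eigenvalues = evals,
    coords = coords,
    groups = groups,
    pc_center = pc$center,
    pc_rotation = pc$rotation[, seq_len(n_pcs), drop = FALSE],
    discriminants = V),
    class = "dapc")
}

#' Species representation per supertype
#'
#' Counts the original nucleotide sequences (variant members, not unique
#' peptides) contributed by each species to each supertype, the table
#' behind a stacked-bar comparison of repertoires across species.
#'
#' @param variants `peptide_variants` with `species` back-references.
#' @param assignments Named supertype assignment per peptide (names =
#'   peptides), as in a [cluster_kmeans()] fit.
#' @return Integer matrix, supertypes x species; column sums equal each
#'   species' input sequence count.
#' @export
species_representation <- function(variants, assignments) {
  sp <- unlist(variants$species, use.names = FALSE)
  st <- rep(assignments[variants$peptide], variants$n_members)
  sp[is.na(sp)] <- "unknown"
  tab <- table(supertype = st, species = sp)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}
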