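#' Fit an MHC functional supertype model
#'
#' End-to-end supertype pipeline over an in-frame exon-2 codon alignment:
#' trim to the positively selected codons, translate, collapse duplicate
#' peptides, encode with the five z-scale descriptors, cluster the unique
#' variants by k-means (with BIC selection of the number of supertypes
#' unless `k` is fixed), describe the clusters by DAPC, and tabulate the
#' species composition of each supertype.
#'
#' @param alignment Codon alignment (path to aligned FASTA, or the
#'   data.frame from [read_codon_alignment()]).
#' @param pss Positively selected codon positions: integer vector, or
#'   path to a one-index-per-line file (see [read_pss()]).  Defaults to
#'   the nine-position preset shipped with the package, which only suits
#'   alignments laid out like the synthetic generator's output.
#' @param species Optional species map (TSV path or data.frame), used
#'   when `alignment` is a path.
#' @param k Fixed number of supertypes, or `NULL` to minimise BIC over
#'   `k_range`.
#' @param k_range,n_starts,pca_pcs,seed Passed to [cluster_kmeans()].
#' @param n_pcs,n_da Passed to [dapc_fit()]; `n_pcs` is reduced (with a
#'   message) when it exceeds what the variant count supports.
#' @return A `supertype_model` with components `variants`, `z`,
#'   `clustering`, `dapc`, `species_table`, `k`.
#' @export
supertype <- function(alignment, pss = NULL, species = NULL, k = NULL,
                      k_range = 2:15, n_pcs = 10, n_da = 3, n_starts = 25,
                      seed = NULL, pca_pcs = NULL) {
  if (is.character(alignment) && length(alignment) == 1L)
    alignment <- read_codon_alignment(alignment, species)
  if (is.null(pss))
    pss <- system.file("extdata", "pss_default.txt", package = "consgen")
  if (is.character(pss)) pss <- read_pss(pss)
  variants <- trim_translate_dedupe(alignment, pss)
  z <- encode_z(variants)
  clustering <- cluster_kmeans(z, k = k, k_range = k_range,
                               n_starts = n_starts, seed = seed,
                               pca_pcs = pca_pcs)
  max_pcs <- min(nrow(z) - 1L, ncol(z))
  if (n_pcs > max_pcs) {
    message("reducing n_pcs from ", n_pcs, " to ", max_pcs)
    n_pcs <- max_pcs
  }
  dapc <- if (clustering$k >= 2L)
    dapc_fit(z, clustering$assignments, n_pcs = n_pcs, n_da = n_da) else NULL
  structure(list(
    variants = variants,
    z = z,
    clustering = clustering,
    dapc = dapc,
    species_table = species_representation(variants, clustering$assignments),
    k = clustering$k),
    class = "supertype_model")
}

#' @export
print.supertype_model <- function(x, ...) {
  cat("MHC functional supertype model\n")
  cat(sprintf("  %d unique peptide variants (%d positions) from %d sequences\n",
              nrow(x$variants), attr(x$variants, "n_positions"),
              sum(x$variants$n_members)))
  cat(sprintf("  %d supertypes (%s)\n", x$k,
              if (is.null(x$clustering$bic_curve)) "fixed k"
              else "BIC-selected"))
  if (!is.null(x$dapc))
    cat(sprintf("  DAPC: %d PCs, %d discriminant axes; eigenvalues %s\n",
                x$dapc$n_pcs, x$dapc$n_da,
                paste(signif(x$dapc$eigenvalues, 3), collapse = ", ")))
  invisible(x)
}

#' @export
summary.supertype_model <- function(object, ...) {
  sizes <- table(object$clustering$assignments)
  members <- tapply(object$variants$n_members,
                    object$clustering$assignments[object$variants$peptide], sum)
  data.frame(supertype = as.integer(names(sizes)),
             n_variants = as.integer(sizes),
             n_sequences = as.integer(members),
             row.names = NULL)
}

#' @export
plot.supertype_model <- function(x, ...) {
  if (is.null(x$dapc)) stop("no DAPC to plot (k < 2)", call. = FALSE)
  co <- x$dapc$coords
  grp <- as.integer(x$dapc$groups)
  op <- graphics::par(fig = c(0, 1, 0, 1))
  on.exit(graphics::par(op))
  if (ncol(co) >= 2L) {
    graphics::plot(co[, 1], co[, 2], col = grp, pch = 19,
                   xlab = "LD1", ylab = "LD2",
                   main = "Supertypes in discriminant space", ...)
  } else {
    graphics::stripchart(co[, 1] ~ grp, method = "jitter", pch = 19,
                         xlab = "LD1", main = "Supertypes on LD1", ...)
  }
  graphics::par(fig = c(0.62, 0.98, 0.62, 0.98), new = TRUE, mar = rep(0.5, 4))
  ev <- x$dapc$all_eigenvalues
  graphics::barplot(ev, col = ifelse(seq_along(ev) <= x$dapc$n_da,
                                     "grey30", "white"),
                    axes = FALSE, main = "", border = "grey40")
  invisible(x)
}

#' Assign new peptides to fitted supertypes
#'
#' Encodes peptides with the model's descriptor layout and assigns each
#' to the nearest k-means centroid (in the clustering space, including
#' any PCA reduction used at fit time is not supported; models fitted on
#' raw z-columns are assigned on raw z-columns).
#'
#' @param object A `supertype_model`.
#' @param newdata Character vector of peptides of the fitted length.
#' @param ... Unused.
#' @return Integer vector of supertype ids named by peptide.
#' @export
predict.supertype_model <- function(object, newdata, ...) {
  if (!is.null(object$clustering$pca_pcs))
    stop("prediction is only supported for models clustered on raw z-columns",
         call. = FALSE)
  z <- encode_z(newdata)
  cen <- object$clustering$centroids
  d2 <- outer(rowSums(z^2), rep(1, nrow(cen))) - 2 * z %*% t(cen) +
    outer(rep(1, nrow(z)), rowSums(cen^2))
  stats::setNames(max.col(-d2), rownames(z))
}
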