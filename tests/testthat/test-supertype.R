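make_aln <- function(seqs, species = NULL) {
  data.frame(seq_id = paste0("s", seq_along(seqs)),
             species = if (is.null(species)) rep("spA", length(seqs)) else species,
             seq = seqs, stringsAsFactors = FALSE)
}

test_that("z-scale table matches the shipped constants file", {
  z <- z_scales()
  expect_equal(dim(z), c(20L, 5L))
  expect_setequal(rownames(z), strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  expect_equal(sum(z), 0.11)               # frozen checksum of all 100 values
  tsv <- read.table(fixture_path("zscales_sandberg1998.tsv"), header = TRUE,
                    sep = "\t", row.names = 1)
  expect_equal(as.matrix(tsv), z)
})

test_that("trimming, translation and deduplication collapse duplicates", {
  s <- paste0(rep("ATGGCT", 6), collapse = "")        # 12 codons: MAMAMA...
  out <- trim_translate_dedupe(make_aln(c(s, s)), pss = c(1, 3, 5))
  expect_equal(nrow(out), 1)
  expect_equal(out$peptide, "MMM")
  expect_equal(out$n_members, 2L)
  expect_setequal(out$members[[1]], c("s1", "s2"))
})

test_that("gap, stop and ambiguous codons at selected positions drop sequences", {
  good <- paste0(rep("GCT", 6), collapse = "")
  gap <- sub("GCT", "G-T", good)
  stopseq <- sub("GCT", "TAA", good)
  fuzzy <- sub("GCT", "ANN", good)
  expect_warning(out <- trim_translate_dedupe(
    make_aln(c(good, gap, stopseq, fuzzy)), pss = 1:3), "dropped 3")
  expect_equal(nrow(out), 1)
  expect_setequal(attr(out, "dropped"), c("s2", "s3", "s4"))
  expect_error(
    suppressWarnings(trim_translate_dedupe(make_aln(gap), pss = 1:3)),
    "all sequences")
})

test_that("synthetic peptides come back with the planted variant count", {
  d <- withr::local_tempdir()
  sim <- simulate_supertype_alignment(
    supertype_spec(k = 3, n_per_species_per_cluster = 5, seed = 21), d)
  aln <- read_codon_alignment(sim$fasta, sim$species)
  out <- trim_translate_dedupe(aln, read_pss(sim$pss))
  expect_equal(nrow(out), length(unique(sim$truth_df$peptide)))
  expect_equal(sum(out$n_members), nrow(sim$truth_df))
})

test_that("encode_z lays out five descriptors per position", {
  z1 <- encode_z("ADKFWCHIV")
  expect_equal(dim(z1), c(1L, 45L))
  zt <- z_scales()
  expect_equal(unname(encode_z("AAAAAAAAA")[1, ]),
               rep(unname(zt["A", ]), 9))
  pair <- encode_z(c("AAAAAAAAA", "AAAAWAAAA"))
  expect_equal(sum(pair[1, ] != pair[2, ]), 5)
  expect_equal(which(pair[1, ] != pair[2, ]), 21:25, ignore_attr = TRUE)
  expect_error(encode_z("AAAA?AAAA"), "unknown residue")
})

test_that("encode_z is injective over distinct peptides", {
  withr::local_seed(5)
  aa <- rownames(z_scales())
  peps <- unique(replicate(60, paste0(sample(aa, 5, TRUE), collapse = "")))
  z <- encode_z(peps)
  expect_equal(anyDuplicated(as.data.frame(z)), 0L)
})

test_that("k-means recovers well-separated planted clusters with k by BIC", {
  withr::local_seed(31)
  centers <- matrix(rnorm(3 * 10, sd = 12), 3, 10)
  x <- centers[rep(1:3, each = 20), ] + matrix(rnorm(60 * 10, sd = 0.5), 60)
  rownames(x) <- paste0("v", 1:60)
  fit <- cluster_kmeans(x, k_range = 2:8, seed = 7)
  expect_equal(fit$k, 3)
  expect_equal(mclust::adjustedRandIndex(fit$assignments, rep(1:3, each = 20)), 1)
  # reported k attains the BIC minimum up to the parsimony tolerance
  expect_lte(fit$bic_curve$bic[fit$bic_curve$k == fit$k],
             min(fit$bic_curve$bic) + 2)
  expect_true(all(is.finite(fit$bic_curve$bic)))
})

test_that("fixed k = 1 on identical rows yields one cluster with zero W", {
  x <- matrix(1, nrow = 6, ncol = 4, dimnames = list(paste0("v", 1:6), NULL))
  fit <- cluster_kmeans(x, k = 1, seed = 1)
  expect_equal(fit$k, 1)
  expect_equal(unname(fit$tot_withinss), 0)
  expect_true(all(fit$assignments == 1))
})

test_that("cluster_kmeans validates k and reproduces under a seed", {
  x <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("v", 1:10), NULL))
  expect_error(cluster_kmeans(x, k = 10), "smaller")
  f1 <- cluster_kmeans(x, k = 3, seed = 5)
  f2 <- cluster_kmeans(x, k = 3, seed = 5)
  expect_identical(f1$assignments, f2$assignments)
})

test_that("DAPC keeps at most k-1 axes and separates planted clusters", {
  withr::local_seed(8)
  centers <- matrix(rnorm(2 * 12, sd = 10), 2, 12)
  x <- centers[rep(1:2, each = 15), ] + matrix(rnorm(30 * 12, sd = 0.4), 30)
  rownames(x) <- paste0("v", 1:30)
  grp <- rep(1:2, each = 15)
  fit <- dapc_fit(x, grp, n_pcs = 5, n_da = 3)
  expect_equal(fit$n_da, 1)               # k - 1 bound beats n_da
  expect_equal(length(fit$eigenvalues), 1)

  centers4 <- matrix(rnorm(4 * 12, sd = 10), 4, 12)
  x4 <- centers4[rep(1:4, each = 12), ] + matrix(rnorm(48 * 12, sd = 0.4), 48)
  rownames(x4) <- paste0("v", 1:48)
  grp4 <- rep(1:4, each = 12)
  fit4 <- dapc_fit(x4, grp4, n_pcs = 8, n_da = 3)
  expect_equal(fit4$n_da, 3)
  expect_true(all(diff(fit4$eigenvalues) <= 1e-8))
  expect_true(all(fit4$eigenvalues >= 0))
  expect_gt(mean_silhouette(fit4$coords, grp4), 0.5)
})

test_that("DAPC is deterministic and invariant to row order", {
  withr::local_seed(9)
  centers <- matrix(rnorm(3 * 10, sd = 8), 3, 10)
  x <- centers[rep(1:3, each = 10), ] + matrix(rnorm(300, sd = 0.5), 30)
  rownames(x) <- paste0("v", 1:30)
  grp <- rep(1:3, each = 10)
  f1 <- dapc_fit(x, grp, n_pcs = 6, n_da = 2)
  f2 <- dapc_fit(x, grp, n_pcs = 6, n_da = 2)
  expect_identical(f1$eigenvalues, f2$eigenvalues)

  perm <- sample(nrow(x))
  f3 <- dapc_fit(x[perm, ], grp[perm], n_pcs = 6, n_da = 2)
  expect_equal(f3$eigenvalues, f1$eigenvalues)
  expect_equal(f3$coords[rownames(x), ], f1$coords, tolerance = 1e-8)
})

test_that("DAPC ridge handles singular within-cluster scatter", {
  x <- rbind(matrix(0, 5, 6), matrix(1, 5, 6))  # identical rows per group
  rownames(x) <- paste0("v", 1:10)
  expect_warning(fit <- dapc_fit(x, rep(1:2, each = 5), n_pcs = 2, n_da = 2),
                 "ridge")
  expect_equal(fit$n_da, 1)
})

test_that("DAPC discriminant axes agree with a reference LDA", {
  withr::local_seed(10)
  centers <- matrix(rnorm(3 * 8, sd = 6), 3, 8)
  x <- centers[rep(1:3, each = 14), ] + matrix(rnorm(42 * 8, sd = 1), 42)
  rownames(x) <- paste0("v", 1:42)
  grp <- rep(1:3, each = 14)
  fit <- dapc_fit(x, grp, n_pcs = 6, n_da = 2)
  pcs <- prcomp(x, center = TRUE)$x[, 1:6]
  ref <- MASS::lda(pcs, grouping = factor(grp))
  refco <- predict(ref, pcs)$x
  for (j in 1:2)
    expect_gt(abs(cor(fit$coords[, j], refco[, j])), 0.999)
})

test_that("species representation counts sequences, not unique peptides", {
  aln <- make_aln(rep(paste0(rep("GCT", 3), collapse = ""), 7),
                  species = c(rep("A", 3), rep("B", 4)))
  v <- trim_translate_dedupe(aln, pss = 1:3)
  tab <- species_representation(v, setNames(1L, v$peptide))
  expect_equal(unname(tab["1", c("A", "B")]), c(3L, 4L))
  expect_equal(unname(colSums(tab)), c(3L, 4L))
})

test_that("species spanning several planted clusters shows that many rows", {
  d <- withr::local_tempdir()
  sim <- simulate_supertype_alignment(
    supertype_spec(k = 4, species = c("X", "Y"),
                   n_per_species_per_cluster = 6, seed = 14), d)
  fit <- supertype(sim$fasta, pss = sim$pss, species = sim$species,
                   k = 4, seed = 2)
  expect_equal(sum(fit$species_table[, "X"] > 0), 4)
  expect_equal(unname(colSums(fit$species_table)),
               unname(table(read.table(sim$species, sep = "\t")$V2)),
               ignore_attr = TRUE)
})

test_that("the full pipeline recovers planted supertype structure", {
  d <- withr::local_tempdir()
  sim <- simulate_supertype_alignment(supertype_spec(k = 5, seed = 33), d)
  fit <- supertype(sim$fasta, pss = sim$pss, species = sim$species,
                   k_range = 2:10, seed = 3)
  expect_equal(fit$k, 5)
  truth <- sim$truth_df
  planted <- truth$cluster[match(fit$variants$peptide, truth$peptide)]
  ari <- mclust::adjustedRandIndex(
    fit$clustering$assignments[fit$variants$peptide], planted)
  expect_gte(ari, 0.9)
  expect_s3_class(fit, "supertype_model")
  expect_output(print(fit), "supertypes")
})
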