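test_that("read_snps converts VCF positions to 0-based and sorts", {
  p <- withr::local_tempfile(fileext = ".vcf")
  write_tiny_vcf(p, c(ctg1 = 1e6),
                 sprintf("ctg1\t%d\t.\tA\tG\t60\tPASS\t.\tGT\t0/1",
                         c(20, 5, 10)))
  expect_identical(read_snps(p), list(ctg1 = c(4L, 9L, 19L)))
})

test_that("read_snps drops indels, multiallelics, fails and missing genotypes", {
  snps <- read_snps(fixture_path("mixed_records.vcf"))
  # fixture holds 3 clean SNPs plus an indel, insertion, multi-allelic,
  # non-PASS and two missing-genotype records
  expect_identical(snps, list(ctg1 = c(4L, 9L, 19L)))
})

test_that("read_snps flags contigs missing from the contig table", {
  p <- withr::local_tempfile(fileext = ".vcf")
  write_tiny_vcf(p, c(ctgX = 1e6), "ctgX\t5\t.\tA\tG\t60\tPASS\t.\tGT\t0/1")
  expect_error(read_snps(p, data.frame(contig = "ctg1", length = 1e6)),
               "ctgX")
})

test_that("malformed VCF records are reported with their line", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "ctg1\tnot_a_position\tbroken"), p)
  expect_error(read_snps(p), "line 3|malformed")
})

test_that("read_snps recovers every planted synthetic SNP", {
  d <- withr::local_tempdir()
  sim <- simulate_genome(genome_spec(c(c1 = 1e6), autozygous_fraction = 0,
                                     background = list(model = "uniform",
                                                       rate_per_kb = 1),
                                     seed = 11), d)
  expect_gt(sim$n_snps, 0)
  expect_identical(sum(lengths(read_snps(sim$vcf))), sim$n_snps)
})

test_that("tile_windows applies the length filter and ceil arithmetic", {
  wt <- tile_windows(c(A = 550000), 1e5)
  expect_equal(nrow(wt), 6)
  expect_equal(wt$start[6], 5e5)
  expect_equal(wt$end[6], 550000)
  expect_equal(wt$window_index, 0:5)

  wt2 <- tile_windows(data.frame(contig = c("A", "B"),
                                 length = c(499999, 500000)), 1e5)
  expect_identical(unique(wt2$contig), "B")
  expect_equal(nrow(wt2), 5)

  wt3 <- tile_windows(c(A = 1e6), 1e5)
  expect_equal(nrow(wt3), 10)
  expect_equal(nrow(wt3) * attr(wt3, "window_size"), 1e6)
})

test_that("tile_windows rejects or warns on relaxed minimum contig lengths", {
  expect_error(tile_windows(c(A = 1e6), 1e5, min_contig_len = 5e4),
               "window")
  expect_warning(tile_windows(c(A = 1e6), 1e5, min_contig_len = 2e5),
                 "five")
})

test_that("count_snps_per_window assigns half-open boundaries and conserves", {
  wt <- tile_windows(c(c1 = 5e5), 1e5)
  out <- count_snps_per_window(list(c1 = c(0, 99999, 100000)), wt)
  expect_equal(out$snp_count, c(2L, 1L, 0L, 0L, 0L))

  empty <- count_snps_per_window(list(), wt)
  expect_true(all(empty$snp_count == 0))

  expect_error(count_snps_per_window(list(c1 = 5e5), wt), "c1")
})

test_that("uniform positions spread evenly across windows", {
  withr::local_seed(4)
  wt <- tile_windows(c(c1 = 1e6), 1e5)
  pos <- floor(runif(10000) * 1e6)
  out <- count_snps_per_window(list(c1 = pos), wt)
  expect_equal(sum(out$snp_count), 10000)
  expect_gt(chisq.test(out$snp_count)$p.value, 0.001)
})

test_that("call_roh finds maximal runs within contigs", {
  wt <- tile_windows(c(c1 = 5e5), 1e5)
  wt$snp_count <- c(0L, 0L, 3L, 0L, 9L)
  seg <- call_roh(wt, "perfect")
  expect_equal(seg$first_window, c(0L, 3L))
  expect_equal(seg$last_window, c(1L, 3L))
  expect_equal(seg$length_bp, c(2e5, 1e5))

  wt$snp_count <- c(1L, 2L, 3L, 9L, 9L)
  seg2 <- call_roh(wt, "0.02")     # <= 2 SNPs per 100-kb window, inclusive
  expect_equal(nrow(seg2), 1)
  expect_equal(seg2$first_window, 0L)
  expect_equal(seg2$last_window, 1L)
})

test_that("ROH segments never span contigs", {
  wt <- tile_windows(c(a = 5e5, b = 5e5), 1e5)
  wt$snp_count <- 0L
  seg <- call_roh(wt, "perfect")
  expect_equal(nrow(seg), 2)
  expect_equal(seg$n_windows, c(5L, 5L))
})

test_that("call_roh agrees with the brute-force run-length oracle", {
  withr::local_seed(99)
  for (i in 1:50) {
    wt <- random_window_table()
    th <- sample(c(0, 0.01, 0.02, 0.04, 0.1), 1)
    got <- call_roh(wt, th)
    want <- oracle_roh(counts_by_contig(wt), attr(wt, "window_size"), th)
    got <- got[order(got$contig, got$first_window), ]
    want <- want[order(want$contig, want$first_window), ]
    rownames(got) <- rownames(want) <- NULL
    attr(got, "threshold") <- attr(got, "window_size") <- NULL
    expect_equal(got, want)
  }
})

test_that("froh reproduces the window-count worked examples", {
  make_table <- function(n_zero, n_total) {
    wt <- tile_windows(c(c1 = n_total * 1e5), 1e5)
    wt$snp_count <- rep(c(0L, 5L), c(n_zero, n_total - n_zero))
    wt
  }
  wt <- make_table(574, 10338)
  fr <- froh(wt, call_roh(wt, "perfect"))
  expect_equal(fr$n_roh_windows, 574)
  expect_equal(fr$froh_percent, 5.6)

  wt <- make_table(416, 9373)
  expect_equal(froh(wt, call_roh(wt, "perfect"))$froh_percent, 4.4)

  wt <- make_table(0, 100)
  expect_equal(froh(wt, call_roh(wt, "perfect"))$froh, 0)
})

test_that("froh errors on an empty window table", {
  wt <- tile_windows(c(c1 = 5e5), 1e5)
  seg <- call_roh(wt, "perfect")
  empty <- wt[0, ]
  attr(empty, "window_size") <- 1e5
  expect_error(froh(empty, seg), "empty")
})

test_that("fROH is non-decreasing in the heterozygosity threshold", {
  withr::local_seed(12)
  for (i in 1:20) {
    wt <- random_window_table(max_count = 12)
    fr <- vapply(c(0, 0.01, 0.02, 0.04, 0.1), function(th)
      froh(wt, call_roh(wt, th))$froh, numeric(1))
    expect_true(all(diff(fr) >= 0))
  }
})

test_that("per-contig fROH summarises ratios per contig", {
  wt <- tile_windows(c(a = 1e6, b = 1e6), 1e5)
  wt$snp_count <- c(rep(5L, 10), rep(0L, 5), rep(5L, 5))
  pc <- per_contig_froh(wt, call_roh(wt, "perfect"))
  expect_equal(pc$per_contig$froh, c(0, 0.5))
  expect_equal(pc$min, 0)
  expect_equal(pc$max, 0.5)
  expect_equal(pc$median, 0.25)  # even count: mean of middle two
  expect_equal(pc$mean, 0.25)

  one <- tile_windows(c(a = 1e6), 1e5)
  one$snp_count <- rep(c(0L, 9L), 5)
  pc1 <- per_contig_froh(one, call_roh(one, "perfect"))
  expect_equal(unname(c(pc1$min, pc1$max, pc1$median, pc1$mean)),
               rep(pc1$per_contig$froh, 4))
})

test_that("snp_encounter_rate divides bases by SNPs", {
  expect_equal(snp_encounter_rate(1000, 1e6), 1000)
  expect_equal(snp_encounter_rate(1, 1), 1)
  # 413,114 SNPs over a rounded 1.02 Gb: about 2469 bp per SNP
  expect_equal(round(snp_encounter_rate(413114, 1.02e9)), 2469)
  expect_error(snp_encounter_rate(0, 1e6), "undefined")
})

test_that("roh_scan drives the whole stage end to end", {
  d <- withr::local_tempdir()
  sim <- simulate_genome(genome_spec(c(c1 = 1e6, c2 = 3e5),
                                     autozygous_fraction = c(1, 0),
                                     background = list(model = "uniform",
                                                       rate_per_kb = 2),
                                     seed = 3), d)
  sc <- roh_scan(sim$vcf, sim$contigs)
  expect_s3_class(sc, "roh_scan")
  expect_equal(nrow(sc$windows), 10)        # the 300-kb contig is dropped
  expect_equal(sc$results$perfect$froh$froh, 1)
  s <- summary(sc)
  expect_equal(s$froh, rep(1, 5))
  # contig lengths can also come from the VCF header
  sc2 <- roh_scan(sim$vcf)
  expect_equal(summary(sc2), s)
})
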