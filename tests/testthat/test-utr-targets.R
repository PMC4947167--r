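test_that("expected site counts behave at the boundaries", {
  expect_equal(expected_sites("", "UGUANAUA"), 0)
  # homopolymer: every shuffle is the identity
  hp <- strrep("A", 200L)
  expect_equal(expected_sites(hp, "AA", method = "shuffle",
                              n_shuffles = 10, seed = 1),
               count_nonoverlapping(hp, "AA"))
  expect_equal(expected_sites(strrep("A", 1000L), "UGUANAUA",
                              method = "analytic"),
               993 * (1 / 4)^7, tolerance = 1e-12)
})

test_that("gene classification partitions genes by site excess", {
  set.seed(31)
  # planted targets in 1-kb backgrounds (expected ~0.06 analytically)
  bgs <- vapply(1:6, function(i) gen_background_seq(1000), character(1))
  utrs <- c(
    vapply(bgs[1:3],
           function(b) plant_motifs(b, "UGUANAUA", 3L, min_gap = 20L)$seq,
           character(1)),
    bgs[4:6])
  names(utrs) <- sprintf("g%02d", 1:6)
  calls <- classify_genes(utrs, method = "analytic")
  expect_equal(calls$klass[1:3], rep("target", 3))
  expect_true(all(calls$klass %in% c("target", "control", "intermediate")))
  # invariants tie klass to excess
  expect_true(all((calls$excess >= 2) == (calls$klass == "target")))
  expect_true(all((calls$observed <= calls$expected) ==
                  (calls$klass == "control")))

  # observed 0 -> control; observed 1 over a small expectation -> intermediate
  one_site <- plant_motifs(gen_background_seq(1000), "UGUANAUA", 1L)$seq
  mixed <- c(zero = gsub("TGT", "AAA",
                         paste(rep("ACG", 400), collapse = "")),
             one = one_site)
  calls2 <- classify_genes(mixed, method = "analytic")
  expect_equal(calls2$klass[calls2$gene_id == "zero"], "control")
  stopifnot(calls2$observed[calls2$gene_id == "one"] == 1L)
  expect_equal(calls2$klass[calls2$gene_id == "one"], "intermediate")
})

test_that("duplicate ids are rejected and empty UTRs excluded", {
  expect_error(classify_genes(c(a = "ACGT", a = "ACGT")), "duplicate")
  calls <- classify_genes(c(a = "ACGTACGTACGT", b = ""),
                          method = "analytic")
  expect_equal(calls$gene_id, "a")
  expect_equal(attr(calls, "excluded"), "b")
})

test_that("planted targets are recovered by the shuffle expectation", {
  u <- gen_utr_universe(40, target_fraction = 0.3, planted_excess = 3,
                        seed = 51)
  calls <- classify_genes(u$utrs, method = "shuffle", n_shuffles = 200,
                          seed = 52)
  truth <- u$truth$is_target[match(calls$gene_id, u$truth$gene_id)]
  sens <- mean(calls$klass[truth] == "target")
  expect_gte(sens, 0.9)
})

test_that("length-matched control sampling matches per-bin counts", {
  calls <- data.frame(
    gene_id = sprintf("g%02d", 1:12),
    utr_length = c(100, 110, 120, 130, 900, 910, 920, 930, 105, 115,
                   905, 915),
    observed = 0, expected = 0, excess = 0,
    klass = c(rep("control", 8), rep("target", 4)))
  class(calls) <- c("target_calls", class(calls))
  cs <- sample_length_matched_controls(calls, n_bins = 2L, seed = 1)
  expect_length(cs$sampled, 4L)
  expect_equal(cs$per_bin$n_sampled, cs$per_bin$n_targets)
  # matched bins: two sampled controls short, two long
  expect_equal(sum(calls$utr_length[match(cs$sampled, calls$gene_id)] < 500),
               2L)
  expect_identical(
    sample_length_matched_controls(calls, n_bins = 2L, seed = 7)$sampled,
    sample_length_matched_controls(calls, n_bins = 2L, seed = 7)$sampled)

  starved <- calls
  starved$klass[starved$klass == "control" &
                starved$utr_length > 500] <- "intermediate"
  expect_error(sample_length_matched_controls(starved, n_bins = 2L,
                                              seed = 1),
               "bin 2")
})

test_that("control samples reproduce the target length distribution", {
  u <- gen_utr_universe(500, target_fraction = 0.1, planted_excess = 3,
                        seed = 61)
  calls <- classify_genes(u$utrs, method = "analytic")
  n_ok <- 0L
  for (seed in 1:10) {
    cs <- sample_length_matched_controls(calls, seed = seed)
    p <- suppressWarnings(wilcox.test(
      calls$utr_length[calls$gene_id %in% cs$sampled],
      calls$utr_length[calls$klass == "target"])$p.value)
    if (p > 0.05) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 9L)
})

test_that("cluster-overlap target definition uses half-open intervals", {
  utr_bed <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                        start = c(100L, 500L, 0L),
                        end = c(200L, 600L, 50L),
                        gene_id = c("a", "b", "c"))
  clusters <- data.frame(chrom = c("chr1", "chr2"),
                         start = c(150L, 50L), end = c(160L, 80L))
  # the chr2 cluster abuts gene c exactly at the boundary: no overlap
  expect_equal(targets_from_clusters(utr_bed, clusters), "a")
})
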