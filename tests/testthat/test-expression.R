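test_that("RPM normalization conserves column totals", {
  m <- matrix(c(5L, 5L), ncol = 1,
              dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(unname(normalize_rpm(m)[, 1]), c(5e5, 5e5))
  expect_equal(unname(normalize_rpm(matrix(7L, 1, 1,
    dimnames = list("g1", "s1")))[1, 1]), 1e6)

  set.seed(1)
  r <- matrix(rpois(600, 30), 100, 6,
              dimnames = list(sprintf("g%03d", 1:100), NULL))
  expect_equal(unname(colSums(normalize_rpm(r))), rep(1e6, 6),
               tolerance = 1e-9)
  r0 <- r; r0[, 3] <- 0L
  expect_error(normalize_rpm(r0), "zero total")
  expect_error(normalize_rpm(r - 100L), "non-negative")
})

test_that("the expression filter is boundary-inclusive on mean RPM", {
  rpm <- rbind(kept = c(100, 0), edge = c(50, 50), dropped = c(49, 49),
               zero = c(0, 0))
  expect_equal(filter_expressed(rpm), c("kept", "edge"))
})

test_that("fold changes use condition means and the pseudocount", {
  fc <- fold_change(c(g = 99.9), c(g = 49.9))
  expect_equal(fc$log2fc, 1.0)
  expect_equal(fold_change(c(g = 0), c(g = 0))$log2fc, 0)
  expect_error(fold_change(c(g = -1), c(g = 1)), "non-negative")
  # replicate columns are averaged per condition first
  t2 <- matrix(c(10, 30), 1, 2, dimnames = list("g", NULL))   # mean 20
  c2 <- matrix(c(9.95, 9.95), 1, 2, dimnames = list("g", NULL))
  expect_equal(fold_change(t2, c2)$log2fc, 1.0)
})

test_that("planted fold-change shifts are recovered from counts", {
  gm <- gen_count_matrix(600, target_ids = 100, planted_log2fc = 1,
                         seed = 71)
  fc <- fold_change(normalize_rpm(gm$treated), normalize_rpm(gm$control))
  tg <- gm$truth$gene_id[gm$truth$is_target]
  # the difference of group medians cancels the RPM composition shift
  # that per-sample renormalisation induces when targets carry mass
  med_t <- median(fc$log2fc[fc$gene_id %in% tg])
  med_c <- median(fc$log2fc[!fc$gene_id %in% tg])
  expect_equal(med_t - med_c, 1.0, tolerance = 0.1)
})

test_that("intron counts subtract exon reads with zero flooring", {
  dn <- list(c("g1", "g2"), c("s1"))
  wl <- matrix(c(100L, 50L), 2, 1, dimnames = dn)
  ex <- matrix(c(60L, 60L), 2, 1, dimnames = dn)
  expect_warning(res <- intronic_counts(wl, ex), "clipped")
  expect_equal(unname(res[, 1]), c(40, 0))
  expect_equal(attr(res, "clipped"), 1L)
  expect_equal(unname(intronic_counts(wl, wl)[, 1]), c(0, 0))
  expect_error(intronic_counts(wl, ex[2:1, , drop = FALSE]), "share")
})

test_that("identical group distributions give p == 1", {
  vals <- setNames(rep(c(-1, 0, 2), 2), paste0("g", 1:6))
  cmp <- compare_groups(vals, paste0("g", 1:3), paste0("g", 4:6))
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$median_difference, 0)
})

test_that("small-sample p-values equal the exact rank-sum distribution", {
  set.seed(81)
  for (rep in 1:20) {
    n1 <- sample(2:5, 1L)
    n2 <- sample(2:5, 1L)
    if (n1 + n2 > 10L) next
    vals <- setNames(rnorm(n1 + n2), paste0("g", seq_len(n1 + n2)))
    cmp <- compare_groups(vals, paste0("g", seq_len(n1)),
                          paste0("g", n1 + seq_len(n2)))
    ref <- wilcox.test(vals[seq_len(n1)], vals[n1 + seq_len(n2)],
                       exact = TRUE)$p.value
    expect_equal(cmp$p_value, ref, tolerance = 1e-12)
    expect_match(cmp$method, "exact")
  }
})

test_that("separated groups are detected with the stated effect size", {
  set.seed(82)
  tg <- setNames(rnorm(200, -0.5, 0.2), paste0("t", 1:200))
  ct <- setNames(rnorm(200, 0, 0.2), paste0("c", 1:200))
  cmp <- compare_groups(c(tg, ct), names(tg), names(ct))
  expect_lt(cmp$p_value, 1e-10)
  expect_equal(cmp$median_difference, -0.5, tolerance = 0.1)
  expect_equal(cmp$direction, "down")
  expect_error(compare_groups(c(tg, ct), character(0), names(ct)),
               "non-empty")
})

test_that("perturbation correlation recovers sign and magnitude", {
  fa <- setNames(c(1, -2, 0.5, 3), paste0("g", 1:4))
  expect_equal(correlate_perturbations(fa, -fa)$rho, -1)
  expect_equal(correlate_perturbations(fa, fa)$rho, 1)
  expect_error(correlate_perturbations(fa[1:2], fa[1:2]), "at least 3")

  kd <- gen_count_matrix(300, target_ids = 120, planted_log2fc = -0.8,
                         seed = 91)
  oe <- gen_count_matrix(300,
                         target_ids = kd$truth$gene_id[kd$truth$is_target],
                         planted_log2fc = 0.8, seed = 92)
  fc_kd <- fold_change(normalize_rpm(kd$treated), normalize_rpm(kd$control))
  fc_oe <- fold_change(normalize_rpm(oe$treated), normalize_rpm(oe$control))
  rho <- correlate_perturbations(fc_kd, fc_oe)$rho
  expect_lte(rho, -0.4)
})

test_that("translation efficiency cancels shared mRNA effects", {
  fp <- setNames(c(10, 20, 30), paste0("g", 1:3))
  expect_equal(unname(translation_efficiency(fp, fp)), c(1, 1, 1))
  expect_equal(unname(translation_efficiency(setNames(0, "g"),
                                             setNames(0, "g"))), 1)
  expect_error(translation_efficiency(setNames(-1, "g"),
                                      setNames(1, "g")), "non-negative")
  # an mRNA-level-only effect leaves delta-TE near zero
  mrna_ctrl <- setNames(rep(100, 3), paste0("g", 1:3))
  fp_ctrl <- setNames(rep(40, 3), paste0("g", 1:3))
  shift <- 2^-0.7
  te_t <- translation_efficiency(fp_ctrl * shift, mrna_ctrl * shift)
  te_c <- translation_efficiency(fp_ctrl, mrna_ctrl)
  expect_equal(unname(delta_te(te_t, te_c)), rep(0, 3), tolerance = 0.01)
})

test_that("consistent regulation needs the threshold in every contrast", {
  fc1 <- setNames(log2(c(0.7, 0.75, 1.3, 1.0)), paste0("g", 1:4))
  fc2 <- setNames(log2(c(0.6, 0.9, 1.25, 1.0)), paste0("g", 1:4))
  res <- consistent_regulation(list(fc1, fc2), threshold = 0.2)
  expect_equal(res$down, "g1")   # g2 misses the 20% cut in contrast 2
  expect_equal(res$up, "g3")
})

test_that("response ECDF and dotplot figures render to file", {
  gm <- gen_count_matrix(200, target_ids = 50, planted_log2fc = -0.5,
                         seed = 95)
  fc <- fold_change(normalize_rpm(gm$treated), normalize_rpm(gm$control))
  tg <- gm$truth$gene_id[gm$truth$is_target]
  png1 <- tempfile(fileext = ".png")
  grDevices::png(png1, width = 400, height = 400)
  cmp <- plot_response_ecdf(fc, tg, setdiff(gm$truth$gene_id, tg))
  grDevices::dev.off()
  expect_true(file.exists(png1) && file.size(png1) > 0)
  expect_s3_class(cmp, "group_comparison")

  tr <- gen_tandem_repeat_seq(100, 3, 0, seed = 96)
  png2 <- tempfile(fileext = ".png")
  grDevices::png(png2, width = 400, height = 400)
  plot(self_dotplot(tr$seq, 8))
  grDevices::dev.off()
  expect_true(file.exists(png2) && file.size(png2) > 0)

  calls <- classify_genes(gen_utr_universe(10, seed = 97)$utrs,
                          method = "analytic")
  tsv <- tempfile(fileext = ".tsv")
  write_target_calls(calls, tsv)
  back <- read.delim(tsv)
  expect_equal(back$gene_id, calls$gene_id)
  expect_equal(back$klass, calls$klass)
})
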