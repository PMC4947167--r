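make_spot_set <- function(df, channel, dims = c(8L, 96L, 96L)) {
  df$channel <- rep(channel, nrow(df))
  structure(list(spots = df, channel = channel, threshold_curve = NULL,
                 no_signal = FALSE, dims = dims),
            class = "spot_set")
}

test_that("the LoG filter annihilates constants and peaks on spots", {
  const <- array(37, c(6, 20, 20))
  resp <- log_filter_3d(const)
  expect_lt(max(abs(resp)), 1e-9 * 37)

  one <- array(0, c(9, 21, 21))
  one[5, 11, 11] <- 100
  r1 <- log_filter_3d(one)
  expect_equal(which.max(r1), which.max(one))

  expect_error(log_filter_3d(array(1, c(1, 10, 10))), "degenerate")
})

test_that("the separable LoG equals direct convolution on a spot", {
  stack <- array(5, c(17, 31, 31))
  z0 <- 9; y0 <- 16; x0 <- 16
  for (z in 1:17) for (y in 8:24) for (x in 8:24) {
    stack[z, y, x] <- stack[z, y, x] +
      120 * exp(-((z - z0)^2 + (y - y0)^2 + (x - x0)^2) / (2 * 1.5^2))
  }
  resp <- log_filter_3d(stack)
  ref <- oracle_log_at(stack, z0, y0, x0)
  expect_equal(resp[z0, y0, x0], ref, tolerance = 1e-8)
  peak <- arrayInd(which.max(resp), dim(resp))
  expect_equal(as.integer(peak), c(z0, y0, x0))
})

test_that("threshold selection sits on the spot-count plateau", {
  sim <- gen_fish_stack(n_spots = 10, cyto_fraction = 1, snr = 20,
                        seed = 301)
  filt <- log_filter_3d(sim$signal)
  curve <- select_threshold(filt)
  expect_equal(curve$component_counts[curve$selected_index], 10L)

  # pure noise: few components survive at the selected threshold
  noise <- gen_fish_stack(n_spots = 0, seed = 302)
  fn <- log_filter_3d(noise$signal)
  cn <- select_threshold(fn)
  expect_lte(cn$component_counts[cn$selected_index], 2L)

  expect_error(select_threshold(array(1, c(4, 8, 8))), "no signal")
})

test_that("a dim spot is not lost to a 10x brighter one", {
  stack <- array(2, c(9, 48, 48))
  add_spot <- function(st, z0, y0, x0, amp) {
    for (z in 1:9) for (y in (y0 - 6):(y0 + 6)) for (x in (x0 - 6):(x0 + 6)) {
      st[z, y, x] <- st[z, y, x] +
        amp * exp(-((z - z0)^2 + (y - y0)^2 + (x - x0)^2) / (2 * 1.5^2))
    }
    st
  }
  stack <- add_spot(stack, 5, 14, 14, 20)
  stack <- add_spot(stack, 5, 34, 34, 200)
  withr::with_seed(303, {
    stack <- stack + array(rnorm(length(stack), sd = 0.4), dim(stack))
  })
  curve <- select_threshold(log_filter_3d(stack))
  expect_equal(curve$component_counts[curve$selected_index], 2L)
})

test_that("spot detection recovers planted spots and handles no signal", {
  empty <- detect_spots(array(0, c(4, 16, 16)))
  expect_true(empty$no_signal)
  expect_equal(nrow(empty$spots), 0L)

  sim <- gen_fish_stack(n_spots = 20, snr = 10, seed = 304)
  ss <- detect_spots(sim$signal)
  expect_equal(nrow(ss$spots), 20L)
  # centroids land within a voxel of the planted truth
  d <- vapply(seq_len(nrow(sim$truth)), function(i) {
    min(sqrt((ss$spots$z - sim$truth$z[i])^2 +
             (ss$spots$y - sim$truth$y[i])^2 +
             (ss$spots$x - sim$truth$x[i])^2))
  }, numeric(1))
  expect_lt(max(d), 1.5)
})

test_that("spot counts are invariant to uniform intensity scaling", {
  sim <- gen_fish_stack(n_spots = 15, seed = 305)
  a <- detect_spots(sim$signal)
  b <- detect_spots(sim$signal * 3.7)
  expect_equal(nrow(a$spots), nrow(b$spots))
})

test_that("component labelling agrees with a flood-fill oracle", {
  set.seed(306)
  for (rep in 1:5) {
    mask <- array(runif(14 * 14 * 14) < 0.15, c(14, 14, 14))
    counts <- decoyscan:::cpp_count_components(
      as.numeric(mask), dim(mask), 0.5)
    expect_equal(counts, oracle_count_components(mask))
  }
})

test_that("background removal filters by size and co-occurrence", {
  a <- data.frame(z = c(2, 4, 6), y = c(10, 40, 70),
                  x = c(10, 40, 70), n_voxels = c(1L, 10L, 10L),
                  peak = 1)
  single <- remove_background(make_spot_set(a, "cy5"))
  expect_equal(nrow(single$spots), 2L)   # the 1-voxel spot is dropped

  b <- data.frame(z = c(4.2, 3), y = c(40.5, 80), x = c(39.8, 15),
                  n_voxels = c(9L, 9L), peak = 1)
  both <- remove_background(list(make_spot_set(a, "cy5"),
                                 make_spot_set(b, "fitc")))
  # the co-occurring (z=4, 40, 40) spot disappears from both channels
  expect_equal(both[[1]]$spots$y, c(70))
  expect_equal(both[[2]]$spots$y, c(80))

  set.seed(307)
  true_sp <- data.frame(z = runif(200, 1, 8), y = runif(200, 5, 92),
                        x = runif(200, 5, 92), n_voxels = 10L, peak = 1)
  artifacts <- true_sp[1:2, ]
  other <- data.frame(z = artifacts$z, y = artifacts$y, x = artifacts$x,
                      n_voxels = 10L, peak = 1)
  res <- remove_background(list(make_spot_set(true_sp, "cy5"),
                                make_spot_set(other, "fitc")))
  expect_equal(res[[1]]$removed_fraction, 0.01, tolerance = 0.005)
})

test_that("compartment assignment follows the DAPI mask", {
  sim <- gen_fish_stack(n_spots = 5, seed = 308)
  centre <- which(sim$nuclear_mask, arr.ind = TRUE)
  inside <- data.frame(z = rep(4, 6),
                       y = centre[seq(1, nrow(centre), length.out = 6), 1],
                       x = centre[seq(1, nrow(centre), length.out = 6), 2],
                       n_voxels = 10L, peak = 1)
  ss <- assign_compartment(make_spot_set(inside, "cy5"), sim$dapi)
  expect_equal(unname(ss$fractions[["nuclear"]]), 1.0)

  # a planted 94/6 split is reported exactly
  out_pts <- which(!sim$nuclear_mask, arr.ind = TRUE)
  out_pts <- out_pts[out_pts[, 1] > 5 & out_pts[, 1] < 91 &
                     out_pts[, 2] > 5 & out_pts[, 2] < 91, ]
  set.seed(309)
  ci <- sample.int(nrow(centre), 30)
  oi <- sample.int(nrow(out_pts), 470)
  mixed <- rbind(
    data.frame(y = centre[ci, 1], x = centre[ci, 2]),
    data.frame(y = out_pts[oi, 1], x = out_pts[oi, 2]))
  mixed <- cbind(z = 4, mixed, n_voxels = 10L, peak = 1)
  ss2 <- assign_compartment(make_spot_set(mixed, "cy5"), sim$dapi)
  expect_equal(unname(ss2$fractions[["cytoplasmic"]]), 0.94,
               tolerance = 0.03)

  expect_warning(res <- assign_compartment(make_spot_set(inside, "cy5"),
                                           NULL), "DAPI")
  expect_null(res$spots$compartment)

  ss3 <- assign_compartment(
    make_spot_set(inside[0, ], "cy5"), sim$dapi)
  expect_null(ss3$fractions)
})

test_that("TIFF stacks round-trip through multi-page files", {
  skip_if_not_installed("tiff")
  sim <- gen_fish_stack(dims = c(4L, 32L, 32L), n_spots = 3,
                        nucleus_semiaxes = c(7, 9), seed = 310)
  path <- tempfile(fileext = ".tif")
  write_stack(sim$signal, path)
  back <- read_stack(path)
  expect_equal(dim(back), dim(sim$signal))
  expect_gt(cor(as.numeric(back), as.numeric(sim$signal)), 0.999)
})
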