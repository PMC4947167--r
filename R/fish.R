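#' 3D Laplacian-of-Gaussian spot-enhancement filter
#'
#' Applies a negated Laplacian-of-Gaussian to a z-stack so that bright
#' diffraction-limited spots become positive peaks.  The separable
#' decomposition `LoG = Gxx*Gy*Gz + Gx*Gyy*Gz + Gx*Gy*Gzz` is used
#' (nine 1D passes); the kernel is truncated to `size` taps, the
#' second-derivative taps are re-centred to sum to zero (a constant
#' stack maps exactly to zero response), and edges are mirror-padded.
#'
#' @param stack 3D numeric array `(z, y, x)` of non-negative
#'   intensities, every dimension >= 2.
#' @param size Kernel support in pixels (odd, default 15).
#' @param sigma Gaussian standard deviation in pixels (default 1.5),
#'   applied isotropically.
#' @param sigma_z Optional separate standard deviation along z for
#'   anisotropic voxels; default `NULL` uses `sigma`.
#' @return Filtered array of the same shape.
#' @export
log_filter_3d <- function(stack, size = 15L, sigma = 1.5,
                          sigma_z = NULL) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  if (any(dim(stack) < 2L)) {
    stop("degenerate stack: every dimension must be >= 2")
  }
  if (size %% 2L == 0L) stop("kernel size must be odd")
  if (is.null(sigma_z)) sigma_z <- sigma
  r <- (size - 1L) / 2L
  t <- seq(-r, r)
  g1 <- function(s) {
    k <- exp(-t^2 / (2 * s^2))
    k / sum(k)
  }
  g2 <- function(s) {
    k <- g1(s) * (t^2 - s^2) / s^4
    k - mean(k)           # zero-sum under truncation
  }
  gy <- g1(sigma); gx <- g1(sigma); gz <- g1(sigma_z)
  conv3 <- function(kz, ky, kx) {
    conv_axis(conv_axis(conv_axis(stack, kz, 1L), ky, 2L), kx, 3L)
  }
  lap <- conv3(g2(sigma_z), gy, gx) + conv3(gz, g2(sigma), gx) +
         conv3(gz, gy, g2(sigma))
  -lap
}

# mirror-boundary (no edge repeat) index into [1, n]
mirror_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * (n - 1L))
  ifelse(p < n, p + 1L, 2L * n - 1L - p)
}

# 1D convolution along one axis of a 3D array, mirror padding
conv_axis <- function(a, kern, axis) {
  r <- (length(kern) - 1L) / 2L
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n <- dim(ap)[1L]
  idx <- mirror_idx((1L - r):(n + r), n)
  padded <- ap[idx, , , drop = FALSE]
  res <- array(0, dim(ap))
  for (k in seq_along(kern)) {
    if (kern[k] == 0) next
    res <- res + kern[k] * padded[k:(k + n - 1L), , , drop = FALSE]
  }
  aperm(res, order(perm))
}

#' Threshold selection by component-count stability
#'
#' Counts 3D connected components (26-connectivity) of the binarised
#' filtered stack over a uniform grid of thresholds spanning the
#' response range, and selects the threshold at which the count is
#' least sensitive to the choice.  Candidate plateaus are the maximal
#' runs of constant component count on the decreasing limb of the
#' curve (at and after its mode; below the mode the binarisation is
#' still dominated by merged background).  Runs whose count is at
#' least 2 and whose length reaches `min_plateau` grid points are
#' preferred (a one-component binarisation cannot separate signal from
#' merged background, and shorter runs are noise flats; both are used
#' only as fallbacks), the longest eligible run wins, ties fall to the
#' lowest threshold, and the centre of the winning run is selected.
#' The smoothed absolute derivative `|d count / d threshold|`
#' (centred differences, 3-point moving average) is reported as the
#' per-threshold stability score.
#'
#' @param filtered Filtered stack from [log_filter_3d()].
#' @param n_thresholds Grid size (default 100).
#' @param min_plateau Minimal run length (in grid points) for a
#'   multi-component plateau to be trusted (default 5).
#' @return Object of class `threshold_curve`: list with `thresholds`,
#'   `component_counts`, `stability`, `selected_threshold`,
#'   `selected_index`.
#' @export
select_threshold <- function(filtered, n_thresholds = 100L,
                             min_plateau = 5L) {
  stopifnot(is.array(filtered), length(dim(filtered)) == 3L)
  rng <- range(filtered)
  if (diff(rng) <= 0) stop("no signal: filtered stack has no dynamic range")
  thr <- seq(rng[1L], rng[2L], length.out = n_thresholds)
  counts <- cpp_count_components(as.numeric(filtered), dim(filtered), thr)

  dt <- thr[2L] - thr[1L]
  n <- length(thr)
  deriv <- numeric(n)
  deriv[2:(n - 1L)] <- abs(counts[3:n] - counts[1:(n - 2L)]) / (2 * dt)
  deriv[1L] <- abs(counts[2L] - counts[1L]) / dt
  deriv[n] <- abs(counts[n] - counts[n - 1L]) / dt
  smooth <- deriv
  smooth[2:(n - 1L)] <- (deriv[1:(n - 2L)] + deriv[2:(n - 1L)] +
                         deriv[3:n]) / 3

  mode_idx <- which.max(counts)
  r <- rle(counts[mode_idx:n])
  ends <- mode_idx - 1L + cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts, end = ends, count = r$values,
                     len = r$lengths)
  eligible <- runs[runs$count >= 2L & runs$len >= min_plateau, ,
                   drop = FALSE]
  if (!nrow(eligible)) eligible <- runs[runs$count >= 1L, , drop = FALSE]
  if (!nrow(eligible)) eligible <- runs
  pick <- which.max(eligible$len)          # ties: first = lowest threshold
  sel <- (eligible$start[pick] + eligible$end[pick]) %/% 2L

  structure(list(thresholds = thr, component_counts = counts,
                 stability = smooth, selected_threshold = thr[sel],
                 selected_index = sel),
            class = "threshold_curve")
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat("<threshold_curve> ", length(x$thresholds), " thresholds; selected ",
      format(x$selected_threshold, digits = 4), " (",
      x$component_counts[x$selected_index], " components)\n", sep = "")
  invisible(x)
}

#' Detect diffraction-limited spots in a 3D stack
#'
#' Runs the LoG filter, selects the stability threshold, labels the
#' supra-threshold voxels into 26-connected components, and reports
#' each component as a spot with its intensity-weighted centroid
#' (weights from the raw stack), voxel count and peak raw intensity.
#'
#' @param stack Raw 3D stack `(z, y, x)`.
#' @param channel Channel label recorded on each spot
#'   (default `"signal"`).
#' @param size,sigma,sigma_z LoG parameters, see [log_filter_3d()].
#' @param n_thresholds Grid size for [select_threshold()].
#' @return Object of class `spot_set`: list with `spots` (data.frame
#'   `z`, `y`, `x`, `n_voxels`, `peak`, `channel`), `channel`,
#'   `threshold_curve` (or `NULL`), `no_signal` flag, `dims`.
#' @export
detect_spots <- function(stack, channel = "signal", size = 15L,
                         sigma = 1.5, sigma_z = NULL,
                         n_thresholds = 100L) {
  filtered <- log_filter_3d(stack, size = size, sigma = sigma,
                            sigma_z = sigma_z)
  empty <- data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                      n_voxels = integer(0), peak = numeric(0),
                      channel = character(0))
  if (diff(range(filtered)) <= 0) {
    return(structure(list(spots = empty, channel = channel,
                          threshold_curve = NULL, no_signal = TRUE,
                          dims = dim(stack)),
                     class = "spot_set"))
  }
  curve <- select_threshold(filtered, n_thresholds = n_thresholds)
  lab <- cpp_label_components(as.numeric(filtered), dim(filtered),
                              curve$selected_threshold)
  ncomp <- attr(lab, "n_components")
  if (ncomp == 0L) {
    return(structure(list(spots = empty, channel = channel,
                          threshold_curve = curve, no_signal = TRUE,
                          dims = dim(stack)),
                     class = "spot_set"))
  }
  idx <- which(lab > 0L)
  li <- lab[idx]
  co <- arrayInd(idx, dim(stack))
  w <- pmax(as.numeric(stack)[idx], 1e-12)
  wsum <- rowsum(w, li)
  cz <- rowsum(w * co[, 1L], li) / wsum
  cy <- rowsum(w * co[, 2L], li) / wsum
  cx <- rowsum(w * co[, 3L], li) / wsum
  nv <- tabulate(li, nbins = ncomp)
  peak <- vapply(split(as.numeric(stack)[idx], li), max, numeric(1L))
  spots <- data.frame(z = as.numeric(cz), y = as.numeric(cy),
                      x = as.numeric(cx), n_voxels = nv,
                      peak = unname(peak),
                      channel = rep(channel, ncomp),
                      stringsAsFactors = FALSE)
  structure(list(spots = spots, channel = channel,
                 threshold_curve = curve, no_signal = FALSE,
                 dims = dim(stack)),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  if (isTRUE(x$no_signal)) {
    cat("<spot_set> channel ", x$channel, ": no signal\n", sep = "")
  } else {
    cat("<spot_set> channel ", x$channel, ": ", nrow(x$spots),
        " spots\n", sep = "")
    if (!is.null(x$fractions)) {
      cat("  nuclear ", format(x$fractions[["nuclear"]], digits = 3),
          ", cytoplasmic ",
          format(x$fractions[["cytoplasmic"]], digits = 3), "\n",
          sep = "")
    }
  }
  invisible(x)
}

#' Remove background spots by size and cross-channel co-occurrence
#'
#' Drops spots whose voxel count falls outside `[min_voxels,
#' max_voxels]`, and spots whose centroid lies within
#' `co_occurrence_radius_px` (Euclidean, in voxels) of a spot centroid
#' in a *different* channel — the signature of autofluorescent debris
#' visible in more than one channel (typically under 1% of spots).
#'
#' @param spotsets A single `spot_set` (size filtering only) or a list
#'   of `spot_set` objects from different channels.
#' @param min_voxels,max_voxels Inclusive size bounds (defaults 2 and
#'   100).
#' @param co_occurrence_radius_px Cross-channel matching radius
#'   (default 2).
#' @return Filtered object(s) of the same shape as the input; each
#'   `spot_set` gains a `removed_fraction` field (fraction of its
#'   spots removed).
#' @export
remove_background <- function(spotsets, min_voxels = 2L,
                              max_voxels = 100L,
                              co_occurrence_radius_px = 2) {
  single <- inherits(spotsets, "spot_set")
  sets <- if (single) list(spotsets) else spotsets
  stopifnot(all(vapply(sets, inherits, logical(1L), "spot_set")))
  n_before <- vapply(sets, function(s) nrow(s$spots), integer(1L))

  keep <- lapply(sets, function(s) {
    s$spots$n_voxels >= min_voxels & s$spots$n_voxels <= max_voxels
  })
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i == j || sets[[i]]$channel == sets[[j]]$channel) next
      a <- sets[[i]]$spots
      b <- sets[[j]]$spots
      if (!nrow(a) || !nrow(b)) next
      d2 <- outer(a$z, b$z, "-")^2 + outer(a$y, b$y, "-")^2 +
            outer(a$x, b$x, "-")^2
      co <- apply(d2 <= co_occurrence_radius_px^2, 1L, any)
      keep[[i]] <- keep[[i]] & !co
    }
  }
  for (i in seq_along(sets)) {
    sets[[i]]$spots <- sets[[i]]$spots[keep[[i]], , drop = FALSE]
    rownames(sets[[i]]$spots) <- NULL
    sets[[i]]$removed_fraction <-
      if (n_before[i] > 0L) 1 - sum(keep[[i]]) / n_before[i] else 0
  }
  if (single) sets[[1L]] else sets
}

#' Assign spots to nucleus or cytoplasm
#'
#' Builds a nuclear mask from the DAPI channel — Otsu threshold on the
#' maximum-intensity z-projection, holes filled — and labels each spot
#' nuclear when its `(y, x)` centroid falls inside the mask, otherwise
#' cytoplasmic.  Compartment fractions are reported when spots exist.
#'
#' @param spotset A `spot_set` from [detect_spots()].
#' @param dapi_stack 3D DAPI stack aligned with the signal stack, or
#'   `NULL` (labels omitted with a warning).
#' @return The `spot_set` with a `compartment` column, plus `counts`
#'   and `fractions` fields (named over nuclear/cytoplasmic) and the
#'   `nuclear_mask`.
#' @export
assign_compartment <- function(spotset, dapi_stack) {
  stopifnot(inherits(spotset, "spot_set"))
  if (is.null(dapi_stack)) {
    warning("no DAPI channel supplied; compartment labels omitted")
    return(spotset)
  }
  stopifnot(is.array(dapi_stack), length(dim(dapi_stack)) == 3L)
  proj <- apply(dapi_stack, c(2L, 3L), max)
  mask <- fill_holes(proj > otsu_threshold(proj))
  spotset$nuclear_mask <- mask
  if (!nrow(spotset$spots)) {
    spotset$counts <- c(nuclear = 0L, cytoplasmic = 0L)
    spotset$fractions <- NULL
    return(spotset)
  }
  yi <- pmin(pmax(round(spotset$spots$y), 1L), nrow(mask))
  xi <- pmin(pmax(round(spotset$spots$x), 1L), ncol(mask))
  nuc <- mask[cbind(yi, xi)]
  spotset$spots$compartment <- ifelse(nuc, "nuclear", "cytoplasmic")
  spotset$counts <- c(nuclear = sum(nuc), cytoplasmic = sum(!nuc))
  spotset$fractions <- spotset$counts / sum(spotset$counts)
  spotset
}

# Otsu's bimodal threshold on a 256-bin histogram
otsu_threshold <- function(x) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) <= 0) return(rng[1L])
  nb <- 256L
  h <- tabulate(pmin(as.integer((x - rng[1L]) / diff(rng) * nb) + 1L, nb),
                nbins = nb)
  p <- h / sum(h)
  mids <- rng[1L] + (seq_len(nb) - 0.5) / nb * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# fill holes: background components not touching the border become TRUE
fill_holes <- function(mask) {
  d <- dim(mask)
  lab <- cpp_label_components(as.numeric(!mask), c(d[1L], d[2L], 1L), 0.5)
  lab <- array(lab, dim = d)
  border <- unique(c(lab[1L, ], lab[d[1L], ], lab[, 1L], lab[, d[2L]]))
  border <- border[border > 0L]
  mask | (lab > 0L & !(lab %in% border))
}

#' Read / write a z-stack as multi-page TIFF
#'
#' Stacks are stored one z-section per page.  `write_stack()` scales
#' intensities into `[0, 1]` by the stack maximum (recorded nowhere:
#' use these helpers for visualisation and interchange, not archival
#' of absolute intensities).
#'
#' @param path TIFF path.
#' @return `read_stack()`: numeric array `(z, y, x)`.
#' @export
read_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF I/O")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(length(pages), dim(pages[[1L]])[1:2]))
  for (z in seq_along(pages)) {
    pg <- pages[[z]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]
    arr[z, , ] <- pg
  }
  arr
}

#' @rdname read_stack
#' @param stack Numeric array `(z, y, x)`.
#' @export
write_stack <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF I/O")
  }
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  mx <- max(stack)
  if (mx <= 0) mx <- 1
  pages <- lapply(seq_len(dim(stack)[1L]),
                  function(z) stack[z, , ] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
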