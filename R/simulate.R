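#' Generate a background sequence with given dinucleotide structure
#'
#' First-order Markov chain whose transition probabilities are derived
#' from the supplied dinucleotide frequency table — the generative
#' counterpart of the dinucleotide-preserving shuffle null.
#'
#' @param length Output length (>= 0).
#' @param dinuc_freqs Named numeric vector over the 16 dinucleotides
#'   (`"AA"`, `"AC"`, ...), or a 4x4 matrix with A/C/G/T dimnames;
#'   non-negative, positive sum.  Default uniform.
#' @param seed Optional integer seed applied locally.
#' @return Character scalar over `{A,C,G,T}`.
#' @export
gen_background_seq <- function(length,
                               dinuc_freqs = NULL, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, gen_background_seq(length, dinuc_freqs)))
  }
  bases <- c("A", "C", "G", "T")
  f <- matrix(1 / 16, 4L, 4L, dimnames = list(bases, bases))
  if (!is.null(dinuc_freqs)) {
    if (is.matrix(dinuc_freqs)) {
      stopifnot(identical(dim(dinuc_freqs), c(4L, 4L)))
      f <- dinuc_freqs[bases, bases]
    } else {
      nm <- names(dinuc_freqs)
      if (is.null(nm) || !all(nchar(nm) == 2L)) {
        stop("dinuc_freqs must be a named dinucleotide vector or 4x4 matrix")
      }
      f[] <- 0
      for (i in seq_along(dinuc_freqs)) {
        a <- substr(nm[i], 1L, 1L); b <- substr(nm[i], 2L, 2L)
        if (!a %in% bases || !b %in% bases) {
          stop("invalid dinucleotide name: ", nm[i])
        }
        f[a, b] <- dinuc_freqs[i]
      }
    }
  }
  if (any(f < 0) || sum(f) <= 0) {
    stop("dinucleotide frequencies must be non-negative with positive sum")
  }
  if (length == 0L) return("")
  marg <- rowSums(f) / sum(f)
  if (any(rowSums(f) == 0) && any(marg == 0)) {
    # absorbing-safe: restrict start to emitting states
    marg <- marg / sum(marg)
  }
  trans <- f / rowSums(f)
  trans[!is.finite(trans)] <- 0.25
  out <- integer(length)
  out[1L] <- sample.int(4L, 1L, prob = marg)
  if (length > 1L) {
    cum <- t(apply(trans, 1L, cumsum))
    u <- runif(length - 1L)
    for (i in 2:length) {
      out[i] <- findInterval(u[i - 1L], cum[out[i - 1L], ],
                             left.open = TRUE) + 1L
    }
  }
  paste(bases[out], collapse = "")
}

#' Plant concrete motif instances into a sequence
#'
#' Writes `n` non-overlapping concrete instantiations of a degenerate
#' pattern (each degenerate position drawn uniformly from its allowed
#' set) at random positions with pairwise gaps of at least `min_gap`,
#' and returns the positions as ground truth.
#'
#' @param seq Background sequence (character scalar).
#' @param pattern Motif (consensus string or [parse_iupac()] object).
#' @param n Number of instances to plant (>= 0).
#' @param min_gap Minimum gap in nt between planted instances
#'   (default 0).
#' @param seed Optional integer seed applied locally.
#' @return List with `seq` (modified sequence) and `positions`
#'   (sorted 0-based start offsets).
#' @export
plant_motifs <- function(seq, pattern, n, min_gap = 0L, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, plant_motifs(seq, pattern, n, min_gap)))
  }
  pattern <- as_motif(pattern)
  seq <- as.character(ingest_seq(seq[[1L]]))
  if (n == 0L) return(list(seq = seq, positions = integer(0)))
  L <- nchar(seq)
  m <- pattern$length
  if (L < n * m + (n - 1L) * min_gap) {
    stop("insufficient room to plant ", n, " instances of length ", m)
  }
  chosen <- integer(0)
  attempts <- 0L
  while (length(chosen) < n) {
    attempts <- attempts + 1L
    if (attempts > 1000L * n) {
      stop("insufficient room to plant ", n,
           " instances with min_gap ", min_gap)
    }
    cand <- sample.int(L - m + 1L, 1L)
    if (all(abs(cand - chosen) >= m + min_gap)) {
      chosen <- c(chosen, cand)
    }
  }
  chosen <- sort(chosen)
  chars <- strsplit(seq, "")[[1L]]
  for (s in chosen) {
    inst <- vapply(pattern$sets, sample_one, character(1L))
    chars[s:(s + m - 1L)] <- inst
  }
  list(seq = paste(chars, collapse = ""), positions = chosen - 1L)
}

#' Generate a diverged tandem-repeat sequence
#'
#' Duplicates one random ancestral unit `n_units` times, mutates each
#' copy independently at `per_base_mutation_rate` (substitutions to a
#' uniformly chosen different base), and appends random flanks —
#' emulating a repeat array that has diverged since duplication
#' (two copies of one ancestor share about `(1-r)^2 + r^2/3` identity
#' per site).
#'
#' @param unit_length Ancestral unit length in nt.
#' @param n_units Number of tandem copies.
#' @param per_base_mutation_rate Per-base substitution probability in
#'   each copy (default 0).
#' @param flank Length of random flanking sequence on each side
#'   (default 0).
#' @param seed Optional integer seed applied locally.
#' @return List with `seq`, `boundaries` (data.frame `start`, `end`,
#'   0-based half-open unit coordinates), `unit_length`, `n_units`,
#'   `ancestor`.
#' @export
gen_tandem_repeat_seq <- function(unit_length, n_units,
                                  per_base_mutation_rate = 0,
                                  flank = 0L, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed, gen_tandem_repeat_seq(unit_length, n_units,
                                  per_base_mutation_rate, flank)))
  }
  bases <- c("A", "C", "G", "T")
  ancestor <- sample(bases, unit_length, replace = TRUE)
  mutate <- function(u) {
    hit <- runif(length(u)) < per_base_mutation_rate
    if (any(hit)) {
      u[hit] <- vapply(u[hit],
                       function(b) sample_one(setdiff(bases, b)),
                       character(1L))
    }
    u
  }
  units <- lapply(seq_len(n_units), function(i) mutate(ancestor))
  left <- sample(bases, flank, replace = TRUE)
  right <- sample(bases, flank, replace = TRUE)
  seq <- paste(c(left, unlist(units), right), collapse = "")
  starts <- flank + unit_length * (seq_len(n_units) - 1L)
  list(seq = seq,
       boundaries = data.frame(start = starts,
                               end = starts + unit_length),
       unit_length = as.integer(unit_length),
       n_units = as.integer(n_units),
       ancestor = paste(ancestor, collapse = ""))
}

#' Generate a 3'-UTR universe with planted target genes
#'
#' Per gene, a random-background UTR with log-normal length (median
#' ~1 kb by default, so 10-bin length matching is non-trivial); a
#' designated fraction of genes receives
#' `ceiling(expected + planted_excess)` planted motif sites and forms
#' the ground-truth target set.
#'
#' @param n_genes Number of genes.
#' @param target_fraction Fraction of genes designated targets
#'   (default 0.1).
#' @param planted_excess Sites planted beyond the length expectation
#'   (default 3).
#' @param pattern Motif (default `UGUANAUA`).
#' @param meanlog,sdlog Log-normal UTR length parameters (defaults
#'   `log(1000)` and 0.6).
#' @param min_length Lower bound on UTR length (default 50).
#' @param seed Optional integer seed applied locally.
#' @return List with `utrs` (named character vector) and `truth`
#'   (data.frame `gene_id`, `utr_length`, `is_target`, `n_planted`).
#' @export
gen_utr_universe <- function(n_genes, target_fraction = 0.1,
                             planted_excess = 3,
                             pattern = "UGUANAUA",
                             meanlog = log(1000), sdlog = 0.6,
                             min_length = 50L, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed, gen_utr_universe(n_genes, target_fraction, planted_excess,
                             pattern, meanlog, sdlog, min_length)))
  }
  pattern <- as_motif(pattern)
  if (n_genes == 0L) {
    return(list(utrs = setNames(character(0), character(0)),
                truth = data.frame(gene_id = character(0),
                                   utr_length = integer(0),
                                   is_target = logical(0),
                                   n_planted = integer(0))))
  }
  ids <- sprintf("gene%04d", seq_len(n_genes))
  lens <- pmax(min_length, round(rlnorm(n_genes, meanlog, sdlog)))
  n_targets <- round(n_genes * target_fraction)
  is_target <- seq_len(n_genes) %in% sample.int(n_genes, n_targets)
  utrs <- character(n_genes)
  n_planted <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    bg <- gen_background_seq(lens[i])
    if (is_target[i]) {
      np <- ceiling(expected_analytic(lens[i], pattern) + planted_excess)
      pl <- plant_motifs(bg, pattern, np, min_gap = 10L)
      utrs[i] <- pl$seq
      n_planted[i] <- np
    } else {
      utrs[i] <- bg
    }
  }
  names(utrs) <- ids
  list(utrs = utrs,
       truth = data.frame(gene_id = ids, utr_length = lens,
                          is_target = is_target, n_planted = n_planted,
                          stringsAsFactors = FALSE))
}

#' Generate a perturbation count-matrix pair
#'
#' Negative-binomial counts around log-normal baseline means for a
#' control and a treated condition; designated target genes have their
#' treated means shifted by `planted_log2fc`.  With `dispersion = 0`
#' counts are Poisson.
#'
#' @param n_genes Number of genes.
#' @param target_ids Gene ids (of the form `gene0001`...) to shift, or
#'   an integer count (that many genes are drawn at random).
#' @param planted_log2fc Log2 shift applied to targets in the treated
#'   condition (default 0).
#' @param n_reps Replicates per condition (default 2).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline expression (defaults `log(200)` and 1; with the
#'   default library behaviour counts are on the RPM scale).
#' @param dispersion NB dispersion (variance `mu + dispersion * mu^2`,
#'   default 0.05).
#' @param seed Optional integer seed applied locally.
#' @return List with `control` and `treated` (gene x replicate integer
#'   matrices) and `truth` (data.frame `gene_id`, `is_target`,
#'   `baseline`, `planted_log2fc`).
#' @export
gen_count_matrix <- function(n_genes, target_ids = 0L,
                             planted_log2fc = 0, n_reps = 2L,
                             baseline_meanlog = log(200),
                             baseline_sdlog = 1,
                             dispersion = 0.05, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed, gen_count_matrix(n_genes, target_ids, planted_log2fc,
                             n_reps, baseline_meanlog, baseline_sdlog,
                             dispersion)))
  }
  ids <- sprintf("gene%04d", seq_len(n_genes))
  if (is.numeric(target_ids) && length(target_ids) == 1L) {
    target_ids <- if (target_ids > 0) sample(ids, target_ids) else character(0)
  }
  is_target <- ids %in% target_ids
  baseline <- rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  mu_treat <- baseline * ifelse(is_target, 2^planted_log2fc, 1)
  draw <- function(mu) {
    m <- matrix(0L, n_genes, n_reps,
                dimnames = list(ids, paste0("rep", seq_len(n_reps))))
    for (j in seq_len(n_reps)) {
      m[, j] <- if (dispersion <= 0) {
        rpois(n_genes, mu)
      } else {
        rnbinom(n_genes, mu = mu, size = 1 / dispersion)
      }
    }
    m
  }
  list(control = draw(baseline), treated = draw(mu_treat),
       truth = data.frame(gene_id = ids, is_target = is_target,
                          baseline = baseline,
                          planted_log2fc =
                            ifelse(is_target, planted_log2fc, 0),
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic smFISH stack pair with ground truth
#'
#' Renders an ellipsoidal nucleus into a DAPI channel and
#' diffraction-limited spots (3D Gaussians of `psf_sigma` pixels) into
#' a signal channel, splitting spots between cytoplasm (outside the
#' nuclear footprint) and nucleus per `cyto_fraction`.  Voxel noise is
#' Poisson shot noise on the clean image plus Gaussian read noise of
#' standard deviation `amplitude / snr`.
#'
#' @param dims Stack dimensions `c(nz, ny, nx)` (default
#'   `c(8, 96, 96)`).
#' @param n_spots Number of spots (default 68).
#' @param cyto_fraction Fraction of spots placed in the cytoplasm
#'   (default 0.94).
#' @param nucleus_semiaxes Ellipse semi-axes `(y, x)` of the nuclear
#'   footprint in pixels (default `c(20, 25)`), centred in the frame.
#' @param amplitude Peak spot amplitude above baseline (default 200).
#' @param baseline Background intensity (default 10).
#' @param psf_sigma Spot sigma in pixels, xy (default 1.5).
#' @param psf_sigma_z Spot sigma along z (default 1).
#' @param snr Amplitude-to-read-noise ratio (default 10).
#' @param min_separation Minimum pairwise spot distance in pixels
#'   (default 6; keeps planted spots resolvable).
#' @param margin Minimum distance of spot centres from the y/x borders
#'   (default 5).
#' @param seed Optional integer seed applied locally.
#' @return List with `signal` and `dapi` (arrays `(z, y, x)`),
#'   `nuclear_mask` (ny x nx logical), and `truth` (data.frame `z`,
#'   `y`, `x`, `compartment`).
#' @export
gen_fish_stack <- function(dims = c(8L, 96L, 96L), n_spots = 68L,
                           cyto_fraction = 0.94,
                           nucleus_semiaxes = c(20, 25),
                           amplitude = 200, baseline = 10,
                           psf_sigma = 1.5, psf_sigma_z = 1,
                           snr = 10, min_separation = 6,
                           margin = 5L, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed, gen_fish_stack(dims, n_spots, cyto_fraction,
                           nucleus_semiaxes, amplitude, baseline,
                           psf_sigma, psf_sigma_z, snr,
                           min_separation, margin)))
  }
  nz <- dims[1L]; ny <- dims[2L]; nx <- dims[3L]
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  mask <- ((yy - cy) / nucleus_semiaxes[1L])^2 +
          ((xx - cx) / nucleus_semiaxes[2L])^2 <= 1

  n_nuc <- round(n_spots * (1 - cyto_fraction))
  n_cyto <- n_spots - n_nuc
  want <- c(rep("nuclear", n_nuc), rep("cytoplasmic", n_cyto))

  pts <- matrix(numeric(0), 0L, 3L)
  comp <- character(0)
  attempts <- 0L
  while (nrow(pts) < n_spots) {
    attempts <- attempts + 1L
    if (attempts > 10000L * max(n_spots, 1L)) {
      stop("could not place ", n_spots,
           " spots with the requested separation")
    }
    y <- runif(1L, margin, ny - margin)
    x <- runif(1L, margin, nx - margin)
    z <- runif(1L, 1.5, nz - 0.5)
    inside <- mask[round(y), round(x)]
    need <- want[nrow(pts) + 1L]
    if ((need == "nuclear") != inside) next
    if (nrow(pts) &&
        any((pts[, 2L] - y)^2 + (pts[, 3L] - x)^2 +
            (pts[, 1L] - z)^2 < min_separation^2)) next
    pts <- rbind(pts, c(z, y, x))
    comp <- c(comp, need)
  }

  clean <- array(baseline, dim = dims)
  if (n_spots > 0L) {
    zg <- seq_len(nz)
    for (s in seq_len(nrow(pts))) {
      z0 <- pts[s, 1L]; y0 <- pts[s, 2L]; x0 <- pts[s, 3L]
      yr <- max(1L, floor(y0 - 4 * psf_sigma)):
            min(ny, ceiling(y0 + 4 * psf_sigma))
      xr <- max(1L, floor(x0 - 4 * psf_sigma)):
            min(nx, ceiling(x0 + 4 * psf_sigma))
      gy <- exp(-(yr - y0)^2 / (2 * psf_sigma^2))
      gx <- exp(-(xr - x0)^2 / (2 * psf_sigma^2))
      gz <- exp(-(zg - z0)^2 / (2 * psf_sigma_z^2))
      blob <- amplitude * outer(gz, outer(gy, gx))
      clean[, yr, xr] <- clean[, yr, xr] + blob
    }
  }
  read_sd <- amplitude / snr
  signal <- array(rpois(length(clean), lambda = clean) +
                  rnorm(length(clean), sd = read_sd), dim = dims)
  signal[signal < 0] <- 0

  dapi_clean <- array(baseline, dim = dims)
  for (z in seq_len(nz)) dapi_clean[z, , ] <- baseline + 150 * mask
  dapi <- array(rpois(length(dapi_clean), lambda = dapi_clean) +
                rnorm(length(dapi_clean), sd = 5), dim = dims)
  dapi[dapi < 0] <- 0

  truth <- if (n_spots > 0L) {
    data.frame(z = pts[, 1L], y = pts[, 2L], x = pts[, 3L],
               compartment = comp, stringsAsFactors = FALSE)
  } else {
    data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
               compartment = character(0))
  }
  list(signal = signal, dapi = dapi, nuclear_mask = mask, truth = truth)
}
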