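#' Decoy binding-capacity arithmetic
#'
#' The number of RNA-binding-protein molecules a decoy transcript can
#' sequester at once: `transcript copies per cell x binding sites per
#' copy` (about 70 x 17 = ~1,200 for NORAD and Pumilio).  When protein
#' copy numbers are supplied, the site-to-protein ratio is reported.
#'
#' @param copies Transcript copies per cell (>= 0).
#' @param sites Functional binding sites per transcript copy (>= 0).
#' @param round_to Optional rounding granularity for the headline
#'   figure (e.g. 100); full precision is always retained.
#' @param protein_copies Optional named numeric vector of protein
#'   copies per cell (e.g. `c(PUM1 = 200, PUM2 = 550)`).
#' @return Object of class `capacity_model`: list with
#'   `transcript_copies_per_cell`, `sites_per_copy`, `site_capacity`,
#'   `site_capacity_rounded` (when `round_to` given), `protein_copies`,
#'   `site_to_protein_ratio` (when proteins given).
#' @examples
#' binding_capacity(70, 17, round_to = 100,
#'                  protein_copies = c(PUM1 = 200, PUM2 = 550))
#' @export
binding_capacity <- function(copies, sites, round_to = NULL,
                             protein_copies = NULL) {
  if (copies < 0 || sites < 0) stop("copies and sites must be >= 0")
  cap <- copies * sites
  out <- list(transcript_copies_per_cell = copies,
              sites_per_copy = as.integer(sites),
              site_capacity = cap,
              site_capacity_rounded =
                if (is.null(round_to)) NULL
                else round(cap / round_to) * round_to,
              protein_copies = protein_copies,
              site_to_protein_ratio =
                if (is.null(protein_copies)) NULL
                else cap / sum(protein_copies))
  structure(out, class = "capacity_model")
}

#' @export
print.capacity_model <- function(x, ...) {
  cat("<capacity_model> ", x$transcript_copies_per_cell, " copies x ",
      x$sites_per_copy, " sites = ", x$site_capacity,
      " simultaneous binding sites", sep = "")
  if (!is.null(x$site_capacity_rounded)) {
    cat(" (~", format(x$site_capacity_rounded, big.mark = ","), ")",
        sep = "")
  }
  cat("\n")
  if (!is.null(x$protein_copies)) {
    cat("  protein copies/cell: ",
        paste(names(x$protein_copies), x$protein_copies, sep = "=",
              collapse = ", "),
        "; site:protein ratio ",
        format(x$site_to_protein_ratio, digits = 3), "\n", sep = "")
  }
  invisible(x)
}

#' Fit a linear quantification standard curve
#'
#' Ordinary least squares fit of `signal = slope * amount + intercept`
#' over calibration points with known amounts (e.g. purified
#' recombinant protein on a quantitative western blot).
#'
#' @param known_amounts Numeric vector of >= 2 distinct amounts.
#' @param signals Matching signal measurements.
#' @return Object of class `standard_curve`: list with `slope`,
#'   `intercept`, `r_squared`, `known_amounts`, `signals`.
#' @export
fit_standard_curve <- function(known_amounts, signals) {
  stopifnot(length(known_amounts) == length(signals))
  if (length(known_amounts) < 2L ||
      length(unique(known_amounts)) < 2L) {
    stop("need at least 2 distinct known amounts")
  }
  fit <- lm(signals ~ known_amounts)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((signals - mean(signals))^2)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 known_amounts = known_amounts, signals = signals),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve> signal = ", format(x$slope, digits = 4),
      " * amount + ", format(x$intercept, digits = 4),
      " (r^2 = ", format(x$r_squared, digits = 4), ", n = ",
      length(x$signals), ")\n", sep = "")
  invisible(x)
}

#' Protein copies per cell from a standard curve
#'
#' Inverts the calibration line at the lysate signal, converts the
#' amount to molecules via `amount_to_molecules`, and divides by the
#' number of cells in the lysate.  Signals below the intercept invert
#' to negative amounts and are reported as 0 with a warning.
#'
#' @param curve A `standard_curve` from [fit_standard_curve()].
#' @param lysate_signal Measured signal of the cell lysate.
#' @param amount_to_molecules Conversion factor from curve amount units
#'   to molecules (default 1).
#' @param n_cells Number of cells in the lysate (> 0).
#' @return Copies per cell (numeric scalar).
#' @export
copies_per_cell <- function(curve, lysate_signal,
                            amount_to_molecules = 1, n_cells = 1) {
  stopifnot(inherits(curve, "standard_curve"), n_cells > 0)
  if (curve$slope == 0) stop("standard curve has zero slope")
  amount <- (lysate_signal - curve$intercept) / curve$slope
  if (amount < 0) {
    warning("lysate signal below the curve intercept; reporting 0")
    amount <- 0
  }
  amount * amount_to_molecules / n_cells
}
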