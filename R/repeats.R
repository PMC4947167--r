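#' Self-comparison dotplot by exact k-word matching
#'
#' Records every pair of distinct positions `(i, j)`, `i < j`, at which
#' the same `k`-mer occurs (words containing `N` are skipped), together
#' with the per-offset match density
#' `density(d) = matches at offset d / (L - d - k + 1)`.  Off-diagonal
#' density bands reveal tandem repeat structure; a word match is the
#' deterministic, alignment-free analogue of the high-scoring local
#' alignments seen in a classical self-dotplot.
#'
#' @param seq Character scalar (RNA or DNA), length >= `k`.
#' @param k Word size (default 8).
#' @return Object of class `dot_matrix`: list with `length`, `k`,
#'   `matches` (data.frame `i`, `j`, 1-based start positions) and
#'   `density` (data.frame `offset`, `n_matches`, `density`).
#' @export
self_dotplot <- function(seq, k = 8L) {
  seq <- as.character(ingest_seq(seq[[1L]]))
  L <- nchar(seq)
  if (L < k) stop("sequence length ", L, " is below word size ", k)
  n_pos <- L - k + 1L
  words <- substring(seq, seq_len(n_pos), seq_len(n_pos) + k - 1L)
  keep <- !grepl("N", words, fixed = TRUE)
  pos_by_word <- split(seq_len(n_pos)[keep], words[keep])
  pos_by_word <- pos_by_word[lengths(pos_by_word) > 1L]

  ii <- integer(0); jj <- integer(0)
  for (p in pos_by_word) {
    cmb <- utils::combn(p, 2L)
    ii <- c(ii, cmb[1L, ]); jj <- c(jj, cmb[2L, ])
  }
  d <- jj - ii
  dens <- if (length(d)) {
    tab <- table(d)
    off <- as.integer(names(tab))
    data.frame(offset = off, n_matches = as.integer(tab),
               density = as.integer(tab) / (L - off - k + 1L))
  } else {
    data.frame(offset = integer(0), n_matches = integer(0),
               density = numeric(0))
  }
  structure(list(length = L, k = as.integer(k),
                 matches = data.frame(i = ii, j = jj),
                 density = dens),
            class = "dot_matrix")
}

#' @export
print.dot_matrix <- function(x, ...) {
  cat("<dot_matrix> L=", x$length, ", k=", x$k, ", ",
      nrow(x$matches), " off-diagonal word matches\n", sep = "")
  invisible(x)
}

#' Estimate tandem-repeat period and segment the repeat region
#'
#' The period is the smallest offset whose match density is a local
#' maximum (within +/-2 offsets) above `min_density` and at least
#' `min_period`.  The repeat-region span is the union of the positions
#' participating in matches at near-multiples of the period, and unit
#' boundaries are cut at period intervals from the span start.
#'
#' @param dm A `dot_matrix` from [self_dotplot()].
#' @param min_density Minimum offset density to call a period
#'   (default 0.2; diverged repeats need a lower value, e.g. 0.1 at
#'   10% per-copy divergence).
#' @param min_period Smallest admissible period in nt (default 30).
#' @param multiple_tol Tolerance, in nt, for an offset to count as a
#'   multiple of the period (default `max(2, 0.02 * period)`).
#' @return Object of class `repeat_units`: list with `period`,
#'   `span` (0-based half-open `c(start, end)`), `boundaries`
#'   (data.frame `start`, `end`, 0-based half-open), `n_units`.
#'   When no offset passes `min_density`, an empty set
#'   (`period = NA`, `n_units = 0`) is returned.
#' @export
estimate_period_and_segment <- function(dm, min_density = 0.2,
                                        min_period = 30L,
                                        multiple_tol = NULL) {
  stopifnot(inherits(dm, "dot_matrix"))
  dens <- dm$density
  empty <- structure(list(period = NA_integer_,
                          span = c(NA_integer_, NA_integer_),
                          boundaries = data.frame(start = integer(0),
                                                  end = integer(0)),
                          n_units = 0L),
                     class = "repeat_units")
  cand <- dens[dens$density > min_density & dens$offset >= min_period, ]
  if (!nrow(cand)) return(empty)
  is_local_max <- vapply(seq_len(nrow(cand)), function(r) {
    d <- cand$offset[r]
    nb <- dens$density[abs(dens$offset - d) <= 2L]
    cand$density[r] >= max(nb)
  }, logical(1L))
  if (!any(is_local_max)) return(empty)
  period <- min(cand$offset[is_local_max])
  if (is.null(multiple_tol)) multiple_tol <- max(2, 0.02 * period)

  m <- dm$matches
  d <- m$j - m$i
  near_mult <- abs(d - round(d / period) * period) <= multiple_tol &
    round(d / period) >= 1
  if (!any(near_mult)) return(empty)
  span_start <- min(m$i[near_mult]) - 1L                    # 0-based
  span_end <- max(m$j[near_mult]) + dm$k - 1L               # half-open
  n_units <- floor((span_end - span_start) / period)
  if (n_units < 1L) return(empty)
  starts <- span_start + period * (seq_len(n_units) - 1L)
  structure(list(period = as.integer(period),
                 span = c(span_start, span_end),
                 boundaries = data.frame(start = starts,
                                         end = starts + period),
                 n_units = as.integer(n_units)),
            class = "repeat_units")
}

#' @export
print.repeat_units <- function(x, ...) {
  if (x$n_units == 0L) {
    cat("<repeat_units> no repeat structure detected\n")
  } else {
    cat("<repeat_units> period ", x$period, " nt, ", x$n_units,
        " units spanning [", x$span[1L], ", ", x$span[2L], ")\n",
        sep = "")
  }
  invisible(x)
}

#' Find simple hairpins (contiguous inverted repeats)
#'
#' Reports loci where a stem of `s` contiguous Watson-Crick pairs
#' (G-U wobble optional) encloses a loop of admissible length.  For
#' each loop locus only the maximal stem is reported (capped at
#' `stem_max`), so nested sub-stems of the same hairpin do not
#' duplicate.  Coordinates are 0-based half-open over the whole
#' hairpin (left arm through right arm).
#'
#' @param seq Character scalar (RNA or DNA).
#' @param stem_min,stem_max Admissible stem lengths in base pairs
#'   (`stem_min >= 2`).
#' @param loop_min,loop_max Admissible loop lengths in nt (defaults
#'   3 and 30).
#' @param allow_gu Count G-U (G-T in DNA alphabet) as paired
#'   (default `FALSE`).
#' @return `data.frame` with columns `start`, `end`, `stem`, `loop_start`,
#'   `loop_len`, `loop_seq`.
#' @examples
#' find_hairpins("GGGGAAAACCCC", stem_min = 4, stem_max = 4)
#' @export
find_hairpins <- function(seq, stem_min, stem_max,
                          loop_min = 3L, loop_max = 30L,
                          allow_gu = FALSE) {
  stopifnot(stem_min >= 2L, stem_max >= stem_min, loop_min >= 1L)
  seq <- as.character(ingest_seq(seq[[1L]]))
  chars <- strsplit(seq, "")[[1L]]
  L <- length(chars)
  pairs_ok <- function(a, b) {
    wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
          (a == "G" & b == "C") | (a == "C" & b == "G")
    if (allow_gu) {
      wc <- wc | (a == "G" & b == "T") | (a == "T" & b == "G")
    }
    wc
  }
  out <- list()
  for (loop_start in seq_len(L)) {          # 1-based first loop base
    for (loop_len in loop_min:loop_max) {
      loop_end <- loop_start + loop_len - 1L
      if (loop_end > L) break
      # grow stem outward from the loop
      s <- 0L
      while (TRUE) {
        left <- loop_start - s - 1L
        right <- loop_end + s + 1L
        if (left < 1L || right > L) break
        if (!pairs_ok(chars[left], chars[right])) break
        s <- s + 1L
      }
      if (s >= stem_min) {
        stem <- min(s, stem_max)
        # trim the reported hairpin to the capped stem closest to the loop
        start <- loop_start - stem - 1L
        end <- loop_end + stem
        out[[length(out) + 1L]] <- data.frame(
          start = start, end = end, stem = stem,
          loop_start = loop_start - 1L, loop_len = loop_len,
          loop_seq = paste(chars[loop_start:loop_end], collapse = ""))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      stem = integer(0), loop_start = integer(0),
                      loop_len = integer(0), loop_seq = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Find U-rich runs
#'
#' Maximal runs of `U` (`T` in the DNA alphabet) whose length falls in
#' `[min_run, max_run]`; longer runs are outside the reported class.
#'
#' @param seq Character scalar (RNA or DNA).
#' @param min_run,max_run Inclusive run-length bounds (defaults 2, 5).
#' @return `data.frame` with columns `start` (0-based), `end`
#'   (half-open), `length`.
#' @export
find_u_rich <- function(seq, min_run = 2L, max_run = 5L) {
  seq <- as.character(ingest_seq(seq[[1L]]))
  r <- rle(strsplit(seq, "")[[1L]] == "T")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run & r$lengths <= max_run
  data.frame(start = starts[keep] - 1L, end = ends[keep],
             length = r$lengths[keep])
}

#' Annotate a repeat unit with its core elements
#'
#' Composes the element finders over one repeat-unit sequence: PRE
#' motif hits, short hairpins (4-bp stem, variable loop), U-rich runs
#' (2-5 nt) and long hairpins (8-9-bp stem), and reports
#' presence/absence of each class.
#'
#' @param unit_seq Character scalar (one repeat unit).
#' @param pattern PRE consensus (default `UGURUAUA`).
#' @param allow_gu Passed to [find_hairpins()].
#' @return Object of class `unit_annotation`: list with `pre_hits`,
#'   `short_hairpins`, `u_rich`, `long_hairpins` (tables) and
#'   `present` (named logical over the four element classes).
#' @export
annotate_unit <- function(unit_seq, pattern = "UGURUAUA",
                          allow_gu = FALSE) {
  pre <- scan_motif(unit_seq, pattern, mode = "nonoverlapping")
  sh <- find_hairpins(unit_seq, stem_min = 4L, stem_max = 4L,
                      allow_gu = allow_gu)
  ur <- find_u_rich(unit_seq)
  lh <- find_hairpins(unit_seq, stem_min = 8L, stem_max = 9L,
                      allow_gu = allow_gu)
  structure(
    list(pre_hits = pre, short_hairpins = sh, u_rich = ur,
         long_hairpins = lh,
         present = c(pre = nrow(pre) > 0L,
                     short_hairpin = nrow(sh) > 0L,
                     u_rich = nrow(ur) > 0L,
                     long_hairpin = nrow(lh) > 0L)),
    class = "unit_annotation")
}

#' @export
print.unit_annotation <- function(x, ...) {
  cat("<unit_annotation> PREs: ", nrow(x$pre_hits),
      ", short hairpins: ", nrow(x$short_hairpins),
      ", U-runs: ", nrow(x$u_rich),
      ", long hairpins: ", nrow(x$long_hairpins), "\n", sep = "")
  invisible(x)
}
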