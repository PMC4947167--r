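IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Parse an IUPAC degenerate consensus into a motif pattern
#'
#' Each consensus position becomes the set of bases it allows
#' (R = A/G, Y = C/T, N = any, and so on); `U` is treated as `T`.
#' The Pumilio recognition element is written `UGURUAUA` for density
#' statistics and `UGUANAUA` for 3'-UTR target calling.
#'
#' @param consensus Non-empty IUPAC consensus string (RNA or DNA).
#' @param name Optional motif name; defaults to the consensus itself.
#' @return An object of class `motif_pattern`: list with `name`,
#'   `consensus`, `sets` (list of allowed-base character vectors) and
#'   `length`.
#' @examples
#' parse_iupac("UGURUAUA")
#' @export
parse_iupac <- function(consensus, name = consensus) {
  stopifnot(is.character(consensus), length(consensus) == 1L)
  if (!nzchar(consensus)) stop("consensus must be non-empty")
  chars <- strsplit(toupper(consensus), "")[[1L]]
  bad <- !chars %in% names(IUPAC_SETS)
  if (any(bad)) {
    stop("non-IUPAC character '", chars[which(bad)[1L]],
         "' at position ", which(bad)[1L])
  }
  structure(
    list(name = name, consensus = consensus,
         sets = unname(IUPAC_SETS[chars]), length = length(chars)),
    class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern> ", x$name, " (", x$consensus, "), ",
      x$length, " positions\n", sep = "")
  invisible(x)
}

as_motif <- function(pattern) {
  if (inherits(pattern, "motif_pattern")) pattern else parse_iupac(pattern)
}

#' Scan a sequence for a degenerate motif
#'
#' Matches the per-position allowed-base sets of `pattern` against a
#' sequence.  `N` in the subject matches nothing (masked sequence never
#' inflates counts).  Only the given strand is scanned unless
#' `revcomp = TRUE`, in which case hits on the reverse complement are
#' also reported (with `strand = "-"`, coordinates on the input).
#'
#' @param seq Character scalar; RNA or DNA (normalised internally).
#' @param pattern A `motif_pattern` from [parse_iupac()], or a consensus
#'   string.
#' @param mode `"overlapping"` returns every matching offset;
#'   `"nonoverlapping"` returns the greedy left-to-right maximal set
#'   (after a hit at `i` the scan resumes at `i + length`).
#' @param seq_id Identifier recorded in the output (default `"seq"`,
#'   or the name of `seq` if present).
#' @param revcomp Also scan the reverse complement (default `FALSE`).
#' @return `data.frame` with columns `seq_id`, `start` (0-based),
#'   `end` (half-open), `match`, `strand`.
#' @examples
#' scan_motif("TGTATATATATA", "TGTATATA", mode = "overlapping")
#' @export
scan_motif <- function(seq, pattern,
                       mode = c("nonoverlapping", "overlapping"),
                       seq_id = NULL, revcomp = FALSE) {
  mode <- match.arg(mode)
  pattern <- as_motif(pattern)
  if (is.null(seq_id)) seq_id <- if (!is.null(names(seq))) names(seq)[1L] else "seq"
  seq <- as.character(ingest_seq(seq[[1L]]))

  hits <- scan_starts(seq, pattern, mode)
  out <- data.frame(
    seq_id = rep(seq_id, length(hits)),
    start = hits - 1L, end = hits - 1L + pattern$length,
    match = substr_many(seq, hits, hits + pattern$length - 1L),
    strand = rep("+", length(hits)),
    stringsAsFactors = FALSE)

  if (isTRUE(revcomp)) {
    rc <- rev_comp(seq)
    h2 <- scan_starts(rc, pattern, mode)
    L <- nchar(seq)
    out2 <- data.frame(
      seq_id = rep(seq_id, length(h2)),
      start = L - (h2 - 1L + pattern$length), end = L - (h2 - 1L),
      match = substr_many(rc, h2, h2 + pattern$length - 1L),
      strand = rep("-", length(h2)),
      stringsAsFactors = FALSE)
    out <- rbind(out, out2)
    out <- out[order(out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# all match start positions (1-based); greedy restart for nonoverlapping
scan_starts <- function(seq, pattern, mode) {
  L <- nchar(seq)
  m <- pattern$length
  if (L < m) return(integer(0))
  chars <- strsplit(seq, "")[[1L]]
  n_win <- L - m + 1L
  ok <- rep(TRUE, n_win)
  for (j in seq_len(m)) {
    ok <- ok & chars[j:(n_win + j - 1L)] %in% pattern$sets[[j]]
  }
  starts <- which(ok)
  if (mode == "overlapping" || length(starts) < 2L) return(starts)
  keep <- integer(0)
  next_free <- 1L
  for (s in starts) {
    if (s >= next_free) {
      keep <- c(keep, s)
      next_free <- s + m
    }
  }
  keep
}

# substring() that tolerates zero hits
substr_many <- function(seq, first, last) {
  if (!length(first)) return(character(0))
  substring(seq, first, last)
}

rev_comp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1L]]), collapse = "")
}

#' Count greedy non-overlapping motif instances
#'
#' Convenience wrapper over [scan_motif()] in non-overlapping mode;
#' the quantity the decoy density statistic is built on (NORAD carries
#' 17 such UGURUAUA instances).
#'
#' @inheritParams scan_motif
#' @return Non-negative integer count.
#' @export
count_nonoverlapping <- function(seq, pattern) {
  nrow(scan_motif(seq, pattern, mode = "nonoverlapping"))
}

#' Write motif hits as BED6
#'
#' @param hits Hit table from [scan_motif()].
#' @param path Output path.
#' @param name Feature name column (default the matched substring).
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path, name = hits$match) {
  bed <- data.frame(chrom = hits$seq_id, start = hits$start,
                    end = hits$end, name = name, score = 0L,
                    strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
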