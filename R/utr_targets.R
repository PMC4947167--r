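#' Expected motif sites in one 3'-UTR
#'
#' The number of sites "expected given the 3'-UTR length", either as
#' the mean non-overlapping count over dinucleotide-preserving shuffles
#' of that UTR (`method = "shuffle"`, consistent with the transcript
#' density statistic) or by the closed form of [expected_analytic()]
#' with supplied mononucleotide frequencies (`method = "analytic"`).
#'
#' @param utr_seq Character scalar; may be empty (expected 0).
#' @param pattern Motif (default `UGUANAUA`, the relaxed Pumilio site
#'   used for target calling).
#' @param method `"shuffle"` or `"analytic"`.
#' @param n_shuffles Shuffles per UTR for the shuffle method
#'   (default 200).
#' @param freqs Mononucleotide frequencies for the analytic method
#'   (estimate them from the whole UTR set with [mono_freqs()]).
#' @param seed Optional integer seed applied locally.
#' @return Non-negative expectation.
#' @export
expected_sites <- function(utr_seq, pattern = "UGUANAUA",
                           method = c("shuffle", "analytic"),
                           n_shuffles = 200L,
                           freqs = c(A = .25, C = .25, G = .25, T = .25),
                           seed = NULL) {
  method <- match.arg(method)
  pattern <- as_motif(pattern)
  utr_seq <- as.character(ingest_seq(utr_seq[[1L]]))
  L <- nchar(utr_seq)
  if (L == 0L) return(0)
  if (method == "analytic") return(expected_analytic(L, pattern, freqs))
  if (L < 2L) return(0)
  run <- function() {
    mean(vapply(seq_len(n_shuffles), function(i) {
      count_nonoverlapping(dinucleotide_shuffle(utr_seq), pattern)
    }, integer(1L)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Classify genes as Pumilio targets, controls or intermediates
#'
#' A gene is a *target* when its 3'-UTR carries at least two motif
#' sites in excess of the number expected given the UTR's length
#' (`excess = observed - expected >= 2`), a *control* when it carries
#' no more sites than expected (`observed <= expected`), and
#' *intermediate* otherwise; intermediates are excluded from both
#' analysis groups downstream.  Genes with empty UTRs are dropped and
#' reported in the `excluded` attribute.
#'
#' @param utrs Named character vector of 3'-UTR sequences (names are
#'   unique gene ids).
#' @param pattern Motif (default `UGUANAUA`).
#' @param method Expectation method, see [expected_sites()].
#' @param n_shuffles Shuffles per UTR for the shuffle method.
#' @param seed Optional integer seed applied locally.
#' @return `data.frame` of class `target_calls` with columns `gene_id`,
#'   `utr_length`, `observed`, `expected`, `excess`, `klass`; attribute
#'   `excluded` lists genes dropped for empty UTRs, attribute `method`
#'   records the expectation mode.
#' @export
classify_genes <- function(utrs, pattern = "UGUANAUA",
                           method = c("shuffle", "analytic"),
                           n_shuffles = 200L, seed = NULL) {
  method <- match.arg(method)
  pattern <- as_motif(pattern)
  ids <- names(utrs)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("utrs must be named with unique gene ids; duplicate: ",
         ids[anyDuplicated(ids)])
  }
  seqs <- ingest_seq(unname(utrs))
  empty <- nchar(seqs) == 0L
  excluded <- ids[empty]
  ids <- ids[!empty]
  seqs <- seqs[!empty]
  freqs <- if (method == "analytic") mono_freqs(seqs) else NULL

  run <- function() {
    observed <- vapply(seqs, count_nonoverlapping, integer(1L),
                       pattern = pattern, USE.NAMES = FALSE)
    expected <- vapply(seqs, function(s) {
      if (method == "analytic") {
        expected_analytic(nchar(s), pattern, freqs)
      } else {
        expected_sites(s, pattern, method = "shuffle",
                       n_shuffles = n_shuffles)
      }
    }, numeric(1L), USE.NAMES = FALSE)
    list(observed = observed, expected = expected)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  excess <- res$observed - res$expected
  klass <- ifelse(excess >= 2, "target",
                  ifelse(res$observed <= res$expected,
                         "control", "intermediate"))
  out <- data.frame(gene_id = ids, utr_length = nchar(seqs),
                    observed = res$observed, expected = res$expected,
                    excess = excess, klass = klass,
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  attr(out, "method") <- method
  class(out) <- c("target_calls", class(out))
  out
}

#' Define targets from binding-site cluster intervals
#'
#' Alternative target definition: genes whose 3'-UTR interval overlaps
#' at least one experimentally derived binding cluster (for example
#' PAR-CLIP clusters), given as BED-like data frames.
#'
#' @param utr_bed `data.frame` with columns `chrom`, `start`, `end`,
#'   `gene_id` (0-based half-open).
#' @param clusters_bed `data.frame` with columns `chrom`, `start`,
#'   `end`.
#' @return Character vector of gene ids with at least one overlapping
#'   cluster.
#' @export
targets_from_clusters <- function(utr_bed, clusters_bed) {
  stopifnot(all(c("chrom", "start", "end", "gene_id") %in% names(utr_bed)),
            all(c("chrom", "start", "end") %in% names(clusters_bed)))
  hit <- vapply(seq_len(nrow(utr_bed)), function(i) {
    same <- clusters_bed$chrom == utr_bed$chrom[i]
    any(same & clusters_bed$start < utr_bed$end[i] &
               clusters_bed$end > utr_bed$start[i])
  }, logical(1L))
  unique(utr_bed$gene_id[hit])
}

#' Sample length-matched control genes
#'
#' Divides all classified genes into `n_bins` bins by 3'-UTR length
#' (decile edges over targets and controls together) and samples, from
#' each bin, as many control genes as it holds targets, without
#' replacement.  This is the standard guard against the longer UTRs of
#' motif-rich genes confounding expression comparisons.
#'
#' @param calls A `target_calls` table from [classify_genes()].
#' @param n_bins Number of length bins (default 10).
#' @param seed Optional integer seed applied locally.
#' @return Object of class `control_sample`: list with `bin_edges`,
#'   `per_bin` (data.frame of bin, n_targets, n_controls_available,
#'   n_sampled), `sampled` (control gene ids), `seed`.
#' @export
sample_length_matched_controls <- function(calls, n_bins = 10L,
                                           seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed, {
        out <- sample_length_matched_controls(calls, n_bins)
        out$seed <- seed
        out
      }))
  }
  stopifnot(inherits(calls, "target_calls") || is.data.frame(calls))
  lens <- calls$utr_length
  edges <- quantile(lens, probs = seq(0, 1, length.out = n_bins + 1L),
                    names = FALSE, type = 7)
  edges[1L] <- -Inf
  edges[n_bins + 1L] <- Inf
  bin <- cut(lens, breaks = edges, labels = FALSE, include.lowest = TRUE)

  sampled <- character(0)
  per_bin <- data.frame(bin = seq_len(n_bins), n_targets = 0L,
                        n_controls_available = 0L, n_sampled = 0L)
  for (b in seq_len(n_bins)) {
    in_bin <- bin == b
    tg <- calls$gene_id[in_bin & calls$klass == "target"]
    ct <- calls$gene_id[in_bin & calls$klass == "control"]
    per_bin$n_targets[b] <- length(tg)
    per_bin$n_controls_available[b] <- length(ct)
    if (length(tg) > length(ct)) {
      stop("bin ", b, " has ", length(tg), " targets but only ",
           length(ct), " controls available")
    }
    take <- if (length(tg)) sample_vec(ct)[seq_along(tg)] else character(0)
    per_bin$n_sampled[b] <- length(take)
    sampled <- c(sampled, take)
  }
  structure(list(bin_edges = edges, per_bin = per_bin,
                 sampled = sampled, seed = NULL),
            class = "control_sample")
}

#' @export
print.control_sample <- function(x, ...) {
  cat("<control_sample> ", length(x$sampled),
      " length-matched controls over ", nrow(x$per_bin), " bins\n",
      sep = "")
  invisible(x)
}
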