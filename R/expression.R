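#' Reads-per-million normalization
#'
#' @param counts Gene x sample matrix of non-negative counts (rownames
#'   are gene ids).
#' @return Matrix of the same shape with each column scaled to sum to
#'   1e6.
#' @export
normalize_rpm <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  }
  sweep(counts, 2L, tot, "/") * 1e6
}

#' Expression filter on mean RPM
#'
#' Keeps genes whose average RPM across the supplied samples is at
#' least `min_avg` (boundary inclusive); the default of 50 restricts
#' fold-change analysis to robustly expressed genes.
#'
#' @param rpm RPM matrix (genes x samples).
#' @param min_avg Minimum mean RPM (default 50).
#' @return Character vector of retained gene ids (rownames).
#' @export
filter_expressed <- function(rpm, min_avg = 50) {
  rownames(rpm)[rowMeans(rpm) >= min_avg]
}

#' Pseudocounted log2 fold changes between conditions
#'
#' RPM values are averaged over replicate columns per condition, a
#' pseudocount is added to each condition, and the log2 ratio taken:
#' `log2((rpm_treat + pc) / (rpm_ctrl + pc))`.
#'
#' @param rpm_treat,rpm_ctrl RPM vectors or matrices (replicate
#'   columns) with identical gene ids (names/rownames).
#' @param pseudocount Added to each condition mean (default 0.1).
#' @return `data.frame` with `gene_id`, `rpm_treat`, `rpm_ctrl`,
#'   `log2fc`; attribute `pseudocount`.
#' @export
fold_change <- function(rpm_treat, rpm_ctrl, pseudocount = 0.1) {
  mt <- condition_mean(rpm_treat)
  mc <- condition_mean(rpm_ctrl)
  if (is.null(names(mt)) || is.null(names(mc))) {
    stop("gene ids (names or rownames) are required")
  }
  if (!identical(names(mt), names(mc))) {
    shared <- intersect(names(mt), names(mc))
    if (!length(shared)) stop("no shared genes between conditions")
    mt <- mt[shared]; mc <- mc[shared]
  }
  if (any(mt < 0) || any(mc < 0)) stop("RPM values must be non-negative")
  out <- data.frame(gene_id = names(mt), rpm_treat = unname(mt),
                    rpm_ctrl = unname(mc),
                    log2fc = log2((unname(mt) + pseudocount) /
                                  (unname(mc) + pseudocount)),
                    stringsAsFactors = FALSE)
  attr(out, "pseudocount") <- pseudocount
  out
}

condition_mean <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) {
    setNames(rowMeans(as.matrix(x)), rownames(x))
  } else {
    x
  }
}

#' Intron-mapping counts by exon subtraction
#'
#' Subtracts exon-mapping from whole-locus counts per gene and sample,
#' flooring at zero (multi-mapping artifacts can invert the
#' subtraction); the number of clipped cells is reported as a warning
#' and recorded in the `clipped` attribute.
#'
#' @param whole_locus,exon Count matrices over identical gene/sample
#'   universes.
#' @return Intronic count matrix with attribute `clipped`.
#' @export
intronic_counts <- function(whole_locus, exon) {
  whole_locus <- as.matrix(whole_locus); exon <- as.matrix(exon)
  if (!identical(dim(whole_locus), dim(exon)) ||
      !identical(rownames(whole_locus), rownames(exon)) ||
      !identical(colnames(whole_locus), colnames(exon))) {
    stop("whole_locus and exon matrices must share genes and samples")
  }
  out <- whole_locus - exon
  clipped <- sum(out < 0)
  if (clipped > 0) {
    warning(clipped, " cell(s) had exon > whole-locus counts; clipped to 0")
    out[out < 0] <- 0
  }
  attr(out, "clipped") <- clipped
  out
}

#' Rank-sum comparison of target and control fold changes
#'
#' Two-sided Wilcoxon rank-sum test on log2 fold changes of targets
#' versus controls.  For total group size <= 10 the p-value is computed
#' by exhaustive enumeration of all relabelings of the pooled values
#' (exact even under ties); above that, the normal approximation with
#' tie correction is used via [stats::wilcox.test()].
#'
#' @param fc Fold-change table from [fold_change()], or a named numeric
#'   vector of log2 fold changes.
#' @param targets,controls Character vectors of gene ids (non-empty
#'   after intersection with `fc`).
#' @return Object of class `group_comparison`: list with `n_targets`,
#'   `n_controls`, `median_targets`, `median_controls`,
#'   `median_difference`, `statistic` (rank-sum W of the target group),
#'   `p_value`, `direction` (`"down"`/`"up"`/`"none"`), `method`.
#' @export
compare_groups <- function(fc, targets, controls) {
  vals <- fc_values(fc)
  x <- vals[intersect(targets, names(vals))]
  y <- vals[intersect(controls, names(vals))]
  if (!length(x) || !length(y)) {
    stop("both groups must be non-empty after matching gene ids")
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(unname(x), unname(y))
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U

  if (n <= 10L) {
    mu <- n1 * (n + 1) / 2
    obs <- abs(sum(r[seq_len(n1)]) - mu)
    combs <- utils::combn(n, n1)
    stats <- colSums(matrix(r[combs], nrow = n1)) - mu
    p <- mean(abs(stats) >= obs - 1e-12)
    method <- "exact enumeration"
  } else {
    p <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    method <- "normal approximation with tie correction"
  }
  md <- median(x) - median(y)
  structure(
    list(n_targets = n1, n_controls = n2,
         median_targets = median(x), median_controls = median(y),
         median_difference = md, statistic = w, p_value = p,
         direction = if (md < 0) "down" else if (md > 0) "up" else "none",
         method = method),
    class = "group_comparison")
}

fc_values <- function(fc) {
  if (is.data.frame(fc)) {
    setNames(fc$log2fc, fc$gene_id)
  } else if (is.numeric(fc) && !is.null(names(fc))) {
    fc
  } else {
    stop("fc must be a fold_change() table or a named numeric vector")
  }
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> targets n=", x$n_targets,
      " (median ", format(x$median_targets, digits = 3),
      ") vs controls n=", x$n_controls,
      " (median ", format(x$median_controls, digits = 3), ")\n",
      "  rank-sum p = ", format(x$p_value, digits = 4),
      " (", x$method, "), direction: ", x$direction, "\n", sep = "")
  invisible(x)
}

#' Spearman correlation between two perturbations
#'
#' Rank correlation of log2 fold changes across the genes shared by two
#' contrasts; knockdown and overexpression of the same regulator are
#' expected to anti-correlate when the responses are genuine.
#'
#' @param fc_a,fc_b Fold-change tables or named log2fc vectors.
#' @return List with `rho`, `p_value`, `n_genes`.
#' @export
correlate_perturbations <- function(fc_a, fc_b) {
  a <- fc_values(fc_a); b <- fc_values(fc_b)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3L) stop("need at least 3 shared genes")
  ct <- suppressWarnings(
    cor.test(a[shared], b[shared], method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_genes = length(shared))
}

#' Translation efficiency and its change between conditions
#'
#' `TE = (footprint_rpm + pc) / (mrna_rpm + pc)` per gene;
#' `delta_te()` gives `log2(TE_treat / TE_ctrl)`.  A regulator acting
#' purely on mRNA stability shifts footprints together with mRNA and
#' leaves delta-TE near zero.
#'
#' @param footprint_rpm,mrna_rpm Named non-negative RPM vectors over
#'   the same genes.
#' @param pseudocount Added to both layers (default 0.1).
#' @return Named numeric vector of TE values.
#' @export
translation_efficiency <- function(footprint_rpm, mrna_rpm,
                                   pseudocount = 0.1) {
  if (any(footprint_rpm < 0) || any(mrna_rpm < 0)) {
    stop("RPM values must be non-negative")
  }
  shared <- intersect(names(footprint_rpm), names(mrna_rpm))
  if (!length(shared)) stop("no shared genes")
  (footprint_rpm[shared] + pseudocount) / (mrna_rpm[shared] + pseudocount)
}

#' @rdname translation_efficiency
#' @param te_treat,te_ctrl TE vectors from [translation_efficiency()].
#' @export
delta_te <- function(te_treat, te_ctrl) {
  shared <- intersect(names(te_treat), names(te_ctrl))
  log2(te_treat[shared] / te_ctrl[shared])
}

#' Genes consistently regulated across contrasts
#'
#' A gene is consistently down (up) when its fold change is below
#' `1 - threshold` (above `1 + threshold`) in every supplied contrast;
#' the criterion behind "consistently downregulated by at least 20%"
#' with two independent siRNAs.
#'
#' @param fc_list List of fold-change tables or named log2fc vectors
#'   (one per contrast).
#' @param threshold Fractional change threshold (e.g. 0.2 for 20%).
#' @return List with character vectors `down` and `up`.
#' @export
consistent_regulation <- function(fc_list, threshold = 0.2) {
  stopifnot(length(fc_list) >= 1L, threshold > 0)
  vals <- lapply(fc_list, fc_values)
  shared <- Reduce(intersect, lapply(vals, names))
  down_thr <- log2(1 - threshold)
  up_thr <- log2(1 + threshold)
  down <- shared
  up <- shared
  for (v in vals) {
    down <- down[v[down] <= down_thr]
    up <- up[v[up] >= up_thr]
  }
  list(down = down, up = up)
}
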