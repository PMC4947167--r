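#' Normalise a nucleotide sequence for scanning
#'
#' Uppercases the sequence and maps RNA (`U`) to DNA (`T`) so that all
#' downstream scanning works on a single alphabet `{A,C,G,T,N}`.
#'
#' @param seq Character scalar (or vector) of nucleotide sequence(s).
#' @return Character vector of the same length, uppercase, `U` mapped to
#'   `T`, with attribute `was_rna` (logical vector) recording whether the
#'   input contained `U`.
#' @examples
#' ingest_seq("augc")
#' @export
ingest_seq <- function(seq) {
  stopifnot(is.character(seq))
  up <- toupper(seq)
  was_rna <- grepl("U", up, fixed = TRUE)
  out <- chartr("U", "T", up)
  bad <- gsub("[ACGTN]", "", out)
  if (any(nzchar(bad))) {
    i <- which(nzchar(bad))[1L]
    stop("sequence ", i, " contains non-nucleotide characters: '",
         substr(bad[i], 1L, 5L), "'")
  }
  attr(out, "was_rna") <- was_rna
  out
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()] that returns plain
#' named character strings normalised with [ingest_seq()] (uppercase,
#' `U` mapped to `T`).  The first whitespace-delimited token of each
#' header is used as the sequence id.
#'
#' @param path Path to a (possibly wrapped) multi-record FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  out <- ingest_seq(unname(seqs))
  names(out) <- names(seqs)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::BStringSet(setNames(as.character(seqs), names(seqs)))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' In-study oligonucleotide and reporter-element sequences
#'
#' The synthetic oligos used in the Pumilio pulldown experiments
#' (the ninth repeat unit of NORAD, wild type and with its first PRE
#' disrupted by a GTG-to-ACA substitution) and the 28-nt PRE reporter
#' element (wild type with one strong `TGTACATA` site, and the mutated
#' version with the site destroyed).  These printed sequences are the
#' fixed inputs for the in-package sequence statistics.
#'
#' @return `repeat9_oligos()`: named character vector with elements
#'   `wt` and `mut` (161 nt each).  `pre_reporter_elements()`: named
#'   character vector with elements `wt` and `mut` (28 nt each).
#' @examples
#' count_nonoverlapping(repeat9_oligos()[["wt"]], parse_iupac("UGURUAUA"))
#' @export
repeat9_oligos <- function() {
  c(wt = paste0(
      "GTCTGCATTTTCATTTACTGTGCTGTGTATATAGTGTATATAAGCGGACATAGGAGTCCT",
      "AATTTACGTCTAGTCGATGTTAAAAAGGTTGCCAGTATATGACAAAAGTAGAATTAGTAA",
      "ACTACTACATTGAGTACACTTTGTGTTAAAATTCATAGGGA"),
    mut = paste0(
      "GTCTGCATTTTCATTTACTGTGCTACATATATAGTGTATATAAGCGGACATAGGAGTCCT",
      "AATTTACGTCTAGTCGATGTTAAAAAGGTTGCCAGTATATGACAAAAGTAGAATTAGTAA",
      "ACTACTACATTGAGTACACTTTGTGTTAAAATTCATAGGGA"))
}

#' @rdname repeat9_oligos
#' @export
pre_reporter_elements <- function() {
  c(wt  = "TTGTTGTCGAAAATTGTACATAAGCCAA",
    mut = "TTGTTGTCGAAAATACAACATAAGCCAA")
}
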