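# Independent reference implementations used to cross-check the package.

rev_comp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# scan-with-restart count: walk the sequence, test every window naively,
# jump pattern-length after each accepted hit
oracle_greedy_count <- function(seq, consensus) {
  sets <- lapply(strsplit(chartr("U", "T", toupper(consensus)), "")[[1]],
                 function(ch) {
                   switch(ch,
                          A = "A", C = "C", G = "G", T = "T",
                          R = c("A", "G"), Y = c("C", "T"),
                          W = c("A", "T"), S = c("C", "G"),
                          K = c("G", "T"), M = c("A", "C"),
                          N = c("A", "C", "G", "T"),
                          stop("oracle: unsupported code ", ch))
                 })
  chars <- strsplit(toupper(seq), "")[[1]]
  m <- length(sets)
  count <- 0L
  i <- 1L
  while (i + m - 1L <= length(chars)) {
    hit <- TRUE
    for (j in seq_len(m)) {
      if (!chars[i + j - 1L] %in% sets[[j]]) { hit <- FALSE; break }
    }
    if (hit) { count <- count + 1L; i <- i + m } else i <- i + 1L
  }
  count
}

# all strings over `alphabet` with the same dinucleotide counts and
# endpoints as `seq` (exhaustive; for tiny sequences only)
oracle_shuffle_universe <- function(seq, alphabet = c("A", "C")) {
  n <- nchar(seq)
  ref <- sort(paste0(substring(seq, 1:(n - 1), 1:(n - 1)),
                     substring(seq, 2:n, 2:n)))
  inner <- expand.grid(rep(list(alphabet), n - 2L),
                       stringsAsFactors = FALSE)
  cand <- apply(inner, 1L, function(m) {
    paste0(substr(seq, 1, 1), paste(m, collapse = ""),
           substr(seq, n, n))
  })
  keep <- vapply(cand, function(s) {
    d <- sort(paste0(substring(s, 1:(n - 1), 1:(n - 1)),
                     substring(s, 2:n, 2:n)))
    identical(d, ref)
  }, logical(1))
  unique(cand[keep])
}

# queue-based 6->26-neighbour flood fill over a logical 3D mask
oracle_count_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nlab <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nlab <- nlab + 1L
    queue <- start
    lab[start] <- nlab
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      ci <- arrayInd(cur, d)
      for (k in seq_len(nrow(offs))) {
        nb <- ci + offs[k, ]
        if (any(nb < 1L) || any(nb > d)) next
        j <- nb[1L] + d[1L] * (nb[2L] - 1L + d[2L] * (nb[3L] - 1L))
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- nlab
          queue <- c(queue, j)
        }
      }
    }
  }
  nlab
}

# matrix-based inverted-repeat search: P[i,j] says positions i<j pair;
# a hairpin at loop (p, l) has stem = run of TRUE down the anti-diagonal
oracle_hairpins <- function(seq, stem_min, stem_max,
                            loop_min = 3, loop_max = 30) {
  chars <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  L <- length(chars)
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  P <- outer(chars, chars,
             function(a, b) unname(comp[a]) == b & !is.na(comp[a]))
  out <- NULL
  for (p in seq_len(L)) {
    for (l in loop_min:loop_max) {
      q <- p + l - 1L
      if (q > L) break
      s <- 0L
      while (p - s - 1L >= 1L && q + s + 1L <= L &&
             P[p - s - 1L, q + s + 1L]) {
        s <- s + 1L
      }
      if (s >= stem_min) {
        out <- rbind(out, c(loop_start = p - 1L, loop_len = l,
                            stem = min(s, stem_max)))
      }
    }
  }
  out
}

# direct (non-separable) negated-LoG response at one interior voxel
oracle_log_at <- function(stack, z, y, x, size = 15, sigma = 1.5,
                          sigma_z = sigma) {
  r <- (size - 1) / 2
  t <- seq(-r, r)
  g <- function(s) { k <- exp(-t^2 / (2 * s^2)); k / sum(k) }
  g2 <- function(s) { k <- g(s) * (t^2 - s^2) / s^4; k - mean(k) }
  kz <- outer(g2(sigma_z), outer(g(sigma), g(sigma)))
  ky <- outer(g(sigma_z), outer(g2(sigma), g(sigma)))
  kx <- outer(g(sigma_z), outer(g(sigma), g2(sigma)))
  kern <- kz + ky + kx
  acc <- 0
  for (a in seq_along(t)) for (b in seq_along(t)) for (c in seq_along(t)) {
    acc <- acc + kern[a, b, c] *
      stack[z + t[a], y + t[b], x + t[c]]
  }
  -acc
}
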