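# Independent brute-force oracles used to validate the dynamic programmes.
# These share no code with the implementation: the folding oracle is a
# plain recursive enumeration over all nested structures, the duplex
# oracle enumerates bulge placements exhaustively, and the scan oracle is
# a vectorised row-by-row edit-distance recurrence.

rna_bases <- c("A", "C", "G", "U")

random_rna <- function(n) {
  paste(sample(rna_bases, n, replace = TRUE), collapse = "")
}

oracle_pair_weight <- function(a, b) {
  if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(-3)
  if ((a == "A" && b == "U") || (a == "U" && b == "A")) return(-2)
  if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(-1)
  Inf
}

# minimum energy over all nested structures by explicit recursion
# (first position unpaired, or paired with every admissible k)
oracle_fold_energy <- function(seq, min_loop = 3) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  W <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) W[i, j] <- oracle_pair_weight(s[i], s[j])
    }
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      w <- W[i, k]
      if (is.finite(w)) {
        e <- w + rec(i + 1, k - 1) + if (k < j) rec(k + 1, j) else 0
        if (e < best) best <- e
      }
    }
    best
  }
  if (n < 2) 0 else rec(1, n)
}

# minimum duplex score over all antiparallel alignments with at most
# max_bulges bulged nucleotides, by enumerating every choice of bulged
# positions on each strand
oracle_duplex_score <- function(mirna, site, max_bulges = 2) {
  q <- strsplit(mirna, "")[[1]]
  s <- rev(strsplit(site, "")[[1]])
  m <- length(q)
  t_len <- length(s)
  pair_cost <- function(a, b) {
    wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
      (a == "G" & b == "C") | (a == "C" & b == "G")
    gu <- (a == "G" & b == "U") | (a == "U" & b == "G")
    ifelse(wc, 0, ifelse(gu, 0.5, 1))
  }
  best <- Inf
  for (bm in 0:max_bulges) {
    bt <- bm + (t_len - m)
    if (bt < 0 || bm + bt > max_bulges) next
    qsets <- if (bm == 0) list(integer(0)) else
      asplit(utils::combn(m, bm), 2)
    ssets <- if (bt == 0) list(integer(0)) else
      asplit(utils::combn(t_len, bt), 2)
    for (qs in qsets) {
      qq <- if (length(qs)) q[-qs] else q
      for (ss in ssets) {
        sk <- if (length(ss)) s[-ss] else s
        sc <- 1.5 * (bm + bt) + sum(pair_cost(qq, sk))
        if (sc < best) best <- sc
      }
    }
  }
  best
}

# best edit distance of the query against every database substring ending
# at each position (free start), via a vectorised DP with the running-min
# trick for the horizontal gap recurrence
oracle_scan_end_edits <- function(db, query) {
  d <- strsplit(db, "")[[1]]
  q <- strsplit(query, "")[[1]]
  n <- length(d)
  m <- length(q)
  prev <- rep(0L, n + 1)  # row 0: D[0][j] = 0
  for (i in seq_len(m)) {
    sub <- as.integer(q[i] != d | q[i] == "N" | d == "N")
    tmp <- pmin(prev[1:n] + sub, prev[2:(n + 1)] + 1L)
    v <- c(i, tmp)
    row <- cummin(v - 0:n) + 0:n
    prev <- row
  }
  prev[-1]
}

revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGUN", "UGCAN", x), "")[[1]]), collapse = "")
}
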