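# Independent oracles used across the suite. These deliberately re-derive
# results by enumeration / recursion, not by calling the package internals.

random_dna <- function(n, alphabet = c("A", "C", "G", "T"), prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

# Brute-force enumeration oracle for maximal, canonically placed, primitive
# tandem arrays. For every (start, period) it counts perfect copies by
# direct character comparison, then keeps triples that (a) meet the
# thresholds, (b) have a primitive leading unit, and (c) are canonical:
# start is the leftmost position of the maximal periodic stretch, i.e. the
# stretch cannot be extended by even one character to the left.
brute_tr_oracle <- function(seq, min_region_len, min_copies,
                            min_unit_len = 1L, max_unit_len = 100L,
                            min_distinct = 1L) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(x)
  is_primitive <- function(u) {
    m <- length(u)
    for (d in seq_len(m - 1L)) {
      if (m %% d == 0L && all(u == u[((seq_len(m) - 1L) %% d) + 1L])) {
        return(FALSE)
      }
    }
    TRUE
  }
  rows <- list()
  for (start in seq_len(n)) {
    m_max <- min(max_unit_len, (n - start + 1L) %/% min_copies)
    for (m in seq_len(m_max)) {
      if (m < min_unit_len) next
      # canonical: cannot extend the periodic stretch left by one char
      if (start > 1L && start + m - 1L <= n && x[start - 1L] == x[start + m - 1L]) next
      unit <- x[start:(start + m - 1L)]
      if (!is_primitive(unit)) next
      if (length(unique(unit)) < min_distinct) next
      # count full copies
      copies <- 1L
      while (start + (copies + 1L) * m - 1L <= n &&
             all(x[(start + copies * m):(start + (copies + 1L) * m - 1L)] ==
                   unit)) {
        copies <- copies + 1L
      }
      if (copies < min_copies || copies * m < min_region_len) next
      # right partial
      b <- 0L
      while (b < m - 1L && start + copies * m + b <= n &&
             x[start + copies * m + b] == unit[b + 1L]) {
        b <- b + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        start = start - 1L, end = start - 1L + copies * m,
        unit = paste(unit, collapse = ""), copies = copies,
        left_partial = 0L, right_partial = b, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      unit = character(0), copies = integer(0),
                      left_partial = integer(0), right_partial = integer(0)))
  }
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$start, nchar(out$unit)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

region_key <- function(d) {
  paste(d$start, d$end, d$unit, d$copies, d$left_partial, d$right_partial,
        sep = "|")
}

# Recursive memoized LCS, independent of the package's iterative DP.
lcs_oracle <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  memo <- new.env()
  rec <- function(i, j) {
    if (i == 0L || j == 0L) return(0L)
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    v <- if (x[i] == y[j]) rec(i - 1L, j - 1L) + 1L else
      max(rec(i - 1L, j), rec(i, j - 1L))
    memo[[key]] <- v
    v
  }
  rec(length(x), length(y))
}

# Adjusted Rand index (closed form over the pair-count contingency table).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- ch2(as.vector(tab))
  sum_a <- ch2(rowSums(tab))
  sum_b <- ch2(colSums(tab))
  n2 <- ch2(sum(tab))
  exp_ind <- sum_a * sum_b / n2
  (sum_ij - exp_ind) / ((sum_a + sum_b) / 2 - exp_ind)
}

# A small repeat-free background: resample until the oracle finds nothing
# at the given thresholds.
repeat_free_background <- function(n, min_region_len = 50L, min_copies = 3L) {
  repeat {
    s <- random_dna(n)
    if (nrow(brute_tr_oracle(s, min_region_len, min_copies)) == 0L) return(s)
  }
}
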