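#' Finder configuration
#'
#' Thresholds for nucleotide and amino-acid tandem repeat detection. The
#' defaults are the stringent settings used throughout the package: a
#' nucleotide TR must span a region of at least 50 nt with at least 3
#' perfectly repeated units; an amino-acid TR must span at least 16 aa with
#' at least 3 units of length >= 3 aa. `min_distinct_chars = 1` permits
#' homopolymer units.
#'
#' @param min_region_len_nt Minimum nucleotide region length (nt).
#' @param min_copies Minimum number of full repeat units.
#' @param min_unit_len_nt Minimum nucleotide unit length.
#' @param min_region_len_aa Minimum amino-acid region length (aa).
#' @param min_unit_len_aa Minimum amino-acid unit length.
#' @param min_distinct_chars Minimum number of distinct characters in a unit.
#' @param max_unit_len_nt Largest unit length searched at the nucleotide
#'   level. A scan cap, not a biological claim; repeat units in the target
#'   genomes are far below it.
#' @return A list of class `finder_config`.
#' @export
finder_config <- function(min_region_len_nt = 50L, min_copies = 3L,
                          min_unit_len_nt = 1L, min_region_len_aa = 16L,
                          min_unit_len_aa = 3L, min_distinct_chars = 1L,
                          max_unit_len_nt = 100L) {
  cfg <- list(min_region_len_nt = as.integer(min_region_len_nt),
              min_copies = as.integer(min_copies),
              min_unit_len_nt = as.integer(min_unit_len_nt),
              min_region_len_aa = as.integer(min_region_len_aa),
              min_unit_len_aa = as.integer(min_unit_len_aa),
              min_distinct_chars = as.integer(min_distinct_chars),
              max_unit_len_nt = as.integer(max_unit_len_nt))
  stopifnot(all(vapply(cfg, function(v) v >= 1L, logical(1))))
  class(cfg) <- "finder_config"
  cfg
}

#' Primitive root of a repeat unit
#'
#' The shortest string `p` such that `unit` equals `p` repeated
#' `nchar(unit)/nchar(p)` times. A unit equal to its own primitive root is
#' called primitive; only primitive units are reported by the finders.
#'
#' @param unit Non-empty string.
#' @return The primitive root of `unit`.
#' @export
primitive_root <- function(unit) {
  m <- nchar(unit)
  stopifnot(m >= 1L)
  for (d in seq_len(m)) {
    if (m %% d != 0L) next
    p <- substr(unit, 1L, d)
    if (strrep(p, m %/% d) == unit) return(p)
  }
  unit  # unreachable: d = m always matches
}

# Maximal periodic-run scan shared by the nt and aa finders.
#
# For each candidate period m, positions i with s[i] == s[i+m] are computed
# on raw bytes and run-length encoded. A maximal TRUE run of length r gives a
# maximal periodic stretch of length r + m; its leftmost window of
# floor((r+m)/m) full units is the canonical placement. Stretches whose
# leading unit is non-primitive are skipped (they are re-found at the
# primitive period with more copies), so each periodic stretch is reported
# once. Characters in `mask_char` (N / X) break runs and can never sit inside
# a reported region.
scan_tandem_arrays <- function(seq, min_region_len, min_copies, min_unit_len,
                               max_unit_len, min_distinct, mask_char) {
  n <- nchar(seq)
  out <- list()
  if (n < min_region_len) {
    return(data.frame(start = integer(0), end = integer(0),
                      unit = character(0), copies = integer(0),
                      left_partial = integer(0), right_partial = integer(0)))
  }
  x <- charToRaw(seq)
  is_mask <- x == charToRaw(mask_char)
  m_hi <- min(max_unit_len, n %/% min_copies)
  for (m in seq.int(min_unit_len, length.out = max(0L, m_hi - min_unit_len + 1L))) {
    eq <- x[seq_len(n - m)] == x[(m + 1L):n]
    if (any(is_mask)) {
      eq <- eq & !is_mask[seq_len(n - m)] & !is_mask[(m + 1L):n]
    }
    r <- rle(eq)
    len <- r$lengths
    ends <- cumsum(len)
    starts <- ends - len + 1L
    ok <- which(r$values & len >= (min_copies - 1L) * m)
    for (k in ok) {
      lext <- len[k] + m
      copies <- lext %/% m
      if (copies * m < min_region_len) next
      i1 <- starts[k]                      # 1-based start of the stretch
      unit <- substr(seq, i1, i1 + m - 1L)
      if (nchar(primitive_root(unit)) != m) next
      if (min_distinct > 1L &&
          length(unique(strsplit(unit, "", fixed = TRUE)[[1]])) < min_distinct) next
      out[[length(out) + 1L]] <- data.frame(
        start = i1 - 1L, end = i1 - 1L + copies * m, unit = unit,
        copies = copies, left_partial = 0L,
        right_partial = lext - copies * m, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      unit = character(0), copies = integer(0),
                      left_partial = integer(0), right_partial = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, nchar(res$unit)), , drop = FALSE]
}

#' Find perfect nucleotide tandem repeats
#'
#' Detects every maximal, mismatch-free tandem array meeting the configured
#' thresholds. Units are primitive and the leftmost maximal placement is
#' reported, so `left_partial` is always 0 and the whole partial flank
#' appears as `right_partial`; alternative placements are available via
#' [enumerate_phases()]. Regions containing N are never reported.
#'
#' @param genome A [genome_record].
#' @param cfg A [finder_config].
#' @return data.frame with columns `contig_id`, `start`, `end` (0-based
#'   half-open), `unit`, `copies`, `left_partial`, `right_partial`,
#'   `context` (initially `"unassigned"`), sorted by `start`.
#' @export
find_nt_tandem_repeats <- function(genome, cfg = finder_config()) {
  stopifnot(inherits(genome, "genome_record"))
  res <- scan_tandem_arrays(genome$seq, cfg$min_region_len_nt, cfg$min_copies,
                            cfg$min_unit_len_nt, cfg$max_unit_len_nt,
                            cfg$min_distinct_chars, "N")
  if (nrow(res) == 0L) {
    return(cbind(data.frame(contig_id = character(0)), res,
                 data.frame(context = character(0))))
  }
  res <- cbind(data.frame(contig_id = genome$id, stringsAsFactors = FALSE),
               res)
  res$context <- "unassigned"
  rownames(res) <- NULL
  res
}

#' Find amino-acid tandem repeats in proteins
#'
#' Same maximality/primitivity contract as the nucleotide finder, with
#' amino-acid thresholds. X is tolerated in the input but never inside a
#' reported region.
#'
#' @param proteins Named character vector of protein sequences (or a single
#'   named element).
#' @param cfg A [finder_config].
#' @return data.frame with columns `protein_id`, `start`, `end` (0-based
#'   half-open, aa coordinates), `unit`, `copies`.
#' @export
find_aa_tandem_repeats <- function(proteins, cfg = finder_config()) {
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  rows <- lapply(names(proteins), function(id) {
    res <- scan_tandem_arrays(proteins[[id]], cfg$min_region_len_aa,
                              cfg$min_copies, cfg$min_unit_len_aa,
                              nchar(proteins[[id]]) %/% cfg$min_copies,
                              cfg$min_distinct_chars, "X")
    if (nrow(res) == 0L) return(NULL)
    cbind(data.frame(protein_id = id, stringsAsFactors = FALSE),
          res[, c("start", "end", "unit", "copies")])
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    return(data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), unit = character(0),
                      copies = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flanking partial repeats of a region
#'
#' `a` is the largest k < m such that the k bases immediately upstream of
#' the region equal the last k characters of the unit; `b` is the analogous
#' downstream match against the unit prefix. Both are clipped at contig
#' bounds. For canonically placed regions `a` is 0 by construction; the
#' function accepts arbitrarily placed (phase-shifted) regions.
#'
#' @param region One-row data.frame (or list) with `start`, `end`, `unit`.
#' @param genome A [genome_record].
#' @return Integer vector `c(a = , b = )`.
#' @export
flanking_partials <- function(region, genome) {
  s <- genome$seq
  n <- nchar(s)
  m <- nchar(region$unit)
  unit <- strsplit(region$unit, "", fixed = TRUE)[[1]]
  a <- 0L
  while (a < m - 1L && region$start - a - 1L >= 0L) {
    up <- substr(s, region$start - a, region$start - a)  # 1-based = start-a
    if (up != unit[m - a]) break
    a <- a + 1L
  }
  b <- 0L
  while (b < m - 1L && region$end + b < n) {
    dn <- substr(s, region$end + b + 1L, region$end + b + 1L)
    if (dn != unit[b + 1L]) break
    b <- b + 1L
  }
  c(a = a, b = b)
}

#' Enumerate phase alternatives of a region
#'
#' All placements of a window of `copies * m` bases inside the extended
#' periodic interval `[start - a, end + b)`; there are exactly
#' `a + b + 1` of them, each paired with the corresponding rotation of the
#' unit. Every placement is itself a perfect tandem array of its rotated
#' unit.
#'
#' @inheritParams flanking_partials
#' @return data.frame with columns `start` (0-based) and `unit` (rotation).
#' @export
enumerate_phases <- function(region, genome) {
  ab <- flanking_partials(region, genome)
  m <- nchar(region$unit)
  starts <- (region$start - ab[["a"]]) + 0:(ab[["a"]] + ab[["b"]])
  data.frame(start = starts,
             unit = substring(genome$seq, starts + 1L, starts + m),
             stringsAsFactors = FALSE)
}

#' Terminal inverted repeat of a linear genome
#'
#' Longest exact match between the genome's prefix and the reverse
#' complement of its suffix. N never matches.
#'
#' @param genome A [genome_record] (linear).
#' @param min_len Minimum length to report.
#' @return `NULL` if no match of at least `min_len`, else a list with
#'   `length` and `mismatches` (always 0: the match is exact).
#' @export
find_terminal_inverted_repeats <- function(genome, min_len = 20L) {
  stopifnot(genome$topology == "linear")
  x <- strsplit(genome$seq, "", fixed = TRUE)[[1]]
  n <- length(x)
  comp <- COMPLEMENT[x]
  L <- 0L
  while (L < n %/% 2L && x[L + 1L] != "N" &&
         x[L + 1L] == comp[n - L]) {
    L <- L + 1L
  }
  if (L >= min_len) list(length = L, mismatches = 0L) else NULL
}

#' Re-validate a TR region against its genome by direct string comparison
#'
#' Checks the full region contract: the span is exactly `copies` repeats of
#' a primitive `unit`, the array is maximal (cannot be extended by a full
#' unit on either side), and the recorded partial-flank lengths are the
#' maximal partial matches.
#'
#' @inheritParams flanking_partials
#' @return `TRUE` (invisibly) or an error describing the violated invariant.
#' @export
validate_tr_region <- function(region, genome) {
  s <- genome$seq
  m <- nchar(region$unit)
  span <- substr(s, region$start + 1L, region$end)
  if (span != strrep(region$unit, region$copies)) {
    stop("region is not unit^copies")
  }
  if (nchar(primitive_root(region$unit)) != m) stop("unit not primitive")
  if (region$start >= m &&
      substr(s, region$start - m + 1L, region$start) == region$unit) {
    stop("region extendable by a full unit on the left")
  }
  if (region$end + m <= nchar(s) &&
      substr(s, region$end + 1L, region$end + m) == region$unit) {
    stop("region extendable by a full unit on the right")
  }
  ab <- flanking_partials(region, genome)
  if (ab[["a"]] != region$left_partial || ab[["b"]] != region$right_partial) {
    stop("recorded partial flanks are not maximal")
  }
  invisible(TRUE)
}
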