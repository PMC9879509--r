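region_label <- function(region) {
  paste0(region$contig_id, ":", region$start, "-", region$end)
}

#' Count TR units in reads spanning a region
#'
#' Alignment-free, exact counting: the repeats are perfect, so a read spans
#' a region iff it contains the `anchor_len` bases immediately left of the
#' extended repeat interval followed by the `anchor_len` bases immediately
#' right of it, each exactly once. The sequence between the anchors must be
#' the region's periodic string with a whole number of units (the known
#' partial flank is tolerated); that unit count is tallied. Reads that
#' contain the unit but do not span validly are counted as non-spanning.
#' Both read orientations are tried.
#'
#' @param reads Character vector of read sequences.
#' @param region One-row region data.frame.
#' @param genome The [genome_record].
#' @param anchor_len Anchor length in bp (default 15).
#' @return A list of class `read_support`: `region_id`, `assessable`
#'   (FALSE when an anchor is not unique in the genome or runs off the
#'   contig), `spanning_counts` (named integer vector: unit count ->
#'   number of reads), `non_spanning`.
#' @export
count_spanning_units <- function(reads, region, genome, anchor_len = 15L) {
  m <- nchar(region$unit)
  ab <- flanking_partials(region, genome)
  ext_start <- region$start - ab[["a"]]
  ext_end <- region$end + ab[["b"]]
  rem <- (ext_end - ext_start) %% m
  res <- list(region_id = region_label(region), assessable = TRUE,
              spanning_counts = integer(0), non_spanning = 0L)
  class(res) <- "read_support"
  if (ext_start - anchor_len < 0L || ext_end + anchor_len > nchar(genome$seq)) {
    res$assessable <- FALSE
    return(res)
  }
  left <- substr(genome$seq, ext_start - anchor_len + 1L, ext_start)
  right <- substr(genome$seq, ext_end + 1L, ext_end + anchor_len)
  count_hits <- function(hay, needle) {
    h <- gregexpr(needle, hay, fixed = TRUE)[[1]]
    if (h[1] == -1L) 0L else length(h)
  }
  if (count_hits(genome$seq, left) != 1L ||
      count_hits(genome$seq, right) != 1L) {
    res$assessable <- FALSE
    return(res)
  }
  unit_ext <- substr(genome$seq, ext_start + 1L, ext_start + m)
  expected <- function(k) substr(strrep(unit_ext, k + 2L), 1L, k * m + rem)
  tally <- new.env()
  non_spanning <- 0L
  for (rd in reads) {
    spanned <- FALSE
    touched <- FALSE
    for (seqv in c(rd, revcomp(rd))) {
      lpos <- gregexpr(left, seqv, fixed = TRUE)[[1]]
      rpos <- gregexpr(right, seqv, fixed = TRUE)[[1]]
      has_unit <- grepl(unit_ext, seqv, fixed = TRUE)
      if (has_unit) touched <- TRUE
      if (lpos[1] == -1L || rpos[1] == -1L) next
      if (length(lpos) != 1L || length(rpos) != 1L) next
      b_start <- lpos + anchor_len         # 1-based start of between-segment
      b_end <- rpos - 1L
      if (b_end < b_start - 1L) next
      between <- substr(seqv, b_start, b_end)
      len <- nchar(between)
      if ((len - rem) %% m != 0L || len < rem) next
      k <- (len - rem) %/% m
      if (between != expected(k)) next
      key <- as.character(k)
      tally[[key]] <- (if (is.null(tally[[key]])) 0L else tally[[key]]) + 1L
      spanned <- TRUE
      break
    }
    if (!spanned && touched) non_spanning <- non_spanning + 1L
  }
  counts <- unlist(as.list(tally))
  if (is.null(counts)) counts <- integer(0)
  res$spanning_counts <- counts[order(as.integer(names(counts)))]
  res$non_spanning <- non_spanning
  res
}

#' Census of TR regions with within-population unit-number variation
#'
#' A region is variable when at least two distinct spanning unit counts are
#' each supported by at least `min_reads` reads. Regions with no spanning
#' reads (or flagged un-assessable) are excluded from the denominator.
#'
#' @param supports List of `read_support` objects.
#' @param min_reads Minimum reads supporting a unit count (default 2).
#' @return List with `n_variable`, `n_assessable`, `fraction`, and
#'   `variable_ids`.
#' @export
variable_region_census <- function(supports, min_reads = 2L) {
  assessable <- vapply(supports, function(s) {
    isTRUE(s$assessable) && sum(s$spanning_counts) > 0L
  }, logical(1))
  variable <- vapply(supports, function(s) {
    sum(s$spanning_counts >= min_reads) >= 2L
  }, logical(1)) & assessable
  list(n_variable = sum(variable),
       n_assessable = sum(assessable),
       fraction = if (sum(assessable) == 0L) NA_real_ else
         sum(variable) / sum(assessable),
       variable_ids = vapply(supports[variable], `[[`, character(1),
                             "region_id"))
}
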