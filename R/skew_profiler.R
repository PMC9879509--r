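#' GC skew profile of a genome
#'
#' Per sliding window, skew = (G - C) / (G + C); windows without any G or C
#' get skew 0 so the cumulative sum stays defined on A/T-rich stretches.
#' The cumulative skew's global minimum and maximum predict the replication
#' origin and terminus respectively (ties resolved leftmost). On the linear
#' two-replichore genomes this package targets, replication runs from the
#' chromosome ends towards an interior terminus, so the cumulative extremes
#' sit at an end and near the replichore junction.
#'
#' @param genome A [genome_record].
#' @param window Window width in bp (default 1000).
#' @param step Step between window starts in bp (default 10).
#' @return A list of class `skew_profile`: `positions` (0-based window
#'   centers), `skew`, `cumulative`, `window`, `step`, `predicted_origin`,
#'   `predicted_terminus` (positions; both `NA` when the profile is flat).
#' @export
gc_skew <- function(genome, window = 1000L, step = 10L) {
  stopifnot(window >= 1L, step >= 1L)
  n <- nchar(genome$seq)
  if (window > n) stop("window larger than genome")
  x <- charToRaw(genome$seq)
  cg <- cumsum(c(0L, as.integer(x == charToRaw("G"))))
  cc <- cumsum(c(0L, as.integer(x == charToRaw("C"))))
  starts <- seq.int(1L, n - window + 1L, by = step)
  g <- cg[starts + window] - cg[starts]
  c_ <- cc[starts + window] - cc[starts]
  tot <- g + c_
  skew <- ifelse(tot == 0L, 0, (g - c_) / tot)
  prof <- list(positions = starts - 1L + window %/% 2L,
               skew = skew,
               cumulative = cumsum(skew),
               window = as.integer(window), step = as.integer(step),
               predicted_origin = NA_integer_,
               predicted_terminus = NA_integer_)
  class(prof) <- "skew_profile"
  pr <- predict_replichores(prof)
  prof$predicted_origin <- pr[["origin"]]
  prof$predicted_terminus <- pr[["terminus"]]
  prof
}

#' Predict replication origin and terminus from a skew profile
#'
#' Origin = position of the global minimum of the cumulative skew,
#' terminus = global maximum (leftmost on ties). A flat cumulative profile
#' (all skew zero) is reported as undetermined (`NA`s).
#'
#' @param profile A `skew_profile` from [gc_skew()].
#' @return Named integer vector `c(origin = , terminus = )`.
#' @export
predict_replichores <- function(profile) {
  cum <- profile$cumulative
  if (all(profile$skew == 0)) {
    return(c(origin = NA_integer_, terminus = NA_integer_))
  }
  c(origin = profile$positions[which.min(cum)],
    terminus = profile$positions[which.max(cum)])
}

#' GC/AT symmetry profile around a TR region
#'
#' Sliding GC fraction with window = floor(m/2) and step 1 over the region
#' plus one full unit of flank on each side (clipped at contig bounds).
#' Over the repeat body the profile is exactly m-periodic for a perfect TR
#' whose unit mixes GC-rich and AT-rich halves -- the symmetry signature
#' seen around real repeat regions.
#'
#' @param genome A [genome_record].
#' @param region One-row region data.frame (unit length must be >= 2).
#' @return data.frame with `position` (0-based window start) and
#'   `gc_fraction`.
#' @export
symmetry_profile <- function(genome, region) {
  m <- nchar(region$unit)
  stopifnot(m >= 2L)
  w <- m %/% 2L
  n <- nchar(genome$seq)
  lo <- max(0L, region$start - m)
  hi <- min(n, region$end + m)
  x <- charToRaw(substr(genome$seq, lo + 1L, hi))
  gc <- cumsum(c(0L, as.integer(x == charToRaw("G") | x == charToRaw("C"))))
  starts <- seq_len(length(x) - w + 1L)
  data.frame(position = lo + starts - 1L,
             gc_fraction = (gc[starts + w] - gc[starts]) / w)
}

#' Write a skew profile as TSV
#' @param profile A `skew_profile`.
#' @param path Output path.
#' @export
write_skew_tsv <- function(profile, path) {
  write.table(data.frame(position = profile$positions, skew = profile$skew,
                         cumulative = profile$cumulative),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
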