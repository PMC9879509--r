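#' Classify TR regions by ORF context
#'
#' A region is `genic` iff fully contained in an ORF (ties between nested
#' ORFs go to the smallest), `boundary` iff it partially overlaps an ORF,
#' and `intergenic` otherwise. Also records whether the unit length is
#' divisible by three and, for genic regions, the frame offset of the
#' region start relative to the ORF reading frame.
#'
#' @param regions data.frame from [find_nt_tandem_repeats()].
#' @param orfs data.frame from [read_gff3()].
#' @return `regions` with added columns `orf_id`, `orf_start`, `orf_end`,
#'   `orf_strand`, `context`, `unit_div3`, `frame_offset`, `inside_frac`
#'   (fraction of the region inside the assigned ORF).
#' @export
classify_tr_context <- function(regions, orfs) {
  n <- nrow(regions)
  out <- regions
  out$orf_id <- NA_character_
  out$orf_start <- NA_integer_
  out$orf_end <- NA_integer_
  out$orf_strand <- NA_character_
  out$context <- "intergenic"
  out$unit_div3 <- nchar(regions$unit) %% 3L == 0L
  out$frame_offset <- NA_integer_
  out$inside_frac <- 0
  ov_warned <- FALSE
  for (i in seq_len(n)) {
    r <- regions[i, ]
    o <- orfs[orfs$contig_id == r$contig_id &
                orfs$start < r$end & orfs$end > r$start, , drop = FALSE]
    if (nrow(o) == 0L) next
    contained <- o$start <= r$start & o$end >= r$end
    if (any(contained)) {
      oc <- o[contained, , drop = FALSE]
      if (nrow(oc) > 1L && !ov_warned) {
        message("note: nested/overlapping ORFs; smallest containing ORF used")
        ov_warned <- TRUE
      }
      j <- which.min(oc$end - oc$start)
      out$context[i] <- "genic"
      out$inside_frac[i] <- 1
      pick <- oc[j, ]
    } else {
      ov <- pmin(o$end, r$end) - pmax(o$start, r$start)
      j <- which.max(ov)
      out$context[i] <- "boundary"
      out$inside_frac[i] <- ov[j] / (r$end - r$start)
      pick <- o[j, ]
    }
    out$orf_id[i] <- pick$id
    out$orf_start[i] <- pick$start
    out$orf_end[i] <- pick$end
    out$orf_strand[i] <- pick$strand
    if (out$context[i] == "genic") {
      out$frame_offset[i] <- if (pick$strand == "+") {
        (r$start - pick$start) %% 3L
      } else {
        (pick$end - r$end) %% 3L
      }
    }
  }
  out
}

#' Derive the amino-acid tandem repeat encoded by a genic nucleotide TR
#'
#' Applicable when the region is genic and its unit length is divisible by
#' three. If the region does not start on a codon boundary of its ORF, the
#' leading bases up to the next boundary are dropped (possibly losing one
#' copy); the amino-acid unit is then the standard-code translation of the
#' correspondingly rotated nucleotide unit. Reverse-strand ORFs are handled
#' through the reverse complement. The amino-acid unit is reduced to its
#' primitive root (a primitive nucleotide unit can translate to a
#' repetitive amino-acid string), with copies scaled accordingly.
#'
#' @param assignment One-row data.frame from [classify_tr_context()].
#' @param genome The [genome_record] the region lies on.
#' @return `NULL` when not applicable, else a list with `protein_id`,
#'   `aa_start`, `aa_end` (0-based aa coordinates in the ORF product),
#'   `unit`, `copies`, and `anomalous_stop` (TRUE if a stop codon occurs in
#'   the repeat -- never expected, flagged rather than fatal).
#' @export
tr_to_aatr <- function(assignment, genome) {
  a <- assignment
  if (a$context != "genic" || !a$unit_div3) return(NULL)
  m <- nchar(a$unit)
  if (a$orf_strand == "+") {
    d <- (3L - (a$start - a$orf_start) %% 3L) %% 3L
    ns <- a$start + d
    copies <- (a$end - ns) %/% m
    if (copies < 1L) return(NULL)
    rot <- substr(genome$seq, ns + 1L, ns + m)
    aa_start <- (ns - a$orf_start) %/% 3L
  } else {
    cstart <- a$orf_end - a$end                 # coding-strand coordinates
    cend <- a$orf_end - a$start
    d <- (3L - cstart %% 3L) %% 3L
    ns_c <- cstart + d
    copies <- (cend - ns_c) %/% m
    if (copies < 1L) return(NULL)
    # rotated unit read on the coding strand: genome interval
    # [orf_end - ns_c - m, orf_end - ns_c), reverse complemented
    g_hi <- a$orf_end - ns_c
    rot <- revcomp(substr(genome$seq, g_hi - m + 1L, g_hi))
    aa_start <- ns_c %/% 3L
  }
  aa_unit <- translate_cds(rot)
  root <- primitive_root(aa_unit)
  aa_copies <- copies * (nchar(aa_unit) %/% nchar(root))
  list(protein_id = a$orf_id,
       aa_start = aa_start,
       aa_end = aa_start + aa_copies * nchar(root),
       unit = root,
       copies = aa_copies,
       anomalous_stop = grepl("*", root, fixed = TRUE))
}

#' Classify TR context and derive all in-frame aaTRs
#'
#' Convenience wrapper: [classify_tr_context()] plus [tr_to_aatr()] per
#' genic region.
#'
#' @inheritParams classify_tr_context
#' @param genome The [genome_record].
#' @return The assignment data.frame with added columns `aa_unit`,
#'   `aa_copies`, `aa_start`, `aa_end`, `anomalous_stop` (NA when no aaTR
#'   is derived).
#' @export
map_tr_to_orfs <- function(regions, orfs, genome) {
  asg <- classify_tr_context(regions, orfs)
  asg$aa_unit <- NA_character_
  asg$aa_copies <- NA_integer_
  asg$aa_start <- NA_integer_
  asg$aa_end <- NA_integer_
  asg$anomalous_stop <- NA
  for (i in seq_len(nrow(asg))) {
    aatr <- tr_to_aatr(asg[i, ], genome)
    if (is.null(aatr)) next
    asg$aa_unit[i] <- aatr$unit
    asg$aa_copies[i] <- aatr$copies
    asg$aa_start[i] <- aatr$aa_start
    asg$aa_end[i] <- aatr$aa_end
    asg$anomalous_stop[i] <- aatr$anomalous_stop
    if (aatr$anomalous_stop) {
      warning("in-frame stop codon inside repeat of ORF ", asg$orf_id[i])
    }
  }
  asg
}

#' Effective two-way context for reporting
#'
#' Collapses the three-way context to genic/intergenic: boundary regions
#' count as genic when at least `boundary_genic_frac` of the region lies
#' inside the ORF, else intergenic.
#'
#' @param assignments data.frame from [classify_tr_context()].
#' @param boundary_genic_frac Containment fraction at which a boundary
#'   region counts as genic.
#' @return Character vector of `"genic"` / `"intergenic"`.
#' @export
effective_context <- function(assignments, boundary_genic_frac = 0.5) {
  ifelse(assignments$context == "genic" |
           (assignments$context == "boundary" &
              assignments$inside_frac >= boundary_genic_frac),
         "genic", "intergenic")
}

#' Percentage of TR unit lengths divisible by three, by context
#'
#' @param assignments data.frame from [classify_tr_context()].
#' @param context_filter Which effective context to summarize.
#' @param boundary_genic_frac Passed to [effective_context()].
#' @return `100 * divisible / total`, rounded to integer; `NA` when the
#'   context class is empty.
#' @export
div3_fraction <- function(assignments,
                          context_filter = c("intergenic", "genic"),
                          boundary_genic_frac = 0.5) {
  context_filter <- match.arg(context_filter)
  eff <- effective_context(assignments, boundary_genic_frac)
  sel <- assignments$unit_div3[eff == context_filter]
  if (length(sel) == 0L) return(NA_integer_)
  as.integer(round(100 * sum(sel) / length(sel)))
}
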