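#' @importFrom stats as.dist cutree hclust
NULL

#' Triple repeat units
#'
#' Each amino-acid unit concatenated three times. Clustering operates on
#' tripled units so that short units (the minimum unit length is 3 aa)
#' still produce alignable strings, and so that rotational phase matters
#' less than composition.
#'
#' @param units Character vector of aa units.
#' @return Character vector of tripled units.
#' @export
triple_units <- function(units) {
  stopifnot(length(units) > 0L)
  strrep(units, 3L)
}

lcs_length <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) return(0L)
  prev <- integer(ny + 1L)
  for (i in seq_len(nx)) {
    cur <- integer(ny + 1L)
    match_i <- x[i] == y
    for (j in seq_len(ny)) {
      cur[j + 1L] <- if (match_i[j]) prev[j] + 1L else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[ny + 1L]
}

#' Alignment-identity distance between two aa strings
#'
#' One minus the identity fraction of an optimal global alignment under
#' match = 1, mismatch/indel = 0. Under that scoring the number of aligned
#' identities is the longest common subsequence, and the alignment length
#' is `|a| + |b| - LCS`. The distance is symmetric, lies in \[0, 1\], and
#' is zero iff the strings are identical.
#'
#' @param a,b Non-empty aa strings.
#' @return Numeric distance in \[0, 1\].
#' @export
pairwise_distance <- function(a, b) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  l <- lcs_length(a, b)
  1 - l / (nchar(a) + nchar(b) - l)
}

#' Distance matrix over tripled units
#'
#' @param units Character vector of aa units (tripled internally).
#' @return Symmetric matrix of [pairwise_distance()] values, zero diagonal.
#' @export
unit_distance_matrix <- function(units) {
  tri <- triple_units(units)
  n <- length(tri)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      d[i, j] <- d[j, i] <- pairwise_distance(tri[i], tri[j])
    }
  }
  d
}

#' Name an aaTR cluster from its members' residue composition
#'
#' Residue counts are pooled over the members' single units; every amino
#' acid reaching at least 10% of the pool is listed, in descending pooled
#' frequency (ties broken alphabetically).
#'
#' @param member_units Character vector of single aa units (>= 1).
#' @param threshold Naming frequency threshold (default 0.10).
#' @return Cluster name string.
#' @export
name_cluster <- function(member_units, threshold = 0.10) {
  stopifnot(length(member_units) >= 1L)
  pool <- strsplit(paste(member_units, collapse = ""), "", fixed = TRUE)[[1]]
  cnt <- sort(table(pool), decreasing = TRUE)
  cnt <- cnt[order(-cnt, names(cnt))]          # descending count, alpha ties
  keep <- cnt / length(pool) >= threshold
  paste(names(cnt)[keep], collapse = "")
}

#' Cluster aaTR units by tripled-unit distance
#'
#' Average-linkage hierarchical clustering of the tripled-unit distance
#' matrix, cut at `cutoff`; flat groups with at least `min_size` members
#' become clusters, everything else is unclustered (`"n.c."`). Cluster ids
#' are assigned by the lexicographic order of each cluster's sorted member
#' units, so the result is invariant to input permutation.
#'
#' @param units Character vector of aa units.
#' @param cutoff Dendrogram cut height in \[0, 1\] (default 0.6).
#' @param min_size Minimum cluster size (default 3).
#' @param unit_ids Optional identifiers (default `unit1..unitN`).
#' @param distances Optional precomputed distance matrix (as from
#'   [unit_distance_matrix()]); must be symmetric with zero diagonal.
#' @return data.frame with `unit_id`, `unit`, `cluster_id` (integer, `NA`
#'   when unclustered), `cluster_name` (`"n.c."` when unclustered).
#' @export
cluster_units <- function(units, cutoff = 0.6, min_size = 3L,
                          unit_ids = NULL, distances = NULL) {
  if (cutoff < 0 || cutoff > 1) stop("cutoff must be in [0, 1]")
  n <- length(units)
  if (is.null(unit_ids)) unit_ids <- paste0("unit", seq_len(n))
  if (is.null(distances)) distances <- unit_distance_matrix(units)
  stopifnot(nrow(distances) == n, isTRUE(all.equal(distances, t(distances))),
            all(diag(distances) == 0))
  grp <- if (n == 1L) 1L else {
    cutree(hclust(as.dist(distances), method = "average"), h = cutoff)
  }
  out <- data.frame(unit_id = unit_ids, unit = units,
                    cluster_id = NA_integer_, cluster_name = "n.c.",
                    stringsAsFactors = FALSE)
  sizes <- table(grp)
  big <- as.integer(names(sizes)[sizes >= min_size])
  if (length(big) > 0L) {
    keys <- vapply(big, function(g) {
      paste(sort(units[grp == g]), collapse = "|")
    }, character(1))
    big <- big[order(keys)]
    for (k in seq_along(big)) {
      sel <- grp == big[k]
      out$cluster_id[sel] <- k
      out$cluster_name[sel] <- name_cluster(units[sel])
    }
  }
  out
}
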