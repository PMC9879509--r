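#' @importFrom stats pchisq fisher.test
NULL

#' TOP-IDP disorder propensity scale
#'
#' Per-residue propensity to promote intrinsic disorder (higher = more
#' disorder-promoting), used to order amino-acid enrichment tables. The
#' values are the TOP-IDP scale of Campen and colleagues (2008); the table
#' is a named constant and can be overridden wherever it is accepted.
#'
#' @format Named numeric vector of length 20.
#' @export
top_idp <- c(W = -0.884, F = -0.697, Y = -0.510, I = -0.486, M = -0.397,
             L = -0.326, V = -0.121, N = 0.007, C = 0.02, T = 0.059,
             A = 0.06, G = 0.166, R = 0.180, D = 0.192, H = 0.303,
             Q = 0.318, S = 0.341, K = 0.586, E = 0.736, P = 0.987)

merge_intervals <- function(starts, ends) {
  if (length(starts) == 0L) return(cbind(start = integer(0), end = integer(0)))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out <- list()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) {
      me <- max(me, ends[i])
    } else {
      out[[length(out) + 1L]] <- c(ms, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  out[[length(out) + 1L]] <- c(ms, me)
  m <- do.call(rbind, out)
  colnames(m) <- c("start", "end")
  m
}

#' Partition a genome into repeat / non-repeat composition samples
#'
#' Repeat segments (the union of the TR region intervals) and the
#' intervening non-repeat segments are each cut into consecutive
#' non-overlapping `width`-bp substrings; remainders shorter than `width`
#' are dropped. Each substring yields one sample: its nucleotide count
#' vector `[N_A, N_T, N_C, N_G]` and a class label. Substrings containing N
#' are excluded.
#'
#' @param genome A [genome_record].
#' @param regions data.frame of TR regions on that genome.
#' @param width Substring width in bp (default 50).
#' @return data.frame with `class_label` (`"repeat"`/`"non_repeat"`) and
#'   integer columns `N_A`, `N_T`, `N_C`, `N_G` summing to `width`.
#' @export
partition_substrings <- function(genome, regions, width = 50L) {
  stopifnot(width >= 1L)
  n <- nchar(genome$seq)
  rep_iv <- merge_intervals(regions$start, regions$end)
  non_starts <- c(0L, rep_iv[, "end"])
  non_ends <- c(rep_iv[, "start"], n)
  keep <- non_ends > non_starts
  x <- charToRaw(genome$seq)
  cums <- lapply(c("A", "T", "C", "G", "N"), function(b) {
    cumsum(c(0L, as.integer(x == charToRaw(b))))
  })
  names(cums) <- c("A", "T", "C", "G", "N")
  chunk <- function(iv_start, iv_end, label) {
    rows <- list()
    for (k in seq_along(iv_start)) {
      len <- iv_end[k] - iv_start[k]
      nch <- len %/% width
      if (nch == 0L) next
      s0 <- iv_start[k] + (seq_len(nch) - 1L) * width  # 0-based chunk starts
      counts <- vapply(cums, function(cu) cu[s0 + width + 1L] - cu[s0 + 1L],
                       integer(length(s0)))
      counts <- matrix(counts, nrow = length(s0))
      colnames(counts) <- names(cums)
      ok <- counts[, "N"] == 0L
      if (!any(ok)) next
      rows[[length(rows) + 1L]] <- data.frame(
        class_label = label, N_A = counts[ok, "A"], N_T = counts[ok, "T"],
        N_C = counts[ok, "C"], N_G = counts[ok, "G"],
        stringsAsFactors = FALSE)
    }
    rows
  }
  rows <- c(chunk(rep_iv[, "start"], rep_iv[, "end"], "repeat"),
            chunk(non_starts[keep], non_ends[keep], "non_repeat"))
  if (length(rows) == 0L) {
    return(data.frame(class_label = character(0), N_A = integer(0),
                      N_T = integer(0), N_C = integer(0), N_G = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis rank test for two groups
#'
#' Rank-based H with tie correction; p-value from the chi-square
#' approximation with df = 1. When every value in both groups is identical
#' the statistic is defined as 0 with p = 1.
#'
#' @param group1,group2 Numeric vectors (non-empty).
#' @return Named numeric vector `c(H = , p = )`.
#' @export
kruskal_wallis <- function(group1, group2) {
  stopifnot(length(group1) > 0L, length(group2) > 0L)
  x <- c(group1, group2)
  g <- rep(1:2, c(length(group1), length(group2)))
  N <- length(x)
  if (length(unique(x)) == 1L) return(c(H = 0, p = 1))
  r <- rank(x)
  R <- tapply(r, g, sum)
  n <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(R^2 / n) - 3 * (N + 1)
  ties <- table(x)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  c(H = H, p = pchisq(H, df = 1L, lower.tail = FALSE))
}

#' Benjamini-Yekutieli FDR correction
#'
#' Step-up adjustment valid under arbitrary dependence:
#' `adj_(i) = min_{j >= i} p_(j) * m * c(m) / j` with
#' `c(m) = sum_{k=1..m} 1/k`, capped at 1, returned in the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
benjamini_yekutieli <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  cm <- sum(1 / seq_len(m))
  o <- order(p_values)
  ranked <- p_values[o] * m * cm / seq_len(m)
  adj <- pmin(1, rev(cummin(rev(ranked))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Nucleotide-composition contrast between TR and non-TR sequence
#'
#' For each nucleotide, a Kruskal-Wallis test compares its per-substring
#' counts between the repeat and non-repeat classes
#' ([partition_substrings()]); the four raw p-values are
#' Benjamini-Yekutieli-corrected as one family. Class means are reported
#' as percentages of the substring width.
#'
#' @param genome A [genome_record].
#' @param regions data.frame of TR regions.
#' @param width Substring width in bp (default 50).
#' @return data.frame with one row per nucleotide (A, T, G, C): `H`,
#'   `p_raw`, `p_adj`, `mean_repeat`, `mean_nonrepeat` (percent). All-NA
#'   statistics (with a warning) when either class has fewer than 2
#'   samples.
#' @export
tr_composition_test <- function(genome, regions, width = 50L) {
  samples <- partition_substrings(genome, regions, width)
  out <- data.frame(nucleotide = c("A", "T", "G", "C"), H = NA_real_,
                    p_raw = NA_real_, p_adj = NA_real_,
                    mean_repeat = NA_real_, mean_nonrepeat = NA_real_,
                    stringsAsFactors = FALSE)
  rep_s <- samples[samples$class_label == "repeat", , drop = FALSE]
  non_s <- samples[samples$class_label == "non_repeat", , drop = FALSE]
  if (nrow(rep_s) < 2L || nrow(non_s) < 2L) {
    warning("fewer than 2 samples in a class; composition test skipped")
    return(out)
  }
  cols <- c(A = "N_A", T = "N_T", G = "N_G", C = "N_C")
  for (i in seq_len(4L)) {
    cl <- cols[[out$nucleotide[i]]]
    kw <- kruskal_wallis(rep_s[[cl]], non_s[[cl]])
    out$H[i] <- kw[["H"]]
    out$p_raw[i] <- kw[["p"]]
    out$mean_repeat[i] <- 100 * mean(rep_s[[cl]]) / width
    out$mean_nonrepeat[i] <- 100 * mean(non_s[[cl]]) / width
  }
  out$p_adj <- benjamini_yekutieli(out$p_raw)
  out
}

ALL_CODONS <- names(Biostrings::GENETIC_CODE)

split_codons <- function(cds) {
  n <- nchar(cds)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Codon usage inside versus outside aaTR regions
#'
#' Counts every codon of the supplied coding sequences, split into aaTR
#' codons (per-ORF codon-aligned intervals) and all other codons.
#' Frequencies are per class; the ratio column is `freq_in / freq_out`
#' (0 when a codon present outside is absent inside aaTRs -- the
#' "absent codon" signature -- and `Inf` when absent outside only).
#' Per-codon enrichment is a two-sided Fisher exact test on the 2x2 count
#' table, Benjamini-Yekutieli-corrected across the 64 codons.
#'
#' @param cds_seqs Named character vector of coding sequences (lengths
#'   divisible by 3, coding strand).
#' @param aatr_intervals Named list (by ORF id) of data.frames with
#'   `start`, `end`: 0-based half-open intervals in codon units.
#' @return data.frame with 64 rows: `codon`, `aa`, `count_in`, `count_out`,
#'   `freq_in`, `freq_out`, `ratio`, `p_raw`, `p_adj`, `absent_in_aatr`.
#' @export
codon_usage <- function(cds_seqs, aatr_intervals = list()) {
  in_codons <- character(0)
  out_codons <- character(0)
  for (id in names(cds_seqs)) {
    cod <- split_codons(cds_seqs[[id]])
    iv <- aatr_intervals[[id]]
    inside <- rep(FALSE, length(cod))
    if (!is.null(iv) && nrow(iv) > 0L) {
      if (any(iv$start < 0L | iv$end > length(cod) | iv$start >= iv$end)) {
        stop("aaTR interval outside ORF or empty: ", id)
      }
      for (k in seq_len(nrow(iv))) {
        inside[(iv$start[k] + 1L):iv$end[k]] <- TRUE
      }
    }
    in_codons <- c(in_codons, cod[inside])
    out_codons <- c(out_codons, cod[!inside])
  }
  count_in <- table(factor(in_codons, levels = ALL_CODONS))
  count_out <- table(factor(out_codons, levels = ALL_CODONS))
  ti <- sum(count_in); to <- sum(count_out)
  freq_in <- if (ti > 0) as.numeric(count_in) / ti else rep(NA_real_, 64L)
  freq_out <- if (to > 0) as.numeric(count_out) / to else rep(NA_real_, 64L)
  ratio <- ifelse(count_out == 0,
                  ifelse(count_in == 0, NA_real_, Inf),
                  freq_in / freq_out)
  p_raw <- vapply(seq_len(64L), function(i) {
    if (ti == 0 || to == 0) return(NA_real_)
    fisher.test(matrix(c(count_in[i], ti - count_in[i],
                         count_out[i], to - count_out[i]), nrow = 2L))$p.value
  }, numeric(1))
  p_adj <- rep(NA_real_, 64L)
  if (!anyNA(p_raw)) p_adj <- benjamini_yekutieli(p_raw)
  data.frame(codon = ALL_CODONS,
             aa = unname(Biostrings::GENETIC_CODE[ALL_CODONS]),
             count_in = as.integer(count_in),
             count_out = as.integer(count_out),
             freq_in = freq_in, freq_out = freq_out, ratio = ratio,
             p_raw = p_raw, p_adj = p_adj,
             absent_in_aatr = count_in == 0 & count_out > 0,
             stringsAsFactors = FALSE)
}

#' Positional nucleotide frequency in codons, per class
#'
#' Fraction of each base at codon positions 1-3, separately for aaTR
#' codons and all other codons. Every column sums to 1.
#'
#' @param codons_in,codons_out Character vectors of codons.
#' @return List with elements `aatr` and `other`, each a 4x3 matrix
#'   (rows A, T, G, C; columns pos1-pos3).
#' @export
positional_nt_frequency <- function(codons_in, codons_out) {
  tab <- function(cod) {
    m <- matrix(0, nrow = 4L, ncol = 3L,
                dimnames = list(c("A", "T", "G", "C"),
                                c("pos1", "pos2", "pos3")))
    if (length(cod) == 0L) return(m)
    for (p in 1:3) {
      f <- table(factor(substr(cod, p, p), levels = c("A", "T", "G", "C")))
      m[, p] <- as.numeric(f) / length(cod)
    }
    m
  }
  list(aatr = tab(codons_in), other = tab(codons_out))
}

#' Amino-acid enrichment in aaTRs relative to the whole proteome
#'
#' Residue frequency within the concatenated aaTR regions (each region is
#' its unit repeated `copies` times) divided by the residue frequency over
#' all proteins. Rows are ordered by a disorder-propensity scale
#' (ascending: order-promoting first), mirroring the usual presentation of
#' such enrichment tables.
#'
#' @param aatrs data.frame with columns `unit`, `copies`.
#' @param proteome Named character vector of protein sequences.
#' @param propensity Named numeric ordering scale (default [top_idp]).
#' @return data.frame with `aa`, `freq_aatr`, `freq_proteome`, `ratio`
#'   (`NA` when the residue is absent from the proteome), `propensity`.
#' @export
aa_enrichment <- function(aatrs, proteome, propensity = top_idp) {
  stopifnot(nrow(aatrs) > 0L, length(proteome) > 0L)
  aas <- names(sort(propensity))
  reg <- paste(strrep(aatrs$unit, aatrs$copies), collapse = "")
  prot <- paste(proteome, collapse = "")
  f_reg <- table(factor(strsplit(reg, "")[[1]], levels = aas))
  f_prot <- table(factor(strsplit(prot, "")[[1]], levels = aas))
  freq_aatr <- as.numeric(f_reg) / sum(f_reg)
  freq_prot <- as.numeric(f_prot) / sum(f_prot)
  data.frame(aa = aas, freq_aatr = freq_aatr, freq_proteome = freq_prot,
             ratio = ifelse(freq_prot == 0, NA_real_, freq_aatr / freq_prot),
             propensity = propensity[aas], stringsAsFactors = FALSE)
}

#' SNP substitution tallies inside and outside TR regions
#'
#' Each variant is assigned to the TR or non-TR class by position; per
#' class a 4x4 ref-by-alt count matrix is tallied, alongside the fraction
#' of substitutions towards each base (the A column captures the A-bias of
#' TR-region SNPs).
#'
#' @param variants data.frame from [read_variants_tsv()].
#' @param regions data.frame of TR regions.
#' @param genome Optional [genome_record]; when given, variants outside the
#'   contig bounds are skipped with a warning.
#' @return List with `tr` and `non_tr` 4x4 matrices (rows ref, cols alt)
#'   and `to_base_fraction`: a 2x4 matrix of per-class fractions of
#'   substitutions towards each base.
#' @export
snp_bias_summary <- function(variants, regions, genome = NULL) {
  bases <- c("A", "T", "G", "C")
  empty <- matrix(0L, 4L, 4L, dimnames = list(ref = bases, alt = bases))
  if (!is.null(genome) && nrow(variants) > 0L) {
    oob <- variants$contig_id == genome$id &
      (variants$position < 0L | variants$position >= nchar(genome$seq))
    if (any(oob)) {
      warning(sum(oob), " variant(s) out of contig bounds skipped")
      variants <- variants[!oob, , drop = FALSE]
    }
  }
  tally <- function(v) {
    m <- empty
    for (i in seq_len(nrow(v))) {
      m[v$ref_base[i], v$alt_base[i]] <- m[v$ref_base[i], v$alt_base[i]] +
        v$count[i]
    }
    m
  }
  in_tr <- rep(FALSE, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    sel <- regions$contig_id == variants$contig_id[i] &
      regions$start <= variants$position[i] &
      regions$end > variants$position[i]
    in_tr[i] <- any(sel)
  }
  tr_m <- tally(variants[in_tr, , drop = FALSE])
  non_m <- tally(variants[!in_tr, , drop = FALSE])
  frac <- function(m) if (sum(m) == 0) rep(NA_real_, 4L) else colSums(m) / sum(m)
  to_base <- rbind(tr = frac(tr_m), non_tr = frac(non_m))
  colnames(to_base) <- bases
  list(tr = tr_m, non_tr = non_m, to_base_fraction = to_base)
}
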