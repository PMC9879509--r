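#' Simulation configuration for synthetic genomes
#'
#' The defaults state the simulated world: a 1 Mbp linear genome whose
#' coding-strand background composition is A>T>G>C (38.4/28.8/20.3/12.5%),
#' planted perfect tandem repeats whose units are strongly A-enriched
#' (48.4% A, 23.7% T, 17.1% G, 10.8% C), genic repeat units of length
#' divisible by three placed codon-aligned inside ORFs with no in-frame
#' stops, optional partial flanks on intergenic repeats, a two-replichore
#' G/C-skew structure, and read populations in which a subset of regions
#' varies by one repeat unit between molecules.
#'
#' @param genome_length Genome length in bp.
#' @param background_base_freqs Background base probabilities (A, T, G, C).
#' @param n_intergenic_trs,n_genic_trs Numbers of planted TRs.
#' @param unit_len_range_nt Intergenic unit length range (nt).
#' @param aa_unit_len_range Genic unit length range (aa; nt unit = 3x).
#' @param copy_range Repeat copy-number range; the lower bound is raised
#'   per unit so every planted region reaches the 50 nt detection floor.
#' @param tr_base_freqs Base probabilities for intergenic repeat units.
#' @param partial_flank_prob Probability that an intergenic region gets a
#'   partial flank on a given side.
#' @param n_orfs Number of planted ORFs.
#' @param orf_len_range ORF length range in nt (rounded to codons).
#' @param two_replichore_skew Plant a G/C skew flip at the genome midpoint.
#' @param skew_delta Fraction of the smaller of the G/C probabilities moved
#'   between G and C per replichore.
#' @param read_length,n_reads Read simulation parameters.
#' @param unit_variation_prob Probability that a molecule of a variable
#'   region carries one unit fewer than the reference.
#' @param n_variable_regions How many planted regions are variable.
#' @param genic_aa_freqs Residue weights for genic (amino-acid) units;
#'   default enriched in P, T, E, K with W, C, F absent.
#' @param avoid_codons Codons never used when reverse-translating genic
#'   units (stops plus the codons empirically absent from aaTRs).
#' @param tr_snp_spec,nontr_snp_spec Named counts (`"G>A"` style) for the
#'   planted variant table; defaults reproduce a 14/18 G-to-A tally in the
#'   TR class and the 462/494/101 split outside.
#' @param seed Integer seed; all outputs are pure functions of (cfg, seed).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    genome_length = 1000000L,
    background_base_freqs = c(A = 0.384, T = 0.288, G = 0.203, C = 0.125),
    n_intergenic_trs = 20L, n_genic_trs = 20L,
    unit_len_range_nt = c(7L, 36L),
    aa_unit_len_range = c(3L, 8L),
    copy_range = c(3L, 8L),
    tr_base_freqs = c(A = 0.484, T = 0.237, G = 0.171, C = 0.108),
    partial_flank_prob = 0.5,
    n_orfs = 60L,
    orf_len_range = c(900L, 3000L),
    two_replichore_skew = TRUE,
    skew_delta = 0.2,
    read_length = 500L, n_reads = 2000L,
    unit_variation_prob = 0.4,
    n_variable_regions = 0L,
    genic_aa_freqs = NULL,
    avoid_codons = c("TGA", "TAA", "TAG", "CGA", "CGT", "CGG", "TTC", "TGC"),
    tr_snp_spec = c("G>A" = 14L, "C>A" = 2L, "T>A" = 2L),
    nontr_snp_spec = c("G>A" = 462L, "C>A" = 494L, "T>A" = 101L),
    seed = 1L) {
  if (is.null(genic_aa_freqs)) {
    genic_aa_freqs <- c(P = 0.12, T = 0.12, E = 0.12, K = 0.12,
                        A = 0.04, R = 0.04, N = 0.04, D = 0.04, Q = 0.04,
                        G = 0.04, H = 0.04, I = 0.04, L = 0.04, M = 0.04,
                        S = 0.04, V = 0.04, Y = 0.04)
  }
  cfg <- as.list(environment())
  stopifnot(abs(sum(background_base_freqs) - 1) < 1e-8,
            abs(sum(tr_base_freqs) - 1) < 1e-8,
            genome_length >= 10000L,
            unit_len_range_nt[1] >= 2L,
            aa_unit_len_range[1] >= 3L,
            copy_range[1] >= 3L,
            partial_flank_prob >= 0, partial_flank_prob <= 1)
  cfg$genic_aa_freqs <- genic_aa_freqs / sum(genic_aa_freqs)
  class(cfg) <- "simulation_config"
  cfg
}

BASES <- c("A", "T", "G", "C")

rand_seq <- function(n, freqs) {
  if (n <= 0L) return("")
  paste(sample(BASES, n, replace = TRUE, prob = freqs[BASES]), collapse = "")
}

# Base frequencies whose non-stop-conditional codon marginal matches the
# target: sampling codons as independent triples and rejecting stops shifts
# the realized base composition; this pre-compensates by fixed point.
compensate_freqs <- function(target) {
  codons <- names(Biostrings::GENETIC_CODE)
  stops <- codons[Biostrings::GENETIC_CODE == "*"]
  q <- target[BASES]
  for (it in 1:60) {
    p1 <- q[substr(codons, 1, 1)]
    p2 <- q[substr(codons, 2, 2)]
    p3 <- q[substr(codons, 3, 3)]
    pc <- p1 * p2 * p3
    pc[codons %in% stops] <- 0
    pc <- pc / sum(pc)
    marg <- (tapply(pc, substr(codons, 1, 1), sum) +
               tapply(pc, substr(codons, 2, 2), sum) +
               tapply(pc, substr(codons, 3, 3), sum)) / 3
    q <- q * (target[BASES] / marg[BASES])
    q <- q / sum(q)
  }
  q
}

sample_codons <- function(n, base_freqs, avoid = c("TAA", "TAG", "TGA")) {
  codons <- names(Biostrings::GENETIC_CODE)
  keep <- !codons %in% avoid
  p <- base_freqs[substr(codons, 1, 1)] * base_freqs[substr(codons, 2, 2)] *
    base_freqs[substr(codons, 3, 3)]
  p[!keep] <- 0
  sample(codons, n, replace = TRUE, prob = p)
}

AA_CODONS <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)

reverse_translate <- function(aa_unit, avoid_codons) {
  aas <- strsplit(aa_unit, "", fixed = TRUE)[[1]]
  vapply(aas, function(a) {
    allowed <- setdiff(AA_CODONS[[a]], avoid_codons)
    if (length(allowed) == 0L) stop("no allowed codon for ", a)
    if (length(allowed) == 1L) allowed else sample(allowed, 1L)
  }, character(1))
}

# A planted stretch must, scanned in isolation, yield exactly its own
# canonical array -- no internal arrays of other periods at detection
# thresholds. Guarantees 100% precision is attainable on planted truth.
stretch_is_clean <- function(stretch, m) {
  hits <- scan_tandem_arrays(stretch, 50L, 3L, 1L, 100L, 1L, "N")
  lp <- nchar(stretch)
  nrow(hits) == 1L && hits$start == 0L && nchar(hits$unit) == m &&
    hits$copies == lp %/% m
}

sample_intergenic_tr <- function(cfg) {
  repeat {
    m <- sample(seq(cfg$unit_len_range_nt[1], cfg$unit_len_range_nt[2]), 1L)
    c_lo <- max(cfg$copy_range[1], as.integer(ceiling(50 / m)))
    c_hi <- max(cfg$copy_range[2], c_lo)
    copies <- sample(seq(c_lo, c_hi), 1L)
    unit <- rand_seq(m, cfg$tr_base_freqs)
    if (nchar(primitive_root(unit)) != m) next
    a <- 0L; b <- 0L
    if (m >= 2L && stats::runif(1) < cfg$partial_flank_prob) {
      a <- sample(seq_len(m - 1L), 1L)
    }
    if (m >= 2L && stats::runif(1) < cfg$partial_flank_prob) {
      b <- sample(seq_len(m - 1L), 1L)
    }
    stretch <- paste0(substr(unit, m - a + 1L, m), strrep(unit, copies),
                      substr(unit, 1L, b))
    if (!stretch_is_clean(stretch, m)) next
    rho <- substr(stretch, 1L, m)
    lp <- nchar(stretch)
    return(list(stretch = stretch, unit = rho, m = m,
                copies = lp %/% m, right_partial = lp %% m,
                planted_unit = unit, planted_copies = copies,
                planted_a = a, planted_b = b))
  }
}

sample_genic_tr <- function(cfg) {
  aas <- names(cfg$genic_aa_freqs)
  repeat {
    k <- sample(seq(cfg$aa_unit_len_range[1], cfg$aa_unit_len_range[2]), 1L)
    aa_unit <- paste(sample(aas, k, replace = TRUE,
                            prob = cfg$genic_aa_freqs), collapse = "")
    if (nchar(primitive_root(aa_unit)) != k) next
    nt_unit <- paste(reverse_translate(aa_unit, cfg$avoid_codons),
                     collapse = "")
    m <- 3L * k
    if (nchar(primitive_root(nt_unit)) != m) next
    c_lo <- max(cfg$copy_range[1], as.integer(ceiling(50 / m)))
    c_hi <- max(cfg$copy_range[2], c_lo)
    copies <- sample(seq(c_lo, c_hi), 1L)
    stretch <- strrep(nt_unit, copies)
    if (!stretch_is_clean(stretch, m)) next
    return(list(nt_unit = nt_unit, aa_unit = aa_unit, m = m, k = k,
                copies = copies, stretch = stretch))
  }
}

local_freqs <- function(cfg, midpoint) {
  f <- cfg$background_base_freqs[BASES]
  if (!cfg$two_replichore_skew) return(f)
  d <- cfg$skew_delta * min(f["G"], f["C"])
  if (midpoint < cfg$genome_length / 2) {
    f["G"] <- f["G"] + d; f["C"] <- f["C"] - d
  } else {
    f["G"] <- f["G"] - d; f["C"] <- f["C"] + d
  }
  f
}

#' Generate a synthetic genome with planted truth
#'
#' Builds a linear genome from the configured background composition (with
#' an optional replichore skew flip at the midpoint), plants ORFs (ATG
#' start, stop-free codon body, TAA stop; forward strand on the left
#' replichore, reverse on the right), plants intergenic and codon-aligned
#' genic tandem repeats whose boundaries are forced non-extendable, and
#' certifies the rest of the genome repeat-free at detection thresholds by
#' rescanning and resampling any accidental array. The returned truth is
#' re-validated against the emitted sequence before being returned.
#'
#' @param cfg A [simulation_config].
#' @return List with `genome` ([genome_record]), `orfs` (data.frame),
#'   `proteins` (named character vector), and `truth` (list: `regions`
#'   data.frame of canonical planted regions with context and aa fields,
#'   `mixtures` per-region unit-count mixtures, `replichore_boundary`,
#'   `config`).
#' @export
generate_genome <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  L <- cfg$genome_length

  inter_specs <- lapply(seq_len(cfg$n_intergenic_trs),
                        function(i) sample_intergenic_tr(cfg))
  genic_specs <- lapply(seq_len(cfg$n_genic_trs),
                        function(i) sample_genic_tr(cfg))

  n_orfs <- max(cfg$n_orfs, cfg$n_genic_trs)
  orf_lens <- 3L * sample(seq(cfg$orf_len_range[1] %/% 3L,
                              cfg$orf_len_range[2] %/% 3L), n_orfs,
                          replace = TRUE)
  # features: ORFs and intergenic-TR slots, shuffled, separated by gaps
  feat <- data.frame(
    kind = c(rep("orf", n_orfs), rep("tr", cfg$n_intergenic_trs)),
    idx = c(seq_len(n_orfs), seq_len(cfg$n_intergenic_trs)),
    len = c(orf_lens,
            vapply(inter_specs, function(s) nchar(s$stretch), integer(1))))
  feat <- feat[sample(nrow(feat)), , drop = FALSE]
  min_gap <- 200L
  slack <- L - sum(feat$len) - min_gap * (nrow(feat) + 1L)
  if (slack < 0L) stop("infeasible config: features exceed genome length")
  cuts <- sort(stats::runif(nrow(feat)))
  extra <- diff(c(0, cuts, 1)) * slack
  gaps <- min_gap + as.integer(floor(extra))
  pos <- 0L
  feat$start <- NA_integer_
  for (i in seq_len(nrow(feat))) {
    pos <- pos + gaps[i]
    feat$start[i] <- pos
    pos <- pos + feat$len[i]
  }

  # ORF coding sequences; genic TRs are planted inside a subset of them
  q_cod <- compensate_freqs(cfg$background_base_freqs)
  orf_rows <- feat[feat$kind == "orf", , drop = FALSE]
  orf_rows <- orf_rows[order(orf_rows$idx), , drop = FALSE]
  tr_orf_choice <- sample(seq_len(n_orfs), cfg$n_genic_trs)
  cds_list <- vector("list", n_orfs)
  genic_meta <- vector("list", cfg$n_genic_trs)
  for (oi in seq_len(n_orfs)) {
    n_cod <- orf_lens[oi] %/% 3L
    body <- sample_codons(n_cod - 2L, q_cod)
    gi <- match(oi, tr_orf_choice)
    if (!is.na(gi)) {
      sp <- genic_specs[[gi]]
      ck <- sp$copies * sp$k
      at <- sample(seq(2L, n_cod - 2L - ck - 1L), 1L)   # body codon index
      unit_cods <- split_codons(sp$stretch)
      body[at:(at + ck - 1L)] <- unit_cods
      # force non-extendable, flankless boundaries at both the nucleotide
      # level (no nt partial flank) and the amino-acid level (protein-side
      # detection then recovers exactly the planted interval)
      code <- Biostrings::GENETIC_CODE
      aa_last <- substr(sp$aa_unit, sp$k, sp$k)
      aa_first <- substr(sp$aa_unit, 1L, 1L)
      while (substr(body[at - 1L], 3L, 3L) ==
               substr(sp$nt_unit, sp$m, sp$m) ||
             code[[body[at - 1L]]] == aa_last) {
        body[at - 1L] <- sample_codons(1L, q_cod)
      }
      while (substr(body[at + ck], 1L, 1L) == substr(sp$nt_unit, 1L, 1L) ||
             code[[body[at + ck]]] == aa_first) {
        body[at + ck] <- sample_codons(1L, q_cod)
      }
      genic_meta[[gi]] <- list(orf = oi, codon_at = at + 1L, spec = sp)
    }
    cds_list[[oi]] <- paste(c("ATG", body, "TAA"), collapse = "")
  }

  # assemble the genome
  segs <- character(0)
  pos <- 0L
  orf_tab <- list()
  for (i in seq_len(nrow(feat))) {
    mid_gap <- pos + gaps[i] / 2
    segs <- c(segs, rand_seq(feat$start[i] - pos, local_freqs(cfg, mid_gap)))
    if (feat$kind[i] == "orf") {
      oi <- feat$idx[i]
      strand <- if (feat$start[i] < L / 2) "+" else "-"
      s <- if (strand == "+") cds_list[[oi]] else revcomp(cds_list[[oi]])
      orf_tab[[oi]] <- data.frame(
        contig_id = "synthetic", start = feat$start[i],
        end = feat$start[i] + feat$len[i], strand = strand,
        id = sprintf("orf%03d", oi), stringsAsFactors = FALSE)
      segs <- c(segs, s)
    } else {
      segs <- c(segs, inter_specs[[feat$idx[i]]]$stretch)
    }
    pos <- feat$start[i] + feat$len[i]
  }
  segs <- c(segs, rand_seq(L - pos, local_freqs(cfg, (pos + L) / 2)))
  gseq <- paste(segs, collapse = "")
  stopifnot(nchar(gseq) == L)
  orfs <- do.call(rbind, orf_tab)

  # truth rows (canonical form) ------------------------------------------
  x <- strsplit(gseq, "", fixed = TRUE)[[1]]
  fix_char <- function(i, forbidden, freqs) {
    # 1-based position i; resample until != forbidden
    while (x[i] == forbidden) {
      x[i] <<- sample(BASES, 1L, prob = freqs[BASES])
    }
  }
  truth_rows <- list()
  for (i in seq_len(nrow(feat))) {
    if (feat$kind[i] != "tr") next
    sp <- inter_specs[[feat$idx[i]]]
    st <- feat$start[i]
    lp <- nchar(sp$stretch)
    rho <- sp$unit
    fix_char(st, substr(rho, sp$m, sp$m), cfg$background_base_freqs)
    nxt <- substr(rho, (lp %% sp$m) + 1L, (lp %% sp$m) + 1L)
    fix_char(st + lp + 1L, nxt, cfg$background_base_freqs)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      contig_id = "synthetic", start = st, end = st + sp$copies * sp$m,
      unit = rho, copies = sp$copies, left_partial = 0L,
      right_partial = sp$right_partial, context = "intergenic",
      orf_id = NA_character_, aa_unit = NA_character_,
      aa_copies = NA_integer_, stringsAsFactors = FALSE)
  }
  for (gi in seq_len(cfg$n_genic_trs)) {
    meta <- genic_meta[[gi]]
    sp <- meta$spec
    orow <- orfs[orfs$id == sprintf("orf%03d", meta$orf), ]
    nt_from_cds <- 3L * (meta$codon_at - 1L)   # 0-based nt offset in cds
    lp <- sp$copies * sp$m
    if (orow$strand == "+") {
      st <- orow$start + nt_from_cds
      unit_fwd <- sp$nt_unit
    } else {
      st <- orow$end - nt_from_cds - lp
      unit_fwd <- revcomp(sp$nt_unit)
    }
    aa_root <- primitive_root(sp$aa_unit)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      contig_id = "synthetic", start = st, end = st + lp,
      unit = unit_fwd, copies = sp$copies, left_partial = 0L,
      right_partial = 0L, context = "genic", orf_id = orow$id,
      aa_unit = aa_root,
      aa_copies = sp$copies * (sp$k %/% nchar(aa_root)),
      stringsAsFactors = FALSE)
  }
  gseq <- paste(x, collapse = "")
  truth_regions <- do.call(rbind, truth_rows)
  truth_regions <- truth_regions[order(truth_regions$start), , drop = FALSE]
  rownames(truth_regions) <- NULL

  # certification: everything detectable must be a planted region --------
  genome <- genome_record("synthetic", gseq)
  det_cfg <- finder_config()
  key <- function(d) paste(d$start, d$end, d$unit, sep = "|")
  for (iter in 1:30) {
    found <- find_nt_tandem_repeats(genome, det_cfg)
    stray <- found[!key(found) %in% key(truth_regions), , drop = FALSE]
    if (nrow(stray) == 0L) break
    if (iter == 30L) stop("could not certify background repeat-free")
    x <- strsplit(genome$seq, "", fixed = TRUE)[[1]]
    for (s_i in seq_len(nrow(stray))) {
      r <- stray[s_i, ]
      ext <- c(max(1L, r$start - 2L), min(L, r$end + r$right_partial + 2L))
      # never touch planted regions or ORF frames; resample codon-aligned
      # inside ORFs, base-wise outside
      for (p in seq(ext[1], ext[2])) {
        p0 <- p - 1L
        in_truth <- any(truth_regions$start - 1L <= p0 &
                          truth_regions$end + truth_regions$right_partial +
                            1L > p0)
        if (in_truth) next
        o <- orfs[orfs$start < p & orfs$end >= p, , drop = FALSE]
        if (nrow(o) == 0L) {
          x[p] <- sample(BASES, 1L, prob = cfg$background_base_freqs[BASES])
        } else {
          cod0 <- (p0 - o$start[1]) %/% 3L       # codon index, fwd coords
          cs <- o$start[1] + 3L * cod0 + 1L
          first <- o$start[1] + 1L
          last <- o$end
          is_edge <- cs <= first + 2L || cs + 2L >= last - 2L
          if (is_edge) next                     # keep start/stop codons
          touches_truth <- any(truth_regions$start - 1L <= cs + 1L &
                                 truth_regions$end +
                                   truth_regions$right_partial + 1L > cs - 1L)
          if (touches_truth) next               # keep planted boundaries
          new_cod <- if (o$strand[1] == "+") {
            sample_codons(1L, q_cod)
          } else {
            revcomp(sample_codons(1L, q_cod))
          }
          x[cs:(cs + 2L)] <- strsplit(new_cod, "", fixed = TRUE)[[1]]
        }
      }
    }
    genome <- genome_record("synthetic", paste(x, collapse = ""))
  }

  proteins <- vapply(seq_len(nrow(orfs)), function(i) {
    o <- orfs[i, ]
    cds <- substr(genome$seq, o$start + 1L, o$end)
    if (o$strand == "-") cds <- revcomp(cds)
    aa <- translate_cds(cds)
    stopifnot(substr(aa, nchar(aa), nchar(aa)) == "*",
              !grepl("*", substr(aa, 1L, nchar(aa) - 1L), fixed = TRUE))
    substr(aa, 1L, nchar(aa) - 1L)
  }, character(1))
  names(proteins) <- orfs$id

  # variable-region mixtures
  mixtures <- stats::setNames(
    vector("list", nrow(truth_regions)),
    paste0(truth_regions$contig_id, ":", truth_regions$start, "-",
           truth_regions$end))
  var_pick <- if (cfg$n_variable_regions > 0L) {
    sample(seq_len(nrow(truth_regions)),
           min(cfg$n_variable_regions, nrow(truth_regions)))
  } else integer(0)
  for (i in seq_len(nrow(truth_regions))) {
    c0 <- truth_regions$copies[i]
    mixtures[[i]] <- if (i %in% var_pick) {
      stats::setNames(c(1 - cfg$unit_variation_prob,
                        cfg$unit_variation_prob), c(c0, c0 - 1L))
    } else {
      stats::setNames(1, as.character(c0))
    }
  }

  # self-validation of the emitted truth
  for (i in seq_len(nrow(truth_regions))) {
    validate_tr_region(truth_regions[i, ], genome)
  }

  list(genome = genome, orfs = orfs, proteins = proteins,
       truth = list(regions = truth_regions, mixtures = mixtures,
                    replichore_boundary = L %/% 2L, config = cfg))
}

#' Simulate reads from a synthetic genome
#'
#' Uniform read start positions. A read overlapping a variable region is
#' drawn from a molecule whose unit count at that region follows the
#' planted mixture; all other reads come from the reference molecule.
#' Orientation is random.
#'
#' @param sim Result of [generate_genome()].
#' @param cfg The [simulation_config] (read_length, n_reads,
#'   mixtures come from `sim$truth`).
#' @param seed Seed for the read stream (default `cfg$seed + 1`).
#' @return Named character vector of reads.
#' @export
generate_reads <- function(sim, cfg = sim$truth$config, seed = cfg$seed + 1L) {
  set.seed(seed)
  g <- sim$genome$seq
  L <- nchar(g)
  rl <- cfg$read_length
  tr <- sim$truth$regions
  variable <- vapply(sim$truth$mixtures, function(m) length(m) > 1L,
                     logical(1))
  mol_cache <- new.env()
  molecule <- function(ri, k) {
    keyk <- paste0(ri, "_", k)
    if (!is.null(mol_cache[[keyk]])) return(mol_cache[[keyk]])
    r <- tr[ri, ]
    mol <- paste0(substr(g, 1L, r$start), strrep(r$unit, k),
                  substr(g, r$end + 1L, L))
    mol_cache[[keyk]] <- mol
    mol
  }
  reads <- character(cfg$n_reads)
  for (i in seq_len(cfg$n_reads)) {
    s <- sample.int(L - rl + 1L, 1L) - 1L       # 0-based
    hit <- which(variable & tr$start < s + rl & tr$end > s)
    seqv <- if (length(hit) > 0L) {
      ri <- hit[1]
      mix <- sim$truth$mixtures[[ri]]
      k <- as.integer(sample(names(mix), 1L, prob = mix))
      mol <- molecule(ri, k)
      s2 <- min(s, nchar(mol) - rl)
      substr(mol, s2 + 1L, s2 + rl)
    } else {
      substr(g, s + 1L, s + rl)
    }
    if (stats::runif(1) < 0.5) seqv <- revcomp(seqv)
    reads[i] <- seqv
  }
  names(reads) <- sprintf("read%06d", seq_len(cfg$n_reads))
  reads
}

#' Generate a variant table with planted TR / non-TR substitution tallies
#'
#' Positions are sampled (without replacement) among genome positions whose
#' base equals the required reference, inside the planted TR regions for
#' the TR-class counts and outside them otherwise.
#'
#' @param sim Result of [generate_genome()].
#' @param cfg The [simulation_config].
#' @param seed Seed for the variant stream (default `cfg$seed + 2`).
#' @return data.frame in [read_variants_tsv()] layout (plus no label
#'   column: class membership is recoverable from the truth intervals).
#' @export
generate_variant_table <- function(sim, cfg = sim$truth$config,
                                   seed = cfg$seed + 2L) {
  set.seed(seed)
  g <- sim$genome$seq
  x <- strsplit(g, "", fixed = TRUE)[[1]]
  tr <- sim$truth$regions
  in_tr <- rep(FALSE, nchar(g))
  for (i in seq_len(nrow(tr))) {
    in_tr[(tr$start[i] + 1L):tr$end[i]] <- TRUE
  }
  plant <- function(spec, class_mask) {
    rows <- list()
    for (nm in names(spec)) {
      n_want <- spec[[nm]]
      if (n_want == 0L) next
      ref <- substr(nm, 1L, 1L)
      alt <- substr(nm, 3L, 3L)
      cand <- which(x == ref & class_mask)
      if (length(cand) < n_want) stop("not enough ", ref, " sites to plant")
      pos <- sample(cand, n_want)
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = sim$genome$id, position = pos - 1L, ref_base = ref,
        alt_base = alt, count = 1L, stringsAsFactors = FALSE)
    }
    rows
  }
  out <- do.call(rbind, c(plant(cfg$tr_snp_spec, in_tr),
                          plant(cfg$nontr_snp_spec, !in_tr)))
  if (is.null(out)) {
    out <- data.frame(contig_id = character(0), position = integer(0),
                      ref_base = character(0), alt_base = character(0),
                      count = integer(0))
  }
  out[order(out$position), , drop = FALSE]
}
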