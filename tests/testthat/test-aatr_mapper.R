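# A small constructed world: one forward ORF with an in-frame 18-nt repeat,
# used by several tests below.
build_orf_world <- function(unit = "GAAGTTCCTAAAGTTGAA", copies = 3L,
                            lead_codons = 10L, tail_codons = 10L,
                            offset_nt = 0L, strand = "+") {
  set.seed(101)
  lead <- paste(rep("GAC", lead_codons), collapse = "")
  tail <- paste(rep("CAC", tail_codons), collapse = "")
  pad <- random_dna(offset_nt, alphabet = c("C"))  # shifts the repeat frame
  cds <- paste0("ATG", lead, pad, strrep(unit, copies),
                if (offset_nt > 0) strrep("C", (3 - offset_nt %% 3) %% 3),
                tail, "TAA")
  stopifnot(nchar(cds) %% 3 == 0)
  flank5 <- "TTGTTGGTTGGA"
  flank3 <- "CCTTGGACGGCT"
  gseq <- if (strand == "+") paste0(flank5, cds, flank3) else
    paste0(flank5, revcomp(cds), flank3)
  g <- genome_record("ctg", gseq)
  orf <- data.frame(contig_id = "ctg", start = nchar(flank5),
                    end = nchar(flank5) + nchar(cds), strand = strand,
                    id = "orfA", stringsAsFactors = FALSE)
  r_start_cds <- 3L + 3L * lead_codons + offset_nt   # 0-based within cds
  r_start <- if (strand == "+") orf$start + r_start_cds else
    orf$end - r_start_cds - copies * nchar(unit)
  region <- data.frame(
    contig_id = "ctg", start = r_start, end = r_start + copies * nchar(unit),
    unit = if (strand == "+") unit else revcomp(unit),
    copies = copies, left_partial = 0L, right_partial = 0L,
    context = "unassigned", stringsAsFactors = FALSE)
  list(genome = g, orf = orf, region = region, cds = cds)
}

test_that("context classification: genic, boundary, intergenic, nested ties", {
  orfs <- data.frame(contig_id = "c", start = c(100L, 110L, 500L),
                     end = c(400L, 300L, 600L), strand = "+",
                     id = c("big", "small", "o3"), stringsAsFactors = FALSE)
  regions <- data.frame(contig_id = "c", start = c(120L, 50L, 420L),
                        end = c(180L, 110L, 480L),
                        unit = c("GATTAC", "AACCG", "TTAGGC"),
                        copies = c(10L, 12L, 10L), stringsAsFactors = FALSE)
  asg <- suppressMessages(classify_tr_context(regions, orfs))
  expect_equal(asg$context, c("genic", "boundary", "intergenic"))
  expect_equal(asg$orf_id[1], "small")   # smallest containing ORF wins
  expect_equal(asg$unit_div3, c(TRUE, FALSE, TRUE))
})

test_that("in-frame 18-nt unit translates to EVPKVE x3", {
  w <- build_orf_world()
  asg <- map_tr_to_orfs(w$region, w$orf, w$genome)
  expect_equal(asg$context, "genic")
  expect_true(asg$unit_div3)
  expect_equal(asg$frame_offset, 0L)
  expect_equal(asg$aa_unit, "EVPKVE")
  expect_equal(asg$aa_copies, 3L)
  expect_false(asg$anomalous_stop)
  # independent protein-side check
  prot <- translate_cds(w$cds)
  prot <- setNames(substr(prot, 1, nchar(prot) - 1), "orfA")
  aatrs <- find_aa_tandem_repeats(prot)
  expect_equal(nrow(aatrs), 1L)
  expect_true(asg$aa_unit %in% vapply(0:5, function(k) {
    paste0(substr(aatrs$unit, k + 1, 6), substr(aatrs$unit, 1, k))
  }, character(1)))
})

test_that("frame offset 1: aa unit is the translation of the 2-nt-rotated unit", {
  # a unit that is stop-free in every reading frame
  w <- build_orf_world(unit = "GAAGTTCCTCAAGTTCAA", copies = 4L,
                       offset_nt = 1L)
  asg <- map_tr_to_orfs(w$region, w$orf, w$genome)
  expect_equal(asg$frame_offset, 1L)
  unit <- w$region$unit
  rot2 <- paste0(substr(unit, 3, nchar(unit)), substr(unit, 1, 2))
  expect_equal(asg$aa_unit, translate_cds(rot2))
  expect_equal(asg$aa_copies, w$region$copies - 1L)
  # protein-side detection recovers a rotation-equivalent unit
  prot <- translate_cds(w$cds)
  prot <- setNames(substr(prot, 1, nchar(prot) - 1), "orfA")
  aatrs <- find_aa_tandem_repeats(prot)
  expect_equal(nrow(aatrs), 1L)
  k <- nchar(aatrs$unit)
  rots <- vapply(seq_len(k) - 1L, function(j) {
    paste0(substr(aatrs$unit, j + 1, k), substr(aatrs$unit, 1, j))
  }, character(1))
  expect_true(asg$aa_unit %in% rots)
})

test_that("reverse-strand ORFs map through the reverse complement", {
  w <- build_orf_world(strand = "-")
  asg <- map_tr_to_orfs(w$region, w$orf, w$genome)
  expect_equal(asg$context, "genic")
  expect_equal(asg$aa_unit, "EVPKVE")
  expect_equal(asg$aa_copies, 3L)
})

test_that("non-divisible unit lengths yield no aaTR", {
  unit20 <- "ACGGATTACCAGTCAGGAAT"
  g <- genome_record("c", paste0("TTGG", strrep(unit20, 3), "CCAA"))
  orfs <- data.frame(contig_id = "c", start = 0L, end = nchar(g$seq),
                     strand = "+", id = "o", stringsAsFactors = FALSE)
  region <- data.frame(contig_id = "c", start = 4L, end = 64L, unit = unit20,
                       copies = 3L, stringsAsFactors = FALSE)
  asg <- map_tr_to_orfs(region, orfs, g)
  expect_false(asg$unit_div3)
  expect_true(is.na(asg$aa_unit))
})

test_that("div3_fraction arithmetic and empty-class NA", {
  asg <- data.frame(
    context = rep("intergenic", 33),
    inside_frac = 0,
    unit_div3 = rep(c(TRUE, FALSE), c(7, 26)))
  expect_equal(div3_fraction(asg, "intergenic"), 21L)
  expect_true(is.na(div3_fraction(asg, "genic")))
})
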