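# Published per-genome statistics used as arithmetic inputs: primary
# columns (genome size, TR count/length, units, protein counts) from which
# the derived columns must be reproducible.
table1_primary <- data.frame(
  genome_id = c("Black", "Brown", "Green", "Lilac", "Orange", "Ochre",
                "Rose", "Red", "Sky", "Purple"),
  genome_size_bp = c(901883L, 937932L, 1094519L, 661708L, 974068L, 725447L,
                     623782L, 685823L, 763094L, 918293L),
  n_tr = c(56L, 50L, 76L, 61L, 53L, 23L, 20L, 23L, 32L, 66L),
  tr_total_len_bp = c(6128L, 5913L, 10223L, 6733L, 5675L, 2108L, 2132L,
                      3181L, 3889L, 6701L),
  total_units = c(289L, 259L, 379L, 299L, 246L, 92L, 98L, 173L, 206L, 326L),
  n_proteins = c(1292L, 1321L, 1517L, 825L, 1403L, 1170L, 937L, 1034L,
                 1138L, 1321L),
  n_tr_in_orf = c(23L, 23L, 30L, 28L, 20L, 11L, 12L, 12L, 11L, 23L),
  n_aatr_proteins = c(26L, 21L, 26L, 22L, 17L, 10L, 11L, 9L, 11L, 23L),
  pct_tr = c(0.68, 0.63, 0.93, 1.02, 0.58, 0.29, 0.34, 0.46, 0.51, 0.73),
  repeats_per_bp = c(0.0003204, 0.0002761, 0.0003463, 0.0004519, 0.0002525,
                     0.0001268, 0.0001571, 0.0002523, 0.0002700, 0.0003550),
  pct_aatr_proteins = c(2.01, 1.59, 1.71, 2.67, 1.21, 0.85, 1.17, 0.87,
                        0.97, 1.74),
  pct_tr_in_orf = c(41L, 46L, 39L, 46L, 38L, 48L, 60L, 52L, 34L, 35L))

test_that("derived summary columns reproduce published rows from primary columns", {
  for (i in seq_len(nrow(table1_primary))) {
    r <- table1_primary[i, ]
    expect_equal(round(100 * r$tr_total_len_bp / r$genome_size_bp, 2),
                 r$pct_tr)
    expect_equal(round(r$total_units / r$genome_size_bp, 7),
                 r$repeats_per_bp)
    expect_equal(round(100 * r$n_aatr_proteins / r$n_proteins, 2),
                 r$pct_aatr_proteins)
    expect_equal(as.integer(round(100 * r$n_tr_in_orf / r$n_tr)),
                 r$pct_tr_in_orf)
  }
})

test_that("summarize_genome computes the stated formulas on a constructed genome", {
  g <- genome_record("toy", strrep("GATC", 300))
  regions <- data.frame(contig_id = "toy", start = c(0L, 600L),
                        end = c(120L, 720L), unit = c("GATC", "ATCG"),
                        copies = c(30L, 30L), stringsAsFactors = FALSE)
  asg <- data.frame(context = c("genic", "intergenic"),
                    inside_frac = c(1, 0), unit_div3 = c(FALSE, FALSE))
  aatrs <- data.frame(protein_id = "p1", unit = "KE", copies = 10L)
  s <- summarize_genome(g, regions, asg, c(p1 = "KEKEKE", p2 = "PPP"), aatrs)
  expect_equal(s$n_tr, 2L)
  expect_equal(s$pct_tr, round(100 * 240 / 1200, 2))
  expect_equal(s$repeats_per_bp, round(60 / 1200, 7))
  expect_equal(s$pct_tr_in_orf, 50L)
  expect_equal(s$pct_aatr_proteins, 50)
  expect_equal(s$pct_intergenic_div3, 0L)

  s0 <- summarize_genome(g, regions[0, ], asg[0, ], c(p1 = "KEKEKE"),
                         aatrs[0, ])
  expect_equal(s0$n_tr, 0L)
  expect_true(is.na(s0$pct_tr_in_orf))
  expect_true(is.na(s0$pct_intergenic_div3))
})

test_that("aggregate rows: published sums and averages; single-row identity", {
  rows <- table1_primary
  rows$pct_intergenic_div3 <- NA_integer_
  agg <- aggregate_summaries(rows)
  expect_equal(agg$sum$n_tr, 460L)
  expect_equal(round(agg$average$pct_tr, 2), 0.62)
  expect_equal(agg$sum$n_proteins, 11958L)
  expect_equal(round(agg$average$genome_size_bp), 828655)

  one <- aggregate_summaries(rows[1, ])
  expect_equal(one$average$n_tr, one$sum$n_tr)
})

test_that("run_pipeline writes all stage outputs on a small synthetic world", {
  cfg <- simulation_config(genome_length = 40000L, n_intergenic_trs = 4L,
                           n_genic_trs = 4L, n_orfs = 8L,
                           orf_len_range = c(600L, 1200L),
                           n_reads = 300L, read_length = 400L,
                           n_variable_regions = 0L, seed = 91L)
  sim <- generate_genome(cfg)
  td <- withr::local_tempdir()
  fa <- file.path(td, "g.fa"); write_fasta(list(sim$genome), fa)
  gff <- file.path(td, "g.gff3"); write_gff3(sim$orfs, gff)
  faa <- file.path(td, "p.faa"); write_fasta(sim$proteins, faa)
  rds <- file.path(td, "r.fa"); write_fasta(generate_reads(sim), rds)
  vtsv <- file.path(td, "v.tsv")
  write_variants_tsv(generate_variant_table(sim), vtsv)
  out <- file.path(td, "out")
  res <- suppressMessages(
    run_pipeline(fa, gff, faa, reads = rds, variants = vtsv, outdir = out))
  for (f in c("regions.tsv", "regions.bed", "assignments.tsv", "aatrs.tsv",
              "skew.tsv", "composition.tsv", "summary.tsv", "census.tsv")) {
    expect_true(file.exists(file.path(out, f)), label = f)
  }
  expect_equal(res$summaries$n_tr, nrow(sim$truth$regions))
  expect_equal(res$summaries$genome_size_bp, 40000L)
  # pipeline determinism: byte-identical summary on a re-run
  out2 <- file.path(td, "out2")
  suppressMessages(run_pipeline(fa, gff, faa, reads = rds, variants = vtsv,
                                outdir = out2))
  expect_identical(readLines(file.path(out, "summary.tsv")),
                   readLines(file.path(out2, "summary.tsv")))
})

test_that("CLI subcommands scan and simulate work through tandemscope_main", {
  td <- withr::local_tempdir()
  g <- genome_record("g", strrep("GATTACA", 10))
  fa <- file.path(td, "g.fa")
  write_fasta(list(g), fa)
  out <- file.path(td, "r.tsv"); bed <- file.path(td, "r.bed")
  res <- suppressMessages(
    tandemscope_main(c("scan", "--fasta", fa, "--out", out, "--bed", bed)))
  expect_true(file.exists(out) && file.exists(bed))
  expect_equal(res$unit, "GATTACA")
})
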