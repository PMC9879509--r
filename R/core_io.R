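#' @importFrom stats setNames
#' @importFrom utils read.delim write.table
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")

#' Construct a genome record
#'
#' A genome record is the package's in-memory representation of one contig:
#' an id, an uppercase sequence over \{A,C,G,T,N\}, and a topology. All
#' coordinates used elsewhere in the package are 0-based half-open offsets
#' into \code{seq}.
#'
#' @param id Contig identifier (non-empty string).
#' @param seq Nucleotide sequence; uppercased on construction.
#' @param topology `"linear"` (default; the giant extrachromosomal elements
#'   this package targets are linear) or `"circular"`.
#' @return A list of class `genome_record` with fields `id`, `seq`,
#'   `topology`.
#' @export
genome_record <- function(id, seq, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  seq <- toupper(seq)
  bad <- setdiff(unique(strsplit(seq, "", fixed = TRUE)[[1]]), DNA_ALPHABET)
  if (length(bad) > 0L) {
    stop("record '", id, "': non-nucleotide characters: ",
         paste(bad, collapse = ", "))
  }
  structure(list(id = id, seq = seq, topology = topology),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp (%s)\n", x$id,
              format(nchar(x$seq), big.mark = ","), x$topology))
  invisible(x)
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param type `"dna"` returns a list of [genome_record]s (U and any
#'   non-\{A,C,G,T,N\} character are rejected); `"aa"` returns a named
#'   character vector of protein sequences (uppercased).
#' @return See `type`.
#' @export
read_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- if (type == "dna") {
    Biostrings::readBStringSet(path)  # BString so we can reject U ourselves
  } else {
    Biostrings::readBStringSet(path)
  }
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (type == "dna") {
    mapply(function(i, s) genome_record(i, s), ids, seqs,
           SIMPLIFY = FALSE, USE.NAMES = TRUE)
  } else {
    bad <- vapply(strsplit(seqs, "", fixed = TRUE),
                  function(ch) any(!ch %in% AA_ALPHABET), logical(1))
    if (any(bad)) {
      stop("record '", ids[which(bad)[1]],
           "': characters outside the amino-acid alphabet")
    }
    setNames(seqs, ids)
  }
}

#' Write sequences to FASTA (60-column wrapped)
#'
#' @param x A list of [genome_record]s or a named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  if (is.list(x) && all(vapply(x, inherits, logical(1), "genome_record"))) {
    x <- setNames(vapply(x, `[[`, character(1), "seq"),
                  vapply(x, `[[`, character(1), "id"))
  }
  stopifnot(is.character(x), !is.null(names(x)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(NULL)
}

#' Read reads from FASTA or FASTQ
#'
#' Qualities are ignored; the format is sniffed from the first character.
#'
#' @param path Path to a FASTA or FASTQ file.
#' @return Named character vector of read sequences (uppercased).
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readChar(path, 1L)
  set <- if (identical(first, "@")) {
    Biostrings::readDNAStringSet(path, format = "fastq")
  } else {
    Biostrings::readDNAStringSet(path)
  }
  setNames(toupper(as.character(set)), sub("\\s.*$", "", names(set)))
}

#' Read ORF features from GFF3
#'
#' CDS and gene records are kept. GFF3's 1-based inclusive coordinates are
#' converted to the package-internal 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `contig_id`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"`/`"-"`), `id`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("CDS", "gene", "ORF")
  gr <- gr[keep]
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) stop("GFF3: unknown strand")
  ids <- gr$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  ids[is.na(ids)] <- paste0("orf", seq_len(sum(is.na(ids))))
  out <- data.frame(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand,
    id = as.character(ids),
    stringsAsFactors = FALSE
  )
  if (any(out$end <= out$start)) stop("GFF3: end <= start")
  if (any(out$end - out$start < 6L)) stop("GFF3: ORF shorter than 6 bp")
  out[order(out$contig_id, out$start), , drop = FALSE]
}

#' Write ORF features to GFF3
#'
#' @param orfs data.frame as returned by [read_gff3()].
#' @param path Output path.
#' @export
write_gff3 <- function(orfs, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = orfs$contig_id,
    ranges = IRanges::IRanges(start = orfs$start + 1L, end = orfs$end),
    strand = orfs$strand
  )
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- orfs$id
  gr$source <- "tandemscope"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(NULL)
}

#' Read a variant table (TSV)
#'
#' Expected columns: contig, pos (1-based in the file), ref, alt, count.
#'
#' @param path Path to the TSV file.
#' @return data.frame with `contig_id`, `position` (0-based), `ref_base`,
#'   `alt_base`, `count`.
#' @export
read_variants_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  names(d) <- tolower(names(d))
  need <- c("contig", "pos", "ref", "alt", "count")
  if (!all(need %in% names(d))) {
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(
    contig_id = as.character(d$contig),
    position = as.integer(d$pos) - 1L,
    ref_base = toupper(d$ref),
    alt_base = toupper(d$alt),
    count = as.integer(d$count),
    stringsAsFactors = FALSE
  )
  stopifnot(all(out$ref_base %in% c("A", "C", "G", "T")),
            all(out$alt_base %in% c("A", "C", "G", "T")),
            all(out$ref_base != out$alt_base),
            all(out$count >= 1L))
  out
}

#' Write a variant table (TSV, 1-based positions)
#' @param variants data.frame as from [read_variants_tsv()].
#' @param path Output path.
#' @export
write_variants_tsv <- function(variants, path) {
  d <- data.frame(contig = variants$contig_id, pos = variants$position + 1L,
                  ref = variants$ref_base, alt = variants$alt_base,
                  count = variants$count)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Write TR regions as BED6 plus a TSV sidecar
#'
#' BED columns: chrom, start, end (0-based half-open), name
#' (`<unit>x<copies>`), score (copy number), strand (`+`). The sidecar TSV
#' carries the full region fields.
#'
#' @param regions data.frame of TR regions (see [find_nt_tandem_repeats()]).
#' @param path Output BED path.
#' @param tsv_path Sidecar path; default replaces/extends the BED suffix.
#' @export
write_regions_bed <- function(regions, path, tsv_path = NULL) {
  if (is.null(tsv_path)) tsv_path <- sub("(\\.bed)?$", ".tsv", path)[1]
  con <- file(path, "w")
  writeLines("#chrom\tstart\tend\tname\tscore\tstrand", con)
  if (nrow(regions) > 0L) {
    writeLines(sprintf("%s\t%d\t%d\t%sx%d\t%d\t+",
                       regions$contig_id, regions$start, regions$end,
                       regions$unit, regions$copies, regions$copies), con)
  }
  close(con)
  write.table(regions, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

# --- shared low-level sequence helpers ---------------------------------------

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a nucleotide string
#' @param seq Character scalar over \{A,C,G,T,N\}.
#' @return Character scalar.
#' @export
revcomp <- function(seq) {
  if (nchar(seq) == 0L) return(seq)
  # plain-string implementation: called in tight per-read loops where the
  # DNAString round-trip would dominate
  comp <- chartr("ACGTN", "TGCAN", seq)
  intToUtf8(rev(utf8ToInt(comp)))
}

#' Translate a codon-aligned coding sequence with the standard genetic code
#' @param cds Character scalar; length must be divisible by 3.
#' @return Amino-acid string; stop codons become `*`.
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return("")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aa)) stop("untranslatable codon (ambiguous base?)")
  paste(aa, collapse = "")
}
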