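## I/O for the standard formats the aligner touches: FASTA/FASTQ in,
## GTF annotation in/out, SAM out (spliced CIGARs with N ops), and the
## plain-TSV ground-truth sidecar used by the simulator and evaluator.
## Internal coordinates are 0-based half-open everywhere; conversion to
## 1-based happens only here, at the SAM/GTF boundary.

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and any non-ACGT letter (IUPAC degenerate codes)
#' is mapped to N.
#'
#' @param path path to a FASTA file.
#' @return named character vector of chromosome sequences.
#' @export
read_fasta <- function(path) {
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop("FASTA format error in '", path,
                                          "': ", conditionMessage(e)))
  if (length(ss) == 0) stop("FASTA format error in '", path, "': no records")
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGT]", "N", seqs)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs))) stop("duplicate sequence names in ", path)
  if (any(nchar(seqs) == 0)) stop("empty sequence record in ", path)
  seqs
}

#' Read long reads from FASTA or FASTQ
#'
#' The format is auto-detected from the first character of the file
#' (`>` = FASTA, `@` = FASTQ).
#'
#' @param path path to the read file.
#' @return data.frame with columns `id`, `seq` and `qual` (NA when FASTA).
#' @export
read_reads <- function(path) {
  first <- substr(readLines(path, n = 1L), 1, 1)
  if (identical(first, ">")) {
    ss <- Biostrings::readDNAStringSet(path)
    qual <- rep(NA_character_, length(ss))
  } else if (identical(first, "@")) {
    nlines <- length(readLines(path, warn = FALSE))
    if (nlines %% 4 != 0)
      stop("FASTQ format error in '", path, "': truncated record (",
           nlines, " lines)")
    parsed <- tryCatch({
      ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                         with.qualities = TRUE)
      list(ss = ss, qual = as.character(S4Vectors::mcols(ss)$qualities))
    }, error = function(e) stop("FASTQ format error in '", path, "': ",
                                conditionMessage(e)))
    ss <- parsed$ss
    qual <- parsed$qual
    bad <- which(nchar(qual) != Biostrings::width(ss))
    if (length(bad))
      stop("FASTQ format error in '", path, "': seq/qual length mismatch ",
           "for record ", bad[1])
  } else {
    stop("cannot detect read format of '", path, "' (expected '>' or '@')")
  }
  seqs <- gsub("[^ACGT]", "N", toupper(as.character(ss)))
  data.frame(id = sub("\\s.*$", "", names(ss)), seq = unname(seqs),
             qual = unname(qual), stringsAsFactors = FALSE)
}

#' Read a gene annotation from GTF
#'
#' Only `exon` feature lines are used; each must carry `gene_id` and
#' `transcript_id` attributes (Ensembl dialect). 1-based inclusive GTF
#' coordinates are converted to the internal 0-based half-open convention.
#'
#' @param path path to a GTF file.
#' @return object of class `gene_annotation`: a list with an `exons`
#'   data.frame (gene_id, transcript_id, chrom, strand, start, end).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("GTF format error: no exon features in ", path)
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
    stop("GTF format error: exon line missing transcript_id in ", path)
  ex <- data.frame(
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  gene_annotation(ex)
}

#' Construct a gene annotation object
#'
#' @param exons data.frame with columns gene_id, transcript_id, chrom,
#'   strand, start, end (0-based half-open).
#' @return `gene_annotation` object.
#' @export
gene_annotation <- function(exons) {
  stopifnot(all(c("gene_id", "transcript_id", "chrom", "strand",
                  "start", "end") %in% names(exons)))
  exons <- exons[order(exons$transcript_id, exons$start), ]
  rownames(exons) <- NULL
  for (tx in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tx, ]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stop("overlapping exons within transcript ", tx)
  }
  structure(list(exons = exons), class = "gene_annotation")
}

#' Write a gene annotation as GTF
#'
#' @param annotation a `gene_annotation` object.
#' @param path output path.
#' @export
write_gtf <- function(annotation, path) {
  ex <- annotation$exons
  lines <- sprintf(
    '%s\tsplicewalk\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id, ex$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Write a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write reads as FASTQ
#'
#' @param reads data.frame with `id`, `seq` and optional `qual` columns.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual
  if (is.null(qual)) qual <- rep(NA_character_, nrow(reads))
  qual <- ifelse(is.na(qual),
                 vapply(nchar(reads$seq),
                        function(n) strrep("I", n), character(1)),
                 qual)
  writeLines(rbind(paste0("@", reads$id), reads$seq, "+", qual), path)
  invisible(path)
}

## SAM ----------------------------------------------------------------------

#' Write spliced alignments as SAM
#'
#' Introns are encoded as N CIGAR operations, secondary alignments carry
#' flag 0x100, the alignment score is emitted in the AS tag, and unplaced
#' reads appear as unmapped records (flag 0x4) so read accounting stays
#' closed. POS is converted from the internal 0-based convention to 1-based.
#'
#' @param alignments data.frame with columns qname, flag, chrom, pos
#'   (0-based), mapq, cigar, seq, and optionally qual and score.
#' @param reference named character vector of reference sequences (for the
#'   `@SQ` header lines).
#' @param path output path.
#' @export
write_sam <- function(alignments, reference, path) {
  a <- alignments
  mapped <- bitwAnd(a$flag, 4L) == 0L
  qlen <- vapply(a$cigar, cigar_qlen, numeric(1))
  bad <- mapped & qlen != nchar(a$seq)
  if (any(bad))
    stop("internal consistency error: CIGAR query length != read length for ",
         paste(a$qname[bad], collapse = ", "))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference), nchar(reference)),
           "@PG\tID:splicewalk\tPN:splicewalk")
  qual <- if (is.null(a$qual)) rep(NA_character_, nrow(a)) else a$qual
  qual <- ifelse(is.na(qual) | qual == "", "*", qual)
  score <- if (is.null(a$score)) rep(NA_real_, nrow(a)) else a$score
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                  a$qname, a$flag,
                  ifelse(mapped, a$chrom, "*"),
                  ifelse(mapped, a$pos + 1L, 0L),
                  ifelse(mapped, a$mapq, 0L),
                  ifelse(mapped, a$cigar, "*"),
                  a$seq, qual,
                  ifelse(is.na(score), "", sprintf("\tAS:i:%d",
                                                   as.integer(score))))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file into a data.frame
#'
#' Parses the subset of SAM emitted by [write_sam()] (and compatible files):
#' mandatory fields plus the AS tag. POS is converted back to 0-based.
#'
#' @param path path to a SAM file.
#' @return data.frame with columns qname, flag, chrom, pos, mapq, cigar,
#'   seq, qual, score.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0)
    return(data.frame(qname = character(0), flag = integer(0),
                      chrom = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      seq = character(0), qual = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  as_field <- vapply(fields, function(f) {
    tag <- grep("^AS:i:", f[-(1:11)], value = TRUE)
    if (length(tag)) as.numeric(sub("^AS:i:", "", tag[1])) else NA_real_
  }, numeric(1))
  data.frame(
    qname = vapply(fields, `[`, character(1), 1),
    flag = as.integer(vapply(fields, `[`, character(1), 2)),
    chrom = vapply(fields, `[`, character(1), 3),
    pos = as.integer(vapply(fields, `[`, character(1), 4)) - 1L,
    mapq = as.integer(vapply(fields, `[`, character(1), 5)),
    cigar = vapply(fields, `[`, character(1), 6),
    seq = vapply(fields, `[`, character(1), 10),
    qual = vapply(fields, `[`, character(1), 11),
    score = as_field, stringsAsFactors = FALSE)
}

## Ground-truth TSV ---------------------------------------------------------

#' Write simulator ground-truth records
#'
#' One row per read: read_id, transcript_id, chrom, strand, the ordered
#' comma-separated genomic exon intervals covered by the read
#' (`start-end`, 0-based half-open), and the genome-oriented truth CIGAR
#' recording the exact simulated read-to-genome alignment.
#'
#' @param truth data.frame with columns read_id, transcript_id, chrom,
#'   strand, exons (character), cigar (character).
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  write.table(truth[, c("read_id", "transcript_id", "chrom", "strand",
                        "exons", "cigar")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read simulator ground-truth records
#'
#' @param path path to a truth TSV written by [write_truth()].
#' @return data.frame of truth records.
#' @export
read_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(read_id = "character",
                            transcript_id = "character",
                            chrom = "character", strand = "character",
                            exons = "character", cigar = "character"))
}

## Parse the `exons` field of one truth record into a start/end data.frame.
truth_exons <- function(exons_field) {
  parts <- strsplit(exons_field, ",", fixed = TRUE)[[1]]
  se <- do.call(rbind, strsplit(parts, "-", fixed = TRUE))
  data.frame(start = as.integer(se[, 1]), end = as.integer(se[, 2]))
}
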