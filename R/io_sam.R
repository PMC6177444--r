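# SAM / FASTQ interop for the simulated alignments. The in-memory alignment
# table (one row per read end; see align_reads) is the package's working
# representation; SAM is the interchange surface for users with real data.

#' Write an alignment table as SAM
#'
#' @param aln Alignment data.frame from [align_reads()].
#' @param path Output SAM path.
#' @param seq_id,ref_len Sequence-dictionary entry; default from `aln`
#'   attributes.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, seq_id = attr(aln, "seq_id"),
                      ref_len = attr(aln, "ref_len")) {
  if (is.null(seq_id)) seq_id <- "chr6"
  if (is.null(ref_len)) ref_len <- max(aln$pos + aln$mapped_len, na.rm = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", seq_id, as.integer(ref_len))), con)
  # paired-end flags: 0x1 paired, 0x2 proper, 0x10/0x20 strand, 0x40/0x80 mate
  flag <- ifelse(aln$mapped,
                 ifelse(aln$mate == 1L, 99L, 147L),
                 ifelse(aln$mate == 1L, 77L, 141L))
  pos1 <- ifelse(aln$mapped, as.integer(aln$pos) + 1L, 0L)
  rname <- ifelse(aln$mapped, seq_id, "*")
  seq_out <- aln$seq
  qual <- strrep("I", nchar(aln$seq))
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                     aln$qname, flag, rname, pos1,
                     ifelse(aln$mapped, 60L, 0L), aln$cigar, seq_out, qual),
             con)
  invisible(path)
}

#' Read a SAM/BAM file into the package's alignment table
#'
#' Uses Rsamtools (SAM files are converted to BAM in a temporary directory
#' first). Only the fields the callers consume are kept; CIGAR soft clips are
#' parsed into mapped length and clip lengths.
#'
#' @param path SAM or BAM file.
#' @return Alignment data.frame in the [align_reads()] layout.
#' @export
read_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading SAM/BAM requires the Rsamtools package")
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, file.path(tempdir(), basename(path)),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "cigar", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  cig <- as.character(x$cigar)
  ops <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))
  parse1 <- function(o) {
    if (length(o) == 0) return(c(0L, 0L, 0L))
    len <- as.integer(sub("[A-Z=]$", "", o))
    op <- sub("^[0-9]+", "", o)
    lc <- if (op[1] == "S") len[1] else 0L
    rc <- if (length(op) > 1 && op[length(op)] == "S") len[length(op)] else 0L
    c(sum(len[op %in% c("M", "=", "X")]), lc, rc)
  }
  pm <- t(vapply(ops, parse1, integer(3)))
  flag <- x$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  data.frame(qname = x$qname,
             mate = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L),
             hap = NA_integer_,
             strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
             mapped = mapped,
             pos = ifelse(mapped, x$pos - 1, NA_real_),
             mapped_len = pm[, 1], left_clip = pm[, 2], right_clip = pm[, 3],
             cigar = cig, seq = as.character(x$seq),
             stringsAsFactors = FALSE)
}

#' Write simulated read pairs as FASTQ
#'
#' Mate 2 is written reverse-complemented (sequenced orientation). Base
#' qualities are constant placeholders.
#'
#' @param reads data.frame from [simulate_reads()].
#' @param path_r1,path_r2 Output FASTQ paths for the two mates.
#' @return `c(path_r1, path_r2)`, invisibly.
#' @export
write_fastq <- function(reads, path_r1, path_r2) {
  q <- strrep("I", nchar(reads$read1[1]))
  w <- function(path, ids, seqs) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", q), con)
  }
  w(path_r1, paste0(reads$qname, "/1"), reads$read1)
  w(path_r2, paste0(reads$qname, "/2"), revcomp(reads$read2))
  invisible(c(path_r1, path_r2))
}

#' Write ground truth as JSON
#' @param truth A `sim_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(seq_id = truth$seq_id, type = truth$spec$type,
         zygosity = truth$spec$zygosity, junctions = truth$junctions,
         errors = truth$errors),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
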