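#' @importFrom stats rbinom rpois runif rnorm setNames median
#' @importFrom utils read.table write.table head tail
NULL

# ---------------------------------------------------------------------------
# Coordinate conventions
#
# All coordinates inside the package are 0-based half-open on a named
# sequence, so length(region) == end - start with no off-by-one bookkeeping.
# Published breakpoint tables in this field usually print 1-based position
# pairs whose difference equals the printed event length; those convert to
# the internal convention with start = printed left, end = printed right
# (the difference, and hence the length, is preserved). `dialect` arguments
# on readers make that conversion explicit.
# ---------------------------------------------------------------------------

#' Create a genomic region
#'
#' Regions are 0-based half-open intervals on a named sequence; this is the
#' universal coordinate carrier used across the package.
#'
#' @param seq_id Sequence (chromosome/contig) name.
#' @param start,end Integer 0-based half-open bounds, `0 <= start <= end`.
#' @return An object of class `genome_region`.
#' @examples
#' r <- region("chr6", 100, 250)
#' region_length(r)  # 150
#' @export
region <- function(seq_id, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || start > end)
    stop("invalid region: need 0 <= start <= end, got [", start, ", ", end, ")")
  structure(list(seq_id = as.character(seq_id), start = start, end = end),
            class = "genome_region")
}

#' Length of a genomic region
#' @param r A `genome_region`.
#' @return `end - start`.
#' @export
region_length <- function(r) r$end - r$start

#' @export
print.genome_region <- function(x, ...) {
  cat(sprintf("<region %s:[%s, %s) len=%s>\n", x$seq_id,
              format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE),
              format(region_length(x), scientific = FALSE)))
  invisible(x)
}

#' Convert published 1-based breakpoint position pairs to internal regions
#'
#' Breakpoint tables in the literature print deletions/duplications as
#' 1-based coordinate pairs whose difference equals the event length.
#' That dialect maps onto the internal 0-based half-open convention with
#' the printed numbers unchanged.
#'
#' @param seq_id Sequence name.
#' @param left_pos,right_pos Printed 1-based positions.
#' @param dialect `"pair_diff"` (the only supported published dialect) or
#'   `"zero_half_open"` for already-internal coordinates.
#' @return A `genome_region`.
#' @export
region_from_published <- function(seq_id, left_pos, right_pos,
                                  dialect = c("pair_diff", "zero_half_open")) {
  dialect <- match.arg(dialect)
  region(seq_id, left_pos, right_pos)
}

# ---------------------------------------------------------------------------
# Gene model
# ---------------------------------------------------------------------------

#' Construct a gene model
#'
#' A gene model is an ordered set of non-overlapping exons (1-based contiguous
#' exon indices) with per-exon coding lengths, used to annotate CNVs by exon
#' span, reading-frame effect, and protein domain.
#'
#' @param exons data.frame with columns `exon_index`, `start`, `end`, and
#'   optionally `coding_len` (coding bases per exon). Coordinates are 0-based
#'   half-open. If `coding_len` is absent, whole exon lengths are used as
#'   coding lengths and a warning is raised.
#' @param gene,transcript,strand,seq_id Gene annotation metadata.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(exons, gene = "GENE", transcript = NA_character_,
                       strand = "+", seq_id = "chr6") {
  if (!is.data.frame(exons) || nrow(exons) == 0)
    stop("gene model needs at least one exon")
  req <- c("exon_index", "start", "end")
  if (!all(req %in% names(exons)))
    stop("exon table must have columns: ", paste(req, collapse = ", "))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (!identical(as.integer(exons$exon_index), seq_len(nrow(exons))))
    stop("exon indices must be 1-based, contiguous, and ordered by coordinate")
  if (any(exons$end <= exons$start))
    stop("exons must have positive length")
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("exons overlap or are unsorted")
  if (is.null(exons$coding_len)) {
    warning("gene model lacks coding-length annotations; using full exon lengths")
    exons$coding_len <- exons$end - exons$start
  }
  rownames(exons) <- NULL
  structure(list(gene = gene, transcript = transcript, strand = strand,
                 seq_id = seq_id, exons = exons),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s (%s) %s exons on %s [%s], span [%s, %s)>\n",
              x$gene, x$transcript, nrow(x$exons), x$seq_id, x$strand,
              format(min(x$exons$start), scientific = FALSE),
              format(max(x$exons$end), scientific = FALSE)))
  invisible(x)
}

#' Read a gene model and a repeat track from BED-dialect files
#'
#' The gene model file is a headerless TSV with columns
#' `chrom, start, end, exon_index[, coding_len]` (0-based half-open starts,
#' BED-style). The repeat track is BED6 plus a 7th column giving the repeat
#' class (`SINE`, `LINE`, `LTR`, `DNA`, `Low_complexity`); the BED name field
#' carries the RepeatMasker-style family label (e.g. `L1PA2`, `AluY`).
#'
#' @param gene_model_path Path to the exon BED file.
#' @param repeat_track_path Optional path to the repeat BED file (`NULL` to
#'   skip).
#' @param gene,transcript,strand Gene metadata passed to [gene_model()].
#' @return A list with elements `model` (a `gene_model`) and `repeats`
#'   (data.frame with `seq_id, start, end, family, class`, or `NULL`).
#' @export
load_region_tracks <- function(gene_model_path, repeat_track_path = NULL,
                               gene = "GENE", transcript = NA_character_,
                               strand = "+") {
  ex <- read_bedlike(gene_model_path,
                     c("chrom", "start", "end", "exon_index", "coding_len"),
                     min_cols = 4)
  if (nrow(ex) == 0) stop("empty exon file: ", gene_model_path)
  model <- gene_model(ex[, setdiff(names(ex), "chrom"), drop = FALSE],
                      gene = gene, transcript = transcript, strand = strand,
                      seq_id = ex$chrom[1])
  repeats <- if (!is.null(repeat_track_path)) read_repeat_track(repeat_track_path)
  list(model = model, repeats = repeats)
}

#' Read a RepeatMasker-style repeat track
#' @param path BED6+class file (see [load_region_tracks()]).
#' @return data.frame with `seq_id, start, end, family, class`.
#' @export
read_repeat_track <- function(path) {
  rt <- read_bedlike(path, c("chrom", "start", "end", "name", "score",
                             "strand", "class"), min_cols = 4)
  if (nrow(rt) > 0 && any(rt$end <= rt$start))
    stop("repeat track contains zero/negative-length elements")
  data.frame(seq_id = rt$chrom, start = rt$start, end = rt$end,
             family = rt$name,
             class = if (is.null(rt$class)) NA_character_ else rt$class,
             stringsAsFactors = FALSE)
}

# shared headerless-TSV reader with line-numbered parse errors
read_bedlike <- function(path, col_names, min_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(col_names))),
                           col_names))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < min_cols)
  if (length(bad))
    stop("malformed line ", bad[1], " in ", path, ": expected >= ", min_cols,
         " tab-separated fields, found ", nf[bad[1]])
  ncol_use <- min(max(nf), length(col_names))
  out <- as.data.frame(do.call(rbind, lapply(parts, function(p)
    p[seq_len(ncol_use)])), stringsAsFactors = FALSE)
  names(out) <- col_names[seq_len(ncol_use)]
  for (nm in intersect(c("start", "end", "exon_index", "coding_len", "score"),
                       names(out))) {
    v <- suppressWarnings(as.numeric(out[[nm]]))
    if (anyNA(v) && !anyNA(out[[nm]]))
      stop("malformed line ", which(is.na(v))[1], " in ", path,
           ": non-numeric '", nm, "' field")
    out[[nm]] <- v
  }
  out
}

# ---------------------------------------------------------------------------
# CNV annotation against the gene model
# ---------------------------------------------------------------------------

#' Exon span of a CNV region
#'
#' Returns the smallest and largest exon indices whose exons intersect the
#' region, or an empty span for purely intronic/intergenic regions.
#'
#' @param cnv_region A `genome_region` on the model's sequence.
#' @param model A `gene_model`.
#' @return Integer vector `c(first, last)`, or `integer(0)` if no exon is hit.
#' @export
exon_span <- function(cnv_region, model) {
  stopifnot(inherits(cnv_region, "genome_region"), inherits(model, "gene_model"))
  if (!identical(cnv_region$seq_id, model$seq_id))
    stop("region is on '", cnv_region$seq_id, "' but the gene model is on '",
         model$seq_id, "'")
  ex <- model$exons
  hit <- which(ex$start < cnv_region$end & ex$end > cnv_region$start)
  if (length(hit) == 0) return(integer(0))
  c(min(ex$exon_index[hit]), max(ex$exon_index[hit]))
}

#' Reading-frame effect of an exon-span deletion/duplication
#'
#' A CNV removing (or duplicating) whole exons is in-frame iff the summed
#' coding length of the spanned exons is divisible by three.
#'
#' @param span Integer `c(first, last)` inclusive exon-index range.
#' @param model A `gene_model`.
#' @return `"in_frame"` or `"out_of_frame"`.
#' @export
frame_effect <- function(span, model) {
  stopifnot(inherits(model, "gene_model"))
  if (length(span) == 0) stop("frame_effect needs a non-empty exon span")
  span <- range(as.integer(span))
  n <- nrow(model$exons)
  if (span[1] < 1 || span[2] > n)
    stop("exon span [", span[1], ", ", span[2], "] exceeds the model's ",
         n, " exons")
  idx <- seq(span[1], span[2])
  total <- sum(model$exons$coding_len[match(idx, model$exons$exon_index)])
  if (total %% 3 == 0) "in_frame" else "out_of_frame"
}

#' Default protein-domain map for the LAMA2-style 65-exon gene
#'
#' N-terminal domain = exons 1-30; G domain = exons 46-63. The two ranges do
#' not tile all 65 exons; unassigned exons return no domain. Override with a
#' custom data.frame for other genes.
#'
#' @return data.frame with columns `domain, exon_first, exon_last`.
#' @export
default_domain_map <- function() {
  data.frame(domain = c("N-terminal", "G domain"),
             exon_first = c(1L, 46L), exon_last = c(30L, 63L),
             stringsAsFactors = FALSE)
}

#' Domains intersected by an exon span
#'
#' @param span Integer `c(first, last)` inclusive exon range (non-empty).
#' @param domains Domain map as from [default_domain_map()]; ranges must not
#'   overlap.
#' @return Character vector of domain names (possibly several, possibly none).
#' @export
domain_assignment <- function(span, domains = default_domain_map()) {
  if (length(span) == 0) stop("domain_assignment needs a non-empty exon span")
  span <- range(as.integer(span))
  ov <- domains$exon_first <= span[2] & domains$exon_last >= span[1]
  domains$domain[ov]
}
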