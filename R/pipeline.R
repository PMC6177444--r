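# End-to-end composite pipeline over one test/control sample pair.

#' Run the composite CNV pipeline on a sample pair
#'
#' Read-depth calling against the control, soft-clip extraction, clustering
#' and consensus assembly, contig remapping, reconciliation into base-precise
#' calls, and junction annotation.
#'
#' @param test_aln,control_aln Alignment data.frames ([align_reads()] or
#'   [read_alignments()]).
#' @param reference Reference sequence string.
#' @param model A `gene_model` for windows and exon annotation.
#' @param repeats Optional repeat track.
#' @param del_threshold,dup_threshold Depth-ratio thresholds (defaults 0.75
#'   and 1.25).
#' @param min_clip_len,jitter,min_support Soft-clip parameters (defaults 20,
#'   5, 3).
#' @param exon_pad,tile Depth-window scheme (defaults 50, 500).
#' @param complex_gap DEL-NML-DEL retained-segment ceiling (default 5000).
#' @return list: `profile`, `depth_calls`, `clips`, `clusters`,
#'   `candidates`, `calls` (resolved CNV calls), `junctions` (annotated
#'   junction records for base-precise calls).
#' @export
run_pipeline <- function(test_aln, control_aln, reference, model,
                         repeats = NULL, del_threshold = 0.75,
                         dup_threshold = 1.25, min_clip_len = 20,
                         jitter = 5, min_support = 3, exon_pad = 50,
                         tile = 500, complex_gap = 5000) {
  region_len <- nchar(reference)
  windows <- make_depth_windows(model, region_len, exon_pad = exon_pad,
                                tile = tile)
  profile <- compute_depth_profile(test_aln, control_aln, windows)
  profile <- call_windows(profile, del_threshold, dup_threshold)
  depth_calls <- merge_calls(profile, model, region_len)
  clips <- extract_softclips(test_aln, min_clip_len = min_clip_len)
  clusters <- cluster_and_assemble(clips, jitter = jitter,
                                   min_support = min_support)
  candidates <- call_sv_candidates(clusters, reference,
                                   min_clip_len = min_clip_len)
  calls <- resolve_breakpoints(depth_calls, candidates, model,
                               complex_gap = complex_gap)
  prec <- which(calls$resolution == "base_precise")
  ann <- lapply(prec, function(i)
    tryCatch(annotate_junction(calls[i, ], reference, repeats = repeats),
             error = function(e) NULL))
  ok <- !vapply(ann, is.null, TRUE)
  # adopt the annotator's left-aligned breakpoints in the call table
  for (k in which(ok)) {
    i <- prec[k]
    calls$start[i] <- min(ann[[k]]$left, ann[[k]]$right)
    calls$end[i] <- max(ann[[k]]$left, ann[[k]]$right)
  }
  junctions <- do.call(rbind, ann[ok])
  list(profile = profile, depth_calls = depth_calls, clips = clips,
       clusters = clusters, candidates = candidates, calls = calls,
       junctions = junctions)
}

#' Export resolved CNV calls as VCF-style symbolic records
#'
#' Minimal VCF 4.2 text with symbolic `<DEL>`/`<DUP>` ALT alleles, `END` and
#' `SVLEN` info, junction contig and resolution level in INFO.
#'
#' @param calls Resolved call data.frame.
#' @param path Output path.
#' @param seq_id Sequence name.
#' @param reference Optional reference string for REF bases (else `N`).
#' @return `path`, invisibly.
#' @export
write_cnv_vcf <- function(calls, path, seq_id = "chr6", reference = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Tandem duplication\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=RES,Number=1,Type=String,Description=\"Resolution\">",
    "##INFO=<ID=CONTIG,Number=1,Type=String,Description=\"Junction contig\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(calls))) {
    pos1 <- as.integer(calls$start[i])  # base before the event, 1-based
    refb <- if (!is.null(reference) && pos1 >= 1)
      subseq0(reference, pos1 - 1, 1) else "N"
    svlen <- as.integer(calls$end[i] - calls$start[i])
    info <- sprintf("END=%d;SVLEN=%d;RES=%s", as.integer(calls$end[i]),
                    if (calls$type[i] == "DEL") -svlen else svlen,
                    calls$resolution[i])
    if (!is.na(calls$contig[i]))
      info <- paste0(info, ";CONTIG=", calls$contig[i])
    writeLines(sprintf("%s\t%d\t.\t%s\t<%s>\t.\tPASS\t%s", seq_id, pos1,
                       refb, calls$type[i], info), con)
  }
  invisible(path)
}
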