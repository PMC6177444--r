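# ---------------------------------------------------------------------------
# Synthetic data: reference, engineered CNVs, paired-end reads, alignments.
#
# The generator reproduces the statistical structure the pipeline assumes:
# a gene-scale reference, deletions / tandem duplications / DEL-NML-DEL
# events whose junctions carry a specified signature (microhomology,
# insertion, or blunt ends), 150-bp paired-end reads at configurable depth,
# and alignments emitted analytically from known read provenance (with
# aligner-like maximal extension of the mapped segment, so soft-clip
# boundaries land where a real aligner would put them).
# ---------------------------------------------------------------------------

BASES <- c("A", "C", "G", "T")

subseq0 <- function(x, start0, len) substring(x, start0 + 1, start0 + len)

set_base0 <- function(x, pos0, base) {
  substr(x, pos0 + 1, pos0 + 1) <- base
  x
}

pick_other <- function(avoid) sample(setdiff(BASES, avoid), 1)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a random reference sequence
#'
#' I.i.d. bases with expected GC content `gc_fraction`; deterministic under
#' a fixed seed.
#'
#' @param length Sequence length (>= 1000).
#' @param gc_fraction Target GC fraction in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @return A single character string over `ACGT`.
#' @export
make_reference <- function(length, gc_fraction = 0.42, seed = 1) {
  if (length < 1000) stop("reference length must be >= 1000")
  if (is.na(gc_fraction) || gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must be in [0, 1]")
  set.seed(seed)
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
}

# --- CNV specifications -----------------------------------------------------

#' Junction signatures for engineered CNVs
#'
#' Exactly one signature kind is attached to each engineered junction:
#' `sig_microhomology()` (1-10 bp shared sequence at both breakpoint ends),
#' `sig_insertion()` (1-328 bp between the breakpoints; random sequence or
#' templated from a reference source region), or `sig_blunt()`.
#'
#' @param seq Signature sequence (microhomology or insertion bases). For a
#'   random insertion, `seq` may be omitted and `len` given instead.
#' @param len Length of a random insertion to draw.
#' @param source Optional `c(start, end)` 0-based half-open reference region
#'   a templated insertion is copied from.
#' @return A signature object used by [cnv_spec()].
#' @name junction_signatures
NULL

#' @rdname junction_signatures
#' @export
sig_microhomology <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) < 1 || nchar(seq) > 10)
    stop("microhomology length must be 1-10 bp")
  structure(list(kind = "microhomology", seq = seq), class = "junction_sig")
}

#' @rdname junction_signatures
#' @export
sig_insertion <- function(seq = NULL, len = NULL, source = NULL) {
  if (is.null(seq) && is.null(source) && is.null(len))
    stop("give an insertion sequence, a length, or a source region")
  if (!is.null(seq)) seq <- toupper(seq)
  structure(list(kind = "insertion", seq = seq, len = len, source = source),
            class = "junction_sig")
}

#' @rdname junction_signatures
#' @export
sig_blunt <- function() structure(list(kind = "blunt"), class = "junction_sig")

#' Specify an engineered copy-number event
#'
#' @param type `"DEL"`, `"TANDEM_DUP"`, or `"DEL_NML_DEL"` (two deletions
#'   separated by a retained segment).
#' @param segments A list of one (DEL, TANDEM_DUP) or two (DEL_NML_DEL)
#'   `c(start, end)` 0-based half-open segments.
#' @param zygosity `"het"` or `"hom"`.
#' @param signature One `junction_sig`, or a list of one per junction.
#' @param errors Optional data.frame of planted near-breakpoint substitutions
#'   with columns `junction` (index), `offset` (mutant-haplotype offset from
#'   the junction point; negative = left flank), `alt` (substituted base).
#' @return A `cnv_spec` object for [apply_cnv()].
#' @export
cnv_spec <- function(type = c("DEL", "TANDEM_DUP", "DEL_NML_DEL"),
                     segments, zygosity = c("het", "hom"),
                     signature = sig_blunt(), errors = NULL) {
  type <- match.arg(type)
  zygosity <- match.arg(zygosity)
  if (!is.list(segments) || is.numeric(segments)) segments <- list(segments)
  n_j <- if (type == "DEL_NML_DEL") 2L else 1L
  if (length(segments) != n_j)
    stop(type, " needs ", n_j, " segment(s), got ", length(segments))
  if (inherits(signature, "junction_sig")) signature <- rep(list(signature), n_j)
  if (length(signature) != n_j)
    stop("need one junction signature per junction")
  segs <- lapply(segments, function(s) {
    s <- as.numeric(s)
    if (length(s) != 2 || s[1] < 0 || s[2] <= s[1]) stop("bad segment: ", toString(s))
    s
  })
  if (n_j == 2 && segs[[2]][1] <= segs[[1]][2])
    stop("DEL_NML_DEL segments must be disjoint and ordered")
  structure(list(type = type, segments = segs, zygosity = zygosity,
                 signature = signature, errors = errors),
            class = "cnv_spec")
}

# Edit the reference so the junction joining ref position x (left side ends
# just before x) to ref position y (right side starts at y) carries exactly
# the requested signature, then return the edited reference plus the
# insertion sequence to place at the junction (if any). The same (x, y)
# algebra covers deletions (x = seg start, y = seg end) and tandem
# duplications (x = seg end, y = seg start): in both cases the junction
# placement is ambiguous by i bases iff ref[x..x+i) == ref[y..y+i).
plant_junction <- function(ref, x, y, sig) {
  L <- nchar(ref)
  ins <- NULL
  if (sig$kind == "microhomology") {
    m <- sig$seq; k <- nchar(m)
    if (x + k >= L || y + k >= L) stop("microhomology would run off the reference")
    substr(ref, x + 1, x + k) <- m
    substr(ref, y + 1, y + k) <- m
    if (subseq0(ref, x + k, 1) == subseq0(ref, y + k, 1))
      ref <- set_base0(ref, y + k, pick_other(subseq0(ref, x + k, 1)))
    if (x > 0 && y > 0 && subseq0(ref, x - 1, 1) == subseq0(ref, y - 1, 1))
      ref <- set_base0(ref, y - 1, pick_other(subseq0(ref, x - 1, 1)))
  } else if (sig$kind == "insertion") {
    ins <- sig$seq
    if (is.null(ins)) {
      if (!is.null(sig$source)) {
        ins <- subseq0(ref, sig$source[1], sig$source[2] - sig$source[1])
      } else {
        ins <- paste(sample(BASES, sig$len, replace = TRUE), collapse = "")
      }
    }
    if (nchar(ins) < 1 || nchar(ins) > 328)
      stop("insertion length must be 1-328 bp")
    first <- substr(ins, 1, 1); last <- substr(ins, nchar(ins), nchar(ins))
    if (subseq0(ref, x, 1) == first) ref <- set_base0(ref, x, pick_other(first))
    if (y > 0 && subseq0(ref, y - 1, 1) == last)
      ref <- set_base0(ref, y - 1, pick_other(last))
  } else { # blunt
    if (subseq0(ref, x, 1) == subseq0(ref, y, 1))
      ref <- set_base0(ref, y, pick_other(subseq0(ref, x, 1)))
    if (x > 0 && y > 0 && subseq0(ref, x - 1, 1) == subseq0(ref, y - 1, 1))
      ref <- set_base0(ref, y - 1, pick_other(subseq0(ref, x - 1, 1)))
  }
  list(ref = ref, ins = if (is.null(ins)) "" else ins)
}

#' Engineer a CNV into a reference sequence
#'
#' Edits the reference so each junction carries exactly the requested
#' signature (for microhomology, both breakpoint ends are made to share the
#' sequence before the event is applied), builds the mutant haplotype(s), and
#' records the ground-truth junctions and the haplotype-to-reference block
#' map used by [align_reads()].
#'
#' @param reference Reference sequence (character string).
#' @param spec A [cnv_spec()].
#' @param seq_id Sequence name carried into truth records.
#' @param seed Seed for random insertion sequences and cap-base edits.
#' @return A `sim_truth` list: `reference` (edited), `haplotypes` (list of
#'   `list(seq, blocks)`; two entries, the second being the unedited-copy
#'   haplotype for het events), `junctions` (truth table with left/right
#'   breakpoints, signature, mutant junction position), `spec`, `seq_id`.
#' @export
apply_cnv <- function(reference, spec, seq_id = "chr6", seed = 1) {
  stopifnot(inherits(spec, "cnv_spec"))
  set.seed(seed)
  L <- nchar(reference)
  for (s in spec$segments)
    if (s[2] > L) stop("segment [", s[1], ", ", s[2], ") outside the reference")

  # junction geometry: (x, y) per junction in reference coordinates
  geom <- switch(spec$type,
    DEL = list(c(spec$segments[[1]][1], spec$segments[[1]][2])),
    TANDEM_DUP = list(c(spec$segments[[1]][2], spec$segments[[1]][1])),
    DEL_NML_DEL = lapply(spec$segments, function(s) c(s[1], s[2])))

  ins_seqs <- character(length(geom))
  for (i in seq_along(geom)) {
    pl <- plant_junction(reference, geom[[i]][1], geom[[i]][2], spec$signature[[i]])
    reference <- pl$ref
    ins_seqs[i] <- pl$ins
  }

  # mutant haplotype + block map (hap_start, len, ref_start; NA = insertion)
  blocks <- list(); mutant_parts <- character(0)
  add_block <- function(len, ref_start) {
    hs <- sum(vapply(blocks, `[[`, 0, "len"))
    blocks[[length(blocks) + 1]] <<- list(hap_start = hs, len = len,
                                          ref_start = ref_start)
  }
  hap_junctions <- numeric(length(geom))
  if (spec$type == "DEL") {
    s <- spec$segments[[1]]
    hap_junctions[1] <- s[1]
    mutant_parts <- c(subseq0(reference, 0, s[1]), ins_seqs[1],
                      subseq0(reference, s[2], L - s[2]))
    add_block(s[1], 0)
    if (nchar(ins_seqs[1])) add_block(nchar(ins_seqs[1]), NA)
    add_block(L - s[2], s[2])
  } else if (spec$type == "TANDEM_DUP") {
    s <- spec$segments[[1]]
    hap_junctions[1] <- s[2]
    mutant_parts <- c(subseq0(reference, 0, s[2]), ins_seqs[1],
                      subseq0(reference, s[1], L - s[1]))
    add_block(s[2], 0)
    if (nchar(ins_seqs[1])) add_block(nchar(ins_seqs[1]), NA)
    add_block(L - s[1], s[1])
  } else {
    s1 <- spec$segments[[1]]; s2 <- spec$segments[[2]]
    hap_junctions[1] <- s1[1]
    hap_junctions[2] <- s1[1] + nchar(ins_seqs[1]) + (s2[1] - s1[2])
    mutant_parts <- c(subseq0(reference, 0, s1[1]), ins_seqs[1],
                      subseq0(reference, s1[2], s2[1] - s1[2]), ins_seqs[2],
                      subseq0(reference, s2[2], L - s2[2]))
    add_block(s1[1], 0)
    if (nchar(ins_seqs[1])) add_block(nchar(ins_seqs[1]), NA)
    add_block(s2[1] - s1[2], s1[2])
    if (nchar(ins_seqs[2])) add_block(nchar(ins_seqs[2]), NA)
    add_block(L - s2[2], s2[2])
  }
  mutant <- paste(mutant_parts, collapse = "")

  # planted near-breakpoint substitutions (mutant haplotype only)
  err_truth <- NULL
  if (!is.null(spec$errors)) {
    ee <- spec$errors
    ref_pos <- alt <- ref_base <- character(0); hp <- numeric(0)
    for (i in seq_len(nrow(ee))) {
      jidx <- if (is.null(ee$junction)) 1L else ee$junction[i]
      pos <- hap_junctions[jidx] +
        (if (ee$offset[i] >= 0) nchar(ins_seqs[jidx]) else 0) + ee$offset[i]
      old <- subseq0(mutant, pos, 1)
      mutant <- set_base0(mutant, pos, ee$alt[i])
      g <- geom[[jidx]]
      lb <- if (spec$type == "TANDEM_DUP") g[2] else g[1]
      rb <- if (spec$type == "TANDEM_DUP") g[1] else g[2]
      rp <- if (ee$offset[i] < 0) lb + ee$offset[i] else rb + ee$offset[i]
      hp <- c(hp, pos); ref_pos <- c(ref_pos, rp)
      ref_base <- c(ref_base, old); alt <- c(alt, ee$alt[i])
    }
    err_truth <- data.frame(hap_pos = hp, ref_pos = as.numeric(ref_pos),
                            ref = ref_base, alt = alt, stringsAsFactors = FALSE)
  }

  jt <- data.frame(
    junction = seq_along(geom),
    left = vapply(geom, function(g) min(g), 0),
    right = vapply(geom, function(g) max(g), 0),
    orientation = if (spec$type == "TANDEM_DUP") "tandem-dup" else "deletion",
    signature = vapply(spec$signature, `[[`, "", "kind"),
    sig_seq = vapply(seq_along(geom), function(i) {
      sg <- spec$signature[[i]]
      if (sg$kind == "microhomology") sg$seq
      else if (sg$kind == "insertion") ins_seqs[i] else ""
    }, ""),
    hap_junction = hap_junctions,
    stringsAsFactors = FALSE)

  blk <- do.call(rbind, lapply(blocks, as.data.frame))
  hap1 <- list(seq = mutant, blocks = blk)
  ref_hap <- list(seq = reference,
                  blocks = data.frame(hap_start = 0, len = L, ref_start = 0))
  haps <- if (spec$zygosity == "hom") list(hap1, hap1) else list(hap1, ref_hap)

  structure(list(reference = reference, haplotypes = haps, junctions = jt,
                 errors = err_truth, spec = spec, seq_id = seq_id),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth %s %s (%s): %d junction(s), ref %d bp, mutant %d bp>\n",
              x$spec$type, x$seq_id, x$spec$zygosity, nrow(x$junctions),
              nchar(x$reference), nchar(x$haplotypes[[1]]$seq)))
  invisible(x)
}

# --- read simulation --------------------------------------------------------

#' Simulate paired-end reads from a sample's haplotypes
#'
#' Fragments are drawn uniformly along each haplotype (het samples: the two
#' haplotypes are sampled 50/50), with normal fragment lengths and i.i.d.
#' per-base substitution errors. Expected pair count is
#' `mean_depth * length / (2 * read_len)` (Poisson).
#'
#' @param truth A `sim_truth` from [apply_cnv()], or a bare character string
#'   (treated as a single CNV-free haplotype, e.g. the control sample).
#' @param mean_depth Mean sequencing depth (>0).
#' @param read_len Read length (default 150 bp).
#' @param fragment_mean,fragment_sd Fragment-length distribution.
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer RNG seed; fixed seed gives identical reads.
#' @return data.frame with one row per pair: `qname, hap, frag_start,
#'   frag_len, read1, read2` (both reads stored in haplotype-forward
#'   orientation; mate 2 was sequenced as the reverse complement).
#' @export
simulate_reads <- function(truth, mean_depth = 100, read_len = 150,
                           fragment_mean = 400, fragment_sd = 60,
                           error_rate = 0.001, seed = 1) {
  if (is.character(truth))
    truth <- list(haplotypes = list(list(
      seq = truth, blocks = data.frame(hap_start = 0, len = nchar(truth),
                                       ref_start = 0))))
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (read_len > fragment_mean) stop("read_len must be <= fragment_mean")
  set.seed(seed)
  haps <- truth$haplotypes
  out <- list()
  for (h in seq_along(haps)) {
    hl <- nchar(haps[[h]]$seq)
    if (fragment_mean > hl) stop("fragment_mean longer than haplotype")
    lambda <- mean_depth * hl / (2 * read_len * length(haps))
    n <- rpois(1, lambda)
    if (n == 0) next
    fl <- pmin(pmax(round(rnorm(n, fragment_mean, fragment_sd)), read_len), hl)
    fs <- floor(runif(n, 0, hl - fl + 1))
    r1 <- substring(haps[[h]]$seq, fs + 1, fs + read_len)
    r2 <- substring(haps[[h]]$seq, fs + fl - read_len + 1, fs + fl)
    out[[h]] <- data.frame(
      qname = sprintf("sim_h%d_%06d", h, seq_len(n)), hap = h,
      frag_start = fs, frag_len = fl, read1 = r1, read2 = r2,
      stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, out)
  rownames(reads) <- NULL
  # i.i.d. substitution errors over all sequenced bases
  total <- 2 * nrow(reads) * read_len
  n_err <- rbinom(1, total, error_rate)
  if (n_err > 0) {
    idx <- sample.int(total, n_err)
    for (ix in idx) {
      row <- (ix - 1) %/% (2 * read_len) + 1
      off <- (ix - 1) %% (2 * read_len)
      col <- if (off < read_len) "read1" else "read2"
      p <- off %% read_len + 1
      old <- substr(reads[[col]][row], p, p)
      substr(reads[[col]][row], p, p) <- pick_other(old)
    }
  }
  attr(reads, "read_len") <- read_len
  reads
}

# --- analytic alignment -----------------------------------------------------

#' Align simulated reads using known provenance
#'
#' Reads fully inside a reference-collinear block are placed full-length with
#' no clip; junction-spanning reads are anchored on the block with the larger
#' overlap, the mapped segment is extended maximally while read bases match
#' the reference (so microhomology shifts the clip boundary exactly as a real
#' aligner would), and the remainder is soft-clipped. Reads landing entirely
#' inside inserted (non-reference) sequence are flagged unmapped.
#'
#' @param reads data.frame from [simulate_reads()].
#' @param truth The `sim_truth` the reads were simulated from (provides the
#'   block map and the reference).
#' @param min_anchor Minimum mapped anchor for a junction-spanning read;
#'   reads with a shorter best anchor are emitted fully clipped on one side.
#' @return data.frame with one row per read end: `qname, mate, hap, strand,
#'   mapped, pos` (0-based mapped start), `mapped_len, left_clip, right_clip,
#'   cigar, seq`.
#' @export
align_reads <- function(reads, truth, min_anchor = 20) {
  ref <- truth$reference
  rl <- attr(reads, "read_len")
  if (is.null(rl)) rl <- nchar(reads$read1[1])
  ends <- rbind(
    data.frame(qname = reads$qname, mate = 1L, hap = reads$hap,
               a = reads$frag_start, seq = reads$read1,
               strand = "+", stringsAsFactors = FALSE),
    data.frame(qname = reads$qname, mate = 2L, hap = reads$hap,
               a = reads$frag_start + reads$frag_len - rl, seq = reads$read2,
               strand = "-", stringsAsFactors = FALSE))
  ends$b <- ends$a + rl

  n <- nrow(ends)
  pos <- rep(NA_real_, n); mlen <- rep(NA_integer_, n)
  lclip <- rep(0L, n); rclip <- rep(0L, n); mapped <- rep(FALSE, n)

  for (h in unique(ends$hap)) {
    blk <- truth$haplotypes[[h]]$blocks
    hi <- which(ends$hap == h)
    a <- ends$a[hi]; b <- ends$b[hi]
    # per block overlap
    ov <- sapply(seq_len(nrow(blk)), function(i)
      pmax(0, pmin(b, blk$hap_start[i] + blk$len[i]) - pmax(a, blk$hap_start[i])))
    if (is.null(dim(ov))) ov <- matrix(ov, nrow = length(hi))
    ref_blk <- !is.na(blk$ref_start)
    ov_ref <- ov; ov_ref[, !ref_blk] <- 0
    anchor <- max.col(ov_ref, ties.method = "first")
    anchor_ov <- ov_ref[cbind(seq_along(hi), anchor)]
    full <- anchor_ov == rl
    # fast path: read fully inside one reference-collinear block
    fi <- hi[full]
    if (length(fi)) {
      ai <- anchor[full]
      pos[fi] <- blk$ref_start[ai] + (ends$a[fi] - blk$hap_start[ai])
      mlen[fi] <- rl; mapped[fi] <- TRUE
    }
    # junction-spanning (or insertion-contained) reads
    for (j in which(!full)) {
      i <- hi[j]
      if (anchor_ov[j] == 0) next  # wholly inside inserted sequence: unmapped
      bi <- anchor[j]
      oa <- max(a[j], blk$hap_start[bi])
      ob <- min(b[j], blk$hap_start[bi] + blk$len[bi])
      ref0 <- blk$ref_start[bi] + (oa - blk$hap_start[bi])
      # maximal extension of the mapped segment against the reference
      lo <- oa; hi2 <- ob
      while (hi2 < b[j]) {
        rp <- ref0 + (hi2 - oa)
        if (rp >= nchar(ref)) break
        if (substr(ends$seq[i], hi2 - a[j] + 1, hi2 - a[j] + 1) !=
            subseq0(ref, rp, 1)) break
        hi2 <- hi2 + 1
      }
      while (lo > a[j]) {
        rp <- ref0 - (oa - lo) - 1
        if (rp < 0) break
        if (substr(ends$seq[i], lo - a[j], lo - a[j]) != subseq0(ref, rp, 1)) break
        lo <- lo - 1
      }
      if (hi2 - lo < min_anchor) next  # anchor too short to place: unmapped
      pos[i] <- ref0 - (oa - lo)
      mlen[i] <- as.integer(hi2 - lo)
      lclip[i] <- as.integer(lo - a[j])
      rclip[i] <- as.integer(b[j] - hi2)
      mapped[i] <- TRUE
    }
  }

  cig <- ifelse(mapped,
                paste0(ifelse(lclip > 0, paste0(lclip, "S"), ""),
                       mlen, "M",
                       ifelse(rclip > 0, paste0(rclip, "S"), "")),
                "*")
  out <- data.frame(qname = ends$qname, mate = ends$mate, hap = ends$hap,
                    strand = ends$strand, mapped = mapped, pos = pos,
                    mapped_len = mlen, left_clip = lclip, right_clip = rclip,
                    cigar = cig, seq = ends$seq, stringsAsFactors = FALSE)
  out <- out[order(out$pos, out$qname, out$mate, na.last = TRUE), ]
  rownames(out) <- NULL
  attr(out, "seq_id") <- if (!is.null(truth$seq_id)) truth$seq_id else "chr6"
  attr(out, "ref_len") <- nchar(ref)
  out
}

#' Simulate and align a control sample from the unedited reference
#'
#' Convenience wrapper mirroring a reference-DNA control: reads are simulated
#' from the reference itself and aligned trivially.
#'
#' @inheritParams simulate_reads
#' @param reference Reference sequence string.
#' @param seq_id Sequence name for the alignment attributes.
#' @return Alignment data.frame as from [align_reads()].
#' @export
simulate_control <- function(reference, mean_depth = 100, read_len = 150,
                             fragment_mean = 400, fragment_sd = 60,
                             error_rate = 0.001, seed = 1, seq_id = "chr6") {
  tr <- structure(list(
    reference = reference, seq_id = seq_id,
    haplotypes = list(list(seq = reference,
                           blocks = data.frame(hap_start = 0,
                                               len = nchar(reference),
                                               ref_start = 0)))),
    class = "sim_truth")
  rd <- simulate_reads(tr, mean_depth, read_len, fragment_mean, fragment_sd,
                       error_rate, seed)
  align_reads(rd, tr)
}

#' Synthetic gene model spanning a reference
#'
#' Evenly spaced exons with varying coding lengths, for driving the depth
#' caller's window scheme on simulated data.
#'
#' @param region_len Reference length the model must fit inside.
#' @param n_exons Number of exons.
#' @param seq_id Sequence name.
#' @param margin Exon-free margin at each end of the region.
#' @param seed RNG seed for coding lengths.
#' @return A `gene_model`.
#' @export
synthetic_gene_model <- function(region_len, n_exons = 10, seq_id = "chr6",
                                 margin = 1000, seed = 1) {
  set.seed(seed)
  coding <- sample(c(60, 90, 99, 120, 150, 153, 180, 210), n_exons,
                   replace = TRUE)
  starts <- round(seq(margin, region_len - margin - max(coding),
                      length.out = n_exons))
  gene_model(data.frame(exon_index = seq_len(n_exons), start = starts,
                        end = starts + coding, coding_len = coding),
             gene = "SYNTH", seq_id = seq_id)
}
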