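# ---------------------------------------------------------------------------
# Sequence-level junction characterization and mechanism classification.
#
# A resolved junction contig is compared with the reference flanks abutting
# the two breakpoints. The maximal prefix of the contig matching the left
# flank and the maximal suffix matching the right flank either overlap
# (microhomology: the shared sequence, within which the true breakpoint is
# inherently ambiguous), abut exactly (blunt ends), or leave a gap
# (an inserted sequence, random or templated from elsewhere in the region).
# The mutational mechanism is then assigned by priority rules: homologous
# repeat pair -> repeat-mediated (NAHR-like); complex DEL-NML-DEL ->
# FoSTeS/MMBIR; templated insertion -> serial replication stalling; random
# insertion or blunt ends -> NHEJ; microhomology -> NHEJ or MMBIR.
# ---------------------------------------------------------------------------

# boundary of a matched flank: the end of the outermost perfect-match run of
# length >= min_run whose cumulative identity from position 1 stays at or
# above min_ident (falls back to earlier runs, so a chance match beyond the
# junction cannot drag the boundary outward)
flank_boundary <- function(m, min_run, min_ident) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  ok <- which(r$values & r$lengths >= min_run)
  if (length(ok) == 0) return(NA_integer_)
  cum <- cumsum(m)
  for (k in rev(ok)) {
    j <- ends[k]
    if (cum[j] / j >= min_ident) return(j)
  }
  NA_integer_
}

#' Characterize a junction's sequence signature
#'
#' `left_ref` must be the reference sequence aligned at the contig's start
#' (the flank running up to and beyond the left breakpoint) and `right_ref`
#' the reference aligned at the contig's end. The match boundaries are found
#' as the last/first positions inside perfect-match runs of at least
#' `min_run` bases, which makes the junction call robust to isolated
#' sequencing or near-breakpoint errors in the outer flanks while keeping
#' the signature itself a maximal exact match.
#'
#' @param contig Junction-spanning consensus sequence.
#' @param left_ref Reference sequence aligned at the contig start.
#' @param right_ref Reference sequence aligned at the contig end.
#' @param min_run Minimum perfect-match run length anchoring a flank
#'   (default 10 bp).
#' @param min_flank_identity Required identity of each matched flank
#'   (default 0.95); below this the junction is considered mis-resolved.
#' @return A list: `kind` (`"microhomology"`/`"insertion"`/`"blunt"`),
#'   `seq` (signature sequence, `""` for blunt), `split_left` (contig index
#'   of the last left-matching base, P), `split_right` (contig index of the
#'   first right-matching base, S).
#' @export
characterize_junction <- function(contig, left_ref, right_ref, min_run = 10,
                                  min_flank_identity = 0.95) {
  n <- nchar(contig)
  cv <- utf8ToInt(contig)
  lv <- utf8ToInt(left_ref)
  rv <- utf8ToInt(right_ref)
  kl <- min(n, length(lv))
  ml <- cv[seq_len(kl)] == lv[seq_len(kl)]
  P <- flank_boundary(ml, min_run, min_flank_identity)
  if (is.na(P))
    stop("contig does not match the left reference flank at >= ",
         min_flank_identity * 100, "% identity (mis-resolved junction?)")
  kr <- min(n, length(rv))
  mr <- rev(cv)[seq_len(kr)] == rev(rv)[seq_len(kr)]  # from the contig end
  Send <- flank_boundary(mr, min_run, min_flank_identity)
  if (is.na(Send))
    stop("contig does not match the right reference flank at >= ",
         min_flank_identity * 100, "% identity (mis-resolved junction?)")
  S <- n - Send + 1
  if (P >= S) {
    list(kind = "microhomology", seq = substr(contig, S, P),
         split_left = P, split_right = S)
  } else if (P + 1 == S) {
    list(kind = "blunt", seq = "", split_left = P, split_right = S)
  } else {
    list(kind = "insertion", seq = substr(contig, P + 1, S - 1),
         split_left = P, split_right = S)
  }
}

#' Locate the origin of an inserted junction sequence
#'
#' Insertions shorter than 5 bp are treated as random filler without a
#' search. Longer insertions are searched (at >= `min_identity`) first
#' within `window` of either breakpoint, then across the whole reference;
#' a hit means the insertion was templated from that source.
#'
#' @param insertion Inserted sequence.
#' @param reference Reference sequence string.
#' @param left,right Breakpoint positions (0-based).
#' @param window Breakpoint-proximal search window (default 2000 bp).
#' @param min_identity Minimum identity of the template match (default 0.90).
#' @return list with `origin` (`"templated"`/`"random"`) and, when
#'   templated, `source_start` (0-based) and `source_near_breakpoint`.
#' @export
locate_insertion_origin <- function(insertion, reference, left, right,
                                    window = 2000, min_identity = 0.90) {
  len <- nchar(insertion)
  if (len < 5) return(list(origin = "random"))
  mm <- floor((1 - min_identity) * len)
  L <- nchar(reference)
  search_in <- function(s0, s1) {
    s0 <- max(0, s0); s1 <- min(L, s1)
    if (s1 - s0 < len) return(NULL)
    hits <- Biostrings::matchPattern(insertion,
                                     Biostrings::DNAString(subseq0(reference, s0, s1 - s0)),
                                     max.mismatch = mm, with.indels = FALSE)
    if (length(hits) == 0) return(NULL)
    BiocGenerics::start(hits)[1] - 1 + s0
  }
  near <- search_in(left - window, left + window)
  if (is.null(near)) near <- search_in(right - window, right + window)
  if (!is.null(near))
    return(list(origin = "templated", source_start = near,
                source_near_breakpoint = TRUE))
  far <- search_in(0, L)
  if (!is.null(far))
    return(list(origin = "templated", source_start = far,
                source_near_breakpoint = FALSE))
  list(origin = "random")
}

#' Detect single-nucleotide changes near a resolved breakpoint
#'
#' Scans up to `scan_window` bases of contig flank on each side of the
#' junction against the reference and reports substitutions as
#' `(position, ref, alt)`. Changes present in an optional polymorphism list
#' are excluded (stand-in for a population-database absence check).
#'
#' @param contig Junction contig.
#' @param junction_at Contig index of the last base left of the junction.
#' @param reference Reference string.
#' @param x_end Reference position the contig's left part ends at (exclusive).
#' @param y_start Reference position the contig's right part starts at.
#' @param ins_len Length of any inserted sequence at the junction (skipped
#'   when mapping the right flank onto the reference).
#' @param scan_window Flank scan width (default 150 bp each side).
#' @param polymorphisms Optional data.frame with `pos` (0-based) and `alt`.
#' @return data.frame `pos` (0-based reference), `ref`, `alt`, `side`.
#' @export
detect_breakpoint_errors <- function(contig, junction_at, reference,
                                     x_end, y_start, ins_len = 0,
                                     scan_window = 150,
                                     polymorphisms = NULL) {
  out <- list()
  n <- nchar(contig)
  # left flank: contig[i] <-> reference[x_end - (junction_at - i) - 1]
  l0 <- max(1, junction_at - scan_window + 1)
  if (junction_at >= l0) {
    ref_from <- x_end - (junction_at - l0) - 1
    if (ref_from >= 0) {
      cpart <- substr(contig, l0, junction_at)
      rpart <- subseq0(reference, ref_from, nchar(cpart))
      mis <- which(utf8ToInt(cpart) != utf8ToInt(rpart))
      if (length(mis))
        out$left <- data.frame(pos = ref_from + mis - 1,
                               ref = substring(rpart, mis, mis),
                               alt = substring(cpart, mis, mis),
                               side = "left", stringsAsFactors = FALSE)
    }
  }
  # right flank: skip the inserted bases, then contig aligns at y_start
  r0 <- junction_at + ins_len + 1
  r1 <- min(n, r0 + scan_window - 1)
  if (r1 >= r0) {
    cpart <- substr(contig, r0, r1)
    if (y_start + nchar(cpart) <= nchar(reference)) {
      rpart <- subseq0(reference, y_start, nchar(cpart))
      mis <- which(utf8ToInt(cpart) != utf8ToInt(rpart))
      if (length(mis))
        out$right <- data.frame(pos = y_start + mis - 1,
                                ref = substring(rpart, mis, mis),
                                alt = substring(cpart, mis, mis),
                                side = "right", stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(pos = numeric(0), ref = character(0),
                      alt = character(0), side = character(0),
                      stringsAsFactors = FALSE)
  if (!is.null(polymorphisms) && nrow(res))
    res <- res[!paste(res$pos, res$alt) %in%
                 paste(polymorphisms$pos, polymorphisms$alt), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate breakpoint ends with repeat elements
#'
#' Each breakpoint is intersected with the repeat track. When both ends lie
#' in repeats of the same class and the reference is supplied, the two
#' repeat copies are locally aligned; an identity block of at least
#' `min_identity_len` at `min_identity` sets the homologous-pair flag
#' (the NAHR-like configuration).
#'
#' @param left,right Breakpoint positions (0-based).
#' @param repeats Repeat track data.frame (`start, end, family, class`) or
#'   `NULL`.
#' @param reference Optional reference string for the identity check.
#' @param min_identity_len Minimum identity-block length (default 100 bp).
#' @param min_identity Minimum identity within the block (default 0.95).
#' @return list `left` and `right` (data.frames of overlapping repeats) and
#'   `homologous_pair` flag.
#' @export
repeat_overlap <- function(left, right, repeats, reference = NULL,
                           min_identity_len = 100, min_identity = 0.95) {
  none <- data.frame(family = character(0), class = character(0),
                     stringsAsFactors = FALSE)
  if (is.null(repeats) || nrow(repeats) == 0)
    return(list(left = none, right = none, homologous_pair = FALSE))
  hit <- function(p) {
    i <- which(repeats$start <= p & repeats$end > p)
    data.frame(family = repeats$family[i], class = repeats$class[i],
               start = repeats$start[i], end = repeats$end[i],
               stringsAsFactors = FALSE)
  }
  lh <- hit(left); rh <- hit(right)
  pair <- FALSE
  shared <- intersect(lh$class, rh$class)
  if (length(shared) && !is.null(reference)) {
    a <- lh[lh$class == shared[1], ][1, ]
    b <- rh[rh$class == shared[1], ][1, ]
    sa <- subseq0(reference, a$start, a$end - a$start)
    sb <- subseq0(reference, b$start, b$end - b$start)
    al <- Biostrings::pairwiseAlignment(sa, sb, type = "local")
    if (Biostrings::nchar(al) >= min_identity_len &&
        Biostrings::pid(al) >= min_identity * 100)
      pair <- TRUE
  }
  list(left = lh[, c("family", "class"), drop = FALSE],
       right = rh[, c("family", "class"), drop = FALSE],
       homologous_pair = pair)
}

#' Classify the mutational mechanism of a junction
#'
#' Deterministic priority rules over the junction's features:
#' \enumerate{
#'   \item homologous repeat pair at both ends: repeat-mediated
#'     rearrangement (NAHR-like);
#'   \item complex DEL-NML-DEL event: FoSTeS/MMBIR;
#'   \item templated insertion: serial replication stalling;
#'   \item random insertion or blunt ends: NHEJ;
#'   \item microhomology: NHEJ or MMBIR (indistinguishable).
#' }
#'
#' @param signature Signature kind (`"microhomology"`, `"insertion"`,
#'   `"blunt"`).
#' @param insertion_origin `"random"` or `"templated"` (insertions only).
#' @param homologous_pair Repeat-pair flag from [repeat_overlap()].
#' @param complex_event Whether the junction belongs to a DEL-NML-DEL event.
#' @return One of `"repeat_mediated_rearrangement"`, `"FoSTeS_MMBIR"`,
#'   `"serial_replication_stalling"`, `"NHEJ"`, `"NHEJ_or_MMBIR"`.
#' @export
classify_mechanism <- function(signature, insertion_origin = "random",
                               homologous_pair = FALSE,
                               complex_event = FALSE) {
  if (isTRUE(homologous_pair)) return("repeat_mediated_rearrangement")
  if (isTRUE(complex_event)) return("FoSTeS_MMBIR")
  if (signature == "insertion" && identical(insertion_origin, "templated"))
    return("serial_replication_stalling")
  if (signature == "insertion" || signature == "blunt") return("NHEJ")
  if (signature == "microhomology") return("NHEJ_or_MMBIR")
  stop("unknown signature kind: ", signature)
}

#' Annotate a resolved base-precise call into a junction record
#'
#' Builds the reference flanks around the candidate breakpoints, runs
#' [characterize_junction()], left-aligns microhomology placements, locates
#' insertion origins, scans for near-breakpoint errors, annotates repeat
#' overlap, and classifies the mechanism.
#'
#' @param call One base-precise row from [resolve_breakpoints()].
#' @param reference Reference string.
#' @param repeats Optional repeat track.
#' @param polymorphisms Optional polymorphism list for the error scan.
#' @param pad Extra flank context beyond each breakpoint (default 50 bp).
#' @return One-row data.frame `junction_record`: breakpoints (left-aligned),
#'   signature columns, `mechanism`, `n_errors`, `errors` (semicolon string),
#'   repeat families, flags.
#' @export
annotate_junction <- function(call, reference, repeats = NULL,
                              polymorphisms = NULL, pad = 50) {
  stopifnot(call$resolution == "base_precise", !is.na(call$contig))
  contig <- call$contig
  j_at <- call$junction_at
  skip <- if (!is.null(call$tail_skip) && !is.na(call$tail_skip))
    call$tail_skip else 0L
  side <- if (!is.null(call$candidate_side) && !is.na(call$candidate_side))
    call$candidate_side else "right"
  n <- nchar(contig)
  L <- nchar(reference)
  orient <- call$candidate_orientation
  lb <- call$start; rb <- call$end
  x <- if (orient == "deletion") lb else rb   # ref pos the left flank ends at
  y <- if (orient == "deletion") rb else lb   # ref pos the right flank starts at
  # reference anchoring of the contig ends: contig[1] <-> ref_l0; the contig's
  # last base <-> ref_r1 - 1. Inserted bases (tail_skip) sit junction-side of
  # the matched block on the clipped side.
  ref_l0 <- if (side == "right") x - j_at else x - (j_at - skip)
  ref_r1 <- if (side == "right") y + (n - j_at - skip) else y + (n - j_at)
  lstart <- max(0, ref_l0)
  left_ref <- subseq0(reference, lstart, min(L - lstart, (x - lstart) + pad))
  rstart <- max(0, min(y - pad, ref_r1 - n))
  right_ref <- subseq0(reference, rstart, min(L, ref_r1) - rstart)
  sig <- characterize_junction(contig, left_ref, right_ref)
  P <- sig$split_left; S <- sig$split_right
  # breakpoints implied by the characterized split, left-aligned for
  # microhomology (leftmost equivalent placement, t = S - 1)
  t0 <- min(S - 1, P)
  x_la <- ref_l0 + t0
  y_la <- ref_r1 - (n - t0) + max(0, S - P - 1)
  if (sig$kind == "insertion") y_la <- ref_r1 - (n - S + 1)
  lb_la <- if (orient == "deletion") x_la else y_la
  rb_la <- if (orient == "deletion") y_la else x_la
  ins_len <- if (sig$kind == "insertion") nchar(sig$seq) else 0L
  origin <- list(origin = NA_character_)
  if (sig$kind == "insertion")
    origin <- locate_insertion_origin(sig$seq, reference, lb_la, rb_la)
  errs <- detect_breakpoint_errors(contig, P, reference,
                                   x_end = ref_l0 + P,
                                   y_start = ref_r1 - (n - P) + ins_len,
                                   ins_len = ins_len,
                                   polymorphisms = polymorphisms)
  rep_ann <- repeat_overlap(lb_la, rb_la, repeats, reference)
  mech <- classify_mechanism(sig$kind,
                             insertion_origin = origin$origin,
                             homologous_pair = rep_ann$homologous_pair,
                             complex_event = isTRUE(call$complex_event))
  data.frame(
    left = lb_la, right = rb_la,
    orientation = orient,
    length = rb_la - lb_la,
    signature = sig$kind,
    microhomology = if (sig$kind == "microhomology") sig$seq else "",
    insertion = if (sig$kind == "insertion") sig$seq else "",
    blunt = sig$kind == "blunt",
    insertion_origin = origin$origin,
    insertion_source = if (!is.null(origin$source_start))
      origin$source_start else NA_real_,
    n_errors = nrow(errs),
    errors = if (nrow(errs))
      paste(sprintf("%s>%s@%d", errs$ref, errs$alt, as.integer(errs$pos)),
            collapse = ";") else "",
    repeat_left = paste(rep_ann$left$family, collapse = ","),
    repeat_right = paste(rep_ann$right$family, collapse = ","),
    homologous_pair = rep_ann$homologous_pair,
    complex_event = isTRUE(call$complex_event),
    mechanism = mech,
    stringsAsFactors = FALSE)
}
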