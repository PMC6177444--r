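# ---------------------------------------------------------------------------
# Split-read breakpoint resolution.
#
# Soft-clipped reads are extracted and clustered by clip side and boundary
# position; each cluster is collapsed to a consensus contig by
# position-anchored majority vote; the clipped consensus is remapped to the
# reference by pattern matching with bounded mismatches to find the partner
# breakpoint; candidates are reconciled with read-depth calls to emit
# base-precise CNVs. Junction microhomology makes the clip boundary
# right-shifted by up to the microhomology length; the junction annotator
# later left-aligns the reported breakpoints.
# ---------------------------------------------------------------------------

#' Extract soft-clipped reads
#'
#' @param aln Alignment data.frame.
#' @param min_clip_len Minimum clip length to keep (default 20 bp).
#' @return data.frame with one row per qualifying clip: `qname, mate, side`
#'   (`"left"` = clip precedes the mapped segment), `pos` (0-based reference
#'   position of the clip boundary), `clip_len, boundary_in_read` (read index
#'   of the last base on the junction's left side), `seq`.
#' @export
extract_softclips <- function(aln, min_clip_len = 20) {
  aln <- aln[aln$mapped, , drop = FALSE]
  out <- list()
  l <- aln[aln$left_clip >= min_clip_len, , drop = FALSE]
  if (nrow(l))
    out$left <- data.frame(qname = l$qname, mate = l$mate, side = "left",
                           pos = l$pos, clip_len = l$left_clip,
                           boundary_in_read = l$left_clip, seq = l$seq,
                           stringsAsFactors = FALSE)
  r <- aln[aln$right_clip >= min_clip_len, , drop = FALSE]
  if (nrow(r))
    out$right <- data.frame(qname = r$qname, mate = r$mate, side = "right",
                            pos = r$pos + r$mapped_len, clip_len = r$right_clip,
                            boundary_in_read = r$left_clip + r$mapped_len,
                            seq = r$seq, stringsAsFactors = FALSE)
  if (length(out) == 0)
    return(data.frame(qname = character(0), mate = integer(0),
                      side = character(0), pos = numeric(0),
                      clip_len = integer(0), boundary_in_read = integer(0),
                      seq = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# majority-vote base per column; ties resolved by count then lexicographic
consensus_column <- function(bases) {
  tab <- sort(table(bases), decreasing = TRUE)
  cands <- names(tab)[tab == tab[1]]
  sort(cands)[1]
}

#' Cluster soft-clipped reads and assemble consensus contigs
#'
#' Clips sharing a side and a boundary position (within `jitter`) are
#' grouped; clusters below `min_support` reads are dropped. The consensus
#' contig is built by position-anchored majority vote over both the aligned
#' portions and the clipped tails of the reads whose boundary equals the
#' cluster's modal position.
#'
#' @param clips Output of [extract_softclips()].
#' @param jitter Maximum boundary scatter within a cluster (default 5 bp).
#' @param min_support Minimum supporting reads per cluster (default 3).
#' @return data.frame of `clip_cluster`s: `cluster_id, side, pos, support,
#'   contig, junction_at` (contig index of the last base left of the
#'   junction), `flank_len, tail_len`.
#' @export
cluster_and_assemble <- function(clips, jitter = 5, min_support = 3) {
  empty <- data.frame(cluster_id = integer(0), side = character(0),
                      pos = numeric(0), support = integer(0),
                      contig = character(0), junction_at = integer(0),
                      flank_len = integer(0), tail_len = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(clips) == 0) return(empty)
  out <- list()
  cid <- 0L
  for (sd in unique(clips$side)) {
    cl <- clips[clips$side == sd, , drop = FALSE]
    cl <- cl[order(cl$pos), , drop = FALSE]
    grp <- cumsum(c(1, diff(cl$pos) > jitter))
    for (g in unique(grp)) {
      members <- cl[grp == g, , drop = FALSE]
      if (nrow(members) < min_support) next
      tab <- sort(table(members$pos), decreasing = TRUE)
      mode_pos <- as.numeric(names(tab)[1])
      core <- members[members$pos == mode_pos, , drop = FALSE]
      # column c = read position - boundary_in_read; c <= 0 is the flank side
      cols <- list()
      for (i in seq_len(nrow(core))) {
        s <- core$seq[i]; b <- core$boundary_in_read[i]
        for (p in seq_len(nchar(s))) {
          c_idx <- as.character(p - b)
          cols[[c_idx]] <- c(cols[[c_idx]], substr(s, p, p))
        }
      }
      ci <- as.integer(names(cols))
      ord <- order(ci)
      bases <- vapply(cols[ord], consensus_column, "")
      contig <- paste(bases, collapse = "")
      junction_at <- sum(ci <= 0)
      cid <- cid + 1L
      out[[cid]] <- data.frame(
        cluster_id = cid, side = sd, pos = mode_pos,
        support = nrow(members), contig = contig,
        junction_at = junction_at, flank_len = junction_at,
        tail_len = nchar(contig) - junction_at, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Seed-and-extend local match of a clipped consensus against the reference.
# Exact 20-mer seeds define diagonals; each diagonal's match vector is cut at
# runs of >= max_gap consecutive mismatches and the segment containing the
# seed becomes the matched block. Returns the best-scoring block per
# diagonal: data.frame(diag, t0, t1 (0-based tail offsets), score, identity).
seed_extend <- function(tail_seq, reference, scope = NULL, seed_len = 20,
                        max_gap = 3) {
  tl <- nchar(tail_seq)
  L <- nchar(reference)
  s0 <- 0; s1 <- L
  if (!is.null(scope)) { s0 <- max(0, scope[1]); s1 <- min(L, scope[2]) }
  seeds <- unique(c(seq(0, tl - seed_len, by = seed_len), tl - seed_len))
  tv <- utf8ToInt(tail_seq)
  diags <- new.env()
  for (ts in seeds) {
    pat <- substr(tail_seq, ts + 1, ts + seed_len)
    hits <- Biostrings::matchPattern(pat, Biostrings::DNAString(
      subseq0(reference, s0, s1 - s0)))
    if (length(hits) == 0) next
    for (p in BiocGenerics::start(hits) - 1 + s0) {
      d <- p - ts
      key <- as.character(d)
      if (is.null(diags[[key]])) diags[[key]] <- ts
    }
  }
  keys <- ls(diags)
  if (length(keys) == 0)
    return(data.frame(diag = numeric(0), t0 = numeric(0), t1 = numeric(0),
                      score = numeric(0), identity = numeric(0)))
  out <- lapply(keys, function(key) {
    d <- as.numeric(key); ts <- diags[[key]]
    t_lo <- max(0, -d); t_hi <- min(tl - 1, L - 1 - d)
    if (t_hi - t_lo + 1 < seed_len) return(NULL)
    rv <- utf8ToInt(subseq0(reference, d + t_lo, t_hi - t_lo + 1))
    mv <- tv[(t_lo + 1):(t_hi + 1)] == rv
    # segment containing the seed, cut at >= max_gap consecutive mismatches
    r <- rle(mv)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    cutpts <- which(!r$values & r$lengths >= max_gap)
    seg_break <- c(0, ends[cutpts], length(mv))
    si <- ts - t_lo + 1
    seg <- findInterval(si, seg_break + 1)
    lo <- seg_break[seg] + 1; hi <- seg_break[seg + 1]
    idx <- lo:hi
    idx <- idx[mv[idx]]
    if (length(idx) == 0) return(NULL)
    a <- min(idx); b <- max(idx)
    data.frame(diag = d, t0 = t_lo + a - 1, t1 = t_lo + b - 1,
               score = sum(mv[a:b]), identity = mean(mv[a:b]))
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(diag = numeric(0), t0 = numeric(0), t1 = numeric(0),
                      score = numeric(0), identity = numeric(0)))
  res[order(-res$score), , drop = FALSE]
}

#' Remap a cluster's clipped consensus to find the partner breakpoint
#'
#' The clipped portion of the contig is aligned to the reference (within
#' `search_scope` if given) by exact-seed-and-extend local matching with
#' mismatches allowed up to `1 - min_identity`. A unique best locus (score
#' margin >= `min_score_margin` over the best other diagonal) yields one
#' `sv_candidate` with orientation inferred from the clip side and partner
#' position; ties or no acceptable locus leave the cluster unresolved
#' (mirroring repeat-mediated junctions that resist unique placement).
#' Clipped bases between the junction and the start of the matched block
#' (`tail_skip`) are inserted sequence, characterized downstream.
#'
#' @param cluster One row of [cluster_and_assemble()] output.
#' @param reference Reference sequence string.
#' @param search_scope Optional `c(start, end)` 0-based half-open scope.
#' @param min_clip_len Minimum clipped-consensus length to attempt remapping.
#' @param min_identity Minimum identity over the matched block (default 0.95).
#' @param min_score_margin Required margin of the best block score over the
#'   best block on any other diagonal (default 5).
#' @return data.frame of candidates (possibly 0 rows): `left, right,
#'   orientation` (`"deletion"`/`"tandem-dup"`), `tail_skip, cluster_id,
#'   side, pos, support, contig, junction_at, remap_score, n_hits,
#'   reciprocal`.
#' @export
remap_contig <- function(cluster, reference, search_scope = NULL,
                         min_clip_len = 20, min_identity = 0.95,
                         min_score_margin = 5) {
  empty <- data.frame(left = numeric(0), right = numeric(0),
                      orientation = character(0), tail_skip = integer(0),
                      cluster_id = integer(0), side = character(0),
                      pos = numeric(0), support = integer(0),
                      contig = character(0), junction_at = integer(0),
                      remap_score = numeric(0), n_hits = integer(0),
                      reciprocal = logical(0), stringsAsFactors = FALSE)
  tail_seq <- if (cluster$side == "right")
    substr(cluster$contig, cluster$junction_at + 1, nchar(cluster$contig))
  else substr(cluster$contig, 1, cluster$junction_at)
  tl <- nchar(tail_seq)
  if (tl < min_clip_len) return(empty)
  blocks <- seed_extend(tail_seq, reference, scope = search_scope)
  blocks <- blocks[blocks$identity >= min_identity &
                     (blocks$t1 - blocks$t0 + 1) >= min_clip_len, ,
                   drop = FALSE]
  if (nrow(blocks) == 0) return(empty)
  if (nrow(blocks) > 1 &&
      blocks$score[1] - blocks$score[2] < min_score_margin)
    return(empty)  # ambiguous placement: unresolved
  b <- blocks[1, ]
  if (cluster$side == "right") {
    partner <- b$diag + b$t0        # ref start of the matched block
    skip <- as.integer(b$t0)        # inserted bases before the block
    if (partner == cluster$pos) return(empty)
    if (partner > cluster$pos) {
      left <- cluster$pos; right <- partner; orient <- "deletion"
    } else { left <- partner; right <- cluster$pos; orient <- "tandem-dup" }
  } else {
    partner <- b$diag + b$t1 + 1    # ref end (exclusive) of the matched block
    skip <- as.integer(tl - 1 - b$t1)
    if (partner == cluster$pos) return(empty)
    if (partner < cluster$pos) {
      left <- partner; right <- cluster$pos; orient <- "deletion"
    } else { left <- cluster$pos; right <- partner; orient <- "tandem-dup" }
  }
  data.frame(left = left, right = right, orientation = orient,
             tail_skip = skip, cluster_id = cluster$cluster_id,
             side = cluster$side, pos = cluster$pos,
             support = cluster$support, contig = cluster$contig,
             junction_at = cluster$junction_at, remap_score = b$score,
             n_hits = nrow(blocks), reciprocal = FALSE,
             stringsAsFactors = FALSE)
}

#' Remap all clusters and reconcile reciprocal pairs
#'
#' Runs [remap_contig()] on every cluster, marks candidates whose partner
#' breakpoint is itself supported by a cluster on the opposite side
#' (reciprocal confirmation), and collapses the two per-event candidates
#' (one per junction side; placements may differ by up to the microhomology
#' length) into one, keeping the left-most placement.
#'
#' @param clusters Output of [cluster_and_assemble()].
#' @param reference Reference sequence string.
#' @param tol Position tolerance for reciprocal matching and candidate
#'   collapsing (default 15 bp, covering clustering jitter plus
#'   microhomology ambiguity).
#' @param ... Passed to [remap_contig()].
#' @return Candidate data.frame (see [remap_contig()]).
#' @export
call_sv_candidates <- function(clusters, reference, tol = 15, ...) {
  cands <- do.call(rbind, lapply(seq_len(nrow(clusters)), function(i)
    remap_contig(clusters[i, , drop = FALSE], reference, ...)))
  if (is.null(cands) || nrow(cands) == 0)
    return(remap_contig(data.frame(side = "right", contig = "", junction_at = 0,
                                   cluster_id = 0L, pos = 0, support = 0L),
                        reference))
  # reciprocal confirmation: a cluster on the opposite side near the partner
  for (i in seq_len(nrow(cands))) {
    partner <- if (cands$side[i] == "right") {
      if (cands$orientation[i] == "deletion") cands$right[i] else cands$left[i]
    } else {
      if (cands$orientation[i] == "deletion") cands$left[i] else cands$right[i]
    }
    opp <- clusters$side != cands$side[i] &
      abs(clusters$pos - partner) <= tol
    cands$reciprocal[i] <- any(opp)
  }
  # collapse equivalent candidates from the two junction sides
  keep <- rep(TRUE, nrow(cands))
  ord <- order(cands$left)
  for (ii in seq_along(ord)) {
    i <- ord[ii]
    if (!keep[i]) next
    for (jj in seq_along(ord)) {
      j <- ord[jj]
      if (j == i || !keep[j]) next
      same <- cands$orientation[i] == cands$orientation[j] &&
        abs(cands$left[i] - cands$left[j]) <= tol &&
        abs((cands$right[i] - cands$left[i]) -
              (cands$right[j] - cands$left[j])) <= 2
      if (same && cands$left[j] >= cands$left[i]) {
        keep[j] <- FALSE
        cands$reciprocal[i] <- cands$reciprocal[i] || cands$reciprocal[j]
      }
    }
  }
  res <- cands[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Reconcile depth calls with split-read candidates
#'
#' Each approximate depth call is paired with the candidate whose breakpoints
#' fall inside its search windows, upgrading it to a base-precise call
#' carrying exact coordinates and the junction contig. Candidates with no
#' depth support (events smaller than a window) create new calls flagged
#' `depth_supported = FALSE`. Depth calls with no candidate stay approximate.
#' Two close base-precise deletions (gap <= `complex_gap`) are flagged as one
#' complex DEL-NML-DEL event.
#'
#' @param depth_calls Output of [merge_calls()].
#' @param candidates Output of [call_sv_candidates()].
#' @param model Optional `gene_model` for exon-span annotation.
#' @param complex_gap Maximum retained-segment length between two deletions
#'   treated as one complex event (default 5000 bp).
#' @return data.frame of `cnv_call`s; base-precise rows carry `contig`,
#'   `junction_at`, `support`, `reciprocal`, `complex_event`.
#' @export
resolve_breakpoints <- function(depth_calls, candidates, model = NULL,
                                complex_gap = 5000) {
  dc <- depth_calls
  n0 <- nrow(dc)
  dc$contig <- rep(NA_character_, n0)
  dc$junction_at <- rep(NA_integer_, n0)
  dc$support <- rep(NA_integer_, n0)
  dc$reciprocal <- rep(NA, n0)
  dc$complex_event <- rep(FALSE, n0)
  dc$candidate_orientation <- rep(NA_character_, n0)
  dc$candidate_side <- rep(NA_character_, n0)
  dc$tail_skip <- rep(NA_integer_, n0)
  used <- rep(FALSE, nrow(candidates))
  rows <- list()
  for (i in seq_len(nrow(dc))) {
    want <- if (dc$type[i] == "DEL") "deletion" else "tandem-dup"
    hit <- which(!used & candidates$orientation == want &
                   candidates$left >= dc$search_left_start[i] &
                   candidates$left < dc$search_left_end[i] &
                   candidates$right >= dc$search_right_start[i] &
                   candidates$right < dc$search_right_end[i])
    if (length(hit) == 0) { rows[[length(rows) + 1]] <- dc[i, ]; next }
    for (h in hit) {
      used[h] <- TRUE
      r <- dc[i, ]
      r$start <- candidates$left[h]; r$end <- candidates$right[h]
      r$resolution <- "base_precise"
      r$contig <- candidates$contig[h]
      r$junction_at <- candidates$junction_at[h]
      r$support <- candidates$support[h]
      r$reciprocal <- candidates$reciprocal[h]
      r$ambiguous <- length(hit) > 1
      r$candidate_orientation <- candidates$orientation[h]
      r$candidate_side <- candidates$side[h]
      r$tail_skip <- candidates$tail_skip[h]
      if (!is.null(model)) {
        span <- exon_span(region(model$seq_id, r$start, r$end), model)
        r$exon_first <- if (length(span)) span[1] else NA_integer_
        r$exon_last <- if (length(span)) span[2] else NA_integer_
      }
      rows[[length(rows) + 1]] <- r
    }
  }
  # candidates with no depth support create their own calls
  for (h in which(!used)) {
    r <- empty_cnv_calls()[0, ]
    r[1, "type"] <- if (candidates$orientation[h] == "deletion") "DEL" else "DUP"
    r$start <- candidates$left[h]; r$end <- candidates$right[h]
    r$resolution <- "base_precise"; r$zygosity <- "unknown"
    r$depth_supported <- FALSE; r$ambiguous <- FALSE
    r$contig <- candidates$contig[h]
    r$junction_at <- candidates$junction_at[h]
    r$support <- candidates$support[h]
    r$reciprocal <- candidates$reciprocal[h]
    r$complex_event <- FALSE
    r$candidate_orientation <- candidates$orientation[h]
    r$candidate_side <- candidates$side[h]
    r$tail_skip <- candidates$tail_skip[h]
    if (!is.null(model)) {
      span <- exon_span(region(model$seq_id, r$start, r$end), model)
      r$exon_first <- if (length(span)) span[1] else NA_integer_
      r$exon_last <- if (length(span)) span[2] else NA_integer_
    }
    rows[[length(rows) + 1]] <- r
  }
  calls <- do.call(rbind, rows)
  if (is.null(calls)) return(dc[0, ])
  rownames(calls) <- NULL
  calls <- calls[order(calls$start), , drop = FALSE]
  # complex DEL-NML-DEL: two precise deletions separated by a short
  # retained segment
  prec <- which(calls$resolution == "base_precise" & calls$type == "DEL")
  if (length(prec) > 1) {
    for (k in seq_len(length(prec) - 1)) {
      a <- prec[k]; b <- prec[k + 1]
      gap <- calls$start[b] - calls$end[a]
      if (gap > 0 && gap <= complex_gap)
        calls$complex_event[c(a, b)] <- TRUE
    }
  }
  rownames(calls) <- NULL
  calls
}
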