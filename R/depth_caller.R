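# ---------------------------------------------------------------------------
# Read-depth CNV calling against a control sample.
#
# First-pass detection: per-window read counts in test vs control are
# normalized by library size; windows with ratio < 0.75 are potential
# deletions and > 1.25 potential duplications. Consecutive called windows
# merge into candidate events with approximate breakpoint search windows
# for the soft-clip resolver.
# ---------------------------------------------------------------------------

#' Build the depth-window track for a gene region
#'
#' Exons padded by `exon_pad` form one window per exon (padded windows that
#' would overlap are merged), and the remaining intronic/intergenic gaps are
#' tiled with `tile`-bp windows so that breakpoints outside exons still bound
#' a search window. Windows are non-overlapping and tile the region.
#'
#' @param model A `gene_model`.
#' @param region_len Total length of the target region.
#' @param exon_pad Padding added to each exon side (default 50 bp).
#' @param tile Intronic tile width (default 500 bp).
#' @return data.frame `start, end, kind` (`"exon"`/`"intron"`), 0-based
#'   half-open, sorted.
#' @export
make_depth_windows <- function(model, region_len, exon_pad = 50, tile = 500) {
  ex <- model$exons
  ws <- pmax(0, ex$start - exon_pad)
  we <- pmin(region_len, ex$end + exon_pad)
  # merge exon windows that touch after padding
  keep_s <- ws[1]; out_s <- c(); out_e <- c()
  cur_s <- ws[1]; cur_e <- we[1]
  for (i in seq_along(ws)[-1]) {
    if (ws[i] <= cur_e) cur_e <- max(cur_e, we[i])
    else { out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
           cur_s <- ws[i]; cur_e <- we[i] }
  }
  out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
  exw <- data.frame(start = out_s, end = out_e, kind = "exon")
  # tile the gaps
  gaps_s <- c(0, exw$end)
  gaps_e <- c(exw$start, region_len)
  tl <- list()
  for (i in seq_along(gaps_s)) {
    gs <- gaps_s[i]; ge <- gaps_e[i]
    if (ge - gs <= 0) next
    starts <- seq(gs, ge - 1, by = tile)
    tl[[length(tl) + 1]] <- data.frame(start = starts,
                                       end = pmin(starts + tile, ge),
                                       kind = "intron")
  }
  w <- rbind(exw, do.call(rbind, tl))
  w <- w[order(w$start), ]
  w <- w[w$end > w$start, ]
  rownames(w) <- NULL
  w$window <- seq_len(nrow(w))
  w[, c("window", "start", "end", "kind")]
}

count_starts <- function(aln, windows) {
  pos <- aln$pos[aln$mapped]
  if (length(pos) == 0) return(rep(0L, nrow(windows)))
  # windows are sorted and non-overlapping; count mapped-start positions
  idx <- findInterval(pos, windows$start)
  idx[idx > 0 & pos >= windows$end[pmax(idx, 1)]] <- 0L
  tab <- tabulate(idx[idx > 0], nbins = nrow(windows))
  as.integer(tab)
}

#' Per-window depth profile of a test sample against a control
#'
#' Counts are reads whose mapped start (first aligned base, clip-aware) lies
#' in the window. The default normalization is median-of-ratios: per-window
#' `test/control` ratios are divided by their median across windows, which
#' keeps copy-neutral windows at 1.0 even when the event itself is a large
#' fraction of the single-gene target (total-count normalization, available
#' as `normalization = "total"`, is biased upward by exactly that fraction).
#' Windows with a zero control count are flagged and excluded from calling.
#'
#' @param test_aln,control_aln Alignment data.frames ([align_reads()] /
#'   [read_alignments()]).
#' @param windows Window track from [make_depth_windows()].
#' @param normalization `"median_ratio"` (default) or `"total"`
#'   (library-size: `(test/test_total) / (control/control_total)`).
#' @return `depth_profile` data.frame: windows plus `test_count,
#'   control_count, ratio, flagged`.
#' @export
compute_depth_profile <- function(test_aln, control_aln, windows,
                                  normalization = c("median_ratio", "total")) {
  normalization <- match.arg(normalization)
  tc <- count_starts(test_aln, windows)
  cc <- count_starts(control_aln, windows)
  t_tot <- sum(test_aln$mapped); c_tot <- sum(control_aln$mapped)
  if (t_tot == 0 || c_tot == 0) stop("no mapped reads in test or control")
  ratio <- ifelse(cc > 0, (tc / t_tot) / (cc / c_tot), NA_real_)
  if (normalization == "median_ratio") {
    raw <- ifelse(cc > 0, tc / cc, NA_real_)
    m <- stats::median(raw, na.rm = TRUE)
    if (!is.na(m) && m > 0) ratio <- raw / m
  }
  out <- cbind(windows,
               data.frame(test_count = tc, control_count = cc, ratio = ratio,
                          flagged = cc == 0))
  class(out) <- c("depth_profile", "data.frame")
  out
}

#' Threshold per-window copy-number calls
#'
#' @param profile A `depth_profile`.
#' @param del_threshold Ratio below which a window is a potential deletion
#'   (default 0.75).
#' @param dup_threshold Ratio above which a window is a potential duplication
#'   (default 1.25).
#' @return The profile with a `call` column (`"DEL"`, `"DUP"`, `"neutral"`,
#'   `NA` for flagged windows).
#' @export
call_windows <- function(profile, del_threshold = 0.75, dup_threshold = 1.25) {
  if (del_threshold >= dup_threshold)
    stop("del_threshold must be below dup_threshold")
  call <- ifelse(is.na(profile$ratio), NA_character_,
                 ifelse(profile$ratio < del_threshold, "DEL",
                        ifelse(profile$ratio > dup_threshold, "DUP", "neutral")))
  profile$call <- call
  profile
}

#' Merge consecutive window calls into candidate CNV events
#'
#' Runs of adjacent same-type called windows become one approximate call.
#' Each call carries breakpoint search windows spanning from the nearest
#' neutral neighbor into the event, the exon span from the gene model, and a
#' zygosity estimate from the mean ratio (hom deletion < 0.1; het deletion in
#' `[0.3, 0.7]`; otherwise unknown — operational bands, not assertions).
#'
#' @param profile Output of [call_windows()].
#' @param model A `gene_model` (for exon-span annotation); `NULL` to skip.
#' @param region_len Region length used to bound search windows.
#' @return data.frame of approximate `cnv_call`s: `type, start, end,
#'   exon_first, exon_last, resolution, zygosity, n_windows, mean_ratio,
#'   search_left_start, search_left_end, search_right_start,
#'   search_right_end`.
#' @export
merge_calls <- function(profile, model = NULL,
                        region_len = max(profile$end)) {
  stopifnot(!is.null(profile$call))
  call <- ifelse(is.na(profile$call), "neutral", profile$call)
  r <- rle(call)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values %in% c("DEL", "DUP"))
  if (length(keep) == 0) return(empty_cnv_calls())
  out <- lapply(keep, function(k) {
    wi <- starts[k]:ends[k]
    mean_ratio <- mean(profile$ratio[wi], na.rm = TRUE)
    type <- r$values[k]
    zyg <- if (type == "DEL" && !is.nan(mean_ratio)) {
      if (mean_ratio < 0.1) "hom"
      else if (mean_ratio >= 0.3 && mean_ratio <= 0.7) "het"
      else "unknown"
    } else "unknown"
    ev_start <- profile$start[wi[1]]; ev_end <- profile$end[wi[length(wi)]]
    sl_start <- if (wi[1] > 1) profile$start[wi[1] - 1] else 0
    sr_end <- if (wi[length(wi)] < nrow(profile))
      profile$end[wi[length(wi)] + 1] else region_len
    span <- if (!is.null(model))
      exon_span(region(model$seq_id, ev_start, ev_end), model) else integer(0)
    data.frame(type = type, start = ev_start, end = ev_end,
               exon_first = if (length(span)) span[1] else NA_integer_,
               exon_last = if (length(span)) span[2] else NA_integer_,
               resolution = "approximate", zygosity = zyg,
               n_windows = length(wi), mean_ratio = mean_ratio,
               search_left_start = sl_start,
               search_left_end = profile$end[wi[1]],
               search_right_start = profile$start[wi[length(wi)]],
               search_right_end = sr_end,
               depth_supported = TRUE, ambiguous = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

empty_cnv_calls <- function() {
  data.frame(type = character(0), start = numeric(0), end = numeric(0),
             exon_first = integer(0), exon_last = integer(0),
             resolution = character(0), zygosity = character(0),
             n_windows = integer(0), mean_ratio = numeric(0),
             search_left_start = numeric(0), search_left_end = numeric(0),
             search_right_start = numeric(0), search_right_end = numeric(0),
             depth_supported = logical(0), ambiguous = logical(0),
             stringsAsFactors = FALSE)
}
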