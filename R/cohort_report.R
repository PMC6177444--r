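# ---------------------------------------------------------------------------
# Cohort-level CNV-spectrum statistics.
#
# Works over three curated tables (shipped for a published LAMA2 muscular
# dystrophy cohort of 96 genetically diagnosed subjects, 29 of them CNV
# probands): a per-junction breakpoint table, a per-proband CNV table (exon
# spans, frame, zygosity), and a per-subject two-allele table. All headline
# statistics (distinct CNVs, founder groups, allele frequencies, exon-span
# and domain distributions) recompute from these integer tables.
# ---------------------------------------------------------------------------

#' Load the shipped LAMA2 cohort fixtures
#'
#' @return list with `junctions` (per-junction breakpoint records),
#'   `probands` (per-proband CNVs with exon spans and zygosity), `cohort`
#'   (per-subject allele table, two slots each), and `repeats` (synthetic
#'   repeat track covering the junction ends).
#' @export
load_lama2_cohort <- function() {
  f <- function(name) system.file("extdata", name, package = "lamacnv",
                                  mustWork = TRUE)
  junctions <- read.table(f("lama2_junctions.tsv"), sep = "\t", header = TRUE,
                          quote = "", stringsAsFactors = FALSE)
  probands <- read.table(f("lama2_proband_cnvs.tsv"), sep = "\t", header = TRUE,
                         quote = "", stringsAsFactors = FALSE)
  cohort <- read.table(f("lama2_cohort_alleles.tsv"), sep = "\t", header = TRUE,
                       quote = "", stringsAsFactors = FALSE)
  repeats <- read_repeat_track(f("lama2_repeats_synthetic.bed"))
  stopifnot(nrow(cohort) == 96)
  list(junctions = junctions, probands = probands, cohort = cohort,
       repeats = repeats)
}

is_cnv_allele <- function(x) grepl("^(DEL|DUP)", x)

# one record per proband event: coordinates id, type, size from coordinates
event_records <- function(junctions) {
  sp <- split(junctions, junctions$subject)
  out <- lapply(sp, function(j) {
    j <- j[order(j$junction_index), , drop = FALSE]
    one_sided <- any(is.na(j$right_pos))
    id <- paste0(j$structure[1], ":",
                 paste(sprintf("%s-%s", j$left_pos,
                               ifelse(is.na(j$right_pos), "open", j$right_pos)),
                       collapse = "+"))
    size <- if (one_sided) NA_real_ else sum(j$right_pos - j$left_pos)
    data.frame(subject = j$subject[1], structure = j$structure[1], cnv_id = id,
               size = size, n_junctions = nrow(j), one_sided = one_sided,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(match(res$subject, unique(junctions$subject))), ]
  rownames(res) <- NULL
  res
}

#' Collapse CNV records into distinct CNVs
#'
#' Records with identical canonical breakpoint coordinates and type collapse
#' into one distinct CNV. Events smaller than `size_floor` are excluded from
#' the CNV tally but returned separately as small variants; unresolved
#' one-sided events count as distinct via their resolved end.
#'
#' @param junctions Per-junction table (as in [load_lama2_cohort()]).
#' @param size_floor Minimum event size in bp to count as a CNV
#'   (default 1000).
#' @return list: `distinct` (data.frame `cnv_id, structure, size,
#'   multiplicity, subjects`), `n_distinct`, `small_variants` (excluded
#'   records).
#' @export
dedupe_distinct <- function(junctions, size_floor = 1000) {
  ev <- event_records(junctions)
  small <- ev[!is.na(ev$size) & ev$size < size_floor, , drop = FALSE]
  big <- ev[is.na(ev$size) | ev$size >= size_floor, , drop = FALSE]
  sp <- split(big, big$cnv_id)
  distinct <- do.call(rbind, lapply(sp, function(g)
    data.frame(cnv_id = g$cnv_id[1], structure = g$structure[1],
               size = g$size[1], multiplicity = nrow(g),
               subjects = paste(g$subject, collapse = ","),
               stringsAsFactors = FALSE)))
  distinct <- distinct[order(-distinct$multiplicity, distinct$cnv_id), ]
  rownames(distinct) <- NULL
  list(distinct = distinct, n_distinct = nrow(distinct),
       small_variants = small)
}

#' Flag founder-candidate CNV groups
#'
#' Alleles from at least `min_families` distinct families sharing identical
#' breakpoint coordinates and an identical junction signature are flagged as
#' founder candidates (a computational proxy for haplotype evidence:
#' identity by descent predicts both).
#'
#' @param junctions Per-junction table.
#' @param probands Per-proband table (for family and zygosity).
#' @param min_families Minimum number of distinct families (default 2).
#' @return data.frame of candidate groups: `cnv_id, signature_seq,
#'   n_subjects, n_families, n_alleles, subjects`.
#' @export
founder_candidates <- function(junctions, probands, min_families = 2) {
  ev <- event_records(junctions)
  sigseq <- vapply(split(junctions, junctions$subject), function(j)
    paste(ifelse(nzchar(j$microhomology), paste0("MH:", j$microhomology),
                 ifelse(nzchar(j$insertion), paste0("INS:", j$insertion),
                        ifelse(j$blunt == "yes", "BLUNT", "NA"))),
          collapse = "|"), "")
  ev$signature_seq <- sigseq[ev$subject]
  ev <- merge(ev, probands[, c("subject", "family", "zygosity")],
              by = "subject")
  key <- paste(ev$cnv_id, ev$signature_seq)
  sp <- split(ev, key)
  out <- lapply(sp, function(g) {
    nf <- length(unique(g$family))
    if (nf < min_families || any(g$signature_seq == "NA")) return(NULL)
    data.frame(cnv_id = g$cnv_id[1], signature_seq = g$signature_seq[1],
               n_subjects = nrow(g), n_families = nf,
               n_alleles = sum(ifelse(g$zygosity == "hom", 2L, 1L)),
               subjects = paste(sort(g$subject), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(cnv_id = character(0), signature_seq = character(0),
                      n_subjects = integer(0), n_families = integer(0),
                      n_alleles = integer(0), subjects = character(0)))
  res <- res[order(-res$n_alleles), ]
  rownames(res) <- NULL
  res
}

#' Allele frequencies and zygosity counts for the cohort
#'
#' All percentages recompute from integer counts.
#'
#' @param cohort Per-subject allele table (two allele slots per subject).
#' @param probands Optional proband table; when given, zygosity counts are
#'   also reported restricted to probands.
#' @return list: `n_subjects`, `n_alleles`, `n_cnv_alleles`,
#'   `cnv_allele_freq_pct`, `per_cnv` (allele counts and share of CNV
#'   alleles per distinct CNV), `zygosity` (per-carrier), `n_het`, `n_hom`,
#'   and proband-restricted counts when available.
#' @export
allele_summary <- function(cohort, probands = NULL) {
  stopifnot(all(c("allele1", "allele2") %in% names(cohort)))
  a1 <- is_cnv_allele(cohort$allele1); a2 <- is_cnv_allele(cohort$allele2)
  n_alleles <- 2L * nrow(cohort)
  n_cnv <- sum(a1) + sum(a2)
  carriers <- cohort[a1 | a2, , drop = FALSE]
  zyg <- data.frame(
    subject = carriers$subject,
    zygosity = ifelse(is_cnv_allele(carriers$allele1) &
                        carriers$allele1 == carriers$allele2, "hom", "het"),
    stringsAsFactors = FALSE)
  ids <- c(cohort$allele1[a1], cohort$allele2[a2])
  tab <- sort(table(ids), decreasing = TRUE)
  per_cnv <- data.frame(cnv_id = names(tab), n_alleles = as.integer(tab),
                        share_pct = 100 * as.integer(tab) / n_cnv,
                        stringsAsFactors = FALSE)
  out <- list(n_subjects = nrow(cohort), n_alleles = n_alleles,
              n_cnv_alleles = n_cnv,
              cnv_allele_freq_pct = 100 * n_cnv / n_alleles,
              per_cnv = per_cnv, zygosity = zyg,
              n_het = sum(zyg$zygosity == "het"),
              n_hom = sum(zyg$zygosity == "hom"))
  if (!is.null(probands)) {
    pz <- zyg[zyg$subject %in% probands$subject, , drop = FALSE]
    out$n_het_probands <- sum(pz$zygosity == "het")
    out$n_hom_probands <- sum(pz$zygosity == "hom")
  }
  out
}

#' CNV-spectrum report for the cohort
#'
#' Tallies single-exon CNVs, domain placement (the N-terminal tally counts
#' events contained entirely within exons 1-30), reading-frame classes,
#' junction-signature and mechanism counts, repeat-end overlap, and size
#' extrema. The signature tally runs over signature-bearing resolved
#' junctions; mean and median sizes are reported descriptively only.
#'
#' @param junctions Per-junction table.
#' @param probands Per-proband table.
#' @param repeats Optional repeat track for junction-end overlap counting.
#' @param domains Domain map (default [default_domain_map()]).
#' @param size_floor Small-variant size floor in bp (default 1000).
#' @return list of tallies (see examples in the package vignette) plus a
#'   Table-style data.frame `table` with one row per junction.
#' @export
spectrum_report <- function(junctions, probands, repeats = NULL,
                            domains = default_domain_map(),
                            size_floor = 1000) {
  ev <- event_records(junctions)
  small_subj <- ev$subject[!is.na(ev$size) & ev$size < size_floor]
  cn <- probands[!probands$subject %in% small_subj, , drop = FALSE]
  n_cnv <- nrow(cn)
  single_exon <- sum(cn$exon_start == cn$exon_end)
  nt <- domains[domains$domain == "N-terminal", ]
  n_nterm <- if (nrow(nt)) sum(cn$exon_start >= nt$exon_first &
                                 cn$exon_end <= nt$exon_last) else NA_integer_
  per_domain <- vapply(seq_len(nrow(domains)), function(i)
    sum(cn$exon_start <= domains$exon_last[i] &
          cn$exon_end >= domains$exon_first[i]), 0L)
  names(per_domain) <- domains$domain
  frame_tab <- table(cn$frame_label)

  j <- junctions[junctions$resolved == "yes" &
                   !junctions$subject %in% small_subj, , drop = FALSE]
  sig <- ifelse(nzchar(j$microhomology), "microhomology",
                ifelse(nzchar(j$insertion), "insertion",
                       ifelse(j$blunt == "yes", "blunt", "none")))
  j$signature <- sig
  sig_counts <- c(microhomology = sum(sig == "microhomology"),
                  insertion = sum(sig == "insertion"),
                  blunt = sum(sig == "blunt"))
  n_signature_junctions <- sum(sig != "none")

  # mechanism per event under the package's classification rules
  ev_resolved <- ev[!ev$subject %in% small_subj & !ev$one_sided, , drop = FALSE]
  mech <- vapply(ev_resolved$subject, function(s) {
    js <- j[j$subject == s, , drop = FALSE]
    if (nrow(js) == 0) return(NA_character_)
    rep_pair <- any(nzchar(js$repeats))
    complex_event <- ev$n_junctions[ev$subject == s] > 1
    s1 <- js$signature[1]
    origin <- if (any(js$insertion_origin == "templated")) "templated" else "random"
    if (s1 == "none" && !rep_pair) return(NA_character_)
    classify_mechanism(if (s1 == "none") "blunt" else s1,
                       insertion_origin = origin,
                       homologous_pair = rep_pair,
                       complex_event = complex_event)
  }, "")
  mech_counts <- table(mech[!is.na(mech)])

  # junction-end repeat overlap per resolved event
  n_repeat_events <- NA_integer_
  if (!is.null(repeats)) {
    n_repeat_events <- sum(vapply(unique(j$subject), function(s) {
      js <- j[j$subject == s, , drop = FALSE]
      pts <- c(js$left_pos, js$right_pos)
      pts <- pts[!is.na(pts)]
      any(vapply(pts, function(p)
        any(repeats$start <= p & repeats$end > p), TRUE))
    }, TRUE))
  }

  sizes <- ev$size[!is.na(ev$size) & ev$size >= size_floor]
  list(n_cnv_probands = n_cnv, single_exon = single_exon,
       n_nterm_contained = n_nterm, per_domain = per_domain,
       frame = frame_tab, signature_counts = sig_counts,
       n_signature_junctions = n_signature_junctions,
       mechanism_counts = mech_counts,
       n_repeat_overlap_events = n_repeat_events,
       n_resolved_events = length(unique(j$subject)),
       size_min = min(sizes), size_max = max(sizes),
       size_mean = mean(sizes), size_median = stats::median(sizes),
       table = j)
}

#' Full cohort report
#'
#' Runs [dedupe_distinct()], [founder_candidates()], [allele_summary()] and
#' [spectrum_report()] over a fixture set and returns the combined results.
#'
#' @param fixtures Fixture list as from [load_lama2_cohort()].
#' @param size_floor CNV size floor in bp (default 1000).
#' @return list with elements `distinct`, `founders`, `alleles`, `spectrum`.
#' @export
cohort_report <- function(fixtures = load_lama2_cohort(), size_floor = 1000) {
  d <- dedupe_distinct(fixtures$junctions, size_floor = size_floor)
  f <- founder_candidates(fixtures$junctions, fixtures$probands)
  a <- allele_summary(fixtures$cohort, fixtures$probands)
  s <- spectrum_report(fixtures$junctions, fixtures$probands,
                       repeats = fixtures$repeats, size_floor = size_floor)
  list(distinct = d, founders = f, alleles = a, spectrum = s)
}
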