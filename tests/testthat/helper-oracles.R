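# Independent brute-force oracles and tiny junction generators shared by the
# unit and acceptance tests. The oracles deliberately avoid the package's
# internal code paths.

rnd_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

rnd_other <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)

last_char <- function(x) substr(x, nchar(x), nchar(x))

# exhaustive split-point oracle for junction characterization: a split at t
# is valid iff contig[1..t] equals left_ref[1..t] and contig[(t+1)..n]
# equals the length-matched suffix of right_ref
oracle_characterize <- function(contig, left_ref, right_ref) {
  n <- nchar(contig)
  nl <- nchar(left_ref); nr <- nchar(right_ref)
  valid <- integer(0)
  for (t in 0:n) {
    if (t > nl || (n - t) > nr) next
    okl <- t == 0 || substr(contig, 1, t) == substr(left_ref, 1, t)
    okr <- t == n ||
      substr(contig, t + 1, n) == substr(right_ref, nr - (n - t) + 1, nr)
    if (okl && okr) valid <- c(valid, t)
  }
  if (length(valid) >= 2) {
    list(kind = "microhomology",
         seq = substr(contig, min(valid) + 1, max(valid)))
  } else if (length(valid) == 1) {
    list(kind = "blunt", seq = "")
  } else {
    pmax <- 0
    while (pmax < min(n, nl) &&
           substr(contig, pmax + 1, pmax + 1) ==
             substr(left_ref, pmax + 1, pmax + 1)) pmax <- pmax + 1
    smax <- 0
    while (smax < min(n, nr) &&
           substr(contig, n - smax, n - smax) ==
             substr(right_ref, nr - smax, nr - smax)) smax <- smax + 1
    list(kind = "insertion", seq = substr(contig, pmax + 1, n - smax))
  }
}

# generate one random planted junction with a known signature; returns the
# inputs for characterize_junction plus the truth
random_junction <- function(flank = 60, ext = 25) {
  kind <- sample(c("microhomology", "insertion", "blunt"), 1)
  L <- rnd_seq(flank); R <- rnd_seq(flank)
  if (kind == "microhomology") {
    k <- sample(1:8, 1)
    m <- rnd_seq(k)
    contig <- paste0(L, m, R)
    cont_l <- rnd_seq(ext)
    substr(cont_l, 1, 1) <- rnd_other(substr(R, 1, 1))
    pre_r <- rnd_seq(ext)
    substr(pre_r, ext, ext) <- rnd_other(last_char(L))
    left_ref <- paste0(L, m, cont_l)
    right_ref <- paste0(pre_r, m, R)
    truth <- m
  } else if (kind == "blunt") {
    contig <- paste0(L, R)
    cont_l <- rnd_seq(ext)
    substr(cont_l, 1, 1) <- rnd_other(substr(R, 1, 1))
    pre_r <- rnd_seq(ext)
    substr(pre_r, ext, ext) <- rnd_other(last_char(L))
    left_ref <- paste0(L, cont_l)
    right_ref <- paste0(pre_r, R)
    truth <- ""
  } else {
    q <- sample(1:40, 1)
    ins <- rnd_seq(q)
    cont_l <- rnd_seq(ext)
    substr(cont_l, 1, 1) <- rnd_other(substr(ins, 1, 1))
    pre_r <- rnd_seq(ext)
    substr(pre_r, ext, ext) <- rnd_other(last_char(ins))
    # also cap against junction-side flank bases so the insertion is maximal
    if (substr(ins, 1, 1) == last_char(pre_r))
      substr(pre_r, ext, ext) <- rnd_other(c(substr(ins, 1, 1), last_char(ins)))
    contig <- paste0(L, ins, R)
    left_ref <- paste0(L, cont_l)
    right_ref <- paste0(pre_r, R)
    truth <- ins
  }
  list(kind = kind, seq = truth, contig = contig, left_ref = left_ref,
       right_ref = right_ref)
}

# naive per-exon intersection scan (exon_span oracle)
oracle_exon_span <- function(start, end, model) {
  hits <- integer(0)
  for (i in seq_len(nrow(model$exons))) {
    e <- model$exons[i, ]
    if (e$start < end && e$end > start) hits <- c(hits, e$exon_index)
  }
  if (length(hits) == 0) integer(0) else c(min(hits), max(hits))
}

# concatenate-and-measure frame oracle
oracle_frame <- function(span, model) {
  seqs <- character(0)
  for (i in span[1]:span[2]) {
    cl <- model$exons$coding_len[model$exons$exon_index == i]
    seqs <- c(seqs, strrep("N", cl))
  }
  if (nchar(paste(seqs, collapse = "")) %% 3 == 0) "in_frame" else "out_of_frame"
}

# naive pairwise-equality grouping (dedupe oracle): returns sorted
# multiplicity profile of groups
oracle_group_sizes <- function(ids) {
  groups <- list()
  for (id in ids) {
    placed <- FALSE
    for (k in seq_along(groups)) {
      if (identical(groups[[k]]$id, id)) {
        groups[[k]]$n <- groups[[k]]$n + 1
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- list(id = id, n = 1)
  }
  sort(vapply(groups, `[[`, 0, "n"))
}

# small end-to-end simulation used by several tests
sim_case <- function(type = "DEL", seg = c(8000, 11000), zyg = "het",
                     sig = sig_microhomology("AACAA"), ref_len = 20000,
                     depth = 100, seed = 1, n_exons = 8, errors = NULL) {
  ref <- make_reference(ref_len, 0.42, seed = seed)
  spec <- cnv_spec(type, if (is.list(seg)) seg else list(seg), zyg, sig,
                   errors = errors)
  tr <- apply_cnv(ref, spec, seed = seed)
  rd <- simulate_reads(tr, mean_depth = depth, seed = seed)
  al <- align_reads(rd, tr)
  ctrl <- simulate_control(tr$reference, mean_depth = depth, seed = seed + 1)
  model <- synthetic_gene_model(ref_len, n_exons = n_exons, seed = seed)
  list(truth = tr, reads = rd, aln = al, ctrl = ctrl, model = model,
       reference = tr$reference)
}
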