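test_that("soft-clip extraction keeps only qualifying clips", {
  cs <- sim_case("DEL", c(8000, 11000), "hom", sig_blunt(), ref_len = 20000,
                 depth = 80, seed = 23)
  # fully mapped read set: nothing extracted
  expect_equal(nrow(extract_softclips(cs$ctrl)), 0)
  # threshold above read length: nothing extracted
  expect_equal(nrow(extract_softclips(cs$aln, min_clip_len = 200)), 0)
  clips <- extract_softclips(cs$aln)
  expect_gt(nrow(clips), 5)
  # clips only at the two breakpoints
  expect_true(all(clips$pos %in% c(8000, 11000)))
  expect_setequal(unique(clips$side), c("left", "right"))
})

test_that("clustering builds majority-vote consensus contigs", {
  # ten identical synthetic clipped reads
  seqs <- strrep("ACGTT", 30)  # 150 bp
  clips <- data.frame(qname = paste0("r", 1:10), mate = 1L, side = "right",
                      pos = 500, clip_len = 50L, boundary_in_read = 100L,
                      seq = seqs, stringsAsFactors = FALSE)
  cl <- cluster_and_assemble(clips)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$support, 10)
  expect_equal(cl$contig, seqs)
  expect_equal(cl$junction_at, 100)

  # two isolated reads with min_support 3: no clusters
  sparse <- clips[1:2, ]; sparse$pos <- c(1000, 5000)
  expect_equal(nrow(cluster_and_assemble(sparse, min_support = 3)), 0)

  # sequencing errors at 0.1%: consensus equals the truth junction sequence
  cs <- sim_case("DEL", c(8000, 11000), "hom", sig_blunt(), ref_len = 20000,
                 depth = 100, seed = 29)
  cl2 <- cluster_and_assemble(extract_softclips(cs$aln))
  right <- cl2[cl2$side == "right", ][1, ]
  truth_tail <- substr(cs$reference, 11001, 11000 + right$tail_len)
  expect_equal(substr(right$contig, right$junction_at + 1,
                      nchar(right$contig)), truth_tail)
  truth_flank <- substr(cs$reference, 8001 - right$junction_at, 8000)
  expect_equal(substr(right$contig, 1, right$junction_at), truth_flank)
})

test_that("contig remapping finds unique partners and flags ambiguity", {
  cs <- sim_case("DEL", c(8000, 11000), "hom", sig_microhomology("AACAA"),
                 ref_len = 20000, depth = 100, seed = 37)
  clusters <- cluster_and_assemble(extract_softclips(cs$aln))
  cands <- call_sv_candidates(clusters, cs$reference)
  expect_equal(nrow(cands), 1)
  expect_equal(cands$orientation, "deletion")
  expect_equal(cands$right - cands$left, 3000)
  expect_true(cands$reciprocal)

  # tandem duplication: partner upstream of the clip, head-to-tail
  cd <- sim_case("TANDEM_DUP", c(6000, 9000), "het", sig_blunt(),
                 ref_len = 20000, depth = 100, seed = 41)
  cands_d <- call_sv_candidates(
    cluster_and_assemble(extract_softclips(cd$aln)), cd$reference)
  expect_equal(cands_d$orientation, "tandem-dup")
  expect_equal(cands_d$right - cands_d$left, 3000)

  # a clipped tail of pure random sequence finds no partner
  set.seed(53)
  fake <- data.frame(cluster_id = 1L, side = "right", pos = 5000,
                     support = 5L,
                     contig = paste0(substr(cs$reference, 4901, 5000),
                                     rnd_seq(60)),
                     junction_at = 100L, flank_len = 100L, tail_len = 60L,
                     stringsAsFactors = FALSE)
  expect_equal(nrow(remap_contig(fake[1, ], cs$reference)), 0)

  # a tail matching two loci equally well is left unresolved
  ref2 <- cs$reference
  dupseg <- substr(ref2, 12001, 12100)
  substr(ref2, 15001, 15100) <- dupseg  # plant an exact second copy
  fake2 <- fake
  fake2$contig <- paste0(substr(ref2, 4901, 5000), dupseg)
  fake2$tail_len <- 100L
  expect_equal(nrow(remap_contig(fake2[1, ], ref2)), 0)
})

test_that("breakpoint resolution recovers exact lengths and fall-through", {
  # large deletion: one base-precise call of the exact planted length
  cs <- sim_case("DEL", c(8000, 13465), "hom", sig_microhomology("AACAA"),
                 ref_len = 25000, depth = 100, seed = 43, n_exons = 10)
  res <- run_pipeline(cs$aln, cs$ctrl, cs$reference, cs$model)
  prec <- res$calls[res$calls$resolution == "base_precise", ]
  expect_equal(nrow(prec), 1)
  expect_equal(prec$end - prec$start, 5465)
  expect_equal(prec$zygosity, "hom")
  expect_equal(res$junctions$microhomology, "AACAA")

  # small intra-exonic deletion: precise call without depth support
  ce <- sim_case("DEL", c(9010, 9066), "het", sig_blunt(), ref_len = 20000,
                 depth = 100, seed = 47)
  res2 <- run_pipeline(ce$aln, ce$ctrl, ce$reference, ce$model)
  prec2 <- res2$calls[res2$calls$resolution == "base_precise", ]
  expect_equal(nrow(prec2), 1)
  expect_equal(prec2$end - prec2$start, 56)
  expect_false(prec2$depth_supported)

  # depth call with no clip clusters stays approximate
  cs3 <- sim_case("DEL", c(6000, 12000), "het", sig_blunt(), ref_len = 20000,
                  depth = 80, seed = 49)
  w <- make_depth_windows(cs3$model, 20000)
  p <- call_windows(compute_depth_profile(cs3$aln, cs3$ctrl, w))
  dcalls <- merge_calls(p, cs3$model, 20000)
  nocand <- call_sv_candidates(
    cluster_and_assemble(extract_softclips(cs3$ctrl)), cs3$reference)
  out <- resolve_breakpoints(dcalls, nocand, cs3$model)
  expect_true(all(out$resolution == "approximate"))
})

test_that("resolution is symmetric under reverse complement of the locus", {
  # same blunt deletion engineered on a reference and on its mirror image:
  # breakpoints must mirror exactly
  L <- 20000; s <- 8000; e <- 11000
  cs <- sim_case("DEL", c(s, e), "hom", sig_blunt(), ref_len = L,
                 depth = 80, seed = 59)
  res <- run_pipeline(cs$aln, cs$ctrl, cs$reference, cs$model)
  fwd <- res$calls[res$calls$resolution == "base_precise", ]

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cs$reference)))
  spec_rc <- cnv_spec("DEL", list(c(L - e, L - s)), "hom", sig_blunt())
  tr_rc <- structure(list(
    reference = rc,
    seq_id = "chr6",
    haplotypes = list(
      list(seq = as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cs$truth$haplotypes[[1]]$seq))),
        blocks = data.frame(hap_start = c(0, L - e),
                            len = c(L - e, s),
                            ref_start = c(0, L - s))),
      list(seq = as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cs$truth$haplotypes[[1]]$seq))),
        blocks = data.frame(hap_start = c(0, L - e),
                            len = c(L - e, s),
                            ref_start = c(0, L - s)))),
    junctions = data.frame(junction = 1, left = L - e, right = L - s,
                           orientation = "deletion", signature = "blunt",
                           sig_seq = "", hap_junction = L - e),
    spec = spec_rc), class = "sim_truth")
  rd_rc <- simulate_reads(tr_rc, mean_depth = 80, seed = 59)
  al_rc <- align_reads(rd_rc, tr_rc)
  ctrl_rc <- simulate_control(rc, mean_depth = 80, seed = 60)
  res_rc <- run_pipeline(al_rc, ctrl_rc, rc, cs$model)
  mir <- res_rc$calls[res_rc$calls$resolution == "base_precise", ]
  expect_equal(nrow(mir), 1)
  expect_equal(mir$start, L - fwd$end)
  expect_equal(mir$end, L - fwd$start)
})
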