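test_that("reference generation is seeded, GC-controlled and validated", {
  expect_identical(make_reference(10000, 0.5, seed = 7),
                   make_reference(10000, 0.5, seed = 7))
  at_only <- make_reference(5000, 0, seed = 3)
  expect_false(grepl("[GC]", at_only))
  expect_error(make_reference(500, 0.5), ">= 1000")
  expect_error(make_reference(5000, 1.5), "gc_fraction")
  # observed GC within 3 binomial s.d. of target over 100 kb
  x <- make_reference(100000, 0.42, seed = 9)
  gc <- lengths(regmatches(x, gregexpr("[GC]", x)))
  expect_lt(abs(gc - 42000), 3 * sqrt(100000 * 0.42 * 0.58))
})

test_that("apply_cnv plants the requested junction signatures and geometry", {
  ref <- make_reference(20000, 0.42, seed = 5)
  L <- nchar(ref)

  # microhomology deletion: both breakpoint ends share the sequence and the
  # share is maximal
  tr <- apply_cnv(ref, cnv_spec("DEL", list(c(8000, 13465)), "hom",
                                sig_microhomology("AACAA")), seed = 5)
  expect_equal(nchar(tr$haplotypes[[1]]$seq), L - 5465)
  r2 <- tr$reference
  expect_equal(substr(r2, 8001, 8005), "AACAA")
  expect_equal(substr(r2, 13466, 13470), "AACAA")
  expect_false(substr(r2, 8006, 8006) == substr(r2, 13471, 13471))
  expect_false(substr(r2, 8000, 8000) == substr(r2, 13465, 13465))

  # blunt deletion: no shared bases at the junction
  trb <- apply_cnv(ref, cnv_spec("DEL", list(c(8000, 9000)), "het",
                                 sig_blunt()), seed = 5)
  rb <- trb$reference
  expect_equal(nchar(trb$haplotypes[[1]]$seq), L - 1000)
  expect_false(substr(rb, 8001, 8001) == substr(rb, 9001, 9001))
  expect_false(substr(rb, 8000, 8000) == substr(rb, 9000, 9000))
  # het: second haplotype is the (edited) reference
  expect_identical(trb$haplotypes[[2]]$seq, rb)

  # tandem duplication gains length and joins end to start
  trd <- apply_cnv(ref, cnv_spec("TANDEM_DUP", list(c(6000, 9000)), "het",
                                 sig_blunt()), seed = 5)
  mut <- trd$haplotypes[[1]]$seq
  expect_equal(nchar(mut), L + 3000)
  expect_equal(substr(mut, 9001, 12000), substr(trd$reference, 6001, 9000))

  # insertion junction carries the inserted bases in the mutant
  tri <- apply_cnv(ref, cnv_spec("DEL", list(c(8000, 9000)), "het",
                                 sig_insertion("TA")), seed = 5)
  expect_equal(nchar(tri$haplotypes[[1]]$seq), L - 1000 + 2)
  expect_equal(substr(tri$haplotypes[[1]]$seq, 8001, 8002), "TA")

  # overlapping DEL_NML_DEL segments rejected
  expect_error(cnv_spec("DEL_NML_DEL", list(c(1000, 3000), c(2500, 4000)),
                        "het", sig_blunt()), "disjoint")
  # segment outside reference rejected
  expect_error(apply_cnv(ref, cnv_spec("DEL", list(c(1000, 30000)), "het",
                                       sig_blunt())), "outside")
})

test_that("read simulation is seeded, Poisson-scaled and validated", {
  ref <- make_reference(50000, 0.42, seed = 2)
  expect_error(simulate_reads(ref, mean_depth = 0), "> 0")
  expect_error(simulate_reads(ref, mean_depth = 10, read_len = 500,
                              fragment_mean = 400), "read_len")

  r1 <- simulate_reads(ref, mean_depth = 20, seed = 4)
  r2 <- simulate_reads(ref, mean_depth = 20, seed = 4)
  expect_identical(r1, r2)
  f1a <- withr::local_tempfile(fileext = ".fq")
  f1b <- withr::local_tempfile(fileext = ".fq")
  f2a <- withr::local_tempfile(fileext = ".fq")
  f2b <- withr::local_tempfile(fileext = ".fq")
  write_fastq(r1, f1a, f1b); write_fastq(r2, f2a, f2b)
  expect_identical(readLines(f1a), readLines(f2a))
  expect_identical(readLines(f1b), readLines(f2b))

  # depth 60 on a 50-kb haplotype: ~10,000 pairs within 3 Poisson s.d.
  rp <- simulate_reads(ref, mean_depth = 60, seed = 8)
  expect_lt(abs(nrow(rp) - 10000), 3 * sqrt(10000))
})

test_that("analytic alignment emits aligner-like placements and clips", {
  cs <- sim_case("DEL", c(8000, 11000), "hom", sig_microhomology("AACAA"),
                 ref_len = 20000, depth = 80, seed = 13)
  al <- cs$aln
  tr <- cs$truth
  # reads fully inside collinear blocks carry a pure-match CIGAR
  inner <- al[al$mapped & al$left_clip == 0 & al$right_clip == 0, ]
  expect_true(all(grepl("^150M$", inner$cigar)))
  # hom deletion: no mapped read starts inside the deleted interior
  expect_equal(sum(al$pos > 8005 & al$pos < 11000 - 150, na.rm = TRUE), 0)
  # soft-clip boundaries cluster at the truth junction up to the planted
  # microhomology length (5 bp, right-shifted by extension)
  clips <- extract_softclips(al)
  expect_gt(nrow(clips), 5)
  expect_true(all(abs(clips$pos[clips$side == "right"] - 8005) <= 5))
  expect_true(all(abs(clips$pos[clips$side == "left"] - 11000) <= 5))
  # mate pairs straddling the deletion have reference spans inflated by the
  # deletion length
  sp <- split(al[al$mapped, ], al$qname[al$mapped])
  sp <- sp[vapply(sp, nrow, 0L) == 2]
  spans <- vapply(sp, function(p) max(p$pos + p$mapped_len) - min(p$pos), 0)
  straddle <- vapply(sp, function(p)
    min(p$pos) < 7800 && max(p$pos) > 11050, TRUE)
  if (any(straddle))
    expect_true(all(spans[straddle] > 3000))
  # base conservation: an error-free fully-mapped read equals the haplotype
  rd0 <- simulate_reads(tr, mean_depth = 10, error_rate = 0, seed = 99)
  al0 <- align_reads(rd0, tr)
  full0 <- al0[al0$mapped & al0$cigar == "150M", ][1, ]
  expect_equal(full0$seq,
               substr(tr$reference, full0$pos + 1, full0$pos + 150))
})

test_that("SAM round trip preserves placements, clips and sequences", {
  cs <- sim_case("DEL", c(5000, 9000), "het", sig_blunt(), ref_len = 15000,
                 depth = 30, seed = 17)
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(cs$aln, f)
  back <- read_alignments(f)
  a <- cs$aln[cs$aln$mapped, ]
  b <- back[back$mapped, ]
  b <- b[order(b$pos, b$qname, b$mate), ]
  a <- a[order(a$pos, a$qname, a$mate), ]
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$pos, b$pos)
  expect_equal(a$cigar, b$cigar)
  expect_equal(a$seq, b$seq)
})
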