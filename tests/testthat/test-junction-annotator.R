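test_that("junction characterization recovers planted signatures", {
  set.seed(61)
  L <- rnd_seq(60); R <- rnd_seq(60)

  # shared AACAA at both ends -> microhomology
  cont_l <- paste0(rnd_other(substr(R, 1, 1)), rnd_seq(19))
  pre_r <- paste0(rnd_seq(19), rnd_other(last_char(L)))
  mh <- characterize_junction(paste0(L, "AACAA", R),
                              paste0(L, "AACAA", cont_l),
                              paste0(pre_r, "AACAA", R))
  expect_equal(mh$kind, "microhomology")
  expect_equal(mh$seq, "AACAA")

  # exact abutment -> blunt
  bl <- characterize_junction(paste0(L, R), paste0(L, cont_l),
                              paste0(pre_r, R))
  expect_equal(bl$kind, "blunt")

  # two foreign bases between the matches -> insertion "TA"
  cont_l2 <- paste0(rnd_other("T"), rnd_seq(19))
  pre_r2 <- paste0(rnd_seq(19), rnd_other("A"))
  ins <- characterize_junction(paste0(L, "TA", R), paste0(L, cont_l2),
                               paste0(pre_r2, R))
  expect_equal(ins$kind, "insertion")
  expect_equal(ins$seq, "TA")

  # flanks that do not match the reference error out
  expect_error(characterize_junction(rnd_seq(120), rnd_seq(80), rnd_seq(80)),
               "does not match")
})

test_that("characterization agrees with the exhaustive split-point oracle", {
  set.seed(67)
  for (i in 1:2000) {
    j <- random_junction()
    got <- characterize_junction(j$contig, j$left_ref, j$right_ref)
    want <- oracle_characterize(j$contig, j$left_ref, j$right_ref)
    expect_identical(got$kind, want$kind)
    expect_identical(got$seq, want$seq)
    expect_identical(got$kind, j$kind)   # and both equal the planted truth
    expect_identical(got$seq, j$seq)
  }
})

test_that("insertion origin search separates templated from random", {
  ref <- make_reference(50000, 0.42, seed = 71)
  # 28-bp insertion copied from 200 bp upstream of the breakpoint
  src <- substr(ref, 19801, 19828)
  o <- locate_insertion_origin(src, ref, 20000, 25000)
  expect_equal(o$origin, "templated")
  expect_true(o$source_near_breakpoint)
  expect_equal(o$source_start, 19800)
  # short insertions are random by rule, no search
  expect_equal(locate_insertion_origin("TA", ref, 20000, 25000)$origin,
               "random")
  # a 50-bp random sequence has no qualifying match
  set.seed(73)
  expect_equal(locate_insertion_origin(rnd_seq(50), ref, 20000, 25000)$origin,
               "random")
})

test_that("near-breakpoint errors are recovered at their coordinates", {
  ref <- make_reference(20000, 0.42, seed = 79)
  x <- 8000; y <- 11000
  flank_l <- substr(ref, x - 99, x)     # 100 bp ending at breakpoint
  flank_r <- substr(ref, y + 1, y + 100)
  contig <- paste0(flank_l, flank_r)
  # error-free junction: empty list
  e0 <- detect_breakpoint_errors(contig, 100, ref, x, y)
  expect_equal(nrow(e0), 0)
  # plant a C>G-style change 18 bp left of the breakpoint and one on the
  # right flank: both recovered
  c2 <- contig
  old_l <- substr(c2, 83, 83)
  substr(c2, 83, 83) <- rnd_other(old_l)         # 18 bp from junction
  old_r <- substr(c2, 130, 130)
  substr(c2, 130, 130) <- rnd_other(old_r)       # 30 bp right of junction
  e2 <- detect_breakpoint_errors(c2, 100, ref, x, y)
  expect_equal(nrow(e2), 2)
  expect_setequal(e2$pos, c(x - 18, y + 29))
  expect_equal(e2$ref[e2$pos == x - 18], old_l)
  # polymorphism list suppresses known variants
  e1 <- detect_breakpoint_errors(c2, 100, ref, x, y,
                                 polymorphisms = e2[e2$side == "left", ])
  expect_equal(nrow(e1), 1)
  expect_equal(e1$side, "right")
})

test_that("repeat overlap annotates ends and flags homologous pairs", {
  # reference with two near-identical LINE copies spanning the breakpoints
  set.seed(83)
  core <- rnd_seq(600)
  copy2 <- core
  for (p in sample(600, 6)) substr(copy2, p, p) <- rnd_other(substr(copy2, p, p))
  ref <- paste0(rnd_seq(2000), core, rnd_seq(3000), copy2, rnd_seq(2000))
  reps <- data.frame(seq_id = "chr6", start = c(2000, 5600),
                     end = c(2600, 6200),
                     family = c("L1PA2", "L1PA5"),
                     class = c("LINE", "LINE"), stringsAsFactors = FALSE)
  ro <- repeat_overlap(2300, 5900, reps, ref)
  expect_equal(ro$left$family, "L1PA2")
  expect_equal(ro$right$family, "L1PA5")
  expect_true(ro$homologous_pair)  # ~600-bp identity block >= 100 bp

  # same-class but dissimilar copies: no pair flag
  reps2 <- reps
  ref2 <- paste0(rnd_seq(2000), rnd_seq(600), rnd_seq(3000), rnd_seq(600),
                 rnd_seq(2000))
  expect_false(repeat_overlap(2300, 5900, reps2, ref2)$homologous_pair)

  # empty track: no annotations
  ro0 <- repeat_overlap(2300, 5900, NULL, ref)
  expect_equal(nrow(ro0$left), 0)
  expect_false(ro0$homologous_pair)
})

test_that("mechanism classification follows the priority rules and is pure", {
  expect_equal(classify_mechanism("microhomology"), "NHEJ_or_MMBIR")
  expect_equal(classify_mechanism("blunt"), "NHEJ")
  expect_equal(classify_mechanism("insertion", insertion_origin = "random"),
               "NHEJ")
  expect_equal(classify_mechanism("insertion", insertion_origin = "templated"),
               "serial_replication_stalling")
  expect_equal(classify_mechanism("microhomology", homologous_pair = TRUE),
               "repeat_mediated_rearrangement")
  expect_equal(classify_mechanism("insertion", insertion_origin = "templated",
                                  complex_event = TRUE), "FoSTeS_MMBIR")
  # purity: rule-irrelevant fields never change the label
  for (orig in c("random", "templated"))
    expect_equal(classify_mechanism("blunt", insertion_origin = orig,
                                    homologous_pair = TRUE),
                 "repeat_mediated_rearrangement")
  for (sig in c("microhomology", "insertion", "blunt"))
    expect_equal(classify_mechanism(sig, insertion_origin = "random",
                                    complex_event = TRUE), "FoSTeS_MMBIR")
  # idempotence / determinism
  expect_identical(classify_mechanism("microhomology"),
                   classify_mechanism("microhomology"))
})

test_that("signature trichotomy holds on the cohort junction fixture", {
  fx <- load_lama2_cohort()
  s <- spectrum_report(fx$junctions, fx$probands)
  expect_equal(sum(s$signature_counts), s$n_signature_junctions)
  expect_equal(s$n_signature_junctions, 27)
  # every signature-bearing junction has exactly one signature kind set
  j <- fx$junctions[fx$junctions$resolved == "yes", ]
  kinds <- (nzchar(j$microhomology)) + (nzchar(j$insertion)) +
    (j$blunt == "yes")
  expect_true(all(kinds <= 1))
})
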