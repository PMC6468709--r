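test_that("three-frame translation follows the standard code", {
  tf <- translate_frames("ATGTAA")
  expect_equal(tf$frame1$peptide, "M*")
  expect_equal(tf$frame1$stop_positions, 2L)
  expect_equal(tf$frame2$peptide, "C")  # TGT; trailing AA dropped
  expect_equal(translate_frames("TTATAG")$frame1$peptide, "L*")
  # codons containing N become X; other symbols are refused
  expect_equal(translate_frames("ATGANA")$frame1$peptide, "MX")
  expect_error(translate_frames("ATGQAA"), "symbols")
})

test_that("peptide length equals floor((len - offset) / 3) in every frame", {
  set.seed(41)
  for (len in c(3, 7, 12, 50, 101)) {
    seq <- rand_dna(len)
    tf <- translate_frames(seq)
    for (off in 0:2)
      expect_equal(nchar(tf[[off + 1]]$peptide), (len - off) %/% 3)
  }
})

test_that("stop-in-all-frames scan agrees with a direct per-frame oracle", {
  # TAA repeats: frame 1 is all stops but frames 2 (AAT) and 3 (ATA) have
  # none, so the all-frames condition fails
  taa <- strrep("TAA", 5)
  expect_false(stops_in_all_frames(taa))
  expect_true(stops_oracle(taa, 1))
  expect_false(stops_oracle(taa, 2))
  expect_false(stops_in_all_frames("ATGGCTGCT"))
  # interleaved stops hit every frame
  allstop <- "TAATAGTGATAATAGTGA"
  expect_equal(stops_in_all_frames(allstop),
               all(vapply(1:3, function(f) stops_oracle(allstop, f),
                          logical(1))))
  expect_error(stops_in_all_frames("ATG"), "short")
  set.seed(42)
  for (i in 1:10) {
    seq <- rand_dna(60)
    expect_equal(stops_in_all_frames(seq),
                 all(vapply(1:3, function(f) stops_oracle(seq, f),
                            logical(1))))
  }
})

test_that("ORF scan is consistent with the frame translations", {
  expect_true(orf_scan("ATGGCTGCTGCT", 1))
  expect_false(orf_scan("ATGTAAGCT", 1))
  set.seed(43)
  for (i in 1:10) {
    seq <- rand_dna(300)
    for (f in 1:3) {
      tf <- translate_frames(seq)[[f]]
      expect_equal(orf_scan(seq, f), length(tf$stop_positions) == 0L)
    }
  }
  # an ORF in one frame means not all frames are interrupted
  set.seed(44)
  repeat {
    seq <- rand_dna(90)
    if (orf_scan(seq, 1)) break
  }
  expect_false(stops_in_all_frames(seq))
})

test_that("stop-skip events capture TAA->TTA and TAA<->TGG differences", {
  pre <- "ATGGCT"; post <- "GCTGCA"
  a <- paste0(pre, "TAA", post)
  b <- paste0(pre, "TTA", post)
  ev <- detect_stop_skip(a, b, frame = 1, species_a = "human",
                         species_b = "gorilla")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$aligned_codon_index, 3L)
  expect_equal(ev$species_with_stop, "human")
  expect_equal(ev$stop_codon, "TAA")
  expect_equal(ev$other_aa, "L")
  ev2 <- detect_stop_skip(a, paste0(pre, "TGG", post), frame = 1,
                          species_a = "chicken", species_b = "mouse")
  expect_equal(ev2$other_aa, "W")
  expect_equal(nrow(detect_stop_skip(a, a, frame = 1)), 0L)
  expect_error(detect_stop_skip("ATG", "ATGGCT"), "length")
})

test_that("stop-skip detection is symmetric under argument swap", {
  set.seed(45)
  a <- rand_dna(90)
  b <- a
  substr(b, 31, 33) <- "TAA"
  substr(a, 31, 33) <- "CAA"
  e1 <- detect_stop_skip(a, b, 1, "x", "y")
  e2 <- detect_stop_skip(b, a, 1, "y", "x")
  expect_equal(e1$aligned_codon_index, e2$aligned_codon_index)
  expect_equal(e1$species_with_stop, e2$species_with_stop)
})

test_that("gapped alignment columns are excluded before codon comparison", {
  a <- "ATG-GCTTAAGCA"
  b <- "ATGCGCTTGGGCA"
  ev <- detect_stop_skip(a, b, frame = 1)
  # after dropping the gap column both read ATG GCT TAA/TGG GCA
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$aligned_codon_index, 3L)
  expect_equal(ev$other_codon, "TGG")
})

test_that("frameshift indels are gap runs with length not divisible by 3", {
  expect_equal(detect_frameshift_indel("50M1I30M")$frame_delta, 1L)
  expect_equal(nrow(detect_frameshift_indel("50M3D30M")), 0L)
  ev <- detect_frameshift_indel("10M1I10M3D10M2I10M")
  expect_equal(ev$indel_length, c(1L, 2L))
  expect_equal(ev$frame_delta, c(1L, 2L))
  expect_equal(ev$alignment_position, c(11L, 35L))
})

test_that("CIS-by-transcript overlap classification and splice flanks", {
  # gene: exon [0,50), intron with CIS [100,220), exon [300,350)
  # variant 2 exonizes the CIS exactly; AG/GT flanks planted
  seq <- strrep("C", 400)
  substr(seq, 99, 100) <- "AG"    # positions 98-99 (0-based): AG upstream
  substr(seq, 221, 222) <- "GT"   # positions 220-221: GT downstream
  g <- gene_model("g", "sp", seq, list(
    transcript_variant("t1", data.frame(start = c(0, 300), end = c(50, 350))),
    transcript_variant("t2", data.frame(start = c(0, 100, 300),
                                        end = c(50, 220, 350)),
                       cds_start = 0L)))
  cis <- list(start = 100L, end = 220L)
  ev <- exonization_status(cis, g)
  expect_equal(nrow(ev), 1L)  # t1 has no overlap at all
  expect_equal(ev$transcript_id, "t2")
  expect_equal(ev$fraction_of_cis, 1.0)
  expect_true(ev$splice_ok)
  # frame: CIS starts at spliced offset 50 with cds_start 0 -> (50 %% 3) + 1
  expect_equal(ev$frame, (50L %% 3L) + 1L)
  # a CIS overlapping no variant returns no events
  ev0 <- exonization_status(list(start = 230L, end = 290L), g)
  expect_equal(nrow(ev0), 0L)
  expect_error(exonization_status(list(start = 390L, end = 500L), g),
               "outside")
})

test_that("sub-threshold partial overlaps are not called exonized", {
  g <- gene_model("g", "sp", strrep("C", 400), list(
    transcript_variant("t1", data.frame(start = 100, end = 120))))
  # 20 nt of a 120-nt CIS: fraction 0.17 and below 30 nt
  ev <- exonization_status(list(start = 100L, end = 220L), g)
  expect_equal(nrow(ev), 0L)
  # 20 nt of a 30-nt CIS: fraction 2/3 passes the fraction rule
  ev2 <- exonization_status(list(start = 100L, end = 130L), g)
  expect_equal(nrow(ev2), 1L)
})
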