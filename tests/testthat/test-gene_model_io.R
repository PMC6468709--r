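test_that("GFF3 1-based closed coordinates convert to 0-based half-open", {
  d <- withr::local_tempdir()
  gff <- file.path(d, "g.gff3"); fa <- file.path(d, "g.fa")
  set.seed(1)
  seq <- rand_dna(100)
  writeLines(c("##gff-version 3",
               "G\tx\tgene\t1\t100\t.\t+\t.\tID=G;species=sp",
               "G\tx\tmRNA\t1\t30\t.\t+\t.\tID=t1;Parent=G",
               "G\tx\texon\t1\t10\t.\t+\t.\tID=t1.e1;Parent=t1",
               "G\tx\texon\t21\t30\t.\t+\t.\tID=t1.e2;Parent=t1"), gff)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(c(G = seq)), fa)
  genes <- read_gene_models(gff, fa)
  expect_length(genes, 1)
  ex <- genes[[1]]$transcripts[[1]]$exons
  expect_equal(ex$start, c(0L, 20L))
  expect_equal(ex$end, c(10L, 30L))
  introns <- extract_introns(genes[[1]])
  expect_equal(introns$start, 10L)
  expect_equal(introns$end, 20L)
  expect_equal(introns$sequence, substring(seq, 11, 20))
})

test_that("out-of-bounds exons raise a structural error naming the feature", {
  d <- withr::local_tempdir()
  gff <- file.path(d, "g.gff3"); fa <- file.path(d, "g.fa")
  writeLines(c("##gff-version 3",
               "G\tx\tgene\t1\t100\t.\t+\t.\tID=G",
               "G\tx\tmRNA\t1\t150\t.\t+\t.\tID=t1;Parent=G",
               "G\tx\texon\t1\t150\t.\t+\t.\tID=t1.e1;Parent=t1"), gff)
  set.seed(1)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(c(G = rand_dna(100))),
                              fa)
  expect_error(read_gene_models(gff, fa), "t1.*bounds")
})

test_that("overlapping exons within one transcript are refused", {
  expect_error(transcript_variant("t", data.frame(start = c(0, 5),
                                                  end = c(10, 20))),
               "overlapping")
  expect_error(transcript_variant("t", data.frame(start = 5, end = 5)),
               "empty")
})

test_that("minus-strand genes are flipped into transcription orientation", {
  d <- withr::local_tempdir()
  gff <- file.path(d, "g.gff3"); fa <- file.path(d, "g.fa")
  set.seed(2)
  plus <- rand_dna(60)
  minus <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(plus)))
  # exon at genomic 1-10 on the minus strand = last 10 nt in transcription
  # orientation
  writeLines(c("##gff-version 3",
               "G\tx\tgene\t1\t60\t.\t-\t.\tID=G",
               "G\tx\tmRNA\t1\t60\t.\t-\t.\tID=t1;Parent=G",
               "G\tx\texon\t1\t10\t.\t-\t.\tID=t1.e1;Parent=t1",
               "G\tx\texon\t31\t60\t.\t-\t.\tID=t1.e2;Parent=t1"), gff)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(c(G = minus)), fa)
  g <- read_gene_models(gff, fa)[[1]]
  expect_equal(g$sequence, plus)
  expect_equal(g$transcripts[[1]]$exons$start, c(0L, 50L))
  expect_equal(g$transcripts[[1]]$exons$end, c(30L, 60L))
})

test_that("intron extraction handles gaps, abutting exons, and single exons", {
  mkgene <- function(exons) {
    gene_model("g", "sp", strrep("A", 60),
               list(transcript_variant("t1", exons)))
  }
  iv <- extract_introns(mkgene(data.frame(start = c(0, 20, 40),
                                          end = c(10, 30, 50))))
  expect_equal(iv$ordinal, c(1L, 2L))
  expect_equal(iv$start, c(10L, 30L))
  expect_equal(iv$end, c(20L, 40L))
  # abutting exons produce no intron (fused-exon convention)
  iv2 <- extract_introns(mkgene(data.frame(start = c(0, 10), end = c(10, 30))))
  expect_equal(nrow(iv2), 0L)
  # single exon: no introns by definition
  iv3 <- extract_introns(mkgene(data.frame(start = 0, end = 10)))
  expect_equal(nrow(iv3), 0L)
})

test_that("total intronic nucleotides is additive over introns and genes", {
  g1 <- gene_model("g1", "sp", strrep("A", 300),
                   list(transcript_variant("t1", data.frame(
                     start = c(0, 110, 180), end = c(10, 160, 200)))))
  # introns: [10,110) = 100 nt and [160,180) = 20 nt
  expect_equal(total_intronic_nucleotides(list(g1)), 120L)
  g2 <- gene_model("g2", "sp", strrep("A", 100),
                   list(transcript_variant("t1", data.frame(
                     start = c(0, 40), end = c(10, 60)))))
  expect_equal(total_intronic_nucleotides(list(g1, g2)), 150L)
  expect_equal(total_intronic_nucleotides(list()), 0L)
})

test_that("gene models round-trip through GFF3 + FASTA", {
  sim <- test_family()
  d <- withr::local_tempdir()
  for (sp in names(sim$genes)) {
    write_gene_models(sim$genes[[sp]], file.path(d, paste0(sp, ".gff3")),
                      file.path(d, paste0(sp, ".fa")))
    back <- read_gene_models(file.path(d, paste0(sp, ".gff3")),
                             file.path(d, paste0(sp, ".fa")))
    for (i in seq_along(back)) {
      orig <- sim$genes[[sp]][[back[[i]]$gene_id]]
      expect_equal(back[[i]]$sequence, orig$sequence)
      expect_equal(back[[i]]$species, orig$species)
      expect_equal(back[[i]]$reference_transcript_id,
                   orig$reference_transcript_id)
      expect_equal(length(back[[i]]$transcripts), length(orig$transcripts))
      for (k in seq_along(orig$transcripts))
        expect_equal(back[[i]]$transcripts[[k]]$exons,
                     orig$transcripts[[k]]$exons)
    }
  }
})

test_that("exon, intron and flank lengths partition every gene", {
  sim <- test_family()
  for (g in sim$genes$chicken) {
    ex <- reference_transcript <- NULL
    tr <- g$transcripts[[1]]
    exon_nt <- sum(tr$exons$end - tr$exons$start)
    intron_nt <- sum(with(extract_introns(g), end - start))
    flank <- min(tr$exons$start) + (nchar(g$sequence) - max(tr$exons$end))
    expect_equal(exon_nt + intron_nt + flank, nchar(g$sequence))
  }
})

test_that("CIS BED output is well-formed and refuses bad intervals", {
  d <- withr::local_tempdir()
  p <- file.path(d, "c.bed")
  calls <- data.frame(gene_id = "G", intron_ordinal = 1L, start = 100L,
                      end = 200L, conserved_in = "chicken+mouse+human")
  write_cis_bed(calls, p)
  lines <- readLines(p)
  expect_equal(lines[2], "G\t100\t200\tG:1:chicken+mouse+human\t0\t+")
  write_cis_bed(calls[0, ], p)
  expect_equal(length(readLines(p)), 1L)  # header comment only
  expect_match(readLines(p)[1], "^#")
  bad <- transform(calls, end = 100L)
  expect_error(write_cis_bed(bad, p), "refused")
})
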