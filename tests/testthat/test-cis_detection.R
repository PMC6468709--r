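mk_gene <- function(id, sp, exons, len = 2000) {
  gene_model(id, sp, strrep("A", len),
             list(transcript_variant("t1", exons)))
}

test_that("equal intron counts pair by ordinal identity", {
  ex <- data.frame(start = seq(0, 1400, by = 200),
                   end = seq(100, 1500, by = 200))
  a <- mk_gene("g", "A", ex); b <- mk_gene("g", "B", ex)
  p <- correspond_introns(a, b)
  expect_equal(p$ordinal_a, 1:7)
  expect_equal(p$ordinal_b, 1:7)
})

test_that("fused exons induce the brute-force optimal partial pairing", {
  # exon lengths (100,90,200,150) vs (100,290,150): exons 2+3 fused in B
  a <- mk_gene("g", "A", data.frame(start = c(0, 110, 210, 420),
                                    end = c(100, 200, 410, 570)))
  b <- mk_gene("g", "B", data.frame(start = c(0, 110, 410),
                                    end = c(100, 400, 560)))
  p <- correspond_introns(a, b)
  expect_equal(p$ordinal_a, c(1L, 3L))
  expect_equal(p$ordinal_b, c(1L, 2L))
  # the exon pairing behind it must equal the exhaustive optimum
  oracle <- exon_pairing_oracle(c(100, 90, 200, 150), c(100, 290, 150))
  expect_equal(unname(oracle$pairs), matrix(c(1, 1, 3, 2, 4, 3), ncol = 2,
                                            byrow = TRUE))
})

test_that("random exon-length vectors pair like the exhaustive oracle", {
  set.seed(31)
  for (rep in 1:5) {
    la <- sample(80:300, sample(3:5, 1))
    lb <- sample(80:300, sample(3:5, 1))
    got <- ciscover:::align_exon_vectors(la, lb)
    oracle <- exon_pairing_oracle(la, lb)
    score_got <- sum(-abs(log(la[got$a] / lb[got$b]))) -
      1.0 * (length(la) - nrow(got)) - 1.0 * (length(lb) - nrow(got))
    expect_equal(score_got, oracle$score, tolerance = 1e-9)
  }
})

test_that("intronless genes yield an empty pairing", {
  a <- mk_gene("g", "A", data.frame(start = 0, end = 100))
  b <- mk_gene("g", "B", data.frame(start = c(0, 200, 400),
                                    end = c(100, 300, 500)))
  expect_equal(nrow(correspond_introns(a, b)), 0L)
})

test_that("the E-value filter boundary is inclusive", {
  hs <- data.frame(q_start = c(0, 10, 20), q_end = c(5, 15, 25),
                   s_start = c(0, 10, 20), s_end = c(5, 15, 25),
                   score = c(100, 90, 80),
                   evalue = c(9e-10, 1e-9, 1e-12))
  kept <- filter_hsps(hs, 9e-10)
  expect_equal(kept$evalue, c(9e-10, 1e-12))
  expect_equal(nrow(filter_hsps(hs[0, ], 9e-10)), 0L)
})

test_that("order-consistent chaining keeps agreeing HSPs, drops crossings", {
  two <- data.frame(q_start = c(0, 200), q_end = c(120, 280),
                    s_start = c(50, 300), s_end = c(170, 380),
                    score = c(1, 1), evalue = 0)
  expect_equal(nrow(chain_order_consistent(two)), 2L)
  # crossing pair of weights 120 and 80: only the heavier survives
  cross <- data.frame(q_start = c(0, 200), q_end = c(120, 280),
                      s_start = c(300, 50), s_end = c(420, 130),
                      score = c(1, 1), evalue = 0)
  kept <- chain_order_consistent(cross)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$q_end - kept$q_start, 120)
})

test_that("chaining equals exhaustive subset maximization on random HSPs", {
  set.seed(32)
  for (rep in 1:10) {
    n <- 8
    hs <- data.frame(q_start = sample(0:500, n), s_start = sample(0:500, n))
    hs$q_end <- hs$q_start + sample(20:120, n, replace = TRUE)
    hs$s_end <- hs$s_start + (hs$q_end - hs$q_start)
    hs$score <- 1; hs$evalue <- 0
    got <- chain_order_consistent(hs)
    expect_equal(sum(got$q_end - got$q_start), chain_oracle(hs)$weight)
  }
})

test_that("interval union never double-counts and matches the bitmap", {
  iv <- data.frame(q_start = c(0, 50), q_end = c(100, 150),
                   s_start = c(0, 50), s_end = c(100, 150))
  u <- conserved_intervals(iv, "query")
  expect_equal(u, data.frame(start = 0L, end = 150L))
  expect_equal(nrow(conserved_intervals(iv[0, ], "query")), 0L)
  set.seed(33)
  for (rep in 1:5) {
    n <- 20
    st <- sample(0:900, n)
    iv <- data.frame(q_start = st, q_end = st + sample(10:80, n, TRUE),
                     s_start = st, s_end = st + 10)
    u <- conserved_intervals(iv, "query")
    expect_equal(sum(u$end - u$start),
                 bitmap_union_len(data.frame(start = iv$q_start,
                                             end = iv$q_end), 1000))
  }
})

test_that("multi-species intersection equals the AND-bitmap oracle", {
  full <- list(chicken = data.frame(start = 100, end = 200),
               mouse = data.frame(start = 100, end = 200),
               human = data.frame(start = 100, end = 200))
  runs <- intersect_multispecies(full, min_len = 30)
  expect_equal(runs$start, 100L)
  expect_equal(runs$end, 200L)
  expect_equal(runs$conserved_in, "chicken+mouse+human")
  disjoint <- list(a = data.frame(start = 0, end = 100),
                   b = data.frame(start = 200, end = 300))
  expect_equal(nrow(intersect_multispecies(disjoint, min_len = 30)), 0L)
  set.seed(34)
  for (rep in 1:5) {
    per <- lapply(1:3, function(i) {
      st <- sample(0:800, 8)
      data.frame(start = st, end = st + sample(30:150, 8, TRUE))
    })
    names(per) <- c("a", "b", "c")
    per <- lapply(per, ciscover:::merge_intervals)
    runs <- intersect_multispecies(per, min_len = 1)
    b <- bitmap_intersect(per, 1000)
    expect_equal(sum(runs$end - runs$start), sum(b[1:960]))
  }
})

test_that("conservation report reproduces published-style accounting", {
  rep1 <- build_report("chicken", c(mouse = 14987, human = 20601), 467846)
  expect_equal(rep1$percentage, c(3.203, 4.403))
  rep2 <- build_report("zebrafish", c(mouse = 1106), 472638)
  expect_equal(rep2$percentage, 0.234)
  expect_equal(build_report("x", c(t = 0), 1000)$percentage, 0)
  expect_error(build_report("x", c(t = 0), 0), "empty intron pool")
})

test_that("exact tandem duplicates are recovered with identity 1", {
  set.seed(35)
  x <- rand_dna(120)
  # bare copy-spacer-copy region: boundaries and identity recovered exactly
  region <- paste0(x, rand_dna(150), x)
  dup <- detect_intragene_duplication(region, params = test_ka_params())
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$identity, 1.0)
  expect_equal(dup$a_start, 0)
  expect_equal(dup$b_start, 270)
  # with random flanks, extension may pick up a few chance matches at the
  # copy boundaries; the copies are still recovered essentially intact
  region2 <- paste0(rand_dna(100), x, rand_dna(150), x, rand_dna(100))
  dup2 <- detect_intragene_duplication(region2, params = test_ka_params())
  expect_equal(nrow(dup2), 1L)
  expect_gte(dup2$identity, 0.97)
  expect_lte(abs(dup2$a_start - 100), 5)
  expect_lte(abs(dup2$b_start - 370), 5)
})

test_that("diverged duplicates report identity near the mutation budget", {
  set.seed(36)
  hits <- 0
  for (rep in 1:5) {
    x <- rand_dna(120)
    xm <- strsplit(x, "")[[1]]
    mut <- sample(120, 12)  # exactly 10% substituted
    for (i in mut) xm[i] <- sample(setdiff(c("A", "C", "G", "T"), xm[i]), 1)
    region <- paste0(rand_dna(100), x, rand_dna(150),
                     paste(xm, collapse = ""), rand_dna(100))
    dup <- detect_intragene_duplication(region, params = test_ka_params())
    if (nrow(dup) >= 1 && dup$identity[1] >= 0.85 && dup$identity[1] <= 0.95)
      hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("random regions contain no significant duplication", {
  set.seed(37)
  for (rep in 1:3) {
    region <- rand_dna(500)
    dup <- detect_intragene_duplication(region, params = test_ka_params())
    expect_equal(nrow(dup), 0L)
  }
})

test_that("conserved counts shrink when the E-value bound tightens", {
  sim <- test_family()
  p <- test_ka_params()
  loose <- find_cis(sim$genes, "zebrafish", c("chicken", "mouse"),
                    params = p, max_evalue = 1e-5)
  tight <- find_cis(sim$genes, "zebrafish", c("chicken", "mouse"),
                    params = p, max_evalue = 1e-30)
  expect_true(all(tight$report$conserved_nt <= loose$report$conserved_nt))
  # raising the length floor never increases the number of calls
  short <- find_cis(sim$genes, "zebrafish", c("chicken", "mouse"),
                    params = p, min_cis_len = 30)
  long <- find_cis(sim$genes, "zebrafish", c("chicken", "mouse"),
                   params = p, min_cis_len = 200)
  expect_lte(nrow(long$calls), nrow(short$calls))
})
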