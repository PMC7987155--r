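test_that("IUPAC enumeration finds overlapping matches on both strands", {
  g <- tiny_genome("GAATCGATTC")
  fwd <- enumerate_iupac_sites(g, "GANTC", strands = "forward")
  expect_equal(fwd$start, c(0, 5))
  expect_equal(fwd$end, c(5, 10))
  both <- enumerate_iupac_sites(g, "GANTC", strands = "both")
  expect_equal(nrow(both), 4)

  expect_equal(nrow(enumerate_iupac_sites(tiny_genome("AAAAA"), "GANTC")), 0)
  # palindrome: one hit per strand at the same interval
  p <- enumerate_iupac_sites(tiny_genome("GAATC"), "GANTC")
  expect_equal(nrow(p), 2)
  expect_equal(unique(p$start), 0)
  expect_error(enumerate_iupac_sites(g, "GAXTC"), "IUPAC")
  # N never matches
  expect_equal(nrow(enumerate_iupac_sites(tiny_genome("GANTC"), "GANTC")), 0)
})

test_that("both-strand counts of a palindromic motif are exactly 2x forward", {
  set.seed(3)
  for (i in 1:5) {
    g <- generate_genome(5000, gc = 0.5, seed = i)$genome
    fwd <- enumerate_iupac_sites(g, "GANTC", strands = "forward")
    both <- enumerate_iupac_sites(g, "GANTC", strands = "both")
    expect_equal(nrow(both), 2 * nrow(fwd))
    # paired identical intervals
    expect_equal(dplyr::filter(both, strand == "-")$start, fwd$start)
  }
})

test_that("operon prediction groups same-strand neighbours within the gap", {
  ann <- tiny_annotation(list("a", 100, 400, "+"), list("b", 430, 700, "+"))
  op <- predict_operons(ann, max_gap = 50)
  expect_equal(op$operon_id[1], op$operon_id[2])
  expect_equal(unique(op$lead_gene_id), "a")      # upstream gene leads

  # gap over the limit splits (boundary: 51 > 50)
  ann2 <- tiny_annotation(list("a", 100, 400, "+"), list("b", 451, 700, "+"))
  op2 <- predict_operons(ann2, max_gap = 50)
  expect_length(unique(op2$operon_id), 2)
  # gap exactly at the limit joins
  ann3 <- tiny_annotation(list("a", 100, 400, "+"), list("b", 450, 700, "+"))
  expect_length(unique(predict_operons(ann3, 50)$operon_id), 1)

  # opposite strands never share an operon; minus-strand lead is 3'-most
  ann4 <- tiny_annotation(list("a", 100, 400, "-"), list("b", 405, 700, "+"))
  expect_length(unique(predict_operons(ann4, 50)$operon_id), 2)
  ann5 <- tiny_annotation(list("a", 100, 400, "-"), list("b", 405, 700, "-"))
  op5 <- predict_operons(ann5, 50)
  expect_equal(unique(op5$lead_gene_id), "b")
})

test_that("promoter windows are strand-aware, oriented and edge-truncated", {
  seq <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
               collapse = "")
  g <- tiny_genome(seq)

  # + gene starting at 500 with window (200, 100): forward [300, 600)
  ann <- tiny_annotation(list("a", 500, 700, "+"))
  pr <- extract_promoters(ann, g, 200, 100)
  expect_equal(c(pr$start, pr$end), c(300, 600))
  expect_equal(pr$seq, substr(seq, 301, 600))

  # - gene on [100, 400): translational start at 400, forward [300, 600),
  # sequence reverse-complemented
  annm <- tiny_annotation(list("m", 100, 400, "-"))
  prm <- extract_promoters(annm, g, 200, 100)
  expect_equal(c(prm$start, prm$end), c(300, 600))
  expect_equal(prm$seq, revcomp(substr(seq, 301, 600)))

  # truncation at the contig start
  anne <- tiny_annotation(list("e", 50, 300, "+"))
  pre <- extract_promoters(anne, g, 200, 100)
  expect_equal(c(pre$start, pre$end), c(0, 150))

  # with operons, only lead genes get windows
  ann2 <- tiny_annotation(list("a", 100, 400, "+"), list("b", 420, 700, "+"))
  ops <- predict_operons(ann2, 50)
  expect_equal(extract_promoters(ann2, g, 200, 100, operons = ops)$gene_id,
               "a")
  expect_error(extract_promoters(tiny_annotation(list("x", 1, 5, "+")),
                                 tiny_genome("ACGT", id = "other")),
               "absent")
})

test_that("promoter scanning recovers planted words and collapses palindromes", {
  m <- toy_pssm()
  thr <- calibrate_threshold(m)
  set.seed(5)
  bg <- paste(sample(c("A", "C"), 120, replace = TRUE), collapse = "")
  seq <- paste0(substr(bg, 1, 60), "GAATC", substr(bg, 66, 120))
  prom <- tibble::tibble(gene_id = "p", contig = "chr", start = 0,
                         end = nchar(seq), strand = "+", seq = seq)
  hits <- scan_promoter_hits(prom, m, thr)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 60)
  expect_equal(hits$score, 8)

  # all-A promoter has no hits; typed empty tibble comes back
  promA <- dplyr::mutate(prom, seq = strrep("A", 100), end = 100)
  expect_equal(nrow(scan_promoter_hits(promA, m, thr)), 0)

  # N windows are excluded
  promN <- dplyr::mutate(prom, seq = paste0("GAANTC", strrep("A", 40)),
                         end = 46)
  expect_equal(nrow(scan_promoter_hits(promN, m, thr)), 0)

  # a palindromic word (GAATC revcomp = GATTC, both consensus) yields one
  # collapsed hit at the interval, two without collapsing
  hits2 <- scan_promoter_hits(prom, m, thr, collapse_palindrome = FALSE)
  expect_equal(nrow(hits2), 2)
  expect_equal(unique(hits2$start), 60)

  # every reported hit re-scores to its reported score from the genome slice
  rescored <- vapply(seq_len(nrow(hits2)), function(i) {
    w <- substr(seq, hits2$start[i] + 1, hits2$end[i])
    if (hits2$strand[i] == "-") w <- revcomp(w)
    score_word(m, w)
  }, numeric(1))
  expect_equal(rescored, hits2$score)
})

test_that("minus-strand promoters report hits in forward coordinates", {
  m <- toy_pssm()
  thr <- calibrate_threshold(m)
  g <- tiny_genome(paste0(strrep("T", 20), strrep("C", 40), "GACTC",
                          strrep("C", 35), strrep("T", 10)))
  ann <- tiny_annotation(list("m", 5, 70, "-"))   # TSS at 70
  pr <- extract_promoters(ann, g, upstream = 60, downstream = 20)
  expect_equal(c(pr$start, pr$end), c(50, 110))
  hits <- scan_promoter_hits(pr, m, thr)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 60)
  w <- substr(g$seq, hits$start + 1, hits$end)
  expect_equal(score_word(m, if (hits$strand == "-") revcomp(w) else w),
               hits$score)
})

test_that("window overlap uses half-open intersection around the start codon", {
  gene <- tiny_annotation(list("g", 500, 900, "+"))
  peak <- tibble::tibble(contig = "chr", start = 390, end = 420,
                         enrichment = 1)
  # + gene start 500, window (-100, +100) = [400, 600)
  expect_true(window_overlap(gene, peak, 100, 100)$overlaps)
  peak2 <- tibble::tibble(contig = "chr", start = 380, end = 400,
                          enrichment = 1)
  expect_false(window_overlap(gene, peak2, 100, 100)$overlaps)  # touching
  expect_false(window_overlap(gene, peak[0, ], 100, 100)$overlaps)
  # other contigs never overlap
  peak3 <- dplyr::mutate(peak, contig = "other")
  expect_false(window_overlap(gene, peak3, 100, 100)$overlaps)
})

test_that("spurious hit rate over random promoters matches 2 * positions * FPR", {
  m <- toy_pssm()
  d <- exact_score_distribution(m)
  thr <- calibrate_threshold(m, dist = d)
  n_prom <- 200
  plen <- 300
  set.seed(17)
  proms <- tibble::tibble(
    gene_id = sprintf("p%03d", seq_len(n_prom)), contig = "chr",
    start = 0, end = plen, strand = "+",
    seq = random_dna_test(n_prom, plen))
  hits <- scan_promoter_hits(proms, m, thr, collapse_palindrome = FALSE)
  positions <- plen - m$length + 1
  expected <- 2 * positions * n_prom * fpr_at(d, thr$t)
  sigma <- sqrt(expected)
  expect_lt(abs(nrow(hits) - expected), 3 * sigma + 1e-9)
})
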