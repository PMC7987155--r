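test_that("reciprocal best hits require mutual unique best scores", {
  tbl <- tibble::tibble(
    gene_a = c("a1", "a1", "a2", "a2"),
    gene_b = c("b1", "b2", "b1", "b2"),
    score = c(10, 2, 3, 9))
  rbh <- reciprocal_best_hits(tbl)
  expect_equal(rbh, tibble::tibble(gene_a = c("a1", "a2"),
                                   gene_b = c("b1", "b2")))

  # a's best is b1 but b1's best is a2: no pair for a1
  tbl2 <- tibble::tibble(gene_a = c("a1", "a2"), gene_b = c("b1", "b1"),
                         score = c(5, 8))
  expect_equal(reciprocal_best_hits(tbl2)$gene_a, "a2")

  # exact tie for best leaves the gene unpaired
  tbl3 <- tibble::tibble(gene_a = c("a1", "a1"), gene_b = c("b1", "b2"),
                         score = c(7, 7))
  expect_equal(nrow(reciprocal_best_hits(tbl3)), 0)

  # symmetry: rbh(A,B) = transposed rbh(B,A)
  set.seed(9)
  tbl4 <- tidyr::crossing(gene_a = sprintf("a%d", 1:6),
                          gene_b = sprintf("b%d", 1:6))
  tbl4$score <- round(stats::runif(nrow(tbl4)), 3)
  fwd <- reciprocal_best_hits(tbl4)
  bwd <- reciprocal_best_hits(dplyr::rename(tbl4, gene_a = gene_b,
                                            gene_b = gene_a))
  bwd <- dplyr::arrange(
    dplyr::select(dplyr::rename(bwd, gene_a = gene_b, gene_b = gene_a),
                  gene_a, gene_b),
    gene_a)
  expect_equal(fwd, bwd)
})

test_that("group statistics and wsmax match the worked 3-species example", {
  members <- tidyr::crossing(group_id = "g1", species_id = c("A", "B", "C"),
                             gene_id = "x")
  hits <- tibble::tibble(group_id = "g1", species_id = c("A", "A", "B"),
                         score = c(8, 6, 7))
  gs <- group_statistics(members, hits)
  expect_equal(gs$mean_smax, 7.5)          # mean of max(8,6) and 7
  expect_equal(gs$pervasiveness, 2 / 3)
  expect_equal(gs$mean_nsites, 1.5)
  expect_equal(gs$wsmax, 7.5)              # 7.5 * 2/3 * 1.5

  # single species, single site of score s -> wsmax = s
  one <- group_statistics(
    tibble::tibble(group_id = "g", species_id = "A", gene_id = "x"),
    tibble::tibble(group_id = "g", species_id = "A", score = 5.5))
  expect_equal(one$wsmax, 5.5)

  # no sites anywhere -> all components and wsmax are 0
  none <- group_statistics(members, hits[0, ])
  expect_equal(c(none$mean_smax, none$pervasiveness, none$mean_nsites,
                 none$wsmax), c(0, 0, 0, 0))

  # invariance under species relabeling
  relab <- c(A = "C", B = "A", C = "B")
  gs2 <- group_statistics(
    dplyr::mutate(members, species_id = relab[species_id]),
    dplyr::mutate(hits, species_id = relab[species_id]))
  expect_equal(gs2$wsmax, gs$wsmax)

  expect_error(group_statistics(members[0, ], hits), "empty")
  expect_error(group_statistics(members,
                                tibble::tibble(group_id = "g1",
                                               species_id = "Z", score = 1)),
               "not group members")
})

test_that("posterior of regulation behaves like the independent-sites model", {
  # one position scoring 10 bits at q = 0.01: L = 0.99 + 10.24 = 11.23
  expect_equal(posterior_regulation(10, prior = 0.5, site_density = 0.01),
               11.23 / 12.23)
  # no positions, or all-zero scores, return the prior
  expect_equal(posterior_regulation(numeric(0), prior = 0.3), 0.3)
  expect_equal(posterior_regulation(rep(0, 50), prior = 0.3), 0.3)
  # -Inf contributes (1 - q) per position
  expect_equal(posterior_regulation(c(-Inf, 0), prior = 0.5,
                                    site_density = 0.1),
               (0.9 / (0.9 + 1)))
  # monotone in any one score, bounded in [0, 1]
  s <- seq(-20, 20, by = 2)
  post <- vapply(s, function(x) posterior_regulation(
    c(x, 1, -3), prior = 0.5, site_density = 0.02), numeric(1))
  expect_true(all(diff(post) >= 0))
  expect_true(all(post >= 0 & post <= 1))
  expect_error(posterior_regulation(1, prior = 1.2), "prior")
  expect_error(posterior_regulation(1, site_density = 2), "site_density")
})

test_that("ranking normalises to (0,1), keeps ties deterministic, and
           distinguishes absent orthologs from zero posteriors", {
  scores <- tibble::tibble(
    group_id = c("g1", "g2", "g3"), n_orth = c(3, 3, 2),
    n_site_species = c(2, 1, 0), mean_smax = c(7.5, 3, 0),
    pervasiveness = c(2 / 3, 1 / 3, 0), mean_nsites = c(1.5, 3, 0),
    wsmax = c(7.5, 3, 0))
  post <- tibble::tibble(group_id = c("g1", "g1", "g2"),
                         species_id = c("A", "B", "A"),
                         posterior = c(0.9, 0, 0.4))
  ranked <- rank_and_export(scores, post)
  expect_equal(ranked$group_id, c("g1", "g2", "g3"))
  expect_equal(ranked$wsmax_norm, c(1, 0.4, 0))
  expect_equal(ranked$posterior_B, c(0, NA, NA))  # zero vs absent
  # min_species filter
  expect_equal(rank_and_export(scores, post, min_species = 3)$group_id,
               c("g1", "g2"))
  expect_equal(rank_and_export(scores, post, top_k = 1)$group_id, "g1")
  # all-equal values normalise to 0 by convention
  flat <- dplyr::mutate(scores, wsmax = 2, n_orth = 3)
  expect_equal(rank_and_export(flat, post)$wsmax_norm, rep(0, 3))
  # wsmax ties broken lexicographically by group id
  tied <- dplyr::mutate(scores, wsmax = c(5, 5, 5))
  expect_equal(rank_and_export(tied, post)$group_id, c("g1", "g2", "g3"))
})

test_that("Spearman permutation test matches rank correlation oracles", {
  x <- 1:10
  expect_equal(spearman_permutation(x, x, n_perm = 99)$rho, 1)
  expect_equal(spearman_permutation(x, rev(x), n_perm = 99)$rho, -1)
  # rho equals cor(..., method = "spearman") with ties
  set.seed(31)
  a <- sample(1:5, 30, replace = TRUE)
  b <- a + sample(0:2, 30, replace = TRUE)
  expect_equal(spearman_permutation(a, b, n_perm = 9)$rho,
               stats::cor(a, b, method = "spearman"))
  # maximal unique rho: p = 1 / (n_perm + 1)
  res <- spearman_permutation(1:8, 1:8, n_perm = 199, seed = 4)
  expect_equal(res$p_perm, 1 / 200)
  expect_error(spearman_permutation(1:5, rep(2, 5)), "constant")
  expect_error(spearman_permutation(1:2, 1:2), "length")
  # same seed reproduces the p-value exactly
  r1 <- spearman_permutation(a, b, n_perm = 199, seed = 7)
  r2 <- spearman_permutation(a, b, n_perm = 199, seed = 7)
  expect_equal(r1$p_perm, r2$p_perm)
})

test_that("permutation test type-I error is calibrated near alpha = 0.05", {
  set.seed(513)
  n_rep <- 500
  rejections <- vapply(seq_len(n_rep), function(i) {
    x <- stats::rnorm(30)
    y <- stats::rnorm(30)
    spearman_permutation(x, y, n_perm = 199, seed = i)$p_perm <= 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("wsmax ranking separates conserved from background groups (AUC >= 0.9)", {
  cfg <- sim_config(seed = 404)
  sim <- generate_ortholog_promoter_set(cfg)
  thr <- calibrate_threshold(cfg$motif)
  hits <- scan_promoter_hits(sim$promoters, cfg$motif, thr)
  hits <- dplyr::left_join(
    hits,
    dplyr::select(sim$promoters, gene_id, group_id, species_id),
    by = "gene_id")
  gs <- group_statistics(sim$members,
                         dplyr::select(hits, group_id, species_id, score))
  lab <- gs$group_id %in% sim$truth$regulated_groups
  # rank-sum AUC of wsmax for regulated vs background groups
  r <- rank(gs$wsmax)
  auc <- (sum(r[lab]) - sum(lab) * (sum(lab) + 1) / 2) /
    (sum(lab) * sum(!lab))
  expect_gte(auc, 0.9)
})
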