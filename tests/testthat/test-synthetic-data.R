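test_that("genome generation is seed-deterministic with controlled GC", {
  g1 <- generate_genome(2000, gc = 0.5, seed = 5)
  g2 <- generate_genome(2000, gc = 0.5, seed = 5)
  expect_identical(g1$genome$seq, g2$genome$seq)
  expect_false(identical(g1$genome$seq,
                         generate_genome(2000, 0.5, seed = 6)$genome$seq))
  at <- generate_genome(500, gc = 0, seed = 1)$genome$seq
  expect_true(grepl("^[AT]+$", at))
  gc <- generate_genome(500, gc = 1, seed = 1)$genome$seq
  expect_true(grepl("^[GC]+$", gc))
  expect_error(generate_genome(100, gc = 2), "gc")
  # annotations are evenly spaced and within bounds
  ann <- generate_genome(5000, gc = 0.5, seed = 5)$annotation
  expect_true(all(ann$end <= 5000))
  expect_equal(unique(diff(ann$start)), 1000)
})

test_that("promoter panel plants recoverable sites exactly where truth says", {
  cfg <- sim_config(seed = 11, n_groups = 30, n_species = 5,
                    frac_regulated = 0.2, conservation_regulated = 1,
                    presence_prob = 1)
  sim <- generate_ortholog_promoter_set(cfg)
  expect_equal(nrow(sim$promoters), 150)
  expect_equal(nchar(sim$promoters$seq[1]), cfg$promoter_length)

  planted <- sim$truth$planted_sites
  # every regulated member promoter carries at least one planted site
  reg_prom <- dplyr::filter(sim$promoters,
                            group_id %in% sim$truth$regulated_groups)
  expect_true(all(reg_prom$gene_id %in% planted$gene_id))
  # planted words are locatable in the emitted promoter sequences
  for (i in seq_len(nrow(planted))) {
    p <- planted[i, ]
    prom <- sim$promoters$seq[sim$promoters$gene_id == p$gene_id]
    slice <- substr(prom, p$offset + 1, p$offset + nchar(p$word))
    expect_equal(if (p$strand == "-") revcomp(slice) else slice, p$word)
  }
  # and in the concatenated per-species genomes at absolute coordinates
  some <- head(planted, 20)
  for (i in seq_len(nrow(some))) {
    p <- some[i, ]
    gseq <- sim$genomes$seq[sim$genomes$id == p$contig]
    slice <- substr(gseq, p$abs_start + 1, p$abs_end)
    expect_equal(if (p$strand == "-") revcomp(slice) else slice, p$word)
  }
  # conservation 0 plants nothing
  cfg0 <- sim_config(seed = 11, n_groups = 10, n_species = 3,
                     frac_regulated = 0, conservation_background = 0)
  expect_equal(nrow(generate_ortholog_promoter_set(cfg0)$truth$planted_sites),
               0)
  # determinism
  expect_identical(generate_ortholog_promoter_set(cfg)$promoters$seq,
                   sim$promoters$seq)
})

test_that("planted consensus sites are recovered at the calibrated threshold", {
  cfg <- sim_config(seed = 21, n_groups = 20, n_species = 4,
                    frac_regulated = 0.5, conservation_regulated = 1)
  sim <- generate_ortholog_promoter_set(cfg)
  thr <- calibrate_threshold(cfg$motif)
  hits <- scan_promoter_hits(sim$promoters, cfg$motif, thr)
  planted <- sim$truth$planted_sites
  found <- dplyr::inner_join(
    planted, hits, by = c("gene_id", "abs_start" = "start"))
  expect_equal(nrow(found), nrow(planted))
})

test_that("expression simulation plants recoverable fold changes", {
  cfg <- sim_config(seed = 31)
  ex <- generate_expression_counts(cfg)
  expect_equal(nrow(ex$expression), cfg$n_genes)
  expect_equal(sum(ex$truth$is_de), round(cfg$frac_de * cfg$n_genes))
  expect_true(all(abs(ex$truth$true_log2fc[ex$truth$is_de]) >= 1))
  expect_true(all(ex$truth$true_log2fc[!ex$truth$is_de] == 0))

  de <- filter_differential(ex$expression, min_fold = 2, max_p = 0.01)
  truth_de <- ex$truth$gene_id[ex$truth$is_de]
  sens <- mean(truth_de %in% de$gene_id)
  fdr <- mean(!de$gene_id %in% truth_de)
  expect_gte(sens, 0.7)
  expect_lte(fdr, 0.05)

  # frac_de = 0 plants nothing
  none <- generate_expression_counts(sim_config(seed = 31, frac_de = 0,
                                                n_genes = 100))
  expect_equal(sum(none$truth$is_de), 0)
  expect_error(generate_expression_counts(sim_config(seed = 1,
                                                     replicates = 1)),
               "replicates")
})

test_that("ChIP peaks cover their planted sites and spurious counts are Poisson", {
  cfg <- sim_config(seed = 41, n_groups = 40, n_species = 6,
                    frac_regulated = 0.5, conservation_regulated = 1,
                    peak_jitter = 0, spurious_peak_rate = 0)
  sim <- generate_ortholog_promoter_set(cfg)
  chip <- generate_chip_and_ipd(cfg, sim)
  expect_false(any(chip$peaks$is_spurious))
  planted <- sim$truth$planted_sites
  expect_equal(nrow(chip$peaks), nrow(planted))
  # jitter 0: every peak contains its planted site
  expect_true(all(chip$peaks$start <= planted$abs_start &
                    chip$peaks$end >= planted$abs_end))

  # spurious-only generator matches the Poisson expectation within 3 sigma
  cfg2 <- sim_config(seed = 42, n_groups = 100, n_species = 10,
                     frac_regulated = 0, conservation_background = 0,
                     spurious_peak_rate = 2e-4)
  sim2 <- generate_ortholog_promoter_set(cfg2)
  chip2 <- generate_chip_and_ipd(cfg2, sim2)
  expected <- 2e-4 * sum(sim2$genomes$length)
  expect_lt(abs(nrow(chip2$peaks) - expected), 3 * sqrt(expected))
})

test_that("methylation calls on synthetic IPD recover truth states >= 99%", {
  cfg <- sim_config(seed = 51, n_groups = 150, n_species = 8)
  sim <- generate_ortholog_promoter_set(cfg)
  chip <- generate_chip_and_ipd(cfg, sim)
  occ <- enumerate_iupac_sites(sim$genomes, "GANTC", strands = "forward")
  paired <- pair_ipd_by_site(occ, chip$ipd)
  expect_equal(nrow(paired), nrow(chip$ipd_truth))
  calls <- call_site_methylation(paired)
  joined <- dplyr::inner_join(calls, chip$ipd_truth,
                              by = c("contig", "start", "end"),
                              suffix = c("", "_true"))
  expect_gte(mean(joined$state == joined$state_true), 0.99)
})

test_that("emitted files validate through the io readers (round trip)", {
  cfg <- sim_config(seed = 61, n_groups = 10, n_species = 3, n_genes = 50)
  od <- withr::local_tempdir()
  res <- run_pipeline(pipeline_config(seed = 61, out_dir = od,
                                      simulate = list(n_groups = 10,
                                                      n_species = 3,
                                                      n_genes = 50)),
                      "simulate")
  g <- read_genome_fasta(file.path(od, "genomes.fasta"))
  expect_equal(nrow(g), 3)
  expect_equal(read_table(file.path(od, "expression.tsv"),
                          "expression")$log2fc,
               signif(res$expression$expression$log2fc, 6))
  ipd <- read_table(file.path(od, "ipd.tsv"), "ipd")
  expect_true(all(ipd$ipd_ratio > 0))
  orth <- read_table(file.path(od, "orthologs.tsv"), "orthologs")
  expect_setequal(names(orth), c("group_id", "species_id", "gene_id"))
})
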