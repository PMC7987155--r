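# Seeded generators for every input the pipeline consumes, with ground
# truth, so all stages are testable offline.
#
# Defaults emulate the study conditions: 23 species, ~200 ortholog groups
# with promoters spanning -200..+100 (300 bp), a degenerate 7-bp extended
# GANTC planting motif (YGAKTCK), Poisson site counts, negative-binomial
# expression counts with planted log2 fold changes, peaks centred on planted
# sites, and well-separated lognormal IPD distributions for methylated vs
# unmethylated adenines.

with_seed_local <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Default planting motif: the degenerate extended GANTC consensus
#'
#' A PSSM built from the 8 words matching YGAKTCK (Y = C/T, K = G/T) with no
#' pseudocount, so letter-wise sampling from its frequencies emits exactly
#' the words matching the consensus. IC = 11 bits under a uniform background.
#'
#' @return A `pssm` of length 7.
#' @export
extended_gantc_pssm <- function() {
  words <- as.vector(outer(
    as.vector(outer(c("C", "T"), c("G", "T"),
                    function(y, k1) paste0(y, "GA", k1, "TC"))),
    c("G", "T"), paste0))
  build_pssm(words, pseudocount = 0)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators with the defaults
#' used throughout the package's tests. The seed is mandatory.
#'
#' @param seed Integer seed (mandatory).
#' @param n_species Number of species in the ortholog panel (default 23).
#' @param n_groups Number of ortholog groups (default 200).
#' @param frac_regulated Fraction of groups carrying conserved sites
#'   (default 0.1).
#' @param conservation_regulated,conservation_background Per-species
#'   probability that a member promoter receives planted sites, for
#'   regulated and background groups (defaults 0.9 and 0.05).
#' @param presence_prob Probability a species carries the group's ortholog
#'   (default 0.95, emulating groups present in >= 20 of 23 species).
#' @param promoter_length Promoter window length in bp (default 300,
#'   i.e. -200..+100).
#' @param site_lambda Poisson mean of planted site counts (at least one site
#'   is planted when planting happens; default 1).
#' @param gc GC content of background sequence (default 0.5, matching the
#'   uniform scanning background).
#' @param motif Planting `pssm` (default [extended_gantc_pssm()]).
#' @param n_genes,frac_de,replicates Expression simulation: genes, fraction
#'   differentially expressed, replicates per condition (2000, 0.05, 3).
#' @param lfc_min,lfc_max Planted |log2 fold change| range (1, 3), sign
#'   random.
#' @param nb_mean,nb_dispersion Negative-binomial mean and dispersion of
#'   counts (100, 0.02).
#' @param peak_width,peak_jitter ChIP peak width and centre jitter in bp
#'   (100, 10).
#' @param spurious_peak_rate Spurious peaks per bp (5e-5).
#' @param peak_enrichment_meanlog,peak_enrichment_sdlog Lognormal enrichment
#'   parameters (log(5), 0.5).
#' @param ipd_meth_meanlog,ipd_meth_sdlog,ipd_unmeth_meanlog,ipd_unmeth_sdlog
#'   Lognormal IPD-ratio parameters for methylated (log 2.0, 0.15) and
#'   unmethylated (log 0.85, 0.10) adenines.
#' @param p_full,p_hemi,p_unmeth True methylation state probabilities per
#'   duplex site (0.99, 0.005, 0.005).
#' @param qv Fixed quality value emitted with IPD records (40).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_species = 23, n_groups = 200, frac_regulated = 0.1,
                       conservation_regulated = 0.9,
                       conservation_background = 0.05,
                       presence_prob = 0.95, promoter_length = 300,
                       site_lambda = 1, gc = 0.5,
                       motif = extended_gantc_pssm(),
                       n_genes = 2000, frac_de = 0.05, replicates = 3,
                       lfc_min = 1, lfc_max = 3,
                       nb_mean = 100, nb_dispersion = 0.02,
                       peak_width = 100, peak_jitter = 10,
                       spurious_peak_rate = 5e-5,
                       peak_enrichment_meanlog = log(5),
                       peak_enrichment_sdlog = 0.5,
                       ipd_meth_meanlog = log(2.0), ipd_meth_sdlog = 0.15,
                       ipd_unmeth_meanlog = log(0.85),
                       ipd_unmeth_sdlog = 0.10,
                       p_full = 0.99, p_hemi = 0.005, p_unmeth = 0.005,
                       qv = 40) {
  if (missing(seed)) abort("sim_config requires a seed")
  cfg <- as.list(environment())
  probs <- c(cfg$frac_regulated, cfg$conservation_regulated,
             cfg$conservation_background, cfg$presence_prob, cfg$gc,
             cfg$frac_de, cfg$p_full, cfg$p_hemi, cfg$p_unmeth)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0,1]")
  if (abs(cfg$p_full + cfg$p_hemi + cfg$p_unmeth - 1) > 1e-9) {
    abort("p_full + p_hemi + p_unmeth must sum to 1")
  }
  structure(cfg, class = "sim_config")
}

random_dna <- function(n, length, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)  # A C G T
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

#' Generate a random genome with evenly spaced genes
#'
#' I.i.d. bases with `P(G) = P(C) = gc/2`; genes of fixed length are laid
#' out at a fixed spacing on the forward strand.
#'
#' @param length Genome length in bp.
#' @param gc GC content in `[0, 1]`.
#' @param seed Integer seed.
#' @param gene_length,gene_spacing Gene body length and start-to-start
#'   spacing (defaults 900 and 1000).
#' @param contig Contig name.
#' @return List with `genome` (tibble `id`, `seq`, `length`) and `annotation`
#'   (annotation tibble).
#' @export
generate_genome <- function(length, gc = 0.5, seed = 1, gene_length = 900,
                            gene_spacing = 1000, contig = "chr") {
  if (length <= 0) abort("length must be positive")
  if (gc < 0 || gc > 1) abort("gc must lie in [0,1]")
  seq <- with_seed_local(seed, random_dna(1, length, gc))
  starts <- seq(from = 200, by = gene_spacing,
                to = max(200, length - gene_length))
  starts <- starts[starts + gene_length <= length]
  ann <- tibble(gene_id = sprintf("g%04d", seq_along(starts)),
                contig = contig, start = starts,
                end = starts + gene_length, strand = "+",
                operon_id = NA_character_)
  list(genome = tibble(id = contig, seq = seq, length = nchar(seq)),
       annotation = ann)
}

sample_pwm_word <- function(freq) {
  paste(vapply(seq_len(nrow(freq)), function(j) {
    sample(DNA_BASES, 1, prob = freq[j, ])
  }, character(1)), collapse = "")
}

plant_sites <- function(seq, n_sites, freq, max_tries = 100) {
  L <- nrow(freq)
  n <- nchar(seq)
  for (try in seq_len(max_tries)) {
    pos <- sort(sample.int(n - L + 1, n_sites))   # 1-based starts
    if (n_sites == 1 || all(diff(pos) >= L)) {
      placed <- purrr::map_dfr(pos, function(p) {
        word <- sample_pwm_word(freq)
        strand <- sample(c("+", "-"), 1)
        planted <- if (strand == "-") revcomp(word) else word
        tibble(offset = p - 1, strand = strand, word = word,
               planted_seq = planted)
      })
      for (i in seq_len(nrow(placed))) {
        substr(seq, placed$offset[i] + 1, placed$offset[i] + L) <-
          placed$planted_seq[i]
      }
      return(list(seq = seq, sites = placed))
    }
  }
  abort(sprintf("could not place %d non-overlapping sites in %d bp", n_sites, n))
}

#' Generate a multi-species ortholog promoter panel with planted sites
#'
#' For each group x species pair present (Bernoulli `presence_prob`), emits a
#' background promoter of `promoter_length` bp. Regulated groups receive,
#' with per-species probability `conservation_regulated`, `max(1, Poisson)`
#' non-overlapping sites sampled letter-wise from the planting PWM at
#' uniform positions on a random strand; background groups use
#' `conservation_background`. Per-species promoters are laid end-to-end on
#' one synthetic contig per species, so planted sites also carry absolute
#' coordinates usable by the ChIP/IPD generator.
#'
#' @param config A [sim_config()].
#' @return List: `promoters` (tibble `group_id`, `species_id`, `gene_id`,
#'   `contig`, `start`, `end`, `strand`, `seq`), `genomes` (per-species
#'   concatenated contigs), `members` (ortholog membership),
#'   `truth` (list with `planted_sites` and `regulated_groups`), `motif`,
#'   `config`.
#' @export
generate_ortholog_promoter_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_local(config$seed, {
    groups <- sprintf("grp%03d", seq_len(config$n_groups))
    species <- sprintf("sp%02d", seq_len(config$n_species))
    n_reg <- round(config$frac_regulated * config$n_groups)
    regulated <- groups[seq_len(n_reg)]
    grid <- tidyr::crossing(group_id = groups, species_id = species)
    grid <- grid[runif(nrow(grid)) < config$presence_prob, , drop = FALSE]
    grid <- dplyr::arrange(grid, .data$species_id, .data$group_id)
    grid <- dplyr::group_by(grid, .data$species_id)
    grid <- dplyr::mutate(grid, slot = dplyr::row_number() - 1)
    grid <- dplyr::ungroup(grid)

    plen <- config$promoter_length
    freq <- config$motif$freq
    cons <- ifelse(grid$group_id %in% regulated,
                   config$conservation_regulated,
                   config$conservation_background)
    rows <- vector("list", nrow(grid))
    sites <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      seq <- random_dna(1, plen, config$gc)
      if (runif(1) < cons[i]) {
        n_sites <- max(1L, rpois(1, config$site_lambda))
        pl <- plant_sites(seq, n_sites, freq)
        seq <- pl$seq
        sites[[i]] <- dplyr::mutate(pl$sites,
                                    group_id = grid$group_id[i],
                                    species_id = grid$species_id[i])
      }
      rows[[i]] <- seq
    }
    contig <- paste0("chr_", grid$species_id)
    start <- grid$slot * plen
    promoters <- tibble(
      group_id = grid$group_id, species_id = grid$species_id,
      gene_id = paste0(grid$group_id, "_", grid$species_id),
      contig = contig, start = start, end = start + plen, strand = "+",
      seq = unlist(rows))
    planted <- dplyr::bind_rows(sites)
    if (nrow(planted)) {
      key <- paste(planted$group_id, planted$species_id)
      pk <- paste(promoters$group_id, promoters$species_id)
      idx <- match(key, pk)
      planted <- dplyr::mutate(planted,
                               gene_id = promoters$gene_id[idx],
                               contig = promoters$contig[idx],
                               abs_start = promoters$start[idx] + .data$offset,
                               abs_end = .data$abs_start + nrow(freq))
    } else {
      planted <- tibble(offset = numeric(), strand = character(),
                        word = character(), planted_seq = character(),
                        group_id = character(), species_id = character(),
                        gene_id = character(), contig = character(),
                        abs_start = numeric(), abs_end = numeric())
    }
    genomes <- dplyr::summarise(
      dplyr::group_by(promoters, id = .data$contig),
      seq = paste(.data$seq[order(.data$start)], collapse = ""),
      .groups = "drop")
    genomes$length <- nchar(genomes$seq)
    list(promoters = promoters, genomes = genomes,
         members = dplyr::select(promoters, "group_id", "species_id",
                                 "gene_id"),
         truth = list(planted_sites = planted, regulated_groups = regulated),
         motif = config$motif, config = config)
  })
}

#' Generate negative-binomial expression counts with planted fold changes
#'
#' Counts are drawn per gene and replicate from a negative binomial with the
#' configured mean and dispersion; differentially expressed genes have their
#' mutant-condition mean scaled by `2^true_log2fc` with
#' `|true_log2fc| ~ Uniform(lfc_min, lfc_max)` and random sign. The emitted
#' table's `log2fc` is the shrunken ratio of simulated condition means and
#' its `pvalue` a two-sided two-sample t-test on `log2(count + 1)` (a
#' documented stand-in for a full count-model fit).
#'
#' @param config A [sim_config()].
#' @return List: `counts` (long tibble `gene_id`, `condition`, `replicate`,
#'   `count`), `expression` (tibble `gene_id`, `log2fc`, `pvalue`), `truth`
#'   (tibble `gene_id`, `is_de`, `true_log2fc`).
#' @export
generate_expression_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$replicates < 2) abort("need at least 2 replicates per condition")
  with_seed_local(config$seed + 1L, {
    n <- config$n_genes
    genes <- sprintf("gene%05d", seq_len(n))
    n_de <- round(config$frac_de * n)
    is_de <- c(rep(TRUE, n_de), rep(FALSE, n - n_de))
    lfc <- ifelse(is_de,
                  sample(c(-1, 1), n, replace = TRUE) *
                    runif(n, config$lfc_min, config$lfc_max),
                  0)
    size <- 1 / config$nb_dispersion
    reps <- config$replicates
    wt <- matrix(rnbinom(n * reps, mu = config$nb_mean, size = size),
                 nrow = n)
    mu_mut <- config$nb_mean * 2^lfc
    mut <- matrix(rnbinom(n * reps, mu = rep(mu_mut, reps), size = size),
                  nrow = n)
    log2fc <- log2((rowMeans(mut) + 0.5) / (rowMeans(wt) + 0.5))
    pvals <- vapply(seq_len(n), function(i) {
      t.test(log2(mut[i, ] + 1), log2(wt[i, ] + 1))$p.value
    }, numeric(1))
    counts <- dplyr::bind_rows(
      tidyr::expand_grid(condition = "wt", replicate = seq_len(reps),
                         gene_id = genes),
      tidyr::expand_grid(condition = "mutant", replicate = seq_len(reps),
                         gene_id = genes))
    counts$count <- c(as.vector(wt), as.vector(mut))
    list(counts = counts,
         expression = tibble(gene_id = genes, log2fc = log2fc,
                             pvalue = pvals),
         truth = tibble(gene_id = genes, is_de = is_de, true_log2fc = lfc))
  })
}

#' Generate ChIP peaks and IPD kinetics records from planted truth
#'
#' True peaks are intervals of `peak_width` bp centred on each planted site
#' (jittered by `Uniform(-peak_jitter, peak_jitter)`) with lognormal
#' enrichment; spurious peaks occur at `spurious_peak_rate` per bp at random
#' positions. IPD records cover every forward-strand GANTC occurrence in the
#' emitted genomes: each duplex site draws a true state
#' (full/hemi/unmethylated) and then per-strand IPD ratios from the
#' methylated or unmethylated lognormal law, with a fixed QV.
#'
#' @param config A [sim_config()].
#' @param sim Output of [generate_ortholog_promoter_set()] (its `genomes` and
#'   `truth$planted_sites` are used).
#' @return List: `peaks` (tibble `contig`, `start`, `end`, `enrichment`,
#'   `is_spurious`), `ipd` (tibble `contig`, `position`, `strand`,
#'   `ipd_ratio`, `qv`), `ipd_truth` (tibble `contig`, `start`, `end`,
#'   `state`).
#' @export
generate_chip_and_ipd <- function(config, sim) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_local(config$seed + 2L, {
    planted <- sim$truth$planted_sites
    w <- config$peak_width
    centre <- floor((planted$abs_start + planted$abs_end) / 2) +
      round(runif(nrow(planted), -config$peak_jitter, config$peak_jitter))
    true_peaks <- tibble(
      contig = planted$contig,
      start = pmax(0, centre - w %/% 2), end = centre - w %/% 2 + w,
      enrichment = rlnorm(nrow(planted), config$peak_enrichment_meanlog,
                          config$peak_enrichment_sdlog),
      is_spurious = FALSE)
    spurious <- purrr::map2_dfr(sim$genomes$id, sim$genomes$length,
                                function(ctg, len) {
      k <- rpois(1, config$spurious_peak_rate * len)
      if (!k) return(NULL)
      st <- sample.int(max(1, len - w), k)
      tibble(contig = ctg, start = st, end = st + w,
             enrichment = rlnorm(k, config$peak_enrichment_meanlog,
                                 config$peak_enrichment_sdlog),
             is_spurious = TRUE)
    })
    peaks <- dplyr::arrange(dplyr::bind_rows(true_peaks, spurious),
                            .data$contig, .data$start)

    occ <- enumerate_iupac_sites(sim$genomes, "GANTC", strands = "forward")
    state <- sample(c("full", "hemi", "unmethylated"), nrow(occ),
                    replace = TRUE,
                    prob = c(config$p_full, config$p_hemi, config$p_unmeth))
    hemi_fwd <- runif(nrow(occ)) < 0.5
    state <- ifelse(state == "hemi",
                    ifelse(hemi_fwd, "hemi_forward_only", "hemi_reverse_only"),
                    state)
    draw_ipd <- function(methylated) {
      n <- length(methylated)
      ifelse(methylated,
             rlnorm(n, config$ipd_meth_meanlog, config$ipd_meth_sdlog),
             rlnorm(n, config$ipd_unmeth_meanlog, config$ipd_unmeth_sdlog))
    }
    meth_f <- state %in% c("full", "hemi_forward_only")
    meth_r <- state %in% c("full", "hemi_reverse_only")
    ipd <- dplyr::bind_rows(
      tibble(contig = occ$contig, position = occ$start + 1, strand = "+",
             ipd_ratio = draw_ipd(meth_f), qv = config$qv),
      tibble(contig = occ$contig, position = occ$start + 3, strand = "-",
             ipd_ratio = draw_ipd(meth_r), qv = config$qv))
    list(peaks = peaks, ipd = ipd,
         ipd_truth = tibble(contig = occ$contig, start = occ$start,
                            end = occ$end, state = state))
  })
}
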