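# End-to-end orchestration: a validated config drives the per-stage
# functions and writes each stage's tables plus a run log. This package is a
# library, not a shell tool; `run_pipeline()` and the per-stage functions are
# the entry points, with `read_pipeline_config()` loading a YAML config.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    inputs = list(genome = NULL, annotation = NULL,
                  annotation_dialect = "gff3", sites = NULL,
                  expression = NULL, peaks = NULL, ipd = NULL,
                  orthologs = NULL),
    motif = list(pseudocount = 0.25, background = rep(0.25, 4),
                 delta = 0.01, iupac = "GANTC"),
    windows = list(scan = c(200, 100), site = c(200, 0), peak = c(100, 100)),
    cutoffs = list(min_fold = 2, max_p = 0.01, relaxed_fold = 1.75),
    operons = list(max_gap = 50),
    posterior = list(prior = 0.5, site_density = NULL),
    permutation = list(n_perm = 999),
    conserve = list(min_species = 1, top_k = NULL),
    simulate = list()
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, "$", key)
    if (!key %in% names(defaults)) {
      abort(paste0("unknown config key: ", full))
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Build a validated pipeline configuration
#'
#' Merges user settings over the package defaults; unknown keys raise an
#' error before any computation. Defaults mirror the per-module defaults
#' (pseudocount 0.25, uniform background, bin width 0.01 bits, windows
#' (200,100)/(200,0)/(100,100), cutoffs fold 2 at p 0.01, operon gap 50 bp,
#' posterior prior 0.5).
#'
#' @param ... Named settings overriding the defaults (nested lists).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- merge_config(pipeline_defaults(), list(...))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys follow [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such config file: ", path))
  user <- yaml::read_yaml(path)
  do.call(pipeline_config, user)
}

log_line <- function(log_path, ...) {
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              sprintf(...)), file = log_path, append = TRUE)
}

require_input <- function(cfg, key) {
  path <- cfg$inputs[[key]]
  if (is.null(path)) abort(paste0("config error: inputs$", key, " is not set"))
  if (!file.exists(path)) {
    abort(paste0("config error: inputs$", key, " does not exist: ", path))
  }
  path
}

load_motif_from_config <- function(cfg) {
  sites <- read_table(require_input(cfg, "sites"), schema = "sites")
  if ("collection" %in% names(sites) &&
      dplyr::n_distinct(sites$collection) > 1) {
    build_mixture(sites, background = cfg$motif$background,
                  pseudocount = cfg$motif$pseudocount)
  } else {
    build_pssm(sites, background = cfg$motif$background,
               pseudocount = cfg$motif$pseudocount)
  }
}

#' Run a pipeline stage
#'
#' Orchestrates the package's stages under one validated config. Available
#' subcommands: `simulate` (write a full synthetic input set),
#' `calibrate` (motif + threshold from a sites file), `scan` (promoter motif
#' hits), `methylome` (methylation calls + motif summary), `regulon`
#' (differential filter + direct-target annotation), `compare` (regulon
#' cascade), `conserve` (scan, group statistics, wsmax, posteriors, ranked
#' table), `correlate` (wsmax components vs ChIP enrichment). Each stage
#' writes its tables into `out_dir` plus `run.log` recording every effective
#' parameter; reruns with the same config are byte-identical (logs carry
#' timestamps, tables do not).
#'
#' @param config A `pipeline_config` (or path to a YAML file).
#' @param subcommand Stage name.
#' @return Named list of the stage's in-memory results, invisibly; files as
#'   a side effect.
#' @export
run_pipeline <- function(config,
                         subcommand = c("simulate", "calibrate", "scan",
                                        "methylome", "regulon", "compare",
                                        "conserve", "correlate")) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    abort("config must be a pipeline_config or a YAML path")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_line(log_path, "regulonscan %s | stage %s | seed %d",
           as.character(utils::packageVersion("regulonscan")), subcommand,
           as.integer(config$seed))
  flat <- unlist(config, use.names = TRUE)
  log_line(log_path, "parameters: %s",
           paste(names(flat), unname(flat), sep = "=", collapse = " "))
  out <- switch(subcommand,
                simulate = stage_simulate(config),
                calibrate = stage_calibrate(config),
                scan = stage_scan(config),
                methylome = stage_methylome(config),
                regulon = stage_regulon(config),
                compare = stage_compare(config),
                conserve = stage_conserve(config),
                correlate = stage_correlate(config))
  log_line(log_path, "stage %s complete", subcommand)
  invisible(out)
}

stage_simulate <- function(cfg) {
  sc <- do.call(sim_config, c(list(seed = cfg$seed), cfg$simulate))
  sim <- generate_ortholog_promoter_set(sc)
  expr <- generate_expression_counts(sc)
  chip <- generate_chip_and_ipd(sc, sim)
  od <- cfg$out_dir
  write_genome_fasta(sim$genomes, file.path(od, "genomes.fasta"))
  write_promoters_fasta(sim$promoters, file.path(od, "promoters.fasta"))
  write_table(dplyr::select(sim$promoters, -"seq"),
              file.path(od, "promoter_annotation.tsv"))
  write_table(sim$members, file.path(od, "orthologs.tsv"))
  write_table(expr$expression, file.path(od, "expression.tsv"))
  write_table(expr$truth, file.path(od, "expression_truth.tsv"))
  write_table(dplyr::select(chip$peaks, "contig", "start", "end",
                            "enrichment"),
              file.path(od, "peaks.tsv"))
  write_table(chip$ipd, file.path(od, "ipd.tsv"))
  write_table(chip$ipd_truth, file.path(od, "ipd_truth.tsv"))
  write_table(sim$truth$planted_sites, file.path(od, "planted_sites.tsv"))
  list(sim = sim, expression = expr, chip = chip)
}

stage_calibrate <- function(cfg) {
  motif <- load_motif_from_config(cfg)
  thr <- calibrate_threshold(motif, delta = cfg$motif$delta)
  if (inherits(motif, "pssm")) {
    write_motif_tsv(motif, file.path(cfg$out_dir, "motif.tsv"))
  } else {
    purrr::iwalk(motif$components, function(cmp, i) {
      write_motif_tsv(cmp, file.path(cfg$out_dir,
                                     sprintf("motif_component%d.tsv", i)))
    })
  }
  write_table(glance(thr), file.path(cfg$out_dir, "threshold.tsv"))
  list(motif = motif, threshold = thr)
}

load_scan_inputs <- function(cfg) {
  genome <- read_genome_fasta(require_input(cfg, "genome"))
  ann <- read_gene_annotation(require_input(cfg, "annotation"),
                              dialect = cfg$inputs$annotation_dialect)
  operons <- predict_operons(ann, max_gap = cfg$operons$max_gap)
  list(genome = genome, annotation = ann, operons = operons)
}

stage_scan <- function(cfg) {
  inp <- load_scan_inputs(cfg)
  cal <- stage_calibrate(cfg)
  prom <- extract_promoters(inp$annotation, inp$genome,
                            upstream = cfg$windows$scan[1],
                            downstream = cfg$windows$scan[2],
                            operons = inp$operons)
  hits <- scan_promoter_hits(prom, cal$motif, cal$threshold)
  write_hits_bed(hits, file.path(cfg$out_dir, "promoter_hits.bed"))
  write_table(hits, file.path(cfg$out_dir, "promoter_hits.tsv"))
  c(inp, cal, list(promoters = prom, hits = hits))
}

stage_methylome <- function(cfg) {
  genome <- read_genome_fasta(require_input(cfg, "genome"))
  ipd <- read_table(require_input(cfg, "ipd"), schema = "ipd")
  occ <- enumerate_iupac_sites(genome, cfg$motif$iupac, strands = "forward")
  paired <- pair_ipd_by_site(occ, ipd)
  calls <- call_site_methylation(paired)
  summary <- summarize_motif_methylation(calls, cfg$motif$iupac,
                                         n_genome = nrow(occ))
  write_table(dplyr::select(calls, "contig", "start", "end", "state",
                            "ipd_forward", "ipd_reverse"),
              file.path(cfg$out_dir, "methylation_calls.tsv"))
  write_table(summary, file.path(cfg$out_dir, "methylation_summary.tsv"))
  list(occurrences = occ, calls = calls, summary = summary)
}

stage_regulon <- function(cfg) {
  inp <- load_scan_inputs(cfg)
  expr <- read_table(require_input(cfg, "expression"), schema = "expression")
  peaks <- read_table(require_input(cfg, "peaks"), schema = "peaks")
  de <- filter_differential(expr, min_fold = cfg$cutoffs$min_fold,
                            max_p = cfg$cutoffs$max_p)
  occ <- enumerate_iupac_sites(inp$genome, cfg$motif$iupac,
                               strands = "forward")
  rec <- annotate_direct_targets(de, inp$annotation, occ, peaks,
                                 operons = inp$operons,
                                 site_window = cfg$windows$site,
                                 peak_window = cfg$windows$peak)
  write_table(rec, file.path(cfg$out_dir, "regulon_records.tsv"))
  list(de = de, records = rec)
}

stage_compare <- function(cfg) {
  reg <- stage_regulon(cfg)
  orth <- read_table(require_input(cfg, "orthologs"), schema = "orthologs")
  # Two-species ortholog table: species A genes map to species B genes.
  sp <- sort(unique(orth$species_id))
  if (length(sp) != 2) {
    abort("compare stage needs an ortholog table with exactly 2 species")
  }
  wide <- tidyr::pivot_wider(orth, id_cols = "group_id",
                             names_from = "species_id",
                             values_from = "gene_id")
  map <- tibble(gene_a = wide[[sp[1]]], gene_b = wide[[sp[2]]])
  map <- map[!is.na(map$gene_a) & !is.na(map$gene_b), , drop = FALSE]
  stages <- list(
    with_peak_and_site = function(d) d$has_peak & d$peak_has_site,
    meets_p = function(d) d$pvalue < cfg$cutoffs$max_p,
    meets_fold = function(d) abs(d$log2fc) >= log2(cfg$cutoffs$relaxed_fold))
  cascade <- compare_regulons_cascade(map$gene_a, map, reg$records, stages)
  write_cascade_tsv(cascade, file.path(cfg$out_dir, "cascade.tsv"))
  c(reg, list(ortholog_map = map, cascade = cascade))
}

stage_conserve <- function(cfg) {
  cal <- stage_calibrate(cfg)
  prom_fa <- read_genome_fasta(require_input(cfg, "genome"))
  orth <- read_table(require_input(cfg, "orthologs"), schema = "orthologs")
  # Genome here holds one promoter per record, ids matching ortholog gene_id
  # ("gene|contig:start-end(strand)" ids from write_promoters_fasta are
  # reduced to the gene token).
  m <- stringr::str_match(prom_fa$id,
                          "^([^|]+)\\|([^:]+):(\\d+)-(\\d+)\\(([+-])\\)$")
  parsed <- !is.na(m[, 1])
  prom <- tibble(
    gene_id = ifelse(parsed, m[, 2], prom_fa$id),
    contig = ifelse(parsed, m[, 3], prom_fa$id),
    start = ifelse(parsed, suppressWarnings(as.numeric(m[, 4])), 0),
    end = ifelse(parsed, suppressWarnings(as.numeric(m[, 5])),
                 prom_fa$length),
    strand = ifelse(parsed, m[, 6], "+"),
    seq = prom_fa$seq)
  prom <- dplyr::inner_join(prom, orth, by = "gene_id")
  hits <- scan_promoter_hits(prom, cal$motif, cal$threshold)
  hits <- dplyr::left_join(
    hits, dplyr::select(prom, "gene_id", "group_id", "species_id"),
    by = "gene_id")
  scores <- group_statistics(
    dplyr::select(prom, "group_id", "species_id", "gene_id"),
    dplyr::select(hits, "group_id", "species_id", "score"))
  post <- promoter_posteriors(prom, cal$motif,
                              prior = cfg$posterior$prior,
                              site_density = cfg$posterior$site_density)
  ranked <- rank_and_export(scores,
                            dplyr::select(post, "group_id", "species_id",
                                          "posterior"),
                            min_species = cfg$conserve$min_species,
                            top_k = cfg$conserve$top_k)
  write_table(scores, file.path(cfg$out_dir, "group_scores.tsv"))
  write_table(ranked, file.path(cfg$out_dir, "ranked_groups.tsv"))
  list(motif = cal$motif, threshold = cal$threshold, promoters = prom,
       hits = hits, scores = scores, posteriors = post, ranked = ranked)
}

stage_correlate <- function(cfg) {
  con <- stage_conserve(cfg)
  peaks <- read_table(require_input(cfg, "peaks"), schema = "peaks")
  # Max peak enrichment within each scanned promoter window, then the group
  # maximum as the correlate of wsmax.
  prom <- con$promoters
  per_group <- dplyr::select(prom, "group_id", "contig", "start", "end") |>
    dplyr::inner_join(peaks, by = "contig", suffix = c("", "_pk"),
                      relationship = "many-to-many") |>
    dplyr::filter(.data$start_pk < .data$end, .data$end_pk > .data$start) |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(enrichment = max(.data$enrichment), .groups = "drop")
  d <- dplyr::inner_join(con$scores, per_group, by = "group_id")
  res <- spearman_permutation(d$wsmax, d$enrichment,
                              n_perm = cfg$permutation$n_perm,
                              seed = cfg$seed)
  write_table(glance(res), file.path(cfg$out_dir, "correlation.tsv"))
  c(con, list(correlation = res))
}
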