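# Ortholog-group conservation scoring: reciprocal best hits, the wsmax
# statistic (mean best site score x site pervasiveness x mean site count),
# posterior probabilities of regulation, ranked heatmap tables, and
# Spearman correlation with a permutation test.

#' Reciprocal best hits from a pairwise similarity table
#'
#' Pairs gene `a` with gene `b` iff `b` is `a`'s unique best-scoring partner
#' and `a` is `b`'s unique best-scoring partner. An exact tie for best on
#' either side leaves the gene unpaired.
#'
#' @param score_table Tibble with columns `gene_a`, `gene_b`, `score`
#'   (nonnegative, higher = more similar).
#' @return Ortholog map tibble: `gene_a`, `gene_b` (one-to-one).
#' @export
reciprocal_best_hits <- function(score_table) {
  unique_best <- function(df, from, to) {
    df <- dplyr::group_by(df, .data[[from]])
    df <- dplyr::filter(df, .data$score == max(.data$score))
    df <- dplyr::filter(df, dplyr::n() == 1)   # drop ties for best
    dplyr::ungroup(df)
  }
  best_a <- unique_best(score_table, "gene_a", "gene_b")
  best_b <- unique_best(score_table, "gene_b", "gene_a")
  out <- dplyr::inner_join(
    dplyr::select(best_a, "gene_a", "gene_b"),
    dplyr::select(best_b, "gene_a", "gene_b"),
    by = c("gene_a", "gene_b"))
  dplyr::arrange(out, .data$gene_a)
}

#' Per-group conservation statistics and the wsmax score
#'
#' For each ortholog group, over the species that carry at least one promoter
#' site: `mean_smax` is the mean of the per-species best hit score and
#' `mean_nsites` the mean per-species hit count; `pervasiveness` is the
#' fraction of ortholog-bearing species with at least one site. The group
#' conservation score is their product,
#' `wsmax = mean_smax * pervasiveness * mean_nsites`, which is 0 exactly when
#' no species has a site. Hits must be promoter-collapsed (one hit per
#' palindromic site) so `mean_nsites` is not inflated.
#'
#' @param members Tibble of group membership: `group_id`, `species_id`,
#'   `gene_id`.
#' @param hits Tibble of promoter hits per member: `group_id`, `species_id`,
#'   `score` (one row per site).
#' @return Tibble: `group_id`, `n_orth`, `n_site_species`, `mean_smax`,
#'   `pervasiveness`, `mean_nsites`, `wsmax`.
#' @export
#' @examples
#' members <- tidyr::crossing(group_id = "g1",
#'                            species_id = c("A", "B", "C"), gene_id = "x")
#' hits <- tibble::tibble(group_id = "g1",
#'                        species_id = c("A", "A", "B"), score = c(8, 6, 7))
#' group_statistics(members, hits)  # mean_smax 7.5, pervasiveness 2/3, wsmax 7.5
group_statistics <- function(members, hits) {
  if (!nrow(members)) abort("empty ortholog group table")
  extra <- dplyr::anti_join(hits, members, by = c("group_id", "species_id"))
  if (nrow(extra)) {
    abort("hits present for species that are not group members")
  }
  orth <- dplyr::summarise(dplyr::group_by(members, .data$group_id),
                           n_orth = dplyr::n_distinct(.data$species_id))
  per_sp <- if (nrow(hits)) {
    dplyr::summarise(
      dplyr::group_by(hits, .data$group_id, .data$species_id),
      smax = max(.data$score), nsites = dplyr::n(), .groups = "drop")
  } else {
    tibble(group_id = character(), species_id = character(),
           smax = numeric(), nsites = integer())
  }
  per_grp <- dplyr::summarise(
    dplyr::group_by(per_sp, .data$group_id),
    n_site_species = dplyr::n(),
    mean_smax = mean(.data$smax),
    mean_nsites = mean(.data$nsites), .groups = "drop")
  out <- dplyr::left_join(orth, per_grp, by = "group_id")
  out <- dplyr::mutate(
    out,
    n_site_species = dplyr::coalesce(.data$n_site_species, 0L),
    mean_smax = dplyr::coalesce(.data$mean_smax, 0),
    mean_nsites = dplyr::coalesce(.data$mean_nsites, 0),
    pervasiveness = .data$n_site_species / .data$n_orth,
    wsmax = wsmax_score(.data$mean_smax, .data$pervasiveness,
                        .data$mean_nsites))
  dplyr::select(out, "group_id", "n_orth", "n_site_species", "mean_smax",
                "pervasiveness", "mean_nsites", "wsmax")
}

#' The wsmax conservation score
#'
#' Product of the three group-level factors: mean best site score, site
#' pervasiveness across ortholog-bearing species, and mean site count.
#'
#' @param mean_smax Mean per-species best site score (bits).
#' @param pervasiveness Fraction of ortholog-bearing species with a site.
#' @param mean_nsites Mean per-species site count.
#' @return Numeric score (vectorised).
#' @export
wsmax_score <- function(mean_smax, pervasiveness, mean_nsites) {
  mean_smax * pervasiveness * mean_nsites
}

#' Posterior probability of regulation for one promoter
#'
#' Combines the motif scores at every scanned position of a promoter (both
#' strands) into a probability that the promoter is regulated, under a model
#' in which each position independently carries a site with small probability
#' `q`. The likelihood ratio of the regulated vs background model is
#' `L = prod_j ((1 - q) + q * 2^(s_j))` and the posterior
#' `pi * L / (pi * L + 1 - pi)`. Positions scoring `-Inf` contribute the
#' factor `1 - q`; with no positions or all-zero scores the posterior equals
#' the prior.
#'
#' @param promoter_scores Numeric vector of per-position scores in bits
#'   (both strands concatenated); may be empty.
#' @param prior Prior probability of regulation `pi` (default 0.5).
#' @param site_density Per-position site probability `q`; default
#'   `1 / length(promoter_scores)` (one expected site per window), or 0.01
#'   for empty input.
#' @return Posterior probability in `[0, 1]`.
#' @export
#' @examples
#' posterior_regulation(10, prior = 0.5, site_density = 0.01)  # ~0.918
posterior_regulation <- function(promoter_scores, prior = 0.5,
                                 site_density = NULL) {
  if (prior <= 0 || prior >= 1) abort("prior must be in (0,1)")
  q <- site_density %||%
    if (length(promoter_scores)) 1 / length(promoter_scores) else 0.01
  if (q <= 0 || q >= 1) abort("site_density must be in (0,1)")
  if (!length(promoter_scores)) return(prior)
  # log scale for numerical safety with many/high-scoring positions
  logL <- sum(log((1 - q) + q * 2^pmax(promoter_scores, -Inf)))
  odds <- exp(log(prior / (1 - prior)) + logL)
  odds / (1 + odds)
}

#' Per-species posterior probabilities for scanned promoters
#'
#' Applies [posterior_regulation()] to the full per-position score profile of
#' each promoter (both strands, `N`-containing windows excluded).
#'
#' @param promoters Promoter tibble (needs `gene_id`, `seq`, `strand`).
#' @param motif A `pssm` or `mixture_motif`.
#' @param prior,site_density Passed to [posterior_regulation()];
#'   `site_density = NULL` uses 1 / (scanned positions per promoter).
#' @return `promoters` with an added `posterior` column.
#' @export
promoter_posteriors <- function(promoters, motif, prior = 0.5,
                                site_density = NULL) {
  post <- purrr::map2_dbl(promoters$seq, promoters$strand, function(seq, st) {
    fwd <- if (st == "-") revcomp(seq) else seq
    s <- c(scan_sequence_scores(fwd, motif),
           scan_sequence_scores(revcomp(fwd), motif))
    s <- s[!is.na(s)]
    posterior_regulation(s, prior = prior, site_density = site_density)
  })
  dplyr::mutate(promoters, posterior = post)
}

normalize01 <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Rank ortholog groups and build the conservation heatmap table
#'
#' Filters groups to those with orthologs in at least `min_species` species,
#' ranks them by descending `wsmax` (ties broken by `group_id`), normalises
#' `wsmax` and the ortholog count to the (0,1) range over the retained
#' groups, and lays out one posterior column per species. Species without an
#' ortholog in a group get `NA` (absence), which is distinct from a posterior
#' of 0.
#'
#' @param group_scores Output of [group_statistics()].
#' @param posteriors Tibble `group_id`, `species_id`, `posterior`.
#' @param min_species Minimum `n_orth` to retain a group.
#' @param top_k Optional: keep only the top `k` rows after ranking.
#' @return Tibble: `group_id`, `wsmax`, `wsmax_norm`, `n_orth`, `n_orth_norm`,
#'   then one `posterior_<species>` column per species.
#' @export
rank_and_export <- function(group_scores, posteriors = NULL, min_species = 1,
                            top_k = NULL) {
  out <- dplyr::filter(group_scores, .data$n_orth >= min_species)
  if (!nrow(out)) abort("no groups pass the min_species filter")
  out <- dplyr::arrange(out, dplyr::desc(.data$wsmax), .data$group_id)
  out <- dplyr::mutate(out,
                       wsmax_norm = normalize01(.data$wsmax),
                       n_orth_norm = normalize01(.data$n_orth))
  if (!is.null(top_k)) out <- head(out, top_k)
  out <- dplyr::select(out, "group_id", "wsmax", "wsmax_norm", "n_orth",
                       "n_orth_norm")
  if (!is.null(posteriors)) {
    wide <- tidyr::pivot_wider(posteriors, id_cols = "group_id",
                               names_from = "species_id",
                               names_prefix = "posterior_",
                               values_from = "posterior")
    out <- dplyr::left_join(out, wide, by = "group_id")
  }
  out
}

#' Spearman rank correlation with a permutation test
#'
#' Spearman's rho on average ranks (ties averaged), with a two-sided
#' permutation p-value: `y` is permuted `n_perm` times with a seeded
#' generator and `p = (1 + #{|rho_b| >= |rho_obs|}) / (1 + n_perm)`.
#'
#' @param x,y Numeric vectors of equal length (>= 3); neither may be
#'   constant.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation generator.
#' @return Object of class `spearman_perm`: `rho`, `p_perm`, `n`, `n_perm`,
#'   `seed`.
#' @export
spearman_permutation <- function(x, y, n_perm = 999, seed = 1) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("x and y must have equal length >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("rho undefined for a constant vector")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho_obs <- cor(rx, ry)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rho_b <- vapply(seq_len(n_perm),
                  function(i) cor(rx, sample(ry)), numeric(1))
  p <- (1 + sum(abs(rho_b) >= abs(rho_obs))) / (1 + n_perm)
  structure(list(rho = rho_obs, p_perm = p, n = length(x), n_perm = n_perm,
                 seed = seed),
            class = "spearman_perm")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.spearman_perm <- function(x, ...) {
  cat(sprintf(
    "Spearman rho = %.4f, permutation p = %.4g (n = %d, %d permutations, seed %d)\n",
    x$rho, x$p_perm, x$n, x$n_perm, x$seed))
  invisible(x)
}

#' Aggregate ChIP enrichment per gene promoter window
#'
#' The enrichment correlate used against conservation scores: the maximum
#' (default) or mean enrichment of peaks overlapping each gene's
#' start-anchored window.
#'
#' @param genes Annotation tibble.
#' @param peaks Peak tibble with `enrichment`.
#' @param upstream,downstream Window extents (default the (100, 100) peak
#'   window).
#' @param agg `"max"` or `"mean"`.
#' @return `genes` with an `enrichment` column (`NA` when no peak overlaps).
#' @export
promoter_enrichment <- function(genes, peaks, upstream = 100,
                                downstream = 100, agg = c("max", "mean")) {
  agg <- match.arg(agg)
  f <- if (agg == "max") max else mean
  ov <- window_overlap(genes, peaks, upstream, downstream)
  enr <- vapply(ov$features, function(pk) {
    if (!nrow(pk)) NA_real_ else f(pk$enrichment)
  }, numeric(1))
  dplyr::mutate(genes, enrichment = enr)
}
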