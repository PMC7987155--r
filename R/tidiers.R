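# broom-style tidy()/glance() methods for the package's fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PSSM into long position-by-base form
#'
#' @param x A `pssm`.
#' @param ... Unused.
#' @return Tibble: `position` (1-based), `base`, `freq`, `logodds`.
#' @method tidy pssm
#' @export
tidy.pssm <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(x$freq), position = dplyr::row_number()),
    cols = dplyr::all_of(DNA_BASES), names_to = "base",
    values_to = "freq") |>
    dplyr::mutate(logodds = x$logodds[cbind(.data$position,
                                            match(.data$base, DNA_BASES))]) |>
    dplyr::arrange(.data$position, .data$base)
}

#' One-row summary of a PSSM
#'
#' @param x A `pssm`.
#' @param ... Unused.
#' @return Tibble: `length`, `n_sites`, `pseudocount`, `ic`.
#' @method glance pssm
#' @export
glance.pssm <- function(x, ...) {
  tibble(length = x$length, n_sites = x$n_sites,
         pseudocount = x$pseudocount, ic = x$ic)
}

#' Tidy a mixture motif: one row per component
#'
#' @param x A `mixture_motif`.
#' @param ... Unused.
#' @return Tibble: `component`, `weight`, `length`, `n_sites`, `ic`.
#' @method tidy mixture_motif
#' @export
tidy.mixture_motif <- function(x, ...) {
  dplyr::bind_cols(
    tibble(component = seq_along(x$components), weight = x$weights),
    dplyr::bind_rows(purrr::map(x$components, glance))
  ) |> dplyr::select("component", "weight", "length", "n_sites", "ic")
}

#' @method glance mixture_motif
#' @export
glance.mixture_motif <- function(x, ...) {
  tibble(n_components = length(x$components), length = x$length, ic = x$ic)
}

#' Tidy a background score distribution
#'
#' @param x A `score_distribution`.
#' @param ... Unused.
#' @return Tibble: `score`, `prob`, `fpr` (`P(S >= score)`).
#' @method tidy score_distribution
#' @export
tidy.score_distribution <- function(x, ...) {
  tibble(score = x$support, prob = x$prob,
         fpr = rev(cumsum(rev(x$prob))))
}

#' @method glance score_distribution
#' @export
glance.score_distribution <- function(x, ...) {
  tibble(n_support = length(x$support), min_score = min(x$support),
         max_score = max(x$support), p_neginf = x$p_neginf, delta = x$delta)
}

#' @method glance motif_threshold
#' @export
glance.motif_threshold <- function(x, ...) {
  tibble(t = x$t, achieved_fpr = x$achieved_fpr,
         neglog2_fpr = -log2(x$achieved_fpr), ic = x$ic,
         warning_flag = x$warning_flag)
}

#' @method tidy motif_threshold
#' @export
tidy.motif_threshold <- function(x, ...) glance.motif_threshold(x)

#' Tidy a cascade result
#'
#' @param x A `cascade_result`.
#' @param ... Unused.
#' @return Tibble: `stage`, `count`, `genes` (comma-joined).
#' @method tidy cascade_result
#' @export
tidy.cascade_result <- function(x, ...) {
  tibble(stage = x$stage, count = x$count,
         genes = vapply(x$genes, paste, character(1), collapse = ","))
}

#' @method glance spearman_perm
#' @export
glance.spearman_perm <- function(x, ...) {
  tibble(rho = x$rho, p_perm = x$p_perm, n = x$n, n_perm = x$n_perm,
         seed = x$seed)
}

#' @method tidy spearman_perm
#' @export
tidy.spearman_perm <- function(x, ...) glance.spearman_perm(x)
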