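# Strand-resolved 6mA methylation calling from SMRT IPD ratios.
#
# A strand's adenine is called methylated iff its IPD ratio exceeds the
# threshold (default 1: ratio < 1 unmethylated, > 1 methylated, exactly 1
# conservatively unmethylated) AND its quality value passes the QV filter
# (default 30, ~99.9% basecall accuracy); a failing QV counts as
# unmethylated for that strand.

#' Call the methylation state of palindromic motif occurrences
#'
#' Classifies each site as fully methylated, hemimethylated on one named
#' strand, or unmethylated, from the strand-resolved consensus IPD ratios.
#'
#' @param sites Data frame with columns `ipd_forward`, `ipd_reverse`,
#'   and optionally `qv_forward`, `qv_reverse` (missing QV columns are
#'   treated as passing). Any other columns (coordinates etc.) pass through.
#' @param ipd_threshold IPD ratio above which a strand is methylated
#'   (default 1).
#' @param min_qv Minimum per-strand quality value (default 30).
#' @return The input tibble with added columns `methylated_forward`,
#'   `methylated_reverse`, `qv_pass`, and `state` in
#'   `{"full", "hemi_forward_only", "hemi_reverse_only", "unmethylated"}`.
#' @export
#' @examples
#' call_site_methylation(
#'   tibble::tibble(ipd_forward = c(1.5, 1.5, 0.9),
#'                  ipd_reverse = c(1.3, 0.8, 0.7)))
call_site_methylation <- function(sites, ipd_threshold = 1, min_qv = 30) {
  sites <- tibble::as_tibble(sites)
  if (any(sites$ipd_forward <= 0) || any(sites$ipd_reverse <= 0)) {
    abort("IPD ratios must be positive")
  }
  qv_f <- if ("qv_forward" %in% names(sites)) sites$qv_forward else Inf
  qv_r <- if ("qv_reverse" %in% names(sites)) sites$qv_reverse else Inf
  mf <- sites$ipd_forward > ipd_threshold & qv_f >= min_qv
  mr <- sites$ipd_reverse > ipd_threshold & qv_r >= min_qv
  dplyr::mutate(
    sites,
    methylated_forward = mf,
    methylated_reverse = mr,
    qv_pass = qv_f >= min_qv & qv_r >= min_qv,
    state = dplyr::case_when(
      mf & mr ~ "full",
      mf ~ "hemi_forward_only",
      mr ~ "hemi_reverse_only",
      TRUE ~ "unmethylated"))
}

#' Pair strand-resolved IPD records per palindromic occurrence
#'
#' Joins an IPD table (one row per interrogated adenine per strand) onto
#' forward-coordinate motif occurrences, producing the two-strand records
#' [call_site_methylation()] consumes. The forward-strand adenine of a GANTC
#' occurrence at `[start, start+5)` sits at `start + 1`, the reverse-strand
#' adenine at `start + 3` (the complementary A of the palindrome).
#'
#' @param occurrences Forward-strand occurrence tibble (`contig`, `start`,
#'   `end`), e.g. `enumerate_iupac_sites(..., strands = "forward")`.
#' @param ipd IPD tibble (`contig`, `position`, `strand`, `ipd_ratio`, `qv`).
#' @param adenine_offset_forward,adenine_offset_reverse Offsets of the
#'   interrogated adenines from the occurrence start (defaults 1 and 3, the
#'   GANTC geometry).
#' @return Tibble: occurrence coordinates plus `ipd_forward`, `ipd_reverse`,
#'   `qv_forward`, `qv_reverse`; occurrences lacking either strand record are
#'   dropped.
#' @export
pair_ipd_by_site <- function(occurrences, ipd, adenine_offset_forward = 1,
                             adenine_offset_reverse = 3) {
  fwd <- dplyr::filter(ipd, .data$strand == "+")
  rev <- dplyr::filter(ipd, .data$strand == "-")
  out <- dplyr::inner_join(
    dplyr::mutate(occurrences, position = .data$start + adenine_offset_forward),
    dplyr::select(fwd, "contig", "position", ipd_forward = "ipd_ratio",
                  qv_forward = "qv"),
    by = c("contig", "position"))
  out$position <- out$start + adenine_offset_reverse
  out <- dplyr::inner_join(
    out,
    dplyr::select(rev, "contig", "position", ipd_reverse = "ipd_ratio",
                  qv_reverse = "qv"),
    by = c("contig", "position"))
  dplyr::select(out, -"position")
}

#' Summarise methylation over a motif's genome occurrences
#'
#' Reports the methylated fraction as printed in motif summary tables:
#' `n_methylated / n_genome` truncated (not rounded) to `precision` decimals,
#' where a site counts as methylated when at least one strand is methylated.
#'
#' @param calls Tibble of calls for this motif (needs a `state` column).
#' @param motif Motif label (IUPAC text).
#' @param n_genome Total occurrences of the motif in the genome (defaults to
#'   the number of calls).
#' @param precision Decimals kept after truncation (default 2).
#' @return One-row tibble: `motif`, `fraction`, `n_methylated`, `n_genome`.
#' @export
#' @examples
#' # 7765 of 7800 methylated -> 0.9955... printed as 0.99
#' calls <- tibble::tibble(state = rep(c("full", "unmethylated"), c(7765, 35)))
#' summarize_motif_methylation(calls, "GANTC")
summarize_motif_methylation <- function(calls, motif, n_genome = nrow(calls),
                                        precision = 2) {
  n_meth <- sum(calls$state != "unmethylated")
  if (n_meth > n_genome) {
    abort("methylated count exceeds genome occurrence count")
  }
  frac <- trunc(n_meth / n_genome * 10^precision) / 10^precision
  tibble(motif = motif, fraction = frac, n_methylated = n_meth,
         n_genome = n_genome)
}
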