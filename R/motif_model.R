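# PSSM and mixture motif models with exact background score distributions.
#
# Scores are log2 likelihood ratios ("bits") of the motif model against a
# mononucleotide background. The significance threshold follows the rule that
# a motif instance is significant when -log2(FPR) at the threshold reaches the
# information content (IC) of the motif.

seq_to_idx <- function(word) {
  idx <- match(strsplit(word, "")[[1]], DNA_BASES)
  if (anyNA(idx)) abort(paste0("word contains non-ACGT character: ", word))
  idx
}

#' Build a position-specific scoring matrix
#'
#' Per-position base frequencies are estimated from aligned equal-length sites
#' with an additive pseudocount: `freq = (count + alpha) / (n + 4 * alpha)`.
#' The information content is
#' `IC = sum_pos sum_b freq * log2(freq / background_b)` with `0 * log 0 := 0`.
#'
#' @param sites Character vector of equal-length DNA words (or a data frame
#'   with a `site` column, as returned by `read_table(schema = "sites")`).
#' @param background Base probabilities in A,C,G,T order; must sum to 1.
#' @param pseudocount Additive count per base (default 0.25, i.e. Laplace-style
#'   smoothing proportional to a uniform background).
#' @return An object of class `pssm` with elements `length`, `freq` (L x 4),
#'   `logodds` (L x 4, `-Inf` where `freq` is 0), `background`, `pseudocount`,
#'   `ic` (bits).
#' @export
#' @examples
#' m <- build_pssm(c("GAATC", "GACTC", "GAGTC", "GATTC"), pseudocount = 0)
#' m$ic  # 8 bits: 2 bits at each of the 4 conserved positions
build_pssm <- function(sites, background = rep(0.25, 4), pseudocount = 0.25) {
  if (is.data.frame(sites)) sites <- sites$site
  sites <- toupper(sites)
  if (length(sites) < 1) abort("need at least one site")
  assert_dna(sites, what = "site collection")
  L <- nchar(sites[1])
  if (any(nchar(sites) != L)) abort("ragged site lengths in collection")
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  if (abs(sum(background) - 1) > 1e-9 || any(background < 0)) {
    abort("background must be a probability vector over A,C,G,T")
  }
  mat <- matrix(match(unlist(strsplit(sites, "")), DNA_BASES),
                nrow = length(sites), byrow = TRUE)
  counts <- vapply(seq_len(L), function(j) tabulate(mat[, j], 4), numeric(4))
  freq <- t(counts + pseudocount) / (length(sites) + 4 * pseudocount)
  colnames(freq) <- DNA_BASES
  lo <- log2(sweep(freq, 2, background, "/"))
  lo[freq == 0] <- -Inf
  term <- freq * lo
  term[freq == 0] <- 0
  structure(list(length = L, freq = freq, logodds = lo,
                 background = setNames(background, DNA_BASES),
                 pseudocount = pseudocount, n_sites = length(sites),
                 ic = sum(term)),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM: %d positions, %d sites, IC = %.3f bits\n",
              x$length, x$n_sites, x$ic))
  invisible(x)
}

#' Score a word against a PSSM or mixture motif
#'
#' For a PSSM the score is the sum of per-position log-odds; `-Inf` is
#' returned if any position has zero motif frequency for the observed base.
#' For a mixture motif the score is
#' `log2(sum_m lambda_m * 2^score_m(word))`.
#'
#' @param motif A `pssm` or `mixture_motif`.
#' @param word DNA word of the motif's length (vectorised).
#' @return Numeric score(s) in bits.
#' @export
score_word <- function(motif, word) {
  UseMethod("score_word")
}

#' @export
score_word.pssm <- function(motif, word) {
  vapply(word, function(w) {
    if (nchar(w) != motif$length) {
      abort(sprintf("word length %d does not match motif length %d",
                    nchar(w), motif$length))
    }
    idx <- seq_to_idx(w)
    sum(motif$logodds[cbind(seq_len(motif$length), idx)])
  }, numeric(1), USE.NAMES = FALSE)
}

#' @export
score_word.mixture_motif <- function(motif, word) {
  comp <- vapply(motif$components, score_word, numeric(length(word)),
                 word = word)
  comp <- matrix(comp, nrow = length(word))
  apply(comp, 1, function(s) mixture_logsum(s, motif$weights))
}

# log2( sum_m w_m 2^{s_m} ), stable against large scores; -Inf components
# contribute nothing and the result is -Inf only if all components are.
mixture_logsum <- function(scores, weights) {
  keep <- is.finite(scores) & weights > 0
  if (!any(keep)) return(-Inf)
  m <- max(scores[keep])
  m + log2(sum(weights[keep] * 2^(scores[keep] - m)))
}

#' Combine site collections into a mixture motif
#'
#' Each collection yields one PSSM component; default component weights are
#' proportional to collection size. Mixture IC is the weight-averaged
#' component IC.
#'
#' @param collections A list of site character vectors (one per component), or
#'   a data frame with `site` and `collection` columns.
#' @param weights Optional mixture weights (normalised to sum to 1); default
#'   proportional to site counts.
#' @param background,pseudocount Passed to [build_pssm()] per component.
#' @return An object of class `mixture_motif` with `components`, `weights`,
#'   `length`, `ic`.
#' @export
build_mixture <- function(collections, weights = NULL,
                          background = rep(0.25, 4), pseudocount = 0.25) {
  if (is.data.frame(collections)) {
    coll <- collections$collection %||% rep("all", nrow(collections))
    collections <- split(collections$site, coll)
  }
  if (length(collections) < 1) abort("need at least one site collection")
  comps <- purrr::map(collections, build_pssm, background = background,
                      pseudocount = pseudocount)
  Ls <- vapply(comps, `[[`, numeric(1), "length")
  if (length(unique(Ls)) != 1) {
    abort("site collections have different motif lengths")
  }
  if (is.null(weights)) {
    weights <- vapply(collections, length, numeric(1))
  }
  if (length(weights) != length(comps) || any(weights < 0) ||
      sum(weights) <= 0) {
    abort("weights must be nonnegative, one per collection, not all zero")
  }
  weights <- weights / sum(weights)
  structure(list(components = comps, weights = unname(weights),
                 length = Ls[[1]],
                 ic = sum(weights * vapply(comps, `[[`, numeric(1), "ic"))),
            class = "mixture_motif")
}

#' @export
print.mixture_motif <- function(x, ...) {
  cat(sprintf("Mixture motif: %d components, %d positions, IC = %.3f bits\n",
              length(x$components), x$length, x$ic))
  invisible(x)
}

bin_scores <- function(scores, delta) {
  round(scores / delta) * delta
}

all_words_scores <- function(motif, background) {
  # Per-word scores and background probabilities for all 4^L words,
  # built incrementally one position at a time.
  L <- motif$length
  if (inherits(motif, "pssm")) {
    comp_lo <- list(motif$logodds)
    weights <- 1
  } else {
    comp_lo <- purrr::map(motif$components, "logodds")
    weights <- motif$weights
  }
  scores <- purrr::map(comp_lo, ~0)
  prob <- 1
  for (j in seq_len(L)) {
    scores <- purrr::map2(scores, comp_lo,
                          ~ rep(.x, each = 4) + rep(.y[j, ], times = length(.x)))
    prob <- rep(prob, each = 4) * rep(background, times = length(prob))
  }
  score <- if (length(scores) == 1) scores[[1]] else {
    apply(do.call(cbind, scores), 1, mixture_logsum, weights = weights)
  }
  list(score = score, prob = prob)
}

new_score_distribution <- function(score, prob, delta) {
  inf <- !is.finite(score)
  p_neginf <- sum(prob[inf])
  score <- bin_scores(score[!inf], delta)
  agg <- rowsum(prob[!inf], group = score)
  support <- as.numeric(rownames(agg))
  o <- order(support)
  structure(list(support = support[o], prob = as.numeric(agg)[o],
                 p_neginf = p_neginf, delta = delta),
            class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf(
    "Background score distribution: %d support points in [%.3f, %.3f], P(-Inf) = %.3g\n",
    length(x$support), min(x$support), max(x$support), x$p_neginf))
  invisible(x)
}

#' Exact background distribution of motif scores
#'
#' Distribution of the score of a random background word. Two exact routes:
#' exhaustive enumeration of all `4^L` words (any motif, `L <= 12`) and, for
#' additive PSSMs, per-position convolution on a score grid of width `delta`.
#' Words scoring `-Inf` (zero motif probability) are kept as a separate mass
#' `p_neginf` that never enters the threshold support.
#'
#' @param motif A `pssm` or `mixture_motif`.
#' @param background Base probabilities (default: the motif's background).
#' @param delta Score bin width in bits.
#' @param method `"auto"` (enumeration up to L = 12, else convolution),
#'   `"enumerate"`, or `"convolve"` (additive PSSM only).
#' @return A `score_distribution` with ascending `support`, `prob` summing to
#'   `1 - p_neginf`, and `p_neginf`.
#' @export
exact_score_distribution <- function(motif, background = NULL, delta = 0.01,
                                     method = c("auto", "enumerate",
                                                "convolve")) {
  method <- match.arg(method)
  background <- background %||%
    if (inherits(motif, "pssm")) unname(motif$background) else
      unname(motif$components[[1]]$background)
  L <- motif$length
  if (method == "auto") {
    method <- if (L <= 12) "enumerate" else "convolve"
  }
  if (method == "convolve" && !inherits(motif, "pssm")) {
    abort("convolution requires an additive PSSM; mixtures with L > 12 are unsupported")
  }
  if (method == "enumerate") {
    if (L > 12) abort("enumeration limited to motifs with L <= 12")
    ws <- all_words_scores(motif, background)
    return(new_score_distribution(ws$score, ws$prob, delta))
  }
  # Convolution: bin each position's four scores, then convolve distributions.
  support <- 0
  prob <- 1
  p_neginf <- 0
  for (j in seq_len(L)) {
    lo <- motif$logodds[j, ]
    fin <- is.finite(lo)
    p_neginf <- p_neginf + sum(prob) * sum(background[!fin])
    s <- as.vector(outer(support, lo[fin], "+"))
    p <- as.vector(outer(prob, background[fin], "*"))
    s <- bin_scores(s, delta)
    agg <- rowsum(p, group = s)
    support <- as.numeric(rownames(agg))
    prob <- as.numeric(agg)
  }
  o <- order(support)
  structure(list(support = support[o], prob = prob[o],
                 p_neginf = p_neginf, delta = delta),
            class = "score_distribution")
}

#' False positive rate at a score threshold
#'
#' `P(score >= t)` for a random background word; the `-Inf` mass never
#' reaches a finite threshold.
#'
#' @param dist A `score_distribution`.
#' @param t Threshold(s) in bits.
#' @return FPR value(s) in `[0, 1]`.
#' @export
fpr_at <- function(dist, t) {
  vapply(t, function(ti) {
    if (ti == -Inf) 1 else sum(dist$prob[dist$support >= ti])
  }, numeric(1))
}

#' Calibrate the significance threshold of a motif
#'
#' Finds the smallest support value `t*` of the background score distribution
#' with `-log2(FPR(t*)) >= IC`, i.e. the point where the negative log false
#' positive rate first reaches the motif's information content. For mixture
#' motifs the IC is the weight-averaged component IC. If even the maximum
#' support cannot reach the IC, that maximum is returned with
#' `warning_flag = TRUE`.
#'
#' @param motif A `pssm` or `mixture_motif`.
#' @param background Base probabilities (default: motif background).
#' @param delta Score bin width for the distribution.
#' @param dist Optional precomputed `score_distribution`.
#' @return An object of class `motif_threshold`: `t`, `achieved_fpr`, `ic`,
#'   `warning_flag`.
#' @export
#' @examples
#' m <- build_pssm(c("GAATC", "GACTC", "GAGTC", "GATTC"), pseudocount = 0)
#' calibrate_threshold(m)  # t* = 8 bits, FPR = 2^-8
calibrate_threshold <- function(motif, background = NULL, delta = 0.01,
                                dist = NULL) {
  dist <- dist %||% exact_score_distribution(motif, background, delta)
  ic <- motif$ic
  fprs <- rev(cumsum(rev(dist$prob)))   # FPR at each support point
  ok <- which(-log2(fprs) >= ic)
  if (length(ok)) {
    i <- ok[1]
    structure(list(t = dist$support[i], achieved_fpr = fprs[i], ic = ic,
                   warning_flag = FALSE),
              class = "motif_threshold")
  } else {
    i <- length(dist$support)
    warn(sprintf(
      "no threshold reaches -log2(FPR) >= IC = %.3f; returning max support", ic))
    structure(list(t = dist$support[i], achieved_fpr = fprs[i], ic = ic,
                   warning_flag = TRUE),
              class = "motif_threshold")
  }
}

#' @export
print.motif_threshold <- function(x, ...) {
  cat(sprintf("Motif threshold: t = %.3f bits (FPR = %.3g, IC = %.3f%s)\n",
              x$t, x$achieved_fpr, x$ic,
              if (x$warning_flag) ", IC unreachable" else ""))
  invisible(x)
}

#' Serialize a motif to a TSV matrix
#'
#' Position x base log-odds matrix with `#`-prefixed metadata header lines
#' (background, pseudocount); read back with [read_motif_tsv()].
#'
#' @param motif A `pssm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_tsv <- function(motif, path) {
  stopifnot(inherits(motif, "pssm"))
  hdr <- c(sprintf("# background\t%s",
                   paste(format(motif$background, digits = 10), collapse = "\t")),
           sprintf("# pseudocount\t%s", format(motif$pseudocount, digits = 10)),
           sprintf("# n_sites\t%d", motif$n_sites),
           paste(c("position", DNA_BASES), collapse = "\t"))
  body <- vapply(seq_len(motif$length), function(j) {
    paste(c(j, format(motif$logodds[j, ], digits = 10)), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a motif serialized by [write_motif_tsv()]
#'
#' @param path Input path.
#' @return A `pssm`.
#' @export
read_motif_tsv <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    row <- meta[grepl(paste0("^# ", key), meta)]
    as.numeric(strsplit(row, "\t")[[1]][-1])
  }
  background <- get_meta("background")
  pseudocount <- get_meta("pseudocount")
  n_sites <- get_meta("n_sites")
  body <- lines[!startsWith(lines, "#")][-1]
  lo <- do.call(rbind, lapply(strsplit(body, "\t"),
                              function(x) as.numeric(x[-1])))
  colnames(lo) <- DNA_BASES
  freq <- sweep(2^lo, 2, background, "*")
  freq[!is.finite(lo)] <- 0
  term <- freq * lo
  term[freq == 0] <- 0
  structure(list(length = nrow(lo), freq = freq, logodds = lo,
                 background = setNames(background, DNA_BASES),
                 pseudocount = pseudocount, n_sites = as.integer(n_sites),
                 ic = sum(term)),
            class = "pssm")
}
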