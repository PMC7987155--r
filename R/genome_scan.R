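# Genome-wide IUPAC motif enumeration, operon prediction, promoter window
# extraction and PSSM scanning of promoter windows.
#
# Promoter windows default to -200..+100 around the translational start,
# taken irrespective of other annotated features; the CcrM direct-target rule
# uses (200, 0) and the GcrA peak-overlap rule (100, 100).

genome_seq_lookup <- function(genome, contig) {
  i <- match(contig, genome$id)
  if (is.na(i)) abort(paste0("contig not found in genome: ", contig))
  genome$seq[i]
}

#' Enumerate IUPAC motif occurrences genome-wide
#'
#' Finds all (possibly overlapping) matches of a fixed IUPAC motif. With
#' `strands = "both"`, reverse-strand matches are reported in forward
#' coordinates with `strand = "-"`; a palindromic motif therefore yields
#' paired hits at identical intervals (the 2x counting used when quoting
#' genome-wide site totals). `N` in the genome never matches.
#'
#' @param genome Genome tibble from [read_genome_fasta()].
#' @param iupac_motif Motif string over IUPAC codes, e.g. `"GANTC"`.
#' @param strands `"both"` (default) or `"forward"`.
#' @return Tibble of hits: `contig`, `start`, `end` (0-based half-open),
#'   `strand`.
#' @export
#' @examples
#' g <- tibble::tibble(id = "c", seq = "GAATCGATTC", length = 10)
#' enumerate_iupac_sites(g, "GANTC", strands = "forward")
enumerate_iupac_sites <- function(genome, iupac_motif,
                                  strands = c("both", "forward")) {
  strands <- match.arg(strands)
  iupac_motif <- toupper(iupac_motif)
  if (!all(strsplit(iupac_motif, "")[[1]] %in% names(IUPAC_MAP))) {
    abort(paste0("invalid IUPAC letter in motif: ", iupac_motif))
  }
  one_strand <- function(seq, pattern, strand) {
    m <- Biostrings::matchPattern(
      Biostrings::DNAString(pattern), Biostrings::DNAString(seq),
      fixed = c(pattern = FALSE, subject = TRUE))
    out <- tibble(start = BiocGenerics::start(m) - 1L,
                  end = BiocGenerics::end(m), strand = strand)
    # windows containing N never match
    out[!grepl("N", as.character(m), fixed = TRUE), , drop = FALSE]
  }
  hits <- purrr::map2_dfr(genome$id, genome$seq, function(id, seq) {
    fwd <- one_strand(seq, iupac_motif, "+")
    out <- if (strands == "both") {
      dplyr::bind_rows(fwd, one_strand(seq, revcomp(iupac_motif), "-"))
    } else fwd
    dplyr::mutate(out, contig = id, .before = 1)
  })
  dplyr::arrange(hits, .data$contig, .data$start, .data$strand)
}

#' Predict operons from gene adjacency
#'
#' A simple distance rule: consecutive genes on the same contig and strand
#' whose intergenic gap is at most `max_gap` bases share an operon. The lead
#' gene is the 5'-most member on the operon's strand (smallest start on `+`,
#' largest end on `-`). An externally supplied operon assignment can be used
#' instead wherever an `operons` argument is accepted.
#'
#' @param annotations Annotation tibble (see [read_gene_annotation()]).
#' @param max_gap Maximum intergenic gap in bases (default 50).
#' @return Tibble: `gene_id`, `operon_id`, `lead_gene_id`.
#' @export
predict_operons <- function(annotations, max_gap = 50) {
  ann <- dplyr::arrange(annotations, .data$contig, .data$start)
  ann <- dplyr::group_by(ann, .data$contig)
  ann <- dplyr::mutate(
    ann,
    gap = .data$start - dplyr::lag(.data$end),
    new_op = is.na(.data$gap) | .data$gap > max_gap |
      .data$strand != dplyr::lag(.data$strand))
  ann <- dplyr::ungroup(ann)
  ann$operon_idx <- cumsum(ann$new_op)
  ann <- dplyr::group_by(ann, .data$operon_idx)
  ann <- dplyr::mutate(
    ann,
    operon_id = paste0("op", .data$operon_idx[1]),
    lead_gene_id = if (.data$strand[1] == "+") {
      .data$gene_id[which.min(.data$start)]
    } else {
      .data$gene_id[which.max(.data$end)]
    })
  dplyr::select(dplyr::ungroup(ann), "gene_id", "operon_id", "lead_gene_id")
}

promoter_window <- function(start, end, strand, upstream, downstream,
                            contig_len) {
  # Translational start: `start` for + genes, `end` for - genes.
  w_start <- ifelse(strand == "+", start - upstream, end - downstream)
  w_end <- ifelse(strand == "+", start + downstream, end + upstream)
  tibble(start = pmax(0, w_start), end = pmin(contig_len, w_end))
}

#' Extract promoter windows
#'
#' One window per operon lead gene (or per gene when `operons` is `NULL`),
#' spanning `upstream` bases 5' and `downstream` bases 3' of the translational
#' start, truncated at contig edges. The returned sequence is oriented
#' 5' to 3' relative to the gene (reverse-complemented for `-` genes), while
#' `start`/`end` stay in forward-strand coordinates.
#'
#' @param annotations Annotation tibble.
#' @param genome Genome tibble.
#' @param upstream,downstream Window extents in bases (defaults 200 and 100).
#' @param operons Optional operon assignment from [predict_operons()]; only
#'   lead genes receive windows.
#' @return Tibble: `gene_id`, `contig`, `start`, `end`, `strand`, `seq`.
#' @export
extract_promoters <- function(annotations, genome, upstream = 200,
                              downstream = 100, operons = NULL) {
  if (upstream < 0 || downstream < 0) abort("window extents must be >= 0")
  ann <- annotations
  if (!is.null(operons)) {
    ann <- dplyr::semi_join(
      ann, dplyr::distinct(operons, gene_id = .data$lead_gene_id),
      by = "gene_id")
  }
  missing <- setdiff(ann$contig, genome$id)
  if (length(missing)) {
    abort(paste0("gene contig absent from genome: ", missing[1]))
  }
  clen <- genome$length[match(ann$contig, genome$id)]
  win <- promoter_window(ann$start, ann$end, ann$strand, upstream, downstream,
                         clen)
  seqs <- substr(genome$seq[match(ann$contig, genome$id)],
                 win$start + 1, win$end)
  seqs <- ifelse(ann$strand == "-", revcomp(seqs), seqs)
  tibble(gene_id = ann$gene_id, contig = ann$contig,
         start = win$start, end = win$end, strand = ann$strand, seq = seqs)
}

# Score every length-L window of `seq` (one strand); windows containing N
# score NA and are excluded downstream.
scan_sequence_scores <- function(seq, motif) {
  L <- motif$length
  n <- nchar(seq)
  if (n < L) return(numeric(0))
  idx <- match(strsplit(seq, "")[[1]], DNA_BASES)   # N -> NA
  n_win <- n - L + 1
  if (inherits(motif, "pssm")) {
    s <- numeric(n_win)
    for (j in seq_len(L)) {
      s <- s + unname(motif$logodds[j, ])[idx[j:(j + n_win - 1)]]
    }
    s
  } else {
    comp <- vapply(motif$components,
                   function(cmp) scan_sequence_scores(seq, cmp),
                   numeric(n_win))
    apply(matrix(comp, nrow = n_win), 1, mixture_logsum,
          weights = motif$weights)
  }
}

#' Scan promoter windows for significant motif hits
#'
#' Both strands of each promoter window are scored at every offset; hits with
#' score at or above the calibrated threshold are reported in forward-strand
#' genome coordinates. Forward/reverse hits at the same interval (the two
#' strand reads of one palindromic site) are collapsed to a single hit
#' keeping the higher score, so per-promoter site counts are not inflated.
#' Positions whose window contains `N` are excluded.
#'
#' @param promoters Promoter tibble from [extract_promoters()].
#' @param motif A `pssm` or `mixture_motif`.
#' @param threshold A `motif_threshold` or a numeric score in bits.
#' @param collapse_palindrome Collapse same-interval strand pairs
#'   (default `TRUE`).
#' @return Tibble of hits: `gene_id`, `contig`, `start`, `end`, `strand`,
#'   `score`.
#' @export
scan_promoter_hits <- function(promoters, motif, threshold,
                               collapse_palindrome = TRUE) {
  t <- if (inherits(threshold, "motif_threshold")) threshold$t else threshold
  L <- motif$length
  out <- purrr::pmap_dfr(
    promoters[, c("gene_id", "contig", "start", "end", "strand", "seq")],
    function(gene_id, contig, start, end, strand, seq) {
      fwd_seq <- if (strand == "-") revcomp(seq) else seq
      s_fwd <- scan_sequence_scores(fwd_seq, motif)
      s_rev <- scan_sequence_scores(revcomp(fwd_seq), motif)
      n_win <- length(s_fwd)
      if (!n_win) return(NULL)
      offs <- seq_len(n_win) - 1
      hits <- dplyr::bind_rows(
        tibble(off = offs, strand = "+", score = s_fwd),
        tibble(off = rev(offs), strand = "-", score = s_rev))
      hits <- hits[!is.na(hits$score) & hits$score >= t, , drop = FALSE]
      if (!nrow(hits)) return(NULL)
      hit_start <- start + hits$off
      tibble(gene_id = gene_id, contig = contig,
             start = hit_start, end = hit_start + L,
             strand = hits$strand, score = hits$score)
    })
  if (!nrow(out)) {
    return(tibble(gene_id = character(), contig = character(),
                  start = numeric(), end = numeric(), strand = character(),
                  score = numeric()))
  }
  if (collapse_palindrome) {
    out <- dplyr::group_by(out, .data$gene_id, .data$contig, .data$start,
                           .data$end)
    out <- dplyr::slice_max(out, .data$score, n = 1, with_ties = FALSE)
    out <- dplyr::ungroup(out)
  }
  dplyr::arrange(out, .data$gene_id, .data$start, .data$strand)
}

#' Test genes for feature overlap within a start-anchored window
#'
#' For each gene, builds the window `(-upstream, +downstream)` around the
#' translational start (strand-aware, forward coordinates) and reports
#' whether any feature interval intersects it (half-open intersection).
#'
#' @param genes Annotation tibble.
#' @param features Tibble with `contig`, `start`, `end` (hits or peaks).
#' @param upstream,downstream Window extents (defaults 100 and 100, the
#'   ChIP peak-overlap rule).
#' @param contig_length Optional named vector of contig lengths for edge
#'   truncation; untruncated otherwise.
#' @return `genes` with added columns `overlaps` (logical), `n_features`, and
#'   a list-column `features` of the overlapping feature rows.
#' @export
window_overlap <- function(genes, features, upstream = 100, downstream = 100,
                           contig_length = NULL) {
  clen <- if (is.null(contig_length)) rep(Inf, nrow(genes)) else
    unname(contig_length[genes$contig])
  win <- promoter_window(genes$start, genes$end, genes$strand, upstream,
                         downstream, clen)
  ov <- purrr::pmap(list(genes$contig, win$start, win$end),
                    function(ctg, ws, we) {
                      features[features$contig == ctg & features$start < we &
                                 features$end > ws, , drop = FALSE]
                    })
  dplyr::mutate(genes,
                window_start = win$start, window_end = win$end,
                n_features = vapply(ov, nrow, integer(1)),
                overlaps = .data$n_features > 0,
                features = ov)
}

#' Write motif hits as BED6
#'
#' Score column is bits scaled by 100 and truncated to integer.
#'
#' @param hits Hit tibble from [scan_promoter_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  name <- if ("gene_id" %in% names(hits)) hits$gene_id else "."
  score <- if ("score" %in% names(hits)) as.integer(hits$score * 100) else 0L
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", hits$contig,
                   as.integer(hits$start), as.integer(hits$end), name, score,
                   hits$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write promoter windows as FASTA
#'
#' Record ids follow `gene_id|contig:start-end(strand)`.
#'
#' @param promoters Promoter tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  ids <- sprintf("%s|%s:%d-%d(%s)", promoters$gene_id, promoters$contig,
                 as.integer(promoters$start), as.integer(promoters$end),
                 promoters$strand)
  write_genome_fasta(tibble(id = ids, seq = promoters$seq), path)
}
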