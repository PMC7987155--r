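# Regulon definition and cross-species comparison: differential-expression
# cutoffs, direct-target annotation from promoter motif hits and ChIP peaks,
# nested comparison cascades, and the RT-qPCR 2^-ddCt fold change.

#' Filter a differential-expression table by fold change and p-value
#'
#' Keeps genes with `pvalue < max_p` (strict) and `|log2fc| >= log2(min_fold)`
#' (non-strict on the fold scale), optionally restricted to one direction.
#' The usual regulon cutoffs are fold 2 at p 0.01; a laxer historical
#' criterion uses 1.75-fold down-regulation.
#'
#' @param records Expression tibble (`gene_id`, `log2fc`, `pvalue`).
#' @param min_fold Fold-change cutoff on the linear scale (>= 1).
#' @param max_p P-value cutoff (strict).
#' @param direction `"any"`, `"down"` (log2fc < 0) or `"up"`.
#' @return The kept rows, with a `direction` column (`"up"`/`"down"`).
#' @export
filter_differential <- function(records, min_fold = 2, max_p = 0.01,
                                direction = c("any", "down", "up")) {
  direction <- match.arg(direction)
  if (min_fold < 1) abort("min_fold must be >= 1")
  out <- dplyr::filter(records,
                       .data$pvalue < max_p,
                       abs(.data$log2fc) >= log2(min_fold))
  out <- dplyr::mutate(out,
                       direction = ifelse(.data$log2fc < 0, "down", "up"))
  switch(direction,
         any = out,
         down = dplyr::filter(out, .data$direction == "down"),
         up = dplyr::filter(out, .data$direction == "up"))
}

#' Annotate differentially expressed genes with direct-target evidence
#'
#' Adds promoter-motif and ChIP-peak flags to each gene. Evidence is
#' evaluated on the operon lead's promoter, and operon members inherit their
#' lead's flags (only the first gene of an operon has its own promoter).
#' Windows are anchored at the translational start: the motif-in-promoter
#' rule uses `site_window` (default (200, 0), the CcrM direct-target rule)
#' and the peak rule `peak_window` (default (100, 100)).
#'
#' @param de_genes Expression tibble rows to annotate (`gene_id`, `log2fc`,
#'   `pvalue`).
#' @param annotations Annotation tibble covering every gene in `de_genes`.
#' @param motif_hits Motif hit tibble (`contig`, `start`, `end`), e.g. GANTC
#'   occurrences or scored promoter hits.
#' @param peaks Peak tibble (`contig`, `start`, `end`, `enrichment`).
#' @param operons Optional operon assignment from [predict_operons()];
#'   without it every gene is its own lead.
#' @param site_window,peak_window Length-2 `(upstream, downstream)` vectors.
#' @return Tibble of regulon records: `gene_id`, `log2fc`, `pvalue`,
#'   `direction`, `has_promoter_site`, `has_peak`, `peak_has_site`,
#'   `lead_gene_id`.
#' @export
annotate_direct_targets <- function(de_genes, annotations, motif_hits, peaks,
                                    operons = NULL,
                                    site_window = c(200, 0),
                                    peak_window = c(100, 100)) {
  missing <- setdiff(de_genes$gene_id, annotations$gene_id)
  if (length(missing)) {
    abort(paste0("gene without annotation: ", missing[1]))
  }
  if (is.null(operons)) {
    operons <- tibble(gene_id = annotations$gene_id,
                      operon_id = annotations$gene_id,
                      lead_gene_id = annotations$gene_id)
  }
  leads <- dplyr::distinct(operons, .data$lead_gene_id)$lead_gene_id
  lead_ann <- annotations[annotations$gene_id %in% leads, , drop = FALSE]

  site_ov <- window_overlap(lead_ann, motif_hits,
                            upstream = site_window[1],
                            downstream = site_window[2])
  peak_ov <- window_overlap(lead_ann, peaks,
                            upstream = peak_window[1],
                            downstream = peak_window[2])
  # A peak "has a site" when an overlapping peak's own interval contains a
  # motif hit.
  peak_site <- vapply(peak_ov$features, function(pk) {
    if (!nrow(pk)) return(FALSE)
    any(vapply(seq_len(nrow(pk)), function(i) {
      any(motif_hits$contig == pk$contig[i] &
            motif_hits$start < pk$end[i] & motif_hits$end > pk$start[i])
    }, logical(1)))
  }, logical(1))

  lead_flags <- tibble(lead_gene_id = lead_ann$gene_id,
                       has_promoter_site = site_ov$overlaps,
                       has_peak = peak_ov$overlaps,
                       peak_has_site = peak_site)
  out <- dplyr::left_join(de_genes, dplyr::select(operons, "gene_id",
                                                  "lead_gene_id"),
                          by = "gene_id")
  out$lead_gene_id <- dplyr::coalesce(out$lead_gene_id, out$gene_id)
  out <- dplyr::left_join(out, lead_flags, by = "lead_gene_id")
  dplyr::mutate(out,
                direction = ifelse(.data$log2fc < 0, "down", "up"),
                dplyr::across(c("has_promoter_site", "has_peak",
                                "peak_has_site"),
                              ~ dplyr::coalesce(.x, FALSE)))
}

#' Compare a regulon across species as a nested cascade
#'
#' Starting from a regulon defined in species A, maps genes to species B via
#' a one-to-one ortholog map and applies successively stricter predicates on
#' the species-B records (e.g. has a peak with a motif, then p < 0.01, then
#' >= 1.75-fold change), yielding nested gene sets whose shrinking counts
#' quantify transcriptional rewiring between the species.
#'
#' @param regulon_a Character vector of species-A gene ids.
#' @param ortholog_map Tibble with columns `gene_a`, `gene_b`, at most one
#'   partner per gene per direction (see [reciprocal_best_hits()]).
#' @param records_b Tibble of species-B records, one row per gene (`gene_id`
#'   plus whatever columns the stage predicates use).
#' @param stages Named list of predicate functions; each takes the
#'   `records_b` rows of the currently surviving genes and returns a logical
#'   vector.
#' @return An object of class `cascade_result`: tibble `stage`, `count`,
#'   `genes` (list-column of species-B ids; the first stage holds species-A
#'   ids).
#' @export
#' @examples
#' stages <- list(
#'   with_peak_and_site = function(d) d$has_peak & d$has_promoter_site,
#'   meets_p = function(d) d$pvalue < 0.01,
#'   meets_fold = function(d) d$log2fc <= -log2(1.75))
compare_regulons_cascade <- function(regulon_a, ortholog_map, records_b,
                                     stages) {
  rows <- list(tibble(stage = "regulon_a", count = length(regulon_a),
                      genes = list(sort(unique(regulon_a)))))
  mapped <- ortholog_map$gene_b[ortholog_map$gene_a %in% regulon_a]
  current <- sort(unique(mapped))
  rows <- c(rows, list(tibble(stage = "orthologs_in_b",
                              count = length(current),
                              genes = list(current))))
  if (is.null(names(stages)) || any(names(stages) == "")) {
    abort("stages must be a named list of predicates")
  }
  for (nm in names(stages)) {
    pred <- stages[[nm]]
    if (!is.function(pred)) abort(paste0("unknown stage predicate: ", nm))
    d <- records_b[match(current, records_b$gene_id), , drop = FALSE]
    keep <- !is.na(d$gene_id) & pred(d)
    keep[is.na(keep)] <- FALSE
    current <- current[keep]
    rows <- c(rows, list(tibble(stage = nm, count = length(current),
                                genes = list(current))))
  }
  structure(dplyr::bind_rows(rows), class = c("cascade_result", class(tibble())))
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("Regulon comparison cascade:\n")
  cat(paste0("  ", format(x$stage, width = max(nchar(x$stage))), "  ",
             x$count, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a cascade result as TSV
#'
#' Columns: stage, count, comma-joined gene ids.
#'
#' @param cascade A `cascade_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cascade_tsv <- function(cascade, path) {
  out <- tibble(stage = cascade$stage, count = cascade$count,
                genes = vapply(cascade$genes, paste, character(1),
                               collapse = ","))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Relative expression by the 2^-ddCt method
#'
#' Fold change of a target transcript in a test sample relative to a control
#' sample, each normalised to a reference transcript:
#' `2^-((Ct_target,test - Ct_ref,test) - (Ct_target,ctrl - Ct_ref,ctrl))`.
#'
#' @param ct_target_test,ct_ref_test,ct_target_ctrl,ct_ref_ctrl Ct values.
#' @return Fold change (vectorised).
#' @export
#' @examples
#' relative_expression_ddct(20, 15, 18, 15)  # 0.25
relative_expression_ddct <- function(ct_target_test, ct_ref_test,
                                     ct_target_ctrl, ct_ref_ctrl) {
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
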