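# Readers and writers for every external format the pipeline touches.
#
# Coordinate convention: all internal coordinates are 0-based half-open
# [start, end); GFF3 input/output is 1-based inclusive. For minus-strand genes
# the translational start is the end-most base of the annotated interval
# (GFF stores intervals in forward-strand coordinates).

#' Read a genome FASTA file
#'
#' Sequences are uppercased and restricted to the alphabet \{A,C,G,T,N\};
#' RNA (`U`) and other letters are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record: `id` (first whitespace-delimited
#'   token of the header), `seq`, `length`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("FASTA parse error in ", path, ": ",
                                     conditionMessage(e)))
  )
  seqs <- unname(toupper(as.character(set)))
  ids <- sub("\\s.*$", "", names(set))
  assert_dna(seqs, allow_n = TRUE, what = paste0("FASTA record in ", path))
  tibble(id = ids, seq = unname(seqs), length = nchar(seqs))
}

#' Write genome sequences to FASTA
#'
#' @param genome Tibble with columns `id`, `seq` (as from [read_genome_fasta()]).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::BStringSet(setNames(genome$seq, genome$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene annotations
#'
#' Supports GFF3 (1-based inclusive coordinates, converted internally to
#' 0-based half-open) and a plain TSV dialect that already uses the internal
#' 0-based half-open convention (columns `gene_id`, `contig`, `start`, `end`,
#' `strand`, optional `operon_id` and extras).
#'
#' @param path Input path.
#' @param dialect `"gff3"` or `"tsv"`.
#' @param feature_type GFF3 rows to keep (matched against column 3).
#' @return Tibble: `gene_id`, `contig`, `start`, `end`, `strand`, `operon_id`
#'   plus any extra attribute columns.
#' @export
read_gene_annotation <- function(path, dialect = c("gff3", "tsv"),
                                 feature_type = "gene") {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    ann <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             gene_id = "c", contig = "c",
                             start = "d", end = "d", strand = "c",
                             .default = "c"))
    if (!"operon_id" %in% names(ann)) ann$operon_id <- NA_character_
  } else {
    raw <- readr::read_tsv(path, comment = "#", col_names = c(
      "contig", "source", "type", "gstart", "gend", "score", "strand",
      "phase", "attributes"), show_col_types = FALSE,
      col_types = "cccddcccc")
    raw <- dplyr::filter(raw, .data$type %in% feature_type)
    ids <- stringr::str_match(raw$attributes, "(?:^|;)\\s*ID=([^;]+)")[, 2]
    locus <- stringr::str_match(raw$attributes,
                                "(?:^|;)\\s*locus_tag=([^;]+)")[, 2]
    ann <- tibble(
      gene_id = dplyr::coalesce(ids, locus,
                                paste0("gene", seq_len(nrow(raw)))),
      contig = raw$contig,
      start = raw$gstart - 1,   # 1-based inclusive -> 0-based half-open
      end = raw$gend,
      strand = raw$strand,
      operon_id = NA_character_
    )
  }
  bad <- which(ann$end <= ann$start)
  if (length(bad)) {
    abort(sprintf("annotation row %d: end <= start (%s)", bad[1],
                  ann$gene_id[bad[1]]))
  }
  bad <- which(!ann$strand %in% c("+", "-"))
  if (length(bad)) {
    abort(sprintf("annotation row %d: strand must be + or -, got '%s'",
                  bad[1], ann$strand[bad[1]]))
  }
  ann
}

#' Write gene annotations as GFF3
#'
#' Converts internal 0-based half-open coordinates back to GFF3's 1-based
#' inclusive convention; exact inverse of [read_gene_annotation()].
#'
#' @param ann Annotation tibble.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gene_annotation_gff3 <- function(ann, path, source = "regulonscan") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     ann$contig, source, as.integer(ann$start + 1),
                     as.integer(ann$end), ann$strand, ann$gene_id))
  writeLines(lines, path)
  invisible(path)
}

table_schemas <- list(
  expression = list(required = c("gene_id", "log2fc", "pvalue"),
                    types = c(gene_id = "c", log2fc = "d", pvalue = "d")),
  peaks = list(required = c("contig", "start", "end", "enrichment"),
               types = c(contig = "c", start = "d", end = "d",
                         enrichment = "d")),
  ipd = list(required = c("contig", "position", "strand", "ipd_ratio", "qv"),
             types = c(contig = "c", position = "d", strand = "c",
                       ipd_ratio = "d", qv = "d")),
  orthologs = list(required = c("group_id", "species_id", "gene_id"),
                   types = c(group_id = "c", species_id = "c", gene_id = "c")),
  sites = list(required = c("site"),
               types = c(site = "c", collection = "c"))
)

validate_schema_rows <- function(df, schema) {
  switch(schema,
    expression = {
      bad <- which(!is.finite(df$log2fc) | is.na(df$pvalue) |
                     df$pvalue < 0 | df$pvalue > 1)
      if (length(bad)) abort(sprintf(
        "expression row %d: log2fc must be finite and pvalue in [0,1]", bad[1]))
    },
    peaks = {
      bad <- which(df$start >= df$end | df$enrichment < 0)
      if (length(bad)) abort(sprintf(
        "peaks row %d: require start < end and enrichment >= 0", bad[1]))
    },
    ipd = {
      bad <- which(!(df$ipd_ratio > 0) | df$qv < 0 |
                     !df$strand %in% c("+", "-"))
      if (length(bad)) abort(sprintf(
        "ipd row %d: require ipd_ratio > 0, qv >= 0, strand in {+,-}", bad[1]))
    },
    sites = {
      assert_dna(toupper(df$site), what = "sites table")
      df$site <- toupper(df$site)
    })
  df
}

#' Read a typed tabular input
#'
#' Reads one of the pipeline's TSV/BED schemas into a typed tibble and
#' validates row-level invariants (e.g. positive IPD ratios, p-values in
#' \[0,1\]). BED4 peak files (no header, columns chrom/start/end/enrichment)
#' are accepted for the `peaks` schema.
#'
#' @param path Input path.
#' @param schema One of `"expression"`, `"peaks"`, `"ipd"`, `"orthologs"`,
#'   `"sites"`.
#' @return A validated tibble with the schema's columns.
#' @export
read_table <- function(path,
                       schema = c("expression", "peaks", "ipd", "orthologs",
                                  "sites")) {
  schema <- match.arg(schema)
  spec <- table_schemas[[schema]]
  first <- readLines(path, n = 1)
  has_header <- length(first) > 0 &&
    any(startsWith(first, spec$required[1]))
  if (schema == "peaks" && !has_header) {
    # BED4: chrom, start, end, enrichment score
    df <- readr::read_tsv(path, col_names = spec$required,
                          col_types = "cddd", show_col_types = FALSE)
  } else if (schema == "sites" && !has_header) {
    df <- tibble(site = readLines(path))
    df <- df[df$site != "", , drop = FALSE]
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
    missing <- setdiff(spec$required, names(df))
    if (length(missing)) {
      abort(sprintf("%s table %s is missing required column(s): %s",
                    schema, path, paste(missing, collapse = ", ")))
    }
    for (col in names(spec$types)) {
      if (!col %in% names(df)) next
      if (spec$types[[col]] == "d") {
        conv <- suppressWarnings(as.numeric(df[[col]]))
        bad <- which(is.na(conv) & !is.na(df[[col]]))
        if (length(bad)) abort(sprintf(
          "%s table row %d: column '%s' value '%s' is not numeric",
          schema, bad[1], col, df[[col]][bad[1]]))
        df[[col]] <- conv
      }
    }
  }
  validate_schema_rows(tibble::as_tibble(df), schema)
}

#' Write records as TSV
#'
#' Header row, input row order preserved, floating-point columns rendered with
#' a fixed number of significant digits so output is deterministic.
#'
#' @param records Data frame of homogeneous records.
#' @param path Output path.
#' @param digits Significant digits for numeric columns.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, digits = 6L) {
  out <- dplyr::mutate(tibble::as_tibble(records), dplyr::across(
    dplyr::where(is.double), ~ signif(.x, digits)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
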