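# Shared in-code fixtures.

# The 4-site toy motif: GA[ACGT]TC with no pseudocount; IC = 8 bits under a
# uniform background (2 bits at each of 4 conserved positions).
toy_pssm <- function() {
  build_pssm(c("GAATC", "GACTC", "GAGTC", "GATTC"), pseudocount = 0)
}

# A PSSM whose frequencies equal the uniform background at every position.
uniform_pssm <- function(L = 1) {
  build_pssm(vapply(DNA_BASES_TEST, strrep, character(1), L),
             pseudocount = 0)
}

DNA_BASES_TEST <- c("A", "C", "G", "T")

random_pssm <- function(L, n_sites = 8, pseudocount = 0.25) {
  sites <- vapply(seq_len(n_sites), function(i) {
    paste(sample(DNA_BASES_TEST, L, replace = TRUE), collapse = "")
  }, character(1))
  build_pssm(sites, pseudocount = pseudocount)
}

random_dna_test <- function(n, length, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES_TEST, length, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
}

tiny_genome <- function(seq, id = "chr") {
  tibble::tibble(id = id, seq = seq, length = nchar(seq))
}

tiny_annotation <- function(...) {
  rows <- list(...)
  tibble::tibble(
    gene_id = vapply(rows, `[[`, character(1), 1),
    contig = "chr",
    start = vapply(rows, function(r) as.numeric(r[[2]]), numeric(1)),
    end = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1)),
    strand = vapply(rows, `[[`, character(1), 4),
    operon_id = NA_character_)
}
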