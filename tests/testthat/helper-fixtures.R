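# Small programmatic fixtures shared across test files.

# a genome_annotation from a list of CDS strings, one scaffold, with
# biased spacers between genes
make_annotation <- function(cds, species = "sp", spacer = 40L,
                            strand = NULL, categories = NULL) {
  n <- length(cds)
  if (is.null(strand)) strand <- rep("+", n)
  segs <- character(0); rows <- list(); cursor <- 0L
  sp_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = "")
  seq_parts <- character(0)
  for (i in seq_len(n)) {
    pad <- sp_seq(spacer)
    seq_parts <- c(seq_parts, pad)
    cursor <- cursor + nchar(pad)
    fwd <- if (strand[i] == "+") cds[i] else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds[i])))
    rows[[i]] <- data.frame(
      gene_id = sprintf("%s_g%03d", species, i), scaffold_id = "s1",
      start = cursor, end = cursor + nchar(fwd), strand = strand[i],
      cds = cds[i], protein = translate_cds(cds[i]),
      category = if (is.null(categories)) NA_character_ else categories[i],
      stringsAsFactors = FALSE)
    seq_parts <- c(seq_parts, fwd)
    cursor <- cursor + nchar(fwd)
  }
  seq_parts <- c(seq_parts, sp_seq(spacer))
  genome_annotation(species, c(s1 = paste(seq_parts, collapse = "")),
                    do.call(rbind, rows))
}

random_cds_fix <- function(n_codons) {
  ct <- triclade:::codon_tables()
  paste(c("ATG", sample(ct$sense, n_codons - 2, replace = TRUE), "TAA"),
        collapse = "")
}

# a trivial gene order table
make_order <- function(ids, scaffold = "s1") {
  data.frame(gene_id = ids, scaffold_id = scaffold,
             position = seq_along(ids), strand = "+",
             stringsAsFactors = FALSE)
}

# config with all evolutionary events switched off except those given
quiet_config <- function(seed = 1, n_genes = 20, ...) {
  zero <- function(...) branch_params(ka = 0, ks = 0, n_inversions = 0,
                                      n_duplications = 0, n_losses = 0,
                                      te_insertions = 0, ...)
  clade_config(seed = seed, n_genes = n_genes, n_te_families = 0,
               branches = list(A = zero(), I = zero(), B = zero(),
                               C = zero()), ...)
}
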