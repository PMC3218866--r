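#' @importFrom stats median rbinom rnorm runif setNames p.adjust chisq.test
#'   fisher.test wilcox.test cor phyper rpois
#' @importFrom utils head read.delim write.table
NULL

# Internal coordinates are 0-based half-open [start, end); GFF3 I/O converts
# to/from 1-based inclusive at the boundary.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and RNA `U` is normalized to `T`.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for id: ", ids[nchar(seqs) == 0L][1])
  names(seqs) <- ids
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  if (any(nchar(seqs) == 0L)) stop("refusing to write empty sequence")
  set <- Biostrings::BStringSet(unlist(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Translate a coding sequence with the standard genetic code
#'
#' Codons containing `N` translate to `X`; a trailing stop codon is dropped.
#' Internal stops are retained as `*` so callers can detect broken models.
#'
#' @param dna CDS string (length a multiple of 3, alphabet ACGTN).
#' @return Amino-acid string.
#' @export
translate_cds <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  if (nchar(dna) %% 3L != 0L || nchar(dna) < 3L)
    stop("CDS length must be a positive multiple of 3, got ", nchar(dna))
  cods <- split_codons(toupper(dna))
  aa <- unname(codon_tables()$gc[cods])
  aa[is.na(aa)] <- "X"  # any codon containing N (or other ambiguity)
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

reverse_complement <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Construct a genome annotation
#'
#' The central data model: a set of scaffolds plus ordered, stranded,
#' non-overlapping gene models with their CDS and protein sequences.
#'
#' @param species species label.
#' @param scaffolds named character vector of scaffold sequences.
#' @param genes data.frame with columns `gene_id`, `scaffold_id`, `start`
#'   (0-based), `end` (exclusive), `strand` (`+`/`-`), `cds`, `protein`, and
#'   optionally `category`.
#' @param validate check all invariants (default TRUE).
#' @return Object of class `genome_annotation`.
#' @export
genome_annotation <- function(species, scaffolds, genes, validate = TRUE) {
  if (is.null(genes$category))
    genes$category <- rep(NA_character_, nrow(genes))
  genes <- genes[order(match(genes$scaffold_id, names(scaffolds)), genes$start), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  ann <- structure(list(species = species, scaffolds = scaffolds, genes = genes),
                   class = "genome_annotation")
  if (validate) validate_annotation(ann)
  ann
}

#' Validate a genome annotation against its invariants
#'
#' Checks coordinates, ordering, non-overlap, CDS length, and that each
#' protein equals the translation of its CDS.
#'
#' @param ann a `genome_annotation`.
#' @return `ann` invisibly; errors on violation.
#' @export
validate_annotation <- function(ann) {
  g <- ann$genes
  if (anyDuplicated(g$gene_id)) stop("duplicate gene_id")
  if (!all(g$scaffold_id %in% names(ann$scaffolds)))
    stop("gene references unknown scaffold")
  slen <- nchar(ann$scaffolds)[g$scaffold_id]
  bad <- which(!(g$start >= 0L & g$start < g$end & g$end <= slen))
  if (length(bad)) stop("gene out of scaffold bounds: ", g$gene_id[bad[1]])
  if (any(nchar(g$cds) %% 3L != 0L | nchar(g$cds) < 3L))
    stop("CDS length not a positive multiple of 3")
  for (sc in unique(g$scaffold_id)) {
    gs <- g[g$scaffold_id == sc, ]
    if (is.unsorted(gs$start, strictly = TRUE) && nrow(gs) > 1L)
      stop("genes not sorted by start on ", sc)
    if (nrow(gs) > 1L && any(gs$start[-1L] < gs$end[-nrow(gs)]))
      stop("overlapping genes on ", sc)
  }
  prot <- vapply(g$cds, translate_cds, "", USE.NAMES = FALSE)
  if (!identical(prot, unname(g$protein)))
    stop("protein does not match CDS translation for: ",
         g$gene_id[which(prot != g$protein)[1]])
  invisible(ann)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d scaffolds (%.1f kb), %d genes\n",
              x$species, length(x$scaffolds),
              sum(nchar(x$scaffolds)) / 1000, nrow(x$genes)))
  invisible(x)
}

#' Read a genome bundle (scaffolds FASTA + GFF3 + CDS/protein FASTA)
#'
#' GFF3 `gene` features (1-based inclusive) are converted to the internal
#' 0-based half-open convention. CDS and protein FASTAs are keyed by gene id.
#'
#' @param fasta_path scaffold FASTA.
#' @param gff3_path GFF3 with `gene` features carrying `ID` attributes.
#' @param cds_fasta FASTA of coding sequences, ids matching gene ids.
#' @param protein_fasta FASTA of proteins, ids matching gene ids.
#' @param categories_tsv optional two-column TSV `gene_id<TAB>category`.
#' @param species species label (default: scaffold FASTA basename).
#' @return A `genome_annotation`.
#' @export
read_genome <- function(fasta_path, gff3_path, cds_fasta, protein_fasta,
                        categories_tsv = NULL, species = NULL) {
  scaffolds <- read_fasta(fasta_path)
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0L) stop("no gene features in ", gff3_path)
  cds <- read_fasta(cds_fasta)
  prot <- read_fasta(protein_fasta)
  ids <- as.character(gr$ID)
  if (!all(ids %in% names(cds))) stop("missing CDS for gene: ",
                                      setdiff(ids, names(cds))[1])
  if (!all(ids %in% names(prot))) stop("missing protein for gene: ",
                                       setdiff(ids, names(prot))[1])
  genes <- data.frame(
    gene_id = ids,
    scaffold_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # GFF3 1-based -> 0-based
    end = GenomicRanges::end(gr),           # inclusive -> exclusive
    strand = as.character(GenomicRanges::strand(gr)),
    cds = unname(cds[ids]),
    protein = unname(prot[ids]),
    stringsAsFactors = FALSE
  )
  if (!is.null(categories_tsv)) {
    cat_df <- read.delim(categories_tsv, header = FALSE,
                         col.names = c("gene_id", "category"),
                         stringsAsFactors = FALSE)
    genes$category <- cat_df$category[match(genes$gene_id, cat_df$gene_id)]
  }
  if (is.null(species))
    species <- sub("\\.[^.]*$", "", basename(fasta_path))
  genome_annotation(species, scaffolds, genes)
}

#' Write a genome annotation as a bundle of standard files
#'
#' Emits `<prefix>.fa`, `<prefix>.gff3`, `<prefix>.cds.fa`,
#' `<prefix>.prot.fa` and, when categories are present,
#' `<prefix>.categories.tsv`.
#'
#' @param ann a `genome_annotation`.
#' @param dir output directory (created if absent).
#' @param prefix file prefix (default: species label).
#' @return Named character vector of the paths written.
#' @export
write_genome <- function(ann, dir, prefix = ann$species) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(ext) file.path(dir, paste0(prefix, ext))
  write_fasta(ann$scaffolds, p(".fa"))
  g <- ann$genes
  gr <- GenomicRanges::GRanges(
    g$scaffold_id,
    IRanges::IRanges(g$start + 1L, g$end),  # 0-based half-open -> 1-based incl.
    strand = g$strand, type = "gene", ID = g$gene_id)
  rtracklayer::export(gr, p(".gff3"), format = "gff3")
  write_fasta(setNames(g$cds, g$gene_id), p(".cds.fa"))
  write_fasta(setNames(g$protein, g$gene_id), p(".prot.fa"))
  paths <- c(fasta = p(".fa"), gff3 = p(".gff3"),
             cds = p(".cds.fa"), protein = p(".prot.fa"))
  if (any(!is.na(g$category))) {
    keep <- !is.na(g$category)
    write.table(g[keep, c("gene_id", "category")], p(".categories.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths <- c(paths, categories = p(".categories.tsv"))
  }
  paths
}

#' Gene order of a genome annotation
#'
#' One row per gene in genomic order (by start coordinate, regardless of
#' strand), with the within-scaffold position index used for synteny.
#'
#' @param ann a `genome_annotation`.
#' @return data.frame with `gene_id`, `scaffold_id`, `position` (1-based
#'   within scaffold), `strand`.
#' @export
gene_order <- function(ann) {
  g <- ann$genes
  pos <- unlist(lapply(split(seq_len(nrow(g)), g$scaffold_id)[unique(g$scaffold_id)],
                       seq_along), use.names = FALSE)
  ord <- data.frame(gene_id = g$gene_id, scaffold_id = g$scaffold_id,
                    position = pos, strand = g$strand,
                    stringsAsFactors = FALSE)
  ord
}
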