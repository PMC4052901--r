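#' Construct a genome object
#'
#' A `genome` bundles the nucleotide sequence of one organism with its gene
#' feature table and (optionally) protein sequences.  Coordinates are stored
#' internally as 0-based half-open intervals; GFF3 I/O converts from/to the
#' 1-based inclusive convention.
#'
#' @param genome_id single string identifying the organism.
#' @param contigs named character vector of contig sequences (A/C/G/T/N).
#' @param genes data.frame with columns `gene_id`, `contig_id`, `start`,
#'   `end` (0-based half-open), `strand` (`+`/`-`), `locus_tag`,
#'   `function_label`, `is_tf` (logical).
#' @param proteins optional named character vector of amino-acid sequences,
#'   names matching `gene_id`s.
#' @return an object of class `genome`.  Genes are sorted per contig by
#'   start coordinate with ties broken by `gene_id`.
#' @export
new_genome <- function(genome_id, contigs, genes, proteins = NULL) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  req <- c("gene_id", "contig_id", "start", "end", "strand")
  miss <- setdiff(req, names(genes))
  if (length(miss)) stop("genes table lacks columns: ", paste(miss, collapse = ", "))
  if (!"locus_tag" %in% names(genes)) genes$locus_tag <- genes$gene_id
  if (!"function_label" %in% names(genes)) genes$function_label <- ""
  if (!"is_tf" %in% names(genes)) genes$is_tf <- FALSE
  genes$is_tf <- as.logical(genes$is_tf)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)

  bad <- !genes$strand %in% c("+", "-")
  if (any(bad)) {
    stop("malformed strand for feature ", genes$gene_id[which(bad)[1]],
         ": '", genes$strand[which(bad)[1]], "'")
  }
  unknown <- setdiff(unique(genes$contig_id), names(contigs))
  if (length(unknown)) {
    first <- genes$gene_id[match(unknown[1], genes$contig_id)]
    stop("feature ", first, " references unknown contig '", unknown[1], "'")
  }
  if (any(genes$start >= genes$end)) {
    stop("gene with start >= end: ",
         genes$gene_id[which(genes$start >= genes$end)[1]])
  }
  clen <- nchar(contigs)[genes$contig_id]
  if (any(genes$start < 0L | genes$end > clen)) {
    stop("gene outside contig bounds: ",
         genes$gene_id[which(genes$start < 0L | genes$end > clen)[1]])
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id: ", genes$gene_id[anyDuplicated(genes$gene_id)])
  }
  ord <- order(genes$contig_id, genes$start, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  structure(
    list(genome_id = genome_id, contigs = contigs, genes = genes,
         proteins = proteins),
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome>", x$genome_id, "|", length(x$contigs), "contig(s),",
      nrow(x$genes), "genes,", sum(x$genes$is_tf), "TF gene(s)\n")
  invisible(x)
}

#' Position of the translation start of a gene
#'
#' On the `+` strand this is the gene start; on the `-` strand it is
#' `end - 1` (the last position of the 0-based half-open interval).
#'
#' @param gene one-row data.frame (a row of a genome's gene table).
#' @return integer genomic position.
#' @export
translation_start <- function(gene) {
  if (gene$strand == "+") gene$start else gene$end - 1L
}

#' Read a genome from FASTA + features
#'
#' @param sequence_file path to a nucleotide FASTA file.
#' @param features path to a GFF3 file (attributes `ID`/`locus_tag`/
#'   `product`/`is_tf`) or a TSV feature table with header
#'   `gene_id contig_id start end strand locus_tag function_label is_tf`
#'   (1-based inclusive coordinates, as in GFF3).
#' @param proteins optional path to a protein FASTA (names = gene_ids).
#' @param genome_id identifier; defaults to the features file base name.
#' @return a `genome` object.
#' @export
read_genome <- function(sequence_file, features, proteins = NULL,
                        genome_id = NULL) {
  seqs <- Biostrings::readDNAStringSet(sequence_file)
  contigs <- setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(gff3?|tsv|txt)$", "", basename(features))
  }
  if (grepl("\\.gff3?$", features)) {
    gr <- rtracklayer::import(features)
    gr <- gr[gr$type == "gene"]
    mc <- S4Vectors::mcols(gr)
    get_attr <- function(nm, default) {
      if (nm %in% names(mc)) as.character(mc[[nm]]) else
        rep(default, length(gr))
    }
    genes <- data.frame(
      gene_id = get_attr("ID", NA_character_),
      contig_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # 1-based incl -> 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      locus_tag = get_attr("locus_tag", NA_character_),
      function_label = get_attr("product", ""),
      is_tf = get_attr("is_tf", "false") %in% c("true", "TRUE", "1"),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- read.delim(features, stringsAsFactors = FALSE)
    genes <- data.frame(
      gene_id = as.character(tab$gene_id),
      contig_id = as.character(tab$contig_id),
      start = as.integer(tab$start) - 1L,
      end = as.integer(tab$end),
      strand = as.character(tab$strand),
      locus_tag = as.character(tab$locus_tag %||% tab$gene_id),
      function_label = as.character(tab$function_label %||% ""),
      is_tf = as.logical(tab$is_tf %||% FALSE),
      stringsAsFactors = FALSE
    )
  }
  prot <- NULL
  if (!is.null(proteins)) {
    aa <- Biostrings::readAAStringSet(proteins)
    prot <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  }
  new_genome(genome_id, contigs, genes, prot)
}

#' Write a genome to FASTA + GFF3 (+ protein FASTA)
#'
#' @param genome a `genome` object.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the paths written.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, genome$genome_id)
  fa <- paste0(base, ".fna")
  gff <- paste0(base, ".gff3")
  seqs <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(seqs, fa)
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$contig_id,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$source <- "regulogr"
  S4Vectors::mcols(gr)$ID <- g$gene_id
  S4Vectors::mcols(gr)$locus_tag <- g$locus_tag
  S4Vectors::mcols(gr)$product <- g$function_label
  S4Vectors::mcols(gr)$is_tf <- ifelse(g$is_tf, "true", "false")
  rtracklayer::export(gr, gff, format = "gff3")
  paths <- list(fasta = fa, gff3 = gff)
  if (!is.null(genome$proteins)) {
    faa <- paste0(base, ".faa")
    Biostrings::writeXStringSet(Biostrings::AAStringSet(genome$proteins), faa)
    paths$proteins <- faa
  }
  invisible(paths)
}

#' Extract the promoter window of a gene
#'
#' Returns the sequence from `window[1]` to `window[2]` bp relative to the
#' translational start of the anchor gene (default -400..+100), oriented
#' 5'->3' on the coding strand, clipped only at contig boundaries.  The
#' window deliberately runs into upstream coding genes: binding sites of
#' this TF family occur inside coding sequence, so no gene-boundary
#' truncation is applied.
#'
#' @param genome a `genome` object.
#' @param anchor a `gene_id` present in the genome, or a one-row gene table.
#' @param window integer pair `(lower, upper)` relative to translation
#'   start; default `c(-400, 100)`.
#' @param operon_id optional operon identifier to record as anchor.
#' @return a `promoter_region`: list with `anchor_gene_id`,
#'   `anchor_operon_id`, `contig_id`, `start`, `end` (genomic, 0-based
#'   half-open), `strand`, `sequence` (oriented), and
#'   `offset_of_start_codon` (oriented position of the translation start).
#' @export
extract_promoter <- function(genome, anchor, window = c(-400L, 100L),
                             operon_id = NA_character_) {
  if (window[1] >= window[2]) stop("promoter window lower bound must be < upper bound")
  if (is.character(anchor)) {
    i <- match(anchor, genome$genes$gene_id)
    if (is.na(i)) stop("anchor gene ", anchor, " not in genome")
    anchor <- genome$genes[i, , drop = FALSE]
  }
  contig <- genome$contigs[[anchor$contig_id]]
  clen <- nchar(contig)
  t <- translation_start(anchor)
  if (anchor$strand == "+") {
    s <- max(0L, t + window[1])
    e <- min(clen, t + window[2])
    seq <- substr(contig, s + 1L, e)
    off <- t - s
  } else {
    # coding-direction window [window1, window2) maps to genomic
    # [t - window2 + 1, t - window1 + 1)
    s <- max(0L, t - window[2] + 1L)
    e <- min(clen, t - window[1] + 1L)
    seq <- revcomp(substr(contig, s + 1L, e))
    off <- e - 1L - t
  }
  structure(
    list(anchor_gene_id = anchor$gene_id, anchor_operon_id = operon_id,
         contig_id = anchor$contig_id, start = s, end = e,
         strand = anchor$strand, sequence = seq,
         offset_of_start_codon = off),
    class = "promoter_region"
  )
}

#' @export
print.promoter_region <- function(x, ...) {
  cat("<promoter>", x$contig_id, sprintf("[%d,%d)", x$start, x$end),
      x$strand, "anchor", x$anchor_gene_id, "len", nchar(x$sequence), "\n")
  invisible(x)
}

#' Write binding sites as BED6
#'
#' @param sites site table as produced by [scan_region()] (columns
#'   `contig_id`, `start`, `end`, `strand`, `score`, and an anchor column).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_sites_bed <- function(sites, path) {
  name <- if ("anchor_operon_id" %in% names(sites)) sites$anchor_operon_id
          else sites$anchor_gene_id %||% rep(".", nrow(sites))
  bed <- data.frame(
    chrom = sites$contig_id,
    chromStart = sites$start,
    chromEnd = sites$end,
    name = ifelse(is.na(name), ".", name),
    score = as.integer(pmax(0, pmin(1000, round(sites$score * 25)))),
    strand = sites$strand
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
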