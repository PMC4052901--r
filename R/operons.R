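# Operon prediction from gene layout, optionally refined by predicted
# internal binding sites, and cross-genome conservation of adjacencies.

#' Predict operons from gene layout
#'
#' Operons are maximal runs of adjacent same-strand genes with
#' intergenic distance up to `max_gap` bp (inclusive; overlapping genes
#' always merge) and no TF-binding site centred in any internal
#' intergenic gap.  The result partitions the gene set.
#'
#' @param genome a `genome` object.
#' @param internal_sites optional site table (columns `contig_id`,
#'   `center`) of the TF under study; a gap containing a site centre is
#'   split.
#' @param max_gap maximum intergenic distance in bp, default 100.
#' @return data.frame with one row per operon: `operon_id`, `genome_id`,
#'   `contig_id`, `strand`, `first_gene_id`, `n_genes`, and a list
#'   column `gene_ids` (5'->3' on the coding strand).
#' @export
predict_operons <- function(genome, internal_sites = NULL, max_gap = 100L) {
  rows <- list()
  for (cid in names(genome$contigs)) {
    g <- genome$genes[genome$genes$contig_id == cid, , drop = FALSE]
    if (!nrow(g)) next
    centers <- if (!is.null(internal_sites) && nrow(internal_sites)) {
      internal_sites$center[internal_sites$contig_id == cid]
    } else integer(0)
    brk <- logical(nrow(g))  # brk[i]: break between gene i-1 and i
    if (nrow(g) > 1L) {
      for (i in 2:nrow(g)) {
        gap <- g$start[i] - g$end[i - 1L]
        same <- g$strand[i] == g$strand[i - 1L]
        site_in_gap <- gap > 0L &&
          any(centers >= g$end[i - 1L] & centers < g$start[i])
        brk[i] <- !same || gap > max_gap || site_in_gap
      }
    }
    run <- cumsum(brk) + 1L
    for (r in unique(run)) {
      idx <- which(run == r)
      strand <- g$strand[idx[1]]
      ids <- g$gene_id[idx]               # genomic left-to-right
      if (strand == "-") ids <- rev(ids)  # 5'->3' on coding strand
      rows[[length(rows) + 1L]] <- data.frame(
        operon_id = paste0("opn_", ids[1]),
        genome_id = genome$genome_id, contig_id = cid, strand = strand,
        first_gene_id = ids[1], n_genes = length(ids),
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$gene_ids <- list(ids)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-genome conservation of operon structure
#'
#' Scores each internal gene adjacency of every operon by the number of
#' genomes in which the same ordered pair of ortholog groups is
#' co-operonic, and annotates each operon with the minimum support over
#' its adjacencies (`NA` for single-gene operons).  With
#' `split = TRUE`, adjacencies supported in fewer than `min_genomes`
#' genomes are cut.
#'
#' @param operon_tables named list (by genome) of [predict_operons()]
#'   outputs.
#' @param ortholog_map data.frame `gene_id`, `group` (genes without a
#'   group are treated as singleton groups, with a warning).
#' @param min_genomes support threshold used when splitting (default 2).
#' @param split cut weakly supported adjacencies (default `FALSE`:
#'   report support only).
#' @return named list (by genome) of operon tables with a
#'   `cross_genome_support` column.
#' @export
operon_conservation <- function(operon_tables, ortholog_map,
                                min_genomes = 2L, split = FALSE) {
  og <- setNames(ortholog_map$group, ortholog_map$gene_id)
  warned <- FALSE
  lookup <- function(id) {
    grp <- og[id]
    if (anyNA(grp)) {
      if (!warned) {
        warning("gene(s) without ortholog group treated as singleton: ",
                id[is.na(grp)][1])
        warned <<- TRUE
      }
      grp[is.na(grp)] <- paste0("singleton_", id[is.na(grp)])
    }
    unname(grp)
  }
  # count genomes per ordered co-operonic adjacency of groups
  adj_support <- new.env(parent = emptyenv())
  for (gid in names(operon_tables)) {
    seen <- character(0)
    tab <- operon_tables[[gid]]
    for (i in seq_len(nrow(tab))) {
      ids <- tab$gene_ids[[i]]
      if (length(ids) < 2L) next
      grp <- lookup(ids)
      for (j in seq_len(length(grp) - 1L)) {
        key <- paste(grp[j], grp[j + 1L], sep = ">")
        if (!key %in% seen) {
          seen <- c(seen, key)
          adj_support[[key]] <- (adj_support[[key]] %||% 0L) + 1L
        }
      }
    }
  }
  out <- list()
  for (gid in names(operon_tables)) {
    tab <- operon_tables[[gid]]
    new_rows <- list()
    for (i in seq_len(nrow(tab))) {
      ids <- tab$gene_ids[[i]]
      grp <- if (length(ids) > 1L) lookup(ids) else character(0)
      supp <- if (length(ids) > 1L) {
        vapply(seq_len(length(grp) - 1L), function(j) {
          adj_support[[paste(grp[j], grp[j + 1L], sep = ">")]]
        }, integer(1))
      } else integer(0)
      if (split && length(supp)) {
        cut_after <- which(supp < min_genomes)
        bounds <- c(0L, cut_after, length(ids))
        pieces <- lapply(seq_len(length(bounds) - 1L), function(b) {
          ids[(bounds[b] + 1L):bounds[b + 1L]]
        })
      } else {
        pieces <- list(ids)
      }
      for (piece in pieces) {
        row <- tab[i, , drop = FALSE]
        row$operon_id <- paste0("opn_", piece[1])
        row$first_gene_id <- piece[1]
        row$n_genes <- length(piece)
        row$gene_ids <- list(piece)
        row$cross_genome_support <-
          if (length(piece) > 1L) {
            keep_j <- match(piece[-length(piece)], ids)
            min(supp[keep_j])
          } else NA_integer_
        new_rows[[length(new_rows) + 1L]] <- row
      }
    }
    res <- do.call(rbind, new_rows)
    rownames(res) <- NULL
    out[[gid]] <- res
  }
  out
}

#' Write operon tables as TSV
#' @param operon_table a [predict_operons()] output.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_operons_tsv <- function(operon_table, path) {
  tab <- operon_table
  tab$gene_ids <- vapply(tab$gene_ids, paste, character(1), collapse = ";")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
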