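# Protein similarity, bidirectional best hits, ortholog groups, and
# TF-group formation.
#
# The tree- and gene-context-based orthology criteria used in manual
# curation are approximated operationally: ortholog groups are connected
# components of the cross-genome BBH graph, and TF groups are further
# split so that all members share highly similar binding motifs.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

protein_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1), k:n))
}

#' Pairwise protein similarity between two proteomes
#'
#' `kmer` (default): similarity of proteins x, y is
#' `|K(x) n K(y)| / min(|K(x)|, |K(y)|)` over their unique k-mer sets
#' (default k = 4), a fast dimensionless score in `[0, 1]`.
#' `alignment`: Smith-Waterman-style local alignment score with BLOSUM62
#' and affine gaps (opening 10, extension 0.5 per residue) via
#' `Biostrings::pairwiseAlignment`.
#'
#' @param proteins_a,proteins_b named character vectors of amino-acid
#'   sequences (names are gene ids).
#' @param method `"kmer"` or `"alignment"`.
#' @param k k-mer size for the kmer method.
#' @return a hit table: data.frame `query`, `subject`, `score`.  Scores
#'   are directional rows over all query x subject pairs;
#'   self-comparisons are excluded when the two proteomes are identical
#'   objects.
#' @export
pairwise_similarity <- function(proteins_a, proteins_b,
                                method = c("kmer", "alignment"), k = 4L) {
  method <- match.arg(method)
  if (!length(proteins_a) || !length(proteins_b)) {
    stop("empty proteome")
  }
  for (set in list(proteins_a, proteins_b)) {
    empty <- which(nchar(set) == 0L)
    if (length(empty)) stop("empty sequence for gene ", names(set)[empty[1]])
  }
  same <- identical(proteins_a, proteins_b)
  if (method == "kmer") {
    ka <- lapply(proteins_a, protein_kmers, k = k)
    kb <- if (same) ka else lapply(proteins_b, protein_kmers, k = k)
    # shared-kmer counts via a sparse binary incidence matrix product
    univ <- unique(c(unlist(ka, use.names = FALSE),
                     unlist(kb, use.names = FALSE)))
    inc <- function(sets) {
      Matrix::sparseMatrix(
        i = match(unlist(sets, use.names = FALSE), univ),
        j = rep(seq_along(sets), lengths(sets)),
        x = 1, dims = c(length(univ), length(sets)))
    }
    ma <- inc(ka)
    mb <- if (same) ma else inc(kb)
    shared <- as.matrix(Matrix::crossprod(ma, mb))
    na <- vapply(ka, length, integer(1))
    nb <- vapply(kb, length, integer(1))
    denom <- outer(na, nb, pmin)
    denom[denom == 0L] <- 1L
    simm <- shared / denom
    out <- data.frame(query = rep(names(proteins_a), length(kb)),
                      subject = rep(names(proteins_b), each = length(ka)),
                      score = as.vector(simm),
                      stringsAsFactors = FALSE)
  } else {
    data_env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
    blosum <- get("BLOSUM62", envir = data_env)
    grid <- expand.grid(q = seq_along(proteins_a), s = seq_along(proteins_b))
    score <- mapply(function(i, j) {
      Biostrings::pairwiseAlignment(
        Biostrings::AAString(proteins_a[[i]]),
        Biostrings::AAString(proteins_b[[j]]),
        type = "local", substitutionMatrix = blosum,
        gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE)
    }, grid$q, grid$s)
    out <- data.frame(query = names(proteins_a)[grid$q],
                      subject = names(proteins_b)[grid$s],
                      score = score, stringsAsFactors = FALSE)
  }
  if (same) out <- out[out$query != out$subject, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# unique best subject per query with lexicographic tie-break
best_hits <- function(tab) {
  # integer sort keys: locale-aware character ordering is slow at scale
  qi <- match(tab$query, unique(tab$query))
  si <- match(tab$subject, sort(unique(tab$subject)))
  o <- order(qi, -tab$score, si)
  t2 <- tab[o, , drop = FALSE]
  idx <- which(!duplicated(t2$query))
  nxt <- idx + 1L
  tie <- nxt <= nrow(t2) & t2$query[pmin(nxt, nrow(t2))] == t2$query[idx] &
    t2$score[pmin(nxt, nrow(t2))] == t2$score[idx]
  data.frame(query = t2$query[idx], subject = t2$subject[idx],
             tie = tie, stringsAsFactors = FALSE)
}

#' Bidirectional best hits between two genomes
#'
#' A pair `(x, y)` is a BBH iff `y` is `x`'s best subject in the A-vs-B
#' table and `x` is `y`'s best subject in the B-vs-A table.  Score ties
#' are broken by lexicographic subject order and the pair is flagged
#' `tie_broken`.
#'
#' @param a_vs_b,b_vs_a hit tables from [pairwise_similarity()].
#' @return data.frame `gene_a`, `gene_b`, `tie_broken`.
#' @export
bidirectional_best_hits <- function(a_vs_b, b_vs_a) {
  if (!nrow(a_vs_b) || !nrow(b_vs_a)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      tie_broken = logical(0)))
  }
  ba <- best_hits(a_vs_b)
  bb <- best_hits(b_vs_a)
  m <- match(ba$subject, bb$query)
  keep <- !is.na(m) & bb$subject[m] == ba$query
  out <- data.frame(gene_a = ba$query[keep], gene_b = ba$subject[keep],
                    tie_broken = ba$tie[keep] | bb$tie[m][keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build ortholog groups from BBH pairs
#'
#' Groups are the connected components of the BBH graph over all genome
#' pairs.  Genes with no pair form singleton groups.  Group labels are
#' deterministic: `OGnnnn` in order of each component's lexicographically
#' smallest member.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b` pooled over
#'   all genome pairs.
#' @param all_genes optional character vector of every gene id, so that
#'   unpaired genes get singleton groups.
#' @return data.frame `gene_id`, `group` (a partition of the gene set).
#' @export
build_ortholog_groups <- function(pairs, all_genes = NULL) {
  verts <- unique(c(pairs$gene_a, pairs$gene_b, all_genes))
  if (!length(verts)) {
    return(data.frame(gene_id = character(0), group = character(0)))
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = pairs$gene_a, to = pairs$gene_b),
    directed = FALSE,
    vertices = data.frame(name = verts))
  comp <- igraph::components(g)$membership
  # deterministic labels keyed by smallest member id
  key <- vapply(split(names(comp), comp), min, character(1))
  ord <- rank(key, ties.method = "first")
  lab <- sprintf("OG%04d", ord)[comp]
  out <- data.frame(gene_id = names(comp), group = lab,
                    stringsAsFactors = FALSE)
  out <- out[order(out$group, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Form TF ortholog groups with motif-similarity splitting
#'
#' BBH-derived candidate TF groups are split into subgroups such that,
#' under single linkage, all pairwise motif similarities within a
#' subgroup reach the threshold `tau`.  TFs lacking a motif stay with
#' their BBH group and are flagged.  TFs from different BBH components
#' are never merged.
#'
#' @param groups data.frame `gene_id`, `group` for TF genes (e.g. the TF
#'   rows of [build_ortholog_groups()] output).
#' @param motifs named list of `pwm` objects keyed by TF gene id; `NULL`
#'   entries allowed.
#' @param tau similarity threshold in `[-1, 1]`, default 0.8.
#' @return data.frame `gene_id`, `group`, `tf_group`, `no_motif`.
#' @export
form_tf_groups <- function(groups, motifs, tau = 0.8) {
  out <- list()
  for (grp in unique(groups$group)) {
    members <- sort(groups$gene_id[groups$group == grp])
    has_motif <- vapply(members, function(m) !is.null(motifs[[m]]), logical(1))
    with_m <- members[has_motif]
    sub <- setNames(rep(1L, length(members)), members)
    if (length(with_m) > 1L) {
      edges <- list()
      for (i in seq_along(with_m)) {
        for (j in seq_len(i - 1L)) {
          if (motif_similarity(motifs[[with_m[i]]],
                               motifs[[with_m[j]]]) >= tau) {
            edges[[length(edges) + 1L]] <- c(with_m[j], with_m[i])
          }
        }
      }
      ed <- if (length(edges)) do.call(rbind, edges) else
        matrix(character(0), ncol = 2)
      g <- igraph::graph_from_data_frame(
        d = data.frame(from = ed[, 1], to = ed[, 2]),
        directed = FALSE, vertices = data.frame(name = with_m))
      comp <- igraph::components(g)$membership
      sub[names(comp)] <- comp + 1L  # motif-bearing TFs in components 2+
      # motifless TFs stay in the subgroup of the full BBH group: give
      # them the majority component if one exists, else their own
      if (any(!has_motif)) {
        sub[members[!has_motif]] <- as.integer(names(which.max(
          table(comp))) ) + 1L
      }
    }
    for (m in members) {
      out[[length(out) + 1L]] <- data.frame(
        gene_id = m, group = grp,
        tf_group = paste0(grp, ".", sub[[m]]),
        no_motif = !has_motif[[match(m, members)]],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
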