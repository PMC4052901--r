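# Regulon assembly: per-genome candidate regulons from promoter scans,
# the cross-genome consistency filter, autoregulation detection,
# global/local classification, and regulog aggregation.

#' Reconstruct a candidate regulon in one genome
#'
#' Scans the promoter window of every operon with the calibrated PWM;
#' operons with at least one above-threshold site become candidate
#' members.  Divergently transcribed operons with overlapping windows
#' each receive the sites falling in their own window, so a shared site
#' is attributed to both (reported once per anchored operon).
#'
#' @param tf_gene_id id of the TF whose motif is being used.
#' @param pwm calibrated `pwm` (threshold set).
#' @param genome a `genome` object.
#' @param operons [predict_operons()] output for this genome.
#' @param window promoter window, default `c(-400, 100)`.
#' @return a `regulon`: list with `tf_gene_id`, `genome_id`, `members`
#'   (operon table rows of members), `sites` (pooled site table with
#'   `genome_id`), `n_operons`, `n_genes`, `pathways`.
#' @export
reconstruct_regulon <- function(tf_gene_id, pwm, genome, operons,
                                window = c(-400L, 100L)) {
  sites <- list()
  for (i in seq_len(nrow(operons))) {
    pr <- extract_promoter(genome, operons$first_gene_id[i], window,
                           operon_id = operons$operon_id[i])
    hit <- scan_region(pwm, pr)
    if (nrow(hit)) {
      hit$genome_id <- genome$genome_id
      sites[[length(sites) + 1L]] <- hit
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites) else {
    es <- empty_site_table()
    es$genome_id <- character(0)
    es
  }
  member_ids <- unique(sites$anchor_operon_id)
  members <- operons[operons$operon_id %in% member_ids, , drop = FALSE]
  regulon(tf_gene_id, genome$genome_id, members, sites)
}

# regulon constructor shared by reconstruction and filtering
regulon <- function(tf_gene_id, genome_id, members, sites) {
  structure(
    list(tf_gene_id = tf_gene_id, genome_id = genome_id,
         members = members, sites = sites,
         n_operons = nrow(members),
         n_genes = if (nrow(members)) sum(members$n_genes) else 0L),
    class = "regulon")
}

#' @export
print.regulon <- function(x, ...) {
  cat("<regulon> TF", x$tf_gene_id, "in", x$genome_id, "|",
      x$n_operons, "operons,", x$n_genes, "genes,",
      nrow(x$sites), "sites\n")
  invisible(x)
}

#' Pathway labels of a regulon's member genes
#'
#' @param reg a `regulon`.
#' @param genome the matching `genome` object.
#' @return character vector of distinct non-empty function labels.
#' @export
regulon_pathways <- function(reg, genome) {
  ids <- unlist(reg$members$gene_ids)
  labs <- genome$genes$function_label[match(ids, genome$genes$gene_id)]
  sort(unique(labs[!is.na(labs) & labs != "" &
                     labs != "hypothetical_protein"]))
}

#' Cross-genome consistency filter
#'
#' A candidate member operon is retained iff operons with the same
#' first-gene ortholog group carry above-threshold sites in at least
#' `min_genomes` genomes (counting itself).  Sites of removed operons
#' are dropped.  Output is always a subset of the input, and raising
#' `min_genomes` never adds members.
#'
#' @param candidates named list (by genome) of `regulon` objects for one
#'   TF group.
#' @param ortholog_map data.frame `gene_id`, `group`.
#' @param min_genomes support threshold, default 2.
#' @return named list of filtered `regulon` objects.
#' @export
consistency_filter <- function(candidates, ortholog_map, min_genomes = 2L) {
  og <- setNames(ortholog_map$group, ortholog_map$gene_id)
  sig <- function(reg) {
    grp <- og[reg$members$first_gene_id]
    grp[is.na(grp)] <- paste0("singleton_",
                              reg$members$first_gene_id[is.na(grp)])
    unname(grp)
  }
  sigs <- lapply(candidates, sig)
  support <- table(unlist(lapply(sigs, unique)))
  out <- lapply(seq_along(candidates), function(i) {
    reg <- candidates[[i]]
    keep <- support[sigs[[i]]] >= min_genomes
    keep[is.na(keep)] <- FALSE
    members <- reg$members[keep, , drop = FALSE]
    sites <- reg$sites[reg$sites$anchor_operon_id %in% members$operon_id, ,
                       drop = FALSE]
    regulon(reg$tf_gene_id, reg$genome_id, members, sites)
  })
  names(out) <- names(candidates)
  out
}

#' Detect autoregulation
#'
#' `TRUE` iff the operon containing the TF gene (at any position, not
#' just first) is a regulon member.
#'
#' @param reg a `regulon`.
#' @param operons the genome's full operon table.
#' @return logical.
#' @export
detect_autoregulation <- function(reg, operons) {
  holds_tf <- vapply(operons$gene_ids, function(ids) reg$tf_gene_id %in% ids,
                     logical(1))
  if (!any(holds_tf)) {
    stop("TF gene ", reg$tf_gene_id, " not found in any operon")
  }
  operons$operon_id[holds_tf][1] %in% reg$members$operon_id
}

#' Classify a regulon as global or local
#'
#' Global iff the regulon has more than 15 target genes arranged in at
#' least 7 operons and controls at least two distinct metabolic
#' pathways; otherwise local.
#'
#' @param reg a `regulon`.
#' @param pathways character vector of the regulon's distinct pathway
#'   labels (see [regulon_pathways()]); defaults to an empty set.
#' @return `"global"` or `"local"`.
#' @export
classify_regulon <- function(reg, pathways = character(0)) {
  if (reg$n_genes > 15L && reg$n_operons >= 7L &&
        length(unique(pathways)) >= 2L) "global" else "local"
}

#' Assemble a regulog from genome-specific regulons
#'
#' A regulog is the set of orthologous regulons controlled by orthologous
#' TFs.  The merged motif is rebuilt (symmetrised) from the union of all
#' member site sequences.  Genomes whose regulon has no retained member
#' are reported in `empty_genomes` and excluded from the counts.
#'
#' @param tf_group_id label of the TF ortholog group.
#' @param regulons named list (by genome) of `regulon` objects.
#' @param pseudocount,background for the merged PWM.
#' @return a `regulog`: list with `tf_group_id`, `regulons`,
#'   `merged_pwm`, `n_regulons`, `n_operons`, `n_genes`, `n_sites`,
#'   `empty_genomes`.
#' @export
assemble_regulog <- function(tf_group_id, regulons, pseudocount = 0.5,
                             background = rep(0.25, 4)) {
  if (!length(regulons)) stop("empty regulon list")
  nonempty <- vapply(regulons, function(r) r$n_operons > 0L, logical(1))
  seqs <- unlist(lapply(regulons, function(r) r$sites$sequence))
  merged <- if (length(seqs)) {
    build_pwm(seqs, pseudocount, background, symmetrize = TRUE)
  } else NULL
  structure(
    list(tf_group_id = tf_group_id,
         regulons = regulons[nonempty],
         merged_pwm = merged,
         n_regulons = sum(nonempty),
         n_operons = sum(vapply(regulons[nonempty], `[[`, integer(1),
                                "n_operons")),
         n_genes = sum(vapply(regulons[nonempty], `[[`, integer(1),
                              "n_genes")),
         n_sites = sum(vapply(regulons[nonempty],
                              function(r) nrow(r$sites), integer(1))),
         empty_genomes = names(regulons)[!nonempty]),
    class = "regulog")
}

#' @export
print.regulog <- function(x, ...) {
  cat("<regulog>", x$tf_group_id, "|", x$n_regulons, "regulons,",
      x$n_operons, "operons,", x$n_genes, "genes,", x$n_sites, "sites\n")
  invisible(x)
}

#' Attribute a candidate TF to a motif/regulon
#'
#' Among annotated TF genes, assigns the one located within
#' `max_distance` bp of a regulated operon (or inside one) in the
#' largest number of genomes; an autoregulatory site upstream of the
#' TF's own operon adds one support unit of confidence.  Ties are
#' reported and left unassigned.
#'
#' @param genomes named list of `genome` objects.
#' @param regulons named list (by genome) of candidate `regulon` objects.
#' @param operon_tables named list of operon tables.
#' @param ortholog_map data.frame `gene_id`, `group` (TF genes counted
#'   per ortholog group).
#' @param max_distance bp, default 10000.
#' @return list with `assigned` (TF group or `NA`), `support` (genome
#'   count), `report` (data.frame of all candidate TF groups and their
#'   support).
#' @export
attribute_tf_to_motif <- function(genomes, regulons, operon_tables,
                                  ortholog_map, max_distance = 10000L) {
  og <- setNames(ortholog_map$group, ortholog_map$gene_id)
  support <- list()
  for (gid in names(genomes)) {
    gen <- genomes[[gid]]
    reg <- regulons[[gid]]
    if (is.null(reg) || !nrow(reg$members)) next
    tfs <- gen$genes[gen$genes$is_tf, , drop = FALSE]
    if (!nrow(tfs)) next
    mem <- reg$members
    for (i in seq_len(nrow(tfs))) {
      near <- FALSE
      auto <- FALSE
      for (j in seq_len(nrow(mem))) {
        ids <- mem$gene_ids[[j]]
        rows <- gen$genes[gen$genes$gene_id %in% ids, , drop = FALSE]
        if (tfs$contig_id[i] != rows$contig_id[1]) next
        span_lo <- min(rows$start); span_hi <- max(rows$end)
        d <- if (tfs$end[i] > span_lo && tfs$start[i] < span_hi) 0L else
          min(abs(tfs$start[i] - span_hi), abs(span_lo - tfs$end[i]))
        if (d <= max_distance) near <- TRUE
        if (tfs$gene_id[i] %in% ids) auto <- TRUE
      }
      if (near) {
        grp <- og[tfs$gene_id[i]]
        if (is.na(grp)) grp <- tfs$gene_id[i]
        support[[grp]] <- (support[[grp]] %||% 0) + 1 + 0.5 * auto
      }
    }
  }
  if (!length(support)) {
    return(list(assigned = NA_character_, support = 0,
                report = data.frame(tf_group = character(0),
                                    support = numeric(0))))
  }
  rep_df <- data.frame(tf_group = names(support),
                       support = unlist(support, use.names = FALSE))
  rep_df <- rep_df[order(-rep_df$support, rep_df$tf_group), , drop = FALSE]
  rownames(rep_df) <- NULL
  top <- rep_df$support == rep_df$support[1]
  if (sum(top) > 1L) {
    list(assigned = NA_character_, support = rep_df$support[1],
         report = rep_df)
  } else {
    list(assigned = rep_df$tf_group[1], support = rep_df$support[1],
         report = rep_df)
  }
}
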