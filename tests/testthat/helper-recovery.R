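# shared end-to-end helper: simulate a clade, run the pipeline, score
# the reconstruction against ground truth
run_e2e <- function(config, pipeline_seed, params = pipeline_params()) {
  sim <- simulate_pangenome(config)
  res <- run_pipeline(sim$genomes, params = params, seed = pipeline_seed)
  pred_members <- do.call(rbind, lapply(res$regulons, function(r) {
    if (nrow(r$members)) {
      data.frame(genome_id = r$genome_id,
                 anchor_gene_id = r$members$first_gene_id)
    }
  }))
  if (is.null(pred_members)) {
    pred_members <- data.frame(genome_id = character(0),
                               anchor_gene_id = character(0))
  }
  ev <- evaluate_recovery(sim$truth,
                          res$sites[, c("genome_id", "center")],
                          pred_members, pwm_consensus(res$pwm))
  list(sim = sim, res = res, ev = ev, pred_members = pred_members)
}

# promoters of the truly regulated operons across a simulated clade
regulated_promoters <- function(sim) {
  tr <- sim$truth
  reg <- unique(tr$sites[tr$sites$kind == "regulon",
                         c("genome_id", "anchor_gene_id")])
  gids <- vapply(sim$genomes, function(g) g$genome_id, character(1))
  lapply(seq_len(nrow(reg)), function(i) {
    extract_promoter(sim$genomes[[match(reg$genome_id[i], gids)]],
                     reg$anchor_gene_id[i])
  })
}

# small synthetic candidate set for the consistency filter
mock_candidates <- function() {
  mk <- function(genome_id, anchors) {
    opn <- if (length(anchors)) paste0("opn_", anchors) else character(0)
    members <- data.frame(
      operon_id = opn,
      genome_id = rep(genome_id, length(anchors)),
      contig_id = rep("c1", length(anchors)),
      strand = rep("+", length(anchors)),
      first_gene_id = anchors,
      n_genes = rep(1L, length(anchors)), stringsAsFactors = FALSE)
    members$gene_ids <- lapply(anchors, identity)
    sites <- data.frame(anchor_operon_id = paste0("opn_", anchors),
                        sequence = "ACGT", stringsAsFactors = FALSE)
    regulogr:::regulon("tf", genome_id, members, sites)
  }
  # ortholog groups are encoded in the anchor ids: "<genome>_<og>"
  cands <- list(
    g1 = mk("g1", c("g1_a", "g1_b", "g1_c")),
    g2 = mk("g2", c("g2_a", "g2_b")),
    g3 = mk("g3", c("g3_a")),
    g4 = mk("g4", character(0)),
    g5 = mk("g5", c("g5_a"))
  )
  genes <- unlist(lapply(cands, function(r) r$members$first_gene_id))
  omap <- data.frame(gene_id = genes, group = sub("^g\\d+_", "OG_", genes))
  list(cands = cands, omap = omap)
}

# operon-membership precision of a filtered regulon set vs ground truth
membership_precision <- function(regulons, truth) {
  pm <- unlist(lapply(regulons, function(r) {
    if (nrow(r$members)) paste(r$genome_id, r$members$first_gene_id)
  }))
  tm <- paste(truth$regulon_members$genome_id,
              truth$regulon_members$anchor_gene_id)
  if (!length(pm)) return(NA_real_)
  mean(pm %in% tm)
}
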