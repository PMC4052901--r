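# End-to-end orchestration: orthology -> operons -> motif discovery on
# the TF's own promoters across genomes -> threshold -> scan ->
# operon re-split -> consistency filter -> refined second pass ->
# regulog assembly -> statistics.
#
# The discovery training set is the promoter of the operon carrying the
# annotated TF gene in each genome: regulators of this family are
# predominantly autoregulated, so pooling the TF's own upstream regions
# across a clade is the cross-genome analogue of starting from known
# regulated genes.  Promoters without a real site are absorbed by the
# zero-or-one-occurrence model.  A second scan pass rebuilds the PWM
# from all consistency-filtered sites and re-derives the threshold
# (minimum training score), recovering weak sites missed by the small
# initial training set.

#' Default pipeline parameters
#'
#' @return named list of stage parameters: promoter `window`, discovery
#'   `widths`/`restarts`/`q`, `pseudocount`, `background`, operon
#'   `max_gap`, filter `min_genomes`, orthology `method`/`kmer_size`,
#'   TF-group motif similarity `tau`, number of scan `passes`.
#' @export
pipeline_params <- function() {
  list(window = c(-400L, 100L), widths = seq(14L, 24L, 2L),
       restarts = 3L, q = 0.75, pseudocount = 0.5,
       background = rep(0.25, 4), max_gap = 100L, min_genomes = 2L,
       method = "kmer", kmer_size = 4L, tau = 0.8, passes = 2L,
       footprint_min_fraction = 0.5, footprint_max_mismatch = 0.25)
}

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file; keys override [pipeline_params()] defaults;
#'   a `seed` key sets the run seed.
#' @return named list of parameters.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  params <- pipeline_params()
  for (nm in names(cfg)) params[[nm]] <- cfg[[nm]]
  params
}

#' Run the regulon-reconstruction pipeline on a set of genomes
#'
#' @param genomes list of `genome` objects (one TF gene flagged per
#'   genome via `is_tf`).
#' @param params parameter list, see [pipeline_params()].
#' @param seed integer seed controlling the stochastic discovery stage.
#' @param out_dir optional directory; when given, site tables (TSV +
#'   BED6), operon tables, the motif (MEME minimal format) and a JSON
#'   run manifest are written.
#' @return list with `orthology` (gene->group table), `bbh_pairs`,
#'   `operons` (per-genome tables after re-splitting), `pwm` (final
#'   calibrated motif), `discovery` (discovery result), `regulons`
#'   (filtered per-genome `regulon`s), `candidate_regulons` (pre-filter),
#'   `regulog`, `autoregulation` (named logical by genome),
#'   `classification` (by genome), `sites` (pooled retained site table),
#'   `stats`, and `manifest`.
#' @export
run_pipeline <- function(genomes, params = pipeline_params(), seed = 1L,
                         out_dir = NULL) {
  stopifnot(length(genomes) >= 2L)
  names(genomes) <- vapply(genomes, function(g) g$genome_id, character(1))

  # ---- stage 1: orthology -------------------------------------------
  gids <- names(genomes)
  pairs <- list()
  for (i in seq_along(gids)) {
    for (j in seq_len(i - 1L)) {
      a <- genomes[[gids[i]]]$proteins
      b <- genomes[[gids[j]]]$proteins
      ab <- pairwise_similarity(a, b, method = params$method,
                                k = params$kmer_size)
      ba <- pairwise_similarity(b, a, method = params$method,
                                k = params$kmer_size)
      pairs[[length(pairs) + 1L]] <- bidirectional_best_hits(ab, ba)
    }
  }
  bbh <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_a = character(0), gene_b = character(0))
  all_genes <- unlist(lapply(genomes, function(g) g$genes$gene_id),
                      use.names = FALSE)
  ortho <- build_ortholog_groups(bbh, all_genes = all_genes)

  # ---- stage 2: layout operons --------------------------------------
  operon_tables <- lapply(genomes, predict_operons, max_gap = params$max_gap)

  # ---- stage 3: discovery on the TF's own promoters -----------------
  tf_of <- vapply(genomes, function(g) {
    ids <- g$genes$gene_id[g$genes$is_tf]
    if (length(ids)) ids[1] else NA_character_
  }, character(1))
  train_proms <- list()
  for (gid in gids) {
    if (is.na(tf_of[[gid]])) next
    tab <- operon_tables[[gid]]
    holds <- vapply(tab$gene_ids, function(ids) tf_of[[gid]] %in% ids,
                    logical(1))
    if (!any(holds)) next
    anchor <- tab$first_gene_id[holds][1]
    train_proms[[gid]] <- extract_promoter(
      genomes[[gid]], anchor, params$window,
      operon_id = tab$operon_id[holds][1])
  }
  if (length(train_proms) < 2L) {
    stop("stage discovery: fewer than 2 genomes have an annotated TF operon")
  }
  disc <- discover_palindromic_motif(
    train_proms, widths = params$widths, restarts = params$restarts,
    seed = derive_seed(seed, 1L), q = params$q,
    pseudocount = params$pseudocount, background = params$background)
  pwm <- calibrate_pwm(disc$pwm, disc$sites$sequence)

  # ---- stages 4-7: scan, re-split, consistency filter, refine -------
  scan_pass <- function(pwm, operon_tables) {
    cand <- list()
    for (gid in gids) {
      cand[[gid]] <- reconstruct_regulon(
        tf_of[[gid]], pwm, genomes[[gid]], operon_tables[[gid]],
        window = params$window)
    }
    # re-split operons on internal sites of this TF, then re-anchor
    retab <- lapply(gids, function(gid) {
      predict_operons(genomes[[gid]], internal_sites = cand[[gid]]$sites,
                      max_gap = params$max_gap)
    })
    names(retab) <- gids
    resplit <- !vapply(gids, function(gid) {
      identical(retab[[gid]]$operon_id, operon_tables[[gid]]$operon_id)
    }, logical(1))
    for (gid in gids[resplit]) {
      cand[[gid]] <- reconstruct_regulon(
        tf_of[[gid]], pwm, genomes[[gid]], retab[[gid]],
        window = params$window)
    }
    filt <- consistency_filter(cand, ortho, min_genomes = params$min_genomes)
    list(candidates = cand, filtered = filt, operon_tables = retab)
  }

  pass <- scan_pass(pwm, operon_tables)
  og <- setNames(ortho$group, ortho$gene_id)
  n_tf_genomes <- sum(!is.na(tf_of))
  for (k in seq_len(max(0L, params$passes - 1L))) {
    # phylogenetic-footprint refinement: for ortholog operon groups whose
    # promoters carry above-threshold sites in a majority of genomes, the
    # best-scoring window of every orthologous promoter is treated as a
    # predicted site and joins the training set, so the re-derived
    # threshold (minimum training score) reflects the weakest conserved
    # site rather than the happenstance minimum of the initial set
    sigs <- lapply(pass$filtered, function(r) {
      unique(unname(og[r$members$first_gene_id]))
    })
    support <- table(unlist(sigs))
    need <- max(params$min_genomes,
                ceiling(params$footprint_min_fraction * n_tf_genomes))
    strong <- names(support)[support >= need]
    seqs <- character(0)
    if (length(strong)) {
      free_pwm <- pwm
      free_pwm$threshold <- -Inf
      cons <- pwm_consensus(pwm)
      for (gid in gids) {
        tab <- pass$operon_tables[[gid]]
        hit_ops <- which(unname(og[tab$first_gene_id]) %in% strong)
        for (i in hit_ops) {
          pr <- extract_promoter(genomes[[gid]], tab$first_gene_id[i],
                                 params$window,
                                 operon_id = tab$operon_id[i])
          all_hits <- scan_region(free_pwm, pr)
          if (!nrow(all_hits)) next
          sq <- all_hits$sequence[which.max(all_hits$score)]
          # conserved-island gate: a promoter's best window joins the
          # training set only when it stays close to the consensus;
          # an arbitrary background argmax (promoter of a group member
          # that genuinely lacks a site) must not set the threshold
          if (hamming(sq, cons) / pwm$width <=
                params$footprint_max_mismatch) {
            seqs <- c(seqs, sq)
          }
        }
      }
    }
    if (length(seqs) < 2L) {
      seqs <- unlist(lapply(pass$filtered, function(r) r$sites$sequence))
    }
    if (length(seqs) < 2L) break
    pwm2 <- build_pwm(seqs, params$pseudocount, params$background,
                      symmetrize = TRUE)
    pwm2 <- calibrate_pwm(pwm2, seqs)
    pwm <- pwm2
    pass <- scan_pass(pwm, pass$operon_tables)
  }

  regs <- pass$filtered
  operon_tables <- pass$operon_tables

  # ---- stage 8: regulog, autoregulation, classification, stats ------
  tf_groups <- unique(ortho$group[match(tf_of[!is.na(tf_of)],
                                        ortho$gene_id)])
  regulog <- assemble_regulog(tf_groups[1], regs,
                              pseudocount = params$pseudocount,
                              background = params$background)
  autoreg <- vapply(gids, function(gid) {
    detect_autoregulation(regs[[gid]], operon_tables[[gid]])
  }, logical(1))
  classification <- vapply(gids, function(gid) {
    classify_regulon(regs[[gid]],
                     regulon_pathways(regs[[gid]], genomes[[gid]]))
  }, character(1))

  sites <- do.call(rbind, c(lapply(unname(regs), function(r) r$sites),
                            list(make.row.names = FALSE)))
  stats <- list(
    positions = site_position_histogram(sites),
    spacing = intersite_distances(sites),
    census = regulon_census(list(regulog), autoregulated = autoreg,
                            classifications = classification))

  manifest <- list(
    seed = seed,
    params = lapply(params, function(x) x),
    n_genomes = length(genomes),
    motif_width = pwm$width,
    consensus = pwm_consensus(pwm),
    threshold = pwm$threshold,
    n_sites = nrow(sites),
    n_member_operons = sum(vapply(regs, `[[`, integer(1), "n_operons")))

  res <- list(orthology = ortho, bbh_pairs = bbh, operons = operon_tables,
              pwm = pwm, discovery = disc, regulons = regs,
              candidate_regulons = pass$candidates, regulog = regulog,
              autoregulation = autoreg, classification = classification,
              sites = sites, stats = stats, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# deterministic text outputs for a pipeline run
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sites <- res$sites
  num <- vapply(sites, is.numeric, logical(1)) &
    !vapply(sites, is.integer, logical(1))
  sites[num] <- lapply(sites[num], function(x) sprintf("%.6f", x))
  write.table(sites, file.path(out_dir, "sites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_sites_bed(res$sites, file.path(out_dir, "sites.bed"))
  for (gid in names(res$operons)) {
    write_operons_tsv(res$operons[[gid]],
                      file.path(out_dir, paste0("operons_", gid, ".tsv")))
  }
  write_meme(list(regulog_motif = res$pwm),
             file.path(out_dir, "motif.meme"))
  write.table(res$orthology, file.path(out_dir, "orthology.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, null = "null",
                       pretty = TRUE)
  invisible(out_dir)
}
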