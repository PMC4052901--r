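# fixture: a genome whose operons carry planted sites for a known PWM
planted_genome <- function(seed = 60, divergon = FALSE) {
  withr::with_seed(seed, {
    cons <- generate_palindromic_consensus(16, seed = seed)
    contig <- rand_dna(6000)
    if (divergon) {
      # two divergently transcribed genes sharing one intergenic region:
      # gA on minus strand ending at 2000, gB on plus strand from 2300
      genes <- data.frame(
        gene_id = c("gA", "gB"), contig_id = "c1",
        start = c(1400L, 2300L), end = c(2000L, 2900L),
        strand = c("-", "+"), stringsAsFactors = FALSE)
      # one site in the middle of the shared region: inside both windows
      substr(contig, 2141, 2156) <- cons
    } else {
      genes <- data.frame(
        gene_id = c("gA", "gB", "gC", "gD"), contig_id = "c1",
        start = c(1000L, 2500L, 4000L, 5400L),
        end = c(1600L, 3100L, 4600L, 5900L),
        strand = "+", stringsAsFactors = FALSE)
      substr(contig, 900, 915) <- cons    # upstream of gA
      substr(contig, 2400, 2415) <- cons  # upstream of gB
    }
    genes$is_tf <- genes$gene_id == "gA"
    g <- new_genome("t", c(c1 = contig), genes)
    pwm <- calibrate_pwm(build_pwm(rep(cons, 3)), cons)
    list(genome = g, pwm = pwm, cons = cons)
  })
}

test_that("operons with above-threshold promoter sites become members", {
  fx <- planted_genome()
  ops <- predict_operons(fx$genome)
  reg <- reconstruct_regulon("gA", fx$pwm, fx$genome, ops)
  anchors <- sort(unique(reg$sites$anchor_gene_id))
  expect_setequal(anchors, c("gA", "gB"))
  expect_equal(reg$n_operons, 2)
  expect_equal(reg$n_genes, 2)
})

test_that("a regulon with no hits is empty but valid", {
  fx <- planted_genome()
  hi <- fx$pwm
  hi$threshold <- 1e6
  reg <- reconstruct_regulon("gA", hi, fx$genome, predict_operons(fx$genome))
  expect_equal(reg$n_operons, 0)
  expect_equal(nrow(reg$sites), 0)
})

test_that("a divergon site is attributed to both operons", {
  fx <- planted_genome(divergon = TRUE)
  ops <- predict_operons(fx$genome)
  expect_equal(nrow(ops), 2)
  reg <- reconstruct_regulon("gA", fx$pwm, fx$genome, ops)
  expect_equal(reg$n_operons, 2)
  # the same genomic site appears once per anchored operon
  expect_equal(nrow(reg$sites), 2)
  expect_equal(length(unique(reg$sites$start)), 1)
  expect_equal(length(unique(reg$sites$anchor_operon_id)), 2)
})

test_that("the consistency filter keeps operons supported across genomes", {
  fx <- mock_candidates()
  filt <- consistency_filter(fx$cands, fx$omap, min_genomes = 2)
  # OG_a regulated in 4 genomes -> retained everywhere it occurs
  expect_true("g1_a" %in% filt$g1$members$first_gene_id)
  expect_true("g3_a" %in% filt$g3$members$first_gene_id)
  # OG_b in 2 genomes -> retained; OG_c in 1 genome -> dropped
  expect_true("g2_b" %in% filt$g2$members$first_gene_id)
  expect_false("g1_c" %in% filt$g1$members$first_gene_id)
  # sites of removed operons are dropped too
  expect_false("opn_g1_c" %in% filt$g1$sites$anchor_operon_id)
})

test_that("min_genomes = 1 is the identity filter", {
  fx <- mock_candidates()
  filt <- consistency_filter(fx$cands, fx$omap, min_genomes = 1)
  for (gid in names(fx$cands)) {
    expect_equal(filt[[gid]]$members$first_gene_id,
                 fx$cands[[gid]]$members$first_gene_id)
  }
})

test_that("raising min_genomes never adds members", {
  fx <- mock_candidates()
  prev <- NULL
  for (mg in 1:5) {
    filt <- consistency_filter(fx$cands, fx$omap, min_genomes = mg)
    tot <- unlist(lapply(filt, function(r) {
      if (nrow(r$members)) paste(r$genome_id, r$members$first_gene_id)
    }))
    if (!is.null(prev)) expect_true(all(tot %in% prev))
    prev <- tot
  }
})

test_that("autoregulation is an operon-level membership call", {
  fx <- planted_genome()
  ops <- predict_operons(fx$genome)
  reg <- reconstruct_regulon("gA", fx$pwm, fx$genome, ops)
  expect_true(detect_autoregulation(reg, ops))       # site upstream of gA
  # TF inside a member operon, not first gene
  reg2 <- reg
  reg2$tf_gene_id <- "gB"
  expect_true(detect_autoregulation(reg2, ops))
  # TF in a non-member operon
  reg3 <- reg
  reg3$tf_gene_id <- "gC"
  expect_false(detect_autoregulation(reg3, ops))
  reg4 <- reg
  reg4$tf_gene_id <- "missing"
  expect_error(detect_autoregulation(reg4, ops), "missing")
})

test_that("global/local classification applies the exact boundaries", {
  mk <- function(n_genes, n_operons) {
    structure(list(tf_gene_id = "t", genome_id = "g",
                   members = NULL, sites = NULL,
                   n_operons = n_operons, n_genes = n_genes),
              class = "regulon")
  }
  two <- c("glycolysis", "gluconeogenesis")
  expect_equal(classify_regulon(mk(16, 7), two), "global")
  expect_equal(classify_regulon(mk(15, 7), two), "local")  # "more than 15"
  expect_equal(classify_regulon(mk(20, 6), two), "local")  # "at least 7"
  expect_equal(classify_regulon(mk(20, 8), "glycolysis"), "local")
  expect_equal(classify_regulon(mk(20, 8), two), "global")
})

test_that("regulog totals are conserved sums over member regulons", {
  fx <- mock_candidates()
  rg <- assemble_regulog("OGTF", fx$cands)
  nonempty <- Filter(function(r) r$n_operons > 0, fx$cands)
  expect_equal(rg$n_regulons, length(nonempty))
  expect_equal(rg$n_operons, sum(vapply(nonempty, `[[`, integer(1),
                                        "n_operons")))
  expect_equal(rg$n_genes, sum(vapply(nonempty, `[[`, integer(1),
                                      "n_genes")))
  expect_equal(rg$empty_genomes, "g4")
  expect_error(assemble_regulog("x", list()), "empty")
})

test_that("the merged regulog motif recovers the planted consensus", {
  withr::with_seed(61, {
    cons <- generate_palindromic_consensus(16, seed = 8)
    mk <- function(gid, n) {
      seqs <- vapply(seq_len(n), function(i) {
        v <- strsplit(cons, "")[[1]]
        j <- sample(16, 1)
        v[j] <- sample(c("A", "C", "G", "T"), 1)
        paste(v, collapse = "")
      }, character(1))
      members <- data.frame(operon_id = paste0("o", seq_len(n)),
                            genome_id = gid, contig_id = "c1", strand = "+",
                            first_gene_id = paste0(gid, "_a", seq_len(n)),
                            n_genes = 1L)
      members$gene_ids <- as.list(members$first_gene_id)
      sites <- data.frame(anchor_operon_id = members$operon_id,
                          sequence = seqs)
      regulogr:::regulon("tf", gid, members, sites)
    }
    regs <- list(g1 = mk("g1", 6), g2 = mk("g2", 6), g3 = mk("g3", 6))
    rg <- assemble_regulog("OGTF", regs)
    expect_lte(consensus_distance(pwm_consensus(rg$merged_pwm), cons), 1)
    expect_true(rg$merged_pwm$palindromic)
  })
})

test_that("TF attribution requires colocation support and unique winners", {
  fx <- planted_genome()
  ops <- predict_operons(fx$genome)
  reg <- reconstruct_regulon("gA", fx$pwm, fx$genome, ops)
  genomes <- list(t = fx$genome)
  omap <- data.frame(gene_id = fx$genome$genes$gene_id,
                     group = paste0("OG_", fx$genome$genes$gene_id))
  res <- attribute_tf_to_motif(genomes, list(t = reg), list(t = ops), omap)
  expect_equal(res$assigned, "OG_gA")
  expect_gte(res$support, 1)
  # two equally placed TFs: tie -> unassigned, both reported
  g2 <- fx$genome
  g2$genes$is_tf <- g2$genes$gene_id %in% c("gC", "gD")
  res2 <- attribute_tf_to_motif(list(t = g2), list(t = reg), list(t = ops),
                                data.frame(gene_id = g2$genes$gene_id,
                                           group = paste0("OG_", g2$genes$gene_id)))
  expect_true(is.na(res2$assigned))
  expect_equal(nrow(res2$report), 2)
  # TF out of range in every genome
  res3 <- attribute_tf_to_motif(list(t = g2), list(t = reg), list(t = ops),
                                omap, max_distance = 0L)
  expect_true(is.na(res3$assigned) || res3$support == 0)
})
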