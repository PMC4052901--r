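test_that("identical single-protein proteomes are mutual best hits", {
  a <- c(x1 = "MKVLAADNQWERTYMKVL")
  b <- c(y1 = "MKVLAADNQWERTYMKVL")
  tab <- pairwise_similarity(a, b, method = "kmer")
  expect_equal(tab$score, 1)
  bbh <- bidirectional_best_hits(tab, pairwise_similarity(b, a))
  expect_equal(bbh$gene_a, "x1")
  expect_equal(bbh$gene_b, "y1")
})

test_that("self-comparisons are excluded for identical proteomes", {
  a <- c(p1 = "MKVLAADNQW", p2 = "GHIKLMNPQR")
  tab <- pairwise_similarity(a, a, method = "kmer")
  expect_false(any(tab$query == tab$subject))
})

test_that("empty proteomes and empty sequences are rejected by name", {
  expect_error(pairwise_similarity(character(0), c(a = "MKV")), "empty")
  expect_error(pairwise_similarity(c(bad = ""), c(a = "MKVL")), "bad")
})

test_that("alignment scores match an independent Gotoh oracle", {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  blosum <- get("BLOSUM62", envir = data_env)
  withr::with_seed(40, {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    a <- setNames(replicate(3, paste(sample(aa, sample(8:20, 1),
                                            replace = TRUE), collapse = "")),
                  paste0("a", 1:3))
    b <- setNames(replicate(3, paste(sample(aa, sample(8:20, 1),
                                            replace = TRUE), collapse = "")),
                  paste0("b", 1:3))
    tab <- pairwise_similarity(a, b, method = "alignment")
    for (i in seq_len(nrow(tab))) {
      expect_equal(tab$score[i],
                   oracle_sw(a[[tab$query[i]]], b[[tab$subject[i]]], blosum),
                   tolerance = 1e-8)
    }
  })
})

test_that("a protein outscores its own shuffle in self-comparison", {
  withr::with_seed(41, {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    p <- paste(sample(aa, 40, replace = TRUE), collapse = "")
    shuf <- paste(sample(strsplit(p, "")[[1]]), collapse = "")
    tab <- pairwise_similarity(c(p = p), c(p = p, s = shuf),
                               method = "alignment")
    expect_gt(tab$score[tab$subject == "p"], tab$score[tab$subject == "s"])
  })
})

test_that("BBH follows the best-hit contract on a 2x2 table", {
  ab <- data.frame(query = c("x1", "x1", "x2", "x2"),
                   subject = c("y1", "y2", "y1", "y2"),
                   score = c(10, 3, 2, 9))
  ba <- data.frame(query = c("y1", "y1", "y2", "y2"),
                   subject = c("x1", "x2", "x1", "x2"),
                   score = c(10, 2, 3, 9))
  bbh <- bidirectional_best_hits(ab, ba)
  expect_setequal(paste(bbh$gene_a, bbh$gene_b),
                  c("x1 y1", "x2 y2"))
  expect_false(any(bbh$tie_broken))
})

test_that("one-sided best hits are not paired", {
  ab <- data.frame(query = "x1", subject = "y1", score = 5)
  ba <- data.frame(query = "y1", subject = c("x1", "x2"), score = c(5, 8))
  bbh <- bidirectional_best_hits(ab, ba)
  expect_equal(nrow(bbh), 0)
})

test_that("score ties are broken lexicographically and flagged", {
  ab <- data.frame(query = c("x1", "x1"), subject = c("y2", "y1"),
                   score = c(7, 7))
  ba <- data.frame(query = c("y1", "y2"), subject = c("x1", "x1"),
                   score = c(7, 7))
  bbh <- bidirectional_best_hits(ab, ba)
  expect_equal(bbh$gene_b, "y1")
  expect_true(bbh$tie_broken)
})

test_that("BBH equals an exhaustive double loop on random tables", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      na <- sample(2:10, 1); nb <- sample(2:10, 1)
      qa <- paste0("a", seq_len(na)); qb <- paste0("b", seq_len(nb))
      ab <- expand.grid(query = qa, subject = qb,
                        stringsAsFactors = FALSE)
      ab$score <- sample(1:50, nrow(ab), replace = TRUE)
      ba <- expand.grid(query = qb, subject = qa,
                        stringsAsFactors = FALSE)
      ba$score <- sample(1:50, nrow(ba), replace = TRUE)
      got <- bidirectional_best_hits(ab, ba)
      want <- oracle_bbh(ab, ba)
      expect_setequal(paste(got$gene_a, got$gene_b),
                      paste(want$gene_a, want$gene_b))
    }
  })
})

test_that("ortholog groups are the BBH connected components", {
  pairs <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"))
  groups <- build_ortholog_groups(pairs)
  expect_equal(length(unique(groups$group)), 1)
  # no pairs: singletons
  g0 <- build_ortholog_groups(data.frame(gene_a = character(0),
                                         gene_b = character(0)),
                              all_genes = c("u", "v", "w"))
  expect_equal(length(unique(g0$group)), 3)
  # two disjoint cliques
  cl <- data.frame(gene_a = c("a", "a", "b", "x", "x", "y"),
                   gene_b = c("b", "c", "c", "y", "z", "z"))
  g2 <- build_ortholog_groups(cl)
  expect_equal(length(unique(g2$group)), 2)
})

test_that("groups match brute-force components and partition the gene set", {
  withr::with_seed(43, {
    for (rep in 1:10) {
      verts <- paste0("g", 1:12)
      ne <- sample(0:14, 1)
      edges <- data.frame(gene_a = sample(verts, ne, replace = TRUE),
                          gene_b = sample(verts, ne, replace = TRUE))
      edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
      got <- build_ortholog_groups(edges, all_genes = verts)
      expect_setequal(got$gene_id, verts)
      expect_false(any(duplicated(got$gene_id)))
      want <- oracle_components(as.matrix(edges), verts)
      # same partition: same co-membership relation
      for (i in seq_along(verts)) {
        for (j in seq_len(i - 1)) {
          same_got <- got$group[got$gene_id == verts[i]] ==
            got$group[got$gene_id == verts[j]]
          same_want <- want[[verts[i]]] == want[[verts[j]]]
          expect_equal(same_got, same_want)
        }
      }
    }
  })
})

test_that("TF groups split by motif similarity under single linkage", {
  withr::with_seed(44, {
    base_sites <- replicate(20, rand_dna(16))
    perturb <- function(sites, n) {
      for (k in seq_len(n)) {
        i <- sample(length(sites), 1)
        s <- strsplit(sites[i], "")[[1]]
        j <- sample(16, 1)
        s[j] <- sample(c("A", "C", "G", "T"), 1)
        sites[i] <- paste(s, collapse = "")
      }
      sites
    }
    pA <- build_pwm(base_sites)
    pB <- build_pwm(perturb(base_sites, 4))    # very similar to A
    pC <- build_pwm(replicate(20, rand_dna(16)))  # unrelated
    groups <- data.frame(gene_id = c("t1", "t2", "t3"), group = "OG0001")
    # similar pair stays together; unrelated TF splits off
    res <- form_tf_groups(groups, list(t1 = pA, t2 = pB, t3 = pC), tau = 0.8)
    expect_equal(res$tf_group[res$gene_id == "t1"],
                 res$tf_group[res$gene_id == "t2"])
    expect_false(res$tf_group[res$gene_id == "t3"] ==
                   res$tf_group[res$gene_id == "t1"])
    # single linkage: A-B and B-C similar implies one group even if A-C
    # is weaker
    pB2 <- build_pwm(perturb(base_sites, 6))
    pC2 <- build_pwm(perturb(base_sites, 12))
    sims <- c(motif_similarity(pA, pB2), motif_similarity(pB2, pC2),
              motif_similarity(pA, pC2))
    res2 <- form_tf_groups(groups, list(t1 = pA, t2 = pB2, t3 = pC2),
                           tau = min(sims[1:2]) - 0.01)
    expect_equal(length(unique(res2$tf_group)), 1)
  })
})

test_that("TF-group splitting never merges different BBH components", {
  p <- build_pwm(replicate(5, rand_dna(16)))
  groups <- data.frame(gene_id = c("t1", "t2"), group = c("OG1", "OG2"))
  res <- form_tf_groups(groups, list(t1 = p, t2 = p), tau = 0.5)
  expect_false(res$tf_group[1] == res$tf_group[2])
})

test_that("TFs without motifs stay with their BBH group, flagged", {
  p <- build_pwm(replicate(5, rand_dna(16)))
  groups <- data.frame(gene_id = c("t1", "t2", "t3"), group = "OG1")
  res <- form_tf_groups(groups, list(t1 = p, t2 = p), tau = 0.5)
  expect_true(res$no_motif[res$gene_id == "t3"])
  expect_equal(res$tf_group[res$gene_id == "t3"],
               res$tf_group[res$gene_id == "t1"])
})
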