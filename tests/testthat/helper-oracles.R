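# Independent brute-force oracles used to cross-check the package's
# implementations.  These deliberately share no code with the package
# internals.

# Smith-Waterman local alignment with affine gaps (Gotoh), gap of
# length L costing open + L * ext.  Returns the best local score.
oracle_sw <- function(a, b, submat, open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(0,
                             M[i, j] + s, X[i, j] + s, Y[i, j] + s)
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# exhaustive bidirectional best hits by double loop; lexicographic
# tie-break on subject
oracle_bbh <- function(ab, ba) {
  best_of <- function(tab, q) {
    d <- tab[tab$query == q, , drop = FALSE]
    mx <- max(d$score)
    sort(d$subject[d$score == mx])[1]
  }
  out <- list()
  for (q in unique(ab$query)) {
    s <- best_of(ab, q)
    if (best_of(ba, s) == q) out[[length(out) + 1L]] <- c(q, s)
  }
  if (!length(out)) {
    return(data.frame(gene_a = character(0), gene_b = character(0)))
  }
  m <- do.call(rbind, out)
  data.frame(gene_a = m[, 1], gene_b = m[, 2], stringsAsFactors = FALSE)
}

# connected components by breadth-first search over an edge list
oracle_components <- function(edges, vertices) {
  adj <- lapply(setNames(vector("list", length(vertices)), vertices), identity)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- setNames(rep(FALSE, length(vertices)), vertices)
  comp <- setNames(integer(length(vertices)), vertices)
  k <- 0L
  for (v in vertices) {
    if (seen[[v]]) next
    k <- k + 1L
    queue <- v
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      if (seen[[x]]) next
      seen[[x]] <- TRUE
      comp[[x]] <- k
      queue <- c(queue, adj[[x]])
    }
  }
  comp
}

# rescore every window of a region independently with score_site
oracle_scan <- function(pwm, region) {
  seq <- region$sequence
  w <- pwm$width
  n <- nchar(seq) - w + 1
  if (n < 1) return(integer(0))
  hits <- integer(0)
  for (p in seq_len(n)) {
    s <- tryCatch(score_site(pwm, substr(seq, p, p + w - 1)),
                  error = function(e) NA_real_)
    if (!is.na(s) && s >= pwm$threshold) hits <- c(hits, p - 1L)
  }
  hits
}

# random DNA helper for fixtures
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# small genome fixture: three genes on one contig, one on the minus strand
toy_genome <- function(seed = 1) {
  withr::with_seed(seed, {
    contig <- rand_dna(3000)
    genes <- data.frame(
      gene_id = c("gA", "gB", "gC"),
      contig_id = "c1",
      start = c(500L, 1200L, 2000L),
      end = c(1100L, 1800L, 2600L),
      strand = c("+", "+", "-"),
      locus_tag = c("tA", "tB", "tC"),
      function_label = c("glycolysis", "", "transcriptional_regulator"),
      is_tf = c(FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE
    )
    prot <- c(gA = "MKVLAADNQWERTY", gB = "MHHGILKNNPQRST", gC = "MAACDEFGHIKLMN")
    new_genome("toy", c(c1 = contig), genes, prot)
  })
}
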