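test_that("PWM frequencies and log-odds follow the stated formula", {
  # two identical sites, pseudocount 1, uniform background:
  # freq(A) = (2+1)/(2+4) = 0.5 per column -> log-odds 1 bit
  p <- build_pwm(c("AA", "AA"), pseudocount = 1, symmetrize = FALSE)
  expect_equal(unname(p$freq["A", ]), c(0.5, 0.5))
  expect_equal(unname(p$log_odds["A", ]), c(1, 1))
  # frequencies equal to background -> all log-odds zero
  p0 <- build_pwm(c("AC", "CA", "GT", "TG"), pseudocount = 0.5,
                  symmetrize = FALSE)
  expect_true(all(abs(p0$log_odds) < 1e-12))
})

test_that("build_pwm rejects empty, unequal-length, and ambiguous sites", {
  expect_error(build_pwm(character(0)), "empty")
  expect_error(build_pwm(c("ACGT", "ACG")), "unequal")
  expect_error(build_pwm(c("ACNT")), "non-ACGT")
})

test_that("symmetrised PWMs satisfy the palindromic invariant exactly", {
  withr::with_seed(20, {
    for (i in 1:10) {
      sites <- replicate(5, rand_dna(12))
      p <- build_pwm(sites, symmetrize = TRUE)
      w <- p$width
      for (j in seq_len(w)) {
        expect_equal(unname(p$log_odds[, j]),
                     unname(rev(p$log_odds[, w + 1 - j])),
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("score_site sums per-position log-odds and handles edge cases", {
  p0 <- build_pwm(c("AC", "CA", "GT", "TG"), symmetrize = FALSE)
  expect_equal(score_site(p0, "GG"), 0)
  expect_error(score_site(p0, "GGG"), "width")
  expect_true(is.na(score_site(p0, "NN")))
})

test_that("the consensus is the argmax over all sequences of the motif width", {
  # one-hot-trained PWM: exhaustively score all 4^4 sequences
  p <- build_pwm("ACGT", pseudocount = 0.5, symmetrize = FALSE)
  all4 <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 4)), 1,
                paste, collapse = "")
  scores <- vapply(all4, function(s) score_site(p, s), numeric(1))
  expect_equal(names(which.max(scores)), "ACGT")
  expect_equal(max(scores), sum(apply(p$log_odds, 2, max)))
})

test_that("palindromic PWMs score both strands identically", {
  withr::with_seed(21, {
    p <- build_pwm(replicate(8, rand_dna(14)), symmetrize = TRUE)
    for (i in 1:1000) {
      s <- rand_dna(14)
      expect_equal(score_site(p, s), score_site(p, revcomp(s)),
                   tolerance = 1e-9)
    }
  })
})

test_that("the threshold is the lowest training-site score", {
  withr::with_seed(22, {
    p <- build_pwm(replicate(6, rand_dna(10)))
    train <- replicate(5, rand_dna(10))
    scores <- vapply(train, function(s) score_site(p, s), numeric(1))
    expect_equal(training_threshold(p, train), min(scores))
    expect_equal(training_threshold(p, train[1]), scores[[1]])
    expect_error(training_threshold(p, character(0)), "empty")
  })
})

test_that("training sites are always recovered at their own threshold", {
  withr::with_seed(23, {
    cons <- generate_palindromic_consensus(16, seed = 5)
    train <- character(0)
    proms <- list()
    for (i in 1:8) {
      site <- cons
      v <- strsplit(site, "")[[1]]
      pos <- sample(16, 2)
      v[pos] <- vapply(v[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      site <- paste(v, collapse = "")
      train <- c(train, site)
      bg <- rand_dna(300)
      at <- sample(50:250, 1)
      substr(bg, at, at + 15) <- site
      proms[[i]] <- structure(
        list(anchor_gene_id = paste0("g", i), anchor_operon_id = NA,
             contig_id = "c1", start = 0L, end = 300L, strand = "+",
             sequence = bg, offset_of_start_codon = 250L),
        class = "promoter_region")
    }
    pwm <- calibrate_pwm(build_pwm(train), train)
    recovered <- lapply(proms, function(pr) scan_region(pwm, pr))
    for (i in seq_along(proms)) {
      expect_true(train[i] %in% recovered[[i]]$sequence)
    }
  })
})

test_that("scanning equals brute-force window rescoring on random regions", {
  withr::with_seed(24, {
    pwm <- build_pwm(replicate(6, rand_dna(12)))
    for (i in 1:100) {
      pwm$threshold <- runif(1, -10, 10)
      region <- structure(
        list(anchor_gene_id = "g", anchor_operon_id = NA,
             contig_id = "c1", start = 0L, end = 120L, strand = "+",
             sequence = rand_dna(120), offset_of_start_codon = 100L),
        class = "promoter_region")
      hits <- scan_region(pwm, region)
      expect_identical(hits$position, oracle_scan(pwm, region))
    }
  })
})

test_that("a permissive threshold reports every window exactly once", {
  withr::with_seed(25, {
    pwm <- build_pwm(replicate(4, rand_dna(10)))
    pwm$threshold <- -Inf
    region <- structure(
      list(anchor_gene_id = "g", anchor_operon_id = NA, contig_id = "c1",
           start = 0L, end = 80L, strand = "+", sequence = rand_dna(80),
           offset_of_start_codon = 40L),
      class = "promoter_region")
    hits <- scan_region(pwm, region)
    expect_equal(nrow(hits), 80 - 10 + 1)
    expect_false(any(duplicated(hits$position)))
    expect_error(scan_region(build_pwm("ACGTACGTAC"), region), "threshold")
  })
})

test_that("raising the threshold never adds scan hits", {
  withr::with_seed(26, {
    pwm <- build_pwm(replicate(5, rand_dna(12)))
    region <- structure(
      list(anchor_gene_id = "g", anchor_operon_id = NA, contig_id = "c1",
           start = 0L, end = 300L, strand = "+", sequence = rand_dna(300),
           offset_of_start_codon = 250L),
      class = "promoter_region")
    thr <- sort(runif(100, -20, 20))
    prev <- NULL
    for (t in thr) {
      pwm$threshold <- t
      hits <- scan_region(pwm, region)$position
      if (!is.null(prev)) expect_true(all(hits %in% prev))
      prev <- hits
    }
  })
})

test_that("windows containing N are skipped, not scored", {
  pwm <- build_pwm(replicate(3, rand_dna(8)))
  pwm$threshold <- -Inf
  seqn <- paste0(rand_dna(20), "N", rand_dna(20))
  region <- structure(
    list(anchor_gene_id = "g", anchor_operon_id = NA, contig_id = "c1",
         start = 0L, end = 41L, strand = "+", sequence = seqn,
         offset_of_start_codon = 20L),
    class = "promoter_region")
  hits <- scan_region(pwm, region)
  # windows overlapping position 20 (0-based) must be absent
  expect_false(any(hits$position > 20 - 8 & hits$position <= 20))
})

test_that("discovery recovers a planted palindrome and its width", {
  withr::with_seed(30, {
    cons <- generate_palindromic_consensus(18, seed = 9)
    proms <- character(10)
    for (i in 1:10) {
      bg <- rand_dna(400)
      at <- sample(30:370, 1)
      substr(bg, at, at + 17) <- cons
      proms[i] <- bg
    }
    d <- discover_palindromic_motif(proms, seed = 4, restarts = 2)
    expect_equal(d$width, 18)
    expect_lte(consensus_distance(d$consensus, cons), 1)
    expect_false(d$low_confidence)
    # determinism
    d2 <- discover_palindromic_motif(proms, seed = 4, restarts = 2)
    expect_identical(d$consensus, d2$consensus)
    expect_equal(d$pwm$log_odds, d2$pwm$log_odds)
  })
})

test_that("discovery on pure background is flagged low-confidence", {
  withr::with_seed(31, {
    proms <- replicate(8, rand_dna(300))
    d <- discover_palindromic_motif(proms, seed = 2, restarts = 2)
    expect_true(d$low_confidence)
  })
})

test_that("discovery rejects undersized promoter sets", {
  expect_error(discover_palindromic_motif(list("ACGTACGTACGTACGT")), "2 promoters")
  expect_error(
    discover_palindromic_motif(c("ACGTACGTAC", rand_dna(300)),
                               widths = c(14, 16)),
    "shorter")
})

test_that("motif similarity is 1 for identical and reverse-complement motifs", {
  withr::with_seed(32, {
    p <- build_pwm(replicate(6, rand_dna(16)), symmetrize = FALSE)
    expect_equal(motif_similarity(p, p), 1, tolerance = 1e-9)
    prc <- p
    prc$freq <- p$freq[c(4:1), rev(seq_len(16))]
    dimnames(prc$freq) <- dimnames(p$freq)
    expect_equal(motif_similarity(p, prc), 1, tolerance = 1e-9)
    # symmetry of the measure
    q <- build_pwm(replicate(6, rand_dna(16)), symmetrize = FALSE)
    expect_equal(motif_similarity(p, q), motif_similarity(q, p))
  })
})

test_that("independent random motifs have similarity near zero on average", {
  withr::with_seed(33, {
    sims <- replicate(300, {
      a <- build_pwm(replicate(4, rand_dna(20)), symmetrize = FALSE)
      b <- build_pwm(replicate(4, rand_dna(20)), symmetrize = FALSE)
      motif_similarity(a, b)
    })
    expect_lt(abs(mean(sims)), 0.1)
  })
})

test_that("width-incomparable motifs return 0 with a flag", {
  a <- build_pwm(replicate(3, rand_dna(14)))
  b <- build_pwm(replicate(3, rand_dna(20)))
  s <- motif_similarity(a, b)
  expect_equal(as.numeric(s), 0)
  expect_true(attr(s, "incomparable"))
})

test_that("MEME minimal format round-trips frequencies and width", {
  withr::with_seed(34, {
    p <- build_pwm(replicate(7, rand_dna(16)))
    path <- withr::local_tempfile(fileext = ".meme")
    write_meme(list(m1 = p), path)
    back <- read_meme(path)
    expect_named(back, "m1")
    expect_equal(back$m1$width, 16)
    expect_equal(unname(back$m1$freq), unname(p$freq), tolerance = 1e-5)
    expect_true(back$m1$palindromic)
  })
})

test_that("logo data carries per-column frequencies and information", {
  p <- build_pwm(c("ACGT", "ACGT", "ACGT"), symmetrize = FALSE)
  ld <- logo_data(p)
  expect_equal(nrow(ld), 16)
  expect_equal(sum(ld$freq[ld$position == 1]), 1)
  agg <- unique(ld[, c("position", "ic")])
  expect_equal(sum(agg$ic), information_content(p))
})
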