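# Position weight matrices for palindromic binding motifs.
#
# PWMs are log-odds matrices in bits against an explicit background.  The
# score scale is self-calibrating: scan thresholds are always derived from
# training sites (minimum training score), never from an absolute cutoff.

# reverse complement of a 4 x w count/frequency matrix:
# reverse the columns and swap A<->T, C<->G rows
revcomp_matrix <- function(m) {
  m[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(m))), drop = FALSE]
}

new_pwm <- function(counts, pseudocount, background, palindromic,
                    threshold = NULL) {
  n <- sum(counts[, 1])
  freq <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount, "/")
  log_odds <- log2(freq / background)
  structure(
    list(width = ncol(counts), counts = counts, freq = freq,
         log_odds = log_odds, background = background,
         pseudocount = pseudocount, palindromic = palindromic,
         n_sites = n, threshold = threshold),
    class = "pwm"
  )
}

#' Build a position weight matrix from aligned sites
#'
#' Counts are optionally symmetrised as `(C + revcomp(C)) / 2`, which
#' enforces the palindromic invariant
#' `log_odds[i, b] == log_odds[w - 1 - i, complement(b)]` exactly.
#' Frequencies are `(count + pseudocount) / (n + 4 * pseudocount)` and
#' log-odds are `log2(freq / background)` in bits.
#'
#' @param sites character vector of equal-length A/C/G/T sequences.
#' @param pseudocount added per base per column; default 0.5.
#' @param background base frequencies (A,C,G,T) summing to 1; default
#'   uniform.
#' @param symmetrize enforce palindromic symmetry (default `TRUE`).
#' @return a `pwm` object (threshold unset).
#' @export
build_pwm <- function(sites, pseudocount = 0.5,
                      background = rep(0.25, 4), symmetrize = TRUE) {
  if (length(sites) < 1L) stop("empty site list")
  w <- nchar(sites[1])
  if (any(nchar(sites) != w)) {
    stop("sites of unequal length: ", sites[which(nchar(sites) != w)[1]])
  }
  if (any(grepl("[^ACGT]", sites))) {
    stop("site contains non-ACGT characters: ",
         sites[grep("[^ACGT]", sites)[1]])
  }
  stopifnot(length(background) == 4, all(background > 0),
            abs(sum(background) - 1) < 1e-6, pseudocount > 0)
  mat <- matrix(0, 4, w, dimnames = list(DNA_BASES, NULL))
  chars <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  for (j in seq_len(w)) {
    tb <- table(factor(chars[, j], levels = DNA_BASES))
    mat[, j] <- as.numeric(tb)
  }
  if (symmetrize) mat <- (mat + revcomp_matrix(mat)) / 2
  new_pwm(mat, pseudocount, background, palindromic = symmetrize)
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> width", x$width, "| n_sites", x$n_sites,
      "| palindromic:", x$palindromic,
      "| IC", round(information_content(x), 2), "bits",
      if (!is.null(x$threshold)) paste("| threshold", round(x$threshold, 2)),
      "\n  consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param pwm a `pwm` object.
#' @return character consensus (per-column argmax base).
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$freq, 2, which.max)], collapse = "")
}

#' Total information content of a PWM (bits)
#' @param pwm a `pwm` object.
#' @return total bits over all columns relative to the PWM background.
#' @export
information_content <- function(pwm) {
  sum(pwm$freq * log2(pwm$freq / pwm$background))
}

#' Score one site under a PWM
#'
#' Sum of per-position log-odds in bits.  Returns `NA` for sequences
#' containing non-ACGT characters (such windows are skipped by scanners).
#'
#' @param pwm a `pwm` object.
#' @param seq sequence of length `pwm$width`.
#' @return numeric score in bits (or `NA`).
#' @export
score_site <- function(pwm, seq) {
  if (nchar(seq) != pwm$width) {
    stop("sequence length ", nchar(seq), " != PWM width ", pwm$width)
  }
  idx <- seq_to_int(seq)
  if (anyNA(idx)) return(NA_real_)
  sum(pwm$log_odds[cbind(idx, seq_len(pwm$width))])
}

#' Training-set threshold of a PWM
#'
#' The threshold is the lowest score observed in the training set of
#' sites, so every training site is recovered when its own promoters are
#' rescanned.
#'
#' @param pwm a `pwm` object.
#' @param training_sites character vector of training site sequences.
#' @return numeric threshold in bits.
#' @export
training_threshold <- function(pwm, training_sites) {
  if (length(training_sites) < 1L) stop("empty training set")
  min(vapply(training_sites, function(s) score_site(pwm, s), numeric(1)))
}

#' Set the scan threshold of a PWM from its training sites
#' @param pwm a `pwm` object.
#' @param training_sites training site sequences.
#' @return the PWM with `$threshold` set.
#' @export
calibrate_pwm <- function(pwm, training_sites) {
  pwm$threshold <- training_threshold(pwm, training_sites)
  pwm
}

# ---- vectorised window machinery ----------------------------------------

# the empty site-instance table (schema shared by scanners)
empty_site_table <- function() {
  data.frame(
    contig_id = character(0), start = integer(0), end = integer(0),
    strand = character(0), center = integer(0), position = integer(0),
    sequence = character(0), score = numeric(0),
    offset_center = integer(0), offset_3p = integer(0),
    anchor_gene_id = character(0), anchor_operon_id = character(0)
  )
}

# windows of width w over an integer-encoded sequence, as an n x w matrix
window_matrix <- function(iv, w) {
  n <- length(iv) - w + 1L
  if (n < 1L) return(NULL)
  idx <- outer(seq_len(n) - 1L, seq_len(w) - 1L, "+") + 1L
  matrix(iv[idx], nrow = n, ncol = w)
}

# score every row of a window matrix; rows containing NA get NA
score_window_matrix <- function(log_odds, W) {
  s <- numeric(nrow(W))
  for (j in seq_len(ncol(W))) s <- s + log_odds[, j][W[, j]]
  s
}

#' Scan a promoter region for above-threshold sites
#'
#' Every window with score >= the PWM threshold is reported once; a
#' symmetric PWM makes the two strands equivalent, so the reported strand
#' is always `+` relative to the oriented promoter.  Overlapping hits are
#' retained.  Windows containing non-ACGT bases are skipped.
#'
#' @param pwm a `pwm` with threshold set (see [calibrate_pwm()]).
#' @param region a `promoter_region` from [extract_promoter()].
#' @return data.frame of site instances: genomic `contig_id`, `start`,
#'   `end`, `strand` (`+`), `center`, oriented `position`, `sequence`,
#'   `score`, `offset_center` and `offset_3p` (bp relative to the anchor
#'   translation start; negative = upstream), `anchor_gene_id`,
#'   `anchor_operon_id`.
#' @export
scan_region <- function(pwm, region) {
  if (is.null(pwm$threshold)) stop("PWM threshold is unset; calibrate first")
  w <- pwm$width
  iv <- seq_to_int(region$sequence)
  W <- window_matrix(iv, w)
  empty <- empty_site_table()
  if (is.null(W)) return(empty)
  sc <- score_window_matrix(pwm$log_odds, W)
  # the 1e-9 bit guard keeps >= robust to summation-order float noise,
  # so a training site scoring exactly at the threshold is never lost
  hit <- which(!is.na(sc) & sc >= pwm$threshold - 1e-9)
  if (!length(hit)) return(empty)
  p <- hit - 1L                       # oriented 0-based window starts
  half <- w %/% 2L
  oc <- p + half                      # oriented center position
  if (region$strand == "+") {
    gstart <- region$start + p
    gcenter <- region$start + oc
  } else {
    gstart <- region$end - p - w
    gcenter <- region$end - 1L - oc
  }
  seqs <- substring(region$sequence, p + 1L, p + w)
  data.frame(
    contig_id = region$contig_id, start = gstart, end = gstart + w,
    strand = "+", center = gcenter, position = p, sequence = seqs,
    score = sc[hit],
    offset_center = oc - region$offset_of_start_codon,
    offset_3p = (p + w - 1L) - region$offset_of_start_codon,
    anchor_gene_id = region$anchor_gene_id,
    anchor_operon_id = region$anchor_operon_id,
    stringsAsFactors = FALSE
  )
}

# ---- palindromic motif discovery ----------------------------------------

#' Discover a palindromic motif in a set of promoters
#'
#' Expectation-maximization under a zero-or-one-occurrence-per-sequence
#' model: each promoter carries at most one site (prior probability `q`),
#' the count matrix is symmetrised every iteration so the motif stays an
#' exact palindrome, and both strands are covered implicitly by the
#' symmetric matrix.  Each candidate width is run from several seeded
#' restarts; the returned motif maximises total information content after
#' subtracting a per-column width penalty, which prevents a trivial
#' preference for the widest motif.
#'
#' @param promoters list of `promoter_region` objects or a character
#'   vector of sequences; at least 2, each at least `min(widths)` long.
#' @param widths candidate motif widths; default the even widths 14-24
#'   (palindromes of homodimeric TFs are predominantly even; pass odd
#'   values explicitly to search non-canonical widths).
#' @param restarts random restarts per width (default 3).
#' @param seed integer seed; discovery is deterministic given the seed.
#' @param q prior probability that a promoter contains a site (default
#'   0.75).
#' @param pseudocount,background as in [build_pwm()].
#' @param max_iter,tol EM stopping rule (iteration cap and largest
#'   absolute log-odds change, bits).
#' @param width_penalty bits per column subtracted from total information
#'   content when comparing widths (default 0.25).
#' @param min_ic mean bits/column below which the result is flagged
#'   low-confidence (default 0.5).
#' @return list with `pwm` (symmetric, threshold unset), `sites`
#'   (data.frame of training sites: promoter index, oriented position,
#'   sequence, score, posterior), `width`, `consensus`, `objective`, and
#'   `low_confidence`.
#' @export
discover_palindromic_motif <- function(promoters, widths = seq(14L, 24L, 2L),
                                       restarts = 3L, seed = 1L, q = 0.75,
                                       pseudocount = 0.5,
                                       background = rep(0.25, 4),
                                       max_iter = 25L, tol = 5e-3,
                                       width_penalty = 0.25, min_ic = 0.5) {
  seqs <- vapply(promoters, function(p) {
    if (inherits(p, "promoter_region")) p$sequence else as.character(p)
  }, character(1))
  if (length(seqs) < 2L) stop("need at least 2 promoters for discovery")
  short <- which(nchar(seqs) < min(widths))
  if (length(short)) {
    stop("promoter ", short[1], " is shorter than the minimum motif width")
  }
  ivs <- lapply(seqs, seq_to_int)

  best <- NULL
  with_seed(seed, {
    for (w in sort(as.integer(widths))) {
      Ws <- lapply(ivs, window_matrix, w = w)
      keep <- !vapply(Ws, is.null, logical(1))
      Wall <- do.call(rbind, Ws[keep])
      prom_of <- rep(which(keep), vapply(Ws[keep], nrow, integer(1)))
      ok <- !apply(is.na(Wall), 1, any)
      Wall <- Wall[ok, , drop = FALSE]
      prom_of <- prom_of[ok]
      if (nrow(Wall) < 2L) next
      m_per <- tabulate(prom_of, nbins = length(seqs))
      ids <- sort(unique(prom_of))
      pidx <- match(prom_of, ids)          # compact promoter index, sorted
      win_pos <- sequence(rle(pidx)$lengths) - 1L  # oriented window starts
      m_win <- m_per[prom_of]
      block_end <- cumsum(tabulate(pidx))  # pidx is sorted: block sums by cumsum
      block_sum <- function(x) diff(c(0, cumsum(x)[block_end]))

      # deterministic seeding: start EM from the most palindromic
      # windows (complement of base b in 1..4 coding is 5-b), which
      # puts the initial matrix on near-palindromes rather than on
      # arbitrary background; one extra random seed adds diversity
      pal <- integer(nrow(Wall))
      for (j in seq_len(w)) pal <- pal + (Wall[, j] == 5L - Wall[, w + 1L - j])
      seed_rows <- order(-pal, seq_len(nrow(Wall)))[seq_len(min(restarts,
                                                               nrow(Wall)))]
      seed_rows <- c(seed_rows, sample.int(nrow(Wall), 1L))

      for (sr in seed_rows) {
        s0 <- Wall[sr, ]
        cnt <- matrix((1 - 0.6) / 3, 4, w)
        cnt[cbind(s0, seq_len(w))] <- 0.6
        cnt <- (cnt + revcomp_matrix(cnt)) / 2
        lo <- log2(sweep(cnt, 2, colSums(cnt), "/") / background)

        for (it in seq_len(max_iter)) {
          sc <- score_window_matrix(lo, Wall)
          z <- (q / m_win) * 2^sc
          denom <- (1 - q) + block_sum(z)
          wt <- z / denom[pidx]
          cnt <- matrix(0, 4, w)
          for (j in seq_len(w)) {
            wj <- Wall[, j]
            for (b in 1:4) cnt[b, j] <- sum(wt[wj == b])
          }
          cnt <- (cnt + revcomp_matrix(cnt)) / 2
          fr <- sweep(cnt + pseudocount, 2, colSums(cnt) + 4 * pseudocount, "/")
          lo_new <- log2(fr / background)
          delta <- max(abs(lo_new - lo))
          lo <- lo_new
          if (delta < tol) break
        }

        # training sites: best window of each promoter with posterior > 0.5
        sc <- score_window_matrix(lo, Wall)
        z <- (q / m_win) * 2^sc
        zsum <- block_sum(z)
        post <- zsum / ((1 - q) + zsum)
        ord <- order(pidx, -sc)
        site_rows <- ord[!duplicated(pidx[ord])]
        use <- post > 0.5
        if (sum(use) < 2L) use <- rep(TRUE, length(ids))
        site_seq <- vapply(site_rows[use], function(rr) int_to_seq(Wall[rr, ]),
                           character(1))
        fit <- build_pwm(site_seq, pseudocount, background, symmetrize = TRUE)
        obj <- information_content(fit) - width_penalty * w
        if (is.null(best) || obj > best$objective) {
          pos <- win_pos[site_rows[use]]
          best <- list(
            pwm = fit,
            sites = data.frame(
              promoter = ids[use], position = pos, sequence = site_seq,
              score = vapply(site_seq, function(s) score_site(fit, s),
                             numeric(1)),
              posterior = post[use], stringsAsFactors = FALSE
            ),
            width = w, consensus = pwm_consensus(fit), objective = obj
          )
        }
      }
    }
  })
  if (is.null(best)) stop("no motif could be fitted in the given widths")
  # trim symmetric edge column pairs whose information content stays
  # below the per-column floor: EM at an overwide width pads the true
  # palindrome with argmax-selected background columns whose apparent
  # information is inflated at small training-set sizes
  repeat {
    w <- best$width
    ic_col <- colSums(best$pwm$freq * log2(best$pwm$freq / background))
    if (w - 2L < min(widths) || mean(ic_col[c(1L, w)]) >= min_ic) break
    best$sites$sequence <- substring(best$sites$sequence, 2L, w - 1L)
    best$sites$position <- best$sites$position + 1L
    best$pwm <- build_pwm(best$sites$sequence, pseudocount, background,
                          symmetrize = TRUE)
    best$sites$score <- vapply(best$sites$sequence,
                               function(s) score_site(best$pwm, s),
                               numeric(1))
    best$width <- w - 2L
    best$consensus <- pwm_consensus(best$pwm)
    best$objective <- information_content(best$pwm) -
      width_penalty * best$width
  }
  best$low_confidence <-
    information_content(best$pwm) / best$width < min_ic
  rownames(best$sites) <- NULL
  best
}

#' Similarity between two motifs
#'
#' Maximum over orientations and full-inclusion offsets of the mean
#' per-column Pearson correlation of frequency columns; symmetric in its
#' arguments.  Motifs whose widths differ by more than 4 get similarity 0
#' with attribute `incomparable = TRUE`.
#'
#' @param pwm_a,pwm_b `pwm` objects.
#' @return numeric in `[-1, 1]`.
#' @export
motif_similarity <- function(pwm_a, pwm_b) {
  if (abs(pwm_a$width - pwm_b$width) > 4L) {
    return(structure(0, incomparable = TRUE))
  }
  a <- pwm_a$freq; b <- pwm_b$freq
  if (ncol(a) > ncol(b)) { tmp <- a; a <- b; b <- tmp }
  wa <- ncol(a); wb <- ncol(b)
  col_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    cor(x, y)
  }
  best <- -1
  for (bb in list(b, revcomp_matrix(b))) {
    for (s in 0:(wb - wa)) {
      cc <- vapply(seq_len(wa),
                   function(i) col_cor(a[, i], bb[, i + s]), numeric(1))
      best <- max(best, mean(cc))
    }
  }
  best
}

# ---- MEME minimal format + TSV export -----------------------------------

#' Write PWMs in MEME minimal motif format
#'
#' @param pwms a named list of `pwm` objects (names become motif ids).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(motif_1 = pwms)
  bg <- pwms[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (nm in names(pwms)) {
    p <- pwms[[nm]]
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      p$width, max(1L, round(p$n_sites))), con)
    for (j in seq_len(p$width)) {
      writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                         p$freq[1, j], p$freq[2, j], p$freq[3, j], p$freq[4, j]),
                 con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read PWMs from MEME minimal motif format
#'
#' @param path a file written by [write_meme()] or another MEME-minimal
#'   producer.
#' @param pseudocount pseudocount recorded on the reconstructed PWMs.
#' @return named list of `pwm` objects (frequencies as stored; counts are
#'   frequencies times nsites).
#' @export
read_meme <- function(path, pseudocount = 0.5) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl)) {
    toks <- strsplit(trimws(lines[bgl[1] + 1]), "\\s+")[[1]]
    bg <- as.numeric(toks[c(2, 4, 6, 8)])
  }
  starts <- grep("^MOTIF ", lines)
  out <- list()
  for (s in starts) {
    nm <- strsplit(lines[s], "\\s+")[[1]][2]
    hl <- s + 1
    while (!grepl("^letter-probability matrix", lines[hl])) hl <- hl + 1
    w <- as.integer(sub(".*w= *(\\d+).*", "\\1", lines[hl]))
    nsites <- as.integer(sub(".*nsites= *(\\d+).*", "\\1", lines[hl]))
    rows <- lines[(hl + 1):(hl + w)]
    freq <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }, numeric(4)))
    counts <- t(freq) * nsites
    dimnames(counts) <- list(DNA_BASES, NULL)
    p <- new_pwm(counts, pseudocount, bg,
                 palindromic = max(abs(counts - revcomp_matrix(counts))) < 1e-6)
    # keep the stored frequencies exactly rather than re-deriving them
    p$freq <- t(freq)
    dimnames(p$freq) <- list(DNA_BASES, NULL)
    p$log_odds <- log2(p$freq / bg)
    out[[nm]] <- p
  }
  out
}

#' Sequence-logo data table for a PWM
#'
#' @param pwm a `pwm` object.
#' @return data.frame with `position`, `base`, `freq`, and per-position
#'   `ic` (bits), suitable for plotting a logo.
#' @export
logo_data <- function(pwm) {
  ic_col <- colSums(pwm$freq * log2(pwm$freq / pwm$background))
  data.frame(
    position = rep(seq_len(pwm$width), each = 4),
    base = rep(DNA_BASES, pwm$width),
    freq = as.vector(pwm$freq),
    ic = rep(ic_col, each = 4)
  )
}

#' Export a PWM as a TSV table
#' @param pwm a `pwm` object.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
export_pwm_tsv <- function(pwm, path) {
  tab <- as.data.frame(t(pwm$freq))
  names(tab) <- DNA_BASES
  tab <- cbind(position = seq_len(pwm$width), tab)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
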