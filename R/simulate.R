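# Seeded pangenome simulator.
#
# Generates a clade of related genomes that share an orthologous gene
# complement (with gene-loss noise), carry exactly one TF gene each, and
# have instances of a palindromic binding motif planted upstream of a
# shared set of regulated operons, plus near-threshold palindromic decoys
# in unrelated promoters.  Ground truth (consensus, site coordinates,
# regulon membership, orthology map) is returned alongside the genomes so
# every pipeline stage can be scored.

#' Generate a palindromic consensus sequence
#'
#' For even widths the result is exactly self-reverse-complementary with
#' the two central bases fixed to `central_pair` (consensus CG by
#' default, the hallmark of this family's even palindromes).  Odd widths
#' carry a single unpaired centre base and are rejected when a 2-base
#' central pair is requested.
#'
#' @param width motif width, 2-24 (palindromic motif searches in this
#'   pipeline use 14-24).
#' @param central_pair two-base centre for even widths (default "CG"), or
#'   a single base for odd widths.
#' @param seed integer seed.
#' @return a DNA string equal to its own reverse complement (even width).
#' @export
generate_palindromic_consensus <- function(width, central_pair = "CG",
                                           seed = 1L) {
  width <- as.integer(width)
  stopifnot(width >= 2L, width <= 24L)
  even <- width %% 2L == 0L
  if (!even && nchar(central_pair) == 2L) {
    stop("odd-width palindromes have a single unpaired centre; ",
         "central_pair must be one base")
  }
  if (even && nchar(central_pair) != 2L) {
    stop("even-width palindromes need a 2-base central_pair")
  }
  half <- width %/% 2L
  with_seed(seed, {
    if (even) {
      narm <- half - 1L
      left <- c(sample(DNA_BASES, narm, replace = TRUE),
                strsplit(central_pair, "")[[1]][1])
    } else {
      left <- sample(DNA_BASES, half, replace = TRUE)
    }
    right <- revcomp(paste(left, collapse = ""))
    if (even) {
      paste0(paste(left, collapse = ""), right)
    } else {
      paste0(paste(left, collapse = ""), central_pair, right)
    }
  })
}

#' Simulation configuration
#'
#' Defaults describe the study conditions used throughout the test suite:
#' 10 related genomes, an 18-bp even palindrome with central CG and 90%
#' per-position conservation, 6 regulated operons shared across the
#' clade, 75% of planted site centres within 140-30 bp upstream of the
#' start codon, autoregulation planted with probability 0.72, gene loss
#' 0.1, and 2 near-threshold decoys per genome.
#'
#' @param n_genomes number of genomes in the clade.
#' @param n_genes genes per genome before loss.
#' @param gene_length_range bp range of gene lengths (min 400 keeps
#'   planted promoters clear of upstream operons' internal gaps).
#' @param operon_size_probs probability of operon sizes 1..4 when laying
#'   out the shared gene complement.
#' @param intra_operon_gap_range,inter_operon_gap_range bp ranges for
#'   gaps within (always <= 100) and between (always > 100) operons.
#' @param motif_width even width in 14-24.
#' @param central_pair central consensus pair.
#' @param motif_conserved_fraction probability a planted site emits the
#'   consensus base at each position.
#' @param max_site_mutations cap on total substitutions per planted
#'   instance (default `floor(motif_width / 4)`); instances beyond the
#'   cap are redrawn so that every ground-truth site stays within the
#'   recognisable (functional) score range.
#' @param n_regulated_operons operon groups regulated in every genome.
#' @param sites_per_operon planted sites per regulated promoter.
#' @param site_core_fraction fraction of planted site centres drawn
#'   uniformly from `site_core_window`; the rest fall elsewhere in the
#'   promoter window.
#' @param site_core_window centre offsets (bp, relative to translation
#'   start) of the core placement region, default `c(-140, -30)`.
#' @param tandem_spacing optional centre-to-centre spacing (bp) of a
#'   second site planted upstream of the first (e.g. 22 or 32); `NULL`
#'   disables tandem sites.
#' @param autoregulation_prob probability that a genome's TF gets a site
#'   upstream of its own operon.
#' @param gene_loss_rate probability a non-anchor, non-TF ortholog is
#'   absent from a genome.
#' @param decoy_rate expected number of near-threshold palindromic decoys
#'   per genome (Poisson).
#' @param protein_length_range residues per ortholog-group ancestor.
#' @param protein_mutation_rate per-residue substitution rate between an
#'   ortholog and its group ancestor.
#' @param gc_content background GC fraction.
#' @param contig_length optional fixed contig length; error if the layout
#'   does not fit.  Default `NULL` sizes the contig to the layout.
#' @param seed integer root seed.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_genomes = 10L, n_genes = 160L,
                       gene_length_range = c(400L, 700L),
                       operon_size_probs = c(0.35, 0.30, 0.20, 0.15),
                       intra_operon_gap_range = c(5L, 80L),
                       inter_operon_gap_range = c(200L, 420L),
                       motif_width = 18L, central_pair = "CG",
                       motif_conserved_fraction = 0.9,
                       max_site_mutations = NULL,
                       n_regulated_operons = 6L, sites_per_operon = 1L,
                       site_core_fraction = 0.75,
                       site_core_window = c(-140L, -30L),
                       tandem_spacing = NULL,
                       autoregulation_prob = 0.72,
                       gene_loss_rate = 0.1, decoy_rate = 2,
                       protein_length_range = c(80L, 160L),
                       protein_mutation_rate = 0.05,
                       gc_content = 0.5, contig_length = NULL,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$max_site_mutations)) {
    cfg$max_site_mutations <- max(1L, motif_width %/% 4L)
  }
  probs <- c(motif_conserved_fraction, site_core_fraction,
             autoregulation_prob, gene_loss_rate, protein_mutation_rate,
             gc_content)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (motif_width < 14L || motif_width > 24L) {
    stop("motif_width must be in [14, 24]")
  }
  if (motif_width %% 2L != 0L) stop("planted motifs are even palindromes")
  if (intra_operon_gap_range[2] > 100L) {
    stop("intra-operon gaps must be <= 100 bp")
  }
  if (inter_operon_gap_range[1] <= 100L) {
    stop("inter-operon gaps must exceed 100 bp")
  }
  class(cfg) <- "sim_config"
  cfg
}

# random DNA at a given GC content
random_dna <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# mutate each position of a DNA string to a random other base w.p. rate
mutate_dna <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  hit <- runif(length(v)) < rate
  if (any(hit)) {
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(DNA_BASES, b), 1L),
                     character(1))
  }
  paste(v, collapse = "")
}

# site instance: per-position substitution at `rate`, truncated at `cap`
# total substitutions.  A planted site is a sequence the factor binds;
# instances so degenerate that they fall outside the recognisable range
# are redrawn, which keeps the ground-truth score distribution within
# the functional regime while leaving the substitution rate itself
# untouched.
mutate_site <- function(s, rate, cap) {
  w <- nchar(s)
  repeat {
    m <- stats::rbinom(1L, w, rate)
    if (m <= cap) break
  }
  if (m == 0L) return(s)
  v <- strsplit(s, "")[[1]]
  pos <- sample.int(w, m)
  v[pos] <- vapply(v[pos], function(b) sample(setdiff(DNA_BASES, b), 1L),
                   character(1))
  paste(v, collapse = "")
}

# reference PWM implied by the planting model: consensus base at
# frequency f, others (1-f)/3
reference_pwm <- function(consensus, conserved_fraction,
                          pseudocount = 0.5, background = rep(0.25, 4)) {
  idx <- seq_to_int(consensus)
  w <- length(idx)
  freq <- matrix((1 - conserved_fraction) / 3, 4, w,
                 dimnames = list(DNA_BASES, NULL))
  freq[cbind(idx, seq_len(w))] <- conserved_fraction
  counts <- freq * 100
  p <- new_pwm(counts, pseudocount, background,
               palindromic = max(abs(counts - revcomp_matrix(counts))) < 1e-6)
  p
}

# near-threshold decoy aimed at `target` under `pwm`: mutate the
# consensus with the substitution count whose score lands closest to the
# target.  Per-position log-odds are quantised, so an exact +-1-bit band
# is not always reachable; the closest achievable score is used.  The
# decoy stays palindromic up to at most one asymmetric substitution.
decoy_sequence <- function(consensus, pwm, target) {
  w <- nchar(consensus)
  half <- w %/% 2L
  v <- strsplit(consensus, "")[[1]]
  idx1 <- seq_to_int(consensus)[1]
  drop <- pwm$log_odds[idx1, 1] - max(pwm$log_odds[-idx1, 1])
  cons_score <- score_site(pwm, consensus)
  # largest achievable lattice score not above target + 1
  m <- max(1L, min(w, ceiling((cons_score - (target + 1)) / drop)))
  n_pairs <- m %/% 2L
  pos <- if (n_pairs > 0L) sample(seq_len(half), n_pairs) else integer(0)
  for (i in pos) {
    b <- sample(setdiff(DNA_BASES, v[i]), 1L)
    v[i] <- b
    v[w + 1L - i] <- COMPLEMENT[[b]]
  }
  if (m %% 2L == 1L) {
    free <- setdiff(seq_len(w), c(pos, w + 1L - pos))
    i <- if (length(free) > 1L) sample(free, 1L) else free
    v[i] <- sample(setdiff(DNA_BASES, v[i]), 1L)
  }
  paste(v, collapse = "")
}

#' Simulate a pangenome with planted regulon ground truth
#'
#' See [sim_config()] for the generative model.  Output is deterministic
#' for a fixed seed.
#'
#' @param config a `sim_config`.
#' @return list with `genomes` (list of `genome` objects) and `truth`,
#'   itself a list: `consensus` (planted palindrome), `reference_pwm`,
#'   `threshold` (minimum planted-site score under the reference PWM),
#'   `sites` (data.frame: genome_id, contig_id, start, end, strand,
#'   center, offset_center, anchor_gene_id, operon_group, kind
#'   regulon/autoregulation), `decoys` (same shape, kind decoy),
#'   `regulon_members` (data.frame: genome_id, anchor_gene_id,
#'   operon_group), `orthology` (gene_id -> group), `tf_genes`
#'   (genome_id -> gene_id), `config`.
#' @export
simulate_pangenome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    # ---- shared clade layout: operon groups over ortholog groups ----
    sizes <- integer(0)
    while (sum(sizes) < cfg$n_genes) {
      sizes <- c(sizes, sample(1:4, 1L, prob = cfg$operon_size_probs))
    }
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - cfg$n_genes)
    sizes <- sizes[sizes > 0L]
    n_operons <- length(sizes)
    if (cfg$n_regulated_operons > n_operons - 1L) {
      stop("infeasible layout: n_regulated_operons exceeds available operons")
    }
    op_strand <- sample(c("+", "-"), n_operons, replace = TRUE)
    group_ids <- sprintf("og%03d", seq_len(cfg$n_genes))
    op_of_gene <- rep(seq_len(n_operons), sizes)

    # the TF is the first gene of a randomly chosen operon; regulated
    # operon groups are chosen among the others
    tf_operon <- sample.int(n_operons, 1L)
    tf_gene_idx <- which(op_of_gene == tf_operon)[1]
    reg_operons <- sample(setdiff(seq_len(n_operons), tf_operon),
                          cfg$n_regulated_operons)

    pathway_pool <- c("fructose_utilization", "gluconate_catabolism",
                      "central_glycolysis", "maltodextrin_transport")
    op_label <- rep("hypothetical_protein", n_operons)
    op_label[reg_operons] <- pathway_pool[
      (seq_along(reg_operons) - 1L) %% length(pathway_pool) + 1L]
    op_label[tf_operon] <- "transcriptional_regulator"

    consensus <- generate_palindromic_consensus(
      cfg$motif_width, cfg$central_pair, seed = sample.int(1e6, 1L))
    ref_pwm <- reference_pwm(consensus, cfg$motif_conserved_fraction)

    # ancestor proteins per ortholog group
    anc_prot <- vapply(seq_len(cfg$n_genes), function(i) {
      n <- sample(cfg$protein_length_range[1]:cfg$protein_length_range[2], 1L)
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
                   replace = TRUE), collapse = "")
    }, character(1))

    anchors <- vapply(seq_len(n_operons), function(o) {
      which(op_of_gene == o)[1]
    }, integer(1))

    parts <- vector("list", cfg$n_genomes)
    site_rows <- list()
    decoy_rows <- list()
    decoy_place <- list()
    member_rows <- list()
    tf_genes <- character(cfg$n_genomes)
    orthology <- list()

    w <- cfg$motif_width
    half <- w %/% 2L

    for (gi in seq_len(cfg$n_genomes)) {
      gid <- sprintf("genome%02d", gi)
      cid <- paste0(gid, "_c1")
      # gene presence: anchors and the TF never drop out, so every operon
      # keeps its promoter anchor and the regulog structure stays scorable
      keep <- runif(cfg$n_genes) >= cfg$gene_loss_rate
      keep[anchors] <- TRUE
      keep[tf_gene_idx] <- TRUE

      # lay out coordinates left to right
      pos <- sample(cfg$inter_operon_gap_range[1]:cfg$inter_operon_gap_range[2], 1L) + 450L
      starts <- ends <- integer(0)
      idx_present <- integer(0)
      for (o in seq_len(n_operons)) {
        members <- which(op_of_gene == o & keep)
        if (!length(members)) next
        if (op_strand[o] == "-") members <- rev(members)
        for (mi in seq_along(members)) {
          glen <- sample(cfg$gene_length_range[1]:cfg$gene_length_range[2], 1L)
          starts <- c(starts, pos)
          ends <- c(ends, pos + glen)
          idx_present <- c(idx_present, members[mi])
          pos <- pos + glen +
            if (mi < length(members)) {
              sample(cfg$intra_operon_gap_range[1]:cfg$intra_operon_gap_range[2], 1L)
            } else {
              sample(cfg$inter_operon_gap_range[1]:cfg$inter_operon_gap_range[2], 1L)
            }
        }
      }
      contig_len <- pos + 500L
      if (!is.null(cfg$contig_length)) {
        if (cfg$contig_length < contig_len) {
          stop("infeasible layout: genes do not fit contig_length ",
               cfg$contig_length)
        }
        contig_len <- cfg$contig_length
      }
      contig <- random_dna(contig_len, cfg$gc_content)

      gene_ids <- sprintf("%s_g%03d", gid, idx_present)
      genes <- data.frame(
        gene_id = gene_ids,
        contig_id = cid,
        start = starts, end = ends,
        strand = op_strand[op_of_gene[idx_present]],
        locus_tag = gene_ids,
        function_label = op_label[op_of_gene[idx_present]],
        is_tf = idx_present == tf_gene_idx,
        stringsAsFactors = FALSE
      )
      orthology[[gid]] <- setNames(group_ids[idx_present], gene_ids)
      tf_genes[gi] <- gene_ids[idx_present == tf_gene_idx]

      proteins <- setNames(vapply(anc_prot[idx_present], function(p) {
        v <- strsplit(p, "")[[1]]
        hit <- runif(length(v)) < cfg$protein_mutation_rate
        if (any(hit)) {
          v[hit] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                           sum(hit), replace = TRUE)
        }
        paste(v, collapse = "")
      }, character(1)), gene_ids)

      # ---- plant sites ----
      plant_ops <- reg_operons
      autoreg <- runif(1) < cfg$autoregulation_prob
      if (autoreg) plant_ops <- c(plant_ops, tf_operon)

      draw_offset <- function() {
        if (runif(1) < cfg$site_core_fraction) {
          sample(cfg$site_core_window[1]:cfg$site_core_window[2], 1L)
        } else {
          lo <- -400L + half; hi <- 100L - half
          out <- cfg$site_core_window[1]:cfg$site_core_window[2]
          sample(setdiff(lo:hi, out), 1L)
        }
      }

      plant_one <- function(anchor_row, off, seqs) {
        # returns genomic start; writes the (possibly revcomp'ed) site
        tstart <- translation_start(anchor_row)
        if (anchor_row$strand == "+") {
          center <- tstart + off
          gstart <- center - half
        } else {
          center <- tstart - off
          gstart <- center - (w - half - 1L)
          seqs <- revcomp(seqs)
        }
        if (gstart < 0L || gstart + w > contig_len) return(NULL)
        substr(contig, gstart + 1L, gstart + w) <<- seqs
        list(start = gstart, center = center)
      }

      for (o in plant_ops) {
        # operon members are laid out so ortholog order follows the
        # transcription direction; the promoter anchor is always the
        # lowest ortholog index of the operon
        first_present <- which(op_of_gene == o & keep)
        agid <- sprintf("%s_g%03d", gid, first_present[1])
        arow <- genes[genes$gene_id == agid, , drop = FALSE]
        kind <- if (o == tf_operon) "autoregulation" else "regulon"
        n_sites <- cfg$sites_per_operon
        off1 <- draw_offset()
        offs <- off1
        if (n_sites > 1L) {
          offs <- c(offs, off1 - (seq_len(n_sites - 1L)) * 25L)
        }
        if (!is.null(cfg$tandem_spacing)) {
          offs <- c(offs, off1 - cfg$tandem_spacing)
        }
        for (off in offs) {
          inst <- mutate_site(consensus, 1 - cfg$motif_conserved_fraction,
                              cfg$max_site_mutations)
          placed <- plant_one(arow, off, inst)
          if (is.null(placed)) next
          site_rows[[length(site_rows) + 1L]] <- data.frame(
            genome_id = gid, contig_id = cid,
            start = placed$start, end = placed$start + w,
            strand = arow$strand, center = placed$center,
            offset_center = off, anchor_gene_id = agid,
            operon_group = group_ids[first_present[1]],
            sequence = inst, kind = kind, stringsAsFactors = FALSE
          )
        }
      }

      # ---- choose decoy placements in unrelated promoters ----
      # decoy sequences are generated after all genomes are laid out,
      # once the ground-truth threshold (minimum planted-site score) is
      # known; only the placements are drawn here
      n_dec <- rpois(1L, cfg$decoy_rate)
      if (n_dec > 0L) {
        free_ops <- sample(setdiff(seq_len(n_operons), plant_ops))
        for (d in seq_len(min(n_dec, length(free_ops)))) {
          o <- free_ops[d]
          first_present <- which(op_of_gene == o & keep)
          agid <- sprintf("%s_g%03d", gid, first_present[1])
          arow <- genes[genes$gene_id == agid, , drop = FALSE]
          decoy_place[[length(decoy_place) + 1L]] <- list(
            gi = gi, gid = gid, cid = cid, agid = agid,
            strand = arow$strand, tstart = translation_start(arow),
            contig_len = contig_len, off = draw_offset(),
            operon_group = group_ids[first_present[1]])
        }
      }

      # ---- true regulon membership: window containment ----
      # a planted site makes every operon whose -400..+100 promoter
      # window contains its centre a true member; in divergons the
      # shared site is attributed to both operons, as in real regulatory
      # annotation
      my_sites <- Filter(function(r) r$genome_id == gid, site_rows)
      if (length(my_sites)) {
        centers <- vapply(my_sites, function(r) r$center, numeric(1))
        for (o in seq_len(n_operons)) {
          first_present <- which(op_of_gene == o & keep)
          if (!length(first_present)) next
          agid <- sprintf("%s_g%03d", gid, first_present[1])
          arow <- genes[genes$gene_id == agid, , drop = FALSE]
          tstart <- translation_start(arow)
          if (arow$strand == "+") {
            lo <- max(0L, tstart - 400L); hi <- min(contig_len, tstart + 100L)
          } else {
            lo <- max(0L, tstart - 99L); hi <- min(contig_len, tstart + 401L)
          }
          if (any(centers >= lo & centers < hi)) {
            member_rows[[length(member_rows) + 1L]] <- data.frame(
              genome_id = gid, anchor_gene_id = agid,
              operon_group = group_ids[first_present[1]],
              stringsAsFactors = FALSE)
          }
        }
      }

      parts[[gi]] <- list(gid = gid, cid = cid, contig = contig,
                          genes = genes, proteins = proteins)
    }

    sites <- if (length(site_rows)) do.call(rbind, site_rows) else
      data.frame()
    members <- if (length(member_rows)) do.call(rbind, member_rows) else
      data.frame()
    thr <- if (nrow(sites)) {
      min(vapply(sites$sequence, function(s) score_site(ref_pwm, s),
                 numeric(1)))
    } else NA_real_

    # ---- plant the deferred decoys against the known threshold ----
    for (pl in decoy_place) {
      dseq <- decoy_sequence(consensus, ref_pwm,
                             if (is.na(thr)) 0 else thr)
      oriented <- dseq
      if (pl$strand == "+") {
        center <- pl$tstart + pl$off
        gstart <- center - half
      } else {
        center <- pl$tstart - pl$off
        gstart <- center - (w - half - 1L)
        oriented <- revcomp(dseq)
      }
      if (gstart < 0L || gstart + w > pl$contig_len) next
      substr(parts[[pl$gi]]$contig, gstart + 1L, gstart + w) <- oriented
      decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
        genome_id = pl$gid, contig_id = pl$cid,
        start = gstart, end = gstart + w,
        strand = pl$strand, center = center,
        offset_center = pl$off, anchor_gene_id = pl$agid,
        operon_group = pl$operon_group,
        sequence = dseq, kind = "decoy", stringsAsFactors = FALSE)
    }
    decoys <- if (length(decoy_rows)) do.call(rbind, decoy_rows) else
      data.frame()

    genomes <- lapply(parts, function(p) {
      new_genome(p$gid, setNames(p$contig, p$cid), p$genes, p$proteins)
    })

    truth <- list(
      consensus = consensus, reference_pwm = ref_pwm, threshold = thr,
      sites = sites, decoys = decoys, regulon_members = members,
      orthology = unlist(unname(orthology)),
      tf_genes = setNames(tf_genes,
                          vapply(genomes, function(g) g$genome_id,
                                 character(1))),
      tf_operon_group = group_ids[tf_gene_idx],
      config = cfg
    )
    list(genomes = genomes, truth = truth)
  })
}

#' Write a simulated pangenome to disk
#'
#' Emits per-genome FASTA/GFF3/protein FASTA, ground-truth sites as BED6
#' with an anchor column (TSV), regulon membership as TSV, and a JSON run
#' manifest recording the configuration and seed.
#'
#' @param sim output of [simulate_pangenome()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_pangenome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in sim$genomes) write_genome(g, dir)
  tr <- sim$truth
  write.table(tr$sites, file.path(dir, "truth_sites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(tr$regulon_members, file.path(dir, "truth_regulons.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ortho <- data.frame(gene_id = names(tr$orthology),
                      group = unname(tr$orthology))
  write.table(ortho, file.path(dir, "truth_orthology.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- tr$config
  cfg_out <- lapply(unclass(cfg), function(x) x)
  jsonlite::write_json(
    list(consensus = tr$consensus, config = cfg_out),
    file.path(dir, "run_manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' Score a reconstruction against simulator ground truth
#'
#' A planted site counts as recovered when a predicted site centre lies
#' within `tolerance` bp of its centre in the same genome.  Operon
#' membership is compared on `(genome_id, anchor_gene_id)` pairs.
#'
#' @param truth the `truth` element of [simulate_pangenome()] output.
#' @param predicted_sites data.frame with `genome_id` and `center`
#'   columns (e.g. pooled [scan_region()] output tagged with genomes).
#' @param predicted_members data.frame with `genome_id`,
#'   `anchor_gene_id`.
#' @param consensus predicted motif consensus string (optional).
#' @param tolerance bp tolerance on site centres (default 3).
#' @return list of metrics in `[0, 1]` (`NA` where undefined, e.g.
#'   precision of an empty prediction): `site_precision`, `site_recall`,
#'   `operon_precision`, `operon_recall`, `consensus_distance`.
#' @export
evaluate_recovery <- function(truth, predicted_sites, predicted_members,
                              consensus = NULL, tolerance = 3L) {
  ts <- truth$sites
  key <- function(df) paste(df$genome_id, df$anchor_gene_id)
  # site matching per genome on centres
  match_one <- function(gid) {
    tc <- ts$center[ts$genome_id == gid]
    pc <- predicted_sites$center[predicted_sites$genome_id == gid]
    if (!length(tc) || !length(pc)) {
      return(c(tp_t = 0L, tp_p = 0L, nt = length(tc), np = length(pc)))
    }
    hit_t <- vapply(tc, function(x) any(abs(pc - x) <= tolerance), logical(1))
    hit_p <- vapply(pc, function(x) any(abs(tc - x) <= tolerance), logical(1))
    c(tp_t = sum(hit_t), tp_p = sum(hit_p), nt = length(tc), np = length(pc))
  }
  gids <- unique(c(ts$genome_id, predicted_sites$genome_id))
  m <- rowSums(vapply(gids, match_one, numeric(4)))
  site_recall <- if (m["nt"] > 0) m[["tp_t"]] / m[["nt"]] else NA_real_
  site_precision <- if (m["np"] > 0) m[["tp_p"]] / m[["np"]] else NA_real_

  tm <- unique(key(truth$regulon_members))
  pm <- unique(key(predicted_members))
  operon_recall <- if (length(tm)) mean(tm %in% pm) else NA_real_
  operon_precision <- if (length(pm)) mean(pm %in% tm) else NA_real_

  cd <- if (!is.null(consensus)) {
    consensus_distance(consensus, truth$consensus)
  } else NA_integer_

  list(site_precision = unname(site_precision),
       site_recall = unname(site_recall),
       operon_precision = operon_precision,
       operon_recall = operon_recall,
       consensus_distance = cd)
}
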