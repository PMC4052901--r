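# Descriptive statistics of reconstructed regulons: site position and
# intersite-distance histograms, palindrome census, regulon/regulog
# census.

#' Histogram of site positions relative to the translation start
#'
#' Distances are measured from the site centre (default) or 3' end to
#' the anchor gene's translation start; negative = upstream.  Also
#' reports the fraction of sites within the core window `[-140, -30]`,
#' inside coding sequence (> 0), and far upstream (< -200).
#'
#' @param sites site table with `offset_center` (and `offset_3p`)
#'   columns, e.g. pooled [scan_region()] output or simulator truth.
#' @param bin_width bp per bin, default 10.
#' @param anchor `"center"` or `"3p"`: which site coordinate to measure
#'   from.
#' @return list with `histogram` (data.frame `bin_start`, `count`) and
#'   `fractions` (named list `core`, `coding`, `far_upstream`; `NULL`
#'   values when there are no sites).
#' @export
site_position_histogram <- function(sites, bin_width = 10L,
                                    anchor = c("center", "3p")) {
  anchor <- match.arg(anchor)
  off <- if (anchor == "center") sites$offset_center else sites$offset_3p
  if (!length(off)) {
    return(list(histogram = data.frame(bin_start = integer(0),
                                       count = integer(0)),
                fractions = list(core = NULL, coding = NULL,
                                 far_upstream = NULL)))
  }
  bin <- floor(off / bin_width) * bin_width
  tb <- table(bin)
  hist <- data.frame(bin_start = as.integer(names(tb)),
                     count = as.integer(tb))
  list(histogram = hist,
       fractions = list(
         core = mean(off >= -140 & off <= -30),
         coding = mean(off > 0),
         far_upstream = mean(off < -200)))
}

#' Distances between adjacent sites in shared regions
#'
#' Groups sites by regulatory region (anchor operon by default), sorts
#' by centre, and reports centre-to-centre distances between adjacent
#' sites.  Regions with a single site yield no record.  Duplicate
#' genomic sites within a region (e.g. a divergon site attributed to two
#' operons appears once per region) are collapsed.
#'
#' @param sites site table with `center` and a region identifier column.
#' @param region_col column defining the region, default
#'   `"anchor_operon_id"`; sites are additionally grouped by `genome_id`
#'   and `contig_id` when present.
#' @return list with `records` (data.frame `region`, `n_sites`,
#'   `distances` list column), `pooled` (integer vector of all adjacent
#'   distances), `mode` (most frequent distance or `NA`), and
#'   `multi_site_counts` (table of region site counts >= 2).
#' @export
intersite_distances <- function(sites, region_col = "anchor_operon_id") {
  if (!nrow(sites)) {
    return(list(records = data.frame(), pooled = integer(0),
                mode = NA_integer_,
                multi_site_counts = table(integer(0))))
  }
  extra <- intersect(c("genome_id", "contig_id"), names(sites))
  keyv <- do.call(paste, c(unname(sites[c(extra, region_col)]), sep = "|"))
  recs <- list()
  pooled <- integer(0)
  for (k in unique(keyv)) {
    cent <- sort(unique(sites$center[keyv == k]))
    if (length(cent) < 2L) next
    d <- diff(cent)
    pooled <- c(pooled, d)
    recs[[length(recs) + 1L]] <- data.frame(
      region = k, n_sites = length(cent), stringsAsFactors = FALSE)
    recs[[length(recs)]]$distances <- list(as.integer(d))
  }
  records <- if (length(recs)) do.call(rbind, recs) else data.frame()
  mode <- if (length(pooled)) {
    tb <- table(pooled)
    as.integer(names(tb)[which.max(tb)])
  } else NA_integer_
  list(records = records, pooled = as.integer(pooled), mode = mode,
       multi_site_counts = if (length(recs)) table(records$n_sites) else
         table(integer(0)))
}

#' Palindrome census over a set of motifs
#'
#' Classifies each motif by width parity and, for even widths, by the
#' central consensus pair: `CG` when the two central consensus bases are
#' C,G each with frequency at or above `degeneracy_cutoff`; `degenerate`
#' when the central consensus is CG but below the cutoff; `other`
#' otherwise.
#'
#' @param pwms list of `pwm` objects.
#' @param degeneracy_cutoff consensus frequency cutoff, default 0.5.
#' @return data.frame with one row per motif: `width`, `parity`,
#'   `central_class` (`NA` for odd widths).
#' @export
palindrome_census <- function(pwms, degeneracy_cutoff = 0.5) {
  rows <- lapply(seq_along(pwms), function(i) {
    p <- pwms[[i]]
    w <- p$width
    even <- w %% 2L == 0L
    cls <- NA_character_
    if (even) {
      c1 <- p$freq[, w / 2]; c2 <- p$freq[, w / 2 + 1]
      cons <- DNA_BASES[c(which.max(c1), which.max(c2))]
      if (identical(cons, c("C", "G"))) {
        cls <- if (max(c1) >= degeneracy_cutoff &&
                     max(c2) >= degeneracy_cutoff) "CG" else "degenerate"
      } else {
        cls <- "other"
      }
    }
    data.frame(motif = names(pwms)[i] %||% as.character(i), width = w,
               parity = if (even) "even" else "odd",
               central_class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Census of regulons and regulogs
#'
#' @param regulogs list of `regulog` objects.
#' @param autoregulated optional named logical vector (by TF gene or
#'   genome) of autoregulation calls to summarise.
#' @param classifications optional character vector of
#'   `"global"`/`"local"` calls.
#' @return list with `summary` (data.frame of totals and means) and
#'   `distributions` (regulons per group, genes per regulon, operons per
#'   regulon).
#' @export
regulon_census <- function(regulogs, autoregulated = NULL,
                           classifications = NULL) {
  per_group <- vapply(regulogs, `[[`, integer(1), "n_regulons")
  genes_per <- unlist(lapply(regulogs, function(rg) {
    vapply(rg$regulons, `[[`, integer(1), "n_genes")
  }))
  operons_per <- unlist(lapply(regulogs, function(rg) {
    vapply(rg$regulons, `[[`, integer(1), "n_operons")
  }))
  summary <- data.frame(
    n_regulogs = length(regulogs),
    n_regulons = sum(per_group),
    n_operons = sum(vapply(regulogs, `[[`, integer(1), "n_operons")),
    n_genes = sum(vapply(regulogs, `[[`, integer(1), "n_genes")),
    n_sites = sum(vapply(regulogs, `[[`, integer(1), "n_sites")),
    mean_regulons_per_group = if (length(per_group)) mean(per_group) else NA,
    autoregulated_fraction = if (!is.null(autoregulated)) {
      mean(autoregulated)
    } else NA,
    global_fraction = if (!is.null(classifications)) {
      mean(classifications == "global")
    } else NA
  )
  list(summary = summary,
       distributions = list(
         regulons_per_group = per_group,
         genes_per_regulon = genes_per,
         operons_per_regulon = operons_per))
}
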