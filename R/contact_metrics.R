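#' Contacting-CpG single-cell compartment vector
#'
#' For every genomic bin a cell touches, the contact-weighted mean CpG
#' frequency of the *other* bins it contacts (excluding self). This is a
#' single-cell compartment proxy: euchromatic bins contact CpG-rich
#' partners. In `"diploid"` mode only fully haplotype-resolved contacts are
#' used and the two alleles of every bin are kept as separate loci; in
#' `"celltype"` mode all contacts are used and alleles are pooled.
#'
#' @param cell a [contact_set()].
#' @param cpg a [cpg_track()].
#' @param bin_size analysis bin size in bp (default 1 Mb).
#' @param mode `"diploid"` or `"celltype"`.
#' @return `data.table(chrom, hap, bin, value, n_contacts)` (`hap` is
#'   `"pooled"` in celltype mode). Bins contacting only themselves are
#'   absent (missing value).
#' @export
contacting_cpg <- function(cell, cpg, bin_size = 1e6,
                           mode = c("diploid", "celltype")) {
  mode <- match.arg(mode)
  dt <- as.data.table(cell)
  if (mode == "diploid") {
    dt <- dt[hap_a != "unknown" & hap_b != "unknown"]
  }
  if (nrow(dt) == 0)
    return(data.table(chrom = character(), hap = character(),
                      bin = integer(), value = numeric(),
                      n_contacts = integer()))
  ba <- bin_of(dt$pos_a, bin_size)
  bb <- bin_of(dt$pos_b, bin_size)
  cpg_b <- cpg_at(cpg, dt$chr_b, bb, bin_size = bin_size)
  cpg_a <- cpg_at(cpg, dt$chr_a, ba, bin_size = bin_size)
  if (anyNA(cpg_a) || anyNA(cpg_b))
    stop("CpG track does not cover all contacted bins")
  hap_a <- if (mode == "diploid") dt$hap_a else "pooled"
  hap_b <- if (mode == "diploid") dt$hap_b else "pooled"
  legs <- rbind(
    data.table(chrom = dt$chr_a, hap = hap_a, bin = ba,
               partner_cpg = cpg_b, self = dt$chr_a == dt$chr_b & ba == bb),
    data.table(chrom = dt$chr_b, hap = hap_b, bin = bb,
               partner_cpg = cpg_a, self = dt$chr_a == dt$chr_b & ba == bb))
  legs <- legs[self == FALSE]  # "excluding self"
  legs[, .(value = mean(partner_cpg), n_contacts = .N),
       by = .(chrom, hap, bin)][order(chrom, hap, bin)]
}

#' PCA and 2-means clustering of single-cell compartment vectors
#'
#' Projects the cells of a cohort on the top principal components of their
#' contacting-CpG vectors (loci missing in any cell are dropped) and labels
#' them by seeded 2-means on the leading components.
#'
#' @param vectors named list of [contacting_cpg()] tables, one per cell.
#' @param n_components components to keep.
#' @param k number of clusters.
#' @param seed k-means seed.
#' @return list with `scores` (cells x components), `var_explained`,
#'   `cluster` (named integer vector) and `n_loci` used.
#' @export
compartment_pca <- function(vectors, n_components = 2, k = 2, seed = 1) {
  if (length(vectors) < 4) stop("need at least 4 cells")
  mats <- lapply(vectors, function(v) {
    x <- stats::setNames(v$value, paste(v$chrom, v$hap, v$bin, sep = ":"))
    x
  })
  common <- Reduce(intersect, lapply(mats, names))
  if (length(common) < length(vectors))
    stop("fewer complete loci (", length(common), ") than cells")
  m <- do.call(rbind, lapply(mats, `[`, common))
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(p$x))
  scores <- p$x[, seq_len(nc), drop = FALSE]
  cl <- with_seed(seed, stats::kmeans(scores, centers = k, nstart = 10))
  list(scores = scores,
       var_explained = p$sdev^2 / sum(p$sdev^2),
       cluster = stats::setNames(cl$cluster, names(vectors)),
       n_loci = length(common))
}

#' Agreement between cluster labels and cohort labels
#'
#' Fraction of cells whose cluster matches the cohort label under the best
#' cluster-to-cohort assignment (both orderings of a 2-way labelling are
#' tried).
#'
#' @param cluster integer cluster vector.
#' @param labels true cohort labels (same order).
#' @return Agreement in `[0, 1]`.
#' @export
cluster_agreement <- function(cluster, labels) {
  labels <- as.integer(factor(labels))
  cluster <- as.integer(factor(cluster))
  if (max(labels) != 2 || max(cluster) != 2)
    return(mean(cluster == labels))
  max(mean(cluster == labels), mean(3L - cluster == labels))
}

#' Interchromosomal contact statistics
#'
#' @param cell a [contact_set()].
#' @return list with `fraction` (interchromosomal contacts / total, NA for
#'   an empty cell) and `pair_counts` (data.table of contacts per unordered
#'   chromosome pair, haplotypes pooled).
#' @export
interchrom_stats <- function(cell) {
  dt <- as.data.table(cell)
  if (nrow(dt) == 0)
    return(list(fraction = NA_real_,
                pair_counts = data.table(chr_a = character(),
                                         chr_b = character(), n = integer())))
  list(fraction = mean(dt$chr_a != dt$chr_b),
       pair_counts = dt[, .(n = .N), by = .(chr_a, chr_b)][order(chr_a, chr_b)])
}

global_bins <- function(genome, bin_size) {
  nb <- n_bins(genome, bin_size)
  off <- cumsum(c(0, nb[-length(nb)]))
  names(off) <- genome$chroms
  list(offsets = off, total = sum(nb), nb = nb)
}

#' Binned contact matrix
#'
#' Symmetric genome-wide contact-count matrix over concatenated bins of all
#' chromosomes, pooled over the given cells.
#'
#' @param cells a [contact_set()] or list of them.
#' @param genome a [genome_spec()].
#' @param bin_size matrix bin size in bp.
#' @return Symmetric numeric matrix with `chrom:bin` dimnames and attribute
#'   `bins`.
#' @export
contact_heatmap <- function(cells, genome, bin_size = 1e6) {
  if (inherits(cells, "contact_set")) cells <- list(cells)
  gb <- global_bins(genome, bin_size)
  m <- matrix(0, gb$total, gb$total)
  for (cell in cells) {
    dt <- as.data.table(cell)
    if (nrow(dt) == 0) next
    i <- gb$offsets[dt$chr_a] + bin_of(dt$pos_a, bin_size) + 1
    j <- gb$offsets[dt$chr_b] + bin_of(dt$pos_b, bin_size) + 1
    for (k in seq_along(i)) {
      m[i[k], j[k]] <- m[i[k], j[k]] + 1
      if (i[k] != j[k]) m[j[k], i[k]] <- m[j[k], i[k]] + 1
    }
  }
  labs <- paste(rep(genome$chroms, gb$nb),
                unlist(lapply(gb$nb, seq_len)) - 1L, sep = ":")
  dimnames(m) <- list(labs, labs)
  attr(m, "bins") <- gb
  m
}

#' Differential contact map between two cohorts
#'
#' `log2((A + eps) / (B + eps))` after scaling B to A's total count, so the
#' view is invariant to sequencing depth.
#'
#' @param a,b contact matrices from [contact_heatmap()] on the same genome.
#' @param eps pseudo-count in raw-count units (default 1).
#' @return Matrix of log2 ratios.
#' @export
contact_heatmap_diff <- function(a, b, eps = 1) {
  stopifnot(all(dim(a) == dim(b)))
  sb <- if (sum(b) > 0) sum(a) / sum(b) else 1
  log2((a + eps) / (b * sb + eps))
}

#' Lieberman-Aiden A/B compartments
#'
#' Per chromosome: bins the pooled intrachromosomal contacts, normalises the
#' matrix to observed/expected using per-diagonal means, takes the Pearson
#' correlation matrix and its first eigenvector, and orients the sign so
#' that positive entries correlate positively with CpG frequency ("A" =
#' positive, CpG-rich/euchromatic).
#'
#' @param contacts pooled [contact_set()].
#' @param cpg a [cpg_track()].
#' @param genome a [genome_spec()].
#' @param bin_size analysis bin size in bp (default 1 Mb).
#' @param min_bins minimum bins per chromosome (default 20).
#' @return `data.table(chrom, bin, score, compartment)` (`"A"`, `"B"` or NA
#'   for masked bins), with attribute `var_explained` per chromosome.
#' @export
ab_compartments <- function(contacts, cpg, genome, bin_size = 1e6,
                            min_bins = 20) {
  dt <- as.data.table(contacts)[chr_a == chr_b]
  out <- vector("list", length(genome$chroms))
  ve <- stats::setNames(numeric(length(genome$chroms)), genome$chroms)
  for (ci in seq_along(genome$chroms)) {
    ch <- genome$chroms[ci]
    nbins <- n_bins(genome, bin_size)[ci]
    if (nbins < min_bins)
      stop("chromosome ", ch, " has fewer than ", min_bins, " bins")
    g <- dt[chr_a == ch]
    m <- matrix(0, nbins, nbins)
    if (nrow(g) > 0) {
      i <- bin_of(g$pos_a, bin_size) + 1
      j <- bin_of(g$pos_b, bin_size) + 1
      for (k in seq_along(i)) {
        m[i[k], j[k]] <- m[i[k], j[k]] + 1
        if (i[k] != j[k]) m[j[k], i[k]] <- m[j[k], i[k]] + 1
      }
    }
    cover <- rowSums(m) > 0
    score <- rep(NA_real_, nbins)
    if (sum(cover) >= min_bins) {
      mm <- m[cover, cover]
      nk <- nrow(mm)
      oe <- mm
      for (d in 0:(nk - 1)) {
        idx <- cbind(seq_len(nk - d), seq_len(nk - d) + d)
        e <- mean(mm[idx])
        if (e > 0) {
          oe[idx] <- mm[idx] / e
          oe[idx[, c(2, 1), drop = FALSE]] <- oe[idx]
        }
      }
      cc <- suppressWarnings(stats::cor(oe))
      cc[!is.finite(cc)] <- 0
      if (sum(abs(cc)) == 0) stop("degenerate contact matrix on ", ch)
      eg <- eigen(cc, symmetric = TRUE)
      ev <- eg$vectors[, 1]
      ve[ci] <- eg$values[1] / sum(pmax(eg$values, 0))
      cpgv <- cpg_at(cpg, rep(ch, nk), which(cover) - 1L, bin_size = bin_size)
      if (isTRUE(cor(ev, cpgv) < 0)) ev <- -ev  # orient A to high CpG
      score[cover] <- ev
    }
    out[[ci]] <- data.table(chrom = ch, bin = seq_len(nbins) - 1L,
                            score = score,
                            compartment = ifelse(is.na(score), NA_character_,
                                                 ifelse(score > 0, "A", "B")))
  }
  res <- rbindlist(out)
  data.table::setattr(res, "var_explained", ve)
  res
}
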