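neighbor_list <- function(structure, radius) {
  prs <- cpp_neighbor_pairs(coords_matrix(structure), radius)
  data.table(i = prs$i + 1L, j = prs$j + 1L, d = prs$d)
}

#' Chromosome intermingling index
#'
#' Per particle, the fraction of particles within the neighbour radius that
#' belong to a different chromosome. By default the two homologs of a
#' chromosome count as the same chromosome (territory mixing is between
#' chromosome names); set `homologs_distinct = TRUE` to count the homolog as
#' foreign. Particles without neighbours are excluded from the cell mean.
#'
#' @param structure a [structure_3d()].
#' @param radius neighbour radius in model units (default 3 x particle
#'   radius).
#' @param homologs_distinct treat homologs as different chromosomes.
#' @return list with `values` (per particle, NA when no neighbours), `mean`
#'   (cell mean) and `n_isolated`.
#' @export
intermingling_index <- function(structure,
                                radius = 3 * particle_radius(structure),
                                homologs_distinct = FALSE) {
  st <- as.data.table(structure)
  if (length(unique(st$chrom)) < 2)
    warning("single-chromosome structure: intermingling is identically 0")
  nb <- neighbor_list(structure, radius)
  key <- if (homologs_distinct) paste(st$chrom, st$hap) else st$chrom
  n <- nrow(st)
  tot <- tabulate(nb$i, n) + tabulate(nb$j, n)
  foreign <- nb[key[i] != key[j]]
  frn <- tabulate(foreign$i, n) + tabulate(foreign$j, n)
  vals <- ifelse(tot > 0, frn / tot, NA_real_)
  list(values = vals, mean = mean(vals, na.rm = TRUE),
       n_isolated = sum(tot == 0))
}

#' Compartmentalization score
#'
#' Spearman correlation between each particle's own CpG frequency and the
#' mean CpG frequency of its spatial neighbours. High values mean CpG-rich
#' and CpG-poor chromatin occupy separate neighbourhoods (strong
#' compartmentalization).
#'
#' @param structure a [structure_3d()].
#' @param cpg a [cpg_track()].
#' @param radius neighbour radius (default 3 x particle radius).
#' @return Scalar score in `[-1, 1]`; 0 with attribute `degenerate = TRUE`
#'   when either variable is constant.
#' @export
compartment_score <- function(structure, cpg,
                              radius = 3 * particle_radius(structure)) {
  st <- as.data.table(structure)
  bs <- structure_bin_size(structure)
  v <- cpg_at(cpg, st$chrom, bin_of(st$pos, bs))
  if (anyNA(v))
    stop("CpG track missing bins: ",
         paste(utils::head(unique(paste0(st$chrom, ":", bin_of(st$pos, bs))[
           is.na(v)]), 5), collapse = ", "))
  nb <- neighbor_list(structure, radius)
  n <- nrow(st)
  cnt <- tabulate(nb$i, n) + tabulate(nb$j, n)
  sm <- numeric(n)
  agg_i <- nb[, .(s = sum(v[j])), by = i]
  agg_j <- nb[, .(s = sum(v[i])), by = j]
  sm[agg_i$i] <- sm[agg_i$i] + agg_i$s
  sm[agg_j$j] <- sm[agg_j$j] + agg_j$s
  ok <- cnt > 0
  if (sum(ok) < 10) stop("fewer than 10 particles with neighbours")
  own <- v[ok]
  nbm <- sm[ok] / cnt[ok]
  if (sd(own) == 0 || sd(nbm) == 0)
    return(structure(0, degenerate = TRUE))
  cor(own, nbm, method = "spearman")
}

#' Normalized radial positions
#'
#' Distance of every particle to the nuclear centre of mass, divided by the
#' cell's mean distance (so the output has mean exactly 1). Invariant to
#' rigid motions of the structure.
#'
#' @param structure a [structure_3d()].
#' @return Numeric vector, one value per particle, mean 1.
#' @export
radial_positions <- function(structure) {
  m <- coords_matrix(structure)
  ctr <- colMeans(m)
  r <- sqrt(rowSums(sweep(m, 2, ctr)^2))
  r / mean(r)
}

#' Radial CpG profile
#'
#' Mean CpG frequency in concentric spherical shells of normalized radius,
#' per cell and averaged (unweighted) over the cells of a cohort.
#'
#' @param structures list of [structure_3d()] (one cohort).
#' @param cpg a [cpg_track()].
#' @param n_shells number of equal-width shells (>= 2).
#' @return `data.table(shell, r_mid, mean_cpg, n_particles, n_cells)`;
#'   shells empty in every cell carry NA.
#' @export
radial_cpg_profile <- function(structures, cpg, n_shells = 20) {
  if (n_shells < 2) stop("need at least 2 shells")
  if (inherits(structures, "structure_3d")) structures <- list(structures)
  per_cell <- lapply(structures, function(s) {
    st <- as.data.table(s)
    v <- cpg_at(cpg, st$chrom, bin_of(st$pos, structure_bin_size(s)))
    r <- radial_positions(s)
    edges <- seq(0, max(r) + 1e-12, length.out = n_shells + 1)
    shell <- findInterval(r, edges, rightmost.closed = TRUE)
    data.table(shell = shell, cpg = v)[, .(mean_cpg = mean(cpg), n = .N),
                                       by = shell]
  })
  all <- rbindlist(per_cell, idcol = "cell")
  prof <- all[, .(mean_cpg = mean(mean_cpg), n_particles = sum(n),
                  n_cells = .N), by = shell]
  full <- data.table(shell = seq_len(n_shells))
  prof <- prof[full, on = "shell"]
  prof[, r_mid := (shell - 0.5) / n_shells]
  setorder(prof, shell)
  prof[, .(shell, r_mid, mean_cpg, n_particles, n_cells)]
}

#' Radial position vs CpG correlation
#'
#' For consecutive genomic bins (default 1 Mb, haplotypes pooled), computes
#' the mean normalized radial distance of the bin's particles and correlates
#' it with the bin's CpG frequency across the genome. Positive values mean
#' CpG-rich chromatin sits toward the periphery ("inside-out"); negative
#' values mean it sits toward the centre ("out-inside").
#'
#' @param structure a [structure_3d()].
#' @param cpg a [cpg_track()].
#' @param bin_size analysis bin size in bp (must be a multiple of the
#'   structure resolution).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Scalar correlation with attribute `table` (per-bin radii and
#'   CpG).
#' @export
radial_cpg_correlation <- function(structure, cpg, bin_size = 1e6,
                                   method = c("spearman", "pearson")) {
  method <- match.arg(method)
  bs <- structure_bin_size(structure)
  if (bin_size %% bs != 0)
    stop("analysis bin size must be a multiple of the structure resolution")
  st <- as.data.table(structure)
  st[, `:=`(abin = bin_of(pos, bin_size), r = radial_positions(structure))]
  tab <- st[, .(r = mean(r)), by = .(chrom, abin)]
  tab[, cpg := cpg_at(cpg, chrom, abin, bin_size = bin_size)]
  tab <- tab[!is.na(cpg)]
  if (nrow(tab) < 5) stop("fewer than 5 analysis bins")
  structure(cor(tab$r, tab$cpg, method = method), table = tab[])
}

#' Radial position of loci
#'
#' Maps each locus to the particles its interval overlaps (half-open
#' coordinates; zero-length loci take the bin containing their coordinate)
#' and reports the mean normalized radial position per haplotype and pooled.
#'
#' @param structure a [structure_3d()].
#' @param loci data.frame with columns `chrom`, `start`, `end`, `name` (BED4
#'   convention, e.g. from [read_loci_bed()]).
#' @return `data.table(name, chrom, hap, radial)`; `hap = "pooled"` rows
#'   average both homologs. Loci in coverage gaps give NA with a warning.
#' @export
locus_radial_position <- function(structure, loci) {
  st <- as.data.table(structure)
  bs <- structure_bin_size(structure)
  st[, `:=`(bin = bin_of(pos, bs), r = radial_positions(structure))]
  loci <- as.data.table(loci)
  out <- vector("list", nrow(loci))
  for (k in seq_len(nrow(loci))) {
    b0 <- bin_of(loci$start[k], bs)
    b1 <- if (loci$end[k] > loci$start[k])
      bin_of(loci$end[k] - 1, bs) else b0
    hit <- st[chrom == loci$chrom[k] & bin >= b0 & bin <= b1]
    if (nrow(hit) == 0) {
      warning("locus ", loci$name[k], " overlaps no particle")
      out[[k]] <- data.table(name = loci$name[k], chrom = loci$chrom[k],
                             hap = c("mat", "pat", "pooled"),
                             radial = NA_real_)
    } else {
      per <- hit[, .(radial = mean(r)), by = hap]
      out[[k]] <- rbind(
        data.table(name = loci$name[k], chrom = loci$chrom[k],
                   hap = per$hap, radial = per$radial),
        data.table(name = loci$name[k], chrom = loci$chrom[k],
                   hap = "pooled", radial = mean(hit$r)))
    }
  }
  rbindlist(out)
}

#' Serial cross-sections of a nucleus
#'
#' Partitions the particles into parallel slabs of the given spacing along
#' one axis (default 7.5 particle radii per slab), for section-by-section
#' visualisation of CpG-coloured structure.
#'
#' @param structure a [structure_3d()].
#' @param cpg optional [cpg_track()] to attach per-particle CpG values.
#' @param spacing slab thickness in model units.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return `data.table` of particles with a `slab` index (1-based, ordered
#'   along the axis); slabs partition all particles.
#' @export
cross_sections <- function(structure, cpg = NULL,
                           spacing = 7.5 * particle_radius(structure),
                           axis = c("z", "x", "y")) {
  if (spacing <= 0) stop("slab spacing must be positive")
  axis <- match.arg(axis)
  st <- copy(as.data.table(structure))
  a <- st[[axis]]
  st[, slab := pmin(floor((a - min(a)) / spacing) + 1L,
                    max(1L, ceiling((max(a) - min(a)) / spacing)))]
  if (!is.null(cpg))
    st[, cpg := cpg_at(cpg, chrom, bin_of(pos, structure_bin_size(structure)))]
  setorder(st, slab)
  st[]
}
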