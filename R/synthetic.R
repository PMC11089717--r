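#' Toy diploid genome and CpG track
#'
#' Generates a small genome and a smooth, strictly positive CpG-frequency
#' track with contiguous CpG-rich and CpG-poor domains (log-normal of a
#' moving-average-smoothed Gaussian), so that compartment-like architecture
#' can be planted in simulated nuclei.
#'
#' The default scale (20 chromosomes of 15 Mb at 1-Mb bins, 600 diploid
#' particles) keeps every chromosome long relative to the 10-Mb imputation
#' neighbourhood while holding the whole-cell particle count at desk scale.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param bin_size bin size in bp.
#' @param cpg_mean mean CpG frequency (dimensionless, per-bin density).
#' @param cpg_sd_log log-scale standard deviation of the CpG process
#'   (0 gives a constant track).
#' @param cpg_smooth moving-average half-width in bins controlling domain
#'   size.
#' @param seed RNG seed (deterministic output for a fixed seed).
#' @return `list(genome = genome_spec, cpg = cpg_track)`.
#' @examples
#' toy <- make_toy_genome(n_chrom = 3, chrom_length = 2e6, bin_size = 2e4,
#'                        seed = 1)
#' range(toy$cpg$cpg)
#' @export
make_toy_genome <- function(n_chrom = 20, chrom_length = 15e6, bin_size = 1e6,
                            cpg_mean = 0.02, cpg_sd_log = 0.6, cpg_smooth = 2,
                            seed = 1) {
  stopifnot(n_chrom >= 1, chrom_length > 0, bin_size > 0)
  genome <- genome_spec(stats::setNames(rep(chrom_length, n_chrom),
                                        paste0("chr", seq_len(n_chrom))),
                        bin_size)
  nb <- n_bins(genome)
  if (any(nb == 0)) stop("chromosomes must contain at least one bin")
  vals <- with_seed(seed, lapply(nb, function(n) {
    if (cpg_sd_log == 0) return(rep(cpg_mean, n))
    w <- 2L * as.integer(cpg_smooth) + 1L
    raw <- rnorm(n + w - 1L)
    sm <- as.numeric(stats::filter(raw, rep(1 / w, w), sides = 2))
    sm <- sm[!is.na(sm)][seq_len(n)]
    zs <- (sm - mean(sm)) / max(sd(sm), 1e-12)
    cpg_mean * exp(cpg_sd_log * zs - cpg_sd_log^2 / 2)
  }))
  list(genome = genome, cpg = cpg_track(genome, vals))
}

#' Simulator cell archetype
#'
#' Parameter bundle defining one simulated cell type. `naive_like` plants an
#' "out-inside" nucleus (CpG-rich chromatin toward the centre, strong
#' chromosome territories); `primed_like` plants an "inside-out" nucleus
#' (CpG-rich chromatin toward the periphery, weak territories, hence more
#' intermingling and more interchromosomal contacts).
#'
#' @param name `"naive_like"`, `"primed_like"` or `"custom"`.
#' @param radial_cpg_sign -1 (CpG-rich toward centre) or +1 (toward
#'   periphery).
#' @param radial_bias_strength dimensionless >= 0; 0 removes the radial bias.
#' @param territory_strength dimensionless >= 0; larger values give more
#'   compact, less intermingled chromosome territories.
#' @param n_contacts contacts sampled per cell.
#' @param capture_radius proximity-ligation capture radius in model units
#'   (bond length = 1).
#' @param phase_rate probability that a leg's haplotype is observed.
#' @param seed per-cell RNG seed (NULL = use current RNG state).
#' @return A `cell_archetype` list.
#' @export
cell_archetype <- function(name = c("custom", "naive_like", "primed_like"),
                           radial_cpg_sign = NULL,
                           radial_bias_strength = NULL,
                           territory_strength = NULL,
                           n_contacts = 20000, capture_radius = 2.5,
                           phase_rate = 0.3, seed = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    naive_like  = list(sign = -1, bias = 4, territory = 6),
    primed_like = list(sign = +1, bias = 4, territory = 0.5),
    custom      = list(sign = +1, bias = 0, territory = 1))
  a <- list(name = name,
            radial_cpg_sign = radial_cpg_sign %||% defaults$sign,
            radial_bias_strength = radial_bias_strength %||% defaults$bias,
            territory_strength = territory_strength %||% defaults$territory,
            n_contacts = n_contacts, capture_radius = capture_radius,
            phase_rate = phase_rate, seed = seed)
  stopifnot(a$radial_cpg_sign %in% c(-1, 1), a$radial_bias_strength >= 0,
            a$territory_strength >= 0, a$n_contacts >= 0,
            a$capture_radius > 0, a$phase_rate >= 0, a$phase_rate <= 1)
  class(a) <- "cell_archetype"
  a
}

# run code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                                envir = globalenv()))
          else assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

# nucleus radius giving the requested particle volume fraction
nucleus_radius <- function(n_particles, particle_r = 0.5, packing = 0.12) {
  (n_particles * particle_r^3 / packing)^(1 / 3)
}

#' Simulate one diploid nucleus structure
#'
#' Each chromosome copy is laid down as a confined random walk and relaxed by
#' Metropolis sampling under three energy terms: harmonic backbone bonds, a
#' radial CpG bias of the archetype's sign and strength, and a harmonic
#' attraction of every particle to its chromosome copy's anchor point
#' (territory formation). The nucleus is a hard sphere whose radius is set
#' from the particle count at a fixed packing fraction.
#'
#' @param genome a [genome_spec()].
#' @param cpg a [cpg_track()] at the genome's bin size.
#' @param archetype a [cell_archetype()].
#' @param cell_id cell identifier.
#' @param bond backbone bond length (model units); the particle radius is
#'   `bond / 2`.
#' @param packing nuclear particle volume fraction (> 0.4 is rejected as
#'   infeasible packing).
#' @param sweeps Metropolis sweeps.
#' @param step proposal step size in model units.
#' @return A [structure_3d()] with one particle per (chromosome, haplotype,
#'   bin).
#' @export
simulate_structure <- function(genome, cpg, archetype, cell_id = "cell",
                               bond = 1, packing = 0.15, sweeps = 400,
                               step = 0.35) {
  stopifnot(inherits(archetype, "cell_archetype"))
  nb <- n_bins(genome)
  grid <- data.table(chrom = rep(rep(genome$chroms, nb), 2),
                     hap = rep(c("mat", "pat"), each = sum(nb)),
                     bin = rep(unlist(lapply(nb, seq_len)) - 1L, 2))
  grid[, chain := as.integer(factor(paste(chrom, hap),
                                    levels = unique(paste(chrom, hap)))) - 1L]
  setorder(grid, chain, bin)
  n <- nrow(grid)
  if (packing > 0.4)
    stop("infeasible packing: nucleus too small for ", n, " particles")
  nuc_r <- nucleus_radius(n, bond / 2, packing)

  cz <- cpg_at(cpg, grid$chrom, grid$bin)
  cz <- (cz - mean(cz)) / max(sd(cz), 1e-12)

  coords <- with_seed(archetype$seed, {
    pos <- matrix(0, n, 3)
    for (ch in unique(grid$chain)) {
      idx <- which(grid$chain == ch)
      # seeded start well inside the wall
      p <- stats::runif(3, -1, 1)
      p <- p / sqrt(sum(p^2)) * stats::runif(1)^(1 / 3) * 0.7 * nuc_r
      pos[idx[1], ] <- p
      for (k in idx[-1]) {
        repeat {
          d <- rnorm(3)
          q <- p + d / sqrt(sum(d^2)) * bond
          if (sum(q^2) < nuc_r^2) break
        }
        p <- q
        pos[k, ] <- p
      }
    }
    anchors <- do.call(rbind, lapply(split(seq_len(n), grid$chain),
                                     function(i) colMeans(pos[i, , drop = FALSE])))
    n_chains <- length(unique(grid$chain))
    territory_r2 <- (nuc_r / n_chains^(1 / 3))^2
    cpp_relax_chains(pos, grid$chain, cz, anchors, bond, nuc_r,
                     archetype$radial_cpg_sign * archetype$radial_bias_strength,
                     archetype$territory_strength, territory_r2,
                     as.integer(sweeps), step, 20)
  })

  structure_3d(data.table(chrom = grid$chrom, hap = grid$hap,
                          pos = grid$bin * genome$bin_size,
                          x = coords[, 1], y = coords[, 2], z = coords[, 3]),
               bin_size = genome$bin_size, radius = bond / 2,
               cell_id = cell_id, genome = genome)
}

#' Sample proximity contacts from a truth structure
#'
#' Contacts are drawn uniformly (with replacement) from all unordered
#' particle pairs within `capture_radius`, excluding self pairs and
#' immediate backbone neighbours. Leg coordinates get a uniform offset
#' within the particle's bin; each leg's haplotype is observed independently
#' with probability `phase_rate`, otherwise reported unknown. The true
#' haplotypes of every contact are recorded.
#'
#' @param structure a [structure_3d()] truth structure.
#' @param archetype a [cell_archetype()].
#' @param genome a [genome_spec()].
#' @param cell_id cell identifier.
#' @return `list(contacts = contact_set (stage "raw"),
#'   truth = data.table(id, hap_a, hap_b))`.
#' @export
sample_contacts <- function(structure, archetype, genome,
                            cell_id = attr(structure, "cell_id")) {
  st <- as.data.table(structure)
  prs <- cpp_neighbor_pairs(coords_matrix(structure), archetype$capture_radius)
  i <- prs$i + 1L
  j <- prs$j + 1L
  same_copy <- st$chrom[i] == st$chrom[j] & st$hap[i] == st$hap[j]
  adjacent <- same_copy &
    abs(st$pos[i] - st$pos[j]) <= structure_bin_size(structure)
  keep <- !adjacent
  if (!any(keep))
    stop("no eligible particle pairs within the capture radius")
  i <- i[keep]; j <- j[keep]

  bs <- structure_bin_size(structure)
  # offset the per-cell seed so the contact stage does not replay the RNG
  # stream already consumed by the structure stage
  out <- with_seed(if (is.null(archetype$seed)) NULL else archetype$seed + 1L,
    {
      pick <- sample.int(length(i), archetype$n_contacts, replace = TRUE)
      a <- i[pick]; b <- j[pick]
      off_a <- floor(stats::runif(length(a)) * bs)
      off_b <- floor(stats::runif(length(b)) * bs)
      pos_a <- pmin(st$pos[a] + off_a, genome$lengths[st$chrom[a]] - 1)
      pos_b <- pmin(st$pos[b] + off_b, genome$lengths[st$chrom[b]] - 1)
      seen_a <- stats::runif(length(a)) < archetype$phase_rate
      seen_b <- stats::runif(length(b)) < archetype$phase_rate
      data.table(chr_a = st$chrom[a], pos_a = pos_a,
                 hap_a = ifelse(seen_a, st$hap[a], "unknown"),
                 true_a = st$hap[a],
                 chr_b = st$chrom[b], pos_b = pos_b,
                 hap_b = ifelse(seen_b, st$hap[b], "unknown"),
                 true_b = st$hap[b])
    })
  # canonicalize legs together with their recorded truth
  ia <- chrom_index(genome, out$chr_a)
  ib <- chrom_index(genome, out$chr_b)
  ha <- hap_to_int(out$hap_a); hb <- hap_to_int(out$hap_b)
  swap <- (ia > ib) | (ia == ib & out$pos_a > out$pos_b) |
    (ia == ib & out$pos_a == out$pos_b & ha > hb)
  if (any(swap)) {
    tmp <- out[swap, .(chr_a, pos_a, hap_a, true_a)]
    out[swap, `:=`(chr_a = chr_b, pos_a = pos_b, hap_a = hap_b,
                   true_a = true_b)]
    out[swap, `:=`(chr_b = tmp$chr_a, pos_b = tmp$pos_a, hap_b = tmp$hap_a,
                   true_b = tmp$true_a)]
  }
  out[, id := seq_len(.N)]
  contacts <- contact_set(out[, .(id, chr_a, pos_a, hap_a, chr_b, pos_b,
                                  hap_b)],
                          genome, cell_id = cell_id, stage = "raw")
  list(contacts = contacts,
       truth = out[, .(id, hap_a = true_a, hap_b = true_b)])
}

#' Simulate a cohort of cells
#'
#' Generates `n_cells` cells per archetype with per-cell seeds derived
#' deterministically from `base_seed`, returning per-cell truth structures,
#' contact sets and truth records plus a cohort manifest.
#'
#' @param genome a [genome_spec()].
#' @param cpg a [cpg_track()].
#' @param archetypes named list of [cell_archetype()]s (names label the
#'   cohorts).
#' @param n_cells cells per archetype.
#' @param base_seed base RNG seed.
#' @param ... further arguments passed to [simulate_structure()].
#' @return `list(cells = named list of list(structure, contacts, truth),
#'   manifest = data.table(cell_id, archetype, seed))`.
#' @export
simulate_cohort <- function(genome, cpg,
                            archetypes = list(
                              naive_like = cell_archetype("naive_like"),
                              primed_like = cell_archetype("primed_like")),
                            n_cells = 5, base_seed = 1, ...) {
  stopifnot(n_cells >= 1)
  manifest <- data.table(cell_id = character(), archetype = character(),
                         seed = integer())
  cells <- list()
  k <- 0L
  for (an in names(archetypes)) {
    for (ci in seq_len(n_cells)) {
      k <- k + 1L
      seed <- as.integer((as.numeric(base_seed) * 10007 + k * 7919) %%
                           2147483647)
      cid <- sprintf("%s_%02d", an, ci)
      if (cid %in% names(cells)) stop("duplicate cell id: ", cid)
      arch <- archetypes[[an]]
      arch$seed <- seed
      s <- simulate_structure(genome, cpg, arch, cell_id = cid, ...)
      sc <- sample_contacts(s, arch, genome, cell_id = cid)
      cells[[cid]] <- list(structure = s, contacts = sc$contacts,
                           truth = sc$truth, archetype = an)
      manifest <- rbind(manifest,
                        data.table(cell_id = cid, archetype = an, seed = seed))
    }
  }
  list(cells = cells, manifest = manifest)
}

#' Synthetic contacts with planted A/B compartments
#'
#' Builds a single-chromosome genome whose bins carry planted compartment
#' labels (contiguous blocks of alternating A/B), a CpG track elevated in A
#' bins, and a pooled contact list in which same-compartment bin pairs are
#' contact-enriched over a power-law distance decay. Used to validate A/B
#' calling against a known truth.
#'
#' @param n_bins number of 1-Mb bins.
#' @param n_contacts contacts to sample.
#' @param boost multiplicative within-compartment contact enrichment.
#' @param decay distance-decay exponent.
#' @param block_min,block_max compartment block sizes in bins.
#' @param seed RNG seed.
#' @return `list(genome, cpg, contacts, labels)` where `labels` is +1 (A) /
#'   -1 (B) per bin.
#' @export
simulate_compartment_contacts <- function(n_bins = 60, n_contacts = 40000,
                                          boost = 4, decay = 1,
                                          block_min = 3, block_max = 8,
                                          seed = 1) {
  bs <- 1e6
  genome <- genome_spec(c(chr1 = n_bins * bs), bs)
  with_seed(seed, {
    labels <- integer(0)
    lab <- 1L
    while (length(labels) < n_bins) {
      labels <- c(labels, rep(lab, sample(block_min:block_max, 1)))
      lab <- -lab
    }
    labels <- labels[seq_len(n_bins)]
    cpgv <- ifelse(labels > 0, 0.03, 0.01) * exp(rnorm(n_bins, 0, 0.1))
    cpg <- cpg_track(genome, list(cpgv))
    pr <- expand.grid(i = seq_len(n_bins), j = seq_len(n_bins))
    pr <- pr[pr$j > pr$i, ]
    w <- (1 + (boost - 1) * (labels[pr$i] == labels[pr$j])) /
      (abs(pr$i - pr$j))^decay
    pick <- sample.int(nrow(pr), n_contacts, replace = TRUE, prob = w)
    dt <- data.table(chr_a = "chr1",
                     pos_a = (pr$i[pick] - 1) * bs +
                       floor(stats::runif(n_contacts) * bs),
                     hap_a = "unknown",
                     chr_b = "chr1",
                     pos_b = (pr$j[pick] - 1) * bs +
                       floor(stats::runif(n_contacts) * bs),
                     hap_b = "unknown")
    list(genome = genome, cpg = cpg,
         contacts = contact_set(dt, genome, cell_id = "pooled"),
         labels = labels)
  })
}
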