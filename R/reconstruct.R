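#' Annealing schedule
#'
#' Controls the simulated-annealing reconstruction: a strictly decreasing
#' geometric temperature ladder and a multi-resolution ladder of bin-size
#' multipliers. Multipliers `>= 1` are coarse stages (the model is built at
#' `multiplier * bin_size` and the solution seeds the next stage through
#' backbone interpolation); multipliers `< 1` are refinement passes at the
#' base resolution with the starting temperature scaled down by the
#' multiplier.
#'
#' @param n_temps number of temperature steps per stage (default 20).
#' @param ladder resolution ladder (default `c(8, 4, 2, 0.4, 0.2, 0.1)`).
#' @param sweeps_per_temp Metropolis sweeps per temperature step.
#' @param t_hi,t_lo top and bottom of the temperature ladder.
#' @param seed RNG seed for the anneal.
#' @return An `anneal_schedule`.
#' @export
anneal_schedule <- function(n_temps = 20, ladder = c(8, 4, 2, 0.4, 0.2, 0.1),
                            sweeps_per_temp = 40, t_hi = 4, t_lo = 0.02,
                            seed = 1) {
  stopifnot(n_temps >= 2, t_hi > t_lo, t_lo > 0, all(ladder > 0),
            !is.unsorted(rev(pmax(ladder, 1))))
  structure(list(n_temps = as.integer(n_temps), ladder = ladder,
                 sweeps_per_temp = as.integer(sweeps_per_temp),
                 t_hi = t_hi, t_lo = t_lo, seed = seed),
            class = "anneal_schedule")
}

temp_ladder <- function(schedule, scale = 1) {
  exp(seq(log(schedule$t_hi * scale), log(schedule$t_lo),
          length.out = schedule$n_temps))
}

#' Build a restraint set from haplotype-resolved contacts
#'
#' Every fully phased contact becomes an upper-bound distance restraint
#' between its two (chromosome, haplotype, bin) particles; duplicate
#' particle pairs collapse to a single restraint whose weight is the
#' multiplicity. Harmonic backbone restraints connect consecutive bins of
#' each chromosome copy, and a soft spherical wall confines the nucleus.
#' Contacts with unknown haplotypes are excluded and counted.
#'
#' @param contacts a [contact_set()].
#' @param genome a [genome_spec()].
#' @param bin_size model resolution in bp.
#' @param bond backbone bond length in model units at this resolution.
#' @param contact_dist restraint target distance (model units).
#' @param packing nuclear volume fraction fixing the confinement radius.
#' @return A `restraint_set` list (particles, bonds, contacts, radii,
#'   exclusion counts).
#' @export
build_restraints <- function(contacts, genome, bin_size = genome$bin_size,
                             bond = 1, contact_dist = 2, packing = 0.12) {
  dt <- as.data.table(contacts)
  n_total <- nrow(dt)
  dt <- dt[hap_a != "unknown" & hap_b != "unknown"]
  if (nrow(dt) == 0)
    stop("zero usable contacts: 100% of ", n_total,
         " contacts have unknown haplotypes")
  nb <- n_bins(genome, bin_size)
  particles <- data.table(chrom = rep(rep(genome$chroms, nb), 2),
                          hap = rep(c("mat", "pat"), each = sum(nb)),
                          bin = rep(unlist(lapply(nb, seq_len)) - 1L, 2))
  particles[, chain := as.integer(factor(paste(chrom, hap),
                                         levels = unique(paste(chrom, hap)))) - 1L]
  setorder(particles, chain, bin)
  particles[, idx := .I]
  key <- function(chrom, hap, bin) paste(chrom, hap, bin, sep = ":")
  lookup <- stats::setNames(particles$idx,
                            key(particles$chrom, particles$hap, particles$bin))
  ia <- lookup[key(dt$chr_a, dt$hap_a, bin_of(dt$pos_a, bin_size))]
  ib <- lookup[key(dt$chr_b, dt$hap_b, bin_of(dt$pos_b, bin_size))]
  cr <- data.table(i = pmin(ia, ib), j = pmax(ia, ib))[i != j,
                                                       .(weight = .N),
                                                       by = .(i, j)]
  bonds <- particles[, if (.N > 1) list(i = idx[-.N], j = idx[-1]),
                     by = chain]
  bonds <- if (nrow(bonds)) bonds[, .(i, j)] else
    data.table(i = integer(), j = integer())
  list(particles = particles[, .(chrom, hap, bin, chain)],
       bonds = bonds, contacts = cr,
       bond = bond, contact_dist = contact_dist,
       nuc_radius = nucleus_radius(nrow(particles), bond / 2, packing),
       bin_size = bin_size,
       n_excluded = n_total - nrow(dt))
}

#' Simulated-annealing structure optimisation
#'
#' Minimises the restraint energy (harmonic backbone + half-harmonic
#' upper-bound contacts + soft spherical confinement) by Metropolis descent
#' over a decreasing temperature ladder. Deterministic under the schedule's
#' seed; solutions are defined up to a global rigid motion and reflection.
#'
#' @param restraints a [build_restraints()] result.
#' @param schedule an [anneal_schedule()].
#' @param init optional starting coordinate matrix (defaults to seeded
#'   confined random walks per chromosome copy).
#' @param t_scale multiplier on the starting temperature.
#' @param cell_id cell identifier for the output structure.
#' @return A [structure_3d()] with attribute `energy` (per-step trace).
#' @export
anneal <- function(restraints, schedule = anneal_schedule(), init = NULL,
                   t_scale = 1, cell_id = "cell") {
  p <- restraints$particles
  n <- nrow(p)
  with_seed(schedule$seed, {
    if (is.null(init)) {
      init <- matrix(0, n, 3)
      for (ch in unique(p$chain)) {
        idx <- which(p$chain == ch)
        q <- stats::runif(3, -0.5, 0.5) * restraints$nuc_radius
        init[idx[1], ] <- q
        for (k in idx[-1]) {
          d <- rnorm(3)
          q <- q + d / sqrt(sum(d^2)) * restraints$bond
          init[k, ] <- q
        }
      }
    }
    res <- cpp_anneal(init,
                      restraints$bonds$i - 1L, restraints$bonds$j - 1L,
                      rep(restraints$bond, nrow(restraints$bonds)), 10,
                      restraints$contacts$i - 1L, restraints$contacts$j - 1L,
                      rep(restraints$contact_dist, nrow(restraints$contacts)),
                      as.numeric(restraints$contacts$weight), 1,
                      restraints$nuc_radius, 5,
                      restraints$bond, 4,  # excluded volume: 2 particle radii
                      temp_ladder(schedule, t_scale),
                      schedule$sweeps_per_temp, 0.4)
    s <- structure_3d(data.table(chrom = p$chrom, hap = p$hap,
                                 pos = p$bin * restraints$bin_size,
                                 x = res$coords[, 1], y = res$coords[, 2],
                                 z = res$coords[, 3]),
                      bin_size = restraints$bin_size,
                      radius = restraints$bond / 2, cell_id = cell_id)
    data.table::setattr(s, "energy", res$energy)
    s
  })
}

# seed a fine-resolution model by interpolating a coarse solution along the
# backbone (plus a small deterministic-free jitter supplied by the caller's
# RNG state via anneal(); here we only interpolate)
interpolate_structure <- function(coarse, particles, bin_size) {
  cs <- as.data.table(coarse)
  ratio <- structure_bin_size(coarse) / bin_size
  out <- matrix(0, nrow(particles), 3)
  for (ch in unique(particles$chain)) {
    idx <- which(particles$chain == ch)
    pp <- particles[idx]
    cc <- cs[chrom == pp$chrom[1] & hap == pp$hap[1]][order(pos)]
    cb <- cc$pos / structure_bin_size(coarse)       # coarse bin indices
    fb <- pp$bin / ratio                            # fine bins on coarse axis
    for (d in 1:3) {
      v <- cc[[c("x", "y", "z")[d]]]
      out[idx, d] <- if (nrow(cc) == 1) v else
        stats::approx(cb, v, xout = pmin(pmax(fb, min(cb)), max(cb)))$y
    }
  }
  out
}

#' Structure-based haplotype imputation
#'
#' For every contact with exactly one unknown leg, compares the distances
#' from the two candidate homolog particles to the partner leg's particle
#' and assigns the nearer homolog when the distance ratio (nearer / farther)
#' is at most `rho`; otherwise the leg stays unknown. Contacts with both
#' legs unknown are skipped.
#'
#' @param contacts a [contact_set()].
#' @param structure a [structure_3d()] covering the contact bins.
#' @param rho acceptance ratio threshold (default 0.5).
#' @return The contacts with additional legs resolved.
#' @export
impute3d <- function(contacts, structure, rho = 0.5) {
  dt <- copy(as.data.table(contacts))
  st <- as.data.table(structure)
  bs <- structure_bin_size(structure)
  st[, bin := as.integer(pos / bs)]
  one_unknown <- xor(dt$hap_a == "unknown", dt$hap_b == "unknown")
  if (!any(one_unknown)) return(rewrap_contacts(dt, contacts))
  w <- which(one_unknown)
  a_unknown <- dt$hap_a[w] == "unknown"
  kn_chr <- ifelse(a_unknown, dt$chr_b[w], dt$chr_a[w])
  kn_hap <- ifelse(a_unknown, dt$hap_b[w], dt$hap_a[w])
  kn_bin <- bin_of(ifelse(a_unknown, dt$pos_b[w], dt$pos_a[w]), bs)
  un_chr <- ifelse(a_unknown, dt$chr_a[w], dt$chr_b[w])
  un_bin <- bin_of(ifelse(a_unknown, dt$pos_a[w], dt$pos_b[w]), bs)
  get_xyz <- function(chrom, hap, bin) {
    q <- data.table(chrom = chrom, hap = hap, bin = bin)
    m <- st[q, on = c("chrom", "hap", "bin")]
    cbind(m$x, m$y, m$z)
  }
  pk <- get_xyz(kn_chr, kn_hap, kn_bin)
  pm <- get_xyz(un_chr, rep("mat", length(w)), un_bin)
  pp <- get_xyz(un_chr, rep("pat", length(w)), un_bin)
  dmat <- sqrt(rowSums((pm - pk)^2))
  dpat <- sqrt(rowSums((pp - pk)^2))
  lo <- pmin(dmat, dpat)
  hi <- pmax(dmat, dpat)
  assign <- is.finite(lo) & is.finite(hi) & hi > 0 & lo / hi <= rho
  newhap <- ifelse(dmat <= dpat, "mat", "pat")
  ia <- w[assign & a_unknown]
  ib <- w[assign & !a_unknown]
  if (length(ia)) dt[ia, hap_a := newhap[assign & a_unknown]]
  if (length(ib)) dt[ib, hap_b := newhap[assign & !a_unknown]]
  rewrap_contacts(dt, contacts)
}

#' Multi-resolution structure reconstruction
#'
#' Runs the schedule's resolution ladder: for every multiplier `>= 1` the
#' model is rebuilt at `multiplier * bin_size` and annealed (the previous
#' stage's solution, interpolated along the backbone, seeds the next); for
#' multipliers `< 1` the base-resolution model is refined with the starting
#' temperature scaled by the multiplier.
#'
#' @param contacts a (partially) haplotype-resolved [contact_set()].
#' @param genome a [genome_spec()].
#' @param bin_size base model resolution in bp.
#' @param schedule an [anneal_schedule()].
#' @param cell_id cell identifier.
#' @return A [structure_3d()] with attribute `energy` (final stage trace).
#' @export
reconstruct_structure <- function(contacts, genome,
                                  bin_size = genome$bin_size,
                                  schedule = anneal_schedule(),
                                  cell_id = attr(contacts, "cell_id",
                                                 exact = TRUE) %||% "cell") {
  s <- NULL
  for (k in seq_along(schedule$ladder)) {
    m <- schedule$ladder[k]
    bs <- bin_size * max(m, 1)
    bond <- sqrt(bs / bin_size)  # random-walk scaling of the bond length
    rs <- build_restraints(contacts, genome, bin_size = bs, bond = bond,
                           contact_dist = 2 * bond)
    sched <- schedule
    sched$seed <- schedule$seed + k
    init <- NULL
    t_scale <- if (m < 1) m else 1
    if (!is.null(s)) init <- interpolate_structure(s, rs$particles, bs)
    s <- anneal(rs, sched, init = init, t_scale = t_scale, cell_id = cell_id)
  }
  s
}

#' Full 3D reconstruction pipeline
#'
#' Alternates multi-resolution reconstruction with structure-based haplotype
#' imputation: `coarse_rounds` rounds at `coarse_bin` resolution, then
#' `fine_rounds` rounds at `fine_bin` resolution, re-imputing after every
#' round. Each round rebuilds restraints from the currently resolved
#' contacts, so newly imputed contacts sharpen the next structure.
#'
#' @param contacts cleaned, (partially) haplotype-resolved [contact_set()].
#' @param genome a [genome_spec()].
#' @param coarse_bin,fine_bin model resolutions in bp.
#' @param coarse_rounds,fine_rounds round counts (defaults 3 and 2).
#' @param schedule an [anneal_schedule()].
#' @param rho [impute3d()] acceptance ratio.
#' @param verbose print per-round progress.
#' @return The final fine-resolution [structure_3d()], with attributes
#'   `contacts` (the contact set after 3D imputation) and `rounds`
#'   (per-round log).
#' @export
reconstruct_pipeline <- function(contacts, genome,
                                 coarse_bin = 5 * genome$bin_size,
                                 fine_bin = genome$bin_size,
                                 coarse_rounds = 3, fine_rounds = 2,
                                 schedule = anneal_schedule(), rho = 0.5,
                                 verbose = FALSE) {
  cur <- contacts
  log <- data.table(round = integer(), bin_size = numeric(),
                    energy = numeric(), newly_imputed = integer())
  plan <- c(rep(coarse_bin, coarse_rounds), rep(fine_bin, fine_rounds))
  if (length(plan) == 0) stop("at least one reconstruction round is required")
  s <- NULL
  for (r in seq_along(plan)) {
    bs <- plan[r]
    sched <- schedule
    sched$seed <- schedule$seed + 100 * r
    s <- reconstruct_structure(cur, genome, bin_size = bs, schedule = sched,
                               cell_id = attr(contacts, "cell_id",
                                              exact = TRUE) %||% "cell")
    before <- sum(cur$hap_a == "unknown") + sum(cur$hap_b == "unknown")
    cur <- impute3d(cur, s, rho = rho)
    after <- sum(cur$hap_a == "unknown") + sum(cur$hap_b == "unknown")
    en <- attr(s, "energy", exact = TRUE)
    log <- rbind(log, data.table(round = r, bin_size = bs,
                                 energy = en[length(en)],
                                 newly_imputed = before - after))
    if (verbose)
      message(sprintf("round %d: bin %s, energy %.1f, +%d legs imputed",
                      r, format(bs, big.mark = ","), en[length(en)],
                      before - after))
  }
  data.table::setattr(s, "contacts", cur)
  data.table::setattr(s, "rounds", log)
  s
}
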