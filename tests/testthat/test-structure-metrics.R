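lattice_structure <- function(n_side = 6, chroms = c("chr1", "chr2")) {
  # two chromosomes' particles alternating on a dense cubic lattice
  grid <- expand.grid(x = seq_len(n_side), y = seq_len(n_side),
                      z = seq_len(n_side))
  n <- nrow(grid)
  chrom <- rep(chroms, length.out = n)
  structure_3d(data.frame(chrom = chrom, hap = "mat",
                          pos = (ave(seq_len(n), chrom, FUN = seq_along) - 1) *
                            1e6,
                          x = grid$x, y = grid$y, z = grid$z),
               bin_size = 1e6, radius = 0.5)
}

test_that("intermingling index matches direct neighbour counting", {
  # a single chromosome copy has no foreign particles
  s1 <- structure_3d(data.frame(chrom = "chr1", hap = "mat",
                                pos = (0:9) * 1e6, x = 0:9, y = 0, z = 0),
                     1e6)
  expect_warning(ii <- intermingling_index(s1), "single-chromosome")
  expect_true(all(ii$values[!is.na(ii$values)] == 0))

  # alternating lattice with a radius enclosing everything:
  # every particle sees all others, so the index is N_other / (N - 1)
  s <- lattice_structure()
  n <- nrow(s)
  big <- intermingling_index(s, radius = 100)
  expect_equal(big$values,
               rep(c(sum(s$chrom == "chr2"), sum(s$chrom == "chr1")) /
                     (n - 1), length.out = n),
               tolerance = 1e-12)

  # two territories separated by more than the radius never mix
  far <- structure_3d(data.frame(
    chrom = rep(c("chr1", "chr2"), each = 10), hap = "mat",
    pos = rep((0:9) * 1e6, 2),
    x = c(1:10 * 0.1, 1:10 * 0.1 + 100), y = 0, z = 0), 1e6)
  ii <- intermingling_index(far, radius = 2)
  expect_true(all(ii$values[!is.na(ii$values)] == 0))

  # homologs count as the same chromosome by default, foreign when asked
  homo <- structure_3d(data.frame(
    chrom = "chr1", hap = rep(c("mat", "pat"), each = 5),
    pos = rep((0:4) * 1e6, 2), x = runif(10), y = runif(10), z = runif(10)),
    1e6)
  expect_warning(expect_equal(intermingling_index(homo, radius = 5)$mean, 0))
  expect_gt(suppressWarnings(
    intermingling_index(homo, radius = 5, homologs_distinct = TRUE)$mean), 0)
})

test_that("compartment score detects spatial CpG sorting", {
  g <- genome_spec(c(chr1 = 40e6, chr2 = 40e6), 1e6)
  # plant: CpG-rich bins clustered at one end of a line, CpG-poor at the other
  vals <- c(seq(0.05, 0.01, length.out = 40),
            seq(0.05, 0.01, length.out = 40))
  cpg <- cpg_track(g, list(vals[1:40], vals[41:80]))
  sorted <- structure_3d(data.frame(
    chrom = rep(c("chr1", "chr2"), each = 40), hap = "mat",
    pos = rep((0:39) * 1e6, 2),
    x = c(1:40, 1:40) + withr::with_seed(1, runif(80, 0, 0.3)),
    y = withr::with_seed(2, runif(80)), z = 0), 1e6)
  expect_gt(as.numeric(compartment_score(sorted, cpg, radius = 3)), 0.8)
  # random permutation of CpG over positions has no compartment signal
  nulls <- sapply(1:20, function(s) {
    perm <- withr::with_seed(s, sample(80))
    cpg2 <- cpg_track(g, list(vals[perm][1:40], vals[perm][41:80]))
    as.numeric(compartment_score(sorted, cpg2, radius = 3))
  })
  expect_lt(abs(mean(nulls)), 0.2)
  # constant track: degenerate zero
  cflat <- cpg_track(g, list(rep(0.02, 40), rep(0.02, 40)))
  sc <- compartment_score(sorted, cflat, radius = 3)
  expect_equal(as.numeric(sc), 0)
  expect_true(attr(sc, "degenerate"))
})

test_that("radial positions are mean-1 normalized and rigid-motion invariant", {
  st <- fixture_cohort(1)$cells[[1]]$structure
  r <- radial_positions(st)
  expect_equal(mean(r), 1, tolerance = 1e-12)
  moved <- transform_structure(st, random_rotation(), c(5, -3, 2))
  expect_equal(radial_positions(moved), r, tolerance = 1e-9)
  # particles at centroid distances 1, 1, 3, 3 normalize to 0.5 and 1.5
  four <- structure_3d(data.frame(chrom = "chr1",
                                  hap = rep(c("mat", "pat"), 2),
                                  pos = rep(c(0, 1e6), each = 2),
                                  x = c(-1, 1, -3, 3), y = 0, z = 0), 1e6)
  expect_equal(sort(radial_positions(four)), c(0.5, 0.5, 1.5, 1.5))
})

test_that("radial CpG profiles recover the planted architectures", {
  toy <- fixture_toy()
  co <- fixture_cohort(1)
  naive <- lapply(co$cells[co$manifest$archetype == "naive_like"],
                  `[[`, "structure")
  primed <- lapply(co$cells[co$manifest$archetype == "primed_like"],
                   `[[`, "structure")
  pn <- radial_cpg_profile(naive, toy$cpg, n_shells = 8)
  pp <- radial_cpg_profile(primed, toy$cpg, n_shells = 8)
  mid <- !is.na(pn$mean_cpg) & pn$shell >= 2 & pn$shell <= 7
  # naive: CpG falls outward; primed: CpG rises outward
  expect_lt(cor(pn$shell[mid], pn$mean_cpg[mid]), 0)
  expect_gt(cor(pp$shell[mid & !is.na(pp$mean_cpg)],
                pp$mean_cpg[mid & !is.na(pp$mean_cpg)]), 0)
  # one all-covering shell reduces to the global mean
  one <- radial_cpg_profile(naive[[1]], toy$cpg, n_shells = 2)
  stx <- data.table::as.data.table(naive[[1]])
  v <- cpg_at(toy$cpg, stx$chrom, bin_of(stx$pos, 1e6))
  expect_equal(sum(one$mean_cpg * one$n_particles, na.rm = TRUE) /
                 sum(one$n_particles, na.rm = TRUE), mean(v),
               tolerance = 1e-9)
  expect_error(radial_cpg_profile(naive, toy$cpg, n_shells = 1), "2 shells")
})

test_that("radial CpG correlation is computed per 1-Mb bin with nulls near 0", {
  toy <- fixture_toy()
  st <- fixture_cohort(1)$cells[["primed_like_01"]]$structure
  rc <- radial_cpg_correlation(st, toy$cpg)
  expect_gt(as.numeric(rc), 0)
  tab <- attr(rc, "table")
  expect_equal(nrow(tab), sum(n_bins(toy$genome)))
  # shuffled CpG kills the correlation
  nulls <- sapply(1:10, function(s) {
    shuf <- withr::with_seed(s, {
      dtc <- data.table::as.data.table(toy$cpg)
      dtc[, cpg := sample(cpg)]
      cpg_track(toy$genome, dtc)
    })
    as.numeric(radial_cpg_correlation(st, shuf))
  })
  expect_lt(abs(mean(nulls)), 0.2)
  expect_error(radial_cpg_correlation(st, toy$cpg, bin_size = 1.5e6),
               "multiple")
})

test_that("locus radial positions follow the planted architecture", {
  toy <- fixture_toy()
  co <- fixture_cohort(1)
  # the most CpG-rich 1-Mb bin as a marker locus
  dtc <- data.table::as.data.table(toy$cpg)
  top <- dtc[which.max(cpg)]
  loci <- data.frame(chrom = top$chrom, start = top$bin * 1e6,
                     end = (top$bin + 1) * 1e6, name = "cpg_rich")
  pool <- function(cells) mean(sapply(cells, function(cl) {
    lr <- locus_radial_position(cl$structure, loci)
    lr[lr$hap == "pooled"]$radial
  }))
  expect_lt(pool(co$cells[co$manifest$archetype == "naive_like"]),
            pool(co$cells[co$manifest$archetype == "primed_like"]))
  # a locus spanning one particle returns that particle's radius
  st <- co$cells[[1]]$structure
  r <- radial_positions(st)
  stx <- data.table::as.data.table(st)
  lr <- locus_radial_position(st, data.frame(chrom = "chr1", start = 0,
                                             end = 1e6, name = "one"))
  expect_equal(lr[lr$hap == "mat"]$radial,
               r[stx$chrom == "chr1" & stx$hap == "mat" & stx$pos == 0])
  # zero-length locus at a bin boundary goes to the containing bin
  lr0 <- locus_radial_position(st, data.frame(chrom = "chr1", start = 1e6,
                                              end = 1e6, name = "pt"))
  expect_equal(lr0[lr0$hap == "mat"]$radial,
               r[stx$chrom == "chr1" & stx$hap == "mat" & stx$pos == 1e6])
  # a locus in a coverage gap yields NA with a warning
  g2 <- genome_spec(c(chr1 = 3e6), 1e6)
  sp <- structure_3d(data.frame(chrom = "chr1", hap = "mat", pos = 0,
                                x = 1, y = 0, z = 0), 1e6, genome = g2)
  expect_warning(na <- locus_radial_position(
    sp, data.frame(chrom = "chr1", start = 2e6, end = 3e6, name = "gap")),
    "no particle")
  expect_true(all(is.na(na$radial)))
})

test_that("cross-sections partition all particles into ordered slabs", {
  st <- fixture_cohort(1)$cells[[1]]$structure
  cx <- cross_sections(st, spacing = 7.5 * particle_radius(st))
  expect_equal(nrow(cx), nrow(st))
  extent <- diff(range(st$z))
  expect_equal(max(cx$slab), ceiling(extent / (7.5 * particle_radius(st))))
  expect_true(all(cx$slab >= 1))
  # spacing beyond the extent gives a single slab
  one <- cross_sections(st, spacing = 1000)
  expect_true(all(one$slab == 1))
  expect_error(cross_sections(st, spacing = 0), "positive")
})

test_that("structure metrics are invariant under rigid motions", {
  toy <- fixture_toy()
  st <- fixture_cohort(1)$cells[[1]]$structure
  rot <- withr::with_seed(11, random_rotation(allow_reflection = TRUE))
  moved <- transform_structure(st, rot, c(-2, 7, 3))
  expect_equal(intermingling_index(moved)$mean,
               intermingling_index(st)$mean, tolerance = 1e-9)
  expect_equal(as.numeric(compartment_score(moved, toy$cpg)),
               as.numeric(compartment_score(st, toy$cpg)), tolerance = 1e-9)
  expect_equal(as.numeric(radial_cpg_correlation(moved, toy$cpg)),
               as.numeric(radial_cpg_correlation(st, toy$cpg)),
               tolerance = 1e-9)
})
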