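cm_genome <- function() genome_spec(c(chr1 = 30e6, chr2 = 30e6), 1e6)

cm_cpg <- function(g = cm_genome()) {
  cpg_track(g, list(seq(0.01, 0.05, length.out = 30),
                    seq(0.05, 0.01, length.out = 30)))
}

test_that("contacting CpG is the contact-weighted partner mean excluding self", {
  g <- cm_genome()
  cpg <- cpg_track(g, list(c(0.2, 0.8, 0.5, rep(0.3, 27)), rep(0.3, 30)))
  # bin 2 of chr1 contacts bin 0 twice and bin 1 once -> (0.2*2 + 0.8)/3 = 0.4
  dt <- data.frame(chr_a = "chr1", pos_a = c(0.1e6, 0.2e6, 1.1e6),
                   hap_a = "mat", chr_b = "chr1",
                   pos_b = c(2.1e6, 2.2e6, 2.3e6), hap_b = "mat")
  cc <- contacting_cpg(contact_set(dt, g), cpg)
  v2 <- cc[cc$bin == 2 & cc$chrom == "chr1"]
  expect_equal(v2$value, 0.4)
  expect_equal(v2$n_contacts, 3L)
  # a bin contacting only constant-CpG partners reports that constant
  expect_equal(cc[cc$bin == 0]$value, 0.5)
  # a bin whose only contact is with itself is absent
  self <- contact_set(data.frame(chr_a = "chr1", pos_a = 5.1e6,
                                 hap_a = "mat", chr_b = "chr1",
                                 pos_b = 5.9e6, hap_b = "mat"), g)
  expect_equal(nrow(contacting_cpg(self, cpg)), 0)
  # diploid mode drops unresolved contacts and keeps alleles apart
  dt2 <- rbind(dt, data.frame(chr_a = "chr1", pos_a = 0.1e6,
                              hap_a = "unknown", chr_b = "chr1",
                              pos_b = 2.4e6, hap_b = "pat"))
  cd <- contacting_cpg(contact_set(dt2, g), cpg, mode = "diploid")
  expect_equal(sum(cd$n_contacts), 6L)   # 3 contacts x 2 legs
  expect_true(all(cd$hap %in% c("mat", "pat")))
  cct <- contacting_cpg(contact_set(dt2, g), cpg, mode = "celltype")
  expect_true(all(cct$hap == "pooled"))
  expect_equal(sum(cct$n_contacts), 8L)
})

test_that("contacting CpG values stay within the track's range", {
  toy <- fixture_toy()
  cell <- fixture_cohort(1)$cells[[1]]$contacts
  cc <- contacting_cpg(cell, toy$cpg, mode = "celltype")
  expect_gte(min(cc$value), min(toy$cpg$cpg))
  expect_lte(max(cc$value), max(toy$cpg$cpg))
})

test_that("interchromosomal statistics count fractions and pairs", {
  g <- cm_genome()
  dt <- data.frame(chr_a = c(rep("chr1", 7), rep("chr1", 3)),
                   pos_a = 1:10 * 1e5, hap_a = "mat",
                   chr_b = c(rep("chr1", 7), rep("chr2", 3)),
                   pos_b = 1:10 * 2e5 + 5e6, hap_b = "pat")
  st <- interchrom_stats(contact_set(dt, g))
  expect_equal(st$fraction, 0.3)
  expect_equal(st$pair_counts[chr_a == "chr1" & chr_b == "chr2"]$n, 3L)
  intra_only <- interchrom_stats(contact_set(dt[1:7, ], g))
  expect_equal(intra_only$fraction, 0)
  empty <- contact_set(dt[0, ], g)
  expect_true(is.na(interchrom_stats(empty)$fraction))
})

test_that("contact heatmaps are symmetric and the differential is scale-free", {
  g <- cm_genome()
  one <- contact_set(data.frame(chr_a = "chr1", pos_a = 2.5e6, hap_a = "mat",
                                chr_b = "chr2", pos_b = 7.5e6, hap_b = "pat"),
                     g)
  m <- contact_heatmap(one, g)
  expect_equal(sum(m != 0), 2)
  expect_true(isSymmetric(unclass(m), check.attributes = FALSE))
  expect_equal(m["chr1:2", "chr2:7"], 1)

  cellA <- fixture_cohort(1)$cells[[1]]$contacts
  mA <- contact_heatmap(cellA, fixture_toy()$genome)
  expect_equal(max(abs(contact_heatmap_diff(mA, mA))), 0)
  # doubling depth leaves the differential unchanged
  expect_equal(contact_heatmap_diff(mA, mA * 2), contact_heatmap_diff(mA, mA),
               tolerance = 1e-12)
})

test_that("A/B calling recovers planted checkerboard compartments", {
  ck <- simulate_compartment_contacts(seed = 2)
  ab <- ab_compartments(ck$contacts, ck$cpg, ck$genome)
  agree <- mean((ab$score > 0) == (ck$labels > 0), na.rm = TRUE)
  expect_gte(agree, 0.95)
  # invariant to duplicating every contact (positive scaling of the matrix)
  df <- as.data.frame(ck$contacts)
  df$id <- NULL
  doubled <- contact_set(rbind(df, df), ck$genome)
  ab2 <- ab_compartments(doubled, ck$cpg, ck$genome)
  expect_equal(ab$compartment, ab2$compartment)
  # orientation is fixed by CpG, so A is the CpG-rich state by construction
  expect_gt(mean(ck$cpg$cpg[ab$compartment == "A"]),
            mean(ck$cpg$cpg[ab$compartment == "B"]))
  # a compartment-free decay profile explains little variance
  null <- simulate_compartment_contacts(boost = 1, seed = 4)
  abn <- ab_compartments(null$contacts, null$cpg, null$genome)
  expect_lt(attr(abn, "var_explained")["chr1"], 0.2)
  expect_error(ab_compartments(ck$contacts, ck$cpg,
                               genome_spec(c(chr1 = 5e6), 1e6)),
               "fewer than")
})

test_that("compartment PCA separates cohorts and flags degenerate ones", {
  toy <- fixture_toy()
  co <- fixture_cohort(1)
  vecs <- lapply(co$cells, function(cl)
    contacting_cpg(cl$contacts, toy$cpg, mode = "celltype"))
  p <- compartment_pca(vecs, seed = 1)
  expect_equal(cluster_agreement(p$cluster, co$manifest$archetype), 1)
  expect_equal(length(p$cluster), 10)
  # a duplicated cell lands on exactly the same embedding
  vecs2 <- c(vecs, list(dup = vecs[[1]]))
  p2 <- compartment_pca(vecs2, seed = 1)
  expect_equal(unname(p2$scores[1, ]), unname(p2$scores[11, ]),
               tolerance = 1e-9)
  # a single-archetype cohort has no stable 2-cluster structure
  co2 <- fixture_cohort(2)
  vecs_b <- lapply(co2$cells, function(cl)
    contacting_cpg(cl$contacts, fixture_toy()$cpg, mode = "celltype"))
  naive_only <- c(vecs[co$manifest$archetype == "naive_like"],
                  vecs_b[co2$manifest$archetype == "naive_like"])
  names(naive_only) <- paste0("cell", seq_along(naive_only))
  p3 <- compartment_pca(naive_only, seed = 1)
  # silhouette in the full locus space (the PC plane is k-means-optimised
  # and therefore biased toward apparent separation)
  expect_lt(silhouette_width(full_vector_matrix(naive_only), p3$cluster),
            0.3)
  expect_error(compartment_pca(vecs[1:2]), "at least 4")
})
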