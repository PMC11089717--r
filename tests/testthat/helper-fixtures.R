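# Session-cached simulated inputs shared across test files (all generated
# deterministically from small seeds; nothing is stored on disk).

.fixtures <- new.env(parent = emptyenv())

fixture_toy <- function() {
  if (is.null(.fixtures$toy)) .fixtures$toy <- make_toy_genome(seed = 1)
  .fixtures$toy
}

# one 5 naive + 5 primed cohort per base seed
fixture_cohort <- function(base_seed = 1) {
  key <- paste0("cohort_", base_seed)
  if (is.null(.fixtures[[key]])) {
    toy <- fixture_toy()
    .fixtures[[key]] <- simulate_cohort(toy$genome, toy$cpg,
                                        n_cells = 5, base_seed = base_seed)
  }
  .fixtures[[key]]
}

# one imputed default cell (primed archetype) with truth
fixture_imputed_cell <- function() {
  if (is.null(.fixtures$imputed)) {
    toy <- fixture_toy()
    a <- cell_archetype("primed_like", seed = 42)
    st <- simulate_structure(toy$genome, toy$cpg, a, cell_id = "default_cell")
    sc <- sample_contacts(st, a, toy$genome)
    res <- impute_pipeline(sc$contacts)
    .fixtures$imputed <- list(structure = st, raw = sc$contacts,
                              truth = sc$truth, cleaned = res)
  }
  .fixtures$imputed
}

# small random contact sets for oracle-equivalence checks: a mix of intra-
# and interchromosomal contacts, clustered so that L^0.5 neighbourhoods are
# populated, with partially random phasing
random_contact_set <- function(n, seed, p_unknown = 0.4, n_chrom = 4,
                               chrom_len = 60e6) {
  genome <- genome_spec(stats::setNames(rep(chrom_len, n_chrom),
                                        paste0("chr", seq_len(n_chrom))),
                        1e6)
  withr::with_seed(seed, {
    n_anchor <- max(3, n %/% 30)
    anchor <- data.frame(ca = sample(genome$chroms, n_anchor, replace = TRUE),
                         cb = sample(genome$chroms, n_anchor, replace = TRUE),
                         pa = runif(n_anchor, 0, chrom_len),
                         pb = runif(n_anchor, 0, chrom_len))
    k <- sample(n_anchor, n, replace = TRUE)
    clustered <- runif(n) < 0.75
    pos_a <- ifelse(clustered, anchor$pa[k] + rnorm(n, 0, 2e6),
                    runif(n, 0, chrom_len))
    pos_b <- ifelse(clustered, anchor$pb[k] + rnorm(n, 0, 2e6),
                    runif(n, 0, chrom_len))
    hap <- function() ifelse(runif(n) < p_unknown, "unknown",
                             ifelse(runif(n) < 0.5, "mat", "pat"))
    dt <- data.frame(
      chr_a = ifelse(clustered, anchor$ca[k],
                     sample(genome$chroms, n, replace = TRUE)),
      pos_a = pmin(pmax(pos_a, 0), chrom_len - 1),
      hap_a = hap(),
      chr_b = ifelse(clustered, anchor$cb[k],
                     sample(genome$chroms, n, replace = TRUE)),
      pos_b = pmin(pmax(pos_b, 0), chrom_len - 1),
      hap_b = hap())
    contact_set(dt, genome)
  })
}

# mean silhouette width for a 2-cluster labelling of PCA scores
silhouette_width <- function(scores, cluster) {
  d <- as.matrix(dist(scores))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cluster == cluster[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- mean(d[i, !own & seq_len(n) != i])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

spearman_distance_fidelity <- function(recon, truth) {
  rd <- data.table::as.data.table(recon)
  td <- data.table::as.data.table(truth)
  m <- merge(td, rd, by = c("chrom", "hap", "pos"))
  stats::cor(as.numeric(dist(as.matrix(m[, c("x.x", "y.x", "z.x")]))),
             as.numeric(dist(as.matrix(m[, c("x.y", "y.y", "z.y")]))),
             method = "spearman")
}

# cells x loci matrix over loci present in every cell
full_vector_matrix <- function(vecs) {
  mats <- lapply(vecs, function(v)
    stats::setNames(v$value, paste(v$chrom, v$hap, v$bin)))
  common <- Reduce(intersect, lapply(mats, names))
  do.call(rbind, lapply(mats, `[`, common))
}
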