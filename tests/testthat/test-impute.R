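mk_genome <- function() genome_spec(c(chr1 = 250e6, chr2 = 250e6,
                                      chr3 = 250e6), 1e6)

mk_contacts <- function(rows, genome = mk_genome()) {
  dt <- do.call(rbind, lapply(rows, function(r)
    data.frame(chr_a = r[[1]], pos_a = as.numeric(r[[2]]), hap_a = r[[3]],
               chr_b = r[[4]], pos_b = as.numeric(r[[5]]), hap_b = r[[6]])))
  contact_set(dt, genome)
}

test_that("l05_distance matches the closed form and is symmetric", {
  a <- data.frame(chr_a = "chr1", pos_a = 10e6, chr_b = "chr2", pos_b = 50e6)
  b <- data.frame(chr_a = "chr1", pos_a = 10e6, chr_b = "chr2", pos_b = 50e6)
  expect_equal(l05_distance(a, b), 0)
  b$pos_a <- 14e6
  expect_equal(l05_distance(a, b), 4e6)        # one-sided: reduces to |dx|
  b$pos_b <- 51e6
  expect_equal(l05_distance(a, b), (sqrt(4e6) + sqrt(1e6))^2)
  d1 <- l05_distance(a, b)
  expect_equal(d1, l05_distance(b, a))
  # dx = dy = 1 Mb gives 4 Mb, the defining non-norm property
  b$pos_a <- 11e6; b$pos_b <- 51e6
  expect_equal(l05_distance(a, b), 4e6)
  c2 <- data.frame(chr_a = "chr1", pos_a = 1, chr_b = "chr3", pos_b = 1)
  expect_error(l05_distance(a, c2), "different chromosome pairs")
  # intrachromosomal contacts use the distance-minimising leg pairing
  p <- data.frame(chr_a = "chr1", pos_a = 10e6, chr_b = "chr1", pos_b = 90e6)
  q <- data.frame(chr_a = "chr1", pos_a = 89e6, chr_b = "chr1", pos_b = 11e6)
  expect_equal(l05_distance(p, q), (sqrt(1e6) + sqrt(1e6))^2)
})

test_that("enumerate_tuples covers the compatible assignments", {
  t4 <- data.frame(hap_a = "unknown", hap_b = "unknown")
  expect_equal(nrow(enumerate_tuples(t4)), 4)
  t2 <- data.frame(hap_a = "mat", hap_b = "unknown")
  e2 <- enumerate_tuples(t2)
  expect_equal(nrow(e2), 2)
  expect_true(all(e2$hap_a == "mat"))
  t0 <- data.frame(hap_a = "mat", hap_b = "pat")
  expect_equal(nrow(enumerate_tuples(t0)), 0)
})

test_that("vote applies the inclusive >=3 votes and >=90% rules", {
  g <- mk_genome()
  target <- data.frame(chr_a = "chr1", pos_a = 50e6, hap_a = "unknown",
                       chr_b = "chr2", pos_b = 50e6, hap_b = "unknown")
  near <- function(n, ha, hb)
    data.frame(chr_a = "chr1", pos_a = 50e6 + seq_len(n) * 1e4, hap_a = ha,
               chr_b = "chr2", pos_b = 50e6 + seq_len(n) * 1e4, hap_b = hb)
  # 3 unanimous votes -> winner
  v <- vote(target, near(3, "pat", "mat"))
  expect_equal(v$winner, c("pat", "mat"))
  expect_equal(unname(v$counts["pat/mat"]), 3L)
  # 2 unanimous votes -> below the vote minimum, no winner
  expect_null(vote(target, near(2, "pat", "mat"))$winner)
  # 9 of 10 votes = exactly 90%, inclusive -> winner
  ev <- rbind(near(9, "pat", "mat"), near(1, "mat", "mat"))
  expect_equal(vote(target, ev)$winner, c("pat", "mat"))
  # 8 of 10 < 90% -> no winner
  ev <- rbind(near(8, "pat", "mat"), near(2, "mat", "mat"))
  expect_null(vote(target, ev)$winner)
  # tie for the maximum -> no winner
  ev <- rbind(near(3, "pat", "mat"), near(3, "mat", "pat"))
  expect_null(vote(target, ev)$winner)
  # evidence outside the 10-Mb window does not vote
  far <- near(3, "pat", "mat")
  far$pos_a <- far$pos_a + 40e6
  expect_equal(sum(vote(target, far)$counts), 0)
  # half-known evidence cannot vote
  half <- near(3, "pat", "unknown")
  expect_equal(sum(vote(target, half)$counts), 0)
})

test_that("impute_round applies the intrachromosomal special rules", {
  g <- mk_genome()
  # shortcut: one known leg, separation <= 10 Mb, no evidence needed
  cs <- mk_contacts(list(list("chr1", 20e6, "mat", "chr1", 25e6, "unknown")))
  out <- impute_round(cs, cs[0])
  expect_equal(out$hap_a, "mat")
  expect_equal(out$hap_b, "mat")
  # both legs unknown: never imputed in 2D, even with strong evidence
  rows <- c(list(list("chr1", 20e6, "unknown", "chr1", 25e6, "unknown")),
            lapply(1:5, function(k)
              list("chr1", 20e6 + k * 1e4, "mat", "chr1", 25e6 + k * 1e4,
                   "mat")))
  cs <- mk_contacts(rows)
  out <- impute_round(cs, cs)
  expect_equal(out$hap_a[1], "unknown")
  # interhomologous winner at 50 Mb separation (< 100 Mb) is rejected...
  rows <- c(list(list("chr1", 20e6, "mat", "chr1", 70e6, "unknown")),
            lapply(1:5, function(k)
              list("chr1", 20e6 + k * 1e4, "mat", "chr1", 70e6 + k * 1e4,
                   "pat")))
  cs <- mk_contacts(rows)
  out <- impute_round(cs, cs)
  expect_equal(out$hap_b[1], "unknown")
  # ...but accepted at 150 Mb separation (>= 100 Mb)
  rows <- c(list(list("chr1", 20e6, "mat", "chr1", 170e6, "unknown")),
            lapply(1:5, function(k)
              list("chr1", 20e6 + k * 1e4, "mat", "chr1", 170e6 + k * 1e4,
                   "pat")))
  cs <- mk_contacts(rows)
  out <- impute_round(cs, cs)
  expect_equal(out$hap_b[1], "pat")
})

test_that("impute_round equals the brute-force reference on random sets", {
  for (s in 1:6) {
    cs <- random_contact_set(300, seed = 100 + s)
    fast <- impute_round(cs, cs)
    ref <- ref_impute_round(cs, cs)
    expect_equal(as.data.frame(fast)[c("hap_a", "hap_b")],
                 ref[c("hap_a", "hap_b")])
  }
})

test_that("imputation never overwrites known legs and never loses ground", {
  cs <- random_contact_set(400, seed = 7)
  known_a <- cs$hap_a != "unknown"
  known_b <- cs$hap_b != "unknown"
  cur <- cs
  n_unknown <- sum(cur$hap_a == "unknown") + sum(cur$hap_b == "unknown")
  for (r in 1:3) {
    cur <- impute_round(cur, cur)
    expect_identical(cur$hap_a[known_a], cs$hap_a[known_a])
    expect_identical(cur$hap_b[known_b], cs$hap_b[known_b])
    n2 <- sum(cur$hap_a == "unknown") + sum(cur$hap_b == "unknown")
    expect_lte(n2, n_unknown)
    n_unknown <- n2
  }
})

test_that("remove_isolated keeps contacts with enough same-haplotype neighbours", {
  g <- mk_genome()
  # a singleton can have no neighbours
  cs <- mk_contacts(list(list("chr1", 1e6, "mat", "chr2", 1e6, "mat")))
  expect_equal(nrow(remove_isolated(cs)), 0)
  # exactly 2 same-haplotype neighbours at 9 Mb suffices ("< 2" removes)
  rows <- list(list("chr1", 50e6, "mat", "chr2", 50e6, "mat"),
               list("chr1", 59e6, "mat", "chr2", 50e6, "mat"),
               list("chr1", 41e6, "mat", "chr2", 50e6, "mat"))
  cs <- mk_contacts(rows)
  kept <- remove_isolated(cs)
  expect_true(1L %in% kept$id)   # centre contact has both neighbours
  # 3 mutually close same-haplotype contacts survive, 1 far contact doesn't
  rows <- c(lapply(0:2, function(k)
    list("chr1", 50e6 + k * 1e5, "mat", "chr2", 50e6 + k * 1e5, "mat")),
    list(list("chr1", 200e6, "mat", "chr2", 200e6, "mat")))
  cs <- mk_contacts(rows)
  kept <- remove_isolated(cs)
  expect_setequal(kept$id, 1:3)
  # haplotype must match: close contacts on the other homolog don't count
  rows <- c(list(list("chr1", 50e6, "mat", "chr2", 50e6, "mat")),
            lapply(1:3, function(k)
              list("chr1", 50e6 + k * 1e4, "pat", "chr2", 50e6 + k * 1e4,
                   "pat")))
  cs <- mk_contacts(rows)
  expect_false(1L %in% remove_isolated(cs)$id)
})

test_that("remove_isolated matches brute force and is order-independent", {
  for (s in 1:5) {
    cs <- random_contact_set(200, seed = 200 + s, p_unknown = 0.15)
    fast <- remove_isolated(cs)
    ref <- ref_remove_isolated(cs)
    expect_setequal(fast$id, ref$id)
    perm <- withr::with_seed(s, sample(nrow(cs)))
    shuffled <- rewrap <- data.table::as.data.table(cs)[perm]
    shuffled <- contact_set(shuffled, attr(cs, "genome"))
    expect_setequal(remove_isolated(shuffled)$id, fast$id)
  }
})

test_that("impute_pipeline resolves a simulated cell against its truth", {
  cell <- fixture_imputed_cell()
  sco <- score_imputation(cell$raw, cell$cleaned, cell$truth)
  # regression floor from design-time pilots on the default study conditions
  expect_gte(sco$resolved_fraction, 0.55)
  expect_gte(sco$accuracy, 0.90)
  lg <- attr(cell$cleaned, "impute_log")
  expect_equal(lg$round, c("input", "round_1", "round_2", "round_3",
                           "cleaned", "final"))
  expect_true(all(diff(lg$unknown_legs[1:4]) <= 0))
  expect_identical(attr(cell$cleaned, "stage"), "cleaned")
})

test_that("impute_pipeline handles degenerate schedules and inputs", {
  # fully phased input: output is input minus isolated contacts
  cs <- random_contact_set(150, seed = 5, p_unknown = 0)
  out <- impute_pipeline(cs)
  expect_setequal(out$id, remove_isolated(cs)$id)
  # rounds = 0: only cleaning plus the final interchromosomal pass
  cs2 <- random_contact_set(150, seed = 6)
  out2 <- impute_pipeline(cs2, imputation_params(rounds = 0))
  expect_identical(attr(out2, "stage"), "cleaned")
  # empty input warns and returns empty
  g <- mk_genome()
  empty <- contact_set(data.frame(chr_a = character(), pos_a = numeric(),
                                  hap_a = character(), chr_b = character(),
                                  pos_b = numeric(), hap_b = character()), g)
  expect_warning(res <- impute_pipeline(empty), "empty")
  expect_equal(nrow(res), 0)
})
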