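# Plain-R reference implementations of the voting round and the isolation
# filter, written directly from the rule statements and kept independent of
# the package's optimized code paths. Used as brute-force oracles.

ref_l05 <- function(dx, dy) (sqrt(abs(dx)) + sqrt(abs(dy)))^2

ref_impute_round <- function(targets, evidence, params = imputation_params()) {
  tg <- as.data.frame(targets)
  ev <- as.data.frame(evidence)
  ev <- ev[ev$hap_a != "unknown" & ev$hap_b != "unknown", , drop = FALSE]
  out <- tg
  eps <- 1e-9
  for (t in seq_len(nrow(tg))) {
    ha <- tg$hap_a[t]
    hb <- tg$hap_b[t]
    if (ha != "unknown" && hb != "unknown") next
    intra <- tg$chr_a[t] == tg$chr_b[t]
    sep <- abs(tg$pos_b[t] - tg$pos_a[t])
    if (intra && ha == "unknown" && hb == "unknown") next
    if (intra && sep <= params$intra_shortcut_sep + eps) {
      k <- if (ha != "unknown") ha else hb
      out$hap_a[t] <- k
      out$hap_b[t] <- k
      next
    }
    same <- (ev$chr_a == tg$chr_a[t] & ev$chr_b == tg$chr_b[t]) |
      (ev$chr_a == tg$chr_b[t] & ev$chr_b == tg$chr_a[t])
    e <- ev[same & ev$id != tg$id[t], , drop = FALSE]
    if (nrow(e) == 0) next
    if (intra) {
      d_dir <- ref_l05(e$pos_a - tg$pos_a[t], e$pos_b - tg$pos_b[t])
      d_swp <- ref_l05(e$pos_b - tg$pos_a[t], e$pos_a - tg$pos_b[t])
      swap <- d_swp < d_dir
      d <- pmin(d_dir, d_swp)
      ea <- ifelse(swap, e$hap_b, e$hap_a)
      eb <- ifelse(swap, e$hap_a, e$hap_b)
    } else {
      dir <- e$chr_a == tg$chr_a[t]
      d <- ifelse(dir,
                  ref_l05(e$pos_a - tg$pos_a[t], e$pos_b - tg$pos_b[t]),
                  ref_l05(e$pos_b - tg$pos_a[t], e$pos_a - tg$pos_b[t]))
      ea <- ifelse(dir, e$hap_a, e$hap_b)
      eb <- ifelse(dir, e$hap_b, e$hap_a)
    }
    ok <- d <= params$window + eps &
      (ha == "unknown" | ea == ha) & (hb == "unknown" | eb == hb)
    v <- paste(ea, eb)[ok]
    if (length(v) == 0) next
    counts <- table(v)
    mx <- max(counts)
    if (sum(counts == mx) != 1) next
    if (mx < params$min_votes) next
    if (mx + eps < params$win_fraction * sum(counts)) next
    w <- strsplit(names(counts)[which.max(counts)], " ", fixed = TRUE)[[1]]
    if (intra && w[1] != w[2] && sep + eps < params$interhomolog_sep) next
    out$hap_a[t] <- w[1]
    out$hap_b[t] <- w[2]
  }
  out
}

ref_remove_isolated <- function(contacts, params = imputation_params()) {
  dt <- as.data.frame(contacts)
  n <- nrow(dt)
  keep <- logical(n)
  eps <- 1e-9
  phased <- dt$hap_a != "unknown" & dt$hap_b != "unknown"
  for (i in seq_len(n)) {
    if (!phased[i]) next
    intra_i <- dt$chr_a[i] == dt$chr_b[i]
    same <- phased &
      ((dt$chr_a == dt$chr_a[i] & dt$chr_b == dt$chr_b[i]) |
         (dt$chr_a == dt$chr_b[i] & dt$chr_b == dt$chr_a[i]))
    same[i] <- FALSE
    e <- dt[same, , drop = FALSE]
    if (nrow(e) == 0) next
    if (intra_i) {
      d_dir <- ref_l05(e$pos_a - dt$pos_a[i], e$pos_b - dt$pos_b[i])
      d_swp <- ref_l05(e$pos_b - dt$pos_a[i], e$pos_a - dt$pos_b[i])
      swap <- d_swp < d_dir
      d <- pmin(d_dir, d_swp)
      match <- ifelse(swap,
                      e$hap_b == dt$hap_a[i] & e$hap_a == dt$hap_b[i],
                      e$hap_a == dt$hap_a[i] & e$hap_b == dt$hap_b[i])
    } else {
      dir <- e$chr_a == dt$chr_a[i]
      d <- ifelse(dir,
                  ref_l05(e$pos_a - dt$pos_a[i], e$pos_b - dt$pos_b[i]),
                  ref_l05(e$pos_b - dt$pos_a[i], e$pos_a - dt$pos_b[i]))
      match <- ifelse(dir,
                      e$hap_a == dt$hap_a[i] & e$hap_b == dt$hap_b[i],
                      e$hap_b == dt$hap_a[i] & e$hap_a == dt$hap_b[i])
    }
    keep[i] <- sum(match & d <= params$isolation_window + eps) >=
      params$isolation_min_neighbors
  }
  dt[keep, , drop = FALSE]
}
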