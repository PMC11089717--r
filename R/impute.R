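#' Imputation parameters
#'
#' Thresholds of the 2D haplotype-imputation voting algorithm. All
#' inequalities are inclusive: an evidence contact votes if it lies within
#' `window` in L^0.5 distance; a tuple wins with `>= min_votes` votes and
#' `>= win_fraction` of all votes; an intrachromosomal target is assumed
#' intrahomologous without voting if its legs are separated by
#' `<= intra_shortcut_sep`; a winning interhomologous vote on an
#' intrachromosomal target is accepted only at separations
#' `>= interhomolog_sep`.
#'
#' @param window evidence window in L^0.5 distance (bp), default 10 Mb.
#' @param min_votes minimum votes for a winner, default 3.
#' @param win_fraction minimum fraction of all votes, default 0.9.
#' @param intra_shortcut_sep intrahomologous shortcut separation (bp),
#'   default 10 Mb.
#' @param interhomolog_sep interhomologous acceptance separation (bp),
#'   default 100 Mb.
#' @param rounds voting rounds before cleaning, default 3.
#' @param isolation_window cleaning neighbourhood in L^0.5 distance (bp),
#'   default 10 Mb.
#' @param isolation_min_neighbors minimum same-haplotype neighbours for a
#'   contact to be kept (default 2; "< 2 other contacts" are removed).
#' @return An `imputation_params` list.
#' @export
imputation_params <- function(window = 10e6, min_votes = 3,
                              win_fraction = 0.9,
                              intra_shortcut_sep = 10e6,
                              interhomolog_sep = 100e6, rounds = 3,
                              isolation_window = 10e6,
                              isolation_min_neighbors = 2) {
  p <- list(window = window, min_votes = as.integer(min_votes),
            win_fraction = win_fraction,
            intra_shortcut_sep = intra_shortcut_sep,
            interhomolog_sep = interhomolog_sep, rounds = as.integer(rounds),
            isolation_window = isolation_window,
            isolation_min_neighbors = as.integer(isolation_min_neighbors))
  stopifnot(p$window > 0, p$intra_shortcut_sep > 0, p$interhomolog_sep > 0,
            p$win_fraction > 0, p$win_fraction <= 1, p$min_votes >= 1,
            p$rounds >= 0)
  class(p) <- "imputation_params"
  p
}

#' L^0.5 distance between two contacts
#'
#' `(sqrt(|dx|) + sqrt(|dy|))^2` over the paired leg coordinate differences.
#' Not a norm (no triangle inequality), but symmetric and non-negative. Both
#' contacts must join the same unordered chromosome pair; for
#' intrachromosomal contacts the leg pairing minimising the distance is
#' used.
#'
#' @param c1,c2 single-row contact data.frames (columns `chr_a`, `pos_a`,
#'   `chr_b`, `pos_b`).
#' @return Distance in bp.
#' @examples
#' a <- data.frame(chr_a = "chr1", pos_a = 0, chr_b = "chr2", pos_b = 0)
#' b <- data.frame(chr_a = "chr1", pos_a = 1e6, chr_b = "chr2", pos_b = 1e6)
#' l05_distance(a, b)  # 4e6
#' @export
l05_distance <- function(c1, c2) {
  same_dir <- c1$chr_a == c2$chr_a && c1$chr_b == c2$chr_b
  same_swp <- c1$chr_a == c2$chr_b && c1$chr_b == c2$chr_a
  if (!same_dir && !same_swp)
    stop("contacts join different chromosome pairs; no neighbourhood defined")
  l05 <- function(dx, dy) (sqrt(abs(dx)) + sqrt(abs(dy)))^2
  if (c1$chr_a == c1$chr_b) {
    min(l05(c1$pos_a - c2$pos_a, c1$pos_b - c2$pos_b),
        l05(c1$pos_a - c2$pos_b, c1$pos_b - c2$pos_a))
  } else if (same_dir) {
    l05(c1$pos_a - c2$pos_a, c1$pos_b - c2$pos_b)
  } else {
    l05(c1$pos_a - c2$pos_b, c1$pos_b - c2$pos_a)
  }
}

#' Enumerate haplotype tuples compatible with a contact's known legs
#'
#' @param contact single-row contact data.frame (columns `hap_a`, `hap_b`).
#' @return data.frame with columns `hap_a`, `hap_b`; 4 rows when both legs
#'   are unknown, 2 when one is known, 0 when fully phased (no-op).
#' @export
enumerate_tuples <- function(contact) {
  ha <- contact$hap_a
  hb <- contact$hap_b
  if (ha != "unknown" && hb != "unknown")
    return(data.frame(hap_a = character(), hap_b = character()))
  opts_a <- if (ha == "unknown") c("mat", "pat") else ha
  opts_b <- if (hb == "unknown") c("mat", "pat") else hb
  expand.grid(hap_a = opts_a, hap_b = opts_b, stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)
}

#' Tally votes for one target contact
#'
#' Each fully phased evidence contact on the same chromosome pair votes for
#' the single enumerated tuple matching its leg haplotypes, provided it lies
#' within `params$window` in L^0.5 distance. The winner must collect
#' `>= min_votes` votes and `>= win_fraction` of all votes (inclusive); a
#' tie for the maximum yields no winner.
#'
#' @param target single-row contact data.frame.
#' @param evidence contact table on the same chromosome pair.
#' @param params an [imputation_params()].
#' @return `list(winner = NULL or c(hap_a, hap_b), counts = named integer
#'   vector of votes per tuple)`.
#' @export
vote <- function(target, evidence, params = imputation_params()) {
  tuples <- enumerate_tuples(target)
  counts <- stats::setNames(integer(nrow(tuples)),
                            paste(tuples$hap_a, tuples$hap_b, sep = "/"))
  if (nrow(tuples) == 0) return(list(winner = NULL, counts = counts))
  ev <- as.data.table(evidence)
  for (k in seq_len(nrow(ev))) {
    e <- ev[k]
    if (e$hap_a == "unknown" || e$hap_b == "unknown") next
    if (l05_distance(target, e) > params$window + 1e-9) next
    ea <- e$hap_a; eb <- e$hap_b
    if (target$chr_a == target$chr_b) {
      # haplotypes follow the distance-minimising leg pairing
      d_dir <- (sqrt(abs(e$pos_a - target$pos_a)) +
                  sqrt(abs(e$pos_b - target$pos_b)))^2
      d_swp <- (sqrt(abs(e$pos_b - target$pos_a)) +
                  sqrt(abs(e$pos_a - target$pos_b)))^2
      if (d_swp < d_dir) { ea <- e$hap_b; eb <- e$hap_a }
    } else if (e$chr_a != target$chr_a) {
      ea <- e$hap_b; eb <- e$hap_a
    }
    hit <- which(tuples$hap_a == ea & tuples$hap_b == eb)
    if (length(hit) == 1) counts[hit] <- counts[hit] + 1L
  }
  total <- sum(counts)
  winner <- NULL
  if (total > 0) {
    mx <- max(counts)
    if (sum(counts == mx) == 1 && mx >= params$min_votes &&
        mx + 1e-9 >= params$win_fraction * total) {
      w <- which.max(counts)
      winner <- c(tuples$hap_a[w], tuples$hap_b[w])
    }
  }
  list(winner = winner, counts = counts)
}

contacts_to_int <- function(x, genome) {
  list(chr_a = chrom_index(genome, x$chr_a), pos_a = as.numeric(x$pos_a),
       hap_a = hap_to_int(x$hap_a), chr_b = chrom_index(genome, x$chr_b),
       pos_b = as.numeric(x$pos_b), hap_b = hap_to_int(x$hap_b),
       id = as.integer(x$id))
}

#' One synchronous round of haplotype imputation
#'
#' Applies the voting rules to every target contact with at least one
#' unknown leg, against a frozen evidence set (self-votes excluded by
#' contact id). Intrachromosomal targets with separation
#' `<= intra_shortcut_sep` and one known leg are assumed intrahomologous
#' without voting; intrachromosomal targets with both legs unknown are never
#' imputed; an interhomologous win on an intrachromosomal target needs
#' separation `>= interhomolog_sep`. Input order is preserved and known
#' haplotypes are never overwritten.
#'
#' @param targets a [contact_set()].
#' @param evidence a [contact_set()] (only fully phased contacts vote).
#' @param params an [imputation_params()].
#' @return The targets with imputed haplotypes filled in (stage `imputed`).
#' @export
impute_round <- function(targets, evidence, params = imputation_params()) {
  genome <- contact_genome(targets)
  if (nrow(targets) == 0) return(set_stage(copy(targets), "imputed"))
  ti <- contacts_to_int(targets, genome)
  ei <- contacts_to_int(evidence, genome)
  res <- cpp_impute_round(ti$chr_a, ti$pos_a, ti$hap_a, ti$chr_b, ti$pos_b,
                          ti$hap_b, ti$id,
                          ei$chr_a, ei$pos_a, ei$hap_a, ei$chr_b, ei$pos_b,
                          ei$hap_b, ei$id,
                          params$window, params$min_votes,
                          params$win_fraction, params$intra_shortcut_sep,
                          params$interhomolog_sep)
  out <- copy(as.data.table(targets))
  # leg positions are untouched, so the canonical leg order is preserved
  out[, `:=`(hap_a = int_to_hap(res[, 1]), hap_b = int_to_hap(res[, 2]))]
  rewrap_contacts(out, targets, stage = "imputed")
}

#' Remove isolated contacts
#'
#' Keeps a contact iff at least `isolation_min_neighbors` other contacts
#' with identical haplotypes on the matched legs lie within
#' `isolation_window` in L^0.5 distance on the same chromosome pair. The
#' filter is evaluated simultaneously on the input set (order-independent).
#' Contacts with unknown haplotypes never match and are always removed.
#'
#' @param contacts a [contact_set()].
#' @param params an [imputation_params()].
#' @return The surviving contacts.
#' @export
remove_isolated <- function(contacts, params = imputation_params()) {
  if (nrow(contacts) == 0) return(copy(contacts))
  genome <- contact_genome(contacts)
  ci <- contacts_to_int(contacts, genome)
  keep <- cpp_isolated_keep(ci$chr_a, ci$pos_a, ci$hap_a, ci$chr_b, ci$pos_b,
                            ci$hap_b, params$isolation_window,
                            params$isolation_min_neighbors)
  rewrap_contacts(as.data.table(contacts)[keep], contacts)
}

#' Full 2D haplotype-imputation pipeline
#'
#' Runs `params$rounds` voting rounds, each using the previous round's
#' output as the new evidence set; removes isolated contacts from the fully
#' phased subset; then runs one final round in which the cleaned set votes
#' on all interchromosomal contacts that still have unknown haplotypes on
#' both legs. Contacts that remain partially or fully unresolved are carried
#' through unchanged (the cleaning neighbourhood is defined on haplotypes,
#' so only phased contacts are subject to it), which leaves them available
#' for structure-based imputation downstream.
#'
#' @param raw a [contact_set()] with stage `raw`.
#' @param params an [imputation_params()].
#' @param verbose print per-round counts.
#' @return A [contact_set()] with stage `cleaned`, with attribute
#'   `impute_log` (data.table of per-round counts).
#' @export
impute_pipeline <- function(raw, params = imputation_params(),
                            verbose = FALSE) {
  if (!identical(contact_stage(raw), "raw"))
    warning("input stage is not 'raw'")
  if (nrow(raw) == 0) {
    warning("empty contact set; nothing to impute")
    return(set_stage(copy(raw), "cleaned"))
  }
  log <- data.table(round = character(), contacts = integer(),
                    unknown_legs = integer())
  note <- function(tag, x) {
    n_unk <- sum(x$hap_a == "unknown") + sum(x$hap_b == "unknown")
    if (verbose) message(sprintf("%-12s %7d contacts, %7d unknown legs",
                                 tag, nrow(x), n_unk))
    rbind(log, data.table(round = tag, contacts = nrow(x),
                          unknown_legs = n_unk))
  }
  log <- note("input", raw)
  cur <- raw
  for (r in seq_len(params$rounds)) {
    cur <- impute_round(cur, cur, params)
    log <- note(sprintf("round_%d", r), cur)
  }
  phased <- rewrap_contacts(
    as.data.table(cur)[hap_a != "unknown" & hap_b != "unknown"], cur)
  unphased <- as.data.table(cur)[hap_a == "unknown" | hap_b == "unknown"]
  cleaned <- remove_isolated(phased, params)
  log <- note("cleaned", cleaned)
  # final pass: interchromosomal contacts still unknown on both legs,
  # imputed with the cleaned set as evidence
  final_targets <- rewrap_contacts(
    copy(unphased)[chr_a != chr_b & hap_a == "unknown" &
                     hap_b == "unknown"], cur)
  if (nrow(final_targets) > 0) {
    final_imp <- impute_round(final_targets, cleaned, params)
    fi <- as.data.table(final_imp)
    resolved_ids <- fi[hap_a != "unknown" & hap_b != "unknown"]$id
    unphased <- rbind(unphased[!id %in% resolved_ids],
                      fi[id %in% resolved_ids])
    setorder(unphased, id)
  }
  out <- rbind(as.data.table(cleaned), unphased)
  setorder(out, id)
  out <- rewrap_contacts(out, raw, stage = "cleaned")
  log <- note("final", out)
  data.table::setattr(out, "impute_log", log)
  out
}

#' Score an imputation against simulator truth
#'
#' @param raw the raw [contact_set()] before imputation.
#' @param result the [impute_pipeline()] output.
#' @param truth truth record `data.table(id, hap_a, hap_b)` from
#'   [sample_contacts()].
#' @return list with `resolved_fraction` (share of initially unknown legs
#'   assigned in the result) and `accuracy` (share of assigned legs that
#'   match the truth).
#' @export
score_imputation <- function(raw, result, truth) {
  r <- as.data.table(raw)[, .(id, raw_a = hap_a, raw_b = hap_b)]
  o <- as.data.table(result)[, .(id, out_a = hap_a, out_b = hap_b)]
  m <- merge(merge(r, truth, by = "id"), o, by = "id", all.x = TRUE)
  m[is.na(out_a), `:=`(out_a = "unknown", out_b = "unknown")]
  unk <- c(m$raw_a == "unknown", m$raw_b == "unknown")
  res <- c(m$out_a != "unknown", m$out_b != "unknown")
  correct <- c(m$out_a == m$hap_a, m$out_b == m$hap_b)
  list(resolved_fraction = mean(res[unk]),
       accuracy = mean(correct[unk & res]),
       n_unknown = sum(unk))
}
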