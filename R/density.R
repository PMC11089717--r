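#' Fit the conditional contact-density law
#'
#' Given coordinate differences `(dx, dy)` between neighbouring contacts on
#' a shared chromosome pair, accumulates them into log-spaced 2D bins,
#' estimates the empirical density per bin, and fits `log(density)` against
#' the log of two candidate metrics by least squares:
#' the L^0.5 form `sqrt(dx) + sqrt(dy)` (the tethered-protrusion model,
#' expected exponent -2) and the L^1 form `dx + dy` (the full-intermingling
#' null, expected exponent -1). The better-fitting model is the one with the
#' smaller residual sum of squares.
#'
#' @param dx,dy positive coordinate differences in bp.
#' @param n_bins number of log-spaced bins per axis.
#' @return list with `exponent_l05`, `exponent_l1`, `rss_l05`, `rss_l1`,
#'   `preferred` (`"l05"` or `"l1"`) and the binned table.
#' @export
fit_contact_decay <- function(dx, dy, n_bins = 12) {
  ok <- dx > 0 & dy > 0
  dx <- dx[ok]; dy <- dy[ok]
  if (length(dx) < 100) stop("insufficient pairs for a density fit")
  if (diff(range(dx)) == 0 && diff(range(dy)) == 0)
    stop("degenerate support: all pairs at a single (dx, dy)")
  brx <- exp(seq(log(min(dx)), log(max(dx)) + 1e-9, length.out = n_bins + 1))
  bry <- exp(seq(log(min(dy)), log(max(dy)) + 1e-9, length.out = n_bins + 1))
  ix <- findInterval(dx, brx, rightmost.closed = TRUE)
  iy <- findInterval(dy, bry, rightmost.closed = TRUE)
  tab <- data.table(ix, iy)[, .N, by = .(ix, iy)]
  tab[, `:=`(cx = sqrt(brx[ix] * brx[ix + 1]),  # geometric bin centres
             cy = sqrt(bry[iy] * bry[iy + 1]),
             area = (brx[ix + 1] - brx[ix]) * (bry[iy + 1] - bry[iy]))]
  tab[, dens := N / area]
  if (nrow(tab) < 5) stop("degenerate support: too few occupied bins")
  fit <- function(metric) {
    m <- stats::lm(log(dens) ~ log(metric), data = tab, weights = tab$N)
    list(exponent = unname(stats::coef(m)[2]),
         rss = sum(stats::resid(m)^2 * tab$N) / sum(tab$N))
  }
  f05 <- fit(sqrt(tab$cx) + sqrt(tab$cy))
  f1 <- fit(tab$cx + tab$cy)
  list(exponent_l05 = f05$exponent, exponent_l1 = f1$exponent,
       rss_l05 = f05$rss, rss_l1 = f1$rss,
       preferred = if (f05$rss <= f1$rss) "l05" else "l1",
       table = tab[])
}

#' Conditional contact-density analysis of a contact set
#'
#' For every ordered pair of contacts sharing a chromosome pair, computes
#' the leg-wise coordinate differences `(dx, dy)` (within `max_sep`) and
#' fits the two candidate density laws with [fit_contact_decay()].
#'
#' @param contacts a [contact_set()].
#' @param max_sep largest difference retained (bp).
#' @param min_sep smallest difference retained (bp); avoids duplicate-read
#'   artefacts at zero separation.
#' @param n_bins log-spaced bins per axis.
#' @return As [fit_contact_decay()].
#' @export
conditional_density <- function(contacts, max_sep = Inf, min_sep = 1,
                                n_bins = 12) {
  dt <- as.data.table(contacts)
  if (nrow(dt) < 2) stop("need at least 2 contacts sharing a chromosome pair")
  dxs <- vector("list", 0L)
  dys <- vector("list", 0L)
  for (grp in split(seq_len(nrow(dt)), paste(dt$chr_a, dt$chr_b))) {
    if (length(grp) < 2) next
    g <- dt[grp]
    pa <- g$pos_a; pb <- g$pos_b
    for (k in seq_along(grp)) {
      dx <- abs(pa - pa[k])[-k]
      dy <- abs(pb - pb[k])[-k]
      keep <- dx >= min_sep & dy >= min_sep & dx <= max_sep & dy <= max_sep
      dxs[[length(dxs) + 1L]] <- dx[keep]
      dys[[length(dys) + 1L]] <- dy[keep]
    }
  }
  fit_contact_decay(unlist(dxs), unlist(dys), n_bins = n_bins)
}

#' Sample (dx, dy) pairs from a contact-decay law
#'
#' Inverse-model sampler used to validate [fit_contact_decay()]: draws pairs
#' from `p(dx, dy) proportional to (sqrt(dx) + sqrt(dy))^-2` (`model =
#' "l05"`) or `(dx + dy)^-1` (`model = "l1"`) on a log-log support square,
#' by rejection sampling.
#'
#' @param n number of pairs.
#' @param model `"l05"` or `"l1"`.
#' @param range support range in bp, `c(lo, hi)`.
#' @param seed RNG seed.
#' @return `data.table(dx, dy)`.
#' @export
sample_decay_pairs <- function(n, model = c("l05", "l1"),
                               range = c(1e4, 1e8), seed = NULL) {
  model <- match.arg(model)
  lo <- log(range[1]); hi <- log(range[2])
  # in (u, v) = (log dx, log dy) the target density is
  #   l05: exp(u + v) / (exp(u/2) + exp(v/2))^2, maximum exp(hi)/4 at (hi, hi)
  #   l1:  exp(u + v) / (exp(u) + exp(v)),       maximum exp(hi)/2 at (hi, hi)
  # (both increase in u and v), so uniform-proposal rejection against that
  # constant bound samples the law exactly on the truncated support
  gmax <- if (model == "l05") exp(hi) / 4 else exp(hi) / 2
  with_seed(seed, {
    out_dx <- numeric(0)
    out_dy <- numeric(0)
    while (length(out_dx) < n) {
      m <- max(20L * (n - length(out_dx)), 10000L)
      u <- runif(m, lo, hi)
      v <- runif(m, lo, hi)
      g <- if (model == "l05") {
        exp(u + v) / (exp(u / 2) + exp(v / 2))^2
      } else {
        exp(u + v) / (exp(u) + exp(v))
      }
      acc <- runif(m) < g / gmax
      out_dx <- c(out_dx, exp(u[acc]))
      out_dy <- c(out_dy, exp(v[acc]))
    }
    data.table(dx = out_dx[seq_len(n)], dy = out_dy[seq_len(n)])
  })
}
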