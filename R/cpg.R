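#' Binned CpG-frequency track
#'
#' Per-bin CpG frequency along the genome, used as a proxy for euchromatin
#' (CpG-rich bins) versus heterochromatin (CpG-poor bins). Stored as a
#' `data.table` with columns `chrom`, `bin` (0-based) and `cpg` (>= 0), one
#' row per bin of every chromosome.
#'
#' @param genome a [genome_spec()].
#' @param values list of numeric vectors (one per chromosome, in genome
#'   order) or a data.frame with columns `chrom`, `bin`, `cpg`.
#' @param bin_size track bin size in bp; defaults to the genome's.
#' @return A `cpg_track`.
#' @export
cpg_track <- function(genome, values, bin_size = genome$bin_size) {
  nb <- n_bins(genome, bin_size)
  if (is.list(values) && !is.data.frame(values)) {
    stopifnot(length(values) == length(genome$chroms))
    dt <- data.table(chrom = rep(genome$chroms, nb),
                     bin = unlist(lapply(nb, function(k) seq_len(k) - 1L)),
                     cpg = unlist(values))
  } else {
    dt <- as.data.table(values)[, .(chrom, bin = as.integer(bin), cpg)]
  }
  if (any(dt$cpg < 0)) stop("CpG frequencies must be non-negative")
  cnt <- dt[, .N, by = chrom]
  expect <- stats::setNames(nb, genome$chroms)
  if (!all(cnt$N == expect[cnt$chrom]) || nrow(cnt) != length(genome$chroms))
    stop("CpG track must have exactly one value per bin of every chromosome")
  if (anyDuplicated(dt[, .(chrom, bin)])) stop("duplicate (chrom, bin) in CpG track")
  setorder(dt, chrom, bin)
  data.table::setattr(dt, "bin_size", bin_size)
  data.table::setattr(dt, "genome", genome)
  data.table::setattr(dt, "class", c("cpg_track", class(dt)))
  dt
}

track_bin_size <- function(track) attr(track, "bin_size", exact = TRUE)

#' Look up CpG values at genomic bins
#'
#' Returns the CpG frequency of the query bins. When `bin_size` is a
#' multiple of the track's own bin size, track bins falling inside each
#' query bin are averaged.
#'
#' @param track a [cpg_track()].
#' @param chrom,bin query chromosome names and 0-based bin indices.
#' @param bin_size bin size of the query bins (defaults to the track's).
#' @return Numeric vector of CpG values (NA where the bin is missing).
#' @export
cpg_at <- function(track, chrom, bin, bin_size = track_bin_size(track)) {
  ts <- track_bin_size(track)
  if (bin_size == ts) {
    q <- data.table(chrom = chrom, bin = as.integer(bin))
    return(track[q, on = c("chrom", "bin")]$cpg)
  }
  if (bin_size %% ts != 0)
    stop("query bin size must be a multiple of the track bin size")
  k <- as.integer(bin_size / ts)
  agg <- track[, .(chrom, bin = bin %/% k, cpg)][
    , .(cpg = mean(cpg)), by = .(chrom, bin)]
  q <- data.table(chrom = chrom, bin = as.integer(bin))
  agg[q, on = c("chrom", "bin")]$cpg
}
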