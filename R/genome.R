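#' Genome specification
#'
#' Defines the coordinate system shared by all other objects: an ordered set
#' of chromosome names, their lengths in bp, and the bin size used when the
#' genome is discretised into particles or analysis bins. Coordinates are
#' 0-based and bins are half-open `[k*bin_size, (k+1)*bin_size)`.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp
#'   (names are the chromosome names; unnamed vectors get `chr1`, `chr2`, ...).
#' @param bin_size bin size in bp (> 0).
#' @return An object of class `genome_spec`.
#' @examples
#' g <- genome_spec(c(chr1 = 50e6, chr2 = 50e6), bin_size = 1e6)
#' n_bins(g)
#' @export
genome_spec <- function(chrom_lengths, bin_size) {
  stopifnot(is.numeric(chrom_lengths), length(chrom_lengths) >= 1,
            all(chrom_lengths > 0), is.numeric(bin_size), length(bin_size) == 1,
            bin_size > 0)
  nm <- names(chrom_lengths)
  if (is.null(nm)) nm <- paste0("chr", seq_along(chrom_lengths))
  if (anyDuplicated(nm)) stop("chromosome names must be unique")
  structure(list(chroms = nm,
                 lengths = stats::setNames(as.numeric(chrom_lengths), nm),
                 bin_size = as.numeric(bin_size)),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("<genome_spec> ", length(x$chroms), " chromosomes, ",
      format(sum(x$lengths), big.mark = ","), " bp total, bin size ",
      format(x$bin_size, big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Number of bins per chromosome
#' @param genome a [genome_spec()].
#' @param bin_size optional bin size overriding the genome's own.
#' @return Named integer vector of bin counts.
#' @export
n_bins <- function(genome, bin_size = genome$bin_size) {
  as.integer(ceiling(genome$lengths / bin_size))
}

chrom_index <- function(genome, chrom) {
  i <- match(chrom, genome$chroms)
  if (anyNA(i)) stop("chromosome(s) not in genome: ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  i
}

#' Bin index of a genomic coordinate
#'
#' Bins are half-open: coordinate `c` falls in bin `floor(c / bin_size)`.
#'
#' @param coordinate coordinate(s) in bp, 0-based, `>= 0`.
#' @param bin_size bin size in bp (> 0).
#' @return Integer bin index (0-based).
#' @examples
#' bin_of(999999, 1e6)  # 0
#' bin_of(1e6, 1e6)     # 1
#' @export
bin_of <- function(coordinate, bin_size) {
  if (length(bin_size) != 1 || !is.finite(bin_size) || bin_size <= 0)
    stop("bin_size must be a single positive number")
  if (any(coordinate < 0)) stop("coordinates must be >= 0")
  as.integer(floor(coordinate / bin_size))
}
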