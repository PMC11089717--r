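#' Diploid 3D genome structure
#'
#' Particle model of one nucleus: one particle per (chromosome, haplotype,
#' bin), stored as a `data.table` with columns `chrom`, `hap` (`"mat"` /
#' `"pat"` / `"unknown"`), `pos` (bin start, bp) and model-unit coordinates
#' `x`, `y`, `z`. Carries the bin size, the nominal particle radius and the
#' cell id as attributes.
#'
#' @param x data.frame with columns `chrom`, `hap`, `pos`, `x`, `y`, `z`.
#' @param bin_size structure resolution in bp.
#' @param radius nominal particle radius in model units.
#' @param cell_id cell identifier.
#' @param genome optional [genome_spec()] for validation and ordering.
#' @return A `structure_3d`.
#' @export
structure_3d <- function(x, bin_size, radius = 0.5, cell_id = "cell",
                         genome = NULL) {
  dt <- as.data.table(x)[, .(chrom, hap, pos = as.numeric(pos),
                             x = as.numeric(x), y = as.numeric(y),
                             z = as.numeric(z))]
  if (!all(dt$hap %in% .HAPS)) stop("haplotype must be one of ",
                                    paste(.HAPS, collapse = ", "))
  if (!all(is.finite(dt$x) & is.finite(dt$y) & is.finite(dt$z)))
    stop("particle coordinates must be finite")
  dup <- duplicated(dt[, .(chrom, hap, pos)])
  if (any(dup)) {
    d <- dt[which(dup)[1]]
    stop(sprintf("duplicate particle key: %s(%s) at %d", d$chrom, d$hap,
                 as.integer(d$pos)))
  }
  if (!is.null(genome)) {
    chrom_index(genome, unique(dt$chrom))
    dt <- dt[order(chrom_index(genome, chrom), hap, pos)]
  } else {
    setorder(dt, chrom, hap, pos)
  }
  data.table::setattr(dt, "bin_size", as.numeric(bin_size))
  data.table::setattr(dt, "radius", as.numeric(radius))
  data.table::setattr(dt, "cell_id", cell_id)
  if (!is.null(genome)) data.table::setattr(dt, "genome", genome)
  data.table::setattr(dt, "class", c("structure_3d", class(dt)))
  dt
}

structure_bin_size <- function(s) attr(s, "bin_size", exact = TRUE)
particle_radius <- function(s) attr(s, "radius", exact = TRUE)

#' @export
print.structure_3d <- function(x, ...) {
  cat("<structure_3d> cell '", attr(x, "cell_id", exact = TRUE) %||% "?", "': ",
      nrow(x), " particles, ", length(unique(x$chrom)), " chromosomes, bin ",
      format(structure_bin_size(x), big.mark = ","), " bp, particle radius ",
      particle_radius(x), "\n", sep = "")
  invisible(x)
}

coords_matrix <- function(s) as.matrix(as.data.table(s)[, .(x, y, z)])

#' Apply a rigid motion (plus optional reflection) to a structure
#'
#' Utility used to verify that downstream metrics are invariant under global
#' rotation, translation and reflection.
#'
#' @param s a [structure_3d()].
#' @param rotation 3x3 orthogonal matrix.
#' @param translation length-3 numeric vector.
#' @return The transformed `structure_3d`.
#' @export
transform_structure <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  m <- coords_matrix(s) %*% t(rotation)
  dt <- as.data.table(s)
  dt[, `:=`(x = m[, 1] + translation[1],
            y = m[, 2] + translation[2],
            z = m[, 3] + translation[3])]
  structure_3d(dt, bin_size = structure_bin_size(s),
               radius = particle_radius(s),
               cell_id = attr(s, "cell_id", exact = TRUE),
               genome = attr(s, "genome", exact = TRUE))
}

#' Random orthogonal 3x3 matrix (possibly a reflection)
#' @param allow_reflection include determinant -1 transforms.
#' @return 3x3 orthogonal matrix.
#' @export
random_rotation <- function(allow_reflection = TRUE) {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (!allow_reflection && det(q) < 0) q[, 1] <- -q[, 1]
  q
}
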