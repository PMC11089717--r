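#' Read a single-cell contact file
#'
#' Contacts are whitespace-delimited with six columns per line:
#' `chrA posA hapA chrB posB hapB`, haplotypes `mat`, `pat` or `.` for
#' unknown. Legs are canonicalized on read.
#'
#' @param path file path.
#' @param genome a [genome_spec()]; unknown chromosomes are an error.
#' @param cell_id cell identifier (defaults to the file name).
#' @param stage provenance stage tag for the returned set.
#' @return A [contact_set()].
#' @export
read_contacts <- function(path, genome, cell_id = basename(path), stage = "raw") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0)
    return(contact_set(data.table(chr_a = character(), pos_a = numeric(),
                                  hap_a = character(), chr_b = character(),
                                  pos_b = numeric(), hap_b = character()),
                       genome, cell_id = cell_id, stage = stage))
  dt <- tryCatch(
    suppressWarnings(
      fread(path, header = FALSE, sep = " ", fill = FALSE,
            colClasses = list(character = c(1, 3, 4, 6), numeric = c(2, 5)))),
    error = function(e) stop("malformed contact file '", path, "': ",
                             conditionMessage(e)))
  if (ncol(dt) != 6) {
    bad <- which(lengths(strsplit(readLines(path), "[ \t]+")) != 6)[1]
    stop("malformed contact file '", path, "': line ", bad %||% 1,
         " does not have 6 fields")
  }
  setnames(dt, c("chr_a", "pos_a", "hap_a", "chr_b", "pos_b", "hap_b"))
  for (col in c("hap_a", "hap_b")) {
    v <- dt[[col]]
    v[v == "."] <- "unknown"
    if (!all(v %in% .HAPS))
      stop("malformed contact file '", path, "': line ",
           which(!dt[[col]] %in% c(".", .HAPS))[1], " has invalid haplotype")
    data.table::set(dt, j = col, value = v)
  }
  contact_set(dt, genome, cell_id = cell_id, stage = stage)
}

#' Write a contact set
#' @param x a [contact_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(x, path) {
  dt <- as.data.table(x)[, .(chr_a, pos_a = format(pos_a, scientific = FALSE,
                                                   trim = TRUE),
                             hap_a, chr_b,
                             pos_b = format(pos_b, scientific = FALSE,
                                            trim = TRUE), hap_b)]
  dt[hap_a == "unknown", hap_a := "."]
  dt[hap_b == "unknown", hap_b := "."]
  fwrite(dt, path, sep = " ", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write 3DG structure files
#'
#' The 3DG dialect is tab-delimited with five columns: chromosome name (with
#' the haplotype as a `(mat)` / `(pat)` suffix), bin start coordinate (bp),
#' and x, y, z in model units. `write_3dg()` followed by `read_3dg()` is the
#' identity up to float formatting.
#'
#' @param path file path.
#' @param bin_size structure resolution in bp.
#' @param radius nominal particle radius in model units.
#' @param cell_id cell identifier.
#' @param genome optional [genome_spec()].
#' @return `read_3dg()` returns a [structure_3d()].
#' @export
read_3dg <- function(path, bin_size, radius = 0.5, cell_id = basename(path),
                     genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- tryCatch(
    suppressWarnings(fread(path, header = FALSE, sep = "\t",
                           colClasses = list(character = 1,
                                             numeric = c(2, 3, 4, 5)))),
    error = function(e) stop("malformed 3DG file '", path, "': ",
                             conditionMessage(e)))
  if (ncol(dt) != 5) stop("malformed 3DG file '", path, "': expected 5 columns")
  setnames(dt, c("name", "pos", "x", "y", "z"))
  if (!all(is.finite(dt$x) & is.finite(dt$y) & is.finite(dt$z)))
    stop("malformed 3DG file '", path, "': non-numeric coordinate")
  hap <- rep("unknown", nrow(dt))
  hap[grepl("\\(mat\\)$", dt$name)] <- "mat"
  hap[grepl("\\(pat\\)$", dt$name)] <- "pat"
  chrom <- sub("\\((mat|pat)\\)$", "", dt$name)
  structure_3d(data.table(chrom = chrom, hap = hap, pos = dt$pos,
                          x = dt$x, y = dt$y, z = dt$z),
               bin_size = bin_size, radius = radius, cell_id = cell_id,
               genome = genome)
}

#' @param structure a [structure_3d()].
#' @rdname read_3dg
#' @export
write_3dg <- function(structure, path) {
  dt <- as.data.table(structure)
  name <- ifelse(dt$hap == "unknown", dt$chrom,
                 paste0(dt$chrom, "(", dt$hap, ")"))
  out <- data.table(name = name,
                    pos = format(dt$pos, scientific = FALSE, trim = TRUE),
                    x = dt$x, y = dt$y, z = dt$z)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CpG track from a bedGraph file
#'
#' @param path bedGraph path (chrom, start, end, value).
#' @param genome a [genome_spec()].
#' @param bin_size track bin size in bp; intervals must align to it.
#' @return A [cpg_track()].
#' @export
read_cpg_bedgraph <- function(path, genome, bin_size = genome$bin_size) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   cpg = gr$score)
  dt[, bin := bin_of(start, bin_size)]
  cpg_track(genome, dt[, .(chrom, bin, cpg)], bin_size = bin_size)
}

#' Write a CpG track as bedGraph
#' @param track a [cpg_track()].
#' @param path output path.
#' @param genome a [genome_spec()] (for chromosome lengths).
#' @export
write_cpg_bedgraph <- function(track, path, genome = attr(track, "genome")) {
  bs <- track_bin_size(track)
  dt <- as.data.table(track)
  gr <- GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$bin * bs + 1,
                              end = pmin((dt$bin + 1) * bs,
                                         genome$lengths[dt$chrom])),
    score = dt$cpg)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read loci from a BED4 file
#'
#' @param path BED path (chrom, start, end, name); BED is 0-based half-open,
#'   matching the package's coordinate convention.
#' @param genome a [genome_spec()].
#' @return `data.table` with columns `chrom`, `start`, `end`, `name`.
#' @export
read_loci_bed <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "bed")
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = gr$name %||% paste0("locus", seq_along(gr)))
  chrom_index(genome, unique(dt$chrom))
  dt[]
}
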