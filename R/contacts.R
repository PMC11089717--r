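#' Single-cell contact set
#'
#' A `contact_set` holds all chromatin contacts of one cell as a
#' `data.table` with columns `chr_a`, `pos_a`, `hap_a`, `chr_b`, `pos_b`,
#' `hap_b` plus a stable integer `id` per contact. Haplotypes take values
#' `"mat"`, `"pat"` or `"unknown"`. Contacts are stored canonically: leg A
#' precedes leg B under the ordering (chromosome index, coordinate,
#' haplotype).
#'
#' @param x data.frame with the six leg columns (an `id` column is preserved
#'   if present, otherwise assigned).
#' @param genome a [genome_spec()]; all chromosomes must be listed in it.
#' @param cell_id cell identifier string.
#' @param stage provenance stage, one of `"raw"`, `"imputed"`, `"cleaned"`.
#' @return A `contact_set` (also a `data.table`).
#' @export
contact_set <- function(x, genome, cell_id = "cell", stage = "raw") {
  stage <- match.arg(stage, c("raw", "imputed", "cleaned"))
  dt <- as.data.table(x)
  need <- c("chr_a", "pos_a", "hap_a", "chr_b", "pos_b", "hap_b")
  if (!all(need %in% names(dt)))
    stop("contact table must have columns ", paste(need, collapse = ", "))
  if (nrow(dt) > 0) {
    bad <- setdiff(unique(c(dt$chr_a, dt$chr_b)), genome$chroms)
    if (length(bad))
      stop("chromosome(s) not in genome: ", paste(bad, collapse = ", "))
    if (!all(dt$hap_a %in% .HAPS) || !all(dt$hap_b %in% .HAPS))
      stop("haplotypes must be one of ", paste(.HAPS, collapse = ", "))
    len_a <- genome$lengths[dt$chr_a]
    len_b <- genome$lengths[dt$chr_b]
    if (any(dt$pos_a < 0) || any(dt$pos_b < 0) ||
        any(dt$pos_a >= len_a) || any(dt$pos_b >= len_b))
      stop("leg coordinates must satisfy 0 <= pos < chromosome length")
  }
  if (!"id" %in% names(dt)) dt[, id := seq_len(.N)]
  dt <- canonicalize_contacts(dt, genome)
  data.table::setattr(dt, "genome", genome)
  data.table::setattr(dt, "cell_id", cell_id)
  data.table::setattr(dt, "stage", stage)
  data.table::setattr(dt, "class", c("contact_set", class(dt)))
  dt
}

#' Canonicalize contact legs
#'
#' Orders the two legs of every contact so that leg A <= leg B under
#' (chromosome index, coordinate, haplotype). Idempotent.
#'
#' @param x contact table (data.frame or `contact_set`).
#' @param genome a [genome_spec()] supplying the chromosome order.
#' @return The table with legs swapped where needed (a copy).
#' @export
canonicalize_contacts <- function(x, genome) {
  dt <- as.data.table(x)
  if (nrow(dt) == 0) return(dt)
  ia <- chrom_index(genome, dt$chr_a)
  ib <- chrom_index(genome, dt$chr_b)
  ha <- hap_to_int(dt$hap_a)
  hb <- hap_to_int(dt$hap_b)
  swap <- (ia > ib) |
    (ia == ib & dt$pos_a > dt$pos_b) |
    (ia == ib & dt$pos_a == dt$pos_b & ha > hb)
  if (any(swap)) {
    tmp <- dt[swap, .(chr_a, pos_a, hap_a)]
    dt[swap, `:=`(chr_a = chr_b, pos_a = pos_b, hap_a = hap_b)]
    dt[swap, `:=`(chr_b = tmp$chr_a, pos_b = tmp$pos_a, hap_b = tmp$hap_a)]
  }
  dt
}

contact_stage <- function(x) attr(x, "stage", exact = TRUE)
contact_genome <- function(x) attr(x, "genome", exact = TRUE)

set_stage <- function(x, stage) {
  data.table::setattr(x, "stage", stage)
  x
}

# rebuild a contact_set around a plain data.table, keeping metadata
rewrap_contacts <- function(dt, template, stage = contact_stage(template)) {
  data.table::setattr(dt, "genome", contact_genome(template))
  data.table::setattr(dt, "cell_id", attr(template, "cell_id", exact = TRUE))
  data.table::setattr(dt, "stage", stage)
  if (!inherits(dt, "contact_set"))
    data.table::setattr(dt, "class", c("contact_set", class(dt)))
  dt
}

#' @export
print.contact_set <- function(x, ...) {
  n_inter <- if (nrow(x)) sum(x$chr_a != x$chr_b) else 0L
  n_unres <- if (nrow(x)) sum(x$hap_a == "unknown") + sum(x$hap_b == "unknown") else 0L
  cat("<contact_set> cell '", attr(x, "cell_id", exact = TRUE) %||% "?",
      "', stage ", contact_stage(x) %||% "?", ": ", nrow(x), " contacts (",
      n_inter, " interchromosomal, ", n_unres, " unknown legs)\n", sep = "")
  if (nrow(x)) print(as.data.table(utils::head(x, 5)))
  invisible(x)
}
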