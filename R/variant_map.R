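#' Build and validate a variant map
#'
#' A variant map is a tibble with one row per biallelic SNP and columns
#' `chrom` (character), `pos_bp` (1-based physical position), `pos_cm`
#' (genetic position in centimorgan), `id`, `ref`, `alt`. Positions must be
#' strictly increasing within a chromosome on both scales.
#'
#' @param chrom Character vector of chromosome labels.
#' @param pos_bp Integer vector of 1-based physical positions.
#' @param pos_cm Numeric vector of genetic positions (cM). If `NULL`, a
#'   uniform 1 cM/Mb map is assumed (the standard convention).
#' @param id Variant identifiers; defaults to `chrom:pos` style labels.
#' @param ref,alt Allele labels (defaults `"A"`/`"G"`).
#' @return A tibble of class `variant_map`.
#' @examples
#' variant_map(chrom = c("1", "1"), pos_bp = c(1000L, 2000L))
#' @export
variant_map <- function(chrom, pos_bp, pos_cm = NULL,
                        id = NULL, ref = "A", alt = "G") {
  chrom <- as.character(chrom)
  pos_bp <- as.integer(pos_bp)
  if (is.null(pos_cm)) pos_cm <- pos_bp * 1e-6 * 1 # 1 cM/Mb
  if (is.null(id)) id <- paste0("snp_", chrom, "_", pos_bp)
  map <- tibble::tibble(
    chrom = chrom, pos_bp = pos_bp, pos_cm = as.numeric(pos_cm),
    id = as.character(id),
    ref = rep_len(as.character(ref), length(chrom)),
    alt = rep_len(as.character(alt), length(chrom))
  )
  validate_variant_map(map)
  class(map) <- c("variant_map", class(tibble::tibble()))
  map
}

validate_variant_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("chrom", "pos_bp", "pos_cm", "id", "ref", "alt") %in% names(map)))
  if (nrow(map) == 0L) abort("variant map is empty")
  if (anyDuplicated(map$id)) abort("variant ids must be unique")
  if (any(map$pos_cm < 0)) abort("pos_cm must be non-negative")
  if (any(map$ref == map$alt)) abort("every variant must be biallelic (ref != alt)")
  for (ch in unique(map$chrom)) {
    i <- map$chrom == ch
    if (is.unsorted(map$pos_bp[i], strictly = TRUE)) {
      abort(paste0("pos_bp not strictly increasing on chromosome ", ch))
    }
    if (is.unsorted(map$pos_cm[i], strictly = TRUE)) {
      abort(paste0("pos_cm not strictly increasing on chromosome ", ch))
    }
  }
  invisible(map)
}

#' Default multi-chromosome variant map
#'
#' Evenly spaced SNPs on five mock chromosomes ("2", "6", "11", "15", "20"),
#' the chromosomes on which the scenario presets place their risk loci. Each
#' chromosome spans `chrom_length_mb` megabases under a uniform 1 cM/Mb map,
#' so scaled-down maps (fewer SNPs) keep a realistic genetic length and
#' recombination behaviour. Inter-SNP spacing is forced even so that tract
#' midpoints fall on integer base pairs.
#'
#' @param n_snps_per_chrom SNPs per chromosome (default 4000).
#' @param chroms Chromosome labels.
#' @param chrom_length_mb Physical length per chromosome in Mb (default 100,
#'   i.e. 100 cM at 1 cM/Mb).
#' @return A `variant_map` tibble.
#' @examples
#' map <- default_variant_map(n_snps_per_chrom = 50)
#' table(map$chrom)
#' @export
default_variant_map <- function(n_snps_per_chrom = 4000,
                                chroms = c("2", "6", "11", "15", "20"),
                                chrom_length_mb = 100) {
  spacing <- floor(chrom_length_mb * 1e6 / n_snps_per_chrom / 2) * 2
  if (spacing < 2) abort("too many SNPs for the requested chromosome length")
  pos <- spacing * seq_len(n_snps_per_chrom)
  variant_map(
    chrom = rep(chroms, each = n_snps_per_chrom),
    pos_bp = rep(pos, times = length(chroms))
  )
}

# Split row indices of a map by chromosome, preserving map order.
map_chrom_index <- function(map) {
  split(seq_len(nrow(map)), factor(map$chrom, levels = unique(map$chrom)))
}

# Half-open cell boundaries around each SNP: boundaries[i], boundaries[i+1]
# delimit the genomic cell owned by SNP i (midpoints between neighbours,
# symmetric extension at chromosome ends). Returns list(bp=, cm=) vectors of
# length n_sites + 1 for one chromosome.
site_cells <- function(pos_bp, pos_cm) {
  n <- length(pos_bp)
  if (n == 1L) {
    return(list(bp = c(pos_bp - 1, pos_bp + 1), cm = c(pos_cm - 1e-9, pos_cm + 1e-9)))
  }
  mid_bp <- (pos_bp[-n] + pos_bp[-1]) / 2
  mid_cm <- (pos_cm[-n] + pos_cm[-1]) / 2
  bp <- c(2 * pos_bp[1] - mid_bp[1], mid_bp, 2 * pos_bp[n] - mid_bp[n - 1])
  cm <- c(2 * pos_cm[1] - mid_cm[1], mid_cm, 2 * pos_cm[n] - mid_cm[n - 1])
  list(bp = bp, cm = cm)
}
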