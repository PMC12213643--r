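#' Local-ancestry matrix with tract representation
#'
#' Holds per-haplotype, per-site ancestry assignments (truth labels from the
#' simulation) together with the equivalent tract representation: half-open
#' `[start_bp, end_bp)` intervals, 1-based, whose boundaries are the midpoints
#' between flanking SNPs (with a symmetric extension at chromosome ends so
#' tracts tile each chromosome exactly).
#'
#' @param assignments Integer matrix (2N haplotypes x M sites, values
#'   `0..K-1`), e.g. the `ancestry` field of a `haplotype_set`.
#' @param map The [variant_map()] the columns are aligned to.
#' @param hap_ids Optional haplotype identifiers.
#' @param n_pops Number of ancestries `K`; inferred from the labels if absent.
#' @return A `local_ancestry` object: list with `assignments`, `tracts`
#'   (tibble: hap_id, chrom, start_bp, end_bp, ancestry), `hap_ids`, `map`,
#'   `n_pops`.
#' @export
local_ancestry <- function(assignments, map, hap_ids = NULL, n_pops = NULL) {
  storage.mode(assignments) <- "integer"
  if (ncol(assignments) != nrow(map)) {
    abort("assignments must have one column per map site")
  }
  if (is.null(hap_ids)) {
    hap_ids <- paste0("ind", rep(seq_len(nrow(assignments) / 2L), each = 2L),
                      "_h", rep(1:2, times = nrow(assignments) / 2L))
  }
  if (is.null(n_pops)) n_pops <- max(assignments) + 1L
  if (any(assignments < 0L | assignments >= n_pops)) {
    abort("ancestry labels must lie in 0..K-1")
  }
  structure(
    list(assignments = assignments,
         tracts = tracts_from_assignments(assignments, map, hap_ids),
         hap_ids = hap_ids, map = map, n_pops = as.integer(n_pops)),
    class = "local_ancestry"
  )
}

#' @export
print.local_ancestry <- function(x, ...) {
  cat("<local_ancestry> ", nrow(x$assignments), " haplotypes x ",
      ncol(x$assignments), " sites; K = ", x$n_pops, "; ",
      nrow(x$tracts), " tracts\n", sep = "")
  invisible(x)
}

#' Compress per-site ancestry assignments to tracts
#'
#' @param assignments Integer matrix (haplotypes x sites).
#' @param map Variant map aligned to the columns.
#' @param hap_ids Haplotype identifiers (one per row).
#' @return Tibble with columns `hap_id`, `chrom`, `start_bp`, `end_bp`,
#'   `ancestry`; intervals are half-open and tile each chromosome.
#' @export
tracts_from_assignments <- function(assignments, map, hap_ids = NULL) {
  if (is.null(hap_ids)) hap_ids <- paste0("h", seq_len(nrow(assignments)))
  idx <- map_chrom_index(map)
  out <- vector("list", length(idx) * nrow(assignments))
  j <- 0L
  for (ch in names(idx)) {
    sites <- idx[[ch]]
    cells <- site_cells(map$pos_bp[sites], map$pos_cm[sites])
    for (h in seq_len(nrow(assignments))) {
      r <- rle(assignments[h, sites])
      ends <- cumsum(r$lengths)
      starts <- c(1L, head(ends, -1L) + 1L)
      j <- j + 1L
      out[[j]] <- tibble::tibble(
        hap_id = hap_ids[h], chrom = ch,
        start_bp = cells$bp[starts], end_bp = cells$bp[ends + 1L],
        ancestry = as.integer(r$values))
    }
  }
  dplyr::bind_rows(out)
}

#' Expand tracts back to per-site assignments
#'
#' Validates that the tracts tile each chromosome (no gaps, no overlaps) and
#' assigns each map site the ancestry of the tract whose half-open interval
#' contains its position.
#'
#' @param tracts Tract tibble as produced by [tracts_from_assignments()].
#' @param map Variant map.
#' @param hap_ids Haplotype identifiers fixing the row order of the result.
#' @return Integer matrix (length(hap_ids) x nrow(map)).
#' @export
assignments_from_tracts <- function(tracts, map, hap_ids = NULL) {
  if (is.null(hap_ids)) hap_ids <- unique(tracts$hap_id)
  idx <- map_chrom_index(map)
  out <- matrix(NA_integer_, nrow = length(hap_ids), ncol = nrow(map))
  key <- split(seq_len(nrow(tracts)),
               list(factor(tracts$hap_id, levels = hap_ids),
                    factor(tracts$chrom, levels = names(idx))), drop = FALSE)
  for (h in seq_along(hap_ids)) {
    for (ch in names(idx)) {
      rows <- key[[paste(hap_ids[h], ch, sep = ".")]]
      if (length(rows) == 0L) {
        abort(paste0("no tracts for haplotype ", hap_ids[h],
                     " on chromosome ", ch))
      }
      tr <- tracts[rows, ]
      tr <- tr[order(tr$start_bp), ]
      if (any(tr$end_bp[-nrow(tr)] != tr$start_bp[-1])) {
        abort(paste0("tracts do not tile chromosome ", ch,
                     " for haplotype ", hap_ids[h], " (gap or overlap)"))
      }
      pos <- map$pos_bp[idx[[ch]]]
      at <- findInterval(pos, tr$start_bp)
      if (any(at == 0L) || any(pos >= tr$end_bp[nrow(tr)])) {
        abort(paste0("tracts do not cover all sites on chromosome ", ch,
                     " for haplotype ", hap_ids[h]))
      }
      out[h, idx[[ch]]] <- tr$ancestry[at]
    }
  }
  out
}

#' Per-individual global ancestry from local-ancestry tracts
#'
#' Global ancestry of individual `i` for ancestry `k` is the cM-weighted
#' genome length assigned to `k` over both haplotypes, divided by twice the
#' total map length. Rows sum to 1.
#'
#' @param la A [local_ancestry()] object.
#' @param map Variant map (defaults to the one stored in `la`).
#' @return N x K matrix of proportions (individuals in haplotype-pair order).
#' @export
global_ancestry_from_tracts <- function(la, map = la$map) {
  stopifnot(inherits(la, "local_ancestry"))
  idx <- map_chrom_index(map)
  # piecewise-linear bp -> cM interpolation per chromosome, extended to the
  # tract tiling boundaries
  interp <- lapply(names(idx), function(ch) {
    sites <- idx[[ch]]
    cells <- site_cells(map$pos_bp[sites], map$pos_cm[sites])
    list(x = c(cells$bp[1], map$pos_bp[sites], cells$bp[length(cells$bp)]),
         y = c(cells$cm[1], map$pos_cm[sites], cells$cm[length(cells$cm)]))
  })
  names(interp) <- names(idx)
  tr <- la$tracts
  cm_len <- numeric(nrow(tr))
  for (ch in names(idx)) {
    rows <- which(tr$chrom == ch)
    ip <- interp[[ch]]
    cm_len[rows] <- approx(ip$x, ip$y, tr$end_bp[rows], rule = 2)$y -
      approx(ip$x, ip$y, tr$start_bp[rows], rule = 2)$y
  }
  hap_of <- match(tr$hap_id, la$hap_ids)
  ind_of <- (hap_of + 1L) %/% 2L
  k <- la$n_pops
  n <- length(la$hap_ids) %/% 2L
  out <- matrix(0, nrow = n, ncol = k)
  for (a in seq_len(k) - 1L) {
    rows <- tr$ancestry == a
    if (any(rows)) {
      s <- tapply(cm_len[rows], factor(ind_of[rows], levels = seq_len(n)), sum)
      s[is.na(s)] <- 0
      out[, a + 1L] <- s
    }
  }
  out / rowSums(out)
}

#' Corrupt local-ancestry labels with independent per-site errors
#'
#' Utility for studying sensitivity of ancestry-aware tests to local-ancestry
#' inference error: each site's label is replaced, with probability `epsilon`,
#' by a uniformly drawn different ancestry.
#'
#' @param la A [local_ancestry()] object.
#' @param epsilon Per-site relabel probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A new `local_ancestry` object.
#' @export
noisy_local_ancestry <- function(la, epsilon, seed = 1) {
  stopifnot(inherits(la, "local_ancestry"), epsilon >= 0, epsilon <= 1)
  if (la$n_pops < 2) abort("need K >= 2 ancestries to corrupt labels")
  with_child_seed(seed, "noisy_local_ancestry", 0L, {
    a <- la$assignments
    hit <- which(matrix(runif(length(a)) < epsilon, nrow(a), ncol(a)))
    if (length(hit)) {
      shift <- sample.int(la$n_pops - 1L, length(hit), replace = TRUE)
      a[hit] <- (a[hit] + shift) %% la$n_pops
    }
    local_ancestry(a, la$map, la$hap_ids, la$n_pops)
  })
}
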