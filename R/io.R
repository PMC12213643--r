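# File formats. Coordinates are 1-based in all files; local-ancestry tracts
# use half-open [start_bp, end_bp) intervals. Missing values are written as
# "." and numbers with explicit C-locale formatting.

fmt_num <- function(x, digits = 10) {
  ifelse(is.na(x), ".", formatC(x, format = "g", digits = digits))
}

#' Write a cohort to VCF (4.2 text subset)
#'
#' Diploid GT records; phased `|` separators when haplotypes are retained,
#' `/` otherwise. Case/control status is stored in a `PHENO=` header line so
#' a VCF round trip is lossless for genotypes, positions, ids and phenotype.
#'
#' @param cohort A `cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  map <- cohort$map
  phased <- !is.null(cohort$haplotypes)
  sep <- if (phased) "|" else "/"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gwasim",
    paste0("##PHENO=", paste(cohort$phenotype, collapse = ",")),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$sample_ids), collapse = "\t"))
  n <- nrow(cohort$genotypes)
  if (phased) {
    h <- cohort$haplotypes
    odd <- seq(1L, nrow(h), by = 2L)
    gt <- matrix(paste(h[odd, ], h[odd + 1L, ], sep = sep),
                 nrow = n) # n x m, column-major preserved
  } else {
    g <- cohort$genotypes
    gt <- matrix("./.", nrow = n, ncol = ncol(g))
    gt[g == 0L] <- paste0("0", sep, "0")
    gt[g == 1L] <- paste0("0", sep, "1")
    gt[g == 2L] <- paste0("1", sep, "1")
  }
  body <- vapply(seq_len(nrow(map)), function(j) {
    paste(c(map$chrom[j], map$pos_bp[j], map$id[j], map$ref[j], map$alt[j],
            ".", "PASS", ".", "GT", gt[, j]), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a cohort from VCF
#'
#' Accepts the diploid biallelic GT subset written by [write_vcf()] (and any
#' VCF that conforms to it). Multi-allelic records are rejected with the
#' offending site id. Phased files (`|` separators throughout) retain
#' haplotypes.
#'
#' @param path VCF path.
#' @param phenotype Optional phenotype vector overriding the `##PHENO` header
#'   (all-zero when absent).
#' @return A `cohort`.
#' @export
read_vcf <- function(path, phenotype = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix)) # single-record file
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    abort(paste0("multi-allelic record(s) not supported: ",
                 paste(fix[multi, "ID"], collapse = ", ")))
  }
  map <- variant_map(chrom = fix[, "CHROM"], pos_bp = as.integer(fix[, "POS"]),
                     id = fix[, "ID"], ref = fix[, "REF"], alt = fix[, "ALT"])
  gt <- vcfR::extract.gt(v, element = "GT")
  phased <- all(grepl("\\|", gt) | gt %in% c(".", "./."), na.rm = TRUE)
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  to_int <- function(x) {
    out <- suppressWarnings(as.integer(x))
    out
  }
  h1 <- to_int(a1); h2 <- to_int(a2)
  m <- nrow(gt); n <- ncol(gt)
  geno <- matrix(h1 + h2, nrow = m, ncol = n)
  haplotypes <- NULL
  if (phased) {
    haplotypes <- matrix(0L, nrow = 2L * n, ncol = m)
    haplotypes[seq(1L, 2L * n, by = 2L), ] <- t(matrix(h1, m, n))
    haplotypes[seq(2L, 2L * n, by = 2L), ] <- t(matrix(h2, m, n))
  }
  if (is.null(phenotype)) {
    meta_line <- grep("^##PHENO=", v@meta, value = TRUE)
    phenotype <- if (length(meta_line)) {
      as.integer(strsplit(sub("^##PHENO=", "", meta_line[1]), ",")[[1]])
    } else rep(0L, n)
  }
  new_cohort(t(geno), phenotype, map, sample_ids = colnames(gt),
             haplotypes = haplotypes)
}

#' Write a cohort to PLINK text (.ped/.map)
#'
#' Unphased genotypes; alleles written as the map's ref/alt letters;
#' phenotype coded 1 = control, 2 = case.
#'
#' @param cohort A `cohort`.
#' @param prefix Output path prefix (writes `prefix.ped` and `prefix.map`).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(cohort, prefix) {
  stopifnot(inherits(cohort, "cohort"))
  map <- cohort$map
  map_df <- data.frame(map$chrom, map$id, fmt_num(map$pos_cm), map$pos_bp)
  write.table(map_df, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  g <- cohort$genotypes
  n <- nrow(g)
  al1 <- matrix(rep(map$ref, each = n), n)
  al2 <- matrix(rep(map$ref, each = n), n)
  al1[g >= 1L] <- rep(map$alt, each = n)[g >= 1L]
  al2[g == 2L] <- rep(map$alt, each = n)[g == 2L]
  al1[is.na(g)] <- "0"; al2[is.na(g)] <- "0"
  geno_cols <- matrix("", n, 2L * ncol(g))
  geno_cols[, seq(1L, 2L * ncol(g), 2L)] <- al1
  geno_cols[, seq(2L, 2L * ncol(g), 2L)] <- al2
  ped <- cbind(cohort$sample_ids, cohort$sample_ids, "0", "0", "0",
               cohort$phenotype + 1L, geno_cols)
  write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a cohort from PLINK text (.ped/.map)
#'
#' @param prefix Path prefix of `prefix.ped` / `prefix.map`.
#' @param alt_alleles Optional character vector naming the alt (counted)
#'   allele per SNP; defaults to the minor allele in the file.
#' @return A `cohort` (unphased).
#' @export
read_plink <- function(prefix, alt_alleles = NULL) {
  mp <- read.table(paste0(prefix, ".map"), sep = "\t",
                   col.names = c("chrom", "id", "cm", "bp"),
                   colClasses = c("character", "character", "numeric", "integer"))
  ped <- read.table(paste0(prefix, ".ped"), sep = " ", colClasses = "character")
  m <- nrow(mp)
  n <- nrow(ped)
  a1 <- as.matrix(ped[, 6L + seq(1L, 2L * m, 2L), drop = FALSE])
  a2 <- as.matrix(ped[, 6L + seq(2L, 2L * m, 2L), drop = FALSE])
  ref <- character(m); alt <- character(m)
  geno <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    alleles <- sort(setdiff(unique(obs), "0"))
    if (length(alleles) > 2L) abort(paste0("more than two alleles at ", mp$id[j]))
    altj <- if (!is.null(alt_alleles)) alt_alleles[j] else {
      cnt <- table(factor(obs, levels = alleles))
      names(cnt)[which.min(cnt)]
    }
    refj <- setdiff(alleles, altj)
    if (length(refj) == 0L) refj <- if (altj == "A") "G" else "A"
    ref[j] <- refj[1]; alt[j] <- altj
    geno[, j] <- (a1[, j] == altj) + (a2[, j] == altj)
    geno[a1[, j] == "0" | a2[, j] == "0", j] <- NA_integer_
  }
  map <- variant_map(mp$chrom, mp$bp, pos_cm = mp$cm, id = mp$id,
                     ref = ref, alt = alt)
  new_cohort(geno, as.integer(ped[[6]]) - 1L, map, sample_ids = ped[[2]])
}

#' Write local-ancestry tracts to TSV
#'
#' Columns `haplotype_id`, `chrom`, `start_bp`, `end_bp`, `ancestry`;
#' half-open intervals, 1-based starts.
#'
#' @param la A [local_ancestry()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_local_ancestry <- function(la, path) {
  stopifnot(inherits(la, "local_ancestry"))
  tr <- la$tracts
  out <- data.frame(haplotype_id = tr$hap_id, chrom = tr$chrom,
                    start_bp = tr$start_bp, end_bp = tr$end_bp,
                    ancestry = tr$ancestry)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read local-ancestry tracts from TSV
#'
#' Validates that the tracts tile each chromosome before expanding them onto
#' the map (gap/overlap fixtures are rejected).
#'
#' @param path TSV path.
#' @param map Variant map the assignments are expanded onto.
#' @param hap_ids Optional haplotype order; defaults to file order.
#' @return A [local_ancestry()] object.
#' @export
read_local_ancestry <- function(path, map, hap_ids = NULL) {
  tr <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "numeric",
                                  "numeric", "integer"))
  tracts <- tibble::tibble(hap_id = tr$haplotype_id, chrom = tr$chrom,
                           start_bp = tr$start_bp, end_bp = tr$end_bp,
                           ancestry = tr$ancestry)
  if (is.null(hap_ids)) hap_ids <- unique(tracts$hap_id)
  a <- assignments_from_tracts(tracts, map, hap_ids)
  local_ancestry(a, map, hap_ids)
}

#' Write association summary statistics to TSV
#'
#' Fixed, bit-stable column order: id, chrom, pos, a1, maf, beta, se, stat,
#' p, log_bf, ppa, n, qc_flag. Missing values are "." and numbers use
#' explicit C-locale formatting.
#'
#' @param result An `assoc_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assoc_tsv <- function(result, path) {
  cols <- c("id", "chrom", "pos", "a1", "maf", "beta", "se", "stat", "p",
            "log_bf", "ppa", "n", "qc_flag")
  df <- as.data.frame(result)[, cols]
  for (cc in c("maf", "beta", "se", "stat", "p", "log_bf", "ppa")) {
    df[[cc]] <- fmt_num(df[[cc]])
  }
  df$qc_flag[is.na(df$qc_flag)] <- "."
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read association summary statistics from TSV
#'
#' @param path TSV path written by [write_assoc_tsv()].
#' @param test_name Test label to attach.
#' @return An `assoc_result` tibble.
#' @export
read_assoc_tsv <- function(path, test_name = "imported") {
  df <- read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                   colClasses = c(id = "character", chrom = "character",
                                  qc_flag = "character", a1 = "character"))
  new_assoc_result(tibble::as_tibble(df), test_name)
}

# --- scenario configuration -------------------------------------------------

config_schema <- list(
  panel = c("k_pops", "fst", "n_hap_per_pop", "n_snps_per_chrom",
            "chrom_length_mb", "ld_block_len", "seed", "pop_names"),
  cohort = c("preset", "size", "n_cases", "n_controls", "generations",
             "proportions", "prevalence", "seed", "force_null"),
  assoc = c("tests", "n_pcs", "maf_min", "hwe_alpha", "max_missing",
            "prior_sd", "prior_pi", "qc"),
  eval = c("alpha", "rule"),
  meta = c("studies", "prior_effect_prob", "effect_prior_sd"))

#' Read and validate a scenario configuration file
#'
#' YAML document with sections `panel`, `cohort`, `assoc`, `eval`, `meta`.
#' Unknown sections or keys are rejected; the resolved configuration is
#' echoed into every run manifest.
#'
#' @param path YAML path.
#' @return Named list of validated sections.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad_sec <- setdiff(names(cfg), names(config_schema))
  if (length(bad_sec)) {
    abort(paste0("unknown config section(s): ", paste(bad_sec, collapse = ", ")))
  }
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
    if (length(bad)) {
      abort(paste0("unknown key(s) in [", sec, "]: ",
                   paste(bad, collapse = ", ")))
    }
  }
  cfg
}
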