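#' Read PLINK PED/MAP text files
#'
#' Parses the PLINK text dialect: the MAP file gives the variant map
#' (chromosome, id, genetic position, bp position), the PED file one row per
#' individual with six leading columns (family, individual, father, mother,
#' sex, phenotype) followed by two allele columns per variant. Dosages count
#' `allele_b`; the allele pair at each variant is inferred from the data with
#' `allele_a` the lexicographically smaller code; at monomorphic variants the
#' single observed allele is `allele_a`, so all calls read 0. "0 0" is a
#' missing call.
#' Variants are sorted by (chromosome, position) on load.
#'
#' @param ped_path,map_path Paths to the `.ped` and `.map` files.
#' @return A [geno_matrix()].
#' @export
read_pedmap <- function(ped_path, map_path) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  if (!ncol(map) %in% c(3L, 4L)) stop("MAP file must have 3 or 4 columns")
  pos_col <- ncol(map)
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0L) stop("empty PED file")
  calls <- matrix(NA_integer_, n, m)
  samples <- character(n)
  a1 <- matrix(NA_character_, n, m)
  a2 <- matrix(NA_character_, n, m)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * m) {
      stop(sprintf("PED line %d has %d fields, expected %d (6 + 2 x %d variants)",
                   i, length(f), 6L + 2L * m, m))
    }
    samples[i] <- f[2L]
    a1[i, ] <- f[seq(7L, by = 2L, length.out = m)]
    a2[i, ] <- f[seq(8L, by = 2L, length.out = m)]
  }
  if (anyDuplicated(samples)) {
    samples <- paste(vapply(strsplit(trimws(lines), "[ \t]+"), `[`, "", 1L),
                     samples, sep = "_")
  }
  allele_a <- character(m); allele_b <- character(m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    obs <- sort(unique(obs[obs != "0"]))
    if (length(obs) > 2L) {
      stop(sprintf("variant %s has >2 alleles: %s", map[j, 2L], paste(obs, collapse = "/")))
    }
    # monomorphic variants keep the single observed allele as allele_a
    # (dosage 0); allele_b is then undefined ("0")
    allele_a[j] <- if (length(obs) >= 1L) obs[1L] else "0"
    allele_b[j] <- if (length(obs) == 2L) obs[2L] else "0"
    missing_j <- a1[, j] == "0" | a2[, j] == "0"
    dose <- (a1[, j] == allele_b[j]) + (a2[, j] == allele_b[j])
    dose[missing_j] <- NA_integer_
    calls[, j] <- as.integer(dose)
  }
  variants <- tibble(
    id = map[, 2L], chrom = as.integer(map[, 1L]),
    pos_bp = as.integer(map[, pos_col]),
    allele_a = allele_a, allele_b = allele_b
  )
  geno_matrix(calls, samples, variants)
}

#' Write PLINK PED/MAP text files
#'
#' @param g A [geno_matrix()].
#' @param ped_path,map_path Output paths.
#' @return Invisibly, the PED path.
#' @export
write_pedmap <- function(g, ped_path, map_path) {
  stopifnot(inherits(g, "geno_matrix"))
  v <- g$variants
  utils::write.table(
    data.frame(v$chrom, v$id, 0, v$pos_bp),
    map_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  aa <- ifelse(v$allele_a == "0", "A", v$allele_a)  # placeholder for monomorphic-missing
  ab <- ifelse(v$allele_b == "0", aa, v$allele_b)
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_along(g$samples)) {
    d <- g$calls[i, ]
    g1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, ab, aa))
    g2 <- ifelse(is.na(d), "0", ifelse(d == 2L, ab, aa))
    writeLines(paste(c("FAM", g$samples[i], "0", "0", "1", "-9",
                       as.vector(rbind(g1, g2))), collapse = " "), con)
  }
  invisible(ped_path)
}

# PLINK 2-bit codes, SNP-major: 00 hom A1, 01 missing, 10 het, 11 hom A2,
# sample 1 in the two lowest-order bits of each byte.
.bed_code_to_call <- c(`0` = 0L, `1` = NA_integer_, `2` = 1L, `3` = 2L)

#' Read PLINK binary BED/BIM/FAM files
#'
#' Reads the SNP-major binary dialect (magic bytes `0x6c 0x1b`, mode byte
#' `0x01`). Produces the same [geno_matrix()] as [read_pedmap()] would on
#' equivalent text data, with BIM allele 1 as `allele_a`.
#'
#' @param bed_path,bim_path,fam_path Paths to the three files.
#' @return A [geno_matrix()].
#' @export
read_bedset <- function(bed_path, bim_path, fam_path) {
  stopifnot(file.exists(bed_path), file.exists(bim_path), file.exists(fam_path))
  bim <- utils::read.table(bim_path, header = FALSE, colClasses = "character")
  fam <- utils::read.table(fam_path, header = FALSE, colClasses = "character")
  m <- nrow(bim); n <- nrow(fam)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b)) {
    stop("not a PLINK .bed file (bad magic bytes)")
  }
  if (raw[3L] != as.raw(0x01)) stop("only SNP-major .bed files are supported")
  bpv <- ceiling(n / 4)
  if (length(raw) - 3L != bpv * m) {
    stop(sprintf(".bed payload has %d bytes, expected %d (%d samples x %d variants)",
                 length(raw) - 3L, bpv * m, n, m))
  }
  body <- as.integer(raw[-(1:3)])
  # unpack 4 two-bit fields per byte, variant-by-variant
  codes <- matrix(0L, 4L * bpv, m)
  bytes <- matrix(body, bpv, m)
  codes[seq(1, 4 * bpv, by = 4), ] <- bytes %% 4L
  codes[seq(2, 4 * bpv, by = 4), ] <- (bytes %/% 4L) %% 4L
  codes[seq(3, 4 * bpv, by = 4), ] <- (bytes %/% 16L) %% 4L
  codes[seq(4, 4 * bpv, by = 4), ] <- (bytes %/% 64L) %% 4L
  calls <- matrix(.bed_code_to_call[codes[seq_len(n), , drop = FALSE] + 1L], n, m)
  samples <- fam[, 2L]
  if (anyDuplicated(samples)) samples <- paste(fam[, 1L], samples, sep = "_")
  variants <- tibble(
    id = bim[, 2L], chrom = as.integer(bim[, 1L]),
    pos_bp = as.integer(bim[, 4L]), allele_a = bim[, 5L], allele_b = bim[, 6L]
  )
  geno_matrix(calls, samples, variants)
}

#' Write PLINK binary BED/BIM/FAM files
#'
#' @param g A [geno_matrix()].
#' @param bed_path,bim_path,fam_path Output paths.
#' @return Invisibly, the BED path.
#' @export
write_bedset <- function(g, bed_path, bim_path, fam_path) {
  stopifnot(inherits(g, "geno_matrix"))
  v <- g$variants
  utils::write.table(
    data.frame(v$chrom, v$id, 0, v$pos_bp, v$allele_a, v$allele_b),
    bim_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  utils::write.table(
    data.frame("FAM", g$samples, 0, 0, 1, -9),
    fam_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  n <- length(g$samples); m <- nrow(v); bpv <- ceiling(n / 4)
  # map dosage -> 2-bit code (00 hom A1, 10 het, 11 hom A2, 01 missing)
  code <- matrix(1L, 4L * bpv, m)
  d <- g$calls
  cd <- ifelse(is.na(d), 1L, c(0L, 2L, 3L)[d + 1L])
  code[seq_len(n), ] <- cd
  w <- code[seq(1, 4 * bpv, by = 4), , drop = FALSE] +
    4L * code[seq(2, 4 * bpv, by = 4), , drop = FALSE] +
    16L * code[seq(3, 4 * bpv, by = 4), , drop = FALSE] +
    64L * code[seq(4, 4 * bpv, by = 4), , drop = FALSE]
  con <- file(bed_path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(w)), con)
  invisible(bed_path)
}

#' Read a phenotype table
#'
#' Expects a TSV with a `sample_id` column plus the fixed effects, covariates
#' and trait columns used downstream (typically `farm`, `year`, `sex`,
#' `weight_before_fattening`, `fattening_days`, `NMW`, `CW`, `LW` and
#' optionally `ADG`).
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble, one row per individual.
#' @export
read_phenotypes <- function(path) {
  stopifnot(file.exists(path))
  ph <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE, check.names = FALSE))
  if (!"sample_id" %in% names(ph)) stop("phenotype table needs a 'sample_id' column")
  ph$sample_id <- as.character(ph$sample_id)
  if (anyDuplicated(ph$sample_id)) stop("duplicate sample_id in phenotype table")
  ph
}
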