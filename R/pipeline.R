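#' Pipeline configuration
#'
#' Bundles every stage parameter with the study's values as defaults, plus
#' the input/output paths. Unknown parameter names are rejected.
#'
#' @param ped,map Paths to the PLINK text genotypes (or use `bed`, `bim`,
#'   `fam` for the binary set).
#' @param phenotypes Path to the phenotype TSV.
#' @param out_dir Output directory for stage TSVs and the manifest.
#' @param bed,bim,fam Optional binary genotype paths (used when `ped` is `NULL`).
#' @param ... Stage parameter overrides: any of `sample_call_rate`,
#'   `max_variant_missing`, `min_maf`, `hwe_p_floor`, `autosomes`, the
#'   [roh_params()] fields, `consensus_min_snps`, `island_rate`,
#'   `island_max_gap_bp`, `group_n`, `alpha`, `p_adjust`, `traits`, `fixed`,
#'   `covariates`, `ld_top_region`, `seed`.
#' @return A list of class `roh_pipeline_config`.
#' @export
roh_pipeline_config <- function(ped = NULL, map = NULL, phenotypes = NULL,
                                out_dir = "roh_out", bed = NULL, bim = NULL,
                                fam = NULL, ...) {
  defaults <- list(
    sample_call_rate = 0.95, max_variant_missing = 0.05, min_maf = 0.05,
    hwe_p_floor = 1e-6, autosomes = 1:29,
    window_snps = 50L, window_max_het = 1L, window_max_missing = 5L,
    window_hit_threshold = 0.05, min_length_bp = 5e5, min_snps = 100L,
    min_density_bp_per_snp = 5e4, max_gap_bp = 1e5, roh_max_het = 1L,
    roh_max_missing = 2L,
    consensus_min_snps = 5L, island_rate = 0.2, island_max_gap_bp = 1e5,
    group_n = 300L, alpha = 0.05, p_adjust = "none",
    traits = c("NMW", "CW", "ADG", "LW"), fixed = c("farm", "year", "sex"),
    covariates = c("weight_before_fattening", "fattening_days"),
    ld_top_region = TRUE, seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, overrides)
  cfg$ped <- ped; cfg$map <- map; cfg$bed <- bed; cfg$bim <- bim; cfg$fam <- fam
  cfg$phenotypes <- phenotypes; cfg$out_dir <- out_dir
  structure(cfg, class = "roh_pipeline_config")
}

write_tsv_stage <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  df <- as.data.frame(x)
  list_cols <- vapply(df, is.list, TRUE)
  for (cl in names(df)[list_cols]) {
    df[[cl]] <- vapply(df[[cl]], paste, "", collapse = ",")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full homozygosity-mapping pipeline
#'
#' Stages, in order: quality control, ROH detection, per-individual and
#' per-chromosome summaries with FROH, consensus ROH and islands, phenotype
#' adjustment, extreme-group construction, per-region Fisher enrichment,
#' the GRM mixed-model validation of Fisher-significant regions, and LD
#' around the top region. Each stage writes a TSV under `out_dir`; a JSON
#' manifest records parameters, input checksums and row counts. Reruns with
#' identical inputs and config are reproducible.
#'
#' @param config A [roh_pipeline_config()].
#' @return Invisibly, a list with every stage's result and the manifest.
#' @export
run_roh_pipeline <- function(config) {
  stopifnot(inherits(config, "roh_pipeline_config"))
  t0 <- Sys.time()
  if (is.null(config$phenotypes) || !file.exists(config$phenotypes)) {
    stop("phenotype file missing: association stages cannot run")
  }
  if (!is.null(config$ped)) {
    stopifnot(file.exists(config$ped), file.exists(config$map))
    g <- read_pedmap(config$ped, config$map)
    geno_inputs <- c(config$ped, config$map)
  } else {
    stopifnot(!is.null(config$bed))
    g <- read_bedset(config$bed, config$bim, config$fam)
    geno_inputs <- c(config$bed, config$bim, config$fam)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pheno <- read_phenotypes(config$phenotypes)
  stages <- list()

  qc <- apply_qc(g, config$sample_call_rate, config$max_variant_missing,
                 config$min_maf, config$hwe_p_floor, config$autosomes)
  g <- qc$genotypes
  stages$qc <- write_tsv_stage(qc$report, config$out_dir, "qc_report")

  params <- roh_params(
    window_snps = config$window_snps, window_max_het = config$window_max_het,
    window_max_missing = config$window_max_missing,
    window_hit_threshold = config$window_hit_threshold,
    min_length_bp = config$min_length_bp, min_snps = config$min_snps,
    min_density_bp_per_snp = config$min_density_bp_per_snp,
    max_gap_bp = config$max_gap_bp, roh_max_het = config$roh_max_het,
    roh_max_missing = config$roh_max_missing
  )
  segments <- detect_roh(g, params)
  stages$roh <- write_tsv_stage(segments, config$out_dir, "roh_segments")

  ind <- summarize_individuals(segments, g)
  chr <- summarize_chromosomes(segments, g)
  stages$stats <- write_tsv_stage(ind, config$out_dir, "individual_summary")
  write_tsv_stage(chr, config$out_dir, "chromosome_summary")

  track <- snp_incidence(segments, g)
  islands <- find_islands(track, config$island_rate, config$island_max_gap_bp)
  consensus <- build_consensus(segments, g, config$consensus_min_snps)
  stages$consensus <- write_tsv_stage(consensus, config$out_dir, "consensus_roh")
  write_tsv_stage(islands, config$out_dir, "roh_islands")
  write_tsv_stage(track, config$out_dir, "incidence_track")

  pheno <- pheno[pheno$sample_id %in% g$samples, , drop = FALSE]
  adjusted <- adjust_phenotypes(pheno, config$traits, config$fixed,
                                config$covariates)
  stages$adjust <- write_tsv_stage(adjusted, config$out_dir, "adjusted_phenotypes")

  group_n <- min(config$group_n, floor(nrow(adjusted) / 2))
  fisher <- list(); groups_all <- list()
  for (tr in config$traits) {
    groups <- split_extremes(adjusted, tr, group_n)
    groups_all[[tr]] <- mutate(groups, trait = tr)
    fe <- fisher_enrichment(consensus, segments, groups, config$alpha,
                            config$p_adjust)
    fisher[[tr]] <- mutate(fe, trait = tr)
  }
  groups_tbl <- bind_rows(groups_all)
  fisher_tbl <- bind_rows(fisher)
  stages$groups <- write_tsv_stage(groups_tbl, config$out_dir, "extreme_groups")
  stages$fisher <- write_tsv_stage(fisher_tbl, config$out_dir,
                                   "fisher_enrichment")

  sig <- filter(fisher_tbl, .data$significant)
  mm_rows <- list()
  if (nrow(sig) > 0) {
    G <- build_grm(g)
    ord <- match(g$samples, pheno$sample_id)
    pheno_o <- pheno[ord[!is.na(ord)], , drop = FALSE]
    Gi <- G[pheno_o$sample_id, pheno_o$sample_id]
    eg <- eigen(Gi, symmetric = TRUE)
    cm <- carrier_matrix(consensus, segments, pheno_o$sample_id)
    for (k in seq_len(nrow(sig))) {
      indc <- cm[, sig$region_id[k]]
      if (var(as.numeric(indc)) == 0) next
      mm <- tryCatch(
        roh_association_test(pheno_o, sig$trait[k], indc, eg,
                             config$fixed, config$covariates),
        error = function(e) NULL
      )
      if (is.null(mm)) next
      r <- tidy.roh_mm(mm)
      r <- r[r$term == "roh", ]
      mm_rows[[length(mm_rows) + 1L]] <- tibble(
        region_id = sig$region_id[k], trait = sig$trait[k],
        effect = r$estimate, se = r$std.error, p_value = r$p.value,
        sigma_g2 = mm$sigma_g2, sigma_e2 = mm$sigma_e2,
        significant = r$p.value < config$alpha
      )
    }
  }
  mm_tbl <- bind_rows(mm_rows)
  if (nrow(mm_tbl) == 0) {
    mm_tbl <- tibble(region_id = character(), trait = character(),
                     effect = numeric(), se = numeric(), p_value = numeric(),
                     sigma_g2 = numeric(), sigma_e2 = numeric(),
                     significant = logical())
  }
  stages$mixed_model <- write_tsv_stage(mm_tbl, config$out_dir, "mixed_model")

  ld_path <- NULL
  if (isTRUE(config$ld_top_region) && nrow(sig) > 0) {
    top <- sig[which.min(sig$p_value), ]
    pad <- 2e5
    ld <- tryCatch(
      ld_matrix(g, top$chrom, top$start_bp - pad, top$end_bp + pad),
      error = function(e) NULL
    )
    if (!is.null(ld)) {
      ld_tbl <- as_tibble(as.data.frame(ld$r2), rownames = "id")
      ld_path <- write_tsv_stage(ld_tbl, config$out_dir, "ld_r2_top_region")
    }
  }
  stages$ld <- if (is.null(ld_path)) NA_character_ else ld_path

  manifest <- list(
    package = "rohtrait",
    version = as.character(utils::packageVersion("rohtrait")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("ped", "map", "bed", "bim",
                                                 "fam", "phenotypes", "out_dir"))],
    inputs = lapply(c(geno_inputs, config$phenotypes), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    stages = names(stages),
    row_counts = list(samples = length(g$samples), variants = nrow(g$variants),
                      roh = nrow(segments), consensus = nrow(consensus),
                      islands = nrow(islands),
                      fisher_significant = nrow(sig),
                      mixed_model_tested = nrow(mm_tbl))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(genotypes = g, qc = qc$report, segments = segments,
                 individual_summary = ind, chromosome_summary = chr,
                 incidence = track, islands = islands, consensus = consensus,
                 adjusted = adjusted, groups = groups_tbl, fisher = fisher_tbl,
                 mixed_model = mm_tbl, manifest = manifest,
                 elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
}
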