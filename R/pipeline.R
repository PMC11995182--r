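#' Pipeline configuration
#'
#' Validates the full set of stage parameters before any stage runs;
#' unknown keys are rejected.
#'
#' @param reference reference species name (must be in \code{species}).
#' @param species named list; each entry a list with \code{bed} (gene
#'   positions, BED/GFF3) and optional \code{cds} (FASTA path).
#' @param pairs named list keyed "a|b" of homolog pair table paths
#'   (gene_a column from species a).
#' @param out_dir output directory.
#' @param seed integer seed used by every stochastic stage.
#' @param tree optional Newick file for Dollo adjacency filtering.
#' @param max_gap,min_block_size,gap_penalty anchor chaining parameters.
#' @param ks_window Ks filter window for mixture fitting.
#' @param max_components maximum mixture components.
#' @param gamma_prior prior location of the shared-event Ks peak.
#' @param rate_r synonymous substitution rate per site per year (> 0).
#' @param retention_window,retention_step retention profiling windows
#'   (ranks).
#' @param karyotype_min_genes minimum ancestral block length (genes).
#' @return a validated \code{pipeline_config} list.
#' @export
pipeline_config <- function(reference, species, pairs, out_dir,
                            seed = 1L, tree = NULL,
                            max_gap = 25L, min_block_size = 5L,
                            gap_penalty = 0.05, ks_window = c(0.005, 5),
                            max_components = 4L, gamma_prior = 1.2,
                            rate_r = 5e-9, retention_window = 100L,
                            retention_step = 50L,
                            karyotype_min_genes = 10L) {
  cfg <- list(reference = reference, species = species, pairs = pairs,
              out_dir = out_dir, seed = as.integer(seed), tree = tree,
              max_gap = max_gap, min_block_size = min_block_size,
              gap_penalty = gap_penalty, ks_window = ks_window,
              max_components = max_components, gamma_prior = gamma_prior,
              rate_r = rate_r, retention_window = retention_window,
              retention_step = retention_step,
              karyotype_min_genes = karyotype_min_genes)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  allowed <- c("reference", "species", "pairs", "out_dir", "seed", "tree",
               "max_gap", "min_block_size", "gap_penalty", "ks_window",
               "max_components", "gamma_prior", "rate_r",
               "retention_window", "retention_step", "karyotype_min_genes")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!cfg$reference %in% names(cfg$species))
    stop("reference species '", cfg$reference, "' not in species list")
  if (!is.numeric(cfg$rate_r) || cfg$rate_r <= 0)
    stop("rate_r must be > 0")
  if (length(cfg$ks_window) != 2L || cfg$ks_window[1L] >= cfg$ks_window[2L])
    stop("ks_window must be (low, high) with low < high")
  for (key in names(cfg$pairs)) {
    sp <- strsplit(key, "|", fixed = TRUE)[[1L]]
    if (length(sp) != 2L || !all(sp %in% names(cfg$species)))
      stop("pairs key '", key, "' must be 'speciesA|speciesB' with both ",
           "species declared")
  }
  invisible(TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes synteny, Ks estimation, mixture fitting, rate correction,
#' event dating, retention profiling and karyotype reconstruction from a
#' single validated config, writing every stage's outputs plus a manifest
#' (parameters, seed, per-file checksums) under \code{out_dir}. Re-running
#' with the same config reproduces identical outputs.
#'
#' @param config a [pipeline_config].
#' @return invisibly, a results list: \code{blocks} (per comparison),
#'   \code{depth_ratios}, \code{ks} (per comparison: values, peak model,
#'   gamma peak), \code{correction} (factors and corrected peaks),
#'   \code{dating}, \code{retention}, \code{karyotype}, \code{manifest}.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  genomes <- lapply(names(config$species), function(sp) {
    e <- config$species[[sp]]
    g <- read_gene_positions(e$bed, species = sp)
    if (!is.null(e$cds)) g$cds <- read_cds_fasta(e$cds)
    g
  })
  names(genomes) <- names(config$species)
  results <- list(blocks = list(), depth_ratios = list(), ks = list())
  written <- character(0L)

  # --- synteny ---------------------------------------------------------
  for (key in names(config$pairs)) {
    sp <- strsplit(key, "|", fixed = TRUE)[[1L]]
    ga <- genomes[[sp[1L]]]; gb <- genomes[[sp[2L]]]
    pr <- read_homolog_pairs(config$pairs[[key]], ga, gb)
    anchors <- build_anchors(pr, ga, gb)
    blocks <- chain_anchors(anchors, max_gap = config$max_gap,
                            min_block_size = config$min_block_size,
                            gap_penalty = config$gap_penalty,
                            species_a = sp[1L], species_b = sp[2L])
    blocks <- classify_blocks(blocks)
    results$blocks[[key]] <- blocks
    results$depth_ratios[[key]] <- estimate_depth_ratio(blocks, ga, gb)
    f <- file.path(config$out_dir, paste0(gsub("\\|", "_vs_", key),
                                          ".collinearity"))
    write_collinearity(blocks, f)
    written <- c(written, f)
    f <- file.path(config$out_dir, paste0(gsub("\\|", "_vs_", key),
                                          ".blocks.tsv"))
    utils::write.table(blocks_summary(blocks), f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- c(written, f)
  }

  # --- Ks + mixture fitting -------------------------------------------
  for (key in names(config$pairs)) {
    sp <- strsplit(key, "|", fixed = TRUE)[[1L]]
    ga <- genomes[[sp[1L]]]; gb <- genomes[[sp[2L]]]
    if (is.null(ga$cds) || is.null(gb$cds)) next
    bk <- compute_block_ks(results$blocks[[key]], ga$cds, gb$cds)
    results$blocks[[key]] <- bk$blocks
    vals <- bk$pairs$ks[!is.na(bk$pairs$ks)]
    entry <- list(values = vals, pairs = bk$pairs)
    entry$model <- tryCatch(
      fit_peaks(vals, max_components = config$max_components,
                window = config$ks_window, seed = config$seed),
      error = function(e) NULL)
    if (!is.null(entry$model))
      entry$gamma_peak <- gamma_component(entry$model,
                                          prior = config$gamma_prior)
    results$ks[[key]] <- entry
    f <- file.path(config$out_dir, paste0(gsub("\\|", "_vs_", key),
                                          ".ks.tsv"))
    utils::write.table(bk$pairs, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, f)
  }

  # --- rate correction + dating ---------------------------------------
  with_peak <- names(results$ks)[!vapply(results$ks, function(e)
    is.null(e$gamma_peak), logical(1L))]
  if (length(with_peak)) {
    ref_key <- with_peak[grepl(paste0("^", config$reference, "\\|"),
                               with_peak) |
                           grepl(paste0("\\|", config$reference, "$"),
                                 with_peak)]
    ref_key <- if (length(ref_key)) ref_key[1L] else with_peak[1L]
    ref_peak <- results$ks[[ref_key]]$gamma_peak
    results$correction <- lapply(with_peak, function(key) {
      cr <- correct_rates(results$ks[[key]]$values,
                          results$ks[[key]]$gamma_peak, ref_peak,
                          species = key, reference = ref_key)
      refit <- tryCatch(
        fit_peaks(cr$corrected, max_components = config$max_components,
                  window = config$ks_window, seed = config$seed),
        error = function(e) NULL)
      cr$corrected_peak <- if (!is.null(refit))
        gamma_component(refit, prior = config$gamma_prior) else NA_real_
      cr
    })
    names(results$correction) <- with_peak
    results$dating <- list(reference_peak = ref_peak,
                           rate_r = config$rate_r,
                           time_mya = date_event(ref_peak, config$rate_r))
  }

  # --- retention along the reference ----------------------------------
  ref <- genomes[[config$reference]]
  ref_first <- names(config$pairs)[vapply(names(config$pairs), function(k)
    strsplit(k, "|", fixed = TRUE)[[1L]][1L] == config$reference,
    logical(1L))]
  results$retention <- lapply(ref_first, function(key) {
    prof <- retention_profile(ref, results$blocks[[key]],
                              window_size = config$retention_window,
                              step = config$retention_step)
    f <- file.path(config$out_dir, paste0(gsub("\\|", "_vs_", key),
                                          ".retention.tsv"))
    utils::write.table(as.data.frame(prof), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(profile = prof, overall = attr(prof, "overall"), file = f)
  })
  names(results$retention) <- ref_first
  written <- c(written, vapply(results$retention, `[[`, character(1L),
                               "file"))

  # --- karyotype -------------------------------------------------------
  if (length(ref_first) >= 1L) {
    blocks_list <- results$blocks[ref_first]
    names(blocks_list) <- vapply(ref_first, function(k)
      strsplit(k, "|", fixed = TRUE)[[1L]][2L], character(1L))
    blocks_list <- blocks_list[names(blocks_list) != config$reference]
    if (length(blocks_list)) {
      tree <- if (!is.null(config$tree)) ape::read.tree(config$tree) else NULL
      bs <- tryCatch(
        partition_ancestral_blocks(blocks_list, ref,
                                   min_block_genes =
                                     config$karyotype_min_genes),
        error = function(e) NULL)
      if (!is.null(bs)) {
        adj <- score_adjacencies(bs, species_tree = tree)
        kar <- linearize_cars(adj, block_ids = bs$blocks$block_id)
        branch_events <- lapply(bs$projections, function(p)
          classify_rearrangements(kar, p))
        results$karyotype <- list(block_set = bs, adjacencies = adj,
                                  karyotype = kar,
                                  branch_events = branch_events)
        f <- file.path(config$out_dir, "cars.tsv")
        car_df <- do.call(rbind, lapply(seq_along(kar$cars), function(i)
          data.frame(car = sprintf("CAR%d", i), kar$cars[[i]],
                     stringsAsFactors = FALSE)))
        utils::write.table(car_df, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        written <- c(written, f)
      }
    }
  }

  # --- manifest + results bundle --------------------------------------
  summary_json <- file.path(config$out_dir, "results.json")
  jsonlite::write_json(results_overview(results), summary_json,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  written <- c(written, summary_json)
  manifest <- list(
    package_version = as.character(utils::packageVersion("syntevo")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("species", "pairs", "out_dir"))],
    files = as.list(tools::md5sum(sort(written))))
  mf <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

results_overview <- function(results) {
  list(
    depth_ratios = lapply(results$depth_ratios, `[[`, "ratio"),
    n_blocks = lapply(results$blocks, length),
    gamma_peaks = lapply(results$ks, function(e)
      e$gamma_peak %||% NA_real_),
    correction_factors = lapply(results$correction %||% list(),
                                `[[`, "factor"),
    corrected_peaks = lapply(results$correction %||% list(),
                             `[[`, "corrected_peak"),
    dating = results$dating %||% NULL,
    retention_overall = lapply(results$retention %||% list(),
                               `[[`, "overall"),
    n_cars = if (!is.null(results$karyotype))
      results$karyotype$karyotype$n_chromosomes else NULL)
}

#' One-command synthetic demonstration
#'
#' Simulates a small clade with a shared triplication and coding sequences,
#' writes the fixture files, assembles a config and runs the full pipeline
#' on them.
#'
#' @param out_dir output directory.
#' @param seed integer seed (default 11).
#' @return invisibly, the [run_pipeline] results.
#' @export
run_demo <- function(out_dir, seed = 11L) {
  fix_dir <- file.path(out_dir, "fixtures")
  cfg <- sim_config(seed = seed, n_chromosomes = 2L,
                    genes_per_chromosome = 60L,
                    tips = c("ref", "spB", "spC"), wgt = TRUE,
                    wgt_retention = 0.6, with_cds = TRUE, n_codons = 120L,
                    ks_wgt = 1.22, ks_tip = 0.1)
  bundle <- simulate_clade(cfg)
  emit_fixtures(bundle, fix_dir)
  species <- lapply(names(bundle$tips), function(tn) list(
    bed = file.path(fix_dir, paste0(tn, ".bed")),
    cds = file.path(fix_dir, paste0(tn, ".cds.fasta"))))
  names(species) <- names(bundle$tips)
  pairs <- list()
  ref <- names(bundle$tips)[1L]
  for (tn in names(bundle$tips))
    pairs[[paste(ref, tn, sep = "|")]] <-
      file.path(fix_dir, paste0(tn, ".pairs.tsv"))
  pcfg <- pipeline_config(reference = ref, species = species, pairs = pairs,
                          out_dir = file.path(out_dir, "results"),
                          seed = seed, gamma_prior = 1.2)
  run_pipeline(pcfg)
}
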