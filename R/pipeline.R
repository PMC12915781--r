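#' Assemble a pipeline run configuration
#'
#' @param fasta Genome FASTA path.
#' @param coverage Named character vector of bedGraph paths, one per
#'   expression profile (names label the profiles, e.g.
#'   `"stage1.control"`).
#' @param mutations Named character vector of VCF/TSV paths, one per
#'   genotype (names label the genotypes).
#' @param mask Optional mask BED3 path.
#' @param gff3 Optional gene annotation path; enables the genic analysis.
#' @param window_sizes List of `c(size, step)` pairs (default 10 kb / 1 kb
#'   and 1 kb / 100 bp, so conclusions can be checked against window
#'   geometry).
#' @param metrics Metric columns to test.
#' @param n_permutations,tie_rule,statistic,add_one Passed to
#'   [permutation_test()].
#' @param gc_band Inclusive GC band for the GC-matched control battery.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A `tam_run_config` list.
#' @export
run_config <- function(fasta, coverage, mutations, mask = NULL, gff3 = NULL,
                       window_sizes = list(c(10000, 1000), c(1000, 100)),
                       metrics = c("depth_tpm", "breadth_pct"),
                       n_permutations = 10000,
                       tie_rule = "strict_greater", statistic = "median",
                       add_one = FALSE, gc_band = c(0.30, 0.50),
                       seed = 1, out_dir = "tamscan_out") {
  cfg <- list(fasta = fasta, coverage = coverage, mutations = mutations,
              mask = mask, gff3 = gff3, window_sizes = window_sizes,
              metrics = metrics, n_permutations = n_permutations,
              tie_rule = tie_rule, statistic = statistic, add_one = add_one,
              gc_band = gc_band, seed = as.integer(seed), out_dir = out_dir)
  for (p in c(cfg$fasta, cfg$coverage, cfg$mutations, cfg$mask, cfg$gff3)) {
    if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
  }
  if (is.null(names(cfg$coverage))) {
    names(cfg$coverage) <- sprintf("profile%d", seq_along(cfg$coverage))
  }
  if (is.null(names(cfg$mutations))) {
    names(cfg$mutations) <- sprintf("g%d", seq_along(cfg$mutations))
  }
  structure(cfg, class = "tam_run_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[tamscan] %s: %s", stage, sprintf(...)))
}

#' Run the complete analysis pipeline
#'
#' Windows -> masking and GC annotation -> expression quantification ->
#' mutation overlap -> permutation battery, GC-matched control battery,
#' quartile enrichment, and (when an annotation is given) the genic
#' analysis. All tables are written as TSV under `out_dir` together with
#' `summary.json` and a `manifest.json` recording the resolved
#' configuration, row counts, and MD5 checksums of every output; reruns
#' with the same configuration and seed reproduce identical checksums.
#'
#' @param config A `tam_run_config` from [run_config()], or a path to a
#'   YAML file of its fields.
#' @return Invisibly, a list of the in-memory result tables plus
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- do.call(run_config, yaml::read_yaml(config))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  index <- read_genome_index(config$fasta)
  stage_log("genome", "%d chromosome(s), %d bp", nrow(index), sum(index$length))
  mask <- if (is.null(config$mask)) NULL else read_mask(config$mask, index)
  stage_log("mask", "%d interval(s)", if (is.null(mask)) 0L else nrow(mask))

  mutations <- purrr::list_rbind(purrr::imap(
    as.list(config$mutations),
    function(path, g) read_mutations(path, genotype_label = g, index = index)))
  stage_log("mutations", "%d call(s), %d genotype(s)", nrow(mutations),
            length(unique(mutations$genotype)))

  tracks <- purrr::imap(as.list(config$coverage), function(path, p) {
    read_coverage(path, index, profile = p)
  })

  outputs <- character()
  results <- list(config = config, out_dir = config$out_dir)
  batteries <- list(); gc_batteries <- list(); quartile_tbls <- list()

  for (ws in config$window_sizes) {
    size <- ws[1]; step <- ws[2]
    tag <- sprintf("w%d", size)
    windows <- make_windows(index, size, step) |>
      apply_mask(mask) |>
      annotate_gc(config$fasta, mask)
    stage_log("windows", "%s: %d windows (%d excluded)", tag, nrow(windows),
              sum(windows$excluded))
    wpath <- file.path(config$out_dir, sprintf("windows_%s.tsv", tag))
    write_windows_bed(windows, wpath)
    outputs <- c(outputs, wpath)

    profiles <- purrr::imap(tracks, function(track, p) {
      quantify_windows(track, windows, index, mask)
    })
    for (p in names(profiles)) {
      epath <- file.path(config$out_dir,
                         sprintf("expression_%s_%s.tsv", tag, p))
      readr::write_tsv(
        dplyr::select(profiles[[p]], "window_id", "effective_length",
                      "excluded", "depth_tpm", "breadth_pct"), epath)
      outputs <- c(outputs, epath)
    }

    map <- mutation_window_map(mutations, windows)
    mpath <- file.path(config$out_dir,
                       sprintf("mutation_window_map_%s.tsv", tag))
    readr::write_tsv(map, mpath)
    outputs <- c(outputs, mpath)

    batt <- run_battery(profiles, mutations, metrics = config$metrics,
                        n_permutations = config$n_permutations,
                        seed = derive_seed(config$seed, paste0("battery|", tag)),
                        tie_rule = config$tie_rule,
                        statistic = config$statistic,
                        add_one = config$add_one)
    batt <- dplyr::mutate(batt, window_size = size, step = step, .before = 1)
    batteries[[tag]] <- batt
    stage_log("battery", "%s: %d test(s), %d significant at 0.05", tag,
              sum(batt$status == "ok"),
              sum(batt$p_value < 0.05, na.rm = TRUE))

    gc_batt <- run_battery(profiles, mutations, metrics = config$metrics,
                           gc_band = config$gc_band,
                           n_permutations = config$n_permutations,
                           seed = derive_seed(config$seed,
                                              paste0("gc_battery|", tag)),
                           tie_rule = config$tie_rule,
                           statistic = config$statistic,
                           add_one = config$add_one)
    gc_batteries[[tag]] <- dplyr::mutate(gc_batt, window_size = size,
                                         step = step, .before = 1)

    # quartile enrichment on the canonical non-overlapping tiling, pooled
    # mutations, depth metric
    qrows <- purrr::imap(profiles, function(prof, p) {
      tiling <- suppressWarnings(
        flag_mutation_windows(mutations,
                              prof[prof$is_canonical, , drop = FALSE]))
      q <- quartile_enrichment(tiling,
                               seed = derive_seed(config$seed,
                                                  paste(tag, p, "quartiles",
                                                        sep = "|")))
      dplyr::mutate(as_tibble(q), window_size = size, profile = p,
                    .before = 1)
    })
    quartile_tbls[[tag]] <- purrr::list_rbind(qrows)
  }

  battery <- purrr::list_rbind(batteries)
  gc_battery <- purrr::list_rbind(gc_batteries)
  quartiles <- purrr::list_rbind(quartile_tbls)

  genic <- NULL
  if (!is.null(config$gff3)) {
    genes <- read_genes(config$gff3)
    genic_rows <- purrr::imap(tracks, function(track, p) {
      ge <- gene_expression(track, genes, index, mask)
      flagged <- genic_overlap(mutations, ge)
      purrr::list_rbind(purrr::map(config$metrics, function(metric) {
        res <- permutation_test(
          flagged, metric = !!rlang::sym(metric),
          n_permutations = config$n_permutations,
          seed = derive_seed(config$seed, paste("genic", p, metric, sep = "|")),
          tie_rule = config$tie_rule, statistic = config$statistic,
          add_one = config$add_one)
        dplyr::mutate(dplyr::bind_cols(tidy(res), glance(res)),
                      profile = p, .before = 1)
      }))
    })
    genic <- purrr::list_rbind(genic_rows)
    gpath <- file.path(config$out_dir, "genic_battery.tsv")
    readr::write_tsv(genic, gpath)
    outputs <- c(outputs, gpath)
    stage_log("genic", "%d gene-level test(s)", nrow(genic))
  }

  report_paths <- write_report(battery, quartiles = quartiles,
                               gc_battery = gc_battery, dir = config$out_dir)
  outputs <- c(outputs, unlist(report_paths, use.names = FALSE))

  manifest <- list(
    package_version = as.character(utils::packageVersion("tamscan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config_for_manifest(config),
    row_counts = list(mutations = nrow(mutations),
                      battery = nrow(battery),
                      gc_battery = nrow(gc_battery),
                      quartiles = nrow(quartiles),
                      genic = if (is.null(genic)) 0L else nrow(genic)),
    checksums = as.list(tools::md5sum(sort(unique(outputs)))))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  results$battery <- battery
  results$gc_battery <- gc_battery
  results$quartiles <- quartiles
  results$genic <- genic
  results$manifest <- manifest
  invisible(results)
}

config_for_manifest <- function(config) {
  cfg <- unclass(config)
  cfg$window_sizes <- lapply(cfg$window_sizes, as.integer)
  cfg
}

#' Significance stars for permutation p-values
#'
#' Strict thresholds: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' otherwise `ns` (so p = 0.05 exactly is `ns`).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ NA_character_,
                   p < 0.001 ~ "***",
                   p < 0.01 ~ "**",
                   p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' Write battery results and a JSON summary
#'
#' Writes one wide TSV per analysis plus `summary.json` counting tests
#' significant at 0.05 / 0.01 / 0.001 (strict inequalities).
#'
#' @param battery Battery tibble from [run_battery()].
#' @param quartiles Optional quartile tibble.
#' @param gc_battery Optional GC-matched battery tibble.
#' @param dir Output directory.
#' @return Invisibly, a named list of the paths written.
#' @export
write_report <- function(battery, quartiles = NULL, gc_battery = NULL,
                         dir = ".") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(battery = file.path(dir, "battery.tsv"))
  batt <- dplyr::mutate(battery, stars = significance_stars(.data$p_value))
  readr::write_tsv(batt, paths$battery)
  if (!is.null(quartiles)) {
    paths$quartiles <- file.path(dir, "quartiles.tsv")
    readr::write_tsv(quartiles, paths$quartiles)
  }
  if (!is.null(gc_battery)) {
    paths$gc_battery <- file.path(dir, "battery_gc.tsv")
    readr::write_tsv(
      dplyr::mutate(gc_battery, stars = significance_stars(.data$p_value)),
      paths$gc_battery)
  }
  ok <- batt$status == "ok"
  summary <- list(
    n_tests = sum(ok),
    n_skipped = sum(!ok),
    significant = list(
      alpha_0.05 = sum(batt$p_value[ok] < 0.05),
      alpha_0.01 = sum(batt$p_value[ok] < 0.01),
      alpha_0.001 = sum(batt$p_value[ok] < 0.001)))
  paths$summary <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
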