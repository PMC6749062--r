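# End-to-end orchestration: map -> meiosis/inbreeding -> phenotypes ->
# competition -> QTL scan, with deterministic seeding and TSV outputs.

# Named substreams derived from one global seed so re-running a stage does
# not perturb the randomness of the others. The offsets are arbitrary fixed
# primes; results stay inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  offsets <- c(map = 10007L, collection = 20011L, qtl = 30011L,
               phenotype = 40009L, heat = 50021L, competition = 60013L,
               scan = 70001L, upd = 80021L)
  if (!stream %in% names(offsets)) stop("unknown seed stream: ", stream)
  (as.integer(seed) %% 1000000L) * 2048L + offsets[[stream]]
}

#' Pipeline configuration
#'
#' Bundles the per-stage configurations with a single global seed. Stage
#' seeds are derived from the global seed through fixed named offsets.
#'
#' @param map_cfg A [map_config()].
#' @param crossover A [crossover_model()].
#' @param n_tetrads Tetrads in the inbreeding design (default 13 -> 78
#'   strains).
#' @param n_qtl_heat,n_qtl_competition Planted causal loci per trait.
#' @param additive_effect,dominance_effect Planted effect sizes.
#' @param phen_cfg A [phenotype_config()].
#' @param coculture A [coculture_config()].
#' @param perm A [permutation_spec()].
#' @param seed Global integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(map_cfg = map_config(),
                            crossover = crossover_model(),
                            n_tetrads = 13,
                            n_qtl_heat = 3, n_qtl_competition = 3,
                            additive_effect = 0.8, dominance_effect = 0,
                            phen_cfg = phenotype_config(),
                            coculture = coculture_config(),
                            perm = permutation_spec(),
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %%
            .Machine$integer.max)
}

write_tsv_with_provenance <- function(df, path, config, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("## lohqtl v%s config_hash=%s seed=%d",
                     as.character(utils::packageVersion("lohqtl")),
                     config_hash(config), seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pipeline
#'
#' Generates a synthetic phased map, simulates the inter-tetrad inbred
#' collection, plants truth QTLs, simulates heat scores and co-culture
#' competitions, scans both traits with permutation thresholds, and writes
#' all tables plus a machine-readable summary to `out_dir`. Identical config
#' and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results (`map`,
#'   `collection`, `truth`, `phenotypes`, `scans`, `regions`, `evaluation`,
#'   `summary`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  map_cfg <- config$map_cfg
  map_cfg$seed <- derive_seed(config$seed, "map")
  map <- stage("map", generate_map(map_cfg))

  coll <- stage("collection", simulate_collection(
    map, n_tetrads = config$n_tetrads, model = config$crossover,
    seed = derive_seed(config$seed, "collection")))

  truth <- stage("qtl_truth", plant_qtls(
    map, c(heat = config$n_qtl_heat, competition = config$n_qtl_competition),
    additive_effect = config$additive_effect,
    dominance_effect = config$dominance_effect,
    seed = derive_seed(config$seed, "qtl")))

  phen <- stage("phenotypes", {
    lat <- phenotypes_from_genotypes(coll$geno, truth, config$phen_cfg,
                                     seed = derive_seed(config$seed,
                                                        "phenotype"))
    heat <- heat_assay(lat$heat_latent, config$phen_cfg,
                       seed = derive_seed(config$seed, "heat"))
    cbind(lat, heat)
  })

  comp <- stage("competition", {
    s <- stats::setNames(phen$s, phen$strain)
    compete_strains(s, config$coculture,
                    seed = derive_seed(config$seed, "competition"))
  })
  # QTL phenotype for growth kinetics: observed fraction at cycle 5
  comp_c5 <- comp$summary$c5

  keep <- stage("marker_filter", filter_linked_markers(map))

  scan_seed <- derive_seed(config$seed, "scan")
  scans <- list(); regions <- list(); thresholds <- list()
  traits <- list(heat = phen$heat_median, competition = comp_c5)
  for (tr in names(traits)) {
    y <- traits[[tr]]
    sc <- stage(paste0("scan_", tr),
                hk_scan(coll$geno, y, map, marker_subset = keep))
    spec <- config$perm
    spec$seed <- scan_seed + match(tr, names(traits))
    thr <- stage(paste0("threshold_", tr),
                 permutation_threshold(coll$geno, y, spec,
                                       marker_subset = keep))
    reg <- summarize_regions(call_regions(sc, thr), coll$geno, y)
    scans[[tr]] <- sc; regions[[tr]] <- reg; thresholds[[tr]] <- thr
  }

  evaluation <- stage("evaluation", {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      tr <- truth$trait[i]
      reg <- regions[[tr]]
      hit <- FALSE; dist <- NA_real_
      if (nrow(reg) > 0) {
        inside <- reg$chrom == truth$chrom[i] &
          reg$start_marker <= truth$marker[i] &
          reg$end_marker >= truth$marker[i]
        hit <- any(inside)
        if (hit) {
          pk <- reg$peak_marker[which(inside)[1]]
          dist <- abs(map$markers$pos[pk] - truth$pos[i])
        }
      }
      data.frame(trait = tr, marker = truth$marker[i],
                 chrom = truth$chrom[i], recovered = hit,
                 peak_distance_bp = dist)
    })
    if (length(rows) == 0) {
      data.frame(trait = character(), marker = integer(), chrom = integer(),
                 recovered = logical(), peak_distance_bp = numeric())
    } else do.call(rbind, rows)
  })

  frac <- vapply(coll$diploids, genotype_fractions, numeric(3))
  summary <- list(
    n_markers = n_markers(map),
    n_markers_scanned = length(keep),
    n_strains = length(coll$diploids),
    mean_f_MP = mean(frac["f_MP", ]),
    mean_f_MM = mean(frac["f_MM", ]),
    mean_f_PP = mean(frac["f_PP", ]),
    threshold_heat = as.numeric(thresholds$heat),
    threshold_competition = as.numeric(thresholds$competition),
    n_regions_heat = nrow(regions$heat),
    n_regions_competition = nrow(regions$competition),
    n_qtl_planted = nrow(truth),
    n_qtl_recovered = sum(evaluation$recovered),
    config_hash = config_hash(config),
    seed = config$seed)

  # outputs
  write_genotype_table(map, coll$geno, file.path(out_dir, "genotypes.tsv"))
  comp_cols <- comp$summary[match(phen$strain, comp$summary$strain),
                            c("c0", "c2", "c5", "c8")]
  phen_out <- data.frame(strain = phen$strain,
                         heat_median = phen$heat_median,
                         heat_se_median = phen$heat_se_median,
                         comp_cols)
  names(phen_out) <- c("strain", "heat_median", "heat_se_median",
                       "comp_fraction_c0", "comp_fraction_c2",
                       "comp_fraction_c5", "comp_fraction_c8")
  write_tsv_with_provenance(phen_out, file.path(out_dir, "phenotypes.tsv"),
                            config, config$seed)
  write_tsv_with_provenance(comp$trajectories,
                            file.path(out_dir, "trajectories.tsv"),
                            config, config$seed)
  write_tsv_with_provenance(as.data.frame(truth),
                            file.path(out_dir, "qtl_truth.tsv"),
                            config, config$seed)
  for (tr in names(scans)) {
    write_tsv_with_provenance(scans[[tr]],
                              file.path(out_dir, sprintf("scan_%s.tsv", tr)),
                              config, config$seed)
    write_tsv_with_provenance(regions[[tr]],
                              file.path(out_dir, sprintf("regions_%s.tsv", tr)),
                              config, config$seed)
  }
  write_tsv_with_provenance(evaluation, file.path(out_dir, "evaluation.tsv"),
                            config, config$seed)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)

  invisible(list(map = map, collection = coll, truth = truth,
                 phenotypes = phen, competition = comp, scans = scans,
                 regions = regions, thresholds = thresholds,
                 evaluation = evaluation, summary = summary))
}

#' Summarize a completed pipeline run directory
#'
#' Re-reads the artifacts of a [run_pipeline()] output directory and prints a
#' human-readable report: heterozygosity accounting, phenotype distributions,
#' scan results and planted-QTL recovery.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return The report lines, invisibly; they are also printed.
#' @export
run_report <- function(run_dir) {
  need <- c("summary.json", "genotypes.tsv", "phenotypes.tsv",
            "evaluation.tsv")
  for (f in need) {
    if (!file.exists(file.path(run_dir, f)))
      stop("missing run artifact: ", f)
  }
  summ <- jsonlite::read_json(file.path(run_dir, "summary.json"))
  gt <- read_genotype_table(file.path(run_dir, "genotypes.tsv"))
  phen <- utils::read.table(file.path(run_dir, "phenotypes.tsv"),
                            header = TRUE, sep = "\t", comment.char = "#")
  ev <- utils::read.table(file.path(run_dir, "evaluation.tsv"),
                          header = TRUE, sep = "\t", comment.char = "#")
  frac <- apply(gt$geno, 2, function(g) genotype_fractions(g))
  lines <- c(
    sprintf("lohqtl run report (%s)", run_dir),
    sprintf("  markers: %d (%d scanned); strains: %d",
            summ$n_markers, summ$n_markers_scanned, summ$n_strains),
    sprintf("  mean genotype fractions: MP %.1f%%  MM %.1f%%  PP %.1f%%",
            100 * summ$mean_f_MP, 100 * summ$mean_f_MM, 100 * summ$mean_f_PP),
    sprintf("  per-strain f_MP range: %.1f%% - %.1f%%",
            100 * min(frac["f_MP", ]), 100 * max(frac["f_MP", ])),
    sprintf("  heat score median range: %s - %s",
            min(phen$heat_median), max(phen$heat_median)),
    sprintf("  competition cycle-5 fraction range: %.3f - %.3f",
            min(phen$comp_fraction_c5), max(phen$comp_fraction_c5)),
    sprintf("  LOD thresholds: heat %.2f, competition %.2f",
            summ$threshold_heat, summ$threshold_competition),
    sprintf("  regions called: heat %d, competition %d",
            summ$n_regions_heat, summ$n_regions_competition),
    sprintf("  planted QTLs recovered: %d / %d",
            summ$n_qtl_recovered, summ$n_qtl_planted))
  if (nrow(ev) > 0) {
    lines <- c(lines, "  planted QTL detail:")
    for (i in seq_len(nrow(ev))) {
      lines <- c(lines, sprintf(
        "    %s chr%d marker %d: %s%s", ev$trait[i], ev$chrom[i],
        ev$marker[i], ifelse(ev$recovered[i], "recovered", "missed"),
        ifelse(ev$recovered[i],
               sprintf(" (peak %.0f bp away)", ev$peak_distance_bp[i]), "")))
    }
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
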