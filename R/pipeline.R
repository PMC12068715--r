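# Config-driven orchestration: simulate -> centromeres -> diffmod -> nonb
# -> hic -> report, with seed control and a run manifest.

default_config <- function() {
  list(
    seed = 1L,
    outdir = "cendyn_out",
    simulate = list(
      chrom = "chrSim", chrom_len = 20e6, bin_width = 10e3,
      background = 100, dispersion = 0.05, enrich_fold = 10, replicates = 2L,
      centromere_start = 9.5e6, centromere_end = 10.5e6,
      loss_start = 9.5e6, loss_end = 9.9e6,
      elevation = list(H3K36me2 = list(r1 = 3, r2 = 1.5),
                       H3K27ac = list(r1 = 2, r2 = 1.3)),
      decay_scale = 1e6,
      genome_length = 200e3, gc = 0.35,
      hic_bins = 120L, hic_depth = 3e6, hic_decay = 1,
      hic_tad_boundaries = c(40L, 80L), hic_compartment_block = 60L),
    centromeres = list(fc_threshold = 4, min_width = 50e3, merge_gap = 100e3,
                       pseudocount = 1),
    diffmod = list(fc_threshold = 1.5, alpha = 0.05, flank = 5e6, box = 1e6),
    nonb = list(density_window = 200e3, n_perm = 1000L,
                energy_width = 300L, energy_step = 150L),
    hic = list(tad_window = 8L, tad_delta = 0.1, tad_alpha = 0.01)
  )
}

check_positive <- function(cfg, fields, where, errors) {
  for (f in fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      errors <- c(errors, sprintf("%s$%s must be a positive number", where, f))
  }
  errors
}

#' Validate a pipeline configuration
#'
#' Reads a YAML config (or takes a list), fills documented defaults, and
#' validates every field, reporting all problems at once. The normalized
#' config round-trips losslessly through [write_config()].
#'
#' @param config path to a YAML file, or a (possibly partial) config list.
#' @return a fully-resolved list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  cfg <- modifyList(default_config(), config)
  errors <- character()
  errors <- check_positive(cfg$simulate,
    c("chrom_len", "bin_width", "background", "enrich_fold", "replicates",
      "genome_length", "hic_bins", "hic_depth"), "simulate", errors)
  if (cfg$simulate$dispersion < 0)
    errors <- c(errors, "simulate$dispersion must be >= 0")
  if (cfg$simulate$gc <= 0 || cfg$simulate$gc >= 1)
    errors <- c(errors, "simulate$gc must be in (0, 1)")
  errors <- check_positive(cfg$centromeres,
    c("fc_threshold", "min_width", "merge_gap"), "centromeres", errors)
  errors <- check_positive(cfg$diffmod,
    c("fc_threshold", "alpha", "flank", "box"), "diffmod", errors)
  errors <- check_positive(cfg$nonb,
    c("density_window", "n_perm", "energy_width", "energy_step"),
    "nonb", errors)
  errors <- check_positive(cfg$hic, c("tad_window", "tad_delta", "tad_alpha"),
                           "hic", errors)
  if (cfg$simulate$loss_start < cfg$simulate$centromere_start ||
      cfg$simulate$loss_end > cfg$simulate$centromere_end)
    errors <- c(errors, "simulate loss interval must lie inside the centromere")
  if (cfg$simulate$centromere_end > cfg$simulate$chrom_len ||
      cfg$simulate$centromere_start < 0)
    errors <- c(errors, "simulate centromere must lie inside the chromosome")
  if (length(errors)) stop("invalid config:\n  ", paste(errors, collapse = "\n  "))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Write a config to YAML
#' @param config a `pipeline_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the analysis pipeline on the built-in synthetic system
#'
#' Executes the requested stages in dependency order on data generated by
#' the synthetic module under the config seed, writing report tables and a
#' manifest to `config$outdir`. Outputs are deterministic under a fixed
#' seed.
#'
#' @param config a `pipeline_config` (see [validate_config()]).
#' @param stages subset of `c("simulate", "centromeres", "diffmod", "nonb",
#'   "hic")`; dependencies are added automatically.
#' @return invisibly, a list of stage results.
#' @export
run_pipeline <- function(config, stages = c("simulate", "centromeres",
                                            "diffmod", "nonb", "hic")) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "centromeres", "diffmod", "nonb", "hic")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (any(c("centromeres", "diffmod", "nonb", "hic") %in% stages))
    stages <- union(stages, "simulate")
  if ("diffmod" %in% stages) stages <- union(stages, "centromeres")
  stages <- all_stages[all_stages %in% stages]
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  sc <- config$simulate

  if ("simulate" %in% stages) {
    cen <- GRanges(sc$chrom, IRanges(sc$centromere_start + 1, sc$centromere_end))
    loss <- GRanges(sc$chrom, IRanges(sc$loss_start + 1, sc$loss_end))
    cfg <- sim_config(chrom = sc$chrom, chrom_len = sc$chrom_len,
                      bin_width = sc$bin_width, enrich_fold = sc$enrich_fold,
                      background = sc$background, dispersion = sc$dispersion,
                      replicates = sc$replicates, seed = config$seed)
    res$system <- simulate_contraction_system(cen, loss, sc$elevation,
                                              sc$decay_scale, cfg)
    res$genome <- simulate_genome(sc$genome_length, sc$gc,
      plantings = list(list(class = "APR",
                            at = as.integer(sc$genome_length * 0.45), n = 40)),
      seed = config$seed)
    nb <- sc$hic_bins
    labels <- rep(rep(c("A", "B"), length.out = ceiling(nb / sc$hic_compartment_block)),
                  each = sc$hic_compartment_block)[seq_len(nb)]
    res$hic_parent <- simulate_contact_matrix(nb, sc$hic_decay, labels,
      tad_boundaries = NULL, depth = sc$hic_depth, seed = config$seed)
    res$hic_derived <- simulate_contact_matrix(nb, sc$hic_decay, labels,
      tad_boundaries = sc$hic_tad_boundaries, depth = sc$hic_depth,
      seed = config$seed + 1L)
    write_fasta(res$genome$seq, file.path(config$outdir, "genome.fasta"))
  }

  if ("centromeres" %in% stages) {
    cc <- config$centromeres
    sys <- res$system
    doms <- list()
    for (smp in c("parent", "derived")) {
      fc <- compute_bin_enrichment(sys$cenh3[[smp]]$chip[[1]],
                                   sys$cenh3[[smp]]$input[[1]], cc$pseudocount)
      doms[[smp]] <- call_enrichment_domains(fc, cc$fc_threshold, cc$min_width,
                                             cc$merge_gap, sample = smp)
    }
    res$domains <- doms
    res$comparison <- compare_domains(doms$parent[1], doms$derived[1])
    res$partition <- partition_variable_stable(doms$parent[1],
                                               list(doms$derived[1]))
    write_tsv(data.frame(sample = c("parent", "derived"),
                         start = c(start(doms$parent[1]), start(doms$derived[1])),
                         end = c(end(doms$parent[1]), end(doms$derived[1])),
                         size_mb = c(width_mb(doms$parent[1]),
                                     width_mb(doms$derived[1]))),
              file.path(config$outdir, "centromere_domains.tsv"))
    write_bed(c(res$partition$R1, res$partition$R2),
              file.path(config$outdir, "partition.bed"))
  }

  if ("diffmod" %in% stages) {
    dc <- config$diffmod
    sys <- res$system
    rows <- list(); dmw_counts <- list()
    for (mk in names(sys$marks$parent)) {
      for (reg in c("R1", "R2")) {
        region <- res$partition[[reg]]
        ip <- region_intensity(sys$marks$parent[[mk]][[1]], region)
        id <- region_intensity(sys$marks$derived[[mk]][[1]], region)
        ft <- region_fold_change_test(id, ip)
        rows[[length(rows) + 1L]] <- data.frame(mark = mk, region = reg,
          fold_change = ft$fold_change, p_value = ft$p_value)
      }
      dm <- call_dmws(sys$marks$parent[[mk]], sys$marks$derived[[mk]],
                      dc$fc_threshold, dc$alpha)
      dmw_counts[[mk]] <- data.frame(mark = mk,
        up = sum(dm$dmws$direction == "up"),
        down = sum(dm$dmws$direction == "down"))
    }
    res$region_fc <- do.call(rbind, rows)
    res$dmw_counts <- do.call(rbind, dmw_counts)
    write_tsv(res$region_fc, file.path(config$outdir, "region_fold_changes.tsv"))
    write_tsv(res$dmw_counts, file.path(config$outdir, "dmw_counts.tsv"))
    cen <- res$partition$parent
    mk1 <- names(sys$marks$parent)[1]
    res$profile <- pericentromere_profile(sys$marks$derived[[mk1]][[1]],
                                          cen, dc$flank, dc$box)
    write_tsv(res$profile, file.path(config$outdir, "pericentromere_profile.tsv"))
  }

  if ("nonb" %in% stages) {
    nc <- config$nonb
    gen <- res$genome
    hits <- scan_motifs(gen$seq, "all")
    glen <- nchar(as.character(gen$seq[[1]]))
    grid <- make_windows(setNames(glen, names(gen$seq)[1]),
                         min(nc$density_window, max(10e3, glen %/% 20)))
    apr <- hits[hits$class == "APR"]
    dens <- motif_density(apr, grid)
    cen_idx <- which(count_in_windows(gen$truth$motifs, grid) > 0)
    res$nonb <- list(hits = hits, density = dens)
    if (length(cen_idx) >= 1 && length(cen_idx) < nrow(dens) / 2) {
      res$nonb$permutation <- permutation_enrichment(dens$count, cen_idx,
                                                     nc$n_perm, config$seed)
    }
    energy <- window_free_energy(gen$seq, nc$energy_width, nc$energy_step)
    res$nonb$energy <- energy
    write_tsv(dens, file.path(config$outdir, "motif_density.tsv"))
    write_tsv(energy, file.path(config$outdir, "energy_windows.tsv"))
  }

  if ("hic" %in% stages) {
    hc <- config$hic
    ma <- balance_matrix(res$hic_parent$matrix, "KR")
    mb <- balance_matrix(res$hic_derived$matrix, "KR")
    res$diff_map <- difference_map(mb, ma)
    ca <- compartment_pc1(ma)
    cb <- compartment_pc1(mb, orientation_track = ca$pc1)
    res$compartments <- list(parent = ca, derived = cb)
    ta <- find_tads(ma, hc$tad_window, hc$tad_delta, hc$tad_alpha)
    tb <- find_tads(mb, hc$tad_window, hc$tad_delta, hc$tad_alpha)
    res$tads <- list(parent = ta, derived = tb)
    res$boundary_comparison <- compare_boundaries(ta, tb)
    write_tsv(data.frame(bin = seq_along(ca$pc1), pc1_parent = ca$pc1,
                         pc1_derived = cb$pc1),
              file.path(config$outdir, "compartments.tsv"))
    write_tsv(data.frame(sample = c(rep("parent", length(ta$boundaries)),
                                    rep("derived", length(tb$boundaries))),
                         boundary_bin = c(ta$boundaries, tb$boundaries)),
              file.path(config$outdir, "tad_boundaries.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cendyn")),
    seed = config$seed, stages = stages,
    parameters = unclass(config),
    outputs = list.files(config$outdir))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
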