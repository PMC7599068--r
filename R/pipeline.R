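#' Default pipeline configuration
#'
#' A complete, serialisable configuration for [run_pipeline()]: which
#' stages to run, the synthetic study conditions (group sizes, occupancy
#' grids, true shift, scatter factors, optokinetic gains), the model
#' parameters (grid shape, prior concentration, posterior sample count,
#' permutation count) and the master seed every stage derives its
#' randomness from.
#'
#' @param seed Master seed.
#' @param out_dir Output directory (created if missing).
#' @param stages Character vector of stages to run, in order, from
#'   `c("synth", "metrics", "occupancy", "mks", "okr", "quant")`.
#' @param ... Overrides for individual parameters.
#' @return A list of class `run_config`.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("nucleotopo_run_"),
                           stages = c("synth", "metrics", "occupancy",
                                      "mks", "okr", "quant"),
                           ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = stages,
    n_z = 15, n_x = 4,
    alpha_prior = NULL,       # NULL = 1/K
    n_samples = 20000,
    n_perm = 999,
    groups = list(
      a = list(genotype = "wt", n_larvae = 19, cells_per_larva = c(10, 20),
               dz = 0, dx = 0),
      b = list(genotype = "mut", n_larvae = 22, cells_per_larva = c(13, 23),
               dz = -1, dx = 0)
    ),
    cluster = list(n_larvae = 6, n_cells_per_side = c(24, 34), sd = 4,
                   scatter_wt = 1, scatter_mut = 3),
    okr = list(gain_nasal = 0.8, gain_temporal = 0.5, stim_speed = 10,
               reversal_period = 6, duration = 60, saccade_rate = 0.2,
               noise_sd = 0.5, sample_rate = 100),
    quant = list(roi_mean = 2000, bg_mean = 500, noise_sd = 50, n_slices = 9)
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

# synthetic clustered-vs-scattered cell table for the metrics stage
gen_cluster_study <- function(cfg) {
  cl <- cfg$cluster
  rows <- list()
  for (g in c("wt", "mut")) {
    fac <- if (g == "wt") cl$scatter_wt else cl$scatter_mut
    for (l in seq_len(cl$n_larvae)) {
      for (s in c("left", "right")) {
        seed_i <- split_seed(cfg$seed, paste("cluster", g, l, s))
        n <- cl$n_cells_per_side[1] +
          (seed_i %% (cl$n_cells_per_side[2] - cl$n_cells_per_side[1] + 1))
        pts <- gen_clustered_nucleus(
          n, centers = rbind(c(0, 0, 0), c(6, 4, 3)), sd = cl$sd,
          scatter_factor = fac, seed = seed_i)
        rows[[length(rows) + 1]] <- data.frame(
          larva_id = sprintf("%s%02d", g, l), genotype = g, side = s,
          x_um = pts[, 1] + if (s == "left") -20 else 20,
          y_um = pts[, 2], z_um = pts[, 3],
          marker = "negative", label = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  validate_cell_table(do.call(rbind, rows))
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in order on synthetic data generated from
#' the configuration: `synth` (occupancy datasets for both groups),
#' `metrics` (clustered-vs-scattered hull/density comparison),
#' `occupancy` (binning, pooling, posterior, KL, axis shifts),
#' `mks` (2D KS permutation test between the groups' binned coordinates),
#' `okr` (gain and eye-range recovery from a synthetic trace) and `quant`
#' (background-corrected intensity on a synthetic stack). Every artifact is
#' written under `out_dir` together with a manifest recording the full
#' configuration, the seed, and the md5 of each file, which suffices to
#' replay the run.
#'
#' @param config A [default_config()] list.
#' @return A list of stage results (invisibly also written to
#'   `out_dir`).
#' @export
run_pipeline <- function(config = default_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  res <- list(config = config)
  log_stage <- function(name) {
    message(sprintf("[%s] stage %s (%.1f s elapsed)",
                    format(Sys.time(), "%H:%M:%S"), name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  if (any(c("synth", "occupancy", "mks") %in% config$stages)) {
    log_stage("synth")
    base <- default_io_grid(config$n_z, config$n_x)
    tabs <- list()
    for (nm in names(config$groups)) {
      g <- config$groups[[nm]]
      probs <- shift_grid(base, g$dz, g$dx)
      truth <- synthetic_truth(
        occupancy_probs = probs, n_larvae = g$n_larvae,
        cells_per_larva = g$cells_per_larva,
        seed = split_seed(config$seed, paste0("synth/", g$genotype)))
      tabs[[nm]] <- gen_occupancy_dataset(truth, genotype = g$genotype)
      write_cell_table(tabs[[nm]],
                       file.path(config$out_dir,
                                 paste0("cells_", g$genotype, ".tsv")))
    }
    res$synth <- tabs
  }

  if ("metrics" %in% config$stages) {
    log_stage("metrics")
    cells <- gen_cluster_study(config)
    res$metrics <- list(
      hull = compare_groups(cells, "hull", seed = config$seed),
      density = compare_groups(cells, "density", seed = config$seed),
      count = compare_groups(cells, "count", seed = config$seed))
    write_cell_table(cells, file.path(config$out_dir, "cells_cluster.tsv"))
    utils::write.table(res$metrics$hull$per_larva,
                       file.path(config$out_dir, "per_larva_hull.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (any(c("occupancy", "mks") %in% config$stages)) {
    log_stage("occupancy")
    binned <- lapply(res$synth, assign_bins,
                     n_z = config$n_z, n_x = config$n_x)
    grids <- mapply(function(b, g) pool_counts(b, genotype = g$genotype,
                                               n_z = config$n_z,
                                               n_x = config$n_x),
                    binned, config$groups, SIMPLIFY = FALSE)
    post <- lapply(names(grids), function(nm) {
      posterior_sample(grids[[nm]], alpha_prior = config$alpha_prior,
                       n_samples = config$n_samples,
                       seed = split_seed(config$seed, paste0("post/", nm)))
    })
    names(post) <- names(grids)
    kl <- kl_posterior(post$a, post$b)
    zs <- axis_shift(post$a, post$b, "dv")
    xs <- axis_shift(post$a, post$b, "ml")
    occ <- list(
      counts = lapply(grids, unclass),
      posterior_mean = lapply(post, posterior_mean_grid),
      differential = differential_map(post$a, post$b),
      kl = list(mean = kl$kl_mean, ci = c(kl$kl_ci_low, kl$kl_ci_high)),
      z_shift = list(mean = zs$shift_mean, ci = c(zs$ci_low, zs$ci_high)),
      x_shift = list(mean = xs$shift_mean, ci = c(xs$ci_low, xs$ci_high)),
      alpha_prior = post$a$alpha_prior, n_samples = config$n_samples,
      seed = config$seed)
    if ("occupancy" %in% config$stages) {
      jsonlite::write_json(occ, file.path(config$out_dir, "occupancy.json"),
                           auto_unbox = TRUE, digits = NA)
      res$occupancy <- c(occ, list(posterior = post, grids = grids))
    }
    if ("mks" %in% config$stages) {
      log_stage("mks")
      res$mks <- mks_test(binned$a, binned$b, n_perm = config$n_perm,
                          seed = split_seed(config$seed, "mks"))
      jsonlite::write_json(res$mks, file.path(config$out_dir, "mks.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  if ("okr" %in% config$stages) {
    log_stage("okr")
    ok <- config$okr
    trace <- gen_eye_trace(
      gain_nasal = ok$gain_nasal, gain_temporal = ok$gain_temporal,
      stim_speed = ok$stim_speed, reversal_period = ok$reversal_period,
      duration = ok$duration, saccade_rate = ok$saccade_rate,
      noise_sd = ok$noise_sd, sample_rate = ok$sample_rate,
      seed = split_seed(config$seed, "okr"))
    res$okr <- okr_analyze(trace)
    write_eye_trace(trace, file.path(config$out_dir, "eye_trace.tsv"))
    jsonlite::write_json(
      list(gain = as.data.frame(res$okr$gain),
           gain_nasal = res$okr$gain_nasal,
           gain_temporal = res$okr$gain_temporal,
           eye_range = as.list(res$okr$eye_range),
           strong_eye = res$okr$strong_eye),
      file.path(config$out_dir, "okr.json"), auto_unbox = TRUE, digits = NA)
  }

  if ("quant" %in% config$stages) {
    log_stage("quant")
    q <- config$quant
    syn <- gen_intensity_stack(roi_mean = q$roi_mean, bg_mean = q$bg_mean,
                               noise_sd = q$noise_sd, n_slices = q$n_slices,
                               seed = split_seed(config$seed, "quant"))
    res$quant <- corrected_mean_intensity(syn$stack, syn$roi_masks,
                                          syn$bg_masks, "synthetic")
    jsonlite::write_json(
      list(specimen_id = res$quant$specimen_id,
           background_mean = res$quant$background_mean,
           corrected_mean = res$quant$corrected_mean,
           category = res$quant$category),
      file.path(config$out_dir, "quant.json"), auto_unbox = TRUE, digits = NA)
  }

  # manifest: config + per-file md5, sufficient to replay the run
  files <- setdiff(list.files(config$out_dir), "manifest.json")
  manifest <- list(
    config = config[setdiff(names(config), "out_dir")],
    seed = config$seed,
    files = lapply(files, function(f) {
      list(name = f,
           md5 = unname(tools::md5sum(file.path(config$out_dir, f))))
    }))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
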