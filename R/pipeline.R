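#' Default pipeline configuration
#'
#' Builds the nested configuration driving [run_pipeline()]. Every stage
#' parameter defaults to the pipeline's standard value (detection 7.9 px /
#' 0.23, 15-frame gate, 1.1 um opening disk with the 0.077 um^2 gate,
#' 100-350 voxel volume gate, k = 5 neighbors with 8 px deduplication,
#' DEG gates padj < 0.05 and |log2FC| >= 1). The synthetic-data blocks
#' define the simulated study conditions for the demo run: a high- versus
#' low-persistence migration contrast, spread versus rounded cell fixtures,
#' flat versus spherical nuclei, a 4:1 density contrast and a 3x enriched
#' genome fixture.
#'
#' @param out_dir directory where stage artifacts are written.
#' @param seed master seed; stage seeds are derived from it.
#' @param stages character vector of stages to run (subset of
#'   `c("tracks", "morpho2d", "morpho3d", "density", "enrichment", "qpcr")`).
#' @return nested configuration list (class `gastruquant_config`).
#' @export
default_config <- function(out_dir = tempfile("gastruquant_run_"), seed = 1,
                           stages = c("tracks", "morpho2d", "morpho3d",
                                      "density", "enrichment", "qpcr")) {
  structure(list(
    version = 1L,
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = stages,
    tracks = list(
      n_embryos = 3L, n_tracks = 60L, n_steps = 120L,
      persistence_wt = 0.9, persistence_mut = 0.4,
      speed_um_min = 0.6, dt_min = 4, arena = c(400, 400),
      min_frames = 15L
    ),
    morpho2d = list(
      pixel_size_um = 0.1,
      spikes_wt = 7L, spikes_mut = 2L, n_cells = 4L,
      fa_total_um_wt = 200, fa_total_um_mut = 80
    ),
    morpho3d = list(
      voxel_size_um = c(0.132, 0.132, 0.24),
      flat_axes_um = c(4, 3, 1.5), round_axes_um = c(3.2, 3, 2.7),
      n_nuclei = 3L
    ),
    density = list(
      rate_active = 0.01, rate_inactive = 0.04, n_embryos = 5L,
      extent_um = c(200, 200), pixel_size_um = 0.15, k = 5L
    ),
    enrichment = list(
      n_genes = 1000L, n_peaks = 100L, enrichment_factor = 3,
      n_deg = 150L
    ),
    qpcr = list(
      genes = c("ctgfa", "lats2", "lamc1", "marcksl1b"),
      ddct_shift = -1.5, noise_sd_ct = 0.08, n_replicates = 3L
    )
  ), class = "gastruquant_config")
}

#' Validate a pipeline configuration
#'
#' Returns a character vector of problems (empty when the configuration is
#' valid); never raises.
#'
#' @param config configuration list from [default_config()].
#' @return character vector of human-readable problems.
#' @export
validate_config <- function(config) {
  probs <- character(0)
  add <- function(msg) probs <<- c(probs, msg)
  ok_num <- function(x) is.numeric(x) && all(is.finite(x))
  if (!is.list(config)) return("config must be a list")
  if (is.null(config$seed) || !ok_num(config$seed)) add("seed: missing or non-numeric")
  if (is.null(config$out_dir) || !is.character(config$out_dir))
    add("out_dir: missing or not a path")
  known <- c("tracks", "morpho2d", "morpho3d", "density", "enrichment", "qpcr")
  bad <- setdiff(config$stages %||% character(0), known)
  if (length(bad)) add(paste0("stages: unknown stage(s) ", paste(bad, collapse = ", ")))
  tr <- config$tracks
  if (!is.null(tr)) {
    if (!ok_num(tr$persistence_wt) || tr$persistence_wt < 0 || tr$persistence_wt > 1)
      add("tracks$persistence_wt: must be in [0, 1]")
    if (!ok_num(tr$persistence_mut) || tr$persistence_mut < 0 || tr$persistence_mut > 1)
      add("tracks$persistence_mut: must be in [0, 1]")
    if (!ok_num(tr$dt_min) || tr$dt_min <= 0) add("tracks$dt_min: must be positive")
  }
  m2 <- config$morpho2d
  if (!is.null(m2) && (!ok_num(m2$pixel_size_um) || m2$pixel_size_um <= 0))
    add("morpho2d$pixel_size_um: must be positive")
  m3 <- config$morpho3d
  if (!is.null(m3) && (!ok_num(m3$voxel_size_um) || length(m3$voxel_size_um) != 3 ||
                         any(m3$voxel_size_um <= 0)))
    add("morpho3d$voxel_size_um: must be 3 positive numbers")
  de <- config$density
  if (!is.null(de) && (!ok_num(de$rate_active) || de$rate_active < 0 ||
                         !ok_num(de$rate_inactive) || de$rate_inactive < 0))
    add("density rates: must be >= 0")
  en <- config$enrichment
  if (!is.null(en) && ok_num(en$enrichment_factor) && ok_num(en$n_peaks) &&
        ok_num(en$n_genes) &&
        en$enrichment_factor * en$n_peaks / en$n_genes > 1)
    add("enrichment: enrichment_factor infeasible (required probability > 1)")
  probs
}

#' Save / load a configuration as YAML
#'
#' @param config configuration list.
#' @param path YAML file path.
#' @return `save_config` returns `path` invisibly; `load_config` the
#'   configuration list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (nm in c("tracks", "morpho3d", "density")) {
    for (f in c("arena", "voxel_size_um", "extent_um", "flat_axes_um", "round_axes_um"))
      if (!is.null(cfg[[nm]][[f]])) cfg[[nm]][[f]] <- as.numeric(cfg[[nm]][[f]])
  }
  structure(cfg, class = "gastruquant_config")
}

.stage_seed <- function(seed, stage_offset) {
  (as.integer(seed) * 1000L + stage_offset) %% .Machine$integer.max
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the synthetic demo pipeline end to end
#'
#' Executes the requested stages on internally generated synthetic data
#' (the three headline analyses: migration comparison, 2D/3D morphometry
#' comparison, density and regulatory enrichment, plus qPCR fold changes),
#' writes per-stage CSV artifacts and a JSON summary to `config$out_dir`,
#' and returns the summary. Every artifact is a pure function of
#' `(config, seed)`, so reruns are byte-identical.
#'
#' @param config configuration from [default_config()].
#' @return named list with one element per executed stage plus `config_hash`
#'   and `seed` (also written to `summary.json`).
#' @export
run_pipeline <- function(config = default_config()) {
  probs <- validate_config(config)
  .assert(length(probs) == 0,
          paste("invalid config:", paste(probs, collapse = "; ")))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  report <- list(config_hash = rlang::hash(unclass(config)), seed = seed)

  if ("tracks" %in% config$stages) {
    tr <- config$tracks
    groups <- list(wt = tr$persistence_wt, mut = tr$persistence_mut)
    per_embryo <- list()
    all_metrics <- list()
    for (g in names(groups)) {
      means <- numeric(tr$n_embryos)
      for (e in seq_len(tr$n_embryos)) {
        tracks <- simulate_persistent_tracks(
          tr$n_tracks, tr$n_steps, dt_min = tr$dt_min,
          speed_um_min = tr$speed_um_min, persistence_p = groups[[g]],
          arena = tr$arena,
          seed = .stage_seed(seed, 10L + 10L * match(g, names(groups)) + e))
        mt <- track_metrics(tracks, detection_params(min_frames = tr$min_frames,
                                                     frame_interval_min = tr$dt_min))
        mt <- filter_tracks(mt, detection_params(min_frames = tr$min_frames))
        mt$group <- g; mt$embryo <- e
        all_metrics[[paste(g, e)]] <- mt
        means[e] <- mean(mt$persistence)
      }
      per_embryo[[g]] <- means
    }
    metrics <- do.call(rbind, all_metrics)
    .write_csv(metrics, file.path(config$out_dir, "track_metrics.csv"))
    cmp <- compare_groups(per_embryo$wt, per_embryo$mut)
    report$tracks <- list(
      persistence_mean_wt = mean(per_embryo$wt),
      persistence_mean_mut = mean(per_embryo$mut),
      t_statistic = cmp$statistic, p_value = cmp$p_two_sided,
      method = cmp$method,
      displacement_bins = as.list(table(metrics$displacement_bin))
    )
  }

  if ("morpho2d" %in% config$stages) {
    m2 <- config$morpho2d
    rows <- list()
    for (g in c("wt", "mut")) {
      nsp <- if (g == "wt") m2$spikes_wt else m2$spikes_mut
      for (i in seq_len(m2$n_cells)) {
        cm <- make_star_cell(n_spikes = nsp, pixel_size_um = m2$pixel_size_um,
                             seed = .stage_seed(seed, 100L + 10L * (g == "mut") + i))
        sd_ <- shape_descriptors(cm)
        rows[[paste(g, i)]] <- data.frame(
          group = g, cell = i, area_um2 = sd_$area_um2,
          compactness = sd_$compactness,
          filopodia = count_filopodia(cm))
      }
    }
    cells <- do.call(rbind, rows)
    .write_csv(cells, file.path(config$out_dir, "morpho2d_cells.csv"))
    fa_len <- function(total_um, sd_seed) {
      n_seg <- 10L
      seg_len <- total_um / n_seg
      # anchors on a wide grid with upward-right angles only, so bars from
      # neighboring anchors can never approach each other
      segs <- .with_seed(sd_seed, {
        t(vapply(seq_len(n_seg), function(i) {
          x0 <- 15 + ((i - 1) %% 5) * 27
          y0 <- 25 + ((i - 1) %/% 5) * 75
          ang <- stats::runif(1, 0, pi / 3)
          c(x0, y0, x0 + seg_len * cos(ang), y0 + seg_len * sin(ang))
        }, numeric(4)))
      })
      pat <- make_fa_pattern(segs, shape_px = c(512, 512), pixel_size_um = 0.3)
      c(measured = total_fa_length(pat$mask, 0.3), truth = pat$truth_length_um)
    }
    wt_fa <- fa_len(m2$fa_total_um_wt, .stage_seed(seed, 130L))
    mut_fa <- fa_len(m2$fa_total_um_mut, .stage_seed(seed, 131L))
    report$morpho2d <- list(
      compactness_mean_wt = mean(cells$compactness[cells$group == "wt"]),
      compactness_mean_mut = mean(cells$compactness[cells$group == "mut"]),
      filopodia_mean_wt = mean(cells$filopodia[cells$group == "wt"]),
      filopodia_mean_mut = mean(cells$filopodia[cells$group == "mut"]),
      fa_length_wt_um = unname(wt_fa["measured"]),
      fa_length_mut_um = unname(mut_fa["measured"]))
  }

  if ("morpho3d" %in% config$stages) {
    m3 <- config$morpho3d
    rows <- list()
    for (g in c("wt", "mut")) {
      axes <- if (g == "wt") m3$flat_axes_um else m3$round_axes_um
      for (i in seq_len(m3$n_nuclei)) {
        st <- make_ellipsoid_stack(axes, voxel_size_um = m3$voxel_size_um,
                                   noise_sd = 0.05,
                                   seed = .stage_seed(seed, 200L + 10L * (g == "mut") + i))
        lab <- segment_nuclei_3d(blur3d(st$grid))
        de <- nucleus_descriptors(lab, m3$voxel_size_um,
                                  intensities = st$grid$intensities)
        de <- de[which.max(de$volume_voxels), , drop = FALSE]
        rows[[paste(g, i)]] <- data.frame(group = g, nucleus = i,
                                          flatness = de$flatness,
                                          sphericity = de$sphericity,
                                          volume_um3 = de$volume_um3)
      }
    }
    nuc <- do.call(rbind, rows)
    .write_csv(nuc, file.path(config$out_dir, "morpho3d_nuclei.csv"))
    report$morpho3d <- list(
      flatness_mean_wt = mean(nuc$flatness[nuc$group == "wt"]),
      flatness_mean_mut = mean(nuc$flatness[nuc$group == "mut"]),
      sphericity_mean_wt = mean(nuc$sphericity[nuc$group == "wt"]),
      sphericity_mean_mut = mean(nuc$sphericity[nuc$group == "mut"]))
  }

  if ("density" %in% config$stages) {
    de <- config$density
    recs <- list()
    for (e in seq_len(de$n_embryos)) {
      fld <- make_point_field(de$rate_active, de$rate_inactive,
                              extent_um = de$extent_um,
                              pixel_size_um = de$pixel_size_um,
                              seed = .stage_seed(seed, 300L + e))
      fld <- exclude_border(dedupe_centroids(fld))
      r <- mean_knn_distance(fld, k = de$k)
      r <- assign_region(r, fld)
      r$embryo <- e
      recs[[e]] <- r
    }
    records <- do.call(rbind, recs)
    .write_csv(records, file.path(config$out_dir, "density_records.csv"))
    cd <- compare_density(records)
    agg <- cd$per_embryo
    report$density <- list(
      mean_dist_active = mean(agg$mean_dist_knn_um[agg$region == "active"]),
      mean_dist_inactive = mean(agg$mean_dist_knn_um[agg$region == "inactive"]),
      t_statistic = cd$test$statistic, p_value = cd$test$p_two_sided)
  }

  if ("enrichment" %in% config$stages) {
    en <- config$enrichment
    fx <- make_genome_fixture(en$n_genes, en$n_peaks, en$enrichment_factor,
                              en$n_deg, seed = .stage_seed(seed, 400L))
    assign_tab <- closest_gene(fx$peaks, fx$genes)
    .write_csv(assign_tab, file.path(config$out_dir, "peak_to_gene.csv"))
    degs <- filter_degs(fx$degs, direction = "down")
    et <- enrichment_test(degs, unique(assign_tab$gene_id), fx$universe)
    report$enrichment <- list(
      deg_fraction = et$deg_fraction, control_fraction = et$control_fraction,
      z = et$z, p_value = et$p)
  }

  if ("qpcr" %in% config$stages) {
    qp <- config$qpcr
    ct <- .with_seed(.stage_seed(seed, 500L), {
      base <- 24
      rows <- list()
      for (grp in c("control", "compressed")) for (g in c(qp$genes, "ef1a"))
        for (r in seq_len(qp$n_replicates)) {
          shift <- if (grp == "compressed" && g != "ef1a") qp$ddct_shift else 0
          rows[[length(rows) + 1L]] <- data.frame(
            sample_group = grp, gene = g, replicate = r,
            ct = base + shift + stats::rnorm(1, 0, qp$noise_sd_ct))
        }
      do.call(rbind, rows)
    })
    dd <- delta_delta_ct(ct, control_group = "control")
    .write_csv(dd$summary, file.path(config$out_dir, "qpcr_folds.csv"))
    comp <- dd$summary[dd$summary$sample_group == "compressed", ]
    report$qpcr <- list(fold_mean_compressed = mean(comp$fold_mean),
                        expected_fold = 2^(-config$qpcr$ddct_shift))
  }

  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, file.path(config$out_dir, "summary.json"))
  invisible(report)
}
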