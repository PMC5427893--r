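#' Configuration for a synthetic cohort experiment
#'
#' Bundles the generator, lesion, ROI and fractal settings for a sham-vs-TBI
#' synthetic experiment. The defaults emulate the study design: a dense
#' bilateral cortical plexus; TBI subjects receive a focal lesion (strong
#' ablation at an epicenter in the right hemisphere, 1.5 mm radius) on top of
#' a global rarefication; concentric 1/2/3 mm rings radiate from the
#' epicenter.
#'
#' @param n_sham,n_tbi subjects per group (>= 1).
#' @param network a [network_config()] (its `rng_seed` is replaced per
#'   subject).
#' @param lesion a [lesion_spec()]; `NULL` places the default lesion at
#'   (H/2, 0.7 W) with radius 1.5 mm, core ablation 0.9, global 0.3.
#' @param ring_radii_mm concentric ring radii.
#' @param fractal a [fractal_config()].
#' @param noise_sd rasterization noise.
#' @param binarize_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold threshold for `binarize_method = "fixed"`.
#' @param rng_master_seed master seed; every per-subject seed derives from it
#'   deterministically.
#' @param output_dir optional directory for CSV/JSON/Markdown outputs.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(n_sham = 5L, n_tbi = 5L,
                              network = network_config(),
                              lesion = NULL,
                              ring_radii_mm = c(1, 2, 3),
                              fractal = fractal_config(),
                              noise_sd = 0.02,
                              binarize_method = c("otsu", "fixed"),
                              fixed_threshold = NULL,
                              rng_master_seed = 1L,
                              output_dir = NULL) {
  check_number(n_sham, "n_sham", min = 1, integer = TRUE)
  check_number(n_tbi, "n_tbi", min = 1, integer = TRUE)
  binarize_method <- match.arg(binarize_method)
  if (!inherits(network, "network_config"))
    stop_config("network must be a network_config")
  if (!inherits(fractal, "fractal_config"))
    stop_config("fractal must be a fractal_config")
  if (is.null(lesion)) {
    radius_px <- 1.5 * 1000 / network$pixel_size_um
    lesion <- lesion_spec(center_rc_px = c(network$image_height_px / 2,
                                           round(0.7 * network$image_width_px)),
                          radius_px = radius_px,
                          core_ablation_fraction = 0.9,
                          falloff = "flat",
                          global_ablation_fraction = 0.3)
  }
  if (!inherits(lesion, "lesion_spec"))
    stop_config("lesion must be a lesion_spec")
  structure(list(n_sham = as.integer(n_sham), n_tbi = as.integer(n_tbi),
                 network = network, lesion = lesion,
                 ring_radii_mm = ring_radii_mm, fractal = fractal,
                 noise_sd = noise_sd, binarize_method = binarize_method,
                 fixed_threshold = fixed_threshold,
                 rng_master_seed = as.integer(rng_master_seed),
                 output_dir = output_dir),
            class = "experiment_config")
}

region_fractal_features <- function(map, region_mask, bin_width = 0.01) {
  sel <- map$valid_mask & region_mask
  if (!any(sel)) {
    return(data.frame(peak_lfd = NA_real_, peak_frequency = NA_real_,
                      skewness = NA_real_, kurtosis = NA_real_, n = 0L))
  }
  as.data.frame(fractal_features(map$lfd[sel], bin_width))
}

#' Analyze one vessel image across the standard regions
#'
#' Binarizes, skeletonizes, extracts the network graph and the LFD map once,
#' then reports classical metrics and fractal features for the whole image,
#' both hemispheres and each concentric ring.
#'
#' @param image a [vessel_image()].
#' @param epicenter_rc_px lesion/sham-surgery epicenter `c(row, col)`.
#' @param ring_radii_mm concentric ring radii.
#' @param fractal a [fractal_config()].
#' @param cortex_mask optional logical analysis mask (default whole image).
#' @param midline_col_px midline column (default: image center).
#' @param ipsilateral hemisphere carrying the epicenter.
#' @param binarize_method,fixed_threshold see [binarize()].
#' @return List with `mask`, `graph`, `lfd_map`, `rois` and `metrics`
#'   (long-format data frame: region, metric, value).
#' @export
analyze_vessel_image <- function(image, epicenter_rc_px,
                                 ring_radii_mm = c(1, 2, 3),
                                 fractal = fractal_config(),
                                 cortex_mask = NULL,
                                 midline_col_px = NULL,
                                 ipsilateral = c("right", "left"),
                                 binarize_method = "otsu",
                                 fixed_threshold = NULL) {
  ipsilateral <- match.arg(ipsilateral)
  mask <- binarize(image, method = binarize_method,
                   fixed_threshold = fixed_threshold)
  ps <- pixel_size(mask)
  if (is.null(cortex_mask)) cortex_mask <- matrix(TRUE, nrow(mask), ncol(mask))
  if (is.null(midline_col_px)) midline_col_px <- round(ncol(mask) / 2)
  skel <- skeletonize_mask(mask)
  graph <- extract_network_graph(skel, ps)
  map <- local_fractal_dimension_map(mask, cortex_mask, fractal)
  rings <- concentric_rings(epicenter_rc_px, ring_radii_mm, ps, cortex_mask)
  hemis <- hemisphere_masks(cortex_mask, midline_col_px, ipsilateral)
  regions <- c(list(whole = cortex_mask,
                    ipsilateral = hemis$ipsilateral,
                    contralateral = hemis$contralateral),
               rings$ring_masks)
  rows <- lapply(names(regions), function(rn) {
    met <- as.data.frame(compute_metrics(mask, graph, regions[[rn]]))
    ff <- region_fractal_features(map, regions[[rn]])
    data.frame(region = rn,
               metric = c("junction_count", "total_length_um",
                          "vessel_area_um2", "vessel_density", "peak_lfd",
                          "peak_frequency", "lfd_skewness", "lfd_kurtosis"),
               value = c(met$junction_count, met$total_length_um,
                         met$vessel_area_um2, met$vessel_density, ff$peak_lfd,
                         ff$peak_frequency, ff$skewness, ff$kurtosis))
  })
  list(mask = mask, graph = graph, lfd_map = map, rois = rings,
       hemispheres = hemis, metrics = do.call(rbind, rows))
}

#' Run a full synthetic sham-vs-TBI experiment
#'
#' Per subject: generate a network (TBI subjects additionally receive the
#' lesion ablation), rasterize, binarize and analyze across whole image,
#' hemispheres and rings; then summarize group effects. All per-subject seeds
#' derive deterministically from `rng_master_seed`, so reruns with the same
#' configuration reproduce the tables exactly.
#'
#' @param config an [experiment_config()].
#' @return List with `metrics` (long table over group, subject, region,
#'   metric), `report` (an `analysis_report`) and `config`. When
#'   `config$output_dir` is set, writes `metrics.csv`, `report.json` and
#'   `report.md` there.
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "experiment_config"))
    stop_config("config must be an experiment_config")
  out_dir <- config$output_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir) || file.access(out_dir, 2L) != 0L)
      stop_config("output directory is not writable: ", out_dir)
  }
  n_total <- config$n_sham + config$n_tbi
  seeds <- derive_seeds(config$rng_master_seed, 3L * n_total)
  subj_rows <- list()
  subj_idx <- 0L
  for (grp in c("sham", "tbi")) {
    n_grp <- if (grp == "sham") config$n_sham else config$n_tbi
    for (i in seq_len(n_grp)) {
      subj_idx <- subj_idx + 1L
      net_cfg <- config$network
      net_cfg$rng_seed <- seeds[subj_idx]
      net <- generate_vessel_network(net_cfg)
      if (grp == "tbi")
        net <- ablate_network(net, config$lesion,
                              rng_seed = seeds[n_total + subj_idx])
      img <- rasterize_network(net, noise_sd = config$noise_sd,
                               rng_seed = seeds[2L * n_total + subj_idx])
      res <- analyze_vessel_image(img,
                                  epicenter_rc_px = config$lesion$center_rc_px,
                                  ring_radii_mm = config$ring_radii_mm,
                                  fractal = config$fractal,
                                  binarize_method = config$binarize_method,
                                  fixed_threshold = config$fixed_threshold)
      m <- res$metrics
      gt <- data.frame(region = "whole",
                       metric = c("gt_junction_count", "gt_total_length_um"),
                       value = c(nrow(net$junction_points),
                                 net$total_length_um))
      m <- rbind(m, gt)
      m$group <- grp
      m$subject <- sprintf("%s_%02d", grp, i)
      subj_rows[[subj_idx]] <- m[, c("group", "subject", "region", "metric",
                                     "value")]
    }
  }
  metrics <- do.call(rbind, subj_rows)
  rownames(metrics) <- NULL
  report <- build_report(metrics, control = "sham", treated = "tbi")
  if (!is.null(out_dir)) {
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    write_report(report, file.path(out_dir, "report.json"),
                 file.path(out_dir, "report.md"))
  }
  list(metrics = metrics, report = report, config = config)
}

#' Read an experiment configuration from YAML
#'
#' Top-level keys mirror [experiment_config()] arguments; `network`, `lesion`
#' and `fractal` are nested maps passed to their constructors.
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("n_sham", "n_tbi", "ring_radii_mm", "noise_sd",
              "binarize_method", "fixed_threshold", "rng_master_seed",
              "output_dir"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$network)) {
    nw <- y$network
    if (!is.null(nw$width_range_px)) nw$width_range_px <- unlist(nw$width_range_px)
    args$network <- do.call(network_config, nw)
  }
  if (!is.null(y$lesion)) {
    ls <- y$lesion
    if (!is.null(ls$center_rc_px)) ls$center_rc_px <- unlist(ls$center_rc_px)
    args$lesion <- do.call(lesion_spec, ls)
  }
  if (!is.null(y$fractal)) args$fractal <- do.call(fractal_config, y$fractal)
  do.call(experiment_config, args)
}

#' Write an experiment configuration as YAML
#' @param config an [experiment_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.null, TRUE)]
  }
  y <- strip(config)
  y$network <- strip(config$network)
  y$lesion <- strip(config$lesion)
  y$fractal <- strip(config$fractal)
  y$fractal$max_box_px <- NULL
  yaml::write_yaml(y, path)
  invisible(path)
}
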