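# Pipeline runners behind the command-line interface.
#
# Each runner takes a plain named-list configuration (typically loaded from
# YAML or JSON with load_pipeline_config), validates it against the module
# preconditions, runs the corresponding stage, and writes its outputs with a
# metadata block (package version + config hash) for provenance. All
# randomness flows from the single `seed` entry.

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path configuration file (\code{.yaml}/\code{.yml} or
#'   \code{.json}).
#' @return A named list.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be YAML or JSON, got .", ext)
}

# "1:201:2" -> c(1, 3, ..., 201); also accepts a numeric vector unchanged.
.parse_sweep <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  p <- as.integer(strsplit(as.character(x), ":")[[1]])
  if (length(p) == 1L) p <- c(p, p, 2L)
  if (length(p) == 2L) p <- c(p, 2L)
  kernel_sweep_sizes(p[1], p[2], p[3])
}

.band_cfg_from <- function(config) {
  band_config(
    signal_band = config$signal_band %||% c(1, 5),
    noise_band = config$noise_band %||% c(10, 19),
    fft_size = config$fft_size %||% 256L,
    n_noise_peaks = config$n_noise_peaks %||% 2L,
    window = config$window %||% "rect")
}

.config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

.meta_block <- function(config) {
  list(tool = "avfpulse", version = as.character(packageVersion("avfpulse")),
       config_hash = .config_hash(config))
}

.stage_log <- function(stage, config, level = "info") {
  if (identical(config$log_level %||% "info", "quiet")) return(invisible())
  message(sprintf("[avfpulse:%s] %s", stage,
                  paste(names(config), vapply(config, function(v)
                    paste(format(v), collapse = ","), ""),
                    sep = "=", collapse = " ")))
}

#' Simulate a phantom recording to disk
#'
#' Config keys (all optional except \code{out_dir}): \code{out_dir},
#' \code{seed}, \code{format} ("raw" or "tiff"), plus any
#' \code{\link{phantom_config}} field under \code{phantom}.
#'
#' @param config named list or path to a YAML/JSON config.
#' @return Invisibly, a list of written paths.
#' @export
run_simulate <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  if (is.null(config$out_dir)) stop("simulate: config needs out_dir")
  .stage_log("simulate", config)
  pc_args <- config$phantom %||% list()
  if (!is.null(config$seed)) pc_args$seed <- config$seed
  cfg <- do.call(phantom_config, pc_args)
  ph <- generate_phantom(cfg)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- config$format %||% "raw"
  stack_path <- file.path(config$out_dir,
                          if (fmt == "tiff") "phantom.tiff" else "phantom.raw")
  write_frame_stack(ph$stack, stack_path, fmt = fmt)
  write_ground_truth(ph$truth, file.path(config$out_dir, "truth"))
  jsonlite::write_json(c(.meta_block(config), list(config = config)),
                       file.path(config$out_dir, "simulate_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(stack = stack_path,
                 truth = file.path(config$out_dir, "truth"),
                 meta = file.path(config$out_dir, "simulate_meta.json")))
}

#' Quantify a recording: kernel sweep and SNAVF
#'
#' Config keys: \code{input} (stack path), \code{out_dir}, \code{roi}
#' (\code{c(row, col)}; default frame center), \code{channel_kind},
#' \code{kernel_sweep} ("min:max:step" or vector), band settings
#' (\code{signal_band}, \code{noise_band}, \code{fft_size},
#' \code{n_noise_peaks}, \code{window}).
#'
#' @param config named list or path to a YAML/JSON config.
#' @return The \code{\link{snavf_sweep}} result, invisibly; writes
#'   \code{sweep.csv} (columns kernel_size, signal_power, noise_power,
#'   ratio) and \code{quantify.json} (optimal_n, snavf, fundamental_freq).
#' @export
run_quantify <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  if (is.null(config$input) || is.null(config$out_dir))
    stop("quantify: config needs input and out_dir")
  .stage_log("quantify", config)
  stack <- read_frame_stack(config$input, fmt = config$format %||% "auto")
  sc <- to_channel(stack, config$channel_kind %||% "luminance")
  d <- dim(sc$values)
  roi <- config$roi %||% c((d[2] + 1L) %/% 2L, (d[3] + 1L) %/% 2L)
  sizes <- .parse_sweep(config$kernel_sweep %||% "1:201:2")
  sizes <- sizes[sizes <= min(d[2], d[3])]
  sw <- snavf_sweep(sc, roi = as.integer(roi), sizes = sizes,
                    cfg = .band_cfg_from(config))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(sw$table, file.path(config$out_dir, "sweep.csv"),
            row.names = FALSE)
  f0 <- sw$table$fundamental_freq[sw$table$kernel_size == sw$optimal_n]
  jsonlite::write_json(
    c(.meta_block(config),
      list(optimal_n = sw$optimal_n, snavf = sw$snavf,
           fundamental_freq = f0, roi = roi,
           kernel_extent = kernel_extent(sw$optimal_n, stack$pixel_pitch))),
    file.path(config$out_dir, "quantify.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sw)
}

#' Render color-mapped hemodynamic frames
#'
#' Config keys: \code{input}, \code{out_dir}, \code{channel_kind},
#' \code{palette}, \code{range} ("auto" or \code{c(vmin, vmax)}),
#' \code{t_range} (frame indices after band-passing), band settings.
#'
#' @param config named list or path to a YAML/JSON config.
#' @return Invisibly, the written PNG paths.
#' @export
run_colormap <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  if (is.null(config$input) || is.null(config$out_dir))
    stop("colormap: config needs input and out_dir")
  .stage_log("colormap", config)
  stack <- read_frame_stack(config$input, fmt = config$format %||% "auto")
  sc <- to_channel(stack, config$channel_kind %||% "luminance")
  cfg <- .band_cfg_from(config)
  bp <- band_pass_stack(sc, band = config$signal_band %||% c(1, 5), cfg = cfg)
  cmap <- NULL
  rng <- config$range %||% "auto"
  if (!identical(rng, "auto"))
    cmap <- build_colormap(config$palette %||% "blue-red", rng[1], rng[2])
  else if (!is.null(config$palette)) {
    m <- max(abs(bp$values)); if (m == 0) m <- 1
    cmap <- build_colormap(config$palette, -m, m)
  }
  t_range <- config$t_range %||% NULL
  frames <- render_sequence(bp, cmap = cmap, t_range = t_range)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_frames_png(frames, config$out_dir)
  jsonlite::write_json(c(.meta_block(config),
                         list(n_frames = dim(frames)[1],
                              vmin = attr(frames, "cmap")$vmin,
                              vmax = attr(frames, "cmap")$vmax)),
                       file.path(config$out_dir, "colormap_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Summarize a cohort of SNAVF values
#'
#' Config keys: \code{input} (CSV with columns subject_id, recording_id,
#' snavf), \code{out_dir}, \code{method} ("relative" or "zscore").
#'
#' @param config named list or path to a YAML/JSON config.
#' @return The \code{\link{cohort_summary}}, invisibly; writes
#'   \code{cohort.json} and \code{cohort_hist.png}.
#' @export
run_cohort <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  if (is.null(config$input) || is.null(config$out_dir))
    stop("cohort: config needs input and out_dir")
  .stage_log("cohort", config)
  tab <- read.csv(config$input)
  if (!"snavf" %in% names(tab)) stop("cohort: input CSV needs a 'snavf' column")
  cs <- cohort_summary(tab$snavf, method = config$method %||% "relative")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    c(.meta_block(config),
      list(n_subjects = cs$n_subjects, mean_raw = cs$mean_raw,
           median_norm = cs$median_norm, q1 = cs$q1, q2 = cs$q2, q3 = cs$q3,
           q4_max = cs$q4_max)),
    file.path(config$out_dir, "cohort.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  png(file.path(config$out_dir, "cohort_hist.png"), width = 640, height = 480)
  hist(cs$normalized_values, breaks = "FD",
       main = "Normalized SNAVF distribution", xlab = "normalized SNAVF")
  dev.off()
  invisible(cs)
}
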