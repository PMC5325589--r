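# Formats, configuration and orchestration: TIFF stack I/O, YAML run
# configuration, provenance-stamped CSV output, and the staged pipeline
# driver tying the modules into reproducible runs.

#' Read a multi-page TIFF as an intensity stack
#'
#' If a YAML sidecar `<path>.meta.yaml` written by [write_stack()] is
#' present, the stored intensity scale is restored and voxel-size
#' metadata attached as the `"voxel_size"` attribute; otherwise values
#' are returned in the reader's native unit scale.
#'
#' @param path Path to a TIFF file.
#' @return A 3D array ordered (z, y, x); a single-plane file yields
#'   z-dimension 1.
#' @export
read_stack <- function(path) {
  stop_if_not(file.exists(path), paste0("file not found: ", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) {
                      stop("format error reading TIFF '", path, "': ",
                           conditionMessage(e), call. = FALSE)
                    })
  if (!is.list(pages)) pages <- list(pages)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1) {
    stop("format error: ragged TIFF pages in '", path, "'", call. = FALSE)
  }
  d <- dims[[1]]
  out <- array(0, c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) out[i, , ] <- pages[[i]]
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    if (!is.null(meta$intensity_scale)) out <- out * meta$intensity_scale
    if (!is.null(meta$voxel_size)) {
      attr(out, "voxel_size") <- as.numeric(meta$voxel_size)
    }
  }
  out
}

#' Write an intensity stack as a multi-page TIFF
#'
#' Intensities (assumed non-negative, arbitrary units) are rescaled to
#' the TIFF writer's unit range and stored as 32-bit floats; the scale
#' factor (and voxel size, when given) is recorded in a YAML sidecar
#' `<path>.meta.yaml` so [read_stack()] restores the original values
#' within float precision.
#'
#' @param stack 3D array (z, y, x) or a 2D matrix.
#' @param path Output path.
#' @param voxel_size Optional voxel edge lengths (micrometers, z/y/x)
#'   recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, voxel_size = NULL) {
  if (is.matrix(stack)) stack <- array(stack, c(1, dim(stack)))
  stop_if_not(all(stack >= 0), "stack intensities must be non-negative")
  scale <- max(stack, 1e-12)
  pages <- lapply(seq_len(dim(stack)[1]), function(z) stack[z, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(intensity_scale = scale, axis_order = "zyx")
  if (!is.null(voxel_size)) meta$voxel_size <- as.numeric(voxel_size)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Write a CSV with a provenance header
#'
#' Every table output carries comment lines (prefixed `#`) recording the
#' package version, a configuration digest and the seed, followed by a
#' regular header row. Read back with `read.csv(comment.char = "#")`.
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param config Optional list serialized (as YAML) into the digest.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_output_csv <- function(df, path, config = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  version <- as.character(utils::packageVersion("lysoquant"))
  writeLines(paste0("# lysoquant ", version), con)
  if (!is.null(config)) {
    digest <- sum(utf8ToInt(yaml::as.yaml(config)) *
                    (seq_along(utf8ToInt(yaml::as.yaml(config))) %% 97 + 1))
    writeLines(paste0("# config_digest: ", format(digest)), con)
  }
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read and validate a YAML run configuration
#'
#' @param path Path to a YAML file with fields `stages` (subset of
#'   simulate, coloc, objects, lysoph, eye), `seed` (integer) and
#'   optional stage parameter blocks.
#' @return The configuration list (class `"run_config"`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' Validate a run-configuration list
#' @param cfg Configuration list.
#' @return `cfg` with class `"run_config"`; errors on unknown stages or
#'   a missing seed.
#' @export
validate_run_config <- function(cfg) {
  known <- c("simulate", "coloc", "objects", "lysoph", "eye")
  stop_if_not(!is.null(cfg$stages), "config must list stages")
  bad <- setdiff(cfg$stages, known)
  if (length(bad) > 0) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; known stages: ", paste(known, collapse = ", "), call. = FALSE)
  }
  stop_if_not(!is.null(cfg$seed), "config must carry an explicit seed")
  structure(cfg, class = c("run_config", "list"))
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the configured stages against synthetic inputs, writing one
#' provenance-stamped CSV per stage into `out_dir` plus a plain-text log.
#' Deterministic: a given (config, seed) pair produces byte-identical
#' outputs.
#'
#' Stages: `simulate` writes the vesicle-scene truth table; `coloc` the
#' per-scene colocalization row; `objects` the 3D object table of the
#' thresholded reference channel; `lysoph` per-lysosome pH records and
#' the pH distribution modes for control ApoD+/ApoD- populations; `eye`
#' the lattice regularity table across jitter levels.
#'
#' @param config A `"run_config"` (or list validated on entry).
#' @param out_dir Output directory, created if needed.
#' @return Named list of written file paths, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_run_config(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  logmsg <- function(...) {
    writeLines(paste0("[", paste0(...), "]"), log_con)
  }
  out <- list(log = log_path)
  logmsg("run start, seed ", seed)

  scene <- NULL
  if (any(c("simulate", "coloc", "objects") %in% config$stages)) {
    spec <- do.call(vesicle_scene_spec,
                    c(config$simulate, list(seed = seed)))
    scene <- make_vesicle_scene(spec)
    logmsg("simulate: ", nrow(scene$truth), " vesicles")
  }
  if ("simulate" %in% config$stages) {
    p <- file.path(out_dir, "scene_truth.csv")
    write_output_csv(scene$truth, p, config, seed)
    out$simulate <- p
  }
  if ("coloc" %in% config$stages) {
    res <- coloc_pair(scene$stack_a, scene$stack_b)
    p <- file.path(out_dir, "coloc.csv")
    write_output_csv(res, p, config, seed)
    out$coloc <- p
    logmsg("coloc: 2xICQ ", format(res$two_icq, digits = 4))
  }
  if ("objects" %in% config$stages) {
    mask <- threshold_channel(gaussian_preprocess(scene$stack_a, 1))
    lab <- label_objects(mask, connectivity = 26)
    p <- file.path(out_dir, "objects.csv")
    write_output_csv(lab$table, p, config, seed)
    out$objects <- p
    logmsg("objects: ", nrow(lab$table), " objects")
  }
  if ("lysoph" %in% config$stages) {
    classes <- c("ApoD+", "ApoD-")
    gt0 <- spectrum_ground_truth(class = classes[1], seed = seed)
    standards <- make_calibration_standards(gt0)
    ratios <- standards_to_ratios(standards)
    curve <- fit_emission_calibration(ratios)
    recs <- do.call(rbind, lapply(seq_along(classes), function(i) {
      gt <- spectrum_ground_truth(class = classes[i], seed = seed + i)
      estimate_lysosome_ph(make_spectra(gt)$spectra, curve)
    }))
    p <- file.path(out_dir, "lysosome_ph.csv")
    write_output_csv(recs, p, config, seed)
    dist <- ph_distribution(recs)
    p2 <- file.path(out_dir, "ph_modes.csv")
    write_output_csv(dist$modes, p2, config, seed)
    out$lysoph <- c(p, p2)
    logmsg("lysoph: ", nrow(recs), " lysosomes")
  }
  if ("eye" %in% config$stages) {
    jit <- c(0, 1, 2, 4)
    rows <- lapply(seq_along(jit), function(i) {
      lat <- make_lattice_image(lattice_spec(jitter_sd = jit[i],
                                             seed = seed + i))
      mx <- detect_maxima(lat$image, min_distance = 0.6 * 12)
      data.frame(jitter_sd = jit[i], n_spots = nrow(mx),
                 ireg = iregularity(mx))
    })
    p <- file.path(out_dir, "eye_regularity.csv")
    write_output_csv(do.call(rbind, rows), p, config, seed)
    out$eye <- p
    logmsg("eye: ", length(jit), " jitter levels")
  }
  logmsg("run complete")
  invisible(out)
}

#' Fitted 470/524 ratios from calibration-standard spectra
#'
#' Fits each clamped standard spectrum with the Weibull-5 model and
#' computes its emission ratio -- the standards are processed through the
#' same fitting path as the samples.
#'
#' @param standards data.frame from [make_calibration_standards()].
#' @return data.frame: `ph`, `ratio`.
#' @export
standards_to_ratios <- function(standards) {
  levels <- unique(standards$ph)
  data.frame(ph = levels, ratio = vapply(levels, function(p) {
    s <- standards[standards$ph == p, ]
    emission_ratio(fit_weibull5(s$wavelength_nm, s$intensity))
  }, numeric(1)))
}
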