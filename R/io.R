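# File I/O: grayscale TIFF stacks in, tab-delimited tables and TIFF out,
# and a flat key=value configuration format.

#' Read a grayscale TIFF stack
#'
#' Reads an 8- or 16-bit grayscale TIFF (single- or multi-page) and
#' organises the pages into frames and channels. Intensities are returned
#' as integer gray levels, preserved exactly.
#'
#' @param path TIFF file path.
#' @param n_channels number of interleaved channels; pages are assumed
#'   channel-major within each time point (c1 t1, c2 t1, c1 t2, ...).
#' @return for a single page, a matrix; otherwise a list with one element
#'   per channel, each a list of frame matrices.
#' @export
read_stack <- function(path, n_channels = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) == 3) {
      stop("RGB/multi-sample TIFF not supported: expected grayscale ",
           "(offending axis: samples-per-pixel)")
    }
  }
  pages <- lapply(pages, function(p) matrix(as.numeric(p), nrow(p), ncol(p)))
  if (length(pages) == 1 && n_channels == 1) return(pages[[1]])
  if (length(pages) %% n_channels != 0) {
    stop("page count is not a multiple of n_channels")
  }
  n_frames <- length(pages) / n_channels
  lapply(seq_len(n_channels), function(ch) {
    pages[seq(ch, by = n_channels, length.out = n_frames)]
  })
}

#' Write a grayscale TIFF stack
#'
#' @param frames a matrix or list of matrices of integer gray levels.
#' @param path output path.
#' @param bit_depth 8 or 16.
#' @export
write_stack <- function(frames, path, bit_depth = 8) {
  if (is.matrix(frames)) frames <- list(frames)
  top <- 2^bit_depth - 1
  imgs <- lapply(frames, function(f) {
    pmin(pmax(f, 0), top) / top
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = bit_depth)
  invisible(path)
}

#' Write a results table
#'
#' Tab-delimited text with a header row, decimal points, 6 significant
#' digits for floating-point columns.
#'
#' @param table a data frame.
#' @param path output path.
#' @export
write_results <- function(table, path) {
  out <- table
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- signif(out[[nm]], 6)
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, dec = ".")
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path input path.
#' @export
read_results <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

#' Default pipeline configuration
#'
#' @param pixel_size pixel size, micrometers per px.
#' @param diffraction_limit diffraction limit, micrometers; the ratio to
#'   `pixel_size` initialises the PSF fit sigma.
#' @param log_sigma LoG detection scale, px.
#' @param spots_per_cell expected spots per cell per channel.
#' @param max_displacement tracking per-frame bound, px.
#' @param weights a [cost_weights()] vector.
#' @param cell_width,cell_margin segmentation initialisation defaults, px.
#' @param fit_window PSF fit window, px.
#' @param loss_k loss-frame threshold multiplier.
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size = 0.16, diffraction_limit = 0.25,
                            log_sigma = 1.5, spots_per_cell = 2,
                            max_displacement = 4,
                            weights = cost_weights(),
                            cell_width = 14, cell_margin = 8,
                            fit_window = 9, loss_k = 3,
                            seed = 1, out_dir = ".") {
  stopifnot(pixel_size > 0, diffraction_limit > 0, log_sigma > 0,
            max_displacement > 0, cell_width > 0, fit_window %% 2 == 1)
  structure(list(
    pixel_size = pixel_size, diffraction_limit = diffraction_limit,
    log_sigma = log_sigma, spots_per_cell = spots_per_cell,
    max_displacement = max_displacement, weights = weights,
    cell_width = cell_width, cell_margin = cell_margin,
    fit_window = fit_window, loss_k = loss_k,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

#' Write a configuration as flat key=value text
#'
#' @param config a [pipeline_config()].
#' @param path output path.
#' @export
write_config <- function(config, path) {
  lines <- c(
    paste0("pixel_size=", config$pixel_size),
    paste0("diffraction_limit=", config$diffraction_limit),
    paste0("log_sigma=", config$log_sigma),
    paste0("spots_per_cell=", config$spots_per_cell),
    paste0("max_displacement=", config$max_displacement),
    paste0("lambda_intensity=", config$weights[["intensity"]]),
    paste0("lambda_intensity_variation=",
           config$weights[["intensity_variation"]]),
    paste0("lambda_distance=", config$weights[["distance"]]),
    paste0("lambda_direction=", config$weights[["direction"]]),
    paste0("lambda_outside_cell=", config$weights[["outside_cell"]]),
    paste0("cell_width=", config$cell_width),
    paste0("cell_margin=", config$cell_margin),
    paste0("fit_window=", config$fit_window),
    paste0("loss_k=", config$loss_k),
    paste0("seed=", config$seed),
    paste0("out_dir=", config$out_dir)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key=value configuration
#'
#' @param path input path.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  g <- function(k, default) {
    if (k %in% keys) vals[match(k, keys)] else default
  }
  num <- function(k, default) as.numeric(g(k, default))
  pipeline_config(
    pixel_size = num("pixel_size", 0.16),
    diffraction_limit = num("diffraction_limit", 0.25),
    log_sigma = num("log_sigma", 1.5),
    spots_per_cell = num("spots_per_cell", 2),
    max_displacement = num("max_displacement", 4),
    weights = cost_weights(
      intensity = num("lambda_intensity", 1),
      intensity_variation = num("lambda_intensity_variation", 0.5),
      distance = num("lambda_distance", 0.5),
      direction = num("lambda_direction", 0.25),
      outside_cell = num("lambda_outside_cell", 10)
    ),
    cell_width = num("cell_width", 14),
    cell_margin = num("cell_margin", 8),
    fit_window = num("fit_window", 9),
    loss_k = num("loss_k", 3),
    seed = as.integer(num("seed", 1)),
    out_dir = g("out_dir", ".")
  )
}
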