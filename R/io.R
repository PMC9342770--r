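## Reading and writing: multi-page TIFF image stacks (exact 16-bit integer
## counts, channel names and calibration in a YAML sidecar, since TIFF
## float pages do not round-trip exactly) and the pipeline's CSV tables.
## CSV dialect: UTF-8, comma separator, header row, "." decimal; coordinate
## columns carry the `_um` suffix and are always micrometres.

TIFF_MAX_COUNT <- 65535

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta.yaml")
}

#' Write an image stack as multi-page TIFF
#'
#' One 16-bit page per channel (counts stored exactly), with channel names,
#' pixel size and intensity scale in a `<stem>.meta.yaml` sidecar so the
#' stack round-trips bit-identically through [read_image_stack()].
#'
#' @param stack an [image_stack()]; channel values must be integers in
#'   `[0, 65535]`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  for (nm in names(stack$channels)) {
    ch <- stack$channels[[nm]]
    if (any(ch != round(ch)) || any(ch > TIFF_MAX_COUNT)) {
      stop("channel '", nm, "' is not integer counts in [0, ",
           TIFF_MAX_COUNT, "]; cannot be stored exactly as 16-bit TIFF")
    }
  }
  pages <- lapply(stack$channels, function(ch) ch / TIFF_MAX_COUNT)
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  yaml::write_yaml(list(channels = as.list(names(stack$channels)),
                        pixel_size_um = stack$pixel_size_um,
                        intensity_scale = TIFF_MAX_COUNT),
                   sidecar_path(path))
  invisible(path)
}

#' Read an image stack from multi-page TIFF
#'
#' @param path TIFF path written by [write_image_stack()], or any multi-page
#'   TIFF when `channels` and `pixel_size_um` are supplied.
#' @param channels channel names in page order (defaults to the sidecar).
#' @param pixel_size_um pixel size (defaults to the sidecar).
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, channels = NULL, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- yaml::read_yaml(sidecar_path(path))
  }
  if (is.null(channels)) channels <- unlist(meta$channels)
  if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
  if (is.null(channels) || is.null(pixel_size_um)) {
    stop("channel names and pixel_size_um are required (no sidecar found)")
  }
  if (!(is.numeric(pixel_size_um) && pixel_size_um > 0)) {
    stop("pixel_size_um must be positive")
  }
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale
           else TIFF_MAX_COUNT
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(channels)) {
    stop("TIFF has ", length(pages), " pages but ", length(channels),
         " channel names were given")
  }
  chans <- lapply(pages, function(p) round(as.matrix(p) * scale))
  names(chans) <- channels
  image_stack(chans, pixel_size_um)
}

#' Write simulation ground truth as CSV tables
#'
#' `foci.csv` (`x_um,y_um,on_axis`) and `axis.csv`
#' (`path_id,vertex_index,x_um,y_um`), plus a `config.yaml` echo when the
#' configuration is supplied.
#'
#' @param truth a `ground_truth` (from [simulate_nucleus()]).
#' @param dir output directory (created if needed).
#' @param config optional [sim_config()] to echo.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(truth$foci, file.path(dir, "foci.csv"),
                   row.names = FALSE)
  ax <- polylines_to_table(truth$axis_polylines)
  utils::write.csv(ax, file.path(dir, "axis.csv"), row.names = FALSE)
  if (!is.null(config)) {
    yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

polylines_to_table <- function(polylines) {
  if (!length(polylines)) {
    return(data.frame(path_id = integer(0), vertex_index = integer(0),
                      x_um = numeric(0), y_um = numeric(0)))
  }
  do.call(rbind, lapply(seq_along(polylines), function(k) {
    p <- polylines[[k]]
    data.frame(path_id = k, vertex_index = seq_len(nrow(p)),
               x_um = p[, 1L], y_um = p[, 2L])
  }))
}

table_to_polylines <- function(tab) {
  lapply(split(tab, tab$path_id), function(d) {
    d <- d[order(d$vertex_index), , drop = FALSE]
    cbind(d$x_um, d$y_um)
  })
}

#' Write detected foci and axis segmentation as CSV tables
#'
#' `foci_detected.csv` (`x_um,y_um,peak,radius`), `axis_skeleton.csv`
#' (`path_id,vertex,x_um,y_um`) and `axis_summary.csv`
#' (`length_um,n_components`).
#'
#' @param foci a `focus_set` from [detect_foci()].
#' @param seg an `axis_segmentation` from [segment_axis()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_detection <- function(foci, seg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fd <- foci$foci
  utils::write.csv(
    data.frame(x_um = fd$x_um, y_um = fd$y_um, peak = fd$peak_intensity,
               radius = fd$radius_um),
    file.path(dir, "foci_detected.csv"), row.names = FALSE)
  sk <- polylines_to_table(seg$skeleton_polylines)
  names(sk)[names(sk) == "vertex_index"] <- "vertex"
  utils::write.csv(sk, file.path(dir, "axis_skeleton.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(length_um = seg$length_um,
               n_components = seg$n_components),
    file.path(dir, "axis_summary.csv"), row.names = FALSE)
  invisible(dir)
}

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("file ", basename(path), " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  tab
}

#' Read detection tables written by [write_detection()]
#'
#' @param dir directory holding `foci_detected.csv`, `axis_skeleton.csv`
#'   and `axis_summary.csv`.
#' @return List with `foci` (a `focus_set`), `axis_polylines`
#'   (micrometre polylines) and `axis_length_um`.
#' @export
read_tables <- function(dir) {
  fd <- read_csv_checked(file.path(dir, "foci_detected.csv"),
                         c("x_um", "y_um"))
  foci <- data.frame(
    x_um = fd$x_um, y_um = fd$y_um,
    peak_intensity = if ("peak" %in% names(fd)) fd$peak else NA_real_,
    radius_um = if ("radius" %in% names(fd)) fd$radius else NA_real_)
  sk <- read_csv_checked(file.path(dir, "axis_skeleton.csv"),
                         c("path_id", "vertex", "x_um", "y_um"))
  names(sk)[names(sk) == "vertex"] <- "vertex_index"
  summ <- read_csv_checked(file.path(dir, "axis_summary.csv"), "length_um")
  list(
    foci = structure(list(foci = foci, source_channel = "foci",
                          detection_params = NULL), class = "focus_set"),
    axis_polylines = table_to_polylines(sk),
    axis_length_um = summ$length_um[1L]
  )
}
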