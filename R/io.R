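# Raster I/O. RGB and mask rasters travel as 8-bit PNG; depth rasters in mm
# need 16 bits, which the png writer here cannot produce, so depth is written
# as 16-bit grayscale TIFF while the reader accepts both 16-bit PNG and TIFF.

#' Read / write 8-bit RGB rasters
#'
#' @param path PNG file path.
#' @return `read_rgb_png()`: H x W x 3 array of 8-bit intensities.
#' @export
read_rgb_png <- function(path) {
  if (!file.exists(path)) abort_parameter(sprintf("no such file: %s", path))
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), dim = c(dim(x), 3))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  round(x * 255)
}

#' @rdname read_rgb_png
#' @param rgb H x W x 3 array of 8-bit intensities.
#' @export
write_rgb_png <- function(rgb, path) {
  check_rgb_image(rgb)
  png::writePNG(rgb / 255, path)
  invisible(path)
}

#' Read / write depth rasters in millimetres
#'
#' Depth values are integers in mm with 0 the invalid sentinel. Writing
#' uses 16-bit grayscale TIFF (exact for 0..65535); reading also accepts
#' 16-bit grayscale PNG.
#'
#' @param path file path (`.tif`/`.tiff` or 16-bit `.png` when reading).
#' @return `read_depth_raster()`: H x W matrix of integer mm.
#' @export
read_depth_raster <- function(path) {
  if (!file.exists(path)) abort_parameter(sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  round(x * 65535)
}

#' @rdname read_depth_raster
#' @param depth H x W matrix of integer mm in 0..65535.
#' @export
write_depth_raster <- function(depth, path) {
  check_depth(depth)
  if (max(depth) > 65535)
    abort_parameter("depth exceeds the 16-bit range (65535 mm)")
  tiff::writeTIFF(depth / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Read / write binary masks as 8-bit PNG (0/255)
#'
#' @param path PNG file path.
#' @return `read_mask_png()`: H x W logical matrix.
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) abort_parameter(sprintf("no such file: %s", path))
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x > 0.5
}

#' @rdname read_mask_png
#' @param mask logical H x W matrix (or a `shoot_mask`).
#' @export
write_mask_png <- function(mask, path) {
  m <- check_mask(mask)
  png::writePNG(m * 1, path)
  invisible(path)
}

#' Persist a synthetic frame + truth as a reloadable fixture
#'
#' Writes `rgb.png` (8-bit), `depth.tif` (16-bit grayscale, mm),
#' `mask.png` (0/255), and `manifest.json` carrying the scene parameters
#' and truth values. The manifest records the seed, so
#' [generate_canopy_frame()] on the stored parameters reproduces the
#' fixture bit for bit; [read_canopy_fixture()] round-trips all arrays
#' exactly.
#'
#' @param frame a [canopy_frame()].
#' @param truth the matching `canopy_truth`.
#' @param directory output directory (created if needed).
#' @return path of the manifest file.
#' @export
write_canopy_fixture <- function(frame, truth, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory))
    abort_teaprof(sprintf("cannot create fixture directory %s", directory),
                  "teaprof_io_error")
  write_rgb_png(frame$rgb, file.path(directory, "rgb.png"))
  write_depth_raster(frame$depth, file.path(directory, "depth.tif"))
  write_mask_png(truth$shoot_mask, file.path(directory, "mask.png"))
  manifest <- list(
    frame_id = frame$frame_id,
    files = list(rgb = "rgb.png", depth = "depth.tif", mask = "mask.png"),
    params = unclass(frame$params),
    truth = list(true_l_near = truth$true_l_near,
                 true_l_far = truth$true_l_far,
                 true_d = truth$true_d, true_alpha = truth$true_alpha)
  )
  path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Reload a fixture written by [write_canopy_fixture()]
#'
#' @param manifest_path path to the fixture's `manifest.json`.
#' @return list with `frame`, `truth` and `params`.
#' @export
read_canopy_fixture <- function(manifest_path) {
  if (!file.exists(manifest_path))
    abort_parameter(sprintf("no such manifest: %s", manifest_path))
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  params <- if (!is.null(man$params)) do.call(scene_params, man$params) else NULL
  frame <- canopy_frame(
    read_rgb_png(file.path(dir, man$files$rgb)),
    read_depth_raster(file.path(dir, man$files$depth)),
    frame_id = man$frame_id, params = params)
  truth <- structure(
    list(shoot_mask = read_mask_png(file.path(dir, man$files$mask)),
         specular_mask = NULL,
         true_l_near = man$truth$true_l_near,
         true_l_far = man$truth$true_l_far,
         true_d = man$truth$true_d, true_alpha = man$truth$true_alpha),
    class = "canopy_truth")
  list(frame = frame, truth = truth, params = params)
}
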