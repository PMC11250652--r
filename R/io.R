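# Readers and writers for the data the tool touches: PNG images, NIfTI
# volumes, and lossless array containers (RDS, plain-JSON dim+data).

detect_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("png", "nifti", "rds", "json")))
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) return("png")
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  if (grepl("\\.rds$", lower)) return("rds")
  if (grepl("\\.json$", lower)) return("json")
  stop_shape("cannot infer format of '%s'; pass `format` explicitly", path)
}

#' Load a tensor from disk
#'
#' Supported formats (inferred from the extension unless `format` is
#' given): `png` (RGB images become `H x W x 3` arrays in `[0, 1]`;
#' grayscale images become order-2 arrays), `nifti` (`.nii`/`.nii.gz`
#' volumes in native intensity, header kept as an attribute so that a
#' completed volume can be written back with the same geometry), `rds`
#' and `json` (lossless array containers).
#'
#' @param path file to read.
#' @param format optional explicit format: `"png"`, `"nifti"`, `"rds"`,
#'   or `"json"`.
#' @param normalize if `TRUE`, linearly rescale intensities to `[0, 1]`
#'   when the maximum exceeds 1 (PNG data is already in `[0, 1]`).
#' @return a numeric array.
#' @export
load_tensor <- function(path, format = NULL, normalize = FALSE) {
  if (!file.exists(path)) stop_shape("file not found: '%s'", path)
  fmt <- detect_format(path, format)
  x <- switch(fmt,
    png = {
      img <- png::readPNG(path)
      if (is.matrix(img)) img <- as.array(img)
      img
    },
    nifti = {
      img <- RNifti::readNifti(path)
      arr <- array(as.numeric(img), dim(img))
      attr(arr, "nifti_header") <- RNifti::niftiHeader(img)
      arr
    },
    rds = {
      obj <- readRDS(path)
      if (!is.array(obj)) stop_shape("'%s' does not contain an array", path)
      obj
    },
    json = {
      obj <- jsonlite::read_json(path, simplifyVector = TRUE)
      if (is.null(obj$dim) || is.null(obj$data))
        stop_shape("'%s' is not a dim+data JSON tensor container", path)
      array(as.numeric(obj$data), as.integer(obj$dim))
    }
  )
  if (normalize) {
    hi <- max(x, na.rm = TRUE)
    lo <- min(0, min(x, na.rm = TRUE))
    if (hi > 1) x <- (x - lo) / (hi - lo)
  }
  message(sprintf("loaded '%s' [%s]: shape %s", path, fmt,
                  paste(dim(x), collapse = " x ")))
  x
}

#' Save a tensor to disk
#'
#' PNG output clips values to `[0, 1]` (with a warning if the range is
#' far outside) and quantizes to 8 bits with round-half-up
#' (`floor(v * 255 + 0.5)`).  NIfTI output reuses the source header
#' geometry when the array carries a `nifti_header` attribute (as set by
#' [load_tensor()]).  The RDS and JSON containers are lossless.
#'
#' @param x numeric array; for PNG, `H x W` or `H x W x {1,3,4}`.
#' @param path destination file.
#' @param format optional explicit format.
#' @return `path`, invisibly.
#' @export
save_tensor <- function(x, path, format = NULL) {
  if (is.null(dim(x)) || length(dim(x)) < 2L || prod(dim(x)) == 0L)
    stop_shape("`x` must be a non-empty array of order >= 2")
  fmt <- detect_format(path, format)
  switch(fmt,
    png = {
      if (min(x) < -0.05 || max(x) > 1.05)
        warning(sprintf("PNG values in [%.3g, %.3g] clipped to [0, 1]",
                        min(x), max(x)), call. = FALSE)
      v <- pmin(pmax(x, 0), 1)
      v <- floor(v * 255 + 0.5) / 255   # round-half-up quantization
      png::writePNG(v, path)
    },
    nifti = {
      hdr <- attr(x, "nifti_header")
      arr <- array(as.numeric(x), dim(x))
      img <- if (!is.null(hdr)) RNifti::asNifti(arr, reference = hdr)
             else RNifti::asNifti(arr)
      RNifti::writeNifti(img, path)
    },
    rds = saveRDS(array(as.numeric(x), dim(x)), path),
    json = jsonlite::write_json(
      list(dim = dim(x), data = as.numeric(x)), path,
      auto_unbox = FALSE, digits = I(17))
  )
  invisible(path)
}

#' Save / load an observation mask
#'
#' Masks are stored in the lossless containers as 0/1 arrays (RDS keeps
#' the logical type directly).
#'
#' @param mask logical array.
#' @param path destination/source file (`.rds` or `.json`).
#' @return `load_mask` returns a logical array.
#' @export
save_mask <- function(mask, path) {
  fmt <- detect_format(path)
  if (fmt == "rds") saveRDS(mask, path)
  else if (fmt == "json")
    jsonlite::write_json(list(dim = dim(mask),
                              data = as.integer(mask)), path,
                         auto_unbox = FALSE, digits = NA)
  else stop_shape("masks are stored as .rds or .json")
  invisible(path)
}

#' @rdname save_mask
#' @export
load_mask <- function(path) {
  fmt <- detect_format(path)
  m <- if (fmt == "rds") readRDS(path)
  else if (fmt == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    array(as.integer(obj$data), as.integer(obj$dim))
  } else stop_shape("masks are stored as .rds or .json")
  array(as.logical(m), dim(m))
}
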