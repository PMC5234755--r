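#' Read a volume from disk
#'
#' Supports NIfTI (`.nii`, `.nii.gz`) and MetaImage (`.mhd` + `.raw`).
#' Voxel sizes come from the header; the MetaImage `Offset` (when present)
#' is used as the grid origin, otherwise the grid is centred on the origin.
#'
#' @param path File path.
#' @return A [volume_image()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  ext <- tolower(sub(".*?(\\.nii\\.gz|\\.[^.]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::readNifti(path)
    vox <- RNifti::pixdim(img)[1:3]
    volume_image(array(as.numeric(img), dim(img)[1:3]), vox)
  } else if (ext == ".mhd") {
    read_metaimage(path)
  } else stop("format error: unknown volume extension: ", ext)
}

#' Write a volume to disk
#'
#' @param volume A [volume_image()].
#' @param path Output path; extension selects the format (`.nii`, `.nii.gz`
#'   or `.mhd`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_image"))
  ext <- tolower(sub(".*?(\\.nii\\.gz|\\.[^.]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    vals <- volume$values
    attr(vals, "pixdim") <- volume$voxel_size
    RNifti::writeNifti(RNifti::asNifti(vals, datatype = "float"), path)
  } else if (ext == ".mhd") {
    write_metaimage(volume, path)
  } else stop("format error: unknown volume extension: ", ext)
  invisible(path)
}

# MetaImage: plain-text .mhd header plus little-endian float32 .raw payload.
read_metaimage <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " = "), "")
  getv <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  if (!identical(getv("ObjectType"), "Image") ||
      !identical(getv("ElementType"), "MET_FLOAT"))
    stop("format error: unsupported MetaImage header")
  dims <- as.integer(strsplit(getv("DimSize"), "\\s+")[[1]])
  vox <- as.numeric(strsplit(getv("ElementSpacing", "1 1 1"), "\\s+")[[1]])
  off <- getv("Offset")
  raw_file <- file.path(dirname(path), getv("ElementDataFile"))
  if (!file.exists(raw_file)) stop("I/O error: missing raw payload: ", raw_file)
  con <- file(raw_file, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = prod(dims), size = 4, endian = "little")
  vol <- volume_image(array(v, dims), vox,
                      origin = if (is.null(off)) NULL
                      else as.numeric(strsplit(off, "\\s+")[[1]]))
  vol
}

write_metaimage <- function(volume, path) {
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  d <- dim(volume$values)
  header <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
              "BinaryDataByteOrderMSB = False",
              paste("DimSize =", paste(d, collapse = " ")),
              paste("ElementSpacing =",
                    paste(format(volume$voxel_size, digits = 10), collapse = " ")),
              paste("Offset =",
                    paste(format(volume$origin, digits = 10), collapse = " ")),
              "ElementType = MET_FLOAT",
              paste("ElementDataFile =", raw_name))
  writeLines(header, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.numeric(volume$values), con, size = 4, endian = "little")
  invisible(path)
}

#' Write a projection set
#'
#' Frames go to a multi-page 32-bit float TIFF (values divided by a `scale`
#' so they fit the TIFF range); angles, pitch, exposure, fingerprint, count
#' type, calibration, seed and `scale` go to a JSON sidecar with the same
#' stem.
#'
#' @param projections A [projection_set()].
#' @param path Output `.tif`/`.tiff` path.
#' @return `path`, invisibly.
#' @export
write_projections <- function(projections, path) {
  stopifnot(inherits(projections, "projection_set"))
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("format error: projections must be written as .tif/.tiff")
  mx <- max(projections$frames)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(dim(projections$frames)[3]),
                  function(a) projections$frames[, , a] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  meta <- list(angles = projections$angles,
               pixel_pitch = projections$pixel_pitch,
               exposure = projections$exposure,
               fingerprint = projections$fingerprint,
               counts = projections$counts,
               calibration = projections$calibration,
               seed = projections$seed,
               scale = scale)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a projection set
#'
#' @param path `.tif`/`.tiff` path written by [write_projections()]; the
#'   JSON sidecar with the same stem must exist.
#' @return A [projection_set()].
#' @export
read_projections <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  sidecar <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  if (!file.exists(sidecar))
    stop("format error: missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(meta$angles))
    stop("consistency error: sidecar angle count (", length(meta$angles),
         ") does not match TIFF page count (", length(pages), ")")
  frames <- array(0, c(dim(pages[[1]]), length(pages)))
  for (a in seq_along(pages)) frames[, , a] <- pages[[a]] * meta$scale
  # r-tiff returns matrices indexed [row, col]; pages were written from
  # [u, v] matrices, and round-trip preserves the layout.
  projection_set(frames, meta$pixel_pitch, meta$angles, meta$exposure,
                 fingerprint = meta$fingerprint, counts = meta$counts,
                 calibration = meta$calibration,
                 seed = if (is.null(meta$seed) || is.na(meta$seed))
                   NA_integer_ else as.integer(meta$seed))
}

#' Write a resolution report as JSON
#'
#' @param report A `resolution_report` from [limiting_resolution()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "resolution_report"))
  out <- list(feature_sizes_mm = report$feature_sizes,
              contrast = unname(report$per_feature_contrast),
              resolved = unname(report$resolved),
              criterion = report$criterion,
              limiting_resolution_mm = report$limiting_resolution)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
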