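#' Voxel volume container
#'
#' A 3-D scalar grid with physical voxel spacing and a modality tag. CT
#' volumes are expected on the Hounsfield scale (air near -1000 HU, water
#' at 0 HU); PET volumes carry an activity-concentration scale (activity
#' per mL). Arrays are stored in R's column-major (x, y, z) axis order with
#' spacing `(dx, dy, dz)` in mm; the third axis is the axial (slice) axis.
#'
#' @param data numeric 3-D array.
#' @param spacing numeric length-3 vector, mm per voxel along (x, y, z);
#'   all entries must be strictly positive.
#' @param modality `"CT_HU"` or `"PET_ACTIVITY"`.
#' @return object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing, modality = c("CT_HU", "PET_ACTIVITY")) {
  modality <- match.arg(modality)
  if (length(dim(data)) != 3L) stop("`data` must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (mm)")
  structure(list(data = data, spacing = spacing, modality = modality),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %s, %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Voxel volume in mm^3
#' @param volume a [voxel_volume()] or a numeric length-3 spacing vector.
#' @export
voxel_volume_mm3 <- function(volume) {
  sp <- if (inherits(volume, "voxel_volume")) volume$spacing else as.numeric(volume)
  prod(sp)
}

#' Binary mask container
#'
#' A logical grid aligned to a parent volume, tagged with a semantic role.
#'
#' @param data logical array (2-D or 3-D).
#' @param role one of `"BODY"`, `"AIR"`, `"LUNG"`, `"FAT_CANDIDATE"`,
#'   `"FAT_FINAL"`, `"ROI"`.
#' @param parent_shape expected grid dimensions (defaults to `dim(data)`).
#' @return object of class `binary_mask`.
#' @export
binary_mask <- function(data, role = c("BODY", "AIR", "LUNG", "FAT_CANDIDATE",
                                       "FAT_FINAL", "ROI"),
                        parent_shape = dim(data)) {
  role <- match.arg(role)
  if (is.null(dim(data))) stop("`data` must be an array")
  if (!identical(as.integer(dim(data)), as.integer(parent_shape)))
    stop("mask dimensions do not match parent_shape")
  storage.mode(data) <- "logical"
  structure(list(data = data, role = role,
                 parent_shape = as.integer(parent_shape)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> role %s, %s voxels, %d set\n", x$role,
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

# Extract the logical array from a binary_mask or pass a plain array through.
mask_data <- function(m) {
  if (inherits(m, "binary_mask")) m$data else m
}

#' Read a volume from NIfTI or MetaImage
#'
#' NIfTI (`.nii`, `.nii.gz`) is read with the RNifti package; uncompressed
#' MetaImage (`.mhd` + raw, or local `.mha`) with a built-in reader. Voxel
#' spacing is taken from the header.
#'
#' @param path file path.
#' @param modality modality tag to attach, `"CT_HU"` or `"PET_ACTIVITY"`.
#' @return a [voxel_volume()].
#' @export
read_volume <- function(path, modality = "CT_HU") {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (tolower(tools::file_ext(path)) == "gz") ext <- "nii"
  if (ext %in% c("nii", "hdr", "img")) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[1:3]
    arr <- array(as.numeric(img), dim = dim(img)[1:3])
    voxel_volume(arr, sp, modality)
  } else if (ext %in% c("mhd", "mha")) {
    read_metaimage(path, modality)
  } else {
    stop("unsupported volume format: ", path)
  }
}

#' Write a volume or mask to NIfTI
#'
#' Masks are written as unsigned 8-bit (0/1) images; volumes keep their
#' numeric values. Spacing is stored in the header.
#'
#' @param x a [voxel_volume()] or [binary_mask()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param spacing spacing override (mm); required when writing a bare mask.
#' @export
write_volume <- function(x, path, spacing = NULL) {
  if (inherits(x, "voxel_volume")) {
    arr <- x$data
    sp <- x$spacing
    dt <- "double"
  } else if (inherits(x, "binary_mask")) {
    arr <- array(as.integer(x$data), dim(x$data))
    sp <- spacing
    if (is.null(sp)) sp <- c(1, 1, 1)
    dt <- "uint8"
  } else {
    stop("`x` must be a voxel_volume or binary_mask")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

# --- MetaImage (uncompressed) -------------------------------------------
# Minimal key = value header parser for .mhd/.mha written by common imaging
# toolkits. Only uncompressed scalar volumes are supported.

.met_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                MET_SHORT = "integer", MET_USHORT = "integer",
                MET_INT = "integer", MET_UINT = "integer",
                MET_FLOAT = "double", MET_DOUBLE = "double")
.met_sizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
                MET_INT = 4L, MET_UINT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)
.met_signed <- c(MET_UCHAR = FALSE, MET_CHAR = TRUE, MET_SHORT = TRUE,
                 MET_USHORT = FALSE, MET_INT = TRUE, MET_UINT = FALSE,
                 MET_FLOAT = TRUE, MET_DOUBLE = TRUE)

read_metaimage <- function(path, modality = "CT_HU") {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  data_offset <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("unexpected end of MetaImage header")
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) hdr[[kv[2]]] <- trimws(kv[3])
    if (identical(kv[2], "ElementDataFile")) {
      data_offset <- seek(con)
      break
    }
  }
  if (isTRUE(toupper(hdr$CompressedData %||% "FALSE") == "TRUE"))
    stop("compressed MetaImage is not supported")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  etype <- hdr$ElementType
  if (!etype %in% names(.met_types)) stop("unsupported ElementType: ", etype)
  msb <- toupper(hdr$BinaryDataByteOrderMSB %||% hdr$ElementByteOrderMSB %||% "FALSE") == "TRUE"
  endian <- if (msb) "big" else "little"
  n <- prod(dims)
  datafile <- hdr$ElementDataFile
  if (identical(datafile, "LOCAL")) {
    raw <- readBin(con, .met_types[[etype]], n = n, size = .met_sizes[[etype]],
                   signed = .met_signed[[etype]], endian = endian)
  } else {
    dpath <- file.path(dirname(path), datafile)
    dcon <- file(dpath, "rb")
    on.exit(close(dcon), add = TRUE)
    raw <- readBin(dcon, .met_types[[etype]], n = n, size = .met_sizes[[etype]],
                   signed = .met_signed[[etype]], endian = endian)
  }
  voxel_volume(array(as.numeric(raw), dim = dims), sp, modality)
}

#' Write a volume as uncompressed MetaImage
#'
#' Writes an `.mha` (header + LOCAL data in one file, MET_FLOAT) or an
#' `.mhd` header with a sibling `.raw` file.
#'
#' @param volume a [voxel_volume()].
#' @param path output path ending in `.mha` or `.mhd`.
#' @export
write_metaimage <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  ext <- tolower(tools::file_ext(path))
  d <- dim(volume$data)
  local <- ext == "mha"
  datafile <- if (local) "LOCAL" else paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c("ObjectType = Image",
           sprintf("NDims = %d", length(d)),
           sprintf("DimSize = %s", paste(d, collapse = " ")),
           sprintf("ElementSpacing = %s", paste(volume$spacing, collapse = " ")),
           "ElementType = MET_FLOAT",
           "BinaryDataByteOrderMSB = False",
           paste0("ElementDataFile = ", datafile))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  vals <- as.numeric(volume$data)
  if (local) {
    writeBin(vals, con, size = 4L, endian = "little")
  } else {
    dcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(dcon), add = TRUE)
    writeBin(vals, dcon, size = 4L, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
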