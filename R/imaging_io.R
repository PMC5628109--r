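#' CT volume in Hounsfield units
#'
#' Container for a 3D CT scan. The data array is ordered `[z, y, x]` with `z`
#' the axial (slice) axis; `spacing` and `origin` follow the same `(z, y, x)`
#' order, in millimetres. Hounsfield values outside the representable CT range
#' `[-1024, 3071]` are clipped with a warning.
#'
#' @param data numeric 3D array, axes `(z, y, x)`.
#' @param spacing numeric length-3, voxel size `(dz, dy, dx)` in mm, all > 0.
#' @param origin numeric length-3, physical position `(z, y, x)` of the first
#'   voxel centre in mm.
#' @return An object of class `ct_volume` with elements `data`, `spacing`,
#'   `origin`.
#' @examples
#' v <- ct_volume(array(0, c(4, 6, 6)), spacing = c(3, 1.35, 1.35))
#' dim(v$data)
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)")
  if (any(dim(data) < 1L)) stop("each axis must have length >= 1")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (dz, dy, dx)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (z, y, x)")
  data <- clip_hu(data)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "ct_volume")
}

# CT numbers below air or above the 12-bit ceiling are reconstruction
# overshoots; clip rather than reject.
clip_hu <- function(data, lo = -1024, hi = 3071) {
  n_out <- sum(data < lo | data > hi, na.rm = TRUE)
  if (n_out > 0L) {
    warning(sprintf("%d HU value(s) outside [%d, %d] clipped", n_out, lo, hi))
    data[data < lo] <- lo
    data[data > hi] <- hi
  }
  data
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing (%s) mm, HU range [%.0f, %.0f]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Binary voxel mask on the grid of a parent CT volume
#'
#' @param data logical or 0/1 3D array with the same shape as `parent$data`.
#' @param parent a [ct_volume] supplying grid geometry.
#' @return An object of class `voxel_mask` with elements `data` (logical
#'   array), `spacing`, `origin`.
#' @export
voxel_mask <- function(data, parent) {
  stopifnot(inherits(parent, "ct_volume"))
  if (!is.array(data) || !identical(dim(data), dim(parent$data)))
    stop("mask shape must equal the parent volume shape")
  structure(list(data = array(as.logical(data), dim(data)),
                 spacing = parent$spacing, origin = parent$origin),
            class = "voxel_mask")
}

is_supported_image_path <- function(path) {
  grepl("\\.(nii|nii\\.gz|mha|mhd)$", path, ignore.case = TRUE)
}

#' Read a CT volume or mask from NIfTI or MetaImage
#'
#' Supported formats are NIfTI-1 (`.nii`, `.nii.gz`) and MetaImage
#' (`.mha`, `.mhd` + raw). Voxel spacing and origin are taken from the header;
#' intensities are used as stored after the header's linear slope/intercept
#' (applied by the NIfTI reader). The array is returned in `(z, y, x)` order.
#'
#' @param path file path.
#' @return A [ct_volume].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  if (!is_supported_image_path(path))
    stop("unsupported image format (want .nii/.nii.gz/.mha/.mhd): ", path)
  if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) {
    v <- read_metaimage(path)
  } else {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
      stop("expected a 3D scalar volume, got ", length(d), " dimensions: ", path)
    pd <- RNifti::pixdim(img)           # (dx, dy, dz)
    o_xyz <- RNifti::voxelToWorld(c(1, 1, 1), img)  # world mm of first voxel
    arr <- aperm(array(as.numeric(img), dim = d), c(3, 2, 1))
    v <- ct_volume(arr, spacing = rev(pd[1:3]), origin = rev(o_xyz))
  }
  v
}

#' Write a CT volume or mask to NIfTI or MetaImage
#'
#' The on-disk file round-trips through [load_volume] with identical data,
#' spacing and origin. Masks (`voxel_mask`) are stored as unsigned 8-bit.
#'
#' @param volume a [ct_volume] or [voxel_mask].
#' @param path output path ending in `.nii`, `.nii.gz`, `.mha` or `.mhd`.
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path) {
  if (!inherits(volume, c("ct_volume", "voxel_mask")))
    stop("`volume` must be a ct_volume or voxel_mask")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write image: no such directory: ", dir)
  if (!is_supported_image_path(path))
    stop("unsupported image format (want .nii/.nii.gz/.mha/.mhd): ", path)
  is_mask <- inherits(volume, "voxel_mask")
  if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) {
    write_metaimage(volume, path, uint8 = is_mask)
  } else {
    arr <- aperm(volume$data + 0, c(3, 2, 1))   # to (x, y, z)
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rev(volume$spacing)  # (dx, dy, dz)
    o <- rev(volume$origin)                     # (x, y, z)
    q <- rbind(cbind(diag(rev(volume$spacing)), o), c(0, 0, 0, 1))
    RNifti::qform(img) <- structure(q, code = 2L)
    RNifti::writeNifti(img, path, datatype = if (is_mask) "uint8" else "double")
  }
  invisible(path)
}

# --- MetaImage (.mha single-file, .mhd + .raw) -------------------------------
# Minimal reader/writer for the subset this package emits: uncompressed,
# little-endian, scalar MET_UCHAR / MET_SHORT / MET_FLOAT / MET_DOUBLE.

metaimage_types <- c(MET_UCHAR = "integer", MET_SHORT = "integer",
                     MET_INT = "integer", MET_FLOAT = "double",
                     MET_DOUBLE = "double")
metaimage_sizes <- c(MET_UCHAR = 1L, MET_SHORT = 2L, MET_INT = 4L,
                     MET_FLOAT = 4L, MET_DOUBLE = 8L)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated MetaImage header: ", path)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: ", line)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims %||% "0")
  if (ndims != 3L)
    stop("expected a 3D scalar volume, got NDims=", ndims, ": ", path)
  dims_xyz <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing_xyz <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  origin_xyz <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
  type <- hdr$ElementType %||% "MET_FLOAT"
  if (!type %in% names(metaimage_types))
    stop("unsupported MetaImage ElementType: ", type)
  msb <- tolower(hdr$ElementByteOrderMSB %||% hdr$BinaryDataByteOrderMSB %||% "false")
  endian <- if (msb == "true") "big" else "little"
  n <- prod(dims_xyz)
  datafile <- hdr$ElementDataFile
  if (identical(datafile, "LOCAL")) {
    raw_vals <- readBin(con, metaimage_types[[type]], n = n,
                        size = metaimage_sizes[[type]], endian = endian,
                        signed = type != "MET_UCHAR")
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath)) stop("cannot read image data: ", rawpath)
    rcon <- file(rawpath, "rb")
    on.exit(close(rcon), add = TRUE)
    raw_vals <- readBin(rcon, metaimage_types[[type]], n = n,
                        size = metaimage_sizes[[type]], endian = endian,
                        signed = type != "MET_UCHAR")
  }
  if (length(raw_vals) != n) stop("truncated MetaImage data: ", path)
  arr <- aperm(array(as.numeric(raw_vals), dim = dims_xyz), c(3, 2, 1))
  ct_volume(arr, spacing = rev(spacing_xyz), origin = rev(origin_xyz))
}

write_metaimage <- function(volume, path, uint8 = FALSE) {
  arr <- aperm(volume$data + 0, c(3, 2, 1))   # x fastest on disk
  type <- if (uint8) "MET_UCHAR" else "MET_DOUBLE"
  mhd <- grepl("\\.mhd$", path, ignore.case = TRUE)
  datafile <- if (mhd) sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE) else "LOCAL"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(dim(arr), collapse = " ")),
    paste("ElementSpacing =", paste(format(rev(volume$spacing), digits = 17), collapse = " ")),
    paste("Offset =", paste(format(rev(volume$origin), digits = 17), collapse = " ")),
    paste("ElementType =", type),
    paste("ElementDataFile =", datafile)
  )
  vals <- as.vector(arr)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (mhd) {
    rcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rcon), add = TRUE)
    target <- rcon
  } else target <- con
  if (uint8) {
    writeBin(as.integer(round(vals)), target, size = 1L)
  } else {
    writeBin(as.numeric(vals), target, size = 8L, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
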