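#' CT volume container
#'
#' A 3D scalar image with physical geometry. Voxels follow the `(z, y, x)` =
#' (depth, height, width) axis convention; world coordinates are `(x, y, z)`
#' millimetres as in LUNA16 annotation files. The axis reorder happens only in
#' [world_to_voxel()].
#'
#' @param voxels 3D numeric array, dim `(D, H, W)`, HU-scale intensities.
#' @param spacing mm per voxel along `(z, y, x)`; all components positive.
#' @param origin world-mm position of voxel `(0, 0, 0)`, given as `(x, y, z)`.
#' @param series_uid opaque series identifier.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      series_uid = "volume") {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array", call. = FALSE)
  if (any(dim(voxels) < 1L)) stop("all volume dimensions must be >= 1", call. = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values (z, y, x)", call. = FALSE)
  if (length(origin) != 3L) stop("origin must be 3 values (x, y, z) mm", call. = FALSE)
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), series_uid = as.character(series_uid)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume %s: %d x %d x %d (z,y,x), spacing %s mm, origin (%s) mm>\n",
              x$series_uid, d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

.mhd_types <- c(MET_SHORT = "integer", MET_USHORT = "integer", MET_FLOAT = "double",
                MET_DOUBLE = "double", MET_UCHAR = "integer", MET_CHAR = "integer")
.mhd_sizes <- c(MET_SHORT = 2L, MET_USHORT = 2L, MET_FLOAT = 4L, MET_DOUBLE = 8L,
                MET_UCHAR = 1L, MET_CHAR = 1L)

#' Read a MetaImage (.mhd/.raw) volume
#'
#' Parses the text header and the accompanying raw payload. On disk MetaImage
#' stores x fastest; the returned volume follows the package's `(z, y, x)`
#' array convention. `ElementSpacing`/`Offset` in the header are `(x, y, z)`;
#' spacing is reordered to `(z, y, x)` in the returned object.
#'
#' @param path path to the `.mhd` header.
#' @return a [ct_volume()].
#' @export
read_mhd <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", ln))[[1L]]
    if (length(m) == 3L) kv[[m[2L]]] <- m[3L]
  }
  need <- c("NDims", "DimSize", "ElementType", "ElementDataFile")
  miss <- setdiff(need, names(kv))
  if (length(miss))
    stop("malformed MetaImage header, missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (as.integer(kv$NDims) != 3L)
    stop("unsupported NDims in MetaImage header: ", kv$NDims, call. = FALSE)
  type <- kv$ElementType
  if (!type %in% names(.mhd_types))
    stop("unsupported ElementType: ", type, call. = FALSE)
  dims <- as.integer(strsplit(kv$DimSize, "\\s+")[[1L]])   # (x, y, z)
  spacing_xyz <- if (!is.null(kv$ElementSpacing))
    as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1L]]) else c(1, 1, 1)
  origin <- if (!is.null(kv$Offset))
    as.numeric(strsplit(kv$Offset, "\\s+")[[1L]]) else c(0, 0, 0)
  msb <- identical(kv$ElementByteOrderMSB %||% kv$BinaryDataByteOrderMSB %||% "False", "True")
  rawfile <- kv$ElementDataFile
  if (identical(rawfile, "LOCAL"))
    stop("inline (LOCAL) MetaImage payloads are not supported", call. = FALSE)
  rawpath <- file.path(dirname(path), rawfile)
  if (!file.exists(rawpath))
    stop("raw payload named by ElementDataFile not found: ", rawpath, call. = FALSE)
  n <- prod(dims)
  sz <- .mhd_sizes[[type]]
  if (file.info(rawpath)$size < as.numeric(n) * sz)
    stop("truncated raw payload: ", rawpath, " holds fewer than ", n,
         " elements of ", type, call. = FALSE)
  con <- file(rawpath, "rb"); on.exit(close(con))
  vals <- readBin(con, what = .mhd_types[[type]], n = n, size = sz,
                  signed = !type %in% c("MET_UCHAR", "MET_USHORT"),
                  endian = if (msb) "big" else "little")
  vox <- array(as.numeric(vals), dim = dims)        # (x, y, z), x fastest
  vox <- aperm(vox, c(3L, 2L, 1L))                  # -> (z, y, x)
  ct_volume(vox, spacing = rev(spacing_xyz), origin = origin,
            series_uid = sub("\\.mhd$", "", basename(path)))
}

#' Write a MetaImage (.mhd/.raw) pair
#'
#' @param volume a [ct_volume()].
#' @param path output `.mhd` path; the raw payload is written alongside.
#' @param element_type `"MET_SHORT"` (rounded) or `"MET_FLOAT"`/`"MET_DOUBLE"`.
#' @return `path`, invisibly.
#' @export
write_mhd <- function(volume, path, element_type = c("MET_SHORT", "MET_FLOAT", "MET_DOUBLE")) {
  element_type <- match.arg(element_type)
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$voxels)                            # (z, y, x)
  rawfile <- paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", d[3], d[2], d[1]),
           paste("ElementSpacing =", volume$spacing[3], volume$spacing[2], volume$spacing[1]),
           paste("Offset =", volume$origin[1], volume$origin[2], volume$origin[3]),
           paste("ElementType =", element_type),
           paste("ElementDataFile =", rawfile))
  writeLines(hdr, path)
  vox <- aperm(volume$voxels, c(3L, 2L, 1L))         # -> (x, y, z), x fastest
  con <- file(file.path(dirname(path), rawfile), "wb"); on.exit(close(con))
  if (element_type == "MET_SHORT") {
    writeBin(as.integer(round(vox)), con, size = 2L, endian = "little")
  } else if (element_type == "MET_FLOAT") {
    writeBin(as.numeric(vox), con, size = 4L, endian = "little")
  } else {
    writeBin(as.numeric(vox), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Map a world-mm coordinate to a voxel index
#'
#' Rounds `(world - origin) / spacing` to the nearest voxel and reorders from
#' the world `(x, y, z)` convention to the array's `(z, y, x)`. The returned
#' index is zero-based (ITK convention); add 1 when subsetting R arrays.
#'
#' @param volume a [ct_volume()].
#' @param world numeric length-3, world `(x, y, z)` in mm.
#' @return integer length-3 zero-based `(z, y, x)` index.
#' @export
world_to_voxel <- function(volume, world) {
  stopifnot(inherits(volume, "ct_volume"), length(world) == 3L)
  sp_xyz <- rev(volume$spacing)                      # spacing stored (z,y,x)
  idx_xyz <- round((as.numeric(world) - volume$origin) / sp_xyz)
  idx <- rev(idx_xyz)                                # -> (z, y, x)
  d <- dim(volume$voxels)
  if (any(idx < 0) || any(idx > d - 1L)) {
    stop(sprintf("voxel index (%s) outside volume of dim (%s)",
                 paste(idx, collapse = ", "), paste(d, collapse = ", ")),
         call. = FALSE)
  }
  as.integer(idx)
}
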