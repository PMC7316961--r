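#' Voxel volume container
#'
#' A 3D scalar grid with spacing and origin. Voxel `(i, j, k)` (1-based)
#' has world-space center `origin + (c(i, j, k) - 1) * spacing`; volumes
#' are axis-aligned (identity direction) by construction.
#'
#' @param array 3D numeric, integer or logical array.
#' @param spacing numeric(3) positive voxel size in mm.
#' @param origin numeric(3) world position of voxel (1,1,1), mm.
#' @return An object of class `voxel_volume` (and `binary_mask` when the
#'   array is logical).
#' @export
voxel_volume <- function(array, spacing, origin = c(0, 0, 0)) {
  if (length(dim(array)) != 3L) stop("array must be 3-dimensional")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values")
  cls <- if (is.logical(array)) c("binary_mask", "voxel_volume") else
    "voxel_volume"
  structure(list(array = array, spacing = spacing, origin = origin),
            class = cls)
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(class(x)[1], ": ", paste(dim(x$array), collapse = " x "),
      " voxels, spacing (", paste(x$spacing, collapse = ", "),
      ") mm\n", sep = "")
  invisible(x)
}

#' Read or write a mask volume
#'
#' Supports NIfTI (`.nii`, `.nii.gz`) via RNifti and MetaImage
#' (`.mha`, `.mhd`) through a built-in reader. Files with a non-identity
#' direction matrix are rejected rather than silently reoriented; missing
#' spacing is an error. Integer volumes round-trip bit-exactly.
#'
#' @param path file path; format chosen by extension.
#' @param vol a [voxel_volume()].
#' @return `read_volume`: a `voxel_volume`; `write_volume`: the path,
#'   invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") read_nifti_volume(path)
  else if (ext %in% c("mha", "mhd")) read_metaimage(path)
  else stop("unknown volume format: ", basename(path))
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") write_nifti_volume(vol, path)
  else if (ext == "mha") write_metaimage(vol, path)
  else stop("unknown volume format: ", basename(path))
  invisible(path)
}

read_nifti_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("format error reading ", path,
                                           ": ", conditionMessage(e)))
  if (length(dim(img)) != 3L) stop("expected a 3D volume: ", path)
  x <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("missing or invalid voxel spacing in ", path)
  dir <- x[1:3, 1:3] %*% diag(1 / spacing)
  # NIfTI stores LPS->RAS style sign flips in the xform; only accept a
  # pure axis-aligned orientation (possibly the RNifti canonical identity)
  if (max(abs(dir - diag(3))) > 1e-4)
    stop("volume has a non-identity direction matrix; reorient it first: ",
         path)
  arr <- array(as.vector(img), dim = dim(img))
  if (all(arr == round(arr))) storage.mode(arr) <- "integer"
  voxel_volume(arr, spacing, as.numeric(x[1:3, 4]))
}

write_nifti_volume <- function(vol, path) {
  arr <- vol$array
  if (is.logical(arr)) {
    arr2 <- array(as.integer(arr), dim = dim(arr))
    arr <- arr2
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(4)
  diag(m)[1:3] <- vol$spacing
  m[1:3, 4] <- vol$origin
  attr(m, "code") <- 2L
  RNifti::qform(img) <- m
  RNifti::writeNifti(img, path)
}

metaimage_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                     MET_SHORT = "integer", MET_USHORT = "integer",
                     MET_INT = "integer", MET_FLOAT = "double",
                     MET_DOUBLE = "double")
metaimage_sizes <- c(MET_UCHAR = 1, MET_CHAR = 1, MET_SHORT = 2,
                     MET_USHORT = 2, MET_INT = 4, MET_FLOAT = 4,
                     MET_DOUBLE = 8)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, 1, warn = FALSE)
    if (length(line) == 0) stop("format error: truncated header in ", path)
    hdr <- c(hdr, line)
    if (grepl("^ElementDataFile", line)) break
  }
  kv <- strsplit(hdr, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = " = "), "")
  get <- function(k) vals[match(k, keys)]
  if (!is.na(get("CompressedData")) && toupper(get("CompressedData")) == "TRUE")
    stop("compressed MetaImage data is not supported: ", path)
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  if (length(dims) != 3L || any(is.na(dims)))
    stop("format error: bad DimSize in ", path)
  if (is.na(get("ElementSpacing")))
    stop("missing voxel spacing (ElementSpacing) in ", path)
  spacing <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
  off <- get("Offset")
  origin <- if (is.na(off)) c(0, 0, 0) else
    as.numeric(strsplit(off, "\\s+")[[1]])
  tm <- get("TransformMatrix")
  if (!is.na(tm)) {
    m <- matrix(as.numeric(strsplit(tm, "\\s+")[[1]]), 3, byrow = TRUE)
    if (max(abs(m - diag(3))) > 1e-9)
      stop("volume has a non-identity direction matrix: ", path)
  }
  etype <- get("ElementType")
  if (is.na(etype) || !(etype %in% names(metaimage_types)))
    stop("unsupported ElementType in ", path)
  n <- prod(dims)
  datafile <- get("ElementDataFile")
  if (datafile == "LOCAL") {
    raw <- readBin(con, metaimage_types[[etype]], n,
                   size = metaimage_sizes[[etype]], endian = "little",
                   signed = !(etype %in% c("MET_USHORT")))
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath)) stop("raw data file not found: ", rawpath)
    raw <- readBin(rawpath, metaimage_types[[etype]], n,
                   size = metaimage_sizes[[etype]], endian = "little",
                   signed = !(etype %in% c("MET_USHORT")))
  }
  if (length(raw) != n) stop("format error: truncated data in ", path)
  voxel_volume(array(raw, dim = dims), spacing, origin)
}

write_metaimage <- function(vol, path) {
  arr <- vol$array
  if (is.logical(arr)) storage.mode(arr) <- "integer"
  etype <- if (is.integer(arr)) "MET_INT" else "MET_DOUBLE"
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(vol$origin, collapse = " ")),
           paste("ElementSpacing =", paste(vol$spacing, collapse = " ")),
           paste("DimSize =", paste(dim(arr), collapse = " ")),
           paste("ElementType =", etype),
           "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  writeBin(as.vector(arr), con, size = metaimage_sizes[[etype]],
           endian = "little")
}

#' Threshold a CT volume into a skeleton mask
#'
#' A voxel is bone iff its intensity is at or above `threshold`. The
#' resulting union of all bone voxels ("skeleton") keeps no per-bone
#' separation.
#'
#' @param vol a [voxel_volume()].
#' @param threshold finite scalar intensity.
#' @return A `binary_mask`.
#' @export
threshold_skeleton <- function(vol, threshold) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (!is.finite(threshold)) stop("threshold must be finite")
  m <- vol$array >= threshold
  if (!any(m)) stop("no bone voxels at threshold ", threshold)
  voxel_volume(m, vol$spacing, vol$origin)
}

#' Convert a binary mask to a point cloud of voxel centers
#'
#' @param mask a `binary_mask`.
#' @param surface_only keep only true voxels with at least one false
#'   6-neighbour (grid boundary counts as false).
#' @param label optional cloud label.
#' @return A [point_cloud()] in world millimetres.
#' @export
mask_to_points <- function(mask, surface_only = TRUE, label = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  arr <- mask$array
  if (!any(arr)) stop("mask is empty")
  if (surface_only)
    arr <- array(cpp_surface_voxels(as.logical(arr), dim(mask$array)),
                 dim = dim(mask$array))
  idx <- which(arr, arr.ind = TRUE)
  pts <- sweep(sweep(idx - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
  point_cloud(pts, label = label)
}

#' Extract the boundary isosurface of a binary mask
#'
#' Marching-tetrahedra isosurface at level 0.5 in world coordinates.
#' Masks touching the array border are padded by one voxel first, so the
#' result is always closed for solid masks.
#'
#' @param mask a `binary_mask`.
#' @return A closed [surface_mesh()].
#' @export
mask_to_mesh <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  arr <- mask$array
  if (!any(arr)) stop("mask is empty")
  d <- dim(arr)
  padded <- array(0, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.numeric(arr)
  res <- cpp_marching_tets(as.numeric(padded), dim(padded),
                           mask$origin - mask$spacing, mask$spacing, 0.5)
  surface_mesh(res$vertices, res$faces)
}
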