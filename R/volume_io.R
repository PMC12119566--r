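# Volumes, label maps, standard-format I/O (NIfTI via RNifti; a minimal
# raw/gzip NRRD reader-writer since no R NRRD package is available), and
# sliding-window patch extraction / mean recomposition.

#' Construct a volume
#'
#' @param data Numeric 3D array, axis order (x, y, z); all values finite.
#' @param spacing Three positive voxel spacings.
#' @param origin Three coordinates of the first voxel.
#' @return A `tpssan_volume`.
#' @export
new_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive lengths")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), axis_order = "xyz"),
            class = "tpssan_volume")
}

#' Construct a label map
#'
#' @param data Integer 3D array with values in `0..num_classes-1`
#'   (0 = background).
#' @param num_classes Number of classes (>= 2).
#' @return A `tpssan_labelmap`.
#' @export
new_labelmap <- function(data, num_classes = 2L) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("label data must be a 3D array")
  num_classes <- as.integer(num_classes)
  if (num_classes < 2L) stop("num_classes must be >= 2")
  storage.mode(data) <- "integer"
  if (any(data < 0L | data >= num_classes))
    stop("label values must lie in {0, ..., num_classes-1}")
  structure(list(data = data, num_classes = num_classes),
            class = "tpssan_labelmap")
}

vol_data <- function(x) {
  if (inherits(x, c("tpssan_volume", "tpssan_labelmap"))) x$data else x
}

#' Read a volume from NIfTI or NRRD
#'
#' The fastest-varying axis on disk becomes the x axis, matching the
#' package-wide (x, y, z) convention.
#'
#' @param path File with extension `.nii`, `.nii.gz` or `.nrrd`.
#' @return A `tpssan_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- vol_format(path)
  if (ext == "nifti") {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)
    data <- array(as.numeric(img), dim = dim(img))
    if (length(dim(data)) != 3L) stop("expected a 3D NIfTI image: ", path)
    new_volume(data, spacing = sp[1:3])
  } else if (ext == "nrrd") {
    read_nrrd(path)
  } else {
    stop("unrecognized volume format (expected .nii, .nii.gz or .nrrd): ",
         path)
  }
}

#' @rdname read_volume
#' @param num_classes Number of classes of the stored label map.
#' @export
read_labelmap <- function(path, num_classes = 2L) {
  v <- read_volume(path)
  new_labelmap(array(as.integer(round(v$data)), dim = dim(v$data)),
               num_classes = num_classes)
}

#' Write a volume (or label map) to NIfTI or NRRD
#'
#' @param v A `tpssan_volume`, `tpssan_labelmap`, or bare 3D array.
#' @param path Destination; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  data <- vol_data(v)
  spacing <- if (inherits(v, "tpssan_volume")) v$spacing else c(1, 1, 1)
  ext <- vol_format(path)
  if (ext == "nifti") {
    img <- RNifti::asNifti(data)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path)
  } else if (ext == "nrrd") {
    origin <- if (inherits(v, "tpssan_volume")) v$origin else c(0, 0, 0)
    write_nrrd(data, path, spacing = spacing, origin = origin)
  } else {
    stop("unrecognized volume format (expected .nii, .nii.gz or .nrrd): ",
         path)
  }
  invisible(path)
}

vol_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) "nifti"
  else if (grepl("\\.nrrd$", lp)) "nrrd"
  else "unknown"
}

# ---- minimal NRRD (attached header, raw or gzip encoding) -------------------

nrrd_types <- c("double" = "double", "float" = "double",
                "int" = "integer", "signed int" = "integer",
                "unsigned int" = "integer",
                "short" = "integer", "signed short" = "integer",
                "unsigned short" = "integer",
                "uchar" = "integer", "unsigned char" = "integer",
                "signed char" = "integer", "uint8" = "integer",
                "int8" = "integer", "int16" = "integer", "uint16" = "integer",
                "int32" = "integer", "float32" = "double", "float64" = "double")

nrrd_sizes <- c("double" = 8L, "float" = 4L, "int" = 4L, "signed int" = 4L,
                "unsigned int" = 4L, "short" = 2L, "signed short" = 2L,
                "unsigned short" = 2L, "uchar" = 1L, "unsigned char" = 1L,
                "signed char" = 1L, "uint8" = 1L, "int8" = 1L, "int16" = 2L,
                "uint16" = 2L, "int32" = 4L, "float32" = 4L, "float64" = 8L)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000", magic)) stop("corrupt NRRD header (bad magic): ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("corrupt NRRD header (no blank line): ", path)
    if (nzchar(line) == FALSE) break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    if (length(kv) < 2L) next
    fields[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = ":"))
  }
  type <- fields[["type"]]
  if (is.null(type) || !(type %in% names(nrrd_types)))
    stop("unsupported NRRD type: ", type)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD volumes are supported: ", path)
  enc <- tolower(fields[["encoding"]] %||% "raw")
  nbytes <- prod(sizes) * nrrd_sizes[[type]]
  payload <- readBin(con, what = "raw", n = file.size(path))
  if (enc %in% c("gzip", "gz")) payload <- memDecompress(payload, type = "gzip")
  else if (enc != "raw") stop("unsupported NRRD encoding: ", enc)
  if (length(payload) < nbytes) stop("truncated NRRD payload: ", path)
  signed <- !grepl("^u", type) && !grepl("unsigned", type)
  vals <- readBin(payload, what = nrrd_types[[type]],
                  n = prod(sizes), size = nrrd_sizes[[type]],
                  signed = if (nrrd_sizes[[type]] <= 2L) signed else TRUE,
                  endian = fields[["endian"]] %||% "little")
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["spacings"]]))
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  if (!is.null(fields[["space directions"]])) {
    dirs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- t(vapply(dirs, function(s)
      as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]]), numeric(3)))
    spacing <- sqrt(rowSums(m^2))
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])
  new_volume(array(as.numeric(vals), dim = sizes), spacing = spacing,
             origin = origin)
}

write_nrrd <- function(data, path, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  header <- c("NRRD0004",
              "# generated by tpssan",
              "type: double",
              "dimension: 3",
              "space dimension: 3",
              paste("sizes:", paste(dim(data), collapse = " ")),
              paste0("space directions: ",
                     sprintf("(%g,0,0) (0,%g,0) (0,0,%g)",
                             spacing[1], spacing[2], spacing[3])),
              paste0("space origin: ", sprintf("(%g,%g,%g)",
                                               origin[1], origin[2], origin[3])),
              "endian: little",
              "encoding: raw",
              "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  writeBin(as.numeric(data), con, size = 8L, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- sliding-window patches -------------------------------------------------

#' Sliding-window patch grid
#'
#' Offsets are 1-based corner coordinates covering every voxel; the last
#' offset per axis is shifted inward so `patch_shape` is always honored
#' (no padding). Offsets are sorted lexicographically by (x, y, z).
#'
#' @param vol_shape Three integers, the source volume shape.
#' @param patch_shape Three positive integers, `<= vol_shape` per axis.
#' @param stride Three positive integers (scalar recycled).
#' @return A `tpssan_patchgrid`: `patch_shape`, `stride`, `offsets`
#'   (n x 3 integer matrix).
#' @export
patch_grid <- function(vol_shape, patch_shape, stride = pmax(1L, patch_shape %/% 2L)) {
  vol_shape <- as.integer(vol_shape)
  patch_shape <- as.integer(patch_shape)
  stride <- as.integer(rep(stride, length.out = 3L))
  if (any(stride < 1L)) stop("stride must be positive")
  if (any(patch_shape < 1L)) stop("patch_shape must be positive")
  if (any(patch_shape > vol_shape))
    stop("patch larger than volume: patch (",
         paste(patch_shape, collapse = "x"), ") vs volume (",
         paste(vol_shape, collapse = "x"), ")")
  axis_offsets <- function(n, p, s) {
    o <- seq.int(1L, n - p + 1L, by = s)
    last <- n - p + 1L
    if (o[length(o)] != last) o <- c(o, last)
    o
  }
  ox <- axis_offsets(vol_shape[1], patch_shape[1], stride[1])
  oy <- axis_offsets(vol_shape[2], patch_shape[2], stride[2])
  oz <- axis_offsets(vol_shape[3], patch_shape[3], stride[3])
  g <- expand.grid(z = oz, y = oy, x = ox)[, c("x", "y", "z")]
  structure(list(patch_shape = patch_shape, stride = stride,
                 offsets = as.matrix(g)),
            class = "tpssan_patchgrid")
}

#' Extract the patches of a grid
#'
#' @param v A `tpssan_volume`, `tpssan_labelmap` or 3D array.
#' @param grid A [patch_grid()].
#' @return List of 3D arrays, one per grid offset.
#' @export
extract_patches <- function(v, grid) {
  data <- vol_data(v)
  p <- grid$patch_shape
  lapply(seq_len(nrow(grid$offsets)), function(i) {
    o <- grid$offsets[i, ]
    data[o[1]:(o[1] + p[1] - 1L), o[2]:(o[2] + p[2] - 1L),
         o[3]:(o[3] + p[3] - 1L), drop = FALSE]
  })
}

#' Recompose patch-wise predictions by averaging overlaps
#'
#' @param patches List of arrays aligned with `grid$offsets`; 3D, or 4D with
#'   a trailing class-probability axis.
#' @param grid The [patch_grid()] used for extraction.
#' @param out_shape Three integers, the recomposed spatial shape.
#' @return Array of shape `out_shape` (plus the class axis if patches are
#'   4D); overlapping voxels hold the mean of all contributing patches.
#' @export
recompose <- function(patches, grid, out_shape) {
  out_shape <- as.integer(out_shape)
  if (length(patches) != nrow(grid$offsets))
    stop("got ", length(patches), " patches for ", nrow(grid$offsets),
         " grid offsets")
  p <- grid$patch_shape
  nch <- if (length(dim(patches[[1]])) == 4L) dim(patches[[1]])[4] else 0L
  full <- if (nch > 0L) c(out_shape, nch) else out_shape
  acc <- array(0, dim = full)
  cnt <- array(0, dim = out_shape)
  for (i in seq_along(patches)) {
    pa <- patches[[i]]
    pd <- dim(pa)
    if (!all(pd[1:3] == p))
      stop("patch ", i, " has shape ", paste(pd[1:3], collapse = "x"),
           ", expected ", paste(p, collapse = "x"))
    o <- grid$offsets[i, ]
    xr <- o[1]:(o[1] + p[1] - 1L)
    yr <- o[2]:(o[2] + p[2] - 1L)
    zr <- o[3]:(o[3] + p[3] - 1L)
    if (nch > 0L) acc[xr, yr, zr, ] <- acc[xr, yr, zr, , drop = FALSE] + pa
    else acc[xr, yr, zr] <- acc[xr, yr, zr] + pa
    cnt[xr, yr, zr] <- cnt[xr, yr, zr] + 1
  }
  if (any(cnt == 0)) stop("patch grid does not cover the requested out_shape")
  if (nch > 0L) acc / array(rep(cnt, nch), dim = full) else acc / cnt
}
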