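#' Read a 3D volume from MetaImage or NIfTI
#'
#' Supports uncompressed MetaImage (`.mha`, local raw data) and NIfTI-1
#' (`.nii`, `.nii.gz`). Spacing and origin are taken from the header; voxel
#' values are returned unmodified (NIfTI `scl_slope`/`scl_inter` are applied
#' when set). DICOM is out of scope.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"metaimage"` or `"nifti"`.
#' @param unit_tag,kernel_tag tags attached to the returned volume; the two
#'   container formats carry no unit metadata.
#' @return a [volume3d()].
#' @export
read_volume <- function(path, format = c("auto", "metaimage", "nifti"),
                        unit_tag = "attenuation", kernel_tag = "native") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  g <- switch(format,
              metaimage = read_mha(path),
              nifti = read_nifti(path))
  if (any(g$dim < 1L)) stop("corrupt header: zero-sized dimension", call. = FALSE)
  volume3d(array(g$data, dim = g$dim), spacing = g$spacing, origin = g$origin,
           unit_tag = unit_tag, kernel_tag = kernel_tag)
}

#' Write a 3D volume to MetaImage or NIfTI
#'
#' @param v a [volume3d()] or [mask3d()]; masks are stored as 8-bit volumes.
#' @param path output path (`.mha`, `.nii` or `.nii.gz`).
#' @param format see [read_volume()].
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, format = c("auto", "metaimage", "nifti")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  is_mask <- is_mask3d(v)
  if (!is_mask && !is_volume3d(v)) stop("`v` must be a volume3d or mask3d", call. = FALSE)
  switch(format,
         metaimage = write_mha(v, path, eight_bit = is_mask),
         nifti = write_nifti(v, path, eight_bit = is_mask))
  invisible(path)
}

#' Read a mask from file
#' @inheritParams read_volume
#' @return a [mask3d()].
#' @export
read_mask <- function(path, format = c("auto", "metaimage", "nifti")) {
  v <- read_volume(path, match.arg(format))
  mask3d(v$values, spacing = v$spacing, origin = v$origin)
}

guess_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.mha$", low)) return("metaimage")
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  stop("cannot guess format from extension: ", path, call. = FALSE)
}

# ---- MetaImage (.mha, ElementDataFile = LOCAL) ------------------------------

met_types <- list(MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE),
                  MET_SHORT = list(what = "integer", size = 2L, signed = TRUE),
                  MET_INT = list(what = "integer", size = 4L, signed = TRUE),
                  MET_FLOAT = list(what = "double", size = 4L, signed = TRUE),
                  MET_DOUBLE = list(what = "double", size = 8L, signed = TRUE))

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("corrupt MetaImage header: no data section",
                                 call. = FALSE)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("corrupt MetaImage header line: ", line, call. = FALSE)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  need <- c("NDims", "DimSize", "ElementType", "ElementDataFile")
  if (!all(need %in% names(hdr)))
    stop("missing MetaImage header fields: ",
         paste(setdiff(need, names(hdr)), collapse = ", "), call. = FALSE)
  if (as.integer(hdr$NDims) != 3L) stop("only 3D MetaImage supported", call. = FALSE)
  if (toupper(hdr$ElementDataFile) != "LOCAL")
    stop("only ElementDataFile = LOCAL supported", call. = FALSE)
  dim <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  ty <- met_types[[hdr$ElementType]]
  if (is.null(ty)) stop("unsupported ElementType: ", hdr$ElementType, call. = FALSE)
  msb <- identical(tolower(hdr$ElementByteOrderMSB %||% "false"), "true")
  n <- prod(dim)
  data <- readBin(con, what = ty$what, n = n, size = ty$size, signed = ty$signed,
                  endian = if (msb) "big" else "little")
  if (length(data) != n) stop("corrupt MetaImage: truncated data", call. = FALSE)
  list(data = as.double(data), dim = dim, spacing = spacing, origin = origin)
}

write_mha <- function(v, path, eight_bit = FALSE) {
  d <- dim(v$values)
  type <- if (eight_bit) "MET_UCHAR" else "MET_DOUBLE"
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementSpacing =", paste(format(v$spacing, digits = 17), collapse = " ")),
           paste("Offset =", paste(format(v$origin, digits = 17), collapse = " ")),
           paste("ElementType =", type),
           "ElementDataFile = LOCAL")
  writeLines(hdr, con, sep = "\n")
  if (eight_bit) {
    writeBin(as.integer(v$values != 0), con, size = 1L, endian = "little")
  } else {
    writeBin(as.double(v$values), con, size = 8L, endian = "little")
  }
}

# ---- NIfTI-1 (.nii, .nii.gz) ------------------------------------------------

nifti_dtypes <- list(`2` = list(what = "integer", size = 1L, signed = FALSE),
                     `4` = list(what = "integer", size = 2L, signed = TRUE),
                     `8` = list(what = "integer", size = 4L, signed = TRUE),
                     `16` = list(what = "double", size = 4L, signed = TRUE),
                     `64` = list(what = "double", size = 8L, signed = TRUE))

read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  endian <- "little"
  if (sizeof_hdr != 348L) {
    if (bitwShiftL(sizeof_hdr, 24) == bitwShiftL(348L, 24) ||
        sizeof_hdr == 1543569408L) {
      endian <- "big"
    } else stop("not a NIfTI-1 file (sizeof_hdr != 348)", call. = FALSE)
  }
  readBin(con, "raw", 36L)                     # unused fields
  dim0 <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "raw", 14L)                     # intent_p*, intent_code
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 1L, size = 2L, endian = endian)  # bitpix
  readBin(con, "integer", 1L, size = 2L, endian = endian)  # slice_start
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", 1L, size = 4L, endian = endian)
  readBin(con, "raw", 132L)  # slice_end .. glmin, descrip, aux_file (bytes 120-251)
  qform_code <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  sform_code <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  quat <- readBin(con, "double", 6L, size = 4L, endian = endian)
  srow <- readBin(con, "double", 12L, size = 4L, endian = endian)
  readBin(con, "raw", 16L)                     # intent_name
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!grepl("^n\\+1", magic)) stop("not a single-file NIfTI-1 (magic != n+1)",
                                    call. = FALSE)
  ndim <- dim0[1]
  if (ndim < 3L) stop("NIfTI volume must be 3D", call. = FALSE)
  d <- dim0[2:4]
  if (ndim > 3L && any(dim0[5:(ndim + 1)] > 1L))
    stop("only single-frame 3D NIfTI supported", call. = FALSE)
  ty <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(ty)) stop("unsupported NIfTI datatype: ", datatype, call. = FALSE)
  spacing <- pixdim[2:4]
  if (sform_code > 0L) {
    m <- matrix(srow, nrow = 3L, byrow = TRUE)
    offd <- abs(m[, 1:3]) - diag(abs(diag(m[, 1:3])))
    if (max(abs(offd)) > 1e-4 * max(abs(m[, 1:3])))
      stop("rotated NIfTI sform not supported", call. = FALSE)
    origin <- m[, 4]
    spacing <- abs(diag(m[, 1:3]))
  } else if (qform_code > 0L) {
    origin <- quat[4:6]
  } else {
    origin <- c(0, 0, 0)
  }
  skip <- round(vox_offset) - 348L
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(as.double(d))
  data <- readBin(con, what = ty$what, n = n, size = ty$size, signed = ty$signed,
                  endian = endian)
  if (length(data) != n) stop("corrupt NIfTI: truncated data", call. = FALSE)
  data <- as.double(data)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  list(data = data, dim = as.integer(d), spacing = spacing, origin = origin)
}

write_nifti <- function(v, path, eight_bit = FALSE) {
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  d <- dim(v$values)
  datatype <- if (eight_bit) 2L else 64L
  bitpix <- if (eight_bit) 8L else 64L
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wr <- function(n) writeBin(raw(n), con)
  wi(348L, 4L); wr(36L)
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2L)            # dim[8]
  wr(14L)                                     # intent_p1..3, intent_code
  wi(datatype, 2L); wi(bitpix, 2L); wi(0L, 2L)
  wf(c(1, v$spacing, 0, 0, 0, 0))             # pixdim[8]
  wf(352)                                     # vox_offset
  wf(1); wf(0)                                # scl_slope, scl_inter
  wr(2L + 1L + 1L); wf(c(0, 0)); wf(0); wf(0) # slice_end..toffset
  wi(c(0L, 0L), 4L)                           # glmax, glmin
  wr(80L + 24L)                               # descrip, aux_file
  wi(0L, 2L); wi(1L, 2L)                      # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))                     # quaternion
  wf(c(v$spacing[1], 0, 0, v$origin[1],
       0, v$spacing[2], 0, v$origin[2],
       0, 0, v$spacing[3], v$origin[3]))      # srow
  wr(16L)
  writeBin(c(charToRaw("n+1"), raw(1)), con)
  wr(4L)                                      # pad to vox_offset 352
  if (eight_bit) {
    writeBin(as.integer(v$values != 0), con, size = 1L, endian = "little")
  } else {
    writeBin(as.double(v$values), con, size = 8L, endian = "little")
  }
}

# ---- VOI sets: directory of mask files + JSON manifest ----------------------

#' Write a VOI set as mask files plus a JSON manifest
#'
#' Each VOI is stored as an 8-bit MetaImage volume; `manifest.json` maps VOI
#' names to files and to their bone/layer/side decomposition.
#'
#' @param vois a [voi_set()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_voi_set <- function(vois, dir) {
  stopifnot(inherits(vois, "voi_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(names(vois), function(nm) {
    fn <- paste0(gsub(".", "_", nm, fixed = TRUE), ".mha")
    write_volume(vois[[nm]], file.path(dir, fn))
    p <- parse_voi_name(nm)
    list(name = nm, file = fn, bone = p$bone, layer = p$layer, side = p$side)
  })
  jsonlite::write_json(entries, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a VOI set written by [write_voi_set()]
#' @param dir directory containing `manifest.json` and mask files.
#' @return a [voi_set()].
#' @export
read_voi_set <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir, call. = FALSE)
  entries <- jsonlite::read_json(mf)
  masks <- lapply(entries, function(e) read_mask(file.path(dir, e$file)))
  names(masks) <- vapply(entries, function(e) e$name, character(1))
  voi_set(masks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
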