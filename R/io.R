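#' Read a binary segmentation mask from a NIfTI-1 file
#'
#' Minimal single-file NIfTI-1 reader (`.nii`, or `.nii.gz` via a gzip
#' connection) sufficient for segmentation masks: handles data types uint8,
#' int16, int32, float32 and float64, both endiannesses, and takes the voxel
#' spacing from `pixdim[1:3]` and the origin from `qoffset_{x,y,z}`. Values
#' above `threshold` become foreground. 4D volumes use the first volume.
#'
#' @param path file path (.nii or .nii.gz).
#' @param threshold foreground threshold applied to the stored values.
#' @return A [voxel_mask()].
#' @export
read_nifti_mask <- function(path, threshold = 0.5) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("not a NIfTI-1 file: header too short")
  rd <- function(what, n, size, off, endian) {
    readBin(hdr[(off + 1):length(hdr)], what, n = n, size = size, endian = endian)
  }
  endian <- "little"
  if (rd("integer", 1, 4, 0, "little") != 348L) {
    if (rd("integer", 1, 4, 0, "big") == 348L) endian <- "big"
    else stop("not a NIfTI-1 file: bad sizeof_hdr")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic: ", magic)
  if (magic == "ni1") stop("two-file (.hdr/.img) NIfTI is not supported")
  dims <- rd("integer", 8, 2, 40, endian)
  if (dims[1] < 3) stop("need a 3D volume")
  d <- dims[2:4]
  nvol <- if (dims[1] >= 4 && dims[5] > 1) dims[5] else 1L
  datatype <- rd("integer", 1, 2, 70, endian)
  pixdim <- rd("numeric", 8, 4, 76, endian)
  vox_offset <- rd("numeric", 1, 4, 108, endian)
  scl_slope <- rd("numeric", 1, 4, 112, endian)
  scl_inter <- rd("numeric", 1, 4, 116, endian)
  qoffset <- rd("numeric", 3, 4, 268, endian)
  n <- prod(d)
  # skip to the data
  skip <- as.integer(vox_offset) - 348L
  if (skip > 0) readBin(con, "raw", skip)
  vals <- switch(as.character(datatype),
    "2"  = as.double(readBin(con, "integer", n, size = 1, signed = FALSE, endian = endian)),
    "4"  = as.double(readBin(con, "integer", n, size = 2, endian = endian)),
    "8"  = as.double(readBin(con, "integer", n, size = 4, endian = endian)),
    "16" = readBin(con, "numeric", n, size = 4, endian = endian),
    "64" = readBin(con, "numeric", n, size = 8, endian = endian),
    stop("unsupported NIfTI datatype code: ", datatype))
  if (nvol > 1L) message("4D NIfTI: using first volume")
  if (is.finite(scl_slope) && scl_slope != 0) vals <- vals * scl_slope + scl_inter
  voxel_mask(array(vals > threshold, d),
             spacing = abs(pixdim[2:4]),
             origin = as.numeric(qoffset))
}

#' Write a binary mask as a NIfTI-1 file (uint8)
#'
#' @param mask a [voxel_mask()].
#' @param path output path; `.gz` suffix selects gzip compression.
#' @export
write_nifti_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  d <- dim(mask$values)
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # unused through dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)               # dim[8]
  writeBin(raw(14), con)                        # intent_p*, intent_code
  wi(2L, 2)                                     # datatype uint8
  wi(8L, 2)                                     # bitpix
  wi(0L, 2)                                     # slice_start
  wf(c(0, mask$spacing, 1, 1, 1, 1))            # pixdim[8]
  wf(352)                                       # vox_offset
  wf(1); wf(0)                                  # scl_slope, scl_inter
  writeBin(raw(3), con)                         # slice_end, slice_code
  writeBin(as.raw(10L), con)                    # xyzt_units: mm
  wf(0); wf(0); wf(0)                           # cal_max/min, slice_duration
  wf(0)                                         # toffset
  wi(c(0L, 0L), 4)                              # glmax/glmin
  writeBin(raw(104), con)                       # descrip + aux_file
  wi(c(0L, 1L), 2)                              # qform_code 0, sform_code 1
  wf(rep(0, 3))                                 # quatern b,c,d
  wf(mask$origin)                               # qoffset x,y,z
  wf(c(mask$spacing[1], 0, 0, mask$origin[1]))  # srow_x
  wf(c(0, mask$spacing[2], 0, mask$origin[2]))  # srow_y
  wf(c(0, 0, mask$spacing[3], mask$origin[3]))  # srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  writeBin(raw(4), con)                         # extension flag
  writeBin(as.raw(as.integer(mask$values)), con)
  invisible(path)
}

#' Write a mesh as binary little-endian PLY
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0("ply\nformat binary_little_endian 1.0\n",
                "element vertex ", nrow(mesh$vertices), "\n",
                "property float x\nproperty float y\nproperty float z\n",
                "element face ", nrow(mesh$faces), "\n",
                "property list uchar int vertex_indices\nend_header\n")
  writeBin(charToRaw(hdr), con)
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4, endian = "little")
  f0 <- t(mesh$faces) - 1L
  for (i in seq_len(ncol(f0))) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(f0[, i]), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Write a mesh as binary STL
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  v <- mesh$vertices
  for (i in seq_len(nf)) {
    tri <- v[mesh$faces[i, ], , drop = FALSE]
    nrm <- c((tri[2, 2] - tri[1, 2]) * (tri[3, 3] - tri[1, 3]) - (tri[2, 3] - tri[1, 3]) * (tri[3, 2] - tri[1, 2]),
             (tri[2, 3] - tri[1, 3]) * (tri[3, 1] - tri[1, 1]) - (tri[2, 1] - tri[1, 1]) * (tri[3, 3] - tri[1, 3]),
             (tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) - (tri[2, 2] - tri[1, 2]) * (tri[3, 1] - tri[1, 1]))
    nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
    writeBin(as.numeric(c(nrm, t(tri))), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  invisible(path)
}
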