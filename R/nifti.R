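# Minimal NIfTI-1 reader/writer (single-file .nii / .nii.gz).
#
# Implemented in base R because no NIfTI package ships with the target
# environment.  Covers the header fields this package produces/consumes:
# dim, datatype, pixdim, vox_offset, scl_slope/inter, qform/sform.  The
# world frame is RAS millimetres; voxel indices are 0-based in the affine
# convention (world = affine %*% c(i, j, k, 1)).

NIFTI_DT <- list(
  uint8   = list(code = 2L,   bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,   bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,   bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L,  bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L,  bitpix = 64L, what = "double",  size = 8L, signed = TRUE),
  int8    = list(code = 256L, bitpix = 8L,  what = "integer", size = 1L, signed = TRUE),
  uint16  = list(code = 512L, bitpix = 16L, what = "integer", size = 2L, signed = FALSE)
)

nifti_open <- function(path, mode) {
  # gzfile() transparently reads both gzip and plain streams.
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

read_nifti_header <- function(con, endian = "little") {
  raw_hdr <- readBin(con, "raw", n = 348L)
  if (length(raw_hdr) < 348L)
    stop_ezloc("file too short to contain a NIfTI-1 header", "ezloc_format_error")
  rd <- function(what, n, size, offset, signed = TRUE) {
    readBin(raw_hdr[(offset + 1L):length(raw_hdr)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  sizeof_hdr <- rd("integer", 1L, 4L, 0L)
  if (sizeof_hdr != 348L) {
    if (endian == "little") {
      # retry as big-endian
      swapped <- readBin(raw_hdr, "integer", 1L, 4L, endian = "big")
      if (swapped == 348L) {
        hdr <- local({
          rd2 <- function(what, n, size, offset, signed = TRUE)
            readBin(raw_hdr[(offset + 1L):length(raw_hdr)], what, n = n,
                    size = size, endian = "big", signed = signed)
          parse_nifti_fields(rd2)
        })
        hdr$endian <- "big"
        return(hdr)
      }
    }
    stop_ezloc(sprintf("not a NIfTI-1 file (sizeof_hdr = %d)", sizeof_hdr),
               "ezloc_format_error")
  }
  hdr <- parse_nifti_fields(rd)
  hdr$endian <- endian
  hdr
}

parse_nifti_fields <- function(rd) {
  dim      <- rd("integer", 8L, 2L, 40L)
  datatype <- rd("integer", 1L, 2L, 70L)
  bitpix   <- rd("integer", 1L, 2L, 72L)
  pixdim   <- rd("double",  8L, 4L, 76L)
  vox_offset <- rd("double", 1L, 4L, 108L)
  scl_slope  <- rd("double", 1L, 4L, 112L)
  scl_inter  <- rd("double", 1L, 4L, 116L)
  qform_code <- rd("integer", 1L, 2L, 252L)
  sform_code <- rd("integer", 1L, 2L, 254L)
  quatern    <- rd("double", 3L, 4L, 256L)
  qoffset    <- rd("double", 3L, 4L, 268L)
  srow_x <- rd("double", 4L, 4L, 280L)
  srow_y <- rd("double", 4L, 4L, 296L)
  srow_z <- rd("double", 4L, 4L, 312L)
  magic  <- rawToChar(rd("raw", 4L, 1L, 344L))
  list(dim = dim, datatype = datatype, bitpix = bitpix, pixdim = pixdim,
       vox_offset = vox_offset, scl_slope = scl_slope, scl_inter = scl_inter,
       qform_code = qform_code, sform_code = sform_code,
       quatern = quatern, qoffset = qoffset,
       srow = rbind(srow_x, srow_y, srow_z), magic = magic)
}

nifti_affine_from_header <- function(hdr) {
  if (hdr$sform_code > 0L) {
    aff <- rbind(hdr$srow, c(0, 0, 0, 1))
  } else if (hdr$qform_code > 0L) {
    b <- hdr$quatern[1]; c_ <- hdr$quatern[2]; d <- hdr$quatern[3]
    a2 <- 1 - b^2 - c_^2 - d^2
    a <- if (a2 < 0) 0 else sqrt(a2)
    R <- rbind(
      c(a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d),    2 * (b * d + a * c_)),
      c(2 * (b * c_ + a * d),   a^2 + c_^2 - b^2 - d^2,  2 * (c_ * d - a * b)),
      c(2 * (b * d - a * c_),   2 * (c_ * d + a * b),    a^2 + d^2 - b^2 - c_^2)
    )
    qfac <- if (hdr$pixdim[1] < 0) -1 else 1
    sp <- hdr$pixdim[2:4]
    R <- R %*% diag(c(sp[1], sp[2], qfac * sp[3]))
    aff <- rbind(cbind(R, hdr$qoffset), c(0, 0, 0, 1))
  } else {
    aff <- diag(4)
    diag(aff)[1:3] <- ifelse(hdr$pixdim[2:4] > 0, hdr$pixdim[2:4], 1)
  }
  dimnames(aff) <- NULL
  aff
}

read_nifti <- function(path) {
  con <- nifti_open(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- read_nifti_header(con)
  if (!hdr$magic %in% c("n+1", "nc1")) {
    if (hdr$magic == "ni1")
      stop_ezloc("detached .hdr/.img NIfTI pairs are not supported; use single-file .nii",
                 "ezloc_format_error")
  }
  nd <- hdr$dim[1]
  shape <- hdr$dim[2:(1 + max(nd, 1L))]
  if (nd > 3L && any(hdr$dim[(4 + 1):(nd + 1)] > 1L))
    stop_ezloc(sprintf("expected a 3-D volume but file has %d-D shape [%s]",
                       nd, paste(shape, collapse = " x ")),
               "ezloc_dimensionality_error")
  shape3 <- hdr$dim[2:4]
  shape3[shape3 < 1L] <- 1L
  dt <- NULL
  for (nm in names(NIFTI_DT))
    if (NIFTI_DT[[nm]]$code == hdr$datatype) dt <- NIFTI_DT[[nm]]
  if (is.null(dt))
    stop_ezloc(sprintf("unsupported NIfTI datatype code %d", hdr$datatype),
               "ezloc_format_error")
  # skip from end of header to vox_offset
  skip <- max(0, round(hdr$vox_offset) - 348L)
  if (skip > 0) readBin(con, "raw", n = skip)
  nvox <- prod(shape3)
  if (dt$size == 1L && !dt$signed) {
    vals <- as.integer(readBin(con, "raw", n = nvox))
  } else if (identical(dt$what, "integer") && !dt$signed) {
    vals <- readBin(con, "integer", n = nvox, size = dt$size,
                    endian = hdr$endian, signed = FALSE)
  } else {
    vals <- readBin(con, dt$what, n = nvox, size = dt$size, endian = hdr$endian)
  }
  if (length(vals) < nvox)
    stop_ezloc("truncated NIfTI data section", "ezloc_format_error")
  if (is.finite(hdr$scl_slope) && hdr$scl_slope != 0 &&
      !(hdr$scl_slope == 1 && hdr$scl_inter == 0))
    vals <- vals * hdr$scl_slope + hdr$scl_inter
  data <- array(vals, dim = shape3)
  list(data = data, affine = nifti_affine_from_header(hdr))
}

write_nifti <- function(data, affine, path, datatype = "float32") {
  dt <- NIFTI_DT[[datatype]]
  if (is.null(dt))
    stop_ezloc(sprintf("unsupported write datatype '%s'", datatype),
               "ezloc_parameter_error")
  stopifnot(length(dim(data)) == 3L)
  con <- nifti_open(path, "wb")
  on.exit(close(con), add = TRUE)
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  pad <- function(n) writeBin(raw(n), con)

  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  wb(348L, 4L)                               # sizeof_hdr
  pad(10L + 18L + 4L + 2L + 1L)              # data_type..regular
  pad(1L)                                    # dim_info
  wb(as.integer(c(3L, dim(data), 1L, 1L, 1L, 1L)), 2L)  # dim[8]
  wb(c(0, 0, 0), 4L)                         # intent_p1..p3
  wb(0L, 2L)                                 # intent_code
  wb(dt$code, 2L)                            # datatype
  wb(dt$bitpix, 2L)                          # bitpix
  wb(0L, 2L)                                 # slice_start
  wb(c(1, sp, 1, 1, 1, 1), 4L)               # pixdim[8]
  wb(352, 4L)                                # vox_offset
  wb(1, 4L)                                  # scl_slope
  wb(0, 4L)                                  # scl_inter
  wb(0L, 2L); pad(1L); pad(1L)               # slice_end, slice_code, xyzt_units
  wb(c(0, 0, 0, 0), 4L)                      # cal_max..toffset
  wb(c(0L, 0L), 4L)                          # glmax, glmin
  desc <- charToRaw("ezloc")
  writeBin(c(desc, raw(80L - length(desc))), con)  # descrip
  pad(24L)                                   # aux_file
  wb(0L, 2L)                                 # qform_code
  wb(1L, 2L)                                 # sform_code
  wb(c(0, 0, 0), 4L)                         # quatern_b,c,d
  wb(c(0, 0, 0), 4L)                         # qoffset_x,y,z
  wb(as.numeric(t(affine[1:3, ])), 4L)       # srow_x, srow_y, srow_z
  pad(16L)                                   # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)  # magic
  pad(4L)                                    # extension flag -> offset 352

  vals <- as.vector(data)
  if (identical(dt$what, "integer")) {
    vals <- as.integer(round(vals))
    if (dt$size == 1L && !dt$signed) {
      writeBin(as.raw(vals), con)
    } else {
      wb(vals, dt$size)
    }
  } else {
    wb(as.numeric(vals), dt$size)
  }
  invisible(path)
}
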