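# Volume input/output: a minimal single-frame DICOM series reader/writer
# (explicit VR, little endian — the tags the pipeline needs) and a NIfTI
# fallback through RNifti.

dicom_tag <- function(group, element) {
  c(as.raw(bitwAnd(group, 0xff)), as.raw(bitwShiftR(group, 8)),
    as.raw(bitwAnd(element, 0xff)), as.raw(bitwShiftR(element, 8)))
}

dicom_write_element <- function(con, group, element, vr, value) {
  writeBin(dicom_tag(group, element), con)
  writeChar(vr, con, nchars = 2, eos = NULL)
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    writeBin(raw(2), con)
    if (vr == "OW") {
      writeBin(as.integer(2 * length(value)), con, size = 4, endian = "little")
      writeBin(as.integer(value), con, size = 2, endian = "little")
    } else stop("unsupported VR")
  } else if (vr == "US") {
    writeBin(2L, con, size = 2, endian = "little")
    writeBin(as.integer(value), con, size = 2, endian = "little")
  } else {
    s <- as.character(value)
    s <- paste(s, collapse = "\\")
    if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
    writeBin(as.integer(nchar(s)), con, size = 2, endian = "little")
    writeChar(s, con, nchars = nchar(s), eos = NULL)
  }
}

#' Write a volume as a single-frame DICOM series
#'
#' One explicit-VR little-endian file per axial slice, carrying rows and
#' columns, pixel spacing, slice location/thickness, rescale
#' slope/intercept and 16-bit pixel data. Intended for round-trip testing
#' and for exporting phantoms; intensities are quantised to the 16-bit
#' range via the written rescale.
#'
#' @param vol a [volume_image()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the file paths, invisibly.
#' @export
write_dicom_series <- function(vol, dir, prefix = "slice") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vol$voxels)
  lo <- min(vol$voxels); hi <- max(vol$voxels)
  slope <- if (hi > lo) (hi - lo) / 60000 else 1
  inter <- lo
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    sl <- vol$voxels[, , k]
    px <- as.integer(round((sl - inter) / slope))
    path <- file.path(dir, sprintf("%s_%03d.dcm", prefix, k))
    con <- file(path, "wb")
    writeBin(raw(128), con)
    writeChar("DICM", con, nchars = 4, eos = NULL)
    dicom_write_element(con, 0x0008, 0x0060, "CS", "CT")
    dicom_write_element(con, 0x0018, 0x0050, "DS", format(vol$spacing[3], digits = 10))
    dicom_write_element(con, 0x0020, 0x1041, "DS",
                        format((k - 1) * vol$spacing[3], digits = 10))
    dicom_write_element(con, 0x0028, 0x0010, "US", d[1])   # rows
    dicom_write_element(con, 0x0028, 0x0011, "US", d[2])   # columns
    dicom_write_element(con, 0x0028, 0x0030, "DS",
                        c(format(vol$spacing[1], digits = 10),
                          format(vol$spacing[2], digits = 10)))
    dicom_write_element(con, 0x0028, 0x0100, "US", 16)     # bits allocated
    dicom_write_element(con, 0x0028, 0x0103, "US", 0)      # unsigned
    dicom_write_element(con, 0x0028, 0x1052, "DS", format(inter, digits = 10))
    dicom_write_element(con, 0x0028, 0x1053, "DS", format(slope, digits = 10))
    dicom_write_element(con, 0x7fe0, 0x0010, "OW", as.vector(px))
    close(con)
    paths[k] <- path
  }
  invisible(paths)
}

dicom_read_file <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 128)
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!identical(magic, "DICM")) stop(sprintf("not a DICOM file: %s", path))
  out <- list()
  repeat {
    tag_raw <- readBin(con, "raw", 4)
    if (length(tag_raw) < 4) break
    group <- as.integer(tag_raw[1]) + 256L * as.integer(tag_raw[2])
    element <- as.integer(tag_raw[3]) + 256L * as.integer(tag_raw[4])
    vr <- rawToChar(readBin(con, "raw", 2))
    if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
      readBin(con, "raw", 2)
      len <- readBin(con, "integer", 1, size = 4, endian = "little")
    } else {
      len <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
    }
    key <- sprintf("%04x,%04x", group, element)
    if (vr == "OW") {
      out[[key]] <- readBin(con, "integer", len / 2, size = 2, signed = FALSE,
                            endian = "little")
    } else if (vr == "US") {
      out[[key]] <- readBin(con, "integer", len / 2, size = 2, signed = FALSE,
                            endian = "little")
    } else {
      out[[key]] <- strsplit(trimws(rawToChar(readBin(con, "raw", len))), "\\\\")[[1]]
    }
    if (seek(con, where = NA) >= sz) break
  }
  out
}

#' Read a DICOM series into a volume
#'
#' Reads every `.dcm` file in a directory, sorts the slices by slice
#' location (not by file name), applies the rescale slope/intercept, and
#' checks that the slice spacing is uniform.
#'
#' @param dir directory of single-frame DICOM slices.
#' @return a [volume_image()].
#' @export
read_dicom_volume <- function(dir) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(files)) stop(sprintf("no DICOM files in %s", dir))
  slices <- lapply(files, dicom_read_file)
  locs <- vapply(slices, function(s) as.numeric(s[["0020,1041"]][1]), 0)
  ord <- order(locs)
  slices <- slices[ord]; locs <- locs[ord]; files <- files[ord]
  if (length(locs) > 2) {
    gaps <- diff(locs)
    bad <- which(abs(gaps - stats::median(gaps)) > 0.25 * stats::median(gaps))
    if (length(bad))
      stop(sprintf("slice spacing gap before %s", basename(files[bad[1] + 1])))
  }
  first <- slices[[1]]
  rows <- first[["0028,0010"]][1]
  cols <- first[["0028,0011"]][1]
  ps <- as.numeric(first[["0028,0030"]])
  vox <- array(0, c(rows, cols, length(slices)))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    if (s[["0028,0010"]][1] != rows || s[["0028,0011"]][1] != cols)
      stop(sprintf("inconsistent slice dimensions in %s", basename(files[k])))
    slope <- as.numeric(s[["0028,1053"]][1]); if (!length(slope) || is.na(slope)) slope <- 1
    inter <- as.numeric(s[["0028,1052"]][1]); if (!length(inter) || is.na(inter)) inter <- 0
    vox[, , k] <- matrix(s[["7fe0,0010"]] * slope + inter, rows, cols)
  }
  dz <- if (length(locs) > 1) stats::median(diff(locs)) else
    as.numeric(first[["0018,0050"]][1])
  if (!length(dz) || is.na(dz) || dz <= 0) dz <- ps[1]
  volume_image(vox, c(ps[1], ps[2], dz))
}

#' Read a NIfTI volume
#'
#' Fallback volume format via the RNifti reader.
#'
#' @param path `.nii` / `.nii.gz` path.
#' @return a [volume_image()].
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- attr(img, "pixdim")
  if (is.null(sp)) sp <- RNifti::pixdim(img)
  volume_image(as.array(img), as.numeric(sp[1:3]))
}
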