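# Mesh and point-cloud file formats: STL (ASCII and binary) and PLY
# (ASCII), the interchange formats of the scanning workflow.

#' Read a triangle mesh (STL or PLY)
#'
#' Dispatches on the file extension; both STL dialects (ASCII and binary)
#' are detected automatically.
#'
#' @param path file path.
#' @return list with `vertices` (n x 3) and `faces` (m x 3, 1-based).
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = {
           pl <- read_ply(path)
           if (is.null(pl$faces)) stop("PLY file has no faces")
           list(vertices = pl$points, faces = pl$faces)
         },
         stop(sprintf("unknown mesh extension '%s'", ext)))
}

#' Write a triangle mesh (STL or PLY)
#'
#' @param mesh list with `vertices` and `faces`.
#' @param path destination; extension selects the format.
#' @param binary write binary STL (ignored for PLY, which is ASCII).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl(mesh, path, binary = binary),
         ply = write_ply(point_cloud(mesh$vertices), path, faces = mesh$faces),
         stop(sprintf("unknown mesh extension '%s'", ext)))
  invisible(path)
}

#' Read an STL mesh (ASCII or binary)
#'
#' Vertices are deduplicated exactly so the triangulation is connected.
#'
#' @param path file path.
#' @return list with `vertices` and `faces`.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  head_raw <- readBin(con, "raw", 80)
  close(con)
  is_ascii <- identical(rawToChar(head_raw[1:5]), "solid") &&
    !stl_binary_plausible(path)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  dedup_triangles(tri)
}

stl_binary_plausible <- function(path) {
  sz <- file.info(path)$size
  if (sz < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  isTRUE(sz == 84 + 50 * n)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl) || length(vl) %% 3 != 0)
    stop(sprintf("malformed ASCII STL '%s': vertex count %d is not a multiple of 3",
                 path, length(vl)))
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  V <- do.call(rbind, nums)
  if (any(!is.finite(V))) stop(sprintf("malformed ASCII STL '%s': non-numeric vertex", path))
  V
}

read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  need <- 84 + 50 * n
  if (is.na(n) || sz < need)
    stop(sprintf("malformed binary STL '%s': truncated at byte %d (need %d)", path, sz, need))
  V <- matrix(0, 3 * n, 3)
  for (i in seq_len(n)) {
    vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
    readBin(con, "raw", 2)
    V[3 * i - 2, ] <- vals[4:6]
    V[3 * i - 1, ] <- vals[7:9]
    V[3 * i, ] <- vals[10:12]
  }
  V
}

dedup_triangles <- function(V) {
  key <- apply(V, 1, function(r) paste(format(r, digits = 12), collapse = "_"))
  uid <- !duplicated(key)
  verts <- V[uid, , drop = FALSE]
  map <- match(key, key[uid])
  faces <- matrix(map, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

#' Write an STL mesh
#'
#' @param mesh list with `vertices` and `faces`.
#' @param path destination path.
#' @param binary write the binary dialect.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = FALSE) {
  V <- mesh$vertices; F_ <- mesh$faces
  e1 <- V[F_[, 2], , drop = FALSE] - V[F_[, 1], , drop = FALSE]
  e2 <- V[F_[, 3], , drop = FALSE] - V[F_[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(fn^2)); len[len == 0] <- 1
  fn <- fn / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(F_)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(F_))) {
      writeBin(as.numeric(c(fn[i, ], V[F_[i, 1], ], V[F_[i, 2], ], V[F_[i, 3], ])),
               con, size = 4, endian = "little")
      writeBin(raw(2), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid phantom", con)
    for (i in seq_len(nrow(F_))) {
      writeLines(sprintf("facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3]), con)
      writeLines(" outer loop", con)
      for (j in 1:3)
        writeLines(sprintf("  vertex %.9g %.9g %.9g",
                           V[F_[i, j], 1], V[F_[i, j], 2], V[F_[i, j], 3]), con)
      writeLines(" endloop", con)
      writeLines("endfacet", con)
    }
    writeLines("endsolid phantom", con)
  }
  invisible(path)
}

#' Write a point cloud (or mesh) as ASCII PLY
#'
#' @param cloud a [point_cloud()].
#' @param path destination path.
#' @param faces optional m x 3 face matrix to store a mesh.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path, faces = NULL) {
  pts <- cloud$points
  nrm <- cloud$normals
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("ply", con)
  writeLines("format ascii 1.0", con)
  writeLines(sprintf("comment source_tag %s", cloud$source_tag), con)
  writeLines(sprintf("element vertex %d", nrow(pts)), con)
  writeLines(c("property float x", "property float y", "property float z"), con)
  if (!is.null(nrm))
    writeLines(c("property float nx", "property float ny", "property float nz"), con)
  if (!is.null(faces)) {
    writeLines(sprintf("element face %d", nrow(faces)), con)
    writeLines("property list uchar int vertex_indices", con)
  }
  writeLines("end_header", con)
  body <- if (is.null(nrm)) pts else cbind(pts, nrm)
  writeLines(apply(body, 1, function(r) paste(format(r, digits = 10), collapse = " ")), con)
  if (!is.null(faces))
    writeLines(apply(faces - 1, 1, function(r) paste(c(3, r), collapse = " ")), con)
  invisible(path)
}

#' Read an ASCII PLY file
#'
#' @param path file path.
#' @return a [point_cloud()]; any faces are attached as attribute
#'   `faces` and also returned in `$faces` when present.
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1] != "ply") stop(sprintf("malformed PLY '%s': missing magic", path))
  if (!any(grepl("^format ascii", lines)))
    stop(sprintf("unsupported PLY dialect in '%s' (ASCII only)", path))
  hdr_end <- match("end_header", lines)
  if (is.na(hdr_end)) stop(sprintf("malformed PLY '%s': no end_header", path))
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf_line <- grep("^element face", hdr, value = TRUE)
  nf <- if (length(nf_line)) as.integer(sub("element face ", "", nf_line)) else 0L
  props <- sub("^property (float|double) ", "", grep("^property (float|double) ", hdr, value = TRUE))
  has_nrm <- all(c("nx", "ny", "nz") %in% props)
  tag_line <- grep("^comment source_tag ", hdr, value = TRUE)
  tag <- if (length(tag_line)) sub("^comment source_tag ", "", tag_line[1]) else "other"
  body <- lines[(hdr_end + 1):length(lines)]
  if (length(body) < nv + nf) stop(sprintf("malformed PLY '%s': truncated body", path))
  vmat <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"), as.numeric))
  pts <- vmat[, 1:3, drop = FALSE]
  nrm <- if (has_nrm) vmat[, 4:6, drop = FALSE] else NULL
  if (!is.null(nrm)) {
    len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
    nrm <- nrm / len
  }
  cl <- point_cloud(pts, nrm, if (tag %in% c("scan", "cbct_crown", "cbct_pulp")) tag else "other")
  if (nf > 0) {
    fmat <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                                  function(x) as.integer(x[2:4]) + 1L))
    attr(cl, "faces") <- fmat
    cl$faces <- fmat
  }
  cl
}
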