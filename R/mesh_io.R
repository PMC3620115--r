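# Surface-mesh file input/output. Units are millimetres throughout.
# STL (ASCII + binary), PLY (ASCII) and OFF are supported; on read,
# duplicate vertices are merged (STL stores one vertex triple per facet).

#' Read a surface mesh from STL, PLY or OFF
#'
#' Format is chosen by file extension (`.stl`, `.ply`, `.off`), with
#' binary/ASCII STL auto-detected. Coordinates are taken as millimetres.
#'
#' @param path file path.
#' @param validate check closedness/orientation (see [surface_mesh()]).
#' @return a `surface_mesh`.
#' @export
read_mesh <- function(path, validate = TRUE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path, validate),
         ply = read_ply(path, validate),
         off = read_off(path, validate),
         stop("unsupported mesh format: .", ext))
}

#' Write a surface mesh to STL, PLY or OFF
#'
#' @param mesh a `surface_mesh`.
#' @param path output path; extension selects the format.
#' @param binary for STL: write the binary layout (default ASCII).
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = if (binary) write_stl_bin(mesh, path) else write_stl_ascii(mesh, path),
         ply = write_ply(mesh, path),
         off = write_off(mesh, path),
         stop("unsupported mesh format: .", ext))
  invisible(path)
}

merge_vertices <- function(V, F1) {
  key <- apply(round(V, 9), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  list(V = V[uk, , drop = FALSE], F = matrix(map[F1], ncol = 3))
}

read_stl <- function(path, validate) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  close(con)
  is_ascii <- grepl("^\\s*solid", rawToChar(head[head != as.raw(0)]))
  if (is_ascii) {
    # confirm: binary files may also start with "solid"; check facet keyword
    txt <- readLines(path, warn = FALSE)
    if (any(grepl("facet normal", txt))) return(read_stl_ascii(txt, validate))
  }
  read_stl_bin(path, validate)
}

read_stl_ascii <- function(txt, validate) {
  vl <- grep("^\\s*vertex", txt, value = TRUE)
  V <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  n <- nrow(V) / 3
  F1 <- matrix(seq_len(3 * n), ncol = 3, byrow = TRUE)
  m <- merge_vertices(V, F1)
  surface_mesh(m$V, m$F, validate = validate)
}

read_stl_bin <- function(path, validate) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nt <- readBin(con, "integer", 1, size = 4, endian = "little")
  V <- matrix(0, 3 * nt, 3)
  for (i in seq_len(nt)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    V[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    readBin(con, "raw", 2)
  }
  F1 <- matrix(seq_len(3 * nt), ncol = 3, byrow = TRUE)
  m <- merge_vertices(V, F1)
  surface_mesh(m$V, m$F, validate = validate)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices; tr <- mesh$triangles; nrm <- mesh$normals
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  for (i in seq_len(nrow(tr))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                       nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
    writeLines("    outer loop", con)
    for (j in 1:3) {
      p <- v[tr[i, j], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid mesh", con)
}

write_stl_bin <- function(mesh, path) {
  v <- mesh$vertices; tr <- mesh$triangles; nrm <- mesh$normals
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(tr)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(tr))) {
    rec <- c(nrm[i, ], t(v[tr[i, ], ]))
    writeBin(as.numeric(rec), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
}

read_ply <- function(path, validate) {
  txt <- readLines(path, warn = FALSE)
  if (txt[1] != "ply") stop("not a PLY file")
  endh <- match("end_header", txt)
  nv <- as.integer(sub(".*vertex\\s+", "", grep("element vertex", txt[1:endh],
                                                value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+", "", grep("element face", txt[1:endh],
                                              value = TRUE)[1]))
  body <- txt[(endh + 1):length(txt)]
  V <- do.call(rbind, lapply(strsplit(trimws(body[1:nv]), "\\s+"), function(p)
    as.numeric(p[1:3])))
  F1 <- do.call(rbind, lapply(strsplit(trimws(body[nv + (1:nf)]), "\\s+"),
                              function(p) as.integer(p[2:4]) + 1L))
  surface_mesh(V, F1, validate = validate)
}

write_ply <- function(mesh, path) {
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(tr)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.12g %.12g %.12g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L), con)
}

read_off <- function(path, validate) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt) & nzchar(trimws(txt))]
  if (trimws(txt[1]) != "OFF") stop("not an OFF file")
  hdr <- as.integer(strsplit(trimws(txt[2]), "\\s+")[[1]])
  nv <- hdr[1]; nf <- hdr[2]
  V <- do.call(rbind, lapply(strsplit(trimws(txt[2 + (1:nv)]), "\\s+"),
                             function(p) as.numeric(p[1:3])))
  F1 <- do.call(rbind, lapply(strsplit(trimws(txt[2 + nv + (1:nf)]), "\\s+"),
                              function(p) as.integer(p[2:4]) + 1L))
  surface_mesh(V, F1, validate = validate)
}

write_off <- function(mesh, path) {
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(v), nrow(tr)), con)
  writeLines(sprintf("%.12g %.12g %.12g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L), con)
}
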