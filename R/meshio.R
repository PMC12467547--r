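#' Read and write triangle meshes in OFF and ASCII PLY
#'
#' Minimal readers/writers for the two plain-text formats used to exchange
#' sensor-surface meshes. Only triangular faces are supported.
#'
#' @param mesh a [trimesh()].
#' @param path file path; format chosen by extension for [read_mesh()].
#' @return readers return a [trimesh()]; writers their input, invisibly.
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)), con)
  utils::write.table(format(mesh$vertices, digits = 12, trim = TRUE,
                            scientific = FALSE),
                     con, sep = " ", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con, sep = " ",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(mesh)
}

#' @rdname write_mesh_off
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (toupper(trimws(lines[1])) != "OFF") stop("not an OFF file")
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  v <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE), nv, 3, byrow = TRUE)
  f <- matrix(scan(text = lines[(3 + nv):(2 + nv + nf)], quiet = TRUE),
              nf, byrow = TRUE, ncol = 4)
  if (any(f[, 1] != 3)) stop("only triangular faces are supported")
  trimesh(v, f[, 2:4] + 1L)
}

#' @rdname write_mesh_off
#' @export
write_mesh_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(mesh$vertices)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(mesh$triangles)),
    "property list uchar int vertex_indices", "end_header"
  ), con)
  utils::write.table(format(mesh$vertices, digits = 12, trim = TRUE,
                            scientific = FALSE),
                     con, sep = " ", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con, sep = " ",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(mesh)
}

#' @rdname write_mesh_off
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("not an ASCII PLY file")
  hdr <- lines[1:hdr_end]
  if (trimws(hdr[1]) != "ply" || !any(grepl("format\\s+ascii", hdr)))
    stop("only ASCII PLY is supported")
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", hdr, value = TRUE)[1]))
  body <- lines[(hdr_end + 1):length(lines)]
  v <- matrix(scan(text = body[1:nv], quiet = TRUE), nv, byrow = TRUE, ncol = 3)
  f <- matrix(scan(text = body[(nv + 1):(nv + nf)], quiet = TRUE),
              nf, byrow = TRUE, ncol = 4)
  if (any(f[, 1] != 3)) stop("only triangular faces are supported")
  trimesh(v, f[, 2:4] + 1L)
}

#' @rdname write_mesh_off
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    off = read_mesh_off(path),
    ply = read_mesh_ply(path),
    stop("unsupported mesh format: ", ext)
  )
}
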