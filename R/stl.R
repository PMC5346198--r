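# Triangle-soup surface meshes and the STL reader/writer (both dialects).
# Aneurysm geometries are stored as STL in the source repository; the loader
# auto-detects the dialect. No mesh repair or geometric measures are done.

#' Triangle mesh
#'
#' A triangle soup: three vertex matrices (row `i` of `v1`, `v2`, `v3` are
#' the corners of facet `i`) and a per-facet normal. Normals are recomputed
#' from the vertex winding when not supplied; degenerate facets get a zero
#' normal.
#'
#' @param v1,v2,v3 numeric matrices with 3 columns, one row per facet.
#' @param normals optional numeric matrix of per-facet normals.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(v1, v2, v3, normals = NULL) {
  v1 <- as_vertex_matrix(v1); v2 <- as_vertex_matrix(v2)
  v3 <- as_vertex_matrix(v3)
  if (nrow(v1) != nrow(v2) || nrow(v1) != nrow(v3))
    stop_schema("v1, v2, v3 must have one row per facet")
  if (!all(is.finite(v1), is.finite(v2), is.finite(v3)))
    stop_biocurate("biocurate_value_error", "mesh coordinates must be finite")
  if (is.null(normals)) normals <- facet_normals(v1, v2, v3)
  normals <- as_vertex_matrix(normals)
  if (nrow(normals) != nrow(v1))
    stop_schema("one normal per facet required")
  structure(list(v1 = v1, v2 = v2, v3 = v3, normals = normals),
            class = "tri_mesh")
}

as_vertex_matrix <- function(m) {
  m <- rbind(matrix(as.numeric(m), ncol = 3L))
  dimnames(m) <- NULL
  m
}

facet_normals <- function(v1, v2, v3) {
  a <- v2 - v1
  b <- v3 - v1
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2))
  ok <- len > 0
  n[ok, ] <- n[ok, , drop = FALSE] / len[ok]
  n[!ok, ] <- 0
  n
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("<tri_mesh>", nrow(x$v1), "facets\n")
  invisible(x)
}

#' Number of facets in a mesh
#' @param mesh a [tri_mesh()].
#' @export
n_facets <- function(mesh) nrow(mesh$v1)

#' Axis-aligned unit cube mesh
#'
#' Twelve triangles with outward windings; handy as a known geometry in
#' examples and tests.
#' @return A [tri_mesh()] with 12 facets.
#' @export
cube_mesh <- function() {
  v <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
    c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)
  )
  # two triangles per face, vertices indexed into v
  f <- rbind(
    c(1, 3, 2), c(1, 4, 3),   # z = 0
    c(5, 6, 7), c(5, 7, 8),   # z = 1
    c(1, 2, 6), c(1, 6, 5),   # y = 0
    c(4, 7, 3), c(4, 8, 7),   # y = 1
    c(1, 8, 4), c(1, 5, 8),   # x = 0
    c(2, 3, 7), c(2, 7, 6)    # x = 1
  )
  tri_mesh(v[f[, 1], ], v[f[, 2], ], v[f[, 3], ])
}

#' Load an STL surface mesh
#'
#' Auto-detects the dialect: ASCII payloads start with `solid` and contain no
#' NUL bytes; anything else is treated as binary (80-byte header, little-
#' endian `uint32` facet count, 50 bytes per facet). A binary facet count
#' inconsistent with the payload length is reported as a truncation error; a
#' payload matching neither dialect is a format error.
#'
#' @param payload raw vector, ASCII STL text, or path to an STL file.
#' @return A [tri_mesh()].
#' @export
load_stl <- function(payload) {
  if (is.character(payload) && length(payload) == 1L && file.exists(payload))
    payload <- readBin(payload, "raw", file.size(payload))
  if (is.character(payload))
    payload <- charToRaw(paste(payload, collapse = "\n"))
  if (!is.raw(payload) || length(payload) < 6L)
    stop_parse("payload is not an STL document")
  looks_ascii <- identical(rawToChar(payload[1:5]), "solid") &&
    !any(payload == as.raw(0L))
  if (looks_ascii) parse_stl_ascii(rawToChar(payload))
  else parse_stl_binary(payload)
}

parse_stl_ascii <- function(text) {
  lines <- trimws(strsplit(text, "\r?\n")[[1]])
  grab <- function(prefix) {
    hits <- lines[startsWith(lines, prefix)]
    if (!length(hits)) return(matrix(numeric(), ncol = 3L))
    nums <- lapply(strsplit(sub(prefix, "", hits), "[[:space:]]+"), function(p) {
      p <- suppressWarnings(as.numeric(p[nzchar(p)]))
      if (length(p) != 3L || anyNA(p))
        stop_parse("malformed coordinate triple in ASCII STL")
      p
    })
    do.call(rbind, nums)
  }
  normals <- grab("facet normal ")
  verts <- grab("vertex ")
  n <- nrow(normals)
  if (nrow(verts) != 3L * n)
    stop_parse(sprintf("ASCII STL has %d facets but %d vertices",
                       n, nrow(verts)))
  idx <- seq_len(n)
  tri_mesh(verts[3L * idx - 2L, , drop = FALSE],
           verts[3L * idx - 1L, , drop = FALSE],
           verts[3L * idx, , drop = FALSE],
           normals)
}

parse_stl_binary <- function(payload) {
  if (length(payload) < 84L)
    stop_parse("payload matches neither STL dialect")
  count <- readBin(payload[81:84], "integer", n = 1L, size = 4L,
                   endian = "little")
  expected <- 84L + 50L * count
  if (count < 0L || length(payload) != expected)
    stop_biocurate(
      "biocurate_truncation_error",
      sprintf("binary STL declares %d facets (%d bytes) but payload has %d bytes",
              count, expected, length(payload))
    )
  if (count == 0L)
    return(tri_mesh(matrix(numeric(), ncol = 3), matrix(numeric(), ncol = 3),
                    matrix(numeric(), ncol = 3)))
  body <- payload[-(1:84)]
  facet_bytes <- matrix(body, nrow = 50L)
  floats <- vapply(seq_len(count), function(j)
    readBin(facet_bytes[1:48, j], "numeric", n = 12L, size = 4L,
            endian = "little"),
    numeric(12L))
  floats <- t(floats)  # one row per facet, 12 columns
  tri_mesh(floats[, 4:6, drop = FALSE], floats[, 7:9, drop = FALSE],
           floats[, 10:12, drop = FALSE], floats[, 1:3, drop = FALSE])
}

#' Write a mesh as STL
#'
#' `write_stl_ascii()` returns the document as a single string;
#' `write_stl_binary()` returns raw bytes. Both are deterministic for a given
#' mesh, so fixture output is byte-stable.
#'
#' @param mesh a [tri_mesh()].
#' @param name solid name recorded in the document.
#' @return Character scalar (ASCII) or raw vector (binary).
#' @export
write_stl_ascii <- function(mesh, name = "mesh") {
  stopifnot(inherits(mesh, "tri_mesh"))
  fmt <- function(v) sprintf("%.9g %.9g %.9g", v[1], v[2], v[3])
  out <- c(paste0("solid ", name))
  for (i in seq_len(n_facets(mesh))) {
    out <- c(out,
             paste0("  facet normal ", fmt(mesh$normals[i, ])),
             "    outer loop",
             paste0("      vertex ", fmt(mesh$v1[i, ])),
             paste0("      vertex ", fmt(mesh$v2[i, ])),
             paste0("      vertex ", fmt(mesh$v3[i, ])),
             "    endloop",
             "  endfacet")
  }
  paste0(paste(c(out, paste0("endsolid ", name)), collapse = "\n"), "\n")
}

#' @rdname write_stl_ascii
#' @export
write_stl_binary <- function(mesh, name = "mesh") {
  stopifnot(inherits(mesh, "tri_mesh"))
  header <- charToRaw(sprintf("%-80s", paste0("binary STL ", name)))[1:80]
  con <- rawConnection(raw(), "wb")
  on.exit(close(con))
  writeBin(header, con)
  writeBin(n_facets(mesh), con, size = 4L, endian = "little")
  for (i in seq_len(n_facets(mesh))) {
    writeBin(as.numeric(c(mesh$normals[i, ], mesh$v1[i, ], mesh$v2[i, ],
                          mesh$v3[i, ])),
             con, size = 4L, endian = "little")
    writeBin(0L, con, size = 2L, endian = "little")
  }
  rawConnectionValue(con)
}
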