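#' Read a triangulated STL file
#'
#' Accepts ASCII and binary STL. Returns the triangle soup as a numeric
#' matrix with 9 columns (the three vertices, x1 y1 z1 x2 y2 z2 x3 y3 z3).
#'
#' @param path STL file path.
#' @return numeric matrix `n_triangles x 9`.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("read_stl: file not found: ", path)
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  close(con)
  txt <- rawToChar(head[head != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", txt)
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0) {
      # "solid" header but no ASCII vertices: treat as binary
      is_ascii <- FALSE
    } else {
      vals <- t(vapply(strsplit(trimws(vl), "\\s+"), function(p)
        as.numeric(p[2:4]), numeric(3)))
      if (any(!is.finite(vals))) stop("read_stl: malformed ASCII vertex line in ", path)
      return(t(matrix(t(vals), nrow = 9)))
    }
  }
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!length(ntri) || ntri < 1) stop("read_stl: no triangles in ", path)
  out <- matrix(NA_real_, ntri, 9)
  for (i in seq_len(ntri)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    readBin(con, "raw", 2)
    out[i, ] <- rec[4:12]
  }
  out
}

#' Write a triangle mesh to STL
#'
#' @param mesh a `sono_mesh` (see [isosurface()]) or a list with `vertices`
#'   (`n x 3`) and `faces` (`m x 3` integer indices).
#' @param path output path.
#' @param binary write binary STL (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  ntri <- if (is.null(f)) 0L else nrow(f)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0, 80)), con)
    writeBin(as.integer(ntri), con, size = 4, endian = "little")
    for (i in seq_len(ntri)) {
      p1 <- v[f[i, 1], ]; p2 <- v[f[i, 2], ]; p3 <- v[f[i, 3], ]
      nrm <- cross3(matrix(p2 - p1, 1), matrix(p3 - p1, 1))[1, ]
      nn <- sqrt(sum(nrm^2))
      if (nn > 0) nrm <- nrm / nn
      writeBin(as.numeric(c(nrm, p1, p2, p3)), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    cat("solid mesh\n", file = con)
    for (i in seq_len(ntri)) {
      p1 <- v[f[i, 1], ]; p2 <- v[f[i, 2], ]; p3 <- v[f[i, 3], ]
      nrm <- cross3(matrix(p2 - p1, 1), matrix(p3 - p1, 1))[1, ]
      nn <- sqrt(sum(nrm^2))
      if (nn > 0) nrm <- nrm / nn
      cat(sprintf(" facet normal %g %g %g\n  outer loop\n", nrm[1], nrm[2], nrm[3]),
          file = con)
      for (p in list(p1, p2, p3))
        cat(sprintf("   vertex %.9g %.9g %.9g\n", p[1], p[2], p[3]), file = con)
      cat("  endloop\n endfacet\n", file = con)
    }
    cat("endsolid mesh\n", file = con)
  }
  invisible(path)
}

#' Write a triangle mesh to Wavefront OBJ
#' @inheritParams write_stl
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  f <- mesh$faces
  for (i in seq_len(if (is.null(v)) 0L else nrow(v)))
    cat(sprintf("v %.9g %.9g %.9g\n", v[i, 1], v[i, 2], v[i, 3]), file = con)
  for (i in seq_len(if (is.null(f)) 0L else nrow(f)))
    cat(sprintf("f %d %d %d\n", f[i, 1], f[i, 2], f[i, 3]), file = con)
  invisible(path)
}
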