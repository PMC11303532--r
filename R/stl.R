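# STL reading/writing. Binary dialect: 80-byte header, little-endian uint32
# facet count, then per facet 12 float32 (normal + 3 vertices) + uint16
# attribute. ASCII dialect: the usual solid/facet/vertex grammar. Identical
# vertex coordinates are merged on read so faces share topology.

#' Read an STL surface model
#'
#' Reads binary or ASCII STL (auto-detected) into a [triangle_mesh()].
#' Vertices with bit-identical coordinates are merged, so a watertight model
#' round-trips with shared topology.
#'
#' @param path path to an STL file
#' @return a [triangle_mesh()]
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = min(84, size))
  if (length(header) < 84) {
    # too short for a binary STL; try ASCII
    txt <- rawToChar(header[header != as.raw(0)])
    if (!grepl("^\\s*solid", txt))
      stopf("malformed STL %s: only %d bytes, header truncated at byte offset %d",
            path, size, length(header))
    close(con)
    on.exit(NULL)
    return(read_stl_ascii(path))
  }
  nfacets <- readBin(header[81:84], "integer", size = 4, endian = "little")
  expected <- 84 + 50 * as.numeric(nfacets)
  starts_solid <- grepl("^solid", rawToChar(header[1:5]))
  if (expected == size && (nfacets > 0 || size == 84)) {
    body <- readBin(con, "raw", n = size - 84)
    return(parse_stl_binary(body, nfacets, path))
  }
  if (starts_solid) {
    close(con)
    on.exit(NULL)
    return(read_stl_ascii(path))
  }
  stopf(paste0("malformed STL %s: header claims %d facets (%d bytes) but file ",
               "has %d bytes; facet block truncated at byte offset %d"),
        path, nfacets, expected, size, size)
}

parse_stl_binary <- function(body, nfacets, path) {
  if (nfacets == 0) return(triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  # strip the per-facet uint16 attribute bytes, then bulk-decode float32
  idx <- rep((seq_len(nfacets) - 1L) * 50L, each = 48L) + seq_len(48L)
  m <- matrix(readBin(body[idx], "numeric", n = nfacets * 12L, size = 4,
                      endian = "little"),
              nfacets, 12, byrow = TRUE)
  tri <- m[, 4:12, drop = FALSE] # drop stored normal
  v <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE], tri[, 7:9, drop = FALSE])
  ord <- c(t(matrix(seq_len(3 * nfacets), nfacets, 3)))
  v <- v[ord, , drop = FALSE] # interleave: v1,v2,v3 per facet
  dedup_to_mesh(v)
}

dedup_to_mesh <- function(v) {
  key <- paste(sprintf("%.9g", v[, 1]), sprintf("%.9g", v[, 2]), sprintf("%.9g", v[, 3]))
  idx <- match(key, key)
  keep <- !duplicated(idx)
  newid <- cumsum(keep)
  vmap <- newid[idx]
  verts <- v[keep, , drop = FALSE]
  faces <- matrix(vmap, ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  offsets <- cumsum(c(0, nchar(lines, type = "bytes") + 1L))
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) == 0) {
    if (!any(grepl("^\\s*solid", lines)))
      stopf("malformed ASCII STL %s: no 'solid' header at byte offset 0", path)
    return(triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  }
  if (length(vl) %% 3 != 0)
    stopf("malformed ASCII STL %s: facet block truncated at byte offset %d (%d vertex lines, not a multiple of 3)",
          path, offsets[vl[length(vl)]], length(vl))
  parse1 <- function(s) {
    p <- strsplit(trimws(s), "\\s+")[[1]]
    as.numeric(p[2:4])
  }
  v <- t(vapply(lines[vl], parse1, numeric(3), USE.NAMES = FALSE))
  if (any(!is.finite(v))) {
    bad <- vl[which(rowSums(!is.finite(v)) > 0)[1]]
    stopf("malformed ASCII STL %s: unparseable vertex at byte offset %d", path, offsets[bad])
  }
  dedup_to_mesh(v)
}

#' Write a mesh as STL
#'
#' @param mesh a [triangle_mesh()]
#' @param path output path
#' @param dialect `"binary"` (default) or `"ascii"`
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "mbwm binary STL"))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(F))) {
      writeBin(as.numeric(c(n[i, ], a[i, ], b[i, ], c[i, ])), con,
               size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    fmt <- function(x) sprintf("%.9g", x)
    out <- character(7 * nrow(F) + 2)
    out[1] <- "solid mbwm"
    k <- 2
    for (i in seq_len(nrow(F))) {
      out[k] <- sprintf("  facet normal %s %s %s", fmt(n[i, 1]), fmt(n[i, 2]), fmt(n[i, 3]))
      out[k + 1] <- "    outer loop"
      out[k + 2] <- sprintf("      vertex %s %s %s", fmt(a[i, 1]), fmt(a[i, 2]), fmt(a[i, 3]))
      out[k + 3] <- sprintf("      vertex %s %s %s", fmt(b[i, 1]), fmt(b[i, 2]), fmt(b[i, 3]))
      out[k + 4] <- sprintf("      vertex %s %s %s", fmt(c[i, 1]), fmt(c[i, 2]), fmt(c[i, 3]))
      out[k + 5] <- "    endloop"
      out[k + 6] <- "  endfacet"
      k <- k + 7
    }
    out[k] <- "endsolid mbwm"
    writeLines(out, path)
  }
  invisible(path)
}
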