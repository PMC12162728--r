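# Minimal baseline-TIFF I/O for binary stacks (multi-page, 8-bit grayscale,
# uncompressed, one strip per page) plus JSON/CSV graph exchange.  The TIFF
# subset written here is the one the reader parses; it is also readable by
# Fiji/scikit-image.

#' Write a binary volume as a multi-page 8-bit TIFF stack
#'
#' One page per z slice, values 0/255, uncompressed little-endian baseline
#' TIFF.
#'
#' @param vol a `binary_volume`
#' @param path output path
#' @export
write_tiff_stack <- function(vol, path) {
  d <- dim(vol$occ)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  con <- file(path, "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  w2(42)
  # layout: header(8) | page data blocks | IFDs
  data_off <- 8
  page_bytes <- nx * ny
  ifd0 <- data_off + nz * page_bytes
  w4(ifd0)
  for (k in seq_len(nz)) {
    # row-major pages (rows = y, x fastest) == R's column-major [x, y] slice
    writeBin(as.raw(as.vector(vol$occ[, , k]) * 255L), con)
  }
  n_entries <- 8L
  ifd_size <- 2 + n_entries * 12 + 4
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count); w4(value)
  }
  for (k in seq_len(nz)) {
    w2(n_entries)
    entry(256, 4, 1, nx)                         # ImageWidth
    entry(257, 4, 1, ny)                         # ImageLength
    entry(258, 3, 1, 8)                          # BitsPerSample
    entry(259, 3, 1, 1)                          # Compression: none
    entry(262, 3, 1, 1)                          # Photometric: BlackIsZero
    entry(273, 4, 1, data_off + (k - 1) * page_bytes)  # StripOffsets
    entry(278, 4, 1, ny)                         # RowsPerStrip
    entry(279, 4, 1, page_bytes)                 # StripByteCounts
    w4(if (k < nz) ifd0 + k * ifd_size else 0)   # next IFD
  }
  invisible(path)
}

#' Read a multi-page 8-bit TIFF stack as a binary volume
#'
#' Supports the uncompressed 8-bit grayscale subset written by
#' [write_tiff_stack()] (any strip layout).  Values > 0 become solid.
#'
#' @param path TIFF file
#' @param pitch voxel pitch to record, um
#' @return a `binary_volume`
#' @export
read_tiff_stack <- function(path, pitch = 15) {
  raw_all <- readBin(path, "raw", file.size(path))
  if (!(rawToChar(raw_all[1:2]) %in% c("II")))
    stop("only little-endian TIFF supported")
  u16 <- function(off) sum(as.integer(raw_all[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw_all[off + 1:4]) * 256^(0:3))
  stopifnot(u16(2) == 42)
  ifd <- u32(4)
  slices <- list()
  dims <- NULL
  while (ifd != 0) {
    ne <- u16(ifd)
    tags <- list()
    for (q in seq_len(ne)) {
      off <- ifd + 2 + (q - 1) * 12
      tag <- u16(off); type <- u16(off + 2); cnt <- u32(off + 4)
      val <- if (type == 3 && cnt == 1) u16(off + 8) else u32(off + 8)
      tags[[as.character(tag)]] <- list(type = type, count = cnt, value = val,
                                        off = off)
    }
    nx <- tags[["256"]]$value; ny <- tags[["257"]]$value
    if (!is.null(tags[["259"]]) && tags[["259"]]$value != 1)
      stop("compressed TIFF not supported")
    if (!is.null(tags[["258"]]) && tags[["258"]]$value != 8)
      stop("only 8-bit TIFF supported")
    # strip offsets/counts may be inline (count 1) or arrays
    get_arr <- function(t) {
      if (t$count == 1) return(t$value)
      base <- t$value
      vapply(seq_len(t$count) - 1L,
             function(i) u32(base + 4 * i), numeric(1))
    }
    so <- get_arr(tags[["273"]])
    sc <- get_arr(tags[["279"]])
    bytes <- unlist(lapply(seq_along(so), function(i)
      as.integer(raw_all[so[i] + seq_len(sc[i])])))
    # rows are y with x fastest: column-major [x, y]
    slices[[length(slices) + 1]] <- matrix(bytes, nrow = nx)[, seq_len(ny)]
    dims <- c(nx, ny)
    ifd <- u32(ifd + 2 + ne * 12)
  }
  nz <- length(slices)
  occ <- array(0L, c(dims[1], dims[2], nz))
  for (k in seq_len(nz)) occ[, , k] <- as.integer(slices[[k]] > 0)
  binary_volume(occ, pitch = pitch)
}

#' Export an edge graph as JSON
#'
#' Nodes, edges (1-based), per-edge orientation and lengths, plus the
#' domain size; round-trips through [read_graph_json()].
#'
#' @param graph an `edge_graph`
#' @param path output path
#' @export
write_graph_json <- function(graph, path) {
  jsonlite::write_json(list(
    L = graph$L,
    nodes = graph$nodes,
    edges = graph$edges,
    theta_z = graph$theta_z,
    length = graph$length
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an edge graph from JSON
#'
#' @param path JSON file written by [write_graph_json()]
#' @return an `edge_graph`
#' @export
read_graph_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_edge_graph(matrix(lst$nodes, ncol = 3),
                 matrix(lst$edges, ncol = 2), lst$L)
}

#' Export the edge table as CSV
#'
#' @param graph an `edge_graph`
#' @param path output path
#' @export
write_graph_csv <- function(graph, path) {
  df <- data.frame(
    node_a = graph$edges[, 1], node_b = graph$edges[, 2],
    theta_z = graph$theta_z, length = graph$length
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
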