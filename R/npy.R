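## Minimal NumPy .npy (format 1.0) reader/writer for dense numeric
## arrays, C-order on disk. Only what the tensor archive needs.

npyHeader <- function(dims, descr) {
  shape <- paste0("(", paste(dims, collapse = ", "),
                  if (length(dims) == 1) "," else "", ")")
  dict <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                  descr, shape)
  ## total header (magic 6 + version 2 + len 2 + dict) padded to 64 bytes
  pad <- 64 - ((10 + nchar(dict) + 1) %% 64)
  if (pad == 64) pad <- 0
  dict <- paste0(dict, strrep(" ", pad), "\n")
  c(as.raw(c(0x93)), charToRaw("NUMPY"), as.raw(c(1, 0)),
    writeBin(as.integer(nchar(dict)), raw(), size = 2, endian = "little"),
    charToRaw(dict))
}

writeNpy <- function(x, path, dtype = c("f8", "f4")) {
  dtype <- match.arg(dtype)
  dims <- dim(x)
  if (is.null(dims)) dims <- length(x)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(npyHeader(dims, paste0("<", dtype)), con)
  ## C-order: last index fastest -> reverse dims then column-major flatten
  v <- if (length(dims) > 1) as.vector(aperm(x, rev(seq_along(dims))))
       else as.vector(x)
  writeBin(as.numeric(v), con, size = if (dtype == "f4") 4L else 8L,
           endian = "little")
  invisible(path)
}

readNpy <- function(path) {
  if (!file.exists(path)) stopMv("FormatError", "no such file: %s", path)
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (length(magic) < 6 ||
      !identical(magic, c(as.raw(0x93), charToRaw("NUMPY"))))
    stopMv("FormatError", "not an .npy file: %s", path)
  ver <- readBin(con, "raw", 2)
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little",
                  signed = FALSE)
  hdr <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr': *'([^']+)'.*", "\\1", hdr)
  fortran <- grepl("'fortran_order': *True", hdr)
  shapeStr <- sub(".*'shape': *\\(([^)]*)\\).*", "\\1", hdr)
  dims <- as.integer(strsplit(gsub(" ", "", shapeStr), ",")[[1]])
  if (anyNA(dims)) stopMv("FormatError", "bad shape in .npy header")
  size <- switch(descr, "<f4" = 4L, "<f8" = 8L,
                 stopMv("FormatError", "unsupported dtype '%s'", descr))
  n <- prod(dims)
  v <- readBin(con, "numeric", n, size = size, endian = "little")
  if (length(v) < n)
    stopMv("FormatError", "truncated .npy file: %s", path)
  x <- if (length(dims) > 1) {
    a <- array(v, rev(dims))
    if (fortran) array(v, dims) else aperm(a, rev(seq_along(dims)))
  } else v
  x
}

#' Save / load a ViewTensor as a .npy file
#'
#' Single-tensor archive, shape 4 x 6 x H x W, C-order. The default
#' float64 encoding round-trips bitwise; \code{dtype = "f4"} writes
#' compact 32-bit floats (lossy for arbitrary doubles).
#'
#' @param t a \linkS4class{ViewTensor}.
#' @param path file path (.npy).
#' @param dtype on-disk element type, "f8" (default, lossless) or "f4".
#' @return \code{saveViewTensor}: the path, invisibly;
#'   \code{loadViewTensor}: a \linkS4class{ViewTensor}.
#' @export
saveViewTensor <- function(t, path, dtype = c("f8", "f4")) {
  stopifnot(is(t, "ViewTensor"))
  writeNpy(t@data, path, match.arg(dtype))
  invisible(path)
}

#' @rdname saveViewTensor
#' @export
loadViewTensor <- function(path) {
  x <- readNpy(path)
  d <- dim(x)
  if (length(d) != 4 || d[1] != 4 || d[2] != 6)
    stopMv("FormatError",
           "expected a 4 x 6 x H x W tensor, got shape %s",
           paste(d, collapse = "x"))
  new("ViewTensor", data = x)
}
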