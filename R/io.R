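#' Read a binary colony mask from a raster image
#'
#' Reads a PNG or TIFF mask and returns a 0/1 matrix, checking that the
#' image is genuinely binary (at most two distinct intensity levels after
#' collapsing colour channels). By default dark pixels are treated as
#' occupied, matching masks in which the colony is drawn black on white.
#'
#' @param path path to a PNG or TIFF file.
#' @param polarity `"dark_is_occupied"` (default) or
#'   `"light_is_occupied"`.
#' @return an integer 0/1 matrix (rows = image rows, top to bottom);
#'   pass to [grid_from_matrix()].
#' @export
read_mask <- function(path, polarity = c("dark_is_occupied", "light_is_occupied")) {
  polarity <- match.arg(polarity)
  if (!file.exists(path)) abort(sprintf("mask file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("unsupported mask format '.%s' (PNG or TIFF required)", ext))
  )
  if (length(dim(img)) == 3L) img <- apply(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE], c(1, 2), mean)
  lv <- unique(as.vector(img))
  if (length(lv) > 2L) {
    abort("mask not binary; pre-threshold required (more than 2 intensity levels)")
  }
  occ <- if (polarity == "dark_is_occupied") img < 0.5 else img >= 0.5
  m <- matrix(as.integer(occ), nrow = nrow(img))
  m
}

#' Write a binary matrix as a PNG mask
#'
#' @param m a 0/1 matrix.
#' @param path output PNG path.
#' @param polarity occupied pixels are written dark (default) or light.
#' @return `path`, invisibly.
#' @export
write_mask <- function(m, path, polarity = c("dark_is_occupied", "light_is_occupied")) {
  polarity <- match.arg(polarity)
  img <- if (polarity == "dark_is_occupied") 1 - m else m
  storage.mode(img) <- "double"
  png::writePNG(img, path)
  invisible(path)
}

#' 4-D colony image stacks
#'
#' A `dataset4d` holds a binary array with dimensions (x, y, time, sample)
#' — a stack of colony masks over time for a sample of colonies — plus the
#' time labels (hours), sample labels and the physical length per lattice
#' spacing. Two on-disk representations are supported: MATLAB MAT v5
#' containers (see [read_dataset4d()]) and the package's own portable
#' plain-text container (see [write_dataset4d()]).
#'
#' @param array a 4-D 0/1 array ordered (x, y, time, sample).
#' @param time_labels hours per time index (defaults to the index).
#' @param sample_labels colony labels (defaults to the index).
#' @param length_scale physical units per lattice spacing.
#' @return an object of class `dataset4d`.
#' @export
dataset4d <- function(array, time_labels = NULL, sample_labels = NULL,
                      length_scale = 1) {
  if (length(dim(array)) != 4L) abort("unrecognized dataset layout: a 4-D array is required")
  if (!all(array %in% c(0, 1))) abort("unrecognized dataset layout: entries must be 0 or 1")
  storage.mode(array) <- "integer"
  d <- dim(array)
  if (is.null(time_labels)) time_labels <- seq_len(d[3])
  if (is.null(sample_labels)) sample_labels <- seq_len(d[4])
  if (length(time_labels) != d[3] || length(sample_labels) != d[4]) {
    abort("label lengths must match the time and sample dimensions")
  }
  structure(list(array = array, time_labels = as.numeric(time_labels),
                 sample_labels = sample_labels, length_scale = length_scale),
            class = "dataset4d")
}

#' @export
print.dataset4d <- function(x, ...) {
  d <- dim(x$array)
  cat(sprintf("<dataset4d> %d x %d lattice, %d time points, %d samples\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Write a 4-D colony stack to the portable text container
#'
#' The container is plain text: a first line holding a JSON header (format
#' tag and version, dimensions, labels, length scale) followed by one
#' `x y time sample` line per occupied entry. It round-trips exactly
#' through [read_dataset4d()].
#'
#' @param ds a [dataset4d()].
#' @param path output path (conventionally `.cg4d`).
#' @return `path`, invisibly.
#' @export
write_dataset4d <- function(ds, path) {
  stopifnot(inherits(ds, "dataset4d"))
  header <- jsonlite::toJSON(list(
    format = "colony-grid-4d", version = 1L, dim = dim(ds$array),
    time_labels = ds$time_labels, sample_labels = ds$sample_labels,
    length_scale = ds$length_scale
  ), auto_unbox = FALSE, digits = NA)
  occ <- which(ds$array == 1L, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(header), con)
  if (nrow(occ) > 0L) {
    writeLines(paste(occ[, 1], occ[, 2], occ[, 3], occ[, 4]), con)
  }
  invisible(path)
}

read_portable_dataset4d <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  if (!identical(header$format, "colony-grid-4d")) {
    abort("unrecognized dataset layout: missing colony-grid-4d header")
  }
  arr <- array(0L, dim = header$dim)
  if (length(lines) > 1L) {
    idx <- matrix(scan(text = lines[-1], what = integer(), quiet = TRUE),
                  ncol = 4, byrow = TRUE)
    arr[idx] <- 1L
  }
  dataset4d(arr, time_labels = header$time_labels,
            sample_labels = header$sample_labels,
            length_scale = header$length_scale)
}

#' Read a 4-D colony stack
#'
#' Reads either the portable text container written by [write_dataset4d()]
#' or a MATLAB MAT v5 file. For MAT input the largest 4-D numeric or
#' logical array in the file is taken as the colony stack (dimension order
#' x, y, time, sample) and must be binary. MAT v7.3 (HDF5) files are not
#' supported.
#'
#' @param path path to a `.cg4d`/text container or a `.mat` file.
#' @param time_labels,sample_labels,length_scale optional overrides for
#'   MAT input, which carries no labelling.
#' @return a [dataset4d()].
#' @export
read_dataset4d <- function(path, time_labels = NULL, sample_labels = NULL,
                           length_scale = 1) {
  if (!file.exists(path)) abort(sprintf("dataset file not found: %s", path))
  if (tolower(tools::file_ext(path)) == "mat") {
    vars <- read_mat5(path)
    dims4 <- vapply(vars, function(v) length(dim(v)) == 4L, logical(1))
    if (!any(dims4)) abort("unrecognized dataset layout: no 4-D array in MAT file")
    sizes <- vapply(vars, length, numeric(1))
    arr <- vars[[which(dims4)[which.max(sizes[dims4])]]]
    return(dataset4d(arr, time_labels = time_labels,
                     sample_labels = sample_labels,
                     length_scale = length_scale))
  }
  read_portable_dataset4d(path)
}

#' Extract per-colony occupancy grids from a 4-D stack
#'
#' Builds one auto-centred [occupancy_grid()] per (sample, time) slice.
#' Empty slices (no occupied sites, e.g. before a colony appears) are
#' dropped with a message.
#'
#' @param ds a [dataset4d()].
#' @return a tibble with columns `colony`, `t`, `grid` (list column).
#' @export
grids_from_dataset4d <- function(ds) {
  stopifnot(inherits(ds, "dataset4d"))
  d <- dim(ds$array)
  out <- tidyr::expand_grid(s = seq_len(d[4]), ti = seq_len(d[3]))
  rows <- purrr::pmap(out, function(s, ti) {
    slice <- ds$array[, , ti, s]
    occ <- which(slice == 1L, arr.ind = TRUE)
    if (nrow(occ) == 0L) return(NULL)
    # first array dimension is x, second is y (already upward)
    g <- occupancy_grid(tibble(x = occ[, 1], y = occ[, 2]),
                        centre = c(mean(occ[, 1]), mean(occ[, 2])),
                        length_scale = ds$length_scale)
    tibble(colony = ds$sample_labels[[s]], t = ds$time_labels[[ti]],
           grid = list(g))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L) inform(sprintf("grids_from_dataset4d: %d empty slice(s) dropped", dropped))
  dplyr::bind_rows(rows)
}

# ---- minimal MAT v5 reader ------------------------------------------------
# Reads little-endian MAT v5 files containing plain N-D numeric/logical
# arrays (optionally zlib-compressed elements). Enough for colony image
# stacks; cells, structs, sparse and character arrays are skipped.

mat5_types <- c("1" = "int8", "2" = "uint8", "3" = "int16", "4" = "uint16",
                "5" = "int32", "6" = "uint32", "7" = "single", "9" = "double",
                "12" = "int64", "13" = "uint64")

read_mat5_numeric <- function(raw, type) {
  switch(mat5_types[[as.character(type)]],
    int8   = as.integer(readBin(raw, "integer", length(raw), size = 1, signed = TRUE)),
    uint8  = as.integer(readBin(raw, "integer", length(raw), size = 1, signed = FALSE)),
    int16  = readBin(raw, "integer", length(raw) / 2, size = 2, signed = TRUE, endian = "little"),
    uint16 = readBin(raw, "integer", length(raw) / 2, size = 2, signed = FALSE, endian = "little"),
    int32  = readBin(raw, "integer", length(raw) / 4, size = 4, endian = "little"),
    uint32 = readBin(raw, "integer", length(raw) / 4, size = 4, endian = "little"),
    single = readBin(raw, "numeric", length(raw) / 4, size = 4, endian = "little"),
    double = readBin(raw, "numeric", length(raw) / 8, size = 8, endian = "little"),
    # 64-bit integers: small magnitudes only (binary data), low word suffices
    int64  = readBin(raw, "integer", length(raw) / 4, size = 4,
                     endian = "little")[c(TRUE, FALSE)],
    uint64 = readBin(raw, "integer", length(raw) / 4, size = 4,
                     endian = "little")[c(TRUE, FALSE)]
  )
}

# Split a raw vector of MAT data elements into (type, data) chunks,
# honouring the small-element format and 8-byte padding.
mat5_elements <- function(raw) {
  out <- list()
  pos <- 1L
  n <- length(raw)
  while (pos + 7L <= n) {
    head32 <- readBin(raw[pos:(pos + 3L)], "integer", 1, size = 4, endian = "little")
    if (head32 == 0L) break
    small_size <- bitwAnd(bitwShiftR(head32, 16L), 0xFFFFL)
    if (small_size > 0L) {  # small element: type and size packed in one word
      type <- bitwAnd(head32, 0xFFFFL)
      data <- raw[(pos + 4L):(pos + 3L + small_size)]
      pos <- pos + 8L
    } else {
      type <- head32
      size <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", 1, size = 4, endian = "little")
      data <- if (size > 0L) raw[(pos + 8L):(pos + 7L + size)] else raw[0]
      pos <- pos + 8L + size
      if (pos %% 8L != 1L) pos <- pos + (8L - (pos - 1L) %% 8L)
    }
    out[[length(out) + 1L]] <- list(type = type, data = data)
  }
  out
}

parse_mat5_matrix <- function(raw) {
  sub <- mat5_elements(raw)
  if (length(sub) < 4L) return(NULL)
  flags <- readBin(sub[[1]]$data[1:4], "integer", 1, size = 4, endian = "little")
  class_id <- bitwAnd(flags, 0xFFL)
  # numeric classes 6..15 (double..uint64); logical arrays report a numeric
  # class with the logical flag set, which still parses below
  if (class_id < 6L || class_id > 15L) return(NULL)
  dims <- readBin(sub[[2]]$data, "integer", length(sub[[2]]$data) / 4,
                  size = 4, endian = "little")
  name <- rawToChar(sub[[3]]$data[sub[[3]]$data != as.raw(0)])
  type <- sub[[4]]$type
  if (!as.character(type) %in% names(mat5_types)) return(NULL)
  values <- read_mat5_numeric(sub[[4]]$data, type)
  if (length(values) != prod(dims)) return(NULL)
  arr <- array(values, dim = dims)
  setNames(list(arr), name)
}

read_mat5 <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 128L) abort("unrecognized dataset layout: file too small for MAT v5")
  endian <- rawToChar(raw[127:128])
  if (identical(endian, "MI")) abort("big-endian MAT files are not supported")
  if (!identical(endian, "IM")) {
    abort("unrecognized dataset layout: not a MAT v5 file (v7.3/HDF5 is not supported)")
  }
  vars <- list()
  pos <- 129L
  n <- length(raw)
  while (pos + 7L <= n) {
    type <- readBin(raw[pos:(pos + 3L)], "integer", 1, size = 4, endian = "little")
    size <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", 1, size = 4, endian = "little")
    if (size < 0L || pos + 7L + size > n) break
    data <- raw[(pos + 8L):(pos + 7L + size)]
    if (type == 15L) {  # zlib-compressed element; decompress then re-parse
      data <- tryCatch(memDecompress(data, type = "gzip"), error = function(e) NULL)
      if (!is.null(data)) {
        inner_type <- readBin(data[1:4], "integer", 1, size = 4, endian = "little")
        if (inner_type == 14L) {
          v <- parse_mat5_matrix(data[-(1:8)])
          if (!is.null(v)) vars <- c(vars, v)
        }
      }
    } else if (type == 14L) {
      v <- parse_mat5_matrix(data)
      if (!is.null(v)) vars <- c(vars, v)
    }
    pos <- pos + 8L + size
    if (pos %% 8L != 1L) pos <- pos + (8L - (pos - 1L) %% 8L)
  }
  if (length(vars) == 0L) abort("unrecognized dataset layout: no readable array in MAT file")
  vars
}
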