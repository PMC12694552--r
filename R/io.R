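#' Read a directory of CT slice images into a voxel volume
#'
#' Slices are single-channel BMP, PNG or TIFF images, one per cross-section,
#' with zero-padded numeric suffixes so that plain ascending filename order
#' is slice order. All slices must share one dimension and one channel.
#' Axis order of the result is `(slice, row, column)`.
#'
#' @param directory_path directory containing the slice images.
#' @param voxel_size_um physical voxel edge length in microns (isotropic).
#' @return A [voxel_volume].
#' @export
read_slice_stack <- function(directory_path, voxel_size_um) {
  if (!dir.exists(directory_path)) stop("no such directory: ", directory_path)
  files <- list.files(directory_path,
                      pattern = "\\.(bmp|png|tif|tiff)$", ignore.case = TRUE)
  if (length(files) == 0L) stop("no readable slice images in ", directory_path)
  files <- sort(files)
  slices <- lapply(file.path(directory_path, files), read_slice_image)
  dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("dimension mismatch across slices (",
         paste(unique(apply(dims, 2, paste, collapse = "x")), collapse = ", "), ")")
  bit_depth <- max(vapply(slices, function(s) s$bit_depth, integer(1)))
  nz <- length(slices)
  arr <- array(0L, dim = c(nz, dims[1, 1], dims[2, 1]))
  for (i in seq_len(nz)) arr[i, , ] <- slices[[i]]$pixels
  voxel_volume(arr, voxel_size_um, bit_depth = bit_depth)
}

# read one slice -> list(pixels = integer matrix (row, col), bit_depth)
read_slice_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    if (length(dim(img)) == 3L) stop("multi-channel image not supported: ", path)
    info <- attr(img, "info")
    bits <- if (!is.null(info$bit.depth)) as.integer(info$bit.depth) else 8L
    bits <- if (bits > 8L) 16L else 8L
    list(pixels = matrix(as.integer(round(img * (2^bits - 1))), nrow(img), ncol(img)),
         bit_depth = bits)
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) stop("multi-channel image not supported: ", path)
    bits <- if (max(img) > 255) 16L else if (attr_bits_tiff(path) > 8L) 16L else 8L
    list(pixels = matrix(as.integer(img), nrow(img), ncol(img)), bit_depth = bits)
  } else if (ext == "bmp") {
    read_bmp_gray(path)
  } else stop("unsupported slice format: ", path)
}

attr_bits_tiff <- function(path) {
  img <- tiff::readTIFF(path, info = TRUE)
  info <- attr(img, "info")
  if (!is.null(info$bits.per.sample)) as.integer(info$bits.per.sample) else 8L
}

# Minimal uncompressed 8-bit BMP reader (grayscale palette or gray triplets).
# CT vendors export plain uncompressed BMP; compressed dialects are rejected.
read_bmp_gray <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 2)
  if (!identical(rawToChar(hdr), "BM")) stop("not a BMP file: ", path)
  readBin(con, "integer", 3, size = 4)                      # size + reserved + offset (re-read below)
  seek(con, 10); offset <- readBin(con, "integer", 1, size = 4)
  hdrsz <- readBin(con, "integer", 1, size = 4)
  if (hdrsz < 40) stop("unsupported BMP header: ", path)
  w <- readBin(con, "integer", 1, size = 4)
  h <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 1, size = 2)                      # planes
  bpp <- readBin(con, "integer", 1, size = 2)
  comp <- readBin(con, "integer", 1, size = 4)
  if (comp != 0) stop("compressed BMP not supported: ", path)
  if (bpp != 8) stop("only 8-bit grayscale BMP supported (got ", bpp, "-bit): ", path)
  flip <- h > 0; h <- abs(h)
  seek(con, offset)
  rowbytes <- ((w + 3) %/% 4) * 4
  px <- readBin(con, "integer", rowbytes * h, size = 1, signed = FALSE)
  m <- matrix(px, nrow = rowbytes)[seq_len(w), , drop = FALSE]  # cols = stored rows
  m <- t(m)                                                 # (stored row, col)
  if (flip) m <- m[rev(seq_len(h)), , drop = FALSE]         # bottom-up storage
  list(pixels = m, bit_depth = 8L)
}

# Minimal uncompressed 8-bit grayscale BMP writer (used by simulate + tests)
write_bmp_gray <- function(pixels, path) {
  stopifnot(is.matrix(pixels), max(pixels) <= 255, min(pixels) >= 0)
  h <- nrow(pixels); w <- ncol(pixels)
  rowbytes <- ((w + 3) %/% 4) * 4
  palette <- raw(1024)                                      # B,G,R,0 gray ramp
  for (i in 0:255) palette[i * 4 + 1:3] <- as.raw(i)
  offset <- 14L + 40L + 1024L
  filesz <- offset + rowbytes * h
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(c(filesz, 0L, offset)), con, size = 4)
  writeBin(40L, con, size = 4)
  writeBin(as.integer(c(w, h)), con, size = 4)
  writeBin(c(1L, 8L), con, size = 2)
  writeBin(as.integer(c(0L, rowbytes * h, 2835L, 2835L, 256L, 0L)), con, size = 4)
  writeBin(palette, con)
  for (r in rev(seq_len(h))) {                              # bottom-up rows
    row <- as.integer(pixels[r, ])
    writeBin(as.raw(c(row, integer(rowbytes - w))), con)
  }
  invisible(path)
}

#' Write a label volume as an indexed slice stack
#'
#' One 8-bit PNG per slice (pixel value = tissue code) plus a
#' `metadata.txt` sidecar holding the voxel size and label legend, so that
#' [read_label_volume()] round-trips losslessly.
#'
#' @param lv a [label_volume].
#' @param path output directory (created if needed).
#' @export
write_label_volume <- function(lv, path) {
  stopifnot(inherits(lv, "label_volume"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path)
  nz <- dim(lv$labels)[1]
  for (i in seq_len(nz)) {
    sl <- lv$labels[i, , , drop = TRUE]
    if (is.null(dim(sl))) sl <- matrix(sl, dim(lv$labels)[2], dim(lv$labels)[3])
    png::writePNG(sl / 255, file.path(path, sprintf("slice_%05d.png", i - 1L)))
  }
  meta <- c(
    sprintf("voxel_size_um=%.17g", lv$voxel_size_um),
    sprintf("n_slices=%d", nz),
    paste0("label_", names(TISSUE_LABELS), "=", TISSUE_LABELS)
  )
  writeLines(meta, file.path(path, "metadata.txt"))
  invisible(path)
}

#' Read a label volume written by [write_label_volume()]
#'
#' @param path directory containing `slice_*.png` and `metadata.txt`.
#' @return A [label_volume].
#' @export
read_label_volume <- function(path) {
  metafile <- file.path(path, "metadata.txt")
  if (!file.exists(metafile)) stop("missing metadata.txt in ", path)
  meta <- read_sidecar(metafile)
  files <- sort(list.files(path, pattern = "^slice_\\d+\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no label slices in ", path)
  slices <- lapply(files, function(f) round(png::readPNG(f) * 255))
  d2 <- dim(slices[[1]])
  arr <- array(0L, dim = c(length(slices), d2[1], d2[2]))
  for (i in seq_along(slices)) arr[i, , ] <- as.integer(slices[[i]])
  label_volume(arr, as.numeric(meta[["voxel_size_um"]]))
}

read_sidecar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
}

# ---- checked CSV tables -----------------------------------------------------

#' Define a table schema for checked CSV reading
#'
#' @param columns named list; each element a list with `type`
#'   (`"numeric"` or `"character"`) and optional `check`, a vectorized
#'   predicate on the column values (NA passes unless `na_ok = FALSE`).
#' @return A `table_schema` object for [read_csv_checked()].
#' @export
table_schema <- function(columns) {
  structure(list(columns = columns), class = "table_schema")
}

#' Read a CSV against a schema
#'
#' Missing required columns raise a schema error; values failing type
#' coercion or a domain predicate raise an error listing the offending
#' rows (and column).
#'
#' @param path CSV file with a header row.
#' @param schema a [table_schema()].
#' @return A data.frame with typed columns.
#' @export
read_csv_checked <- function(path, schema) {
  stopifnot(inherits(schema, "table_schema"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  missing <- setdiff(names(schema$columns), names(df))
  if (length(missing))
    stop("schema error: missing required column(s): ", paste(missing, collapse = ", "))
  for (nm in names(schema$columns)) {
    spec <- schema$columns[[nm]]
    col <- df[[nm]]
    col[col == ""] <- NA_character_
    if (identical(spec$type, "numeric")) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad))
        stop("row error in column '", nm, "': unparseable numeric at row(s) ",
             paste(bad, collapse = ", "))
      df[[nm]] <- num
    }
    if (!is.null(spec$check)) {
      vals <- df[[nm]]
      ok <- spec$check(vals)
      ok[is.na(vals)] <- if (isFALSE(spec$na_ok)) FALSE else TRUE
      bad <- which(!ok)
      if (length(bad))
        stop("row error in column '", nm, "': value domain violated at row(s) ",
             paste(bad, collapse = ", "), " (e.g. '", df[[nm]][bad[1]], "')")
    }
  }
  df
}

#' Read a genetic map CSV
#'
#' Columns `chrom,marker,cM,Mb`; within each chromosome both the cM and Mb
#' positions must be non-decreasing in file order (genetic and physical
#' order must agree), and each chromosome needs at least two markers.
#'
#' @param path CSV file.
#' @return A `genetic_map` data.frame.
#' @export
read_genetic_map <- function(path) {
  schema <- table_schema(list(
    chrom  = list(type = "character", na_ok = FALSE, check = function(x) nzchar(x)),
    marker = list(type = "character", na_ok = FALSE, check = function(x) nzchar(x)),
    cM     = list(type = "numeric", na_ok = FALSE, check = function(x) x >= 0),
    Mb     = list(type = "numeric", na_ok = FALSE, check = function(x) x >= 0)
  ))
  df <- read_csv_checked(path, schema)
  validate_genetic_map(df)
}

#' Validate (and class) a genetic map data.frame
#' @param df data.frame with columns chrom, marker, cM, Mb.
#' @return The same data.frame with class `genetic_map` prepended.
#' @export
validate_genetic_map <- function(df) {
  stopifnot(all(c("chrom", "marker", "cM", "Mb") %in% names(df)))
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (nrow(sub) < 2L) stop("chromosome ", ch, " has fewer than 2 markers")
    if (is.unsorted(sub$cM))
      stop("ordering error: cM positions not non-decreasing on chromosome ", ch)
    if (is.unsorted(sub$Mb))
      stop("ordering error: Mb positions not non-decreasing on chromosome ", ch)
  }
  if (anyDuplicated(df$marker)) stop("duplicated marker names")
  class(df) <- unique(c("genetic_map", class(df)))
  df
}

#' Read a RIL genotype matrix CSV
#'
#' First column `line_id`, then one column per marker with codes `A`
#' (parent-1 homozygote), `B` (parent-2 homozygote) or `NA`/empty for
#' missing. RILs are treated as fully inbred: no heterozygote class.
#'
#' @param path CSV file.
#' @return data.frame with `line_id` plus character marker columns.
#' @export
read_genotype_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (!"line_id" %in% names(df)) stop("schema error: missing required column(s): line_id")
  markers <- setdiff(names(df), "line_id")
  if (length(markers) == 0L) stop("schema error: no marker columns")
  for (m in markers) {
    col <- df[[m]]
    col[col == "" | col == "NA"] <- NA_character_
    bad <- which(!is.na(col) & !col %in% c("A", "B"))
    if (length(bad))
      stop("row error: genotype code outside {A,B,NA} at row ", bad[1],
           ", marker '", m, "' (value '", col[bad[1]], "')")
    df[[m]] <- col
    miss <- mean(is.na(col))
    if (miss >= 0.5) stop("marker '", m, "' has missing fraction >= 0.5")
  }
  df
}

#' Read a differential-expression table CSV
#'
#' Columns `gene_id,chrom,pos_mb,log2fc,pvalue`; p-values must lie in (0, 1].
#'
#' @param path CSV file.
#' @return A data.frame with a derived `direction` column (up/down by the
#'   sign of `log2fc`).
#' @export
read_deg_table <- function(path) {
  schema <- table_schema(list(
    gene_id = list(type = "character", na_ok = FALSE, check = function(x) nzchar(x)),
    chrom   = list(type = "character", na_ok = FALSE, check = function(x) nzchar(x)),
    pos_mb  = list(type = "numeric", na_ok = FALSE, check = function(x) x >= 0),
    log2fc  = list(type = "numeric", na_ok = FALSE, check = function(x) is.finite(x)),
    pvalue  = list(type = "numeric", na_ok = FALSE, check = function(x) x > 0 & x <= 1)
  ))
  df <- read_csv_checked(path, schema)
  df$direction <- ifelse(df$log2fc >= 0, "up", "down")
  df
}

#' Read a per-grain trait table CSV
#'
#' Requires `line_id`; all other columns except `grain_id` are numeric traits.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"line_id" %in% names(df)) stop("schema error: missing required column(s): line_id")
  traits <- setdiff(names(df), c("line_id", "grain_id"))
  for (nm in traits) {
    suppressWarnings(num <- as.numeric(df[[nm]]))
    bad <- which(!is.na(df[[nm]]) & is.na(num))
    if (length(bad))
      stop("row error in column '", nm, "': unparseable numeric at row(s) ",
           paste(bad, collapse = ", "))
    df[[nm]] <- num
  }
  df
}
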