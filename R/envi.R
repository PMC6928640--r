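# ENVI raster I/O. One canonical dialect: band-sequential (BSQ), unsigned
# 16-bit little-endian (ENVI data type 12), wavelengths in nm in the header.

envi_header_path <- function(path) {
  if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
}

#' Write a spectral cube as an ENVI header/binary pair
#'
#' The binary is band-sequential (BSQ): for each band, pixels in row-major
#' order. DN values are stored as unsigned 16-bit little-endian integers
#' (ENVI data type 12), which holds 12-bit data exactly. The text header
#' `<path>.hdr` carries dimensions, interleave, the wavelength table (nm)
#' and the acquisition metadata.
#'
#' @param cube A valid [spectral_cube()].
#' @param path Path for the binary file; the header is written alongside as
#'   `<path>.hdr`.
#' @return `path`, invisibly.
#' @seealso [read_cube()]
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  # revalidate: cubes may have been edited in place
  cube <- spectral_cube(cube$dn, cube$wavelengths, cube$bit_depth,
                        cube$platform_height_mm, cube$acquisition_id)
  d <- dim(cube$dn)
  hdr <- c(
    "ENVI",
    "description = {weedspec spectral cube}",
    sprintf("samples = %d", d[3L]),
    sprintf("lines = %d", d[2L]),
    sprintf("bands = %d", d[1L]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 12",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("bit depth = %d", cube$bit_depth),
    sprintf("platform height mm = %s",
            format(cube$platform_height_mm, scientific = FALSE)),
    sprintf("acquisition id = %s", cube$acquisition_id),
    paste0("wavelength = {",
           paste(sprintf("%.17g", cube$wavelengths), collapse = ", "),
           "}"))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing", call. = FALSE))
  on.exit(close(con), add = TRUE)
  # BSQ with row-major pixels: aperm to (col, row, band) so that writing in
  # R's column-major order emits sample-fastest, then line, then band.
  vals <- as.integer(round(aperm(cube$dn, c(3L, 2L, 1L))))
  writeBin(vals, con, size = 2L, endian = "little")
  writeLines(hdr, envi_header_path(path))
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  if (!file.exists(hdr_path))
    stop("missing ENVI header: ", hdr_path, call. = FALSE)
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  if (!grepl("^ENVI", txt))
    stop("not an ENVI header (missing ENVI magic): ", hdr_path, call. = FALSE)
  get_field <- function(key, required = TRUE) {
    # value is either up to end-of-line or a brace-delimited block
    pat <- paste0("(?mi)^", key, "\\s*=\\s*(\\{[^}]*\\}|[^\n]*)")
    m <- regmatches(txt, regexpr(pat, txt, perl = TRUE))
    if (length(m) == 0L) {
      if (required) stop("ENVI header missing field '", key, "'",
                         call. = FALSE)
      return(NULL)
    }
    val <- sub(paste0("(?mi)^", key, "\\s*=\\s*"), "", m, perl = TRUE)
    trimws(gsub("[{}]", "", val))
  }
  num <- function(key) as.numeric(get_field(key))
  list(samples = num("samples"), lines = num("lines"), bands = num("bands"),
       data_type = num("data type"),
       interleave = tolower(get_field("interleave")),
       byte_order = num("byte order"),
       bit_depth = {
         bd <- get_field("bit depth", required = FALSE)
         if (is.null(bd)) 12L else as.integer(bd)
       },
       platform_height_mm = {
         ph <- get_field("platform height mm", required = FALSE)
         if (is.null(ph)) NA_real_ else as.numeric(ph)
       },
       acquisition_id = {
         id <- get_field("acquisition id", required = FALSE)
         if (is.null(id)) basename(hdr_path) else id
       },
       wavelengths = as.numeric(strsplit(get_field("wavelength"),
                                         ",")[[1L]]))
}

#' Read an ENVI header/binary pair as a spectral cube
#'
#' Supports the dialect written by [write_cube()]: BSQ interleave, unsigned
#' 16-bit little-endian samples (data type 12). The declared dimensions are
#' checked against the binary file size; a mismatch is an integrity error.
#'
#' @param path Path to the binary file (header expected at `<path>.hdr`)
#'   or to the `.hdr` itself.
#' @return A [spectral_cube()].
#' @export
read_cube <- function(path) {
  hdr_path <- envi_header_path(path)
  bin_path <- sub("\\.hdr$", "", path)
  h <- parse_envi_header(hdr_path)
  if (h$data_type != 12 || h$interleave != "bsq" || h$byte_order != 0)
    stop("unsupported ENVI dialect (need data type 12, bsq, byte order 0)",
         call. = FALSE)
  if (length(h$wavelengths) != h$bands)
    stop("integrity error: header wavelength table has ",
         length(h$wavelengths), " entries for ", h$bands, " bands",
         call. = FALSE)
  n_expect <- h$bands * h$lines * h$samples
  n_bytes <- file.info(bin_path)$size
  if (is.na(n_bytes) || n_bytes != 2 * n_expect)
    stop("integrity error: binary holds ", n_bytes %/% 2,
         " samples but header declares ", n_expect, call. = FALSE)
  con <- file(bin_path, "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, "integer", n = n_expect, size = 2L,
                  signed = FALSE, endian = "little")
  dn <- aperm(array(as.double(vals), dim = c(h$samples, h$lines, h$bands)),
              c(3L, 2L, 1L))
  spectral_cube(dn, h$wavelengths, bit_depth = h$bit_depth,
                platform_height_mm = h$platform_height_mm,
                acquisition_id = h$acquisition_id)
}

#' Write a label image as a single-band ENVI raster
#'
#' Class labels are encoded as integer codes (0 = soil, then classes in
#' `legend` order); the legend is written as a JSON sidecar `<path>.json`.
#'
#' @param labels Character matrix of per-pixel labels (`"soil"` or a class).
#' @param path Binary output path.
#' @param legend Character vector of plant class names defining the coding.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(labels, path,
                              legend = sort(setdiff(unique(c(labels)),
                                                    "soil"))) {
  codes <- match(labels, legend, nomatch = 0L)  # soil -> 0
  dim(codes) <- dim(labels)
  hdr <- c("ENVI", sprintf("samples = %d", ncol(labels)),
           sprintf("lines = %d", nrow(labels)), "bands = 1",
           "header offset = 0", "file type = ENVI Classification",
           "data type = 12", "interleave = bsq", "byte order = 0")
  con <- file(path, "wb"); on.exit(close(con), add = TRUE)
  writeBin(as.integer(t(codes)), con, size = 2L, endian = "little")
  writeLines(hdr, envi_header_path(path))
  jsonlite::write_json(list(soil = 0L,
                            classes = as.list(stats::setNames(
                              seq_along(legend), legend))),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
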