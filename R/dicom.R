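# Minimal DICOM support: uncompressed single-frame CT slices, explicit VR
# little endian (implicit VR is accepted on read for the tags used here).
# Covers what frame-CT planning needs: geometry tags, rescale, pixel data.

.dcm_tags <- list(
  sop_class = c(0x0008, 0x0016), sop_instance = c(0x0008, 0x0018),
  modality = c(0x0008, 0x0060),
  study_uid = c(0x0020, 0x000D), series_uid = c(0x0020, 0x000E),
  instance_number = c(0x0020, 0x0013),
  ipp = c(0x0020, 0x0032), iop = c(0x0020, 0x0037),
  samples = c(0x0028, 0x0002), photometric = c(0x0028, 0x0004),
  rows = c(0x0028, 0x0010), cols = c(0x0028, 0x0011),
  pixel_spacing = c(0x0028, 0x0030),
  bits_alloc = c(0x0028, 0x0100), bits_stored = c(0x0028, 0x0101),
  high_bit = c(0x0028, 0x0102), pixel_rep = c(0x0028, 0x0103),
  intercept = c(0x0028, 0x1052), slope = c(0x0028, 0x1053),
  pixel_data = c(0x7FE0, 0x0010))

# VR lookup for implicit-VR fallback, keyed "gggg,eeee"
.dcm_vr_dict <- c(
  "0008,0016" = "UI", "0008,0018" = "UI", "0008,0060" = "CS",
  "0020,000d" = "UI", "0020,000e" = "UI", "0020,0013" = "IS",
  "0020,0032" = "DS", "0020,0037" = "DS",
  "0028,0002" = "US", "0028,0004" = "CS",
  "0028,0010" = "US", "0028,0011" = "US", "0028,0030" = "DS",
  "0028,0100" = "US", "0028,0101" = "US", "0028,0102" = "US",
  "0028,0103" = "US", "0028,1052" = "DS", "0028,1053" = "DS",
  "7fe0,0010" = "OW")

.dcm_uint16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
.dcm_uint32 <- function(raw4)
  as.numeric(raw4[1]) + 256 * as.numeric(raw4[2]) +
  65536 * as.numeric(raw4[3]) + 16777216 * as.numeric(raw4[4])

# parse one slice file into a list of tag values
.dcm_read_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  pos <- 1L
  if (length(raw) > 132 && rawToChar(raw[129:132]) == "DICM") pos <- 133L
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  out <- list()
  while (pos + 8 <= length(raw) + 1) {
    group <- .dcm_uint16(raw[pos:(pos + 1)])
    elem <- .dcm_uint16(raw[(pos + 2):(pos + 3)])
    pos <- pos + 4L
    vr <- rawToChar(raw[pos:(pos + 1)])
    if (grepl("^[A-Z]{2}$", vr)) {
      if (vr %in% long_vrs) {
        len <- .dcm_uint32(raw[(pos + 4):(pos + 7)])
        pos <- pos + 8L
      } else {
        len <- .dcm_uint16(raw[(pos + 2):(pos + 3)])
        pos <- pos + 4L
      }
    } else {  # implicit VR
      len <- .dcm_uint32(raw[pos:(pos + 3)])
      pos <- pos + 4L
      vr <- unname(.dcm_vr_dict[sprintf("%04x,%04x", group, elem)])
      if (is.na(vr) || is.null(vr)) vr <- "UN"
    }
    if (len > length(raw) - pos + 1)
      stop("corrupt DICOM element in ", path, call. = FALSE)
    value_raw <- if (len > 0) raw[pos:(pos + len - 1)] else raw(0)
    pos <- pos + as.integer(len)
    key <- sprintf("%04x,%04x", group, elem)
    if (group == 0x0002) next  # file meta: only needed to advance
    if (vr %in% c("UI", "CS", "LO", "SH", "DS", "IS"))
      value_raw <- value_raw[value_raw != as.raw(0)]  # strip UI padding
    out[[key]] <- switch(vr,
      UI = , CS = , LO = , SH = sub("\\s+$", "", rawToChar(value_raw)),
      DS = as.numeric(strsplit(trimws(rawToChar(value_raw)),
                               "\\\\")[[1]]),
      IS = as.integer(trimws(rawToChar(value_raw))),
      US = .dcm_uint16(value_raw[1:2]),
      OW = value_raw,
      value_raw)
    if (group == 0x7FE0 && elem == 0x0010) break
  }
  out
}

#' Read a DICOM series directory as a CT volume
#'
#' Reads every `.dcm` file in `path` (uncompressed, little-endian,
#' single-frame slices), verifies that they form exactly one series with
#' consistent geometry, sorts the slices along the slice normal, applies the
#' rescale slope/intercept to obtain HU, and converts DICOM patient (LPS)
#' coordinates to RAS by negating the first two world axes.
#'
#' @param path Directory containing one DICOM series.
#' @return A [ct_volume()].
#' @export
read_dicom_series <- function(path) {
  files <- list.files(path, pattern = "\\.dcm$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) < 2)
    stop("read_dicom_series: need at least 2 slice files in ", path,
         call. = FALSE)
  slices <- lapply(files, .dcm_read_file)
  get <- function(s, tag) s[[sprintf("%04x,%04x", .dcm_tags[[tag]][1],
                                     .dcm_tags[[tag]][2])]]
  uids <- vapply(slices, function(s) get(s, "series_uid"), "")
  if (length(unique(uids)) != 1)
    stop("read_dicom_series: directory contains ", length(unique(uids)),
         " interleaved series; expected exactly one", call. = FALSE)
  rows <- vapply(slices, function(s) get(s, "rows"), 0)
  cols <- vapply(slices, function(s) get(s, "cols"), 0)
  if (length(unique(rows)) != 1 || length(unique(cols)) != 1)
    stop("read_dicom_series: mixed slice dimensions", call. = FALSE)
  iop <- get(slices[[1]], "iop")
  row_dir <- iop[1:3]; col_dir <- iop[4:6]
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])
  pos <- t(vapply(slices, function(s) get(s, "ipp"), numeric(3)))
  proj <- drop(pos %*% normal)
  ord <- order(proj)
  slices <- slices[ord]; pos <- pos[ord, , drop = FALSE]; proj <- proj[ord]
  gaps <- diff(proj)
  if (any(gaps <= 0))
    stop("read_dicom_series: duplicate slice positions", call. = FALSE)
  med <- stats::median(gaps)
  if (max(abs(gaps - med)) > 0.01 * med)
    stop("read_dicom_series: non-uniform slice spacing beyond 1% tolerance",
         call. = FALSE)
  ps <- get(slices[[1]], "pixel_spacing")  # (between-rows, between-cols)
  nr <- rows[1]; nc <- cols[1]
  vox <- array(0, dim = c(nc, nr, length(slices)))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    pix <- readBin(get(s, "pixel_data"), "integer", n = nr * nc, size = 2,
                   signed = TRUE, endian = "little")
    slope <- get(s, "slope"); icept <- get(s, "intercept")
    if (is.null(slope)) slope <- 1
    if (is.null(icept)) icept <- 0
    vox[, , k] <- matrix(pix * slope + icept, nrow = nc)
  }
  # LPS affine: i follows the row direction (column index), j the column
  # direction (row index), k the slice normal
  aff <- diag(4)
  aff[1:3, 1] <- row_dir * ps[2]
  aff[1:3, 2] <- col_dir * ps[1]
  aff[1:3, 3] <- normal * med
  aff[1:3, 4] <- pos[1, ]
  aff[1:2, ] <- -aff[1:2, ]  # LPS -> RAS
  ct_volume(vox, aff)
}

.dcm_elem <- function(con, group, elem, vr, value) {
  writeBin(as.integer(c(group, elem)), con, size = 2, endian = "little")
  long <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  if (vr %in% c("UI", "CS", "DS", "IS", "LO", "SH")) {
    val <- charToRaw(value)
    if (length(val) %% 2 == 1)
      val <- c(val, if (vr == "UI") as.raw(0) else charToRaw(" "))
  } else if (vr == "US") {
    val <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else {
    val <- value  # raw
  }
  writeChar(vr, con, nchars = 2, eos = NULL)
  if (long) {
    writeBin(as.integer(0), con, size = 2, endian = "little")
    writeBin(length(val), con, size = 4, endian = "little")
  } else {
    writeBin(length(val), con, size = 2, endian = "little")
  }
  if (length(val)) writeBin(val, con)
}

.dcm_uid_root <- "1.2.826.0.1.3680043.9999"

#' Write a CT volume as a DICOM series
#'
#' Writes one explicit-VR little-endian single-frame CT file per axial slice
#' (signed 16-bit pixels holding HU directly, rescale slope 1 / intercept 0).
#' RAS world coordinates are converted to the DICOM patient (LPS) convention
#' by negating the first two axes.
#'
#' @param v A [ct_volume()].
#' @param dir Output directory (created if missing).
#' @param series_uid Series instance UID; a fixed-root default is generated.
#' @return `dir`, invisibly.
#' @export
write_dicom_series <- function(v, dir,
                               series_uid = paste0(.dcm_uid_root, ".1.1")) {
  stopifnot(inherits(v, "ct_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aff_lps <- v$affine
  aff_lps[1:2, ] <- -aff_lps[1:2, ]
  row_dir <- aff_lps[1:3, 1] / v$spacing[1]
  col_dir <- aff_lps[1:3, 2] / v$spacing[2]
  nr <- v$dims[2]; nc <- v$dims[1]
  study_uid <- paste0(.dcm_uid_root, ".1")
  for (k in seq_len(v$dims[3])) {
    ipp <- aff_lps[1:3, ] %*% c(0, 0, k - 1, 1)
    sl <- v$voxels[, , k]
    pix <- as.integer(pmax(pmin(round(sl), 32767), -32768))
    f <- file(file.path(dir, sprintf("slice%04d.dcm", k)), "wb")
    writeBin(raw(128), f)
    writeChar("DICM", f, nchars = 4, eos = NULL)
    # file meta group (group length computed for the fixed layout below)
    ts <- "1.2.840.10008.1.2.1"
    sop_class <- "1.2.840.10008.5.1.4.1.1.2"
    sop_inst <- sprintf("%s.2.%d", .dcm_uid_root, k)
    meta <- local({
      tmp <- rawConnection(raw(0), "wb")
      .dcm_elem(tmp, 0x0002, 0x0001, "OB", as.raw(c(0, 1)))
      .dcm_elem(tmp, 0x0002, 0x0002, "UI", sop_class)
      .dcm_elem(tmp, 0x0002, 0x0003, "UI", sop_inst)
      .dcm_elem(tmp, 0x0002, 0x0010, "UI", ts)
      out <- rawConnectionValue(tmp); close(tmp); out
    })
    .dcm_elem(f, 0x0002, 0x0000, "UL",
              writeBin(length(meta), raw(), size = 4, endian = "little"))
    writeBin(meta, f)
    .dcm_elem(f, 0x0008, 0x0016, "UI", sop_class)
    .dcm_elem(f, 0x0008, 0x0018, "UI", sop_inst)
    .dcm_elem(f, 0x0008, 0x0060, "CS", "CT")
    .dcm_elem(f, 0x0020, 0x000D, "UI", study_uid)
    .dcm_elem(f, 0x0020, 0x000E, "UI", series_uid)
    .dcm_elem(f, 0x0020, 0x0013, "IS", as.character(k))
    .dcm_elem(f, 0x0020, 0x0032, "DS",
              paste(sprintf("%.8f", ipp), collapse = "\\"))
    .dcm_elem(f, 0x0020, 0x0037, "DS",
              paste(sprintf("%.8f", c(row_dir, col_dir)), collapse = "\\"))
    .dcm_elem(f, 0x0028, 0x0002, "US", 1)
    .dcm_elem(f, 0x0028, 0x0004, "CS", "MONOCHROME2")
    .dcm_elem(f, 0x0028, 0x0010, "US", nr)
    .dcm_elem(f, 0x0028, 0x0011, "US", nc)
    .dcm_elem(f, 0x0028, 0x0030, "DS",
              sprintf("%.8f\\%.8f", v$spacing[2], v$spacing[1]))
    .dcm_elem(f, 0x0028, 0x0100, "US", 16)
    .dcm_elem(f, 0x0028, 0x0101, "US", 16)
    .dcm_elem(f, 0x0028, 0x0102, "US", 15)
    .dcm_elem(f, 0x0028, 0x0103, "US", 1)
    .dcm_elem(f, 0x0028, 0x1052, "DS", "0")
    .dcm_elem(f, 0x0028, 0x1053, "DS", "1")
    # pixel data: column index fastest, matching the in-memory [i, j] layout
    .dcm_elem(f, 0x7FE0, 0x0010, "OW",
              writeBin(pix, raw(), size = 2, endian = "little"))
    close(f)
  }
  invisible(dir)
}
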