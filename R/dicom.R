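# Minimal DICOM I/O for raw-encoded 16-bit monochrome portal images.
# Writes Explicit VR Little Endian (transfer syntax 1.2.840.10008.1.2.1)
# secondary-capture objects and reads back the subset it writes. Geometry
# and acquisition metadata (seed, beam-axis origin, SDD/SAD) travel in the
# Image Comments element as JSON, so files are self-describing.

dcm_uid_root <- "1.2.826.0.1.3680043.10.1437"

dcm_pad <- function(x, pad = as.raw(0x20)) {
  if (length(x) %% 2 == 1) c(x, pad) else x
}

dcm_element <- function(group, element, vr, value_raw) {
  tag <- writeBin(as.integer(c(group, element)), raw(), size = 2,
                  endian = "little")
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    len <- writeBin(length(value_raw), raw(), size = 4, endian = "little")
    c(tag, charToRaw(vr), as.raw(c(0, 0)), len, value_raw)
  } else {
    len <- writeBin(as.integer(length(value_raw)), raw(), size = 2,
                    endian = "little")
    c(tag, charToRaw(vr), len, value_raw)
  }
}

dcm_str <- function(group, element, vr, value) {
  pad <- if (vr == "UI") as.raw(0x00) else as.raw(0x20)
  dcm_element(group, element, vr, dcm_pad(charToRaw(value), pad))
}

dcm_us <- function(group, element, value) {
  dcm_element(group, element, "US",
              writeBin(as.integer(value), raw(), size = 2, endian = "little"))
}

#' Write an EPID image as a DICOM file
#'
#' Stores the raw-encoded 16-bit pixel matrix (row-major, little endian)
#' as an Explicit-VR Little-Endian monochrome secondary-capture object.
#' The panel geometry and the acquisition metadata are serialized as JSON
#' into the Image Comments element so [read_dicom()] can reconstruct the
#' full [epid_image()].
#'
#' @param image An [epid_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(image, path) {
  g <- image$geometry
  instance_uid <- sprintf("%s.%d.%.0f", dcm_uid_root, nrow(image$stored),
                          sum(as.double(image$stored)) %% 1e9)
  sop_class <- "1.2.840.10008.5.1.4.1.1.7"
  comments <- jsonlite::toJSON(
    list(geometry = list(sdd_cm = g$sdd_cm, sad_cm = g$sad_cm,
                         pixel_pitch_panel_mm = g$pixel_pitch_panel_mm,
                         rows = g$rows, cols = g$cols, origin = g$origin),
         meta = image$meta),
    auto_unbox = TRUE, digits = NA, null = "null")

  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    dcm_str(0x0002, 0x0002, "UI", sop_class),
    dcm_str(0x0002, 0x0003, "UI", instance_uid),
    dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    dcm_str(0x0002, 0x0012, "UI", paste0(dcm_uid_root, ".1"))
  )
  meta <- c(
    dcm_element(0x0002, 0x0000, "UL",
                writeBin(length(meta_body), raw(), size = 4,
                         endian = "little")),
    meta_body
  )

  # DICOM pixel data is row-major; R matrices are column-major
  pixels <- writeBin(as.integer(t(image$stored)), raw(), size = 2,
                     endian = "little")
  dataset <- c(
    dcm_str(0x0008, 0x0016, "UI", sop_class),
    dcm_str(0x0008, 0x0018, "UI", instance_uid),
    dcm_str(0x0008, 0x0060, "CS", "RTIMAGE"),
    dcm_str(0x0008, 0x0070, "LO", "mlcqa synthetic linac"),
    dcm_str(0x0020, 0x4000, "LT", as.character(comments)),
    dcm_us(0x0028, 0x0002, 1),
    dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_us(0x0028, 0x0010, g$rows),
    dcm_us(0x0028, 0x0011, g$cols),
    dcm_str(0x0028, 0x0030, "DS",
            sprintf("%g\\%g", g$pixel_pitch_panel_mm, g$pixel_pitch_panel_mm)),
    dcm_us(0x0028, 0x0100, 16),
    dcm_us(0x0028, 0x0101, 16),
    dcm_us(0x0028, 0x0102, 15),
    dcm_us(0x0028, 0x0103, 0),
    dcm_element(0x7FE0, 0x0010, "OW", pixels)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  invisible(path)
}

#' Read a DICOM portal image written by [write_dicom()]
#'
#' Parses Explicit-VR Little-Endian monochrome 16-bit files and rebuilds
#' the [epid_image()] including its geometry (taken from the JSON metadata
#' when present, otherwise from Rows/Columns/PixelSpacing defaults).
#'
#' @param path DICOM file path.
#' @return An [epid_image()].
#' @export
read_dicom <- function(path) {
  blob <- readBin(path, "raw", n = file.info(path)$size)
  if (length(blob) < 160 || rawToChar(blob[129:132]) != "DICM") {
    abort_mlcqa("not a DICOM file (missing DICM marker).", "mlcqa_dicom")
  }
  pos <- 133L
  u16 <- function(at) sum(as.integer(blob[at:(at + 1)]) * c(1L, 256L))
  u32 <- function(at) sum(as.double(blob[at:(at + 3)]) * 256^(0:3))
  elements <- list()
  while (pos + 7 <= length(blob)) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(blob[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
      len <- u32(pos + 8L)
      start <- pos + 12L
    } else if (grepl("^[A-Z]{2}$", vr)) {
      len <- u16(pos + 6L)
      start <- pos + 8L
    } else {
      abort_mlcqa("unsupported (implicit VR?) DICOM encoding.", "mlcqa_dicom")
    }
    value <- if (len > 0) blob[start:(start + len - 1L)] else raw(0)
    elements[[sprintf("%04X%04X", group, element)]] <-
      list(vr = vr, value = value)
    pos <- start + len
  }
  need <- function(key, what) {
    el <- elements[[key]]
    if (is.null(el)) abort_mlcqa(sprintf("DICOM file lacks %s.", what),
                                 "mlcqa_dicom")
    el
  }
  u16_of <- function(el) sum(as.integer(el$value[1:2]) * c(1L, 256L))
  rows <- u16_of(need("00280010", "Rows"))
  cols <- u16_of(need("00280011", "Columns"))
  px <- need("7FE00010", "PixelData")$value
  if (length(px) != 2 * rows * cols) {
    abort_mlcqa("PixelData length does not match Rows x Columns.",
                "mlcqa_dicom")
  }
  stored <- readBin(px, "integer", n = rows * cols, size = 2, signed = FALSE,
                    endian = "little")
  stored <- matrix(stored, nrow = rows, ncol = cols, byrow = TRUE)

  meta <- list()
  geometry <- NULL
  cm <- elements[["00204000"]]
  if (!is.null(cm)) {
    parsed <- tryCatch(
      jsonlite::fromJSON(trimws(rawToChar(cm$value)), simplifyVector = TRUE),
      error = function(e) NULL)
    if (!is.null(parsed$geometry)) {
      gg <- parsed$geometry
      geometry <- geometry_model(
        sdd_cm = gg$sdd_cm, sad_cm = gg$sad_cm,
        pixel_pitch_panel_mm = gg$pixel_pitch_panel_mm,
        rows = gg$rows, cols = gg$cols, origin = as.numeric(gg$origin))
    }
    if (!is.null(parsed$meta)) meta <- parsed$meta
  }
  if (is.null(geometry)) {
    pitch <- 0.4
    ps <- elements[["00280030"]]
    if (!is.null(ps)) {
      pitch <- as.numeric(strsplit(rawToChar(ps$value), "\\\\")[[1]][1])
    }
    geometry <- geometry_model(pixel_pitch_panel_mm = pitch, rows = rows,
                               cols = cols)
  }
  epid_image(stored, geometry, meta)
}
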