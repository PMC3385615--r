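# Minimal single-frame DICOM reader (little-endian, explicit or implicit VR).
# Scope: 2-D grayscale MR images as exported by clinical scanners; no
# encapsulated (compressed) transfer syntaxes, no sequences of interest.

TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

is_dicom_file <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n < 136) return(FALSE)
  head <- readBin(path, "raw", 132)
  identical(head[129:132], charToRaw("DICM"))
}

u16 <- function(bytes, pos) {
  readBin(bytes[pos:(pos + 1L)], "integer", size = 2L, endian = "little",
          signed = FALSE)
}

u32 <- function(bytes, pos) {
  # returns -1 for the undefined-length sentinel 0xFFFFFFFF
  readBin(bytes[pos:(pos + 3L)], "integer", size = 4L, endian = "little")
}

# Parse one data element starting at pos; returns list(tag, vr, length,
# data_pos, next_pos). length == -1 flags undefined length.
dicom_element <- function(bytes, pos, explicit) {
  group <- u16(bytes, pos)
  elem <- u16(bytes, pos + 2L)
  tag <- sprintf("%04X,%04X", group, elem)
  if (explicit && group != 0xFFFE) {
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% LONG_VRS) {
      len <- u32(bytes, pos + 8L)
      data_pos <- pos + 12L
    } else {
      len <- u16(bytes, pos + 6L)
      data_pos <- pos + 8L
    }
  } else {
    vr <- NA_character_
    len <- u32(bytes, pos + 4L)
    data_pos <- pos + 8L
  }
  next_pos <- if (len >= 0L) data_pos + len else NA_integer_
  list(tag = tag, group = group, elem = elem, vr = vr, length = len,
       data_pos = data_pos, next_pos = next_pos)
}

# Skip an undefined-length value (sequence): scan for the sequence
# delimitation item (FFFE,E0DD) with zero length.
skip_undefined <- function(bytes, data_pos) {
  pat <- as.raw(c(0xFE, 0xFF, 0xDD, 0xE0, 0x00, 0x00, 0x00, 0x00))
  n <- length(bytes)
  i <- data_pos
  while (i + 7L <= n) {
    if (identical(bytes[i:(i + 7L)], pat)) return(i + 8L)
    i <- i + 2L  # elements are even-aligned
  }
  abort("malformed DICOM: unterminated undefined-length sequence")
}

elem_string <- function(bytes, el) {
  if (el$length == 0L) return("")
  b <- bytes[el$data_pos:(el$data_pos + el$length - 1L)]
  b <- b[b != as.raw(0)]  # strings are NUL- or space-padded to even length
  trimws(rawToChar(b))
}

elem_u16s <- function(bytes, el) {
  readBin(bytes[el$data_pos:(el$data_pos + el$length - 1L)], "integer",
          n = el$length %/% 2L, size = 2L, endian = "little", signed = FALSE)
}

read_dicom_image <- function(path, subject_id = NULL) {
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 140 || !identical(bytes[129:132], charToRaw("DICM"))) {
    abort(paste0("not a DICOM part-10 file: ", path))
  }
  pos <- 133L
  n <- length(bytes)

  # File meta information (group 0002) is always explicit little endian.
  transfer_syntax <- TS_EXPLICIT_LE
  while (pos + 7L <= n) {
    el <- dicom_element(bytes, pos, explicit = TRUE)
    if (el$group != 0x0002) break
    if (el$tag == "0002,0010") transfer_syntax <- elem_string(bytes, el)
    pos <- el$next_pos
  }
  explicit <- switch(transfer_syntax,
    "1.2.840.10008.1.2.1" = TRUE,
    "1.2.840.10008.1.2" = FALSE,
    abort(paste0("unsupported DICOM transfer syntax (compressed or big-endian): ",
                 transfer_syntax))
  )

  fields <- list()
  pixel <- NULL
  while (pos + 7L <= n) {
    el <- dicom_element(bytes, pos, explicit = explicit)
    if (el$length == -1L) {
      pos <- skip_undefined(bytes, el$data_pos)
      next
    }
    switch(el$tag,
      "0010,0020" = { fields$patient_id <- elem_string(bytes, el) },
      "0028,0002" = { fields$samples_per_pixel <- elem_u16s(bytes, el)[1] },
      "0028,0008" = { fields$n_frames <- as.integer(elem_string(bytes, el)) },
      "0028,0010" = { fields$rows <- elem_u16s(bytes, el)[1] },
      "0028,0011" = { fields$cols <- elem_u16s(bytes, el)[1] },
      "0028,0100" = { fields$bits_allocated <- elem_u16s(bytes, el)[1] },
      "0028,0101" = { fields$bits_stored <- elem_u16s(bytes, el)[1] },
      "0028,0103" = { fields$pixel_representation <- elem_u16s(bytes, el)[1] },
      "0028,1052" = { fields$rescale_intercept <- as.numeric(elem_string(bytes, el)) },
      "0028,1053" = { fields$rescale_slope <- as.numeric(elem_string(bytes, el)) },
      "7FE0,0010" = {
        pixel <- bytes[el$data_pos:(el$data_pos + el$length - 1L)]
      },
      NULL
    )
    pos <- el$next_pos
  }

  if (is.null(pixel)) abort(paste0("DICOM file has no pixel data: ", path))
  if ((fields$samples_per_pixel %||% 1L) != 1L) {
    abort(paste0("unsupported format (color DICOM image): ", path))
  }
  if ((fields$n_frames %||% 1L) != 1L) {
    abort(paste0("unsupported format (multi-frame DICOM): ", path))
  }
  rows <- fields$rows
  cols <- fields$cols
  if (is.null(rows) || is.null(cols)) abort("DICOM file lacks Rows/Columns")
  ba <- fields$bits_allocated %||% 16L
  signed <- (fields$pixel_representation %||% 0L) == 1L
  vals <- if (ba == 8L) {
    readBin(pixel, "integer", n = length(pixel), size = 1L, signed = signed)
  } else if (ba == 16L) {
    readBin(pixel, "integer", n = length(pixel) %/% 2L, size = 2L,
            endian = "little", signed = signed)
  } else {
    abort(sprintf("unsupported BitsAllocated: %d", ba))
  }
  if (length(vals) < rows * cols) abort("truncated DICOM pixel data")
  vals <- vals[seq_len(rows * cols)]

  # Stored values unless slope/intercept are both present and integer-valued.
  sl <- fields$rescale_slope
  ic <- fields$rescale_intercept
  if (!is.null(sl) && !is.null(ic)) {
    resc <- sl * vals + ic
    if (all(resc == round(resc)) && all(resc >= 0)) vals <- round(resc)
  }
  if (any(vals < 0)) {
    warn("negative DICOM pixel values clipped to 0")
    vals <- pmax(vals, 0)
  }

  px <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  sid <- subject_id %||% fields$patient_id %||%
    tools::file_path_sans_ext(basename(path))
  raw_image(px, subject_id = sid, bit_depth = fields$bits_stored %||% 16L)
}
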