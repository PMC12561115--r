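# Pure-R writer for minimal single-frame grayscale DICOM files (little
# endian), used to build test fixtures in code. Cross-validated against
# pydicom during development.

dcm_raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                    endian = "little")
dcm_raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                    endian = "little")

dcm_pad_even <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2 == 1) c(r, pad) else r
}

# One data element. Explicit VR uses the short form for US/DS/CS/IS and the
# long form (2 reserved + 4-byte length) for OW/OB.
dcm_element <- function(group, elem, vr, value, explicit = TRUE) {
  head <- c(dcm_raw_u16(group), dcm_raw_u16(elem))
  if (!explicit)
    return(c(head, dcm_raw_u32(length(value)), value))
  if (vr %in% c("OW", "OB", "UN", "UT", "SQ", "OF"))
    c(head, charToRaw(vr), as.raw(c(0, 0)), dcm_raw_u32(length(value)), value)
  else
    c(head, charToRaw(vr), dcm_raw_u16(length(value)), value)
}

dcm_str <- function(s) dcm_pad_even(charToRaw(s))

# Write a single-frame grayscale DICOM. `pixels` holds stored values
# (integers); photometric is the DICOM string.
write_test_dicom <- function(path, pixels, slope = 1, intercept = 0,
                             bits = 16, signed = FALSE,
                             photometric = "MONOCHROME2", explicit = TRUE,
                             n_frames = NULL) {
  stopifnot(is.matrix(pixels))
  # transposed fill: DICOM PixelData is row-major
  stored <- as.integer(t(pixels))
  pd <- writeBin(stored, raw(), size = bits / 8, endian = "little")
  meta_body <- c(
    dcm_element(2, 0x0010, "UI",
                dcm_pad_even(charToRaw(
                  if (explicit) "1.2.840.10008.1.2.1" else "1.2.840.10008.1.2"),
                  as.raw(0)), TRUE))
  meta <- c(dcm_element(2, 0x0000, "UL", dcm_raw_u32(length(meta_body)), TRUE),
            meta_body)
  body <- c(
    dcm_element(0x0028, 0x0002, "US", dcm_raw_u16(1), explicit),
    dcm_element(0x0028, 0x0004, "CS", dcm_str(photometric), explicit),
    if (!is.null(n_frames))
      dcm_element(0x0028, 0x0008, "IS", dcm_str(as.character(n_frames)),
                  explicit),
    dcm_element(0x0028, 0x0010, "US", dcm_raw_u16(nrow(pixels)), explicit),
    dcm_element(0x0028, 0x0011, "US", dcm_raw_u16(ncol(pixels)), explicit),
    dcm_element(0x0028, 0x0100, "US", dcm_raw_u16(bits), explicit),
    dcm_element(0x0028, 0x0103, "US", dcm_raw_u16(as.integer(signed)),
                explicit),
    dcm_element(0x0028, 0x1052, "DS", dcm_str(as.character(intercept)),
                explicit),
    dcm_element(0x0028, 0x1053, "DS", dcm_str(as.character(slope)), explicit),
    dcm_element(0x7fe0, 0x0010, "OW", dcm_pad_even(pd, as.raw(0)), explicit)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}
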