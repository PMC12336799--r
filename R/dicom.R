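# Minimal DICOM reader for RT Structure Set name metadata.
#
# Only ROI names are consumed, never contour geometry, so a focused parser
# suffices: it walks the data-element stream (explicit or implicit VR, little
# endian), descends into sequences, and collects ROIName (3006,0026) values
# that occur inside the StructureSetROISequence (3006,0020). Both defined and
# undefined sequence/item lengths are handled.

TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

#' Extract structure names from a DICOM RT Structure Set
#'
#' Reads the ROI names of an RTstruct file, in file order, without touching
#' contour data. Files that are not DICOM, or DICOM files without a
#' structure-set ROI sequence (e.g. CT images), raise an error naming the
#' path.
#'
#' @param path path to an RTstruct DICOM file.
#' @param center_id optional center identifier stored on every record.
#' @return a tibble of raw-structure records: `raw_name`, `roi_number`,
#'   `center_id`, `patient_id`, `language_hint`, `ground_truth`, `source_file`.
#' @export
read_rtstruct_names <- function(path, center_id = NA_character_) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "rtnomen_missing_file")
  }
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM") {
    abort(
      paste0("Not a DICOM file (missing DICM magic): ", path),
      class = "rtnomen_not_dicom"
    )
  }
  meta <- parse_file_meta(bytes)
  explicit <- !identical(meta$transfer_syntax, TS_IMPLICIT_LE)
  if (!meta$transfer_syntax %in% c(TS_IMPLICIT_LE, TS_EXPLICIT_LE)) {
    abort(
      paste0(
        "Unsupported transfer syntax ", meta$transfer_syntax, " in ", path,
        " (only little-endian uncompressed syntaxes are supported)"
      ),
      class = "rtnomen_not_dicom"
    )
  }
  rois <- scan_roi_names(bytes, meta$data_start, length(bytes), explicit)
  if (!rois$seen_sequence) {
    abort(
      paste0("No structure-set ROI sequence in ", path, " (not an RTstruct?)"),
      class = "rtnomen_no_structure_set"
    )
  }
  nms <- rois$names
  tibble(
    raw_name = nms,
    roi_number = seq_along(nms),
    center_id = center_id,
    patient_id = rois$patient_id %||% NA_character_,
    language_hint = NA_character_,
    ground_truth = NA_character_,
    source_file = path
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

u16 <- function(bytes, pos) {
  as.integer(bytes[pos]) + 256L * as.integer(bytes[pos + 1])
}

u32 <- function(bytes, pos) {
  as.numeric(bytes[pos]) + 256 * as.numeric(bytes[pos + 1]) +
    65536 * as.numeric(bytes[pos + 2]) + 16777216 * as.numeric(bytes[pos + 3])
}

LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
UNDEF_LEN <- 4294967295

# read one element header; returns group, elem, vr, len, value_start
read_header <- function(bytes, pos, explicit) {
  group <- u16(bytes, pos)
  elem <- u16(bytes, pos + 2)
  if (group == 0xFFFE) {
    return(list(
      group = group, elem = elem, vr = NA_character_,
      len = u32(bytes, pos + 4), value_start = pos + 8
    ))
  }
  if (explicit) {
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (vr %in% LONG_VRS) {
      list(group = group, elem = elem, vr = vr, len = u32(bytes, pos + 8), value_start = pos + 12)
    } else {
      list(group = group, elem = elem, vr = vr, len = u16(bytes, pos + 6), value_start = pos + 8)
    }
  } else {
    list(group = group, elem = elem, vr = NA_character_, len = u32(bytes, pos + 4), value_start = pos + 8)
  }
}

parse_file_meta <- function(bytes) {
  pos <- 133 # first byte after the DICM magic
  transfer <- TS_EXPLICIT_LE
  end <- length(bytes)
  # group 0002 is always explicit VR little endian
  while (pos + 7 <= end) {
    h <- read_header(bytes, pos, explicit = TRUE)
    if (h$group != 2) break
    if (h$elem == 0x0010) {
      v <- bytes[h$value_start:(h$value_start + h$len - 1)]
      transfer <- trimws(rawToChar(v[v != as.raw(0)]))
    }
    pos <- h$value_start + h$len
  }
  list(transfer_syntax = transfer, data_start = pos)
}

decode_string <- function(raw_value) {
  txt <- rawToChar(raw_value[raw_value != as.raw(0)])
  enc <- iconv(txt, from = "UTF-8", to = "UTF-8")
  if (is.na(enc)) enc <- iconv(txt, from = "latin1", to = "UTF-8")
  trimws(enc)
}

# stream scanner: collects ROIName values inside StructureSetROISequence
scan_roi_names <- function(bytes, start, end, explicit) {
  pos <- start
  names_out <- character()
  patient_id <- NULL
  seen_sequence <- FALSE
  # stacks of container end offsets (NA = undefined length) and a parallel
  # flag marking whether the container is the target ROI sequence
  sq_end <- numeric()
  sq_target <- logical()

  pop_done <- function() {
    while (length(sq_end) > 0 && !is.na(sq_end[length(sq_end)]) &&
      pos >= sq_end[length(sq_end)]) {
      sq_end <<- sq_end[-length(sq_end)]
      sq_target <<- sq_target[-length(sq_target)]
    }
  }

  in_target <- function() length(sq_target) > 0 && any(sq_target)

  while (pos + 7 <= end) {
    pop_done()
    h <- read_header(bytes, pos, explicit)

    if (h$group == 0xFFFE) {
      if (h$elem == 0xE000) { # item: treat as transparent container
        pos <- h$value_start
        if (!is.na(h$len) && h$len != UNDEF_LEN) {
          # defined-length item: nothing to push, elements follow directly and
          # container ends are tracked by the enclosing sequence end
        }
        next
      }
      # item or sequence delimiter
      if (h$elem == 0xE0DD && length(sq_end) > 0) {
        sq_end <- sq_end[-length(sq_end)]
        sq_target <- sq_target[-length(sq_target)]
      }
      pos <- h$value_start
      next
    }

    is_sq <- identical(h$vr, "SQ") ||
      (!explicit && h$len == UNDEF_LEN) ||
      (h$group == 0x3006 && h$elem %in% c(0x0020, 0x0039, 0x0080))

    if (h$group == 0x0010 && h$elem == 0x0020) {
      patient_id <- decode_string(bytes[h$value_start:(h$value_start + h$len - 1)])
    }

    if (is_sq) {
      target <- h$group == 0x3006 && h$elem == 0x0020
      if (target) seen_sequence <- TRUE
      sq_end <- c(sq_end, if (h$len == UNDEF_LEN) NA_real_ else h$value_start + h$len)
      sq_target <- c(sq_target, target)
      pos <- h$value_start
      next
    }

    if (h$group == 0x3006 && h$elem == 0x0026 && in_target() && h$len > 0) {
      names_out <- c(
        names_out,
        decode_string(bytes[h$value_start:(h$value_start + h$len - 1)])
      )
    }
    pos <- h$value_start + h$len
  }
  list(names = names_out, patient_id = patient_id, seen_sequence = seen_sequence)
}
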