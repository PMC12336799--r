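# Shared fixtures: the bundled lexicon (loaded once) and DICOM RTstruct
# files written at test time by pydicom (independent writer for the DICOM
# format), so no binary files live in the repository.

test_lexicon <- local({
  lex <- NULL
  function() {
    if (is.null(lex)) lex <<- load_lexicon()
    lex
  }
})

dicom_fixture_dir <- local({
  dir <- NULL
  function() {
    if (!is.null(dir)) {
      return(dir)
    }
    d <- file.path(tempdir(), "rtnomen-dicom-fixtures")
    dir.create(d, showWarnings = FALSE)
    script <- file.path(d, "make_fixtures.py")
    writeLines(c(
      "import sys, pydicom",
      "from pydicom.dataset import Dataset, FileDataset",
      "from pydicom.uid import ExplicitVRLittleEndian, ImplicitVRLittleEndian, CTImageStorage",
      "out = sys.argv[1]",
      "def rtstruct(path, names, implicit=False):",
      "    ds = FileDataset(path, Dataset())",
      "    ds.PatientID = 'PAT001'",
      "    ds.Modality = 'RTSTRUCT'",
      "    ds.SOPClassUID = '1.2.840.10008.5.1.4.1.1.481.3'",
      "    ds.SOPInstanceUID = pydicom.uid.generate_uid(entropy_srcs=[path])",
      "    seq = []",
      "    for i, n in enumerate(names):",
      "        it = Dataset()",
      "        it.ROINumber = i + 1",
      "        it.ReferencedFrameOfReferenceUID = '1.2.3'",
      "        it.ROIName = n",
      "        it.ROIGenerationAlgorithm = 'MANUAL'",
      "        seq.append(it)",
      "    ds.StructureSetROISequence = seq",
      "    ds.file_meta = pydicom.dataset.FileMetaDataset()",
      "    ds.file_meta.TransferSyntaxUID = ImplicitVRLittleEndian if implicit else ExplicitVRLittleEndian",
      "    ds.file_meta.MediaStorageSOPClassUID = ds.SOPClassUID",
      "    ds.file_meta.MediaStorageSOPInstanceUID = ds.SOPInstanceUID",
      "    ds.save_as(path, enforce_file_format=True)",
      "rtstruct(out + '/rs_explicit.dcm', ['Niere li', 'PTV'])",
      "rtstruct(out + '/rs_implicit.dcm', ['Niere li', 'PTV'], implicit=True)",
      "rtstruct(out + '/rs_empty.dcm', [])",
      "ct = FileDataset(out + '/ct.dcm', Dataset())",
      "ct.Modality = 'CT'",
      "ct.SOPClassUID = CTImageStorage",
      "ct.SOPInstanceUID = pydicom.uid.generate_uid(entropy_srcs=['ct'])",
      "ct.file_meta = pydicom.dataset.FileMetaDataset()",
      "ct.file_meta.TransferSyntaxUID = ExplicitVRLittleEndian",
      "ct.file_meta.MediaStorageSOPClassUID = ct.SOPClassUID",
      "ct.file_meta.MediaStorageSOPInstanceUID = ct.SOPInstanceUID",
      "ct.save_as(out + '/ct.dcm', enforce_file_format=True)"
    ), script)
    status <- system2("python", c(script, d), stdout = FALSE, stderr = FALSE)
    if (status != 0) stop("failed to build DICOM fixtures with pydicom")
    dir <<- d
    d
  }
})

# write a lexicon file from a tibble of entries (for malformed-input tests)
write_lexicon_file <- function(entries, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(entries, path)
  path
}

lexicon_header <- function() {
  tibble::tibble(
    standard_name = character(), concept_id = character(),
    category = character(), laterality = character(),
    spatial_qualifier = character(), plurality = character(),
    synonyms = character()
  )
}

# independent entropy oracle: direct evaluation of the defining formula
entropy_oracle <- function(labels) {
  counts <- as.numeric(table(labels))
  p <- counts / sum(counts)
  -sum(p * log(p))
}

# independent phi oracle: Pearson correlation of the expanded 0/1 vectors
phi_oracle <- function(a, b, c, d) {
  x <- c(rep(1, a + b), rep(0, c + d))
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  stats::cor(x, y)
}

# ground-truth pools for which specific error injections are constructible
laterality_pool <- function(lex) {
  e <- lex$entries
  ok <- purrr::map_lgl(seq_len(nrow(e)), function(i) {
    sib <- e[e$concept_id == e$concept_id[i] &
      e$standard_name != e$standard_name[i] &
      e$plurality == e$plurality[i], ]
    any(sib$laterality != e$laterality[i] |
      !purrr::map2_lgl(sib$spatial_qualifier, e$spatial_qualifier[i], identical))
  })
  e$standard_name[ok]
}

plurality_pool <- function(lex) {
  e <- lex$entries
  plural <- e[e$plurality == "plural", ]
  ok <- purrr::map_lgl(seq_len(nrow(plural)), function(i) {
    sib <- e[e$concept_id == plural$concept_id[i] & e$plurality == "singular", ]
    nrow(sib) > 0 &&
      any(lex$synonyms$standard_name %in% sib$standard_name & lex$synonyms$lang == "en")
  })
  plural$standard_name[ok]
}
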