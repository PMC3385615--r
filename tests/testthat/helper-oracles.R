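# Independent oracles used across the suite. These deliberately use naive
# formulations (explicit loops, pair enumeration) so they share no code path
# with the implementation they check.

# Exhaustive Otsu: split values at every k, compute between-class variance
# w0 * w1 * (mu0 - mu1)^2 from the raw subsets.
oracle_otsu <- function(values) {
  best_k <- NA_integer_
  best_s <- -Inf
  n <- length(values)
  for (k in 0:62) {
    lo <- values[values <= k]
    hi <- values[values > k]
    if (length(lo) == 0L || length(hi) == 0L) next
    s <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) {
      best_s <- s
      best_k <- k
    }
  }
  best_k
}

# Mann-Whitney AUC by exhaustive pair counting (lower abnormal score wins).
oracle_auc <- function(scores_normal, scores_abnormal) {
  wins <- 0
  for (a in scores_abnormal) {
    for (n in scores_normal) {
      wins <- wins + if (a < n) 1 else if (a == n) 0.5 else 0
    }
  }
  wins / (length(scores_abnormal) * length(scores_normal))
}

# Shannon entropy in bits from first principles.
oracle_entropy <- function(values) {
  p <- table(values) / length(values)
  -sum(p * log2(p))
}

# A small in-memory phantom cohort for tests that need features quickly.
tiny_cohort_features <- function(n = 5L, seed = 7L, params = phantom_params()) {
  simulate_cohort_features(params, n_normal = n, n_abnormal = n, seed = seed)
}

# Write a single-frame DICOM via pydicom (independent writer) and return the
# path. `values` is an integer matrix (row-major image).
write_dicom_fixture <- function(values, path, bits_stored = 12L,
                                implicit = FALSE, slope = NULL,
                                intercept = NULL) {
  script <- sprintf('
import numpy as np
import pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ImplicitVRLittleEndian, ExplicitVRLittleEndian

arr = np.array(%s, dtype=np.uint16).reshape(%d, %d)
meta = FileMetaDataset()
meta.MediaStorageSOPClassUID = pydicom.uid.MRImageStorage
meta.MediaStorageSOPInstanceUID = pydicom.uid.generate_uid()
meta.TransferSyntaxUID = %s
ds = Dataset()
ds.file_meta = meta
ds.PatientID = "fixture"
ds.Rows, ds.Columns = arr.shape
ds.SamplesPerPixel = 1
ds.PhotometricInterpretation = "MONOCHROME2"
ds.BitsAllocated = 16
ds.BitsStored = %d
ds.HighBit = %d
ds.PixelRepresentation = 0
%s
ds.PixelData = arr.tobytes()
ds.is_little_endian = True
ds.is_implicit_VR = %s
ds.save_as(r"%s", write_like_original=False)
',
    paste0("[", paste(as.integer(t(values)), collapse = ","), "]"),
    nrow(values), ncol(values),
    if (implicit) "ImplicitVRLittleEndian" else "ExplicitVRLittleEndian",
    bits_stored, bits_stored - 1L,
    if (!is.null(slope)) {
      sprintf("ds.RescaleSlope = %s\nds.RescaleIntercept = %s", slope, intercept)
    } else "",
    if (implicit) "True" else "False",
    path
  )
  tmp_py <- tempfile(fileext = ".py")
  writeLines(script, tmp_py)
  status <- system2("python", tmp_py, stdout = TRUE, stderr = TRUE)
  if (!file.exists(path)) {
    stop("pydicom fixture generation failed: ", paste(status, collapse = "\n"))
  }
  path
}
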