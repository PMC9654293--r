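# compact phantom used by unit tests (fast; exact recovery holds as for the
# default geometry)
small_phantom_spec <- function(...) {
  phantom_spec(body_axes = c(55, 45), subcut_thickness = 8,
               musclewall_thickness = 8, grid_shape = c(128L, 128L), ...)
}

# brute-force band area: explicit per-pixel loop, the oracle for band_area()
brute_band_area <- function(slice, region, band) {
  acc <- 0
  for (i in seq_len(nrow(slice$hu))) {
    for (j in seq_len(ncol(slice$hu))) {
      if (region[i, j] && slice$hu[i, j] >= band[1] &&
          slice$hu[i, j] <= band[2])
        acc <- acc + 1
    }
  }
  acc * prod(slice$pixel_spacing) / 100
}

# brute-force adjusted standardized residual, written out cell by cell
brute_haberman <- function(tab) {
  n <- sum(tab)
  out <- matrix(NA_real_, nrow(tab), ncol(tab))
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      r <- sum(tab[i, ]); c <- sum(tab[, j])
      E <- r * c / n
      den <- sqrt(E * (1 - r / n) * (1 - c / n))
      if (den > 0) out[i, j] <- (tab[i, j] - E) / den
    }
  }
  out
}

# random 2x2 co-occurrence table of two independent binaries
random_cooccurrence_table <- function(n = 400, pmin = 0.2, pmax = 0.8) {
  px <- stats::runif(1, pmin, pmax)
  py <- stats::runif(1, pmin, pmax)
  x <- stats::runif(n) < px
  y <- stats::runif(n) < py
  matrix(c(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y)), 2, 2)
}

# minimal single-slice DICOM written by pydicom (independent oracle for the
# package's DICOM reader); returns NULL if python is unavailable
write_pydicom_fixture <- function(path, values, slope = 1,
                                  intercept = -1024, spacing = c(0.8, 0.7),
                                  with_rescale = TRUE) {
  script <- tempfile(fileext = ".py")
  vals <- paste(as.integer(t(values)) - as.integer(intercept),
                collapse = ",")
  writeLines(sprintf('
import numpy as np
import pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian
fm = FileMetaDataset()
fm.TransferSyntaxUID = ExplicitVRLittleEndian
fm.MediaStorageSOPClassUID = "1.2.840.10008.5.1.4.1.1.2"
fm.MediaStorageSOPInstanceUID = "2.25.123456789"
ds = Dataset()
ds.file_meta = fm
ds.PatientID = "PYFIX"
ds.Rows, ds.Columns = %d, %d
ds.SamplesPerPixel = 1
ds.PhotometricInterpretation = "MONOCHROME2"
ds.PixelSpacing = [%g, %g]
ds.BitsAllocated = 16
ds.BitsStored = 16
ds.HighBit = 15
ds.PixelRepresentation = 1
%s
arr = np.array([%s], dtype=np.int16).reshape(%d, %d)
ds.PixelData = arr.tobytes()
ds.save_as(r"%s", enforce_file_format=True)
', nrow(values), ncol(values), spacing[1], spacing[2],
    if (with_rescale)
      sprintf("ds.RescaleSlope = %g\nds.RescaleIntercept = %g",
              slope, intercept) else "",
    vals, nrow(values), ncol(values), path), script)
  status <- suppressWarnings(
    system2("python", script, stdout = FALSE, stderr = FALSE))
  if (!identical(status, 0L)) return(NULL)
  path
}
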