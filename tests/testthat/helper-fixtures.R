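# Shared fixtures, all built in code at test time.

theta_ref <- function() peak_params(100, 500, 2, 4, 0.3, 0.7)

random_theta <- function() {
  peak_params(runif(1, 50, 150), runif(1, 100, 1000),
              runif(1, 0.5, 5), runif(1, 0.5, 5), runif(1), runif(1))
}

write_text_spectrum <- function(lines, path = tempfile(fileext = ".txt")) {
  writeLines(lines, path)
  path
}

# minimal profile-mode mzML with one spectrum, 64-bit uncompressed arrays
write_mzml_fixture <- function(mz, intensity,
                               path = tempfile(fileext = ".mzML")) {
  enc <- function(x) base64enc::base64encode(
    writeBin(as.numeric(x), raw(), size = 8L, endian = "little"))
  arr <- function(x, accession, name) paste0(
    '<binaryDataArray encodedLength="0">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="MS" accession="', accession, '" name="', name, '"/>',
    '<binary>', enc(x), '</binary></binaryDataArray>')
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<run id="r"><spectrumList count="1">',
    '<spectrum index="0" id="scan=1" defaultArrayLength="', length(mz), '">',
    '<binaryDataArrayList count="2">',
    arr(mz, "MS:1000514", "m/z array"),
    arr(intensity, "MS:1000515", "intensity array"),
    '</binaryDataArrayList></spectrum></spectrumList></run></mzML>')
  writeLines(xml, path)
  path
}

# Infinite-limit adaptive quadrature oracle for the mAPV area, split at
# the summit where the profile's derivative jumps. The Lorentzian tail
# decays only as 1/x^2, so finite windows cannot reach 1e-6 relative
# accuracy.
quadrature_area <- function(th) {
  a <- th[["alpha"]]
  f <- function(x) mapv_eval(x, th)
  integrate(f, -Inf, a, rel.tol = 1e-10, subdivisions = 2000L)$value +
    integrate(f, a, Inf, rel.tol = 1e-10, subdivisions = 2000L)$value
}

# clean multi-peak test signal on a fixed grid
clean_two_gauss <- function() {
  m <- seq(100, 200, by = 0.05)
  y <- gaussian_eval(m, 100, 130, 2) + gaussian_eval(m, 80, 170, 3)
  list(m = m, y = y)
}
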