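# Shared fixture helpers: everything is generated in code at test time.

# Crop a ground-truth mask to the 32^3 window extract_patch() uses.
crop_mask <- function(mask, center_voxel, size = 32L) {
  half <- size %/% 2L
  out <- array(FALSE, rep(size, 3L))
  d <- dim(mask)
  lo <- center_voxel - half
  hi <- lo + size - 1L
  slo <- pmax(lo, 0L); shi <- pmin(hi, d - 1L); dlo <- slo - lo
  out[dlo[1] + seq_len(shi[1] - slo[1] + 1L),
      dlo[2] + seq_len(shi[2] - slo[2] + 1L),
      dlo[3] + seq_len(shi[3] - slo[3] + 1L)] <-
    mask[slo[1] + seq_len(shi[1] - slo[1] + 1L),
         slo[2] + seq_len(shi[2] - slo[2] + 1L),
         slo[3] + seq_len(shi[3] - slo[3] + 1L)]
  out
}

# Labelled 32^3 patches from phantom cases.
make_phantom_patches <- function(spec, classes, indices) {
  patches <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    cs <- phantom_case(spec, classes[i], indices[i])
    patches[[i]] <- extract_patch(cs$volume, cs$annotation)
  }
  patches
}

# A small trained-ish network fixture is deliberately NOT shared across test
# files; each heavy study lives in exactly one file so timings are visible.

expect_identical_arrays <- function(a, b, tol = 0) {
  expect_equal(dim(a), dim(b))
  if (tol == 0) expect_identical(as.numeric(a), as.numeric(b))
  else expect_lt(max(abs(a - b)), tol)
}
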