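.onLoad <- function(libname, pkgname) {
  # single BLAS thread unless the user asked otherwise: keeps results
  # bit-reproducible and avoids oversubscription under CPU quotas
  if (!nzchar(Sys.getenv("OPENBLAS_NUM_THREADS"))) {
    try(cpp_pin_blas_threads(1L), silent = TRUE)
  }
  # retain large scratch buffers between mini-batches (glibc)
  try(cpp_tune_allocator(), silent = TRUE)
  invisible()
}
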