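# Build small sync objects from per-library count matrices (rows = sites,
# columns = A,T,C,G,N,del).
make_sync <- function(chrom, pos, ref, ..., libs = NULL) {
  mats <- list(...)
  libs <- libs %||% names(mats) %||% paste0("lib", seq_along(mats))
  counts <- array(0L, dim = c(length(pos), 6L, length(mats)))
  for (j in seq_along(mats)) counts[, , j] <- as.matrix(mats[[j]])
  sync_data(chrom, pos, ref, counts, libs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-site count row helper
crow <- function(A = 0, T = 0, C = 0, G = 0, N = 0, del = 0) {
  matrix(c(A, T, C, G, N, del), nrow = 1)
}

# Small merged biallelic table for filter/association tests
make_bi <- function(d_major, d_minor, nd_major, nd_minor,
                    chrom = "2R", pos = seq_along(d_major)) {
  data.frame(chrom = chrom, pos = pos, major = "A", minor = "T",
             d_major = d_major, d_minor = d_minor,
             nd_major = nd_major, nd_minor = nd_minor)
}
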