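# Synchronized-pileup (sync) container and I/O.
#
# The sync format is the PoPoolation2 text format: one line per genomic
# position with tab-separated fields chromosome, 1-based position, reference
# base, then one colon-separated "A:T:C:G:N:del" count block per sequencing
# library. Reading and writing are bit-exact for canonical files.

#' Construct a sync object
#'
#' A `sync` object holds pooled allele counts for one or more sequencing
#' libraries: a site catalog (chromosome, 1-based position, reference base)
#' plus a 3-dimensional count array with one 6-vector (A, T, C, G, N, del)
#' per site and library.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param ref character vector of reference bases.
#' @param counts integer array of dimension `n_sites x 6 x n_libraries`.
#' @param libraries character vector of library names.
#' @return an object of class `sync`.
#' @export
sync_data <- function(chrom, pos, ref, counts, libraries = NULL) {
  n <- length(chrom)
  if (length(pos) != n || length(ref) != n)
    stop("chrom, pos and ref must have equal length", call. = FALSE)
  if (length(dim(counts)) != 3L || dim(counts)[1] != n || dim(counts)[2] != 6L)
    stop("counts must be an n_sites x 6 x n_libraries array", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  libraries <- libraries %||% dimnames(counts)[[3]] %||%
    paste0("lib", seq_len(dim(counts)[3]))
  dimnames(counts) <- list(NULL, BASES6, libraries)
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), counts = counts),
            class = "sync")
}

#' @export
print.sync <- function(x, ...) {
  cat(sprintf("sync: %d sites, %d libraries (%s)\n", n_sites(x),
              length(sync_libraries(x)), paste(sync_libraries(x), collapse = ", ")))
  invisible(x)
}

#' Number of sites in a sync object
#' @param x a `sync` object.
#' @return integer count of sites.
#' @export
n_sites <- function(x) length(x$pos)

#' Library names of a sync object
#' @param x a `sync` object.
#' @return character vector of library names.
#' @export
sync_libraries <- function(x) dimnames(x$counts)[[3]]

#' Subset a sync object by site index
#' @param x a `sync` object.
#' @param idx logical or integer site index.
#' @return a `sync` object restricted to the selected sites.
#' @export
sync_subset <- function(x, idx) {
  sync_data(x$chrom[idx], x$pos[idx], x$ref[idx],
            x$counts[idx, , , drop = FALSE], sync_libraries(x))
}

#' Read a sync file
#'
#' Parses a PoPoolation2 synchronized pileup. Malformed lines (wrong field
#' count, count blocks without exactly six integer fields) are reported with
#' their line number.
#'
#' @param path path to a sync file.
#' @param libraries optional library names; defaults to lib1, lib2, ...
#' @return a `sync` object.
#' @export
read_sync <- function(path, libraries = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty sync file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop(sprintf("sync parse error at line %d: expected at least 4 tab-separated fields, found %d",
                 which(nf < 4L)[1], nf[which(nf < 4L)[1]]), call. = FALSE)
  if (length(unique(nf)) != 1L)
    stop(sprintf("sync parse error at line %d: inconsistent field count (%d vs %d)",
                 which(nf != nf[1])[1], nf[which(nf != nf[1])[1]], nf[1]), call. = FALSE)
  n_lib <- nf[1] - 3L
  mat <- matrix(unlist(fields, use.names = FALSE), nrow = length(lines), byrow = TRUE)
  pos <- suppressWarnings(as.integer(mat[, 2]))
  if (anyNA(pos))
    stop(sprintf("sync parse error at line %d: non-integer position '%s'",
                 which(is.na(pos))[1], mat[which(is.na(pos))[1], 2]), call. = FALSE)
  counts <- array(0L, dim = c(length(lines), 6L, n_lib))
  for (j in seq_len(n_lib)) {
    blk <- strsplit(mat[, 3L + j], ":", fixed = TRUE)
    bad <- which(lengths(blk) != 6L)
    if (length(bad))
      stop(sprintf("sync parse error at line %d: count block '%s' has %d colon-separated fields (expected 6)",
                   bad[1], mat[bad[1], 3L + j], lengths(blk)[bad[1]]), call. = FALSE)
    v <- unlist(blk, use.names = FALSE)
    iv <- suppressWarnings(as.integer(v))
    if (anyNA(iv)) {
      bad_line <- ceiling(which(is.na(iv))[1] / 6)
      stop(sprintf("sync parse error at line %d: non-integer count in '%s'",
                   bad_line, mat[bad_line, 3L + j]), call. = FALSE)
    }
    counts[, , j] <- matrix(iv, ncol = 6L, byrow = TRUE)
  }
  libraries <- libraries %||% paste0("lib", seq_len(n_lib))
  sync_data(mat[, 1], pos, mat[, 3], counts, libraries)
}

#' Write a sync file
#'
#' Inverse of [read_sync()]: `write_sync(read_sync(f), g)` reproduces `f`
#' byte for byte for canonical files.
#'
#' @param x a `sync` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(x, path) {
  stopifnot(inherits(x, "sync"))
  blocks <- vapply(seq_along(sync_libraries(x)), function(j) {
    m <- x$counts[, , j, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    do.call(paste, c(lapply(seq_len(6), function(b) m[, b]), sep = ":"))
  }, character(n_sites(x)))
  if (is.null(dim(blocks))) blocks <- matrix(blocks, nrow = 1L)
  lines <- do.call(paste, c(list(x$chrom, x$pos, x$ref),
                            lapply(seq_len(ncol(blocks)), function(j) blocks[, j]),
                            sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of masked intervals
#'
#' Intervals are 0-based, half-open. Lines with fewer than three fields,
#' non-integer coordinates, or start >= end are reported with their line
#' number.
#'
#' @param path path to a BED file.
#' @return a data.frame with columns chrom, start, end.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(data.frame(chrom = character(), start = integer(), end = integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop(sprintf("BED format error at line %d: fewer than 3 fields", bad[1]), call. = FALSE)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("BED format error at line %d: non-integer coordinates", bad[1]), call. = FALSE)
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("BED format error at line %d: start (%d) >= end (%d)",
                 bad[1], start[bad[1]], end[bad[1]]), call. = FALSE)
  data.frame(chrom = chrom, start = start, end = end)
}

#' Write a BED file
#' @param bed data.frame with columns chrom, start, end (0-based half-open).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  writeLines(paste(bed$chrom, bed$start, bed$end, sep = "\t"), path)
  invisible(path)
}

#' Remove repeat/TE-masked positions from a sync object
#'
#' A site at 1-based position p on chromosome c is removed iff p - 1 falls
#' inside any BED interval (0-based, half-open) on c.
#'
#' @param x a `sync` object.
#' @param bed a BED data.frame (from [read_bed()]) or path to a BED file.
#' @return a `sync` object with masked sites removed.
#' @export
mask_sites <- function(x, bed) {
  stopifnot(inherits(x, "sync"))
  if (is.character(bed)) bed <- read_bed(bed)
  if (any(bed$start >= bed$end)) stop("BED format error: start >= end", call. = FALSE)
  if (!nrow(bed)) return(x)
  mask <- GenomicRanges::GRanges(bed$chrom, IRanges::IRanges(bed$start + 1L, bed$end))
  sites <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos, x$pos))
  keep <- !IRanges::overlapsAny(sites, mask)
  sync_subset(x, keep)
}

#' Binomially down-sample one library
#'
#' Replaces each count c by a Binomial(c, fraction) draw — per-read Bernoulli
#' thinning, the count-level equivalent of `samtools view -s`. With
#' `fraction = 1` the object is returned unchanged. The default use is to
#' equalize libraries to a common read total (fraction = target / total reads
#' of that library).
#'
#' @param x a `sync` object.
#' @param library library name or index.
#' @param fraction retention probability in (0, 1].
#' @param seed integer seed for the thinning draws.
#' @return a `sync` object with the library thinned.
#' @export
downsample_library <- function(x, library, fraction, seed = 1L) {
  stopifnot(inherits(x, "sync"))
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction <= 0 || fraction > 1)
    stop("'fraction' must lie in (0, 1]", call. = FALSE)
  if (is.character(library)) {
    library <- match(library, sync_libraries(x))
    if (is.na(library)) stop("unknown library", call. = FALSE)
  }
  if (fraction == 1) return(x)
  cnts <- x$counts[, , library]
  thinned <- withr::with_seed(seed,
    rbinom(length(cnts), size = as.vector(cnts), prob = fraction))
  x$counts[, , library] <- thinned
  x
}

#' Merge replicate libraries into phenotype groups
#'
#' Sums the per-site 6-vectors of all libraries assigned to each group. The
#' output has exactly two libraries in fixed order: D then ND.
#'
#' @param x a `sync` object.
#' @param groups named character vector mapping every library to "D" or "ND",
#'   or a data.frame with columns library, group.
#' @return a two-library `sync` object with columns D and ND.
#' @export
merge_groups <- function(x, groups) {
  stopifnot(inherits(x, "sync"))
  if (is.data.frame(groups)) groups <- stats::setNames(as.character(groups$group), groups$library)
  libs <- sync_libraries(x)
  missing <- setdiff(libs, names(groups))
  if (length(missing))
    stop("design error: unassigned libraries: ", paste(missing, collapse = ", "), call. = FALSE)
  g <- groups[libs]
  if (!all(g %in% c("D", "ND")))
    stop("design error: groups must be 'D' or 'ND'", call. = FALSE)
  out <- array(0L, dim = c(n_sites(x), 6L, 2L), dimnames = list(NULL, BASES6, c("D", "ND")))
  for (grp in c("D", "ND")) {
    sel <- which(g == grp)
    if (!length(sel)) stop("design error: group ", grp, " has no libraries", call. = FALSE)
    m <- x$counts[, , sel, drop = FALSE]
    out[, , grp] <- rowSums(m, dims = 2L)
  }
  sync_data(x$chrom, x$pos, x$ref, out, c("D", "ND"))
}

#' Extract biallelic counts from a merged two-group sync object
#'
#' The two candidate alleles at each site are the two of A, T, C, G with the
#' highest combined (D + ND) counts; ties are broken in sync column order
#' A, T, C, G. N and deletion counts are never alleles, and reads supporting a
#' third or fourth allele are dropped from the 2x2 table. Sites where fewer
#' than two alleles are observed are omitted. Polarity: the major allele has
#' combined count >= the minor allele's.
#'
#' @param x a merged `sync` object with libraries D and ND.
#' @return a data.frame with columns chrom, pos, major, minor, d_major,
#'   d_minor, nd_major, nd_minor.
#' @export
extract_biallelic <- function(x) {
  stopifnot(inherits(x, "sync"))
  if (!identical(sync_libraries(x), c("D", "ND")))
    stop("extract_biallelic expects a merged sync with libraries D and ND", call. = FALSE)
  n <- n_sites(x)
  d <- x$counts[, 1:4, "D", drop = FALSE]; dim(d) <- c(n, 4L)
  nd <- x$counts[, 1:4, "ND", drop = FALSE]; dim(nd) <- c(n, 4L)
  comb <- d + nd
  maj <- max.col(comb, ties.method = "first")
  tmp <- comb
  tmp[cbind(seq_len(n), maj)] <- -1L
  mnr <- max.col(tmp, ties.method = "first")
  keep <- comb[cbind(seq_len(n), mnr)] > 0L
  i <- which(keep)
  data.frame(
    chrom = x$chrom[i], pos = x$pos[i],
    major = NUCS[maj[i]], minor = NUCS[mnr[i]],
    d_major = d[cbind(i, maj[i])], d_minor = d[cbind(i, mnr[i])],
    nd_major = nd[cbind(i, maj[i])], nd_minor = nd[cbind(i, mnr[i])])
}
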