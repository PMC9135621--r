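#' Read and write 3D/4D volumes as NIfTI-1
#'
#' Thin wrappers around RNifti that preserve the data bit-for-bit
#' (float64 storage) with an RAS+ affine; `NA`s are stored as NaN and
#' restored on read.
#'
#' @param map Numeric array (3D or 4D).
#' @param path File path (`.nii` or `.nii.gz`).
#' @param pixdim Voxel size(s) in mm (recycled).
#' @return `write_map` returns `path` invisibly; `read_map` returns a
#'   plain numeric array.
#' @export
write_map <- function(map, path, pixdim = c(3, 3, 3)) {
  d <- dim(map)
  map <- array(as.numeric(map), dim = d)
  attr(map, "pixdim") <- rep_len(pixdim, length(d))
  img <- RNifti::asNifti(map, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  arr[is.nan(arr)] <- NA_real_
  arr
}

#' Read and write typed TSV tables
#'
#' Tab-separated, header row, no quoting surprises; round-trips the
#' phenotype, manifest and results tables used across the pipeline.
#'
#' @param table A data frame.
#' @param path File path.
#' @return `write_table_tsv` returns `path` invisibly; `read_table_tsv`
#'   returns a data frame.
#' @export
write_table_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Validate that a set of volumes shares one grid
#'
#' @param paths Character vector of NIfTI paths, or a list of arrays.
#' @return The common grid dims, invisibly; mismatches raise an error
#'   naming every offender.
#' @export
check_cohort_grid <- function(paths) {
  dims <- lapply(paths, function(p) {
    a <- if (is.character(p)) read_map(p) else p
    dim(a)
  })
  ref <- dims[[1]]
  bad <- which(!vapply(dims, identical, logical(1), ref))
  if (length(bad)) {
    nm <- if (is.character(paths)) paths[bad] else paste("map", bad)
    stop("grid mismatch against ", paste(ref, collapse = "x"), " in: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  invisible(ref)
}

# small deterministic content hash (FNV-1a over the serialized object)
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
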