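# Shared format readers/writers: NIfTI-1 volumes (via RNifti), FSL-style
# bvals/bvecs text files, MRtrix TCK streamline files, and TSV tables.
#
# Volume ordering convention on disk: b0 volumes first, then the
# diffusion-weighted volumes in scheme order (mirrored in the bvals/bvecs
# columns).

#' Write a 3-D/4-D array as NIfTI-1 with an explicit affine
#' @param arr numeric/logical array.
#' @param path output path (.nii or .nii.gz).
#' @param grid_to_world 4 x 4 affine (0-based voxel index -> world mm).
#' @param datatype RNifti datatype string (e.g. "float", "uint8", "int32").
#' @return the path, invisibly.
#' @export
write_nifti_volume <- function(arr, path, grid_to_world, datatype = "float") {
  img <- RNifti::asNifti(arr + 0, datatype = datatype)
  img <- RNifti::`sform<-`(img, structure(grid_to_world, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume together with its affine
#' @param path NIfTI file path.
#' @return list with `data` (array) and `grid_to_world` (4 x 4 affine).
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  list(data = as.array(img), grid_to_world = matrix(as.numeric(aff), 4, 4))
}

#' Write a DWI volume as NIfTI + FSL-style bvals/bvecs
#'
#' Produces `<prefix>.nii.gz`, `<prefix>.bvals` (one whitespace-separated
#' row) and `<prefix>.bvecs` (3 rows x N columns), b0 columns first.
#'
#' @param dwi `dwi_volume`.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_dwi <- function(dwi, prefix) {
  write_nifti_volume(dwi$signal, paste0(prefix, ".nii.gz"), dwi$grid_to_world)
  scheme <- dwi$scheme
  bvals <- c(rep(0, scheme$n_b0), scheme$bvalues)
  bvecs <- cbind(matrix(0, 3, scheme$n_b0), t(scheme$directions))
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "),
             paste0(prefix, ".bvals"))
  writeLines(apply(bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")),
    paste0(prefix, ".bvecs"))
  invisible(prefix)
}

#' Read a DWI volume written by [write_dwi()]
#' @param prefix path prefix.
#' @param b0_tol b-values at or below this are treated as b0 volumes.
#' @return `dwi_volume` (with a reconstructed `gradient_scheme`).
#' @export
read_dwi <- function(prefix, b0_tol = 10) {
  vol <- read_nifti_volume(paste0(prefix, ".nii.gz"))
  bvals <- scan(paste0(prefix, ".bvals"), quiet = TRUE)
  bvecs <- matrix(scan(paste0(prefix, ".bvecs"), quiet = TRUE), nrow = 3,
                  byrow = TRUE)
  if (length(bvals) != ncol(bvecs) || length(bvals) != dim(vol$data)[4])
    stop("bvals/bvecs column count does not match the number of volumes")
  isb0 <- bvals <= b0_tol
  if (!any(isb0)) stop("no b0 volume found in bvals")
  if (any(which(isb0) > which.max(!isb0)) && any(!isb0))
    stop("b0 volumes must precede the diffusion-weighted volumes")
  dirs <- t(bvecs[, !isb0, drop = FALSE])
  nrm <- sqrt(rowSums(dirs^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    warning("non-unit gradient vectors in bvecs; normalizing")
    dirs <- dirs / nrm
  }
  scheme <- structure(list(directions = dirs, bvalues = bvals[!isb0],
                           n_b0 = sum(isb0), energy = c(NA, NA)),
                      class = "gradient_scheme")
  vsz <- sqrt(colSums(vol$grid_to_world[1:3, 1:3]^2))
  structure(list(signal = vol$data, voxel_size = vsz,
                 grid_to_world = vol$grid_to_world, scheme = scheme,
                 s0 = NA_real_, noise_sigma = NA_real_),
            class = "dwi_volume")
}

#' Write streamlines in MRtrix TCK format
#'
#' World-mm coordinates, little-endian Float32 triplets; streamlines are
#' separated by NaN triplets and the file ends with an Inf triplet.
#'
#' @param tractogram `tractogram` (or list of n x 3 point matrices).
#' @param path output .tck path.
#' @return the path, invisibly.
#' @export
write_tck <- function(tractogram, path) {
  pts <- if (inherits(tractogram, "tractogram"))
    lapply(tractogram$streamlines, `[[`, "points") else tractogram
  hdr_lines <- c("mrtrix tracks",
                 "datatype: Float32LE",
                 sprintf("count: %d", length(pts)))
  # compute the data offset; "file: . <offset>" line length feeds back into
  # the offset, so fix the field width first
  base <- sum(nchar(hdr_lines, type = "bytes")) + length(hdr_lines) +
    nchar("END\n")
  offset_line <- function(off) sprintf("file: . %d", off)
  off <- base + nchar(offset_line(10^9)) + 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr_lines, sprintf("file: . %-10d", off), "END"), con, sep = "\n")
  flat <- lapply(pts, function(p) rbind(p, c(NaN, NaN, NaN)))
  dat <- c(t(do.call(rbind, flat)))
  dat <- c(dat[seq_len(length(dat) - 3)], NaN, NaN, NaN, Inf, Inf, Inf)
  seek(con, off)
  writeBin(as.numeric(dat), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRtrix TCK file
#' @param path .tck path.
#' @return list of n x 3 streamline point matrices (world mm).
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "mrtrix tracks")) stop("not a TCK file: bad magic line")
  off <- NULL
  repeat {
    ln <- readLines(con, n = 1)
    if (identical(ln, "END")) break
    if (grepl("^file:", ln))
      off <- as.integer(sub("^file:\\s*\\.\\s*(\\d+)\\s*$", "\\1", ln))
    if (grepl("^datatype:", ln) && !grepl("Float32LE", ln))
      stop("unsupported TCK datatype field: only Float32LE is handled")
  }
  if (is.null(off)) stop("TCK header missing its file offset field")
  seek(con, off)
  raw <- readBin(con, what = "numeric", n = file.size(path) %/% 4L, size = 4L,
                 endian = "little")
  m <- matrix(raw, ncol = 3, byrow = TRUE)
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(m))) {
    r <- m[i, ]
    if (all(is.infinite(r))) break
    if (all(is.nan(r))) {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- NULL
    } else cur <- rbind(cur, r)
  }
  lapply(out, unname)
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) read.delim(path, sep = "\t", check.names = FALSE)
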