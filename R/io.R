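#' Read and write two-column CSV for signals and distribution functions
#'
#' The on-disk interchange format is a plain CSV with an abscissa column
#' (time in ms for signals, T2 in ms for DFs) and a value column.
#'
#' @param x Values (signal or density).
#' @param abscissa Times or T2 values, same length as \code{x}.
#' @param path Output file.
#' @return \code{write_xy_csv} returns \code{path} invisibly;
#'   \code{read_xy_csv} returns a data frame with columns \code{abscissa},
#'   \code{value}.
#' @export
write_xy_csv <- function(x, abscissa, path) {
  if (length(x) != length(abscissa)) stop("lengths differ")
  utils::write.csv(data.frame(abscissa = abscissa, value = x),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_xy_csv
#' @export
read_xy_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("abscissa", "value") %in% names(d)))
    stop("expected columns 'abscissa' and 'value'")
  d[c("abscissa", "value")]
}

#' Persist and restore an offline basis
#'
#' Bases are expensive to build; these helpers store them as RDS files
#' together with the noise level, ladder, dictionary and seed they were
#' built with.
#'
#' @param basis An \code{\link{offline_basis}} (or \code{\link{basis_bank}}).
#' @param path File path.
#' @return \code{write_basis} returns \code{path} invisibly;
#'   \code{read_basis} returns the restored object.
#' @export
write_basis <- function(basis, path) {
  if (!inherits(basis, c("offline_basis", "basis_bank")))
    stop("not an offline_basis or basis_bank")
  saveRDS(basis, path)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, c("offline_basis", "basis_bank")))
    stop("file does not contain an offline basis")
  obj
}

#' Read a multi-echo image stack from NIfTI
#'
#' Expects a 3D (x, y, echo) or 4D single-slice (x, y, 1, echo) volume.
#' Requires the RNifti package.
#'
#' @param path NIfTI file.
#' @return Numeric array.
#' @export
read_echo_stack <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI requires the RNifti package")
  arr <- as.array(RNifti::readNifti(path))
  storage.mode(arr) <- "double"
  arr
}

#' Write an MWF map to NIfTI
#'
#' @param map Matrix of MWF values.
#' @param path Output NIfTI file.
#' @return \code{path}, invisibly.
#' @export
write_mwf_map <- function(map, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("writing NIfTI requires the RNifti package")
  RNifti::writeNifti(RNifti::asNifti(map), path)
  invisible(path)
}
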