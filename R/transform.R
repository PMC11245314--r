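#' Affine change-of-variables record
#'
#' Links a preprocessed (reduced and/or rounded) parameter space to the
#' original one via `full = basis %*% reduced + shift`. Records compose, so a
#' pipeline of equality embedding followed by rounding is carried as a single
#' record.
#'
#' @param basis numeric matrix (n_full x n_reduced) with full column rank.
#' @param shift numeric vector of length n_full.
#' @return An object of class `"transform_record"`.
#' @export
transform_record <- function(basis, shift) {
  basis <- as.matrix(basis)
  storage.mode(basis) <- "double"
  shift <- as.numeric(shift)
  cw_check_dim(nrow(basis) == length(shift),
               "basis row count must equal shift length")
  if (qr(basis)$rank < ncol(basis)) {
    cw_stop("transform basis must have full column rank", "cw_validation_error")
  }
  structure(list(basis = basis, shift = shift), class = "transform_record")
}

#' Identity transform in n dimensions
#' @param n dimension.
#' @return a [transform_record()] with identity basis and zero shift.
#' @export
identity_transform <- function(n) {
  transform_record(diag(n), rep(0, n))
}

#' Map reduced-space points to the original space
#'
#' Applies `full = basis %*% reduced + shift` to each row of a sample matrix.
#'
#' @param record a [transform_record()].
#' @param samples numeric matrix (points x n_reduced) or a single vector.
#' @return numeric matrix (points x n_full).
#' @export
map_back <- function(record, samples) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1L)
  cw_check_dim(ncol(samples) == ncol(record$basis),
               sprintf("samples have %d columns but basis expects %d",
                       ncol(samples), ncol(record$basis)))
  sweep(samples %*% t(record$basis), 2L, record$shift, "+")
}

#' Map a single reduced point to the original space
#' @param record a [transform_record()] or `NULL` (identity).
#' @param point numeric vector in the reduced space.
#' @return numeric vector in the original space.
#' @export
map_point <- function(record, point) {
  if (is.null(record)) return(point)
  cw_check_dim(length(point) == ncol(record$basis),
               "point length must equal basis column count")
  as.numeric(record$basis %*% point) + record$shift
}

#' Project an original-space point into the reduced space
#'
#' Uses the Moore-Penrose pseudo-inverse of the basis; for an orthonormal
#' basis this is `t(basis) %*% (full - shift)` and inverts [map_point()]
#' exactly for points in the affine subspace.
#'
#' @param record a [transform_record()].
#' @param point numeric vector in the original space.
#' @return numeric vector in the reduced space.
#' @export
reduce_point <- function(record, point) {
  cw_check_dim(length(point) == nrow(record$basis),
               "point length must equal basis row count")
  as.numeric(qr.solve(record$basis, point - record$shift))
}

#' Compose two transform records
#'
#' Applying `outer` after `inner` (reduced -> intermediate -> full) equals the
#' single record with `basis = B_outer B_inner` and
#' `shift = B_outer s_inner + s_outer`.
#'
#' @param outer,inner [transform_record()] objects.
#' @return the composed [transform_record()].
#' @export
compose_transforms <- function(outer, inner) {
  cw_check_dim(ncol(outer$basis) == nrow(inner$basis),
               "transform dimensions do not chain")
  transform_record(outer$basis %*% inner$basis,
                   as.numeric(outer$basis %*% inner$shift) + outer$shift)
}
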