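#' Create a volume: a 3D numeric array carrying its voxel size
#'
#' All pipeline stages operate on plain 3D arrays with a `voxel_size`
#' attribute (physical edge lengths in mm). Voxel `(i, j, k)` has its center
#' at physical coordinate `((i - 0.5) * dx, (j - 0.5) * dy, (k - 0.5) * dz)`,
#' i.e. the physical origin sits at the corner of the first voxel.
#'
#' @param x numeric 3D array (or vector reshaped by `dim`)
#' @param voxel_size_mm numeric length-3, voxel edge lengths in mm
#' @param dim optional dimensions when `x` is a vector
#' @return the array with class `gliomapr_volume` and a `voxel_size` attribute
#' @export
as_volume <- function(x, voxel_size_mm = c(1, 1, 1), dim = NULL) {
  if (!is.null(dim)) dim(x) <- dim
  if (length(dim(x)) != 3L) stop("a volume must be a 3D array")
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  attr(x, "voxel_size") <- as.numeric(voxel_size_mm)
  class(x) <- c("gliomapr_volume", class(x))
  x
}

#' Voxel size of a volume
#' @param x a volume
#' @return numeric length-3 voxel edge lengths in mm (defaults to 1 mm)
#' @export
voxel_size <- function(x) {
  vs <- attr(x, "voxel_size")
  if (is.null(vs)) c(1, 1, 1) else vs
}

# voxel volume in mm^3
voxel_volume <- function(x) prod(voxel_size(x))

# strip volume class/attrs to a bare array (internal)
bare <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

# error unless a and b share grid shape (and voxel size when both carry one)
check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s are on different grids: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  va <- attr(a, "voxel_size"); vb <- attr(b, "voxel_size")
  if (!is.null(va) && !is.null(vb) && !isTRUE(all.equal(va, vb)))
    stop(sprintf("%s have different voxel sizes", what))
  invisible(TRUE)
}

# coordinate arrays of voxel centers along each axis, as 3D arrays
coord_arrays <- function(grid_shape, voxel_size_mm) {
  n <- grid_shape
  cx <- (seq_len(n[1]) - 0.5) * voxel_size_mm[1]
  cy <- (seq_len(n[2]) - 0.5) * voxel_size_mm[2]
  cz <- (seq_len(n[3]) - 0.5) * voxel_size_mm[3]
  list(
    x = array(cx, dim = n),
    y = array(rep(cy, each = n[1]), dim = n),
    z = array(rep(cz, each = n[1] * n[2]), dim = n)
  )
}
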