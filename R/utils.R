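# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# deterministic local RNG: run expr under a seed without touching global state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

check_voxel_size <- function(voxel_size) {
  if (!is.numeric(voxel_size) || length(voxel_size) != 3L || any(voxel_size <= 0))
    stopf("voxel_size must be 3 strictly positive numbers (z, y, x) in um")
  as.numeric(voxel_size)
}

# physical um position -> 0-based containing voxel index, clipped to the grid
um_to_voxel <- function(pos_um, voxel_size, dim) {
  idx <- floor(sweep(pos_um, 2L, voxel_size, "/"))
  for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 0L), dim[a] - 1L)
  storage.mode(idx) <- "integer"
  idx
}

# 0-based (z,y,x) voxel index matrix -> 1-based linear index into [z,y,x] array
voxel_linear <- function(idx, dim) {
  idx[, 1L] + dim[1L] * (idx[, 2L] + dim[2L] * idx[, 3L]) + 1
}

# centre of 0-based voxel indices in um
voxel_center_um <- function(idx, voxel_size) {
  sweep(idx + 0.5, 2L, voxel_size, "*")
}

# anisotropic Euclidean distance transform: distance of each TRUE voxel to the
# nearest FALSE voxel centre, in the units of `spacing`
edt <- function(mask, spacing) {
  d <- dim(mask)
  out <- .edt3d(as.logical(mask), as.integer(d), as.numeric(spacing))
  array(out, d)
}

# connected components of a logical 3D array
label_components <- function(mask, connectivity = 6L) {
  .label3d(as.logical(mask), as.integer(dim(mask)), as.integer(connectivity))
}

fmt_num <- function(x) {
  ifelse(is.na(x), NA, signif(x, 6))
}
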