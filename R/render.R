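#' Render a multi-channel synthetic smFISH image stack
#'
#' Renders the ground-truth molecules of a synthetic embryo into a
#' diffraction-limited smFISH channel (one anisotropic 3D Gaussian kernel per
#' molecule), plus a membrane-marker channel highlighting cell boundaries and
#' a DAPI channel highlighting nuclei, with optional Poisson shot noise and
#' Gaussian read noise. An optional nuclear GFP reporter channel can be added
#' for reporter-fluorescence quantification.
#'
#' Each molecule at µm position `p` contributes
#' `amplitude * exp(-sum((v - p)^2 / (2 * psf_sigma^2)))` evaluated at voxel
#' centres `v` (voxel `i` spans `[i, i+1) * voxel_size`, centre at
#' `(i + 0.5) * voxel_size`), truncated at 4 sigma. With noise disabled and
#' zero background the summed channel intensity is exactly
#' `amplitude * sum(discrete kernel)`.
#'
#' @param geometry An `embryo_geometry`.
#' @param truth A `ground_truth` table from [place_spots()].
#' @param psf_sigma PSF standard deviation `c(z, y, x)` in µm. The default
#'   `c(0.35, 0.13, 0.13)` is a typical widefield 60x/1.42 NA scale.
#' @param spot_amplitude Peak signal per molecule, photons/counts.
#' @param noise List: `poisson` (logical; apply shot noise to the full
#'   expected photon count) and `gaussian_sd` (read-noise SD, counts).
#' @param background Constant background offset, counts (default 100; gives
#'   the Poisson model a realistic off-spot variance).
#' @param seed Integer seed for the noise draws; identical calls give
#'   identical stacks.
#' @param gfp_nuclear If non-`NULL`, adds a `gfp` reporter channel with this
#'   mean nuclear intensity above background.
#' @return An object of class `image_stack`: list with `channels` (named list
#'   of 3D arrays: `smfish`, `membrane`, `dapi`, optionally `gfp`),
#'   `voxel_size`, and the render parameters.
#' @export
render_stack <- function(geometry, truth,
                         psf_sigma = c(0.35, 0.13, 0.13),
                         spot_amplitude = 200,
                         noise = list(poisson = TRUE, gaussian_sd = 10),
                         background = 100, seed = 1L, gfp_nuclear = NULL) {
  stopifnot(inherits(geometry, "embryo_geometry"))
  psf_sigma <- as.numeric(psf_sigma)
  if (length(psf_sigma) != 3L || any(psf_sigma <= 0)) stopf("psf_sigma must be 3 positive um values")
  if (spot_amplitude <= 0) stopf("spot_amplitude must be > 0")
  vs <- geometry$voxel_size
  d <- dim(geometry$labels)
  ext <- d * vs
  pos <- as.matrix(truth[, c("z_um", "y_um", "x_um")])
  if (any(pos < 0) || any(sweep(pos, 2L, ext, ">") ))
    stopf("render error: truth positions outside the volume")

  smfish <- array(0, d)
  rad <- ceiling(4 * psf_sigma / vs)  # kernel half-width, voxels
  for (i in seq_len(nrow(pos))) {
    p <- pos[i, ]
    ctr <- p / vs - 0.5               # fractional 0-based voxel coordinate
    lo <- pmax(floor(ctr) - rad, 0)
    hi <- pmin(floor(ctr) + rad + 1, d - 1)
    kz <- exp(-0.5 * (((lo[1]:hi[1]) - ctr[1]) * vs[1] / psf_sigma[1])^2)
    ky <- exp(-0.5 * (((lo[2]:hi[2]) - ctr[2]) * vs[2] / psf_sigma[2])^2)
    kx <- exp(-0.5 * (((lo[3]:hi[3]) - ctr[3]) * vs[3] / psf_sigma[3])^2)
    ker <- outer(outer(kz, ky), kx)
    smfish[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1), (lo[3] + 1):(hi[3] + 1)] <-
      smfish[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1), (lo[3] + 1):(hi[3] + 1)] +
      spot_amplitude * ker
  }
  smfish <- smfish + background

  # membrane channel: blurred label boundaries
  memb <- boundary_mask(geometry$labels)
  memb_ch <- array(.gauss3d(as.numeric(memb) * 4 * background,
                            as.integer(d), psf_sigma / vs), d) + background

  # DAPI channel: blurred nuclear ellipsoids
  dapi <- array(0, d)
  nuc_r <- pmin(0.25 * geometry$radii, 1.5)  # nuclear semi-axes, um
  for (k in seq_len(geometry$stage)) {
    nc <- geometry$nuclei_um[k, ]
    zc <- ((seq_len(d[1]) - 0.5) * vs[1] - nc[1]) / nuc_r[1]
    yc <- ((seq_len(d[2]) - 0.5) * vs[2] - nc[2]) / nuc_r[2]
    xc <- ((seq_len(d[3]) - 0.5) * vs[3] - nc[3]) / nuc_r[3]
    dapi <- dapi + (outer(outer(zc^2, yc^2, "+"), xc^2, "+") <= 1)
  }
  dapi_ch <- array(.gauss3d(as.numeric(dapi) * 4 * background,
                            as.integer(d), psf_sigma / vs), d) + background

  channels <- list(smfish = smfish, membrane = memb_ch, dapi = dapi_ch)
  if (!is.null(gfp_nuclear)) {
    channels$gfp <- background + gfp_nuclear * (dapi > 0)
  }

  with_seed(seed, {
    for (nm in names(channels)) {
      ch <- channels[[nm]]
      if (isTRUE(noise$poisson)) ch <- array(rpois(length(ch), pmax(ch, 0)), d)
      gsd <- noise$gaussian_sd %||% 0
      if (gsd > 0) ch <- ch + array(rnorm(length(ch), 0, gsd), d)
      channels[[nm]] <- ch
    }
    structure(list(channels = channels, voxel_size = vs,
                   psf_sigma = psf_sigma, spot_amplitude = spot_amplitude,
                   noise = noise, background = background, seed = as.integer(seed)),
              class = "image_stack")
  })
}

# voxels of a labelled cell that touch (6-neighbourhood) a different label
boundary_mask <- function(labels) {
  d <- dim(labels)
  b <- array(FALSE, d)
  shift_neq <- function(ax, by) {
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    src <- idx; src[[ax]] <- pmin(pmax(idx[[ax]] + by, 1L), d[ax])
    labels[src[[1]], src[[2]], src[[3]]] != labels
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) b <- b | shift_neq(ax, by)
  b & (labels > 0L)
}

#' Spot amplitude needed for a target signal-to-noise ratio
#'
#' SNR is defined as peak spot amplitude over the off-spot noise SD, which is
#' `sqrt(background + gaussian_sd^2)` with Poisson noise enabled and
#' `gaussian_sd` otherwise.
#'
#' @param snr Target SNR.
#' @param background Background offset, counts.
#' @param noise Noise list as in [render_stack()].
#' @return Amplitude in counts.
#' @export
amplitude_for_snr <- function(snr, background = 100,
                              noise = list(poisson = TRUE, gaussian_sd = 10)) {
  gsd <- noise$gaussian_sd %||% 0
  base_var <- if (isTRUE(noise$poisson)) background + gsd^2 else gsd^2
  if (base_var <= 0) stopf("noise-free model has no defined SNR")
  snr * sqrt(base_var)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("image_stack: %s voxels (%s um), channels: %s\n",
              paste(d, collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}
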