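#' Dual-echo UTE sequence parameters
#'
#' Echo times of the dual-echo ultrashort echo time protocol: an
#' ultrashort first echo (short enough to catch signal from short-T2*
#' collagen-rich tissue) and a short second echo (long enough that nearly
#' all tendon signal has decayed, but short enough that long-T2* muscle
#' signal is nearly unchanged). TR and flip angle are recorded for
#' completeness but unused by the default pure-T2* decay model.
#'
#' @param TE1 first (ultrashort) echo time, ms.
#' @param TE2 second (short) echo time, ms; must exceed `TE1`.
#' @param TR repetition time, ms (recorded, unused).
#' @param flip flip angle, degrees (recorded, unused).
#' @param resolution isotropic voxel spacing, mm.
#' @return list of class `sequence_params`.
#' @export
sequence_params <- function(TE1 = 0.08, TE2 = 2.54, TR = 6, flip = 10,
                            resolution = 0.8) {
  stopifnot(TE1 > 0, TE2 > TE1, resolution > 0)
  structure(list(TE1 = TE1, TE2 = TE2, TR = TR, flip = flip,
                 resolution = resolution),
            class = "sequence_params")
}

#' Synthetic ankle tissue phantom
#'
#' A labeled voxel grid with per-tissue proton density (`S0`, arbitrary
#' units) and effective transverse relaxation time (`T2*`, ms). The
#' default tissue table uses literature-typical values: tendon T2* ~ 1 ms
#' (signal is gone by TE ~ 1 ms or more), muscle 30 ms, fat 40 ms,
#' cortical bone 0.4 ms; background carries no signal.
#'
#' @param labels integer or character matrix/array of tissue labels, or
#'   `NULL` to build the default synthetic sagittal ankle slice (tendon
#'   strip, muscle belly, fat pad, bone) of size `n` x `n`.
#' @param tissues data frame with columns `tissue`, `S0`, `T2star_ms`.
#' @param spacing voxel spacing, mm.
#' @param n grid size of the default phantom.
#' @return list of class `tissue_phantom` with `labels` (character
#'   matrix), `tissues`, `spacing`.
#' @export
tissue_phantom <- function(labels = NULL,
                           tissues = data.frame(
                             tissue = c("background", "tendon", "muscle",
                                        "fat", "bone"),
                             S0 = c(0, 1, 1, 1.1, 0.25),
                             T2star_ms = c(Inf, 1, 30, 40, 0.4)),
                           spacing = 0.8, n = 96) {
  stopifnot(spacing > 0,
            all(tissues$T2star_ms > 0 | tissues$S0 == 0))
  if (is.null(labels)) {
    g <- expand.grid(x = seq_len(n), y = seq_len(n))
    cx <- n / 2
    lab <- matrix("background", n, n)
    inside <- function(x0, y0, rx, ry)
      matrix(((g$x - x0) / rx)^2 + ((g$y - y0) / ry)^2 <= 1, n, n)
    lab[inside(0.42 * n, 0.50 * n, 0.30 * n, 0.42 * n)] <- "muscle"
    lab[inside(0.40 * n, 0.45 * n, 0.12 * n, 0.20 * n)] <- "fat"
    lab[inside(0.30 * n, 0.35 * n, 0.10 * n, 0.12 * n)] <- "bone"
    # tendon: thin near-vertical strip posterior to the muscle
    tend <- abs(g$x - (0.72 * n + 0.04 * n * (g$y / n - 0.5))) <= 0.035 * n &
      g$y > 0.18 * n & g$y < 0.85 * n
    lab[matrix(tend, n, n)] <- "tendon"
    labels <- lab
  }
  labels <- matrix(as.character(labels), nrow(labels), ncol(labels))
  if (!all(unique(as.vector(labels)) %in% tissues$tissue))
    stop("labels contain tissues missing from the tissue table")
  structure(list(labels = labels, tissues = tissues, spacing = spacing),
            class = "tissue_phantom")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat(sprintf("Tissue phantom %d x %d voxels at %.2g mm\n",
              nrow(x$labels), ncol(x$labels), x$spacing))
  tab <- table(x$labels)
  for (nm in names(tab)) {
    row <- x$tissues[x$tissues$tissue == nm, ]
    cat(sprintf("  %-10s %6d voxels  S0 = %.3g, T2* = %g ms\n",
                nm, tab[[nm]], row$S0, row$T2star_ms))
  }
  invisible(x)
}

#' Simulate a gradient-echo image at a given echo time
#'
#' Mono-exponential transverse decay per voxel,
#' \eqn{S = S_0 e^{-TE / T_2^*}}, with optional additive Gaussian noise.
#'
#' @param phantom a [tissue_phantom()] object.
#' @param te echo time, ms, >= 0.
#' @param noise_sd standard deviation of additive Gaussian noise
#'   (signal units); 0 for a noiseless image.
#' @param seed integer seed for the noise (required when `noise_sd > 0`
#'   for reproducibility).
#' @return list of class `echo_image` with `signal` (matrix) and `te`.
#' @export
simulate_echo <- function(phantom, te, noise_sd = 0, seed = NULL) {
  stopifnot(te >= 0, noise_sd >= 0)
  tis <- phantom$tissues
  S0 <- setNames(tis$S0, tis$tissue)
  T2 <- setNames(tis$T2star_ms, tis$tissue)
  lab <- phantom$labels
  sig <- matrix(S0[lab] * exp(-te / T2[lab]), nrow(lab), ncol(lab))
  sig[S0[lab] == 0] <- 0
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    sig <- sig + matrix(rnorm(length(sig), 0, noise_sd),
                        nrow(sig), ncol(sig))
  }
  structure(list(signal = sig, te = te), class = "echo_image")
}

#' Subtract the second echo from the first
#'
#' Voxelwise dual-echo subtraction: long-T2* tissue (similar signal at
#' both echoes) cancels while short-T2* tendon (signal present only at the
#' ultrashort echo) is retained, maximizing tendon signal and contrast.
#'
#' @param first image at the ultrashort echo TE1.
#' @param second image at the short echo TE2 (same grid, `TE2 > TE1`).
#' @return an `echo_image` with the difference signal (`te` = `NA`).
#' @export
subtract_echoes <- function(first, second) {
  if (!all(dim(first$signal) == dim(second$signal)))
    stop("echo images are on different grids")
  if (first$te >= second$te)
    stop("the subtracted echo must have the longer echo time")
  structure(list(signal = first$signal - second$signal, te = NA_real_,
                 te_pair = c(first$te, second$te)),
            class = "echo_image")
}

#' Region contrast of an image
#'
#' Normalized mean-signal contrast `(mean_a - mean_b) / (mean_a + mean_b)`
#' between two regions (tissue names resolved through the phantom's label
#' map, or logical masks).
#'
#' @param image an `echo_image`.
#' @param phantom the [tissue_phantom()] defining the labels (may be
#'   omitted when masks are given).
#' @param region_a,region_b tissue names or logical masks.
#' @return unitless contrast in `[-1, 1]`.
#' @export
echo_contrast <- function(image, phantom = NULL, region_a = "tendon",
                          region_b = "muscle") {
  mask <- function(r) {
    if (is.logical(r)) return(r)
    if (is.null(phantom)) stop("tissue-name regions require the phantom")
    phantom$labels == r
  }
  ma <- mask(region_a); mb <- mask(region_b)
  if (!any(ma) || !any(mb)) stop("empty region")
  a <- mean(image$signal[ma]); b <- mean(image$signal[mb])
  (a - b) / (a + b)
}

#' Tendon-muscle contrast as a function of the second echo time
#'
#' Sweeps the second echo time, computing the tendon-muscle contrast of
#' the subtracted image at each value. Contrast rises as TE2 first
#' exceeds the tendon T2* and then falls again as increasingly long
#' second echoes let muscle signal into the difference image.
#'
#' @param phantom a [tissue_phantom()] object.
#' @param te2_grid vector of second echo times, ms, all > `TE1`.
#' @param seq_params a [sequence_params()] object providing TE1.
#' @return data frame with columns `TE2_ms` and `contrast`.
#' @export
te2_sweep <- function(phantom, te2_grid, seq_params = sequence_params()) {
  stopifnot(all(te2_grid > seq_params$TE1))
  first <- simulate_echo(phantom, seq_params$TE1)
  ct <- vapply(te2_grid, function(te2) {
    echo_contrast(subtract_echoes(first, simulate_echo(phantom, te2)),
                  phantom)
  }, numeric(1))
  data.frame(TE2_ms = te2_grid, contrast = ct)
}

#' Write an echo image or phantom as a NIfTI volume
#'
#' Requires the optional RNifti package.
#'
#' @param x an `echo_image` or `tissue_phantom`.
#' @param file output path (`.nii` / `.nii.gz`).
#' @param spacing voxel spacing, mm.
#' @return the path, invisibly.
#' @export
write_nifti <- function(x, file, spacing = 0.8) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("writing NIfTI volumes requires the RNifti package")
  dat <- if (inherits(x, "echo_image")) x$signal
  else matrix(as.integer(factor(x$labels)), nrow(x$labels), ncol(x$labels))
  img <- RNifti::asNifti(array(dat, c(dim(dat), 1)),
                         pixdim = c(spacing, spacing, spacing))
  RNifti::writeNifti(img, file)
  invisible(file)
}
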