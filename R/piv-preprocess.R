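#' POD-based background removal
#'
#' Removes the quasi-static image background by proper orthogonal
#' decomposition: the frames are arranged as columns of a pixels-by-frames
#' matrix, its leading `n_background_modes` singular modes are taken as the
#' background, and the reconstruction is subtracted from each frame.
#' Negative residual intensities are clipped to zero in the returned frames;
#' the unclipped residual and the background reconstruction are carried
#' along for diagnostics (the background is orthogonal to the unclipped
#' residual by construction).
#'
#' @param stack An `image_stack` or a frames array (n_frames x h x w).
#' @param n_background_modes Number of leading modes treated as background
#'   (default 1). Must be >= 1 and < the number of frames.
#' @return An `image_stack` with cleaned `frames`, plus `background` and
#'   `residual_raw` arrays.
#' @examples
#' st <- generate_particle_images(image_stack_config(n_frames = 6))
#' out <- pod_background_removal(st)
#' @export
pod_background_removal <- function(stack, n_background_modes = 1L) {
  frames <- stack_frames(stack)
  d <- dim(frames)
  if (n_background_modes < 1L || n_background_modes >= d[1])
    stop("`n_background_modes` must be >= 1 and < the number of frames",
         call. = FALSE)
  # pixels x frames snapshot matrix
  M <- t(matrix(frames, d[1], d[2] * d[3]))
  sv <- svd(M, nu = n_background_modes, nv = n_background_modes)
  bg <- sv$u %*% (sv$d[seq_len(n_background_modes)] *
                    t(sv$v[, seq_len(n_background_modes), drop = FALSE]))
  resid <- M - bg
  out <- structure(list(
    frames = array(t(pmax(resid, 0)), dim = d),
    background = array(t(bg), dim = d),
    residual_raw = array(t(resid), dim = d),
    singular_values = sv$d,
    n_background_modes = as.integer(n_background_modes)
  ), class = "image_stack")
  out
}

#' Anisotropic-diffusion background removal
#'
#' Estimates a per-frame background by evolving the frame under
#' Perona-Malik diffusion with edge-stopping function
#' `g(s) = 1 / (1 + (s / kappa)^2)` on a 4-neighbour stencil, then
#' subtracts it. Strong structures (wall reflections, the vocal-fold
#' silhouette edge) survive the diffusion and are therefore removed by the
#' subtraction, while weak small-scale particle images diffuse away from
#' the background estimate and are retained in the output. Negatives are
#' clipped to zero.
#'
#' @param stack An `image_stack` or a frames array.
#' @param kappa Edge-stopping contrast scale; default 10% of the stack's
#'   dynamic range.
#' @param n_iter Number of explicit diffusion steps (default 50).
#' @param dt Step size; must be <= 0.25 for explicit-scheme stability on the
#'   4-neighbour stencil (default 0.2).
#' @return An `image_stack` with cleaned `frames` and the estimated
#'   `background`.
#' @export
anisotropic_diffusion_background <- function(stack, kappa = NULL,
                                             n_iter = 50L, dt = 0.2) {
  frames <- stack_frames(stack)
  if (is.null(kappa)) kappa <- 0.1 * diff(range(frames))
  if (!is.numeric(kappa) || kappa <= 0)
    stop("`kappa` must be positive", call. = FALSE)
  if (n_iter < 1L) stop("`n_iter` must be >= 1", call. = FALSE)
  if (dt > 0.25 || dt <= 0)
    stop("`dt` must be in (0, 0.25] for explicit stability", call. = FALSE)
  d <- dim(frames)
  bg <- frames
  for (fr in seq_len(d[1])) {
    b <- bg[fr, , ]
    for (it in seq_len(n_iter)) {
      dN <- rbind(b[1, , drop = FALSE], b[-d[2], , drop = FALSE]) - b
      dS <- rbind(b[-1, , drop = FALSE], b[d[2], , drop = FALSE]) - b
      dW <- cbind(b[, 1, drop = FALSE], b[, -d[3], drop = FALSE]) - b
      dE <- cbind(b[, -1, drop = FALSE], b[, d[3], drop = FALSE]) - b
      b <- b + dt * (dN / (1 + (dN / kappa)^2) + dS / (1 + (dS / kappa)^2) +
                       dW / (1 + (dW / kappa)^2) + dE / (1 + (dE / kappa)^2))
    }
    bg[fr, , ] <- b
  }
  structure(list(frames = pmax(frames - bg, 0), background = bg),
            class = "image_stack")
}

#' Blend two conditioned stacks by image region
#'
#' Combines the diffusion-conditioned glottis-proximal strip (columns left
#' of `split_x`) with the POD-conditioned remainder, optionally cross-faded
#' linearly over `overlap` pixels centred on the split column.
#'
#' @param glottal `image_stack` (or array) used left of the split.
#' @param downstream `image_stack` (or array) used right of the split.
#' @param split_x Pixel column separating the two regions (0 selects the
#'   downstream result everywhere, `width` the glottal result everywhere).
#' @param overlap Cross-fade width in pixels (default 4; 0 for a hard seam).
#' @return An `image_stack`.
#' @export
blend_preprocessed <- function(glottal, downstream, split_x, overlap = 4L) {
  A <- stack_frames(glottal)
  B <- stack_frames(downstream)
  if (!identical(dim(A), dim(B)))
    stop("stacks must have identical shapes", call. = FALSE)
  w <- dim(A)[3]
  if (split_x < 0 || split_x > w)
    stop("`split_x` must lie within the image width", call. = FALSE)
  # weight of the glottal stack per column: 1 left of the split, 0 right
  wt <- as.numeric(seq_len(w) <= split_x)
  if (overlap > 0 && split_x > 0 && split_x < w) {
    ramp <- split_x + seq(-overlap / 2, overlap / 2, length.out = overlap + 1L)
    for (i in seq_len(w))
      if (i >= ramp[1] && i <= ramp[length(ramp)])
        wt[i] <- 1 - (i - ramp[1]) / (ramp[length(ramp)] - ramp[1])
  }
  W <- array(rep(wt, each = dim(A)[1] * dim(A)[2]), dim = dim(A))
  structure(list(frames = W * A + (1 - W) * B), class = "image_stack")
}

#' Planar vector field container
#'
#' @param u,v Velocity component matrices (ny x nx).
#' @param valid Optional logical validity mask, same shape.
#' @return A `vector_field`.
#' @export
vector_field <- function(u, v, valid = NULL) {
  if (!is.matrix(u) || !identical(dim(u), dim(v)))
    stop("`u` and `v` must be matrices of identical shape", call. = FALSE)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(u), ncol(u))
  if (!identical(dim(valid), dim(u)))
    stop("`valid` must match the grid shape", call. = FALSE)
  structure(list(u = u, v = v, valid = valid), class = "vector_field")
}

#' Normalized-median outlier detection and repair
#'
#' Westerweel-Scarano universal outlier detection: for every vector and
#' each component, the residual to the median of the 3x3 neighbourhood
#' (centre excluded; borders use the available neighbours) is normalised by
#' the median of the neighbours' own residuals plus `eps`,
#' `r* = |U - U_med| / (r_med + eps)`. A vector whose larger component
#' `r*` exceeds `threshold` is flagged and replaced by the per-component
#' median of its non-flagged neighbours. Vectors whose neighbours are all
#' flagged are left unrepaired and reported.
#'
#' @param field A [vector_field()] (its `valid` mask marks vectors already
#'   known bad; they are excluded from medians and repaired too).
#' @param threshold Detection threshold on `r*` (default 2, the customary
#'   value for PIV data).
#' @param eps Residual floor in velocity units, representing the
#'   measurement noise level (default 0.1).
#' @return A list with `field` (repaired `vector_field` whose `valid` mask
#'   is FALSE at flagged vectors), `outliers` (logical matrix of flagged
#'   vectors), `r_star` (matrix of the max-component test statistic) and
#'   `unrepaired` (logical matrix of vectors left unrepaired).
#' @export
universal_outlier_detection <- function(field, threshold = 2, eps = 0.1) {
  stopifnot(inherits(field, "vector_field"))
  ny <- nrow(field$u); nx <- ncol(field$u)
  if (ny < 3L || nx < 3L) stop("grid must be at least 3 x 3", call. = FALSE)
  if (eps < 0) stop("`eps` must be >= 0", call. = FALSE)

  rstar_component <- function(U, valid) {
    out <- matrix(0, ny, nx)
    for (i in seq_len(ny)) for (j in seq_len(nx)) {
      ii <- max(1L, i - 1L):min(ny, i + 1L)
      jj <- max(1L, j - 1L):min(nx, j + 1L)
      nb <- U[ii, jj]
      ok <- valid[ii, jj]
      ok[which(ii == i), which(jj == j)] <- FALSE  # drop the centre
      nb <- nb[ok]
      if (!length(nb)) { out[i, j] <- Inf; next }
      med <- stats::median(nb)
      rmed <- stats::median(abs(nb - med))
      out[i, j] <- abs(U[i, j] - med) / (rmed + eps)
    }
    out
  }
  rs <- pmax(rstar_component(field$u, field$valid),
             rstar_component(field$v, field$valid))
  flagged <- rs > threshold | !field$valid

  u <- field$u; v <- field$v
  unrepaired <- matrix(FALSE, ny, nx)
  idx <- which(flagged, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    ii <- max(1L, i - 1L):min(ny, i + 1L)
    jj <- max(1L, j - 1L):min(nx, j + 1L)
    ok <- !flagged[ii, jj]
    ok[which(ii == i), which(jj == j)] <- FALSE
    if (!any(ok)) { unrepaired[i, j] <- TRUE; next }
    u[i, j] <- stats::median(field$u[ii, jj][ok])
    v[i, j] <- stats::median(field$v[ii, jj][ok])
  }
  list(field = vector_field(u, v, valid = !flagged | (flagged & !unrepaired)),
       outliers = flagged, r_star = rs, unrepaired = unrepaired)
}
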