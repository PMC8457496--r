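#' Visser-corrected vertical random-walk step
#'
#' One step of the vertical diffusion scheme for particles in a water
#' column with depth-varying eddy diffusivity. The naive random walk
#' accumulates particles where diffusivity is low; the corrected scheme
#'
#' \deqn{z' = z + K'(z)\,\Delta t + R \sqrt{2 K(z + \tfrac12 K'(z)\Delta t)\,\Delta t / r}}
#'
#' with `R` a zero-mean random deviate of variance `r`, advects particles
#' up the diffusivity gradient and evaluates the diffusive amplitude at the
#' offset midpoint, restoring the well-mixed condition. Boundaries are
#' reflective at the surface (z = 0) and the bottom (z = H). Note depth is
#' positive downward, so `K'` here is dK/dz with z downward.
#'
#' The scheme is only consistent when the time step resolves the curvature
#' of the diffusivity profile; the step is rejected when `dt` exceeds
#' `1 / max |K''(z)|` estimated over the column.
#'
#' @param depth particle depths (m, positive down), vectorized.
#' @param K function of depth returning eddy diffusivity (m^2/s).
#' @param dKdz function of depth returning dK/dz (m/s).
#' @param dt time step (s).
#' @param H bottom depth (m); scalar or one value per particle.
#' @param draws optional uniform(-1, 1) deviates (one per particle); drawn
#'   from the session RNG when omitted. Uniform deviates have variance
#'   r = 1/3.
#' @return new depths (m).
#' @export
visser_step <- function(depth, K, dKdz, dt, H, draws = NULL) {
  bound <- visser_stability_bound(K, H = max(H))
  .assert(dt <= bound,
          sprintf("dt = %g s exceeds the Visser stability bound %g s (1/max|K''|) for this diffusivity profile",
                  dt, bound))
  n <- length(depth)
  if (is.null(draws)) draws <- runif(n, -1, 1)
  r <- 1 / 3
  grad <- dKdz(depth)
  zmid <- depth + 0.5 * grad * dt
  zmid <- pmin(pmax(zmid, 0), H)
  z_new <- depth + grad * dt + draws * sqrt(2 * pmax(K(zmid), 0) * dt / r)
  reflect_depth(z_new, H)
}

#' @rdname visser_step
#' @param n_grid grid resolution for the numerical curvature scan.
#' @return `visser_stability_bound()`: the largest admissible time step
#'   (s), `1 / max |K''|` over the column (Inf for profiles with no
#'   curvature).
#' @export
visser_stability_bound <- function(K, H, n_grid = 201) {
  z <- seq(0, H, length.out = n_grid)
  h <- z[2] - z[1]
  k <- K(z)
  if (length(k) == 1) k <- rep(k, n_grid)
  curv <- abs(diff(k, differences = 2)) / h^2
  m <- max(curv, 0)
  if (m < .Machine$double.eps) return(Inf)
  1 / m
}

# reflect depths into [0, H]; repeated folding handles large excursions
reflect_depth <- function(z, H) {
  for (i in 1:4) {
    z <- ifelse(z < 0, -z, z)
    z <- ifelse(z > H, 2 * H - z, z)
    if (all(z >= 0 & z <= H)) break
  }
  pmin(pmax(z, 0), H)
}
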