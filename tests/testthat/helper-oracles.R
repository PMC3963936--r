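# Independent numerical oracles used by the tests.  These deliberately share
# no code path with the package's Monte Carlo / closed-form routines.

# Deterministic quadrature of the straight-track electron absorbed fraction:
# dense grid over emission points (each thyroid voxel subdivided split^3) and
# a Fibonacci-sphere direction grid; per ray, the deposited fraction is the
# share of track midpoints (n_step per range) lying inside the thyroid.
oracle_electron_fraction <- function(phantom, energy_keV, n_dirs = 48,
                                     n_step = 64, split = 2) {
  R <- csda_range_mm(energy_keV, phantom$densities[["soft"]])
  vox <- phantom$voxel_mm
  nx <- phantom$dims[1]; ny <- phantom$dims[2]; nz <- phantom$dims[3]
  lin0 <- phantom$thyroid_idx
  iz <- lin0 %/% (nx * ny); rem <- lin0 %% (nx * ny)
  iy <- rem %/% nx; ix <- rem %% nx

  offs <- (seq_len(split) - 0.5) / split
  og <- expand.grid(ox = offs, oy = offs, oz = offs)
  px <- as.vector(outer(ix, og$ox, `+`)) * vox
  py <- as.vector(outer(iy, og$oy, `+`)) * vox
  pz <- as.vector(outer(iz, og$oz, `+`)) * vox
  npts <- length(px)

  i <- seq_len(n_dirs) - 1
  z <- 1 - (2 * i + 1) / n_dirs
  phi <- i * pi * (3 - sqrt(5))
  sx <- sqrt(1 - z^2) * cos(phi); sy <- sqrt(1 - z^2) * sin(phi); sz <- z

  lab <- as.integer(phantom$labels)
  total <- 0
  for (d in seq_len(n_dirs)) {
    inside <- 0
    for (k in seq_len(n_step)) {
      s <- (k - 0.5) * R / n_step
      jx <- floor((px + s * sx[d]) / vox)
      jy <- floor((py + s * sy[d]) / vox)
      jz <- floor((pz + s * sz[d]) / vox)
      ok <- jx >= 0 & jx < nx & jy >= 0 & jy < ny & jz >= 0 & jz < nz
      idx <- jx[ok] + nx * jy[ok] + nx * ny * jz[ok] + 1
      inside <- inside + sum(lab[idx] == 2L)
    }
    total <- total + inside / (npts * n_step)
  }
  total / n_dirs
}

# Adaptive quadrature of a fitted piecewise time-activity curve in Bq s.
oracle_cumulated_Bq_s <- function(fit, t_end_h) {
  up <- stats::integrate(function(t) predict(fit, t), 0, fit$peak_time_h,
                         rel.tol = 1e-10)$value
  down <- stats::integrate(function(t) predict(fit, t), fit$peak_time_h,
                           t_end_h, rel.tol = 1e-10)$value
  (up + down) * 1e6 * 3600
}

# Run expr under a fixed seed without touching the package's RNG helpers.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

# Small shared fixtures (built once per test run)
phantom_default <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- build_phantom()
    ph
  }
})
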