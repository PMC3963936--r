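#' Thyroid self S-value by Monte Carlo
#'
#' Computes the self S-value (absorbed dose per unit cumulated activity,
#' Gy/Bq/s) of the thyroid region in a voxel phantom for a given emission
#' spectrum:
#' \deqn{S = \sum_i y_i E_i \phi(E_i) / m}
#' where the absorbed fraction \eqn{\phi} of each electron line is estimated
#' by seeded straight-track Monte Carlo ([electron_absorbed_fraction()]) and
#' each photon line by the analytic mean-chord model
#' ([photon_absorbed_fraction()]).  The statistical uncertainty is a
#' batch-means standard error over `n_batch` equal batches of histories,
#' shared across electron lines.
#'
#' @param phantom A [build_phantom()] object.
#' @param spectrum An [load_emission_spectrum()] object.
#' @param n Monte Carlo histories per electron line (>= 1000 for a reported
#'   standard error).
#' @param seed RNG seed (default 20140324).
#' @param n_batch Batches for the standard error (default 20).
#' @param n_sub Track sub-steps per history (default 32).
#' @param transport `"mc"` (default) for Monte Carlo electron transport, or
#'   `"local"` to force every electron absorbed fraction to 1 (full local
#'   deposition closed form, useful as an analytic limit).
#' @return An object of class `svalue_result`: list with `s_value`
#'   (Gy/Bq/s), `relative_se`, `n_histories`, `electron_fraction` (share of
#'   absorbed energy carried by electrons), `seed`, `mass_mg`, `per_line`
#'   (data frame of per-line absorbed fractions) and `batch_s` (per-batch
#'   S-values).
#' @examples
#' ph <- build_phantom()
#' sp <- tc99m_spectrum()
#' self_svalue(ph, sp, n = 2000, seed = 1)
#' @export
self_svalue <- function(phantom, spectrum, n = 1e5, seed = 20140324,
                        n_batch = 20, n_sub = 32,
                        transport = c("mc", "local")) {
  stopifnot(inherits(phantom, "voxel_phantom"),
            inherits(spectrum, "emission_spectrum"))
  transport <- match.arg(transport)
  stopifnot_scalar(n, "n", positive = TRUE)
  if (transport == "mc" && n < 1000)
    stop("n must be >= 1000 for a reported standard error", call. = FALSE)
  lines <- spectrum$lines
  if (nrow(lines) == 0L) stop("spectrum has no lines", call. = FALSE)

  mass_kg <- phantom$thyroid_mass_mg * 1e-6
  el <- lines[lines$kind == "electron", , drop = FALSE]
  ph <- lines[lines$kind == "photon", , drop = FALSE]

  # Photon part: analytic, no Monte Carlo noise.
  phi_ph <- if (nrow(ph)) vapply(ph$energy_keV, photon_absorbed_fraction,
                                 numeric(1), phantom = phantom) else numeric(0)
  photon_dep_keV <- sum(ph$yield * ph$energy_keV * phi_ph)

  n_batch <- as.integer(min(n_batch, n))
  if (nrow(el)) {
    if (transport == "local") {
      batch_mat <- matrix(1, nrow = nrow(el), ncol = n_batch)
    } else {
      # One RNG stream across lines: deterministic for a fixed spectrum order.
      # Sub-table-minimum electrons (< 1 keV) deposit fully at the decay site.
      emin <- min(load_range_table()$energy)
      batch_mat <- with_seed(seed, {
        t(vapply(seq_len(nrow(el)), function(i) {
          if (el$energy_keV[i] < emin) return(rep(1, n_batch))
          range_mm <- csda_range_mm(el$energy_keV[i], phantom$densities[["soft"]])
          cpp_track_batch_fractions(
            as.integer(phantom$labels), as.integer(phantom$dims),
            phantom$voxel_mm, phantom$thyroid_idx, range_mm,
            as.integer(n), n_batch, as.integer(n_sub))
        }, numeric(n_batch)))
      })
    }
    w <- el$yield * el$energy_keV
    electron_dep_batch <- as.vector(w %*% batch_mat)   # keV per decay, per batch
    phi_el <- rowMeans(batch_mat)
  } else {
    electron_dep_batch <- rep(0, n_batch)
    phi_el <- numeric(0)
  }

  batch_s <- (electron_dep_batch + photon_dep_keV) * .KEV_TO_J / mass_kg
  s_value <- mean(batch_s)
  se <- if (n_batch > 1) sd(batch_s) / sqrt(n_batch) else NA_real_
  electron_dep_keV <- mean(electron_dep_batch)

  per_line <- rbind(
    if (nrow(el)) data.frame(kind = "electron", energy_keV = el$energy_keV,
                             yield = el$yield, absorbed_fraction = phi_el),
    if (nrow(ph)) data.frame(kind = "photon", energy_keV = ph$energy_keV,
                             yield = ph$yield, absorbed_fraction = phi_ph))

  structure(list(
    s_value = s_value,
    relative_se = if (is.na(se)) NA_real_ else se / s_value,
    n_histories = as.integer(n),
    electron_fraction = electron_dep_keV / (electron_dep_keV + photon_dep_keV),
    seed = seed,
    mass_mg = phantom$thyroid_mass_mg,
    transport = transport,
    per_line = per_line,
    batch_s = batch_s
  ), class = "svalue_result")
}

#' @export
print.svalue_result <- function(x, ...) {
  cat(sprintf("<svalue_result> S = %.4e Gy/Bq/s  (mass %.3f mg)\n",
              x$s_value, x$mass_mg))
  cat(sprintf("  relative SE %.3f%%  |  %d histories/line  |  electron fraction %.3f  |  seed %s\n",
              100 * x$relative_se, x$n_histories, x$electron_fraction,
              format(x$seed)))
  invisible(x)
}
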