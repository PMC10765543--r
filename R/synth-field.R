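# Synthetic repolarization/activation fields on the mapping lattice.
# RT follows a linear restitution law per wall plus apicobasal and
# transmural gradients and iid dispersion noise; every generated value is
# kept as ground truth so downstream detectors can be scored exactly.

#' Parameters for synthetic repolarization fields
#'
#' The repolarization time of electrode e at cycle length \code{rr_ms} is
#' \deqn{RT(e) = \alpha_w + \beta_w rr + g_{ab}(level-1) + g_{tm} depth +
#'   \Delta + N(0, \sigma^2)}
#' with wall-specific restitution intercept \eqn{\alpha_w} (ms) and slope
#' \eqn{\beta_w} (ms RT per ms RR, LV steeper than RV), an apicobasal
#' gradient per level, a transmural gradient per depth step, a global offset
#' \eqn{\Delta} (used for pre-steady-state timepoints) and dispersion noise
#' \eqn{\sigma}. Activation times come from a paced-activation template:
#' wall means (RV earliest, reflecting right-ventricular apical pacing) with
#' a base-to-apex slope and activation noise.
#'
#' Default restitution coefficients are anchored by least squares to the
#' serial wall means of the chronic AV-block dog under dofetilide across the
#' four fixed pacing rates (RR 600/750/1000/1200 ms), giving
#' \eqn{\beta_{LV} = 0.194 > \beta_{RV} = 0.111}.
#'
#' @param alpha named restitution intercepts (ms) per wall.
#' @param beta named restitution slopes (ms/ms) per wall; the
#'   interventricular-divergence mode requires \code{beta["LV"] > beta["RV"]}.
#' @param apicobasal_gradient_ms_per_level RT increase per base-to-apex level.
#' @param transmural_gradient_ms_per_depth RT increase per depth step
#'   (epicardium to endocardium).
#' @param dispersion_noise_sd_ms SD of electrode-level dispersion noise (ms).
#' @param rt_offset_ms global RT offset (ms), e.g. negative before dofetilide
#'   reaches steady state.
#' @param dofetilide_effect list with \code{rt_prolongation_ms} and
#'   \code{dispersion_multiplier}; applied when \code{dofetilide = TRUE} in
#'   [generate_rt_field()].
#' @param at_mean_ms named activation-time wall means (ms after stimulus).
#' @param at_level_slope_ms_per_level activation slope towards the base
#'   (apex is captured first under apical pacing).
#' @param at_noise_sd_ms SD of activation noise (ms).
#' @return list of class \code{rt_field_params}.
#' @export
rt_field_params <- function(alpha = c(RV = 277, LV = 258, SEPTUM = 267),
                            beta = c(RV = 0.111, LV = 0.194, SEPTUM = 0.150),
                            apicobasal_gradient_ms_per_level = 4,
                            transmural_gradient_ms_per_depth = 3,
                            dispersion_noise_sd_ms = 10,
                            rt_offset_ms = 0,
                            dofetilide_effect = list(rt_prolongation_ms = 0,
                                                     dispersion_multiplier = 1),
                            at_mean_ms = c(RV = 40, LV = 61, SEPTUM = 50),
                            at_level_slope_ms_per_level = -3,
                            at_noise_sd_ms = 10) {
  stopifnot(dispersion_noise_sd_ms >= 0, at_noise_sd_ms >= 0)
  stopifnot(all(WALLS %in% names(alpha)), all(WALLS %in% names(beta)))
  structure(list(
    alpha = alpha, beta = beta,
    apicobasal_gradient_ms_per_level = apicobasal_gradient_ms_per_level,
    transmural_gradient_ms_per_depth = transmural_gradient_ms_per_depth,
    dispersion_noise_sd_ms = dispersion_noise_sd_ms,
    rt_offset_ms = rt_offset_ms,
    dofetilide_effect = dofetilide_effect,
    at_mean_ms = at_mean_ms,
    at_level_slope_ms_per_level = at_level_slope_ms_per_level,
    at_noise_sd_ms = at_noise_sd_ms
  ), class = "rt_field_params")
}

.sdrmap_cache <- new.env(parent = emptyenv())

# Expected range of {deterministic offsets + sigma * Z} over the electrodes
# of one cubic unit, estimated by Monte Carlo with common random numbers so
# the curve is smooth in sigma and the inversion is deterministic.
expected_unit_range <- function(sigma, offsets, n_sims = 4000L) {
  key <- paste0("Z", length(offsets), "_", n_sims)
  if (is.null(.sdrmap_cache[[key]])) {
    .sdrmap_cache[[key]] <- with_local_seed(204861L,
      matrix(stats::rnorm(n_sims * length(offsets)), nrow = n_sims))
  }
  Z <- .sdrmap_cache[[key]]
  X <- sweep(Z * sigma, 2L, offsets, "+")
  mean(apply(X, 1L, max) - apply(X, 1L, min))
}

#' Invert a target cubic dispersion to a dispersion-noise SD
#'
#' Solves, by root finding on a Monte-Carlo estimate of the expected
#' max-minus-min over one 2 x 2 needle square (16 electrodes, deterministic
#' apicobasal/transmural offsets plus iid noise), for the noise SD at which
#' the expected cubic dispersion unit value equals \code{target_cubic_ms}.
#' This is how the timepoint presets realize the study's cubic dispersion
#' levels.
#'
#' @param target_cubic_ms requested expected cubic dispersion (ms).
#' @param apicobasal_gradient_ms_per_level,transmural_gradient_ms_per_depth
#'   deterministic gradients inside a square.
#' @return noise SD in ms.
#' @export
calibrate_dispersion_noise <- function(target_cubic_ms,
                                       apicobasal_gradient_ms_per_level = 4,
                                       transmural_gradient_ms_per_depth = 3) {
  key <- sprintf("cal_%g_%g_%g", target_cubic_ms,
                 apicobasal_gradient_ms_per_level,
                 transmural_gradient_ms_per_depth)
  if (!is.null(.sdrmap_cache[[key]])) return(.sdrmap_cache[[key]])
  # 16 electrodes: 2 levels x 2 columns x 4 depths; columns carry no
  # deterministic offset, so each level/depth offset appears twice
  offsets <- rep(as.vector(outer(apicobasal_gradient_ms_per_level * (0:1),
                                 transmural_gradient_ms_per_depth * (0:3),
                                 "+")), times = 2)
  det_range <- max(offsets) - min(offsets)
  if (target_cubic_ms <= det_range) {
    stop("target cubic dispersion (", target_cubic_ms,
         " ms) not reachable: deterministic gradients alone span ",
         det_range, " ms")
  }
  f <- function(s) expected_unit_range(s, offsets) - target_cubic_ms
  sd <- stats::uniroot(f, lower = 1e-3, upper = max(200, target_cubic_ms),
                       tol = 1e-3)$root
  .sdrmap_cache[[key]] <- sd
  sd
}

#' Timepoint presets for the pacing protocol
#'
#' Returns field parameters and cycle length for one of the six analysis
#' timepoints of the RVA50-100-80-60 protocol: just before the first ectopic
#' beat (\code{"EB"}) and just before the first Torsade de Pointes
#' (\code{"TdP"}), both during RVA50 pacing after dofetilide; 60 s into the
#' RVA100, RVA80 and RVA60 blocks; and the retrospective-control arm
#' (\code{"RVA60_retro"}, RVA60 shortly after defibrillation without prior
#' high-rate pacing). The dispersion-noise SD of each preset is calibrated
#' with [calibrate_dispersion_noise()] so the expected cubic dispersion
#' matches the study-level group mean for that timepoint (103, 125, 49, 62,
#' 107 and 101 ms respectively).
#'
#' @param timepoint one of \code{"EB"}, \code{"TdP"}, \code{"RVA100"},
#'   \code{"RVA80"}, \code{"RVA60"}, \code{"RVA60_retro"}.
#' @return list with elements \code{timepoint}, \code{rr_ms}, \code{qt_ms}
#'   (surface-lead QT for the synthetic lead), \code{target_cubic_ms} and
#'   \code{params} (an [rt_field_params()] object).
#' @export
preset_field_params <- function(timepoint = c("EB", "TdP", "RVA100", "RVA80",
                                              "RVA60", "RVA60_retro")) {
  timepoint <- match.arg(timepoint)
  tab <- list(
    EB          = list(rr = 1200, qt = 573, cubic = 103, offset = -35),
    TdP         = list(rr = 1200, qt = 626, cubic = 125, offset = 0),
    RVA100      = list(rr = 600,  qt = 453, cubic = 49,  offset = 0),
    RVA80       = list(rr = 750,  qt = 508, cubic = 62,  offset = 0),
    RVA60       = list(rr = 1000, qt = 598, cubic = 107, offset = 0),
    RVA60_retro = list(rr = 1000, qt = 513, cubic = 101, offset = -33)
  )[[timepoint]]
  sd <- calibrate_dispersion_noise(tab$cubic)
  list(timepoint = timepoint, rr_ms = tab$rr, qt_ms = tab$qt,
       target_cubic_ms = tab$cubic,
       params = rt_field_params(dispersion_noise_sd_ms = sd,
                                rt_offset_ms = tab$offset))
}

#' Generate a ground-truthed repolarization field
#'
#' Draws per-electrode activation and repolarization times on a mapping grid
#' under [rt_field_params()]. Reproducible: the same seed and parameters
#' give an identical field.
#'
#' @param grid a [build_mapping_grid()] object.
#' @param params an [rt_field_params()] object.
#' @param rr_ms paced cycle length in ms (> 0).
#' @param timepoint label attached to the field.
#' @param dofetilide apply \code{params$dofetilide_effect}?
#' @param seed optional integer; when given, the field is drawn from a local
#'   RNG stream seeded with it (the caller's RNG state is untouched).
#' @return an [rt_field()] object whose \code{values} carry the exact truth.
#' @export
generate_rt_field <- function(grid, params = rt_field_params(), rr_ms,
                              timepoint = "RVA100", dofetilide = FALSE,
                              seed = NULL) {
  stopifnot(inherits(grid, "mapping_grid"), inherits(params, "rt_field_params"),
            rr_ms > 0)
  el <- grid$electrodes
  if (!all(el$wall %in% names(params$alpha))) stop("invalid wall in grid")
  draw <- function() {
    sd_disp <- params$dispersion_noise_sd_ms
    prolong <- 0
    if (dofetilide) {
      sd_disp <- sd_disp * params$dofetilide_effect$dispersion_multiplier
      prolong <- params$dofetilide_effect$rt_prolongation_ms
    }
    rt <- params$alpha[el$wall] + params$beta[el$wall] * rr_ms +
      params$apicobasal_gradient_ms_per_level * (el$level - 1L) +
      params$transmural_gradient_ms_per_depth * el$depth +
      params$rt_offset_ms + prolong +
      stats::rnorm(nrow(el), 0, sd_disp)
    at <- params$at_mean_ms[el$wall] +
      params$at_level_slope_ms_per_level * (el$level - mean(range(el$level))) +
      stats::rnorm(nrow(el), 0, params$at_noise_sd_ms)
    at <- pmax(at, 5)
    list(at = as.numeric(at), rt = as.numeric(rt))
  }
  v <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  rt_field(grid, at_ms = v$at, rt_ms = v$rt, rr_ms = rr_ms,
           timepoint = timepoint)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}
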