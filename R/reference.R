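# Published group-level reference values for the chronic AV-block dog
# under the RVA50-100-80-60 protocol. These printed means are inputs to
# desk-scale checks (rate-correction arithmetic, interventricular dRT,
# restitution direction) and anchor the synthetic-data presets.

#' Reference electrophysiology values per protocol timepoint
#'
#' Group means from serial intramural mapping in the chronic AV-block dog
#' model challenged with dofetilide: just before the first ectopic beat
#' (EB) and first Torsade de Pointes (TdP) during RVA50 pacing, 60 s into
#' the RVA100/RVA80/RVA60 blocks, and the retrospective-control arm paced
#' at RVA60 after defibrillation (\code{RVA60_retro}). \code{qtc_ms} and
#' \code{drt_ms} are the published rounded values; both are recomputable
#' from the other columns (\code{qtc_van_de_water(qt, rr)};
#' \code{lv_rt_ms - rv_rt_ms}).
#'
#' @return data.frame, one row per timepoint: \code{timepoint},
#'   \code{rr_ms}, \code{qt_ms}, \code{qtc_ms}, \code{rv_at_ms},
#'   \code{lv_at_ms}, \code{rv_rt_ms}, \code{lv_rt_ms}, \code{drt_ms},
#'   \code{sdr_transmural_ms}, \code{sdr_vertical_ms},
#'   \code{sdr_horizontal_ms}, \code{sdr_cubic_ms}.
#' @export
#' @examples
#' ref <- reference_intervals()
#' with(ref[ref$timepoint == "RVA100", ],
#'      round_ms(qtc_van_de_water(qt_ms, rr_ms)))  # 488
reference_intervals <- function() {
  data.frame(
    timepoint = c("EB", "TdP", "RVA100", "RVA80", "RVA60", "RVA60_retro"),
    rr_ms = c(1200, 1200, 600, 750, 1000, 1000),
    qt_ms = c(573, 626, 453, 508, 598, 513),
    qtc_ms = c(555, 609, 488, 530, 598, 513),
    rv_at_ms = c(40, 41, 39, 39, 38, 42),
    lv_at_ms = c(63, 62, 60, 60, 60, 59),
    rv_rt_ms = c(363, 403, 330, 376, 392, 360),
    lv_rt_ms = c(453, 480, 363, 413, 464, 395),
    drt_ms = c(90, 78, 33, 37, 73, 35),
    sdr_transmural_ms = c(48, 62, 25, 30, 48, 49),
    sdr_vertical_ms = c(69, 74, 32, 47, 66, 59),
    sdr_horizontal_ms = c(78, 98, 38, 46, 75, 75),
    sdr_cubic_ms = c(103, 125, 49, 62, 107, 101),
    stringsAsFactors = FALSE
  )
}
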