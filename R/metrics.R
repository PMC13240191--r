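# desk metrics of the storage platform

#' Per-area payload density
#'
#' Reciprocal of the per-molecule surface footprint: with one strand per
#' `footprint_nm2` square nanometres, the areal density is
#' `1 / footprint_nm2` copies per nm^2.
#'
#' @param footprint_nm2 Surface area allocated per molecule (nm^2).
#' @return Copies per nm^2.
#' @examples
#' payload_density(28.57)   # ~0.035 copies/nm^2
#' @export
payload_density <- function(footprint_nm2) {
  stopifnot(footprint_nm2 > 0)
  1 / footprint_nm2
}

#' Electrode capacity from areal density
#'
#' @param density Copies per nm^2, e.g. from [payload_density()].
#' @param area_nm2 Electrode area in nm^2.
#' @return Copies per electrode.
#' @export
electrode_capacity <- function(density, area_nm2) density * area_nm2

#' Percent reduction in protocol time
#'
#' Reduction from a sequential protocol (hybridization followed by
#' synthesis) to a simultaneous hybridization-plus-synthesis protocol.
#'
#' @param standard_min Total minutes of the sequential protocol.
#' @param simultaneous_min Minutes of the combined protocol.
#' @return Percent reduction.
#' @examples
#' protocol_time_reduction(1.5 + 20, 1.5)   # ~93%
#' @export
protocol_time_reduction <- function(standard_min, simultaneous_min) {
  stopifnot(standard_min > 0, simultaneous_min >= 0)
  100 * (standard_min - simultaneous_min) / standard_min
}
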