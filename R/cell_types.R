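#' Cell-type spaces used throughout the package
#'
#' The recurrent populations of the layer 2/3 circuit and the external
#' sources driving them, in the fixed order used for every block layout
#' (stacked state vectors, Jacobians, response matrices, kernel tables).
#'
#' @format `ssn_recurrent_types()` returns `c("E","PV","SST","VIP")`;
#'   `ssn_source_types()` returns `c("L4","LM","R")`;
#'   `ssn_presynaptic_types()` returns their concatenation (the 7 columns of
#'   the kernel amplitude/scale tables).
#' @name cell_types
NULL

#' @rdname cell_types
#' @export
ssn_recurrent_types <- function() c("E", "PV", "SST", "VIP")

#' @rdname cell_types
#' @export
ssn_source_types <- function() c("L4", "LM", "R")

#' @rdname cell_types
#' @export
ssn_presynaptic_types <- function() c(ssn_recurrent_types(), ssn_source_types())

# presynaptic types whose outgoing amplitudes must be >= 0 (excitatory or
# external drive); the remaining (PV, SST, VIP) must be <= 0
excitatory_presynaptic <- function() c("E", "L4", "LM", "R")

inhibitory_presynaptic <- function() c("PV", "SST", "VIP")
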