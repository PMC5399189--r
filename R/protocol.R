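#' Voltage-step protocol for whole-cell recordings
#'
#' Describes the depolarizing step family used to elicit delayed-rectifier
#' currents: from a fixed holding potential, test pulses sweep a voltage
#' range in equal increments, each followed by a tail pulse. Defaults are
#' the standard protocol for somatic Kv2.1 currents: holding -60 mV (to
#' inactivate A-type channels), 1 s test pulses from -100 to +60 mV in
#' 10 mV steps, then a 500 ms tail at -30 mV.
#'
#' @param holding_mV holding potential (mV).
#' @param step_start_mV,step_stop_mV first and last test potential (mV).
#' @param step_increment_mV step size (mV), > 0.
#' @param pulse_duration_s test-pulse duration (s).
#' @param tail_mV tail-pulse potential (mV).
#' @param tail_duration_s tail-pulse duration (s).
#' @return an object of class `voltage_protocol`.
#' @examples
#' p <- voltage_protocol()
#' protocol_voltages(p)
#' @export
voltage_protocol <- function(holding_mV = -60,
                             step_start_mV = -100,
                             step_stop_mV = 60,
                             step_increment_mV = 10,
                             pulse_duration_s = 1.0,
                             tail_mV = -30,
                             tail_duration_s = 0.5) {
  if (step_increment_mV <= 0) stop_param("step_increment_mV must be > 0")
  if (step_stop_mV < step_start_mV) stop_param("step_stop_mV must be >= step_start_mV")
  if (pulse_duration_s <= 0 || tail_duration_s <= 0) stop_param("durations must be > 0")
  volts <- c(holding_mV, step_start_mV, step_stop_mV, tail_mV)
  if (any(abs(volts) > 200)) stop_param("protocol voltages must lie within +/-200 mV")
  structure(list(
    holding_mV = holding_mV,
    step_start_mV = step_start_mV,
    step_stop_mV = step_stop_mV,
    step_increment_mV = step_increment_mV,
    pulse_duration_s = pulse_duration_s,
    tail_mV = tail_mV,
    tail_duration_s = tail_duration_s
  ), class = "voltage_protocol")
}

#' Test potentials of a protocol
#' @param protocol a [voltage_protocol()].
#' @return numeric vector of test potentials (mV).
#' @export
protocol_voltages <- function(protocol) {
  seq(protocol$step_start_mV, protocol$step_stop_mV, by = protocol$step_increment_mV)
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf(
    "Voltage protocol: hold %g mV; %g s steps %g..%g mV by %g mV; tail %g mV (%g s)\n",
    x$holding_mV, x$pulse_duration_s, x$step_start_mV, x$step_stop_mV,
    x$step_increment_mV, x$tail_mV, x$tail_duration_s))
  invisible(x)
}
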