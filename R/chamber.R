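# Discrete-time growth-chamber control simulator. The goal is to reproduce
# the controller's actuator logic and operating envelopes — PID temperature
# tracking in 10-44 degC, dual-actuation CO2 (solenoid release vs. sodasorb
# scrub fan) in 150-5000 PPM, additive-only drip irrigation on %VWC, a
# seven-channel LED mix, and the curtain/damper imaging interlock — not the
# chamber's thermodynamics.

# Default LED channel mix: fractions of total output per channel
# (cool white, warm white, royal blue 451 nm, green 520-535 nm,
# red 620-630 nm, deep red 650-670 nm, far red 720-740 nm).
#' Default seven-channel LED mix
#'
#' Channel fractions of total output for the seven-color LED modules, in
#' canopy order: cool white 22%, warm white 22%, royal blue 14%, green 6%,
#' red 12%, deep red 16%, far red 9%.
#'
#' @return named numeric vector of 7 fractions summing to ~1
#' @export
led_channel_mix <- function() {
  c(cool_white = 0.22, warm_white = 0.22, royal_blue = 0.14, green = 0.06,
    red = 0.12, deep_red = 0.16, far_red = 0.09)
}

#' Instantaneous chamber state
#'
#' @param T_air air temperature, degC
#' @param RH relative humidity, percent
#' @param CO2 CO2 concentration, PPM (> 0)
#' @param VWC volumetric water content of the pot medium, percent in [0, 100]
#' @param led_levels 7 channel fractions in [0, 1]
#' @param curtain `"up"` or `"down"`; `door` `"open"`/`"closed"`;
#'   `dampers` `"open"`/`"closed"`
#' @param curtain,door,dampers discrete states
#' @return object of class `chamber_state`
#' @export
chamber_state <- function(T_air = 22, RH = 60, CO2 = 400, VWC = 30,
                          led_levels = led_channel_mix(),
                          curtain = "down", door = "closed", dampers = "open") {
  if (CO2 <= 0) stop("'CO2' must be positive")
  if (VWC < 0 || VWC > 100) stop("'VWC' must lie in [0, 100]")
  if (length(led_levels) != 7 || any(led_levels < 0 | led_levels > 1))
    stop("'led_levels' must be 7 fractions in [0, 1]")
  structure(list(T_air = T_air, RH = RH, CO2 = CO2, VWC = VWC,
                 led_levels = led_levels,
                 curtain = match.arg(curtain, c("down", "up")),
                 door = match.arg(door, c("closed", "open")),
                 dampers = match.arg(dampers, c("open", "closed")),
                 pid = list(T_int = 0)),
            class = "chamber_state")
}

#' Chamber setpoints
#'
#' Validated against the chamber operating envelope: temperature 10-44 degC,
#' CO2 150-5000 PPM (sensor saturation limit), RH no lower than 40%
#' (the stated controllable floor between 15 and 30 degC).
#'
#' @param T_set temperature setpoint, degC in [10, 44]
#' @param RH_set relative humidity setpoint, percent in [40, 100]
#' @param CO2_set CO2 setpoint, PPM in [150, 5000]
#' @param VWC_set volumetric water content setpoint, percent in [0, 100]
#' @param led_levels 7 commanded channel fractions in [0, 1]
#' @return object of class `chamber_setpoints`
#' @export
chamber_setpoints <- function(T_set = 22, RH_set = 60, CO2_set = 400,
                              VWC_set = 30, led_levels = led_channel_mix()) {
  if (T_set < 10 || T_set > 44)
    stop("'T_set' outside the controllable range [10, 44] degC")
  if (CO2_set < 150 || CO2_set > 5000)
    stop("'CO2_set' outside the controllable range [150, 5000] PPM")
  if (RH_set < 40 || RH_set > 100)
    stop("'RH_set' outside the controllable range [40, 100] %")
  if (VWC_set < 0 || VWC_set > 100) stop("'VWC_set' must lie in [0, 100]")
  if (length(led_levels) != 7 || any(led_levels < 0 | led_levels > 1))
    stop("'led_levels' must be 7 fractions in [0, 1]")
  structure(list(T_set = T_set, RH_set = RH_set, CO2_set = CO2_set,
                 VWC_set = VWC_set, led_levels = led_levels),
            class = "chamber_setpoints")
}

#' Environmental disturbances acting on a chamber
#'
#' All rates are per minute and default to zero (an idealized sealed
#' chamber); `default_disturbances()` gives a mildly loaded chamber with
#' plant CO2 draw-down, evapotranspiration and thermal leakage toward the
#' building ambient.
#'
#' @param co2_drawdown plant CO2 uptake, PPM/min
#' @param vwc_loss evapotranspiration, %VWC/min
#' @param thermal_leak_rate fractional pull of T toward `ambient_T`, 1/min
#' @param ambient_T building ambient temperature, degC
#' @return object of class `chamber_disturbances`
#' @export
chamber_disturbances <- function(co2_drawdown = 0, vwc_loss = 0,
                                 thermal_leak_rate = 0, ambient_T = 20) {
  if (co2_drawdown < 0 || vwc_loss < 0 || thermal_leak_rate < 0)
    stop("disturbance rates must be non-negative")
  structure(list(co2_drawdown = co2_drawdown, vwc_loss = vwc_loss,
                 thermal_leak_rate = thermal_leak_rate, ambient_T = ambient_T),
            class = "chamber_disturbances")
}

#' @rdname chamber_disturbances
#' @export
default_disturbances <- function() {
  chamber_disturbances(co2_drawdown = 2, vwc_loss = 0.02,
                       thermal_leak_rate = 0.005, ambient_T = 20)
}

#' Control-loop gains and actuator rates
#'
#' The real controller's PID gains and valve/fan rates are unpublished;
#' these defaults are tuned for stable, overshoot-free tracking at the
#' 1-minute logging cadence. CO2 addition (solenoid, 25 PPM/min) outpaces
#' removal (scrub fan, 10 PPM/min), matching the stated asymmetry.
#'
#' @param T_kp,T_ki temperature PI gains (degC/min per degC error)
#' @param T_rate_max heater/cooler authority, degC/min
#' @param co2_deadband PPM; no actuation within setpoint +/- deadband
#' @param co2_add_rate,co2_remove_rate PPM/min
#' @param vwc_fill_rate drip valve delivery, %VWC/min
#' @param rh_rate RH tracking rate, %/min
#' @return list of gains
#' @export
chamber_gains <- function(T_kp = 0.4, T_ki = 0.02, T_rate_max = 1.5,
                          co2_deadband = 25, co2_add_rate = 25,
                          co2_remove_rate = 10, vwc_fill_rate = 0.5,
                          rh_rate = 2) {
  list(T_kp = T_kp, T_ki = T_ki, T_rate_max = T_rate_max,
       co2_deadband = co2_deadband, co2_add_rate = co2_add_rate,
       co2_remove_rate = co2_remove_rate, vwc_fill_rate = vwc_fill_rate,
       rh_rate = rh_rate)
}

#' Advance the chamber one control step
#'
#' Temperature follows a rate-limited PI command clamped to the 10-44 degC
#' envelope. CO2 uses bang-bang dual actuation with a deadband: below
#' setpoint - deadband the solenoid valve releases CO2; above setpoint +
#' deadband the scrub fan removes it; the two are never active in the same
#' step. Irrigation is additive-only: the drip valve opens iff VWC is below
#' setpoint and the controller's water flux is never negative. Disturbances
#' (plant CO2 draw-down, evapotranspiration, thermal leakage) are applied
#' within the same step.
#'
#' @param state `chamber_state`
#' @param sp `chamber_setpoints`
#' @param dt_min step length, minutes (> 0)
#' @param disturbances `chamber_disturbances`
#' @param gains from [chamber_gains()]
#' @return list with `state` (next `chamber_state`) and `report`: active
#'   actuators and fluxes (`solenoid`, `fan`, `valve` logicals;
#'   `water_flux` %VWC/min >= 0; `T_command` degC/min)
#' @export
chamber_step <- function(state, sp, dt_min = 1,
                         disturbances = chamber_disturbances(),
                         gains = chamber_gains()) {
  stopifnot(inherits(state, "chamber_state"), inherits(sp, "chamber_setpoints"))
  if (dt_min <= 0) stop("'dt_min' must be positive")
  g <- gains
  nxt <- state

  # temperature: PI with conditional-integration anti-windup
  err <- sp$T_set - state$T_air
  T_int <- state$pid$T_int + err * dt_min
  u_raw <- g$T_kp * err + g$T_ki * T_int
  u <- max(-g$T_rate_max, min(g$T_rate_max, u_raw))
  if (u != u_raw) T_int <- state$pid$T_int  # saturated: hold the integral
  leak <- disturbances$thermal_leak_rate * (disturbances$ambient_T - state$T_air)
  nxt$T_air <- state$T_air + (u + leak) * dt_min
  nxt$T_air <- max(10 - 0.5, min(44 + 0.5, nxt$T_air))
  nxt$pid$T_int <- T_int

  # CO2: mutually exclusive solenoid / scrub fan around a deadband
  solenoid <- state$CO2 < sp$CO2_set - g$co2_deadband
  fan <- !solenoid && state$CO2 > sp$CO2_set + g$co2_deadband
  dco2 <- 0
  if (solenoid) dco2 <- min(g$co2_add_rate * dt_min, sp$CO2_set - state$CO2)
  if (fan) dco2 <- -min(g$co2_remove_rate * dt_min, state$CO2 - sp$CO2_set)
  nxt$CO2 <- max(1, state$CO2 + dco2 - disturbances$co2_drawdown * dt_min)

  # irrigation: additive only
  valve <- state$VWC < sp$VWC_set
  water_flux <- if (valve)
    min(g$vwc_fill_rate, (sp$VWC_set - state$VWC) / dt_min) else 0
  nxt$VWC <- min(100, max(0, state$VWC + water_flux * dt_min -
                            disturbances$vwc_loss * dt_min))

  # RH: rate-limited tracking within sensor bounds
  rh_step <- max(-g$rh_rate * dt_min, min(g$rh_rate * dt_min, sp$RH_set - state$RH))
  nxt$RH <- max(0, min(100, state$RH + rh_step))

  nxt$led_levels <- sp$led_levels

  list(state = nxt,
       report = list(solenoid = solenoid, fan = fan, valve = valve,
                     water_flux = water_flux, T_command = u))
}

#' Curtain/damper imaging interlock
#'
#' Whenever the rover opens the chamber curtain to image, the airflow
#' dampers close to stop leaf flutter; closing the curtain reopens them.
#' Both transitions are idempotent.
#'
#' @param state `chamber_state`
#' @param rover_event `"curtain_open"` or `"curtain_close"`
#' @return updated `chamber_state`
#' @export
imaging_interlock <- function(state, rover_event = c("curtain_open", "curtain_close")) {
  rover_event <- match.arg(rover_event)
  if (rover_event == "curtain_open") {
    state$curtain <- "up"
    state$dampers <- "closed"
  } else {
    state$curtain <- "down"
    state$dampers <- "open"
  }
  state
}

#' Per-chamber schedule program
#'
#' @param events list of `list(time = "HH:MM", setpoints = <patch list>,
#'   label = <chr>)`; the patch fields override the current setpoints when
#'   the (offset-shifted) virtual clock passes the event time each day
#' @param photoperiod_offset_h hours added to this chamber's virtual clock,
#'   so the rover meets every chamber at the same virtual time of day
#' @return object of class `schedule_program`
#' @export
schedule_program <- function(events = list(), photoperiod_offset_h = 0) {
  mins <- vapply(events, function(e) parse_clock(e$time), numeric(1))
  if (any(mins < 0 | mins >= 24 * 60)) stop("event times must lie within 24 h")
  if (length(mins) > 1) {
    o <- order(mins)
    events <- events[o]; mins <- mins[o]
    for (i in which(duplicated(mins))) {
      a <- events[[i - 1]]$setpoints; b <- events[[i]]$setpoints
      if (length(intersect(names(a), names(b))))
        stop(sprintf("conflicting events at %s patch the same setpoint field",
                     events[[i]]$time))
    }
  }
  structure(list(events = events, event_min = mins,
                 photoperiod_offset_h = photoperiod_offset_h),
            class = "schedule_program")
}

parse_clock <- function(x) {
  if (is.numeric(x)) return(x)
  p <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
  p[1] * 60 + p[2]
}

#' Run scheduled multi-chamber simulations
#'
#' Simulates every chamber over the horizon at a fixed step, applying each
#' chamber's schedule events shifted by its photoperiod offset, and logs —
#' like the real controller's per-minute log — setpoints, process values
#' and digital actuator states at every step.
#'
#' @param programs named list of `schedule_program`, one per chamber
#' @param horizon_h simulation horizon, hours
#' @param dt_min step, minutes
#' @param seed integer; seeds any stochastic disturbance jitter
#' @param init initial `chamber_state` (shared; copied per chamber)
#' @param setpoints initial `chamber_setpoints`
#' @param disturbances `chamber_disturbances`
#' @param gains from [chamber_gains()]
#' @param jitter_sd optional Gaussian jitter (degC) on the thermal
#'   disturbance, default 0 (deterministic)
#' @return list with `trace` (data.frame: chamber, step, t_min, virtual_min,
#'   process values, setpoints, actuator states) and `events` (data.frame
#'   log of applied schedule events)
#' @export
run_schedule <- function(programs, horizon_h, dt_min = 1, seed = 1,
                         init = chamber_state(),
                         setpoints = chamber_setpoints(),
                         disturbances = chamber_disturbances(),
                         gains = chamber_gains(), jitter_sd = 0) {
  if (horizon_h <= 0) stop("'horizon_h' must be positive")
  n_steps <- as.integer(ceiling(horizon_h * 60 / dt_min))
  chambers <- names(programs)
  if (is.null(chambers)) chambers <- as.character(seq_along(programs))
  with_seed(seed, {
    traces <- vector("list", length(programs))
    ev_log <- list()
    for (ci in seq_along(programs)) {
      prog <- programs[[ci]]
      st <- init
      sp <- setpoints
      col <- list(step = integer(n_steps), t_min = numeric(n_steps),
                  virtual_min = numeric(n_steps),
                  T_air = numeric(n_steps), RH = numeric(n_steps),
                  CO2 = numeric(n_steps), VWC = numeric(n_steps),
                  T_set = numeric(n_steps), RH_set = numeric(n_steps),
                  CO2_set = numeric(n_steps), VWC_set = numeric(n_steps),
                  solenoid = logical(n_steps), fan = logical(n_steps),
                  valve = logical(n_steps), water_flux = numeric(n_steps))
      for (k in seq_len(n_steps)) {
        t_min <- (k - 1) * dt_min
        virt <- (t_min + prog$photoperiod_offset_h * 60) %% (24 * 60)
        prev_virt <- (virt - dt_min) %% (24 * 60)
        for (ei in seq_along(prog$events)) {
          em <- prog$event_min[ei]
          fired <- if (prev_virt < virt) (em > prev_virt && em <= virt)
                   else (em > prev_virt || em <= virt)  # midnight wrap
          if (k == 1 && em == virt) fired <- TRUE
          if (fired) {
            patch <- prog$events[[ei]]$setpoints
            spl <- unclass(sp)
            spl[names(patch)] <- patch
            sp <- do.call(chamber_setpoints, spl)
            ev_log[[length(ev_log) + 1L]] <- data.frame(
              chamber = chambers[ci], t_min = t_min, virtual_min = virt,
              label = if (is.null(prog$events[[ei]]$label)) "setpoint_change"
                      else prog$events[[ei]]$label,
              stringsAsFactors = FALSE)
          }
        }
        dist_k <- disturbances
        if (jitter_sd > 0)
          dist_k$thermal_leak_rate <- max(0, disturbances$thermal_leak_rate +
                                            stats::rnorm(1, 0, jitter_sd))
        res <- chamber_step(st, sp, dt_min, dist_k, gains)
        st <- res$state
        col$step[k] <- k; col$t_min[k] <- t_min; col$virtual_min[k] <- virt
        col$T_air[k] <- st$T_air; col$RH[k] <- st$RH
        col$CO2[k] <- st$CO2; col$VWC[k] <- st$VWC
        col$T_set[k] <- sp$T_set; col$RH_set[k] <- sp$RH_set
        col$CO2_set[k] <- sp$CO2_set; col$VWC_set[k] <- sp$VWC_set
        col$solenoid[k] <- res$report$solenoid; col$fan[k] <- res$report$fan
        col$valve[k] <- res$report$valve
        col$water_flux[k] <- res$report$water_flux
      }
      traces[[ci]] <- cbind(data.frame(chamber = rep(chambers[ci], n_steps),
                                       stringsAsFactors = FALSE),
                            as.data.frame(col))
    }
    list(trace = do.call(rbind, traces),
         events = if (length(ev_log)) do.call(rbind, ev_log) else
           data.frame(chamber = character(0), t_min = numeric(0),
                      virtual_min = numeric(0), label = character(0)))
  })
}
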