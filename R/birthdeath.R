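# Linear birth-death process: each cell independently divides at rate k_div
# and dies at rate k_dth (reactions C -> 2C and C -> 0). With no state
# switching, a colony founded by one cell of state i is a one-state process
# with that state's rates for its entire lineage.

#' Cell-state rate constants
#'
#' A cell state of a birth-death model: a division and a death rate
#' constant, in units of per hour.
#'
#' @param label state identifier.
#' @param k_div division rate constant (h^-1), non-negative.
#' @param k_dth death rate constant (h^-1), non-negative.
#' @return A `bd_state` object.
#' @examples
#' # untreated PC9-like proliferation
#' bd_state("untreated", k_div = 0.04 * log(2), k_dth = 0.005 * log(2))
#' @export
bd_state <- function(label, k_div, k_dth) {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(k_div), length(k_div) == 1L, is.finite(k_div),
            is.numeric(k_dth), length(k_dth) == 1L, is.finite(k_dth))
  if (k_div < 0 || k_dth < 0) {
    stop("invalid model: rate constants must be non-negative", call. = FALSE)
  }
  structure(list(label = label, k_div = k_div, k_dth = k_dth),
            class = "bd_state")
}

#' Birth-death model with one or more cell states
#'
#' States are fixed per lineage: there is no state switching, so a colony's
#' state is its founder's state. `founder_fractions` gives the probability
#' that a founding cell is of each state.
#'
#' @param states list of [bd_state()] objects.
#' @param founder_fractions numeric vector summing to 1, one entry per state.
#' @return A `bd_model` object.
#' @export
bd_model <- function(states, founder_fractions = NULL) {
  if (inherits(states, "bd_state")) states <- list(states)
  stopifnot(is.list(states), length(states) >= 1L,
            all(vapply(states, inherits, logical(1), "bd_state")))
  n <- length(states)
  if (is.null(founder_fractions)) founder_fractions <- rep(1 / n, n)
  stopifnot(is.numeric(founder_fractions), length(founder_fractions) == n,
            all(founder_fractions >= 0))
  if (abs(sum(founder_fractions) - 1) > 1e-8) {
    stop("invalid model: founder_fractions must sum to 1", call. = FALSE)
  }
  labels <- vapply(states, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("invalid model: duplicated state labels", call. = FALSE)
  }
  structure(list(states = states, founder_fractions = founder_fractions,
                 labels = labels),
            class = "bd_model")
}

#' @export
print.bd_model <- function(x, ...) {
  cat(sprintf("<bd_model> %d state(s)\n", length(x$states)))
  for (i in seq_along(x$states)) {
    s <- x$states[[i]]
    cat(sprintf("  %s: k_div = %.6g, k_dth = %.6g h^-1 (founder %.2f)\n",
                s$label, s$k_div, s$k_dth, x$founder_fractions[i]))
  }
  invisible(x)
}

#' In-silico cFP simulation protocol
#'
#' Single-cell-founded colonies expand drug-free for `expansion_hours`
#' (default 8 days), after which "treatment" switches every state's rate
#' constants to those of `treatment_model`. Counts are recorded at
#' `sampling_times`; a colony reaching `population_cap` halts and holds at
#' the cap (a confluency surrogate).
#'
#' @param treatment_model [bd_model()] active after treatment, with the same
#'   state labels as the pre-treatment model, or `NULL` (set later, e.g. by
#'   parameter scans).
#' @param initial_cells founding cell count, default 1.
#' @param expansion_hours drug-free expansion, default 192 h (8 days).
#' @param sampling_times strictly increasing recording times in hours;
#'   default daily sampling over 8 days expansion plus 7 days of treatment.
#' @param population_cap halt-and-hold cap, default 1e5 cells.
#' @return A `sim_protocol` object.
#' @export
sim_protocol <- function(treatment_model = NULL,
                         initial_cells = 1L,
                         expansion_hours = 192,
                         sampling_times = seq(0, 360, by = 24),
                         population_cap = 1e5) {
  if (length(sampling_times) == 0L) {
    stop("invalid protocol: sampling_times must be non-empty", call. = FALSE)
  }
  stopifnot(is.numeric(sampling_times), is.numeric(expansion_hours),
            initial_cells >= 1, population_cap > initial_cells)
  if (any(diff(sampling_times) <= 0)) {
    stop("invalid protocol: sampling_times must be strictly increasing",
         call. = FALSE)
  }
  if (expansion_hours < min(sampling_times) ||
      expansion_hours > max(sampling_times)) {
    stop("invalid protocol: expansion_hours outside sampling range",
         call. = FALSE)
  }
  if (!is.null(treatment_model)) stopifnot(inherits(treatment_model, "bd_model"))
  structure(list(treatment_model = treatment_model,
                 initial_cells = as.integer(initial_cells),
                 expansion_hours = expansion_hours,
                 sampling_times = as.numeric(sampling_times),
                 population_cap = population_cap),
            class = "sim_protocol")
}

#' One colony's sampled cell counts over time
#'
#' @param colony_id identifier.
#' @param times sampling times in hours.
#' @param counts non-negative integer counts, one per time.
#' @param founder_state optional ground-truth state label (synthetic data
#'   only; never used by analysis stages).
#' @return A `colony_trace` object.
#' @export
colony_trace <- function(colony_id, times, counts, founder_state = NULL) {
  stopifnot(length(times) == length(counts), all(counts >= 0))
  structure(list(colony_id = as.character(colony_id),
                 times = as.numeric(times),
                 counts = as.integer(counts),
                 founder_state = founder_state),
            class = "colony_trace")
}

#' A set of cFP colony traces sharing one treatment time
#'
#' @param traces list of [colony_trace()] objects.
#' @param treatment_time treatment (drug addition) time in hours.
#' @param metadata free-form provenance list.
#' @return A `cfp_dataset` object.
#' @export
cfp_dataset <- function(traces, treatment_time, metadata = list()) {
  stopifnot(is.list(traces),
            all(vapply(traces, inherits, logical(1), "colony_trace")),
            is.numeric(treatment_time), length(treatment_time) == 1L)
  structure(list(traces = traces, treatment_time = treatment_time,
                 metadata = metadata),
            class = "cfp_dataset")
}

#' @export
print.cfp_dataset <- function(x, ...) {
  cat(sprintf("<cfp_dataset> %d colonies, treatment at %g h\n",
              length(x$traces), x$treatment_time))
  invisible(x)
}

#' @export
length.cfp_dataset <- function(x) length(x$traces)

rates_matrix <- function(model) {
  do.call(rbind, lapply(model$states,
                        function(s) c(s$k_div, s$k_dth)))
}

check_treatment_model <- function(model, protocol) {
  tm <- protocol$treatment_model
  if (is.null(tm)) {
    stop("protocol has no treatment_model", call. = FALSE)
  }
  if (!identical(tm$labels, model$labels)) {
    stop("treatment_model states must match the pre-treatment model",
         call. = FALSE)
  }
  tm
}

#' Exact Gillespie simulation of one colony
#'
#' Runs the stochastic simulation algorithm for the linear birth-death
#' process with propensities `k_div * N` and `k_dth * N`, using the
#' pre-treatment rates before `protocol$expansion_hours` and the
#' `treatment_model` rates after. Extinction is absorbing; reaching
#' `population_cap` halts and holds.
#'
#' @param model pre-treatment [bd_model()].
#' @param founder_state state label of the founding cell.
#' @param protocol [sim_protocol()] with a `treatment_model`.
#' @param seed integer master seed.
#' @param colony_id identifier for the returned trace.
#' @return A [colony_trace()].
#' @examples
#' untr <- bd_model(bd_state("A", 0.04 * log(2), 0.005 * log(2)))
#' trt  <- bd_model(bd_state("A", 0.02 * log(2), 0.03 * log(2)))
#' tr <- simulate_ssa(untr, "A", sim_protocol(trt), seed = 1)
#' tail(tr$counts)
#' @export
simulate_ssa <- function(model, founder_state, protocol, seed,
                         colony_id = "c1") {
  stopifnot(inherits(model, "bd_model"), inherits(protocol, "sim_protocol"))
  tm <- check_treatment_model(model, protocol)
  i <- match(founder_state, model$labels)
  if (is.na(i)) stop("founder_state not in model", call. = FALSE)
  pre <- model$states[[i]]
  post <- tm$states[[i]]
  counts <- ssa_trace_cpp(protocol$initial_cells,
                          pre$k_div, pre$k_dth, post$k_div, post$k_dth,
                          protocol$expansion_hours, protocol$sampling_times,
                          protocol$population_cap, seed, 0)
  colony_trace(colony_id, protocol$sampling_times, counts,
               founder_state = founder_state)
}

#' Closed-form expected cell count of a birth-death state
#'
#' `E[N(t)] = n0 * exp((k_div - k_dth) * t)`; the deterministic oracle for
#' the stochastic simulator.
#'
#' @param state a [bd_state()].
#' @param n0 initial cell count.
#' @param t time in hours, non-negative.
#' @return Expected count.
#' @export
expected_count <- function(state, n0, t) {
  stopifnot(inherits(state, "bd_state"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  n0 * exp((state$k_div - state$k_dth) * t)
}

#' Closed-form variance of the count of a linear birth-death process
#'
#' With net rate r given by k_div - k_dth, nonzero r gives
#' `Var[N(t)] = n0 * (k_div + k_dth) / r * exp(r t) * (exp(r t) - 1)`;
#' the critical case gives `2 * n0 * k_div * t`.
#'
#' @inheritParams expected_count
#' @return Variance of the count.
#' @export
count_variance <- function(state, n0, t) {
  stopifnot(inherits(state, "bd_state"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  r <- state$k_div - state$k_dth
  if (abs(r) < 1e-15) return(2 * n0 * state$k_div * t)
  n0 * (state$k_div + state$k_dth) / r * exp(r * t) * (exp(r * t) - 1)
}

#' Extinction probability of a birth-death colony
#'
#' For a single founder and finite `t` with `k_div != k_dth`,
#' `alpha(t) = k_dth * (exp(r t) - 1) / (k_div * exp(r t) - k_dth)` where
#' r is the net rate k_div - k_dth; the critical case `k_div = k_dth = k` gives
#' `k t / (1 + k t)`. For `n0` founders the probability is `alpha(t)^n0`.
#' At `t = Inf` this reduces to `(k_dth / k_div)^n0` when supercritical and
#' 1 otherwise.
#'
#' @inheritParams expected_count
#' @param t time in hours, possibly `Inf`.
#' @return Probability that the colony is extinct by time `t`.
#' @export
extinction_prob <- function(state, n0 = 1, t = Inf) {
  stopifnot(inherits(state, "bd_state"), n0 >= 1)
  kd <- state$k_div
  km <- state$k_dth
  if (km == 0) return(0)
  if (is.infinite(t)) {
    a <- if (kd > km) km / kd else 1
    return(a^n0)
  }
  if (t < 0) stop("t must be non-negative", call. = FALSE)
  if (abs(kd - km) < 1e-15) {
    a <- km * t / (1 + km * t)
  } else {
    r <- kd - km
    ert <- exp(r * t)
    a <- km * (ert - 1) / (kd * ert - km)
  }
  a^n0
}

#' Battery of independent in-silico cFP colonies
#'
#' Runs `n_colonies` independent single-founder Gillespie simulations. Each
#' founder's state is drawn from `model$founder_fractions` using a
#' per-colony substream of the master seed, so results are reproducible and
#' independent of execution order.
#'
#' @inheritParams simulate_ssa
#' @param n_colonies number of colonies (in the study, matched to the
#'   number of experimental cFP trajectories).
#' @return A [cfp_dataset()]; traces carry ground-truth `founder_state`.
#' @export
simulate_cfp_battery <- function(model, protocol, n_colonies, seed) {
  stopifnot(inherits(model, "bd_model"), inherits(protocol, "sim_protocol"),
            n_colonies >= 1)
  tm <- check_treatment_model(model, protocol)
  sim <- ssa_battery_cpp(as.integer(n_colonies), model$founder_fractions,
                         rates_matrix(model), rates_matrix(tm),
                         protocol$expansion_hours, protocol$sampling_times,
                         protocol$population_cap, protocol$initial_cells,
                         seed)
  traces <- lapply(seq_len(n_colonies), function(j) {
    colony_trace(sprintf("c%04d", j), protocol$sampling_times,
                 sim$counts[, j],
                 founder_state = model$labels[sim$founder[j]])
  })
  cfp_dataset(traces, treatment_time = protocol$expansion_hours,
              metadata = list(seed = seed, n_colonies = n_colonies,
                              source = "simulate_cfp_battery"))
}

# Matrix fast path used by parameter scans: one column of counts per colony.
battery_matrix <- function(model, protocol, n_colonies, seed) {
  tm <- check_treatment_model(model, protocol)
  ssa_battery_cpp(as.integer(n_colonies), model$founder_fractions,
                  rates_matrix(model), rates_matrix(tm),
                  protocol$expansion_hours, protocol$sampling_times,
                  protocol$population_cap, protocol$initial_cells, seed)
}
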