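# Well-tempered metadynamics: hill bookkeeping, wall potentials, free-energy
# recovery from the deposited bias, the time-dependent bias offset c(t) and
# ensemble reweighting, plus a BAOAB Langevin integrator for toy systems.
#
# Reduced units throughout the toy engine: energies in kJ/mol, lengths in
# Angstrom-equivalents, times in ps, mass in kJ/mol ps^2/A^2 (default 1).

#' Boltzmann constant in kJ/mol/K
#' @export
kB <- 0.0083144621

#' Well-tempered metadynamics parameters
#'
#' The bias-factor convention is gamma = (T + dT)/T, so the fictitious CV
#' temperature is dT = (gamma - 1) T and hill heights decay as
#' exp(-V / (kB dT)).
#'
#' @param temperature system temperature in K (default 298).
#' @param bias_factor gamma > 1 (dimensionless).
#' @param pace time between hill depositions in ps.
#' @param initial_height initial Gaussian height in kJ/mol.
#' @param widths per-CV Gaussian widths (sigma), CV units.
#' @return object of class `wtmetad_params`.
#' @export
wtmetad_params <- function(temperature = 298, bias_factor, pace = 2,
                           initial_height = 0.25, widths) {
  stopifnot(bias_factor > 1, pace > 0, initial_height > 0, all(widths > 0))
  structure(list(temperature = temperature, bias_factor = bias_factor,
                 delta_T = (bias_factor - 1) * temperature,
                 pace = pace, initial_height = initial_height,
                 widths = as.numeric(widths)),
            class = "wtmetad_params")
}

#' Wall potential specification
#'
#' One-sided polynomial restraint `kappa * ((s - at)/rescale)^exponent`,
#' active only beyond the bound; exactly zero (and C1-continuous for even
#' exponent >= 2) inside the allowed region.
#'
#' @param cv 1-based index of the restrained CV.
#' @param at bound position in CV units.
#' @param side `"upper"` or `"lower"`.
#' @param kappa force constant in kJ/mol.
#' @param rescale rescaling factor in CV units (default 0.1, the piston
#'   value; use ~1 degree for angle CVs).
#' @param exponent even integer >= 2 (default 4).
#' @return object of class `wall_spec`.
#' @export
wall_spec <- function(cv = 1L, at, side = c("upper", "lower"), kappa = 500,
                      rescale = 0.1, exponent = 4L) {
  side <- match.arg(side)
  stopifnot(kappa > 0, rescale > 0, exponent >= 2, exponent %% 2 == 0)
  structure(list(cv = as.integer(cv), at = at, side = side, kappa = kappa,
                 rescale = rescale, exponent = as.integer(exponent)),
            class = "wall_spec")
}

#' Wall energy at a CV value
#' @param spec a [wall_spec].
#' @param s scalar or vector of CV values.
#' @return energy in kJ/mol (vectorized over `s`).
#' @export
wall_energy <- function(spec, s) {
  active <- if (spec$side == "upper") s > spec$at else s < spec$at
  e <- numeric(length(s))
  e[active] <- spec$kappa * ((s[active] - spec$at) / spec$rescale)^spec$exponent
  e
}

wall_gradient <- function(spec, s) {
  active <- if (spec$side == "upper") s > spec$at else s < spec$at
  g <- numeric(length(s))
  g[active] <- spec$kappa * spec$exponent *
    ((s[active] - spec$at) / spec$rescale)^(spec$exponent - 1L) / spec$rescale
  g
}

#' Accumulated bias state of a metadynamics run
#'
#' @param hills data.frame with columns `time` (ps), `center.1..d`,
#'   `sigma.1..d`, `height` (kJ/mol), time-ordered.
#' @param params a [wtmetad_params].
#' @param walls list of [wall_spec] objects.
#' @return object of class `bias_state`.
#' @export
bias_state <- function(hills, params, walls = list()) {
  d <- sum(grepl("^center\\.", names(hills)))
  if (d < 1) stop("hills must have center.1..d columns")
  if (nrow(hills) && is.unsorted(hills$time))
    stop("hills must be time-ordered")
  if (any(hills$height < 0) || any(as.matrix(hills[grepl("^sigma\\.", names(hills))]) <= 0))
    stop("hill widths must be positive and heights non-negative")
  structure(list(hills = hills, params = params, walls = walls, d = d),
            class = "bias_state")
}

#' @export
print.bias_state <- function(x, ...) {
  cat(sprintf("<bias_state> %d hills, %dD, gamma = %g, %d wall(s)\n",
              nrow(x$hills), x$d, x$params$bias_factor, length(x$walls)))
  invisible(x)
}

hill_parts <- function(state) {
  h <- state$hills
  list(centers = as.matrix(h[, paste0("center.", seq_len(state$d)), drop = FALSE]),
       sigmas = as.matrix(h[, paste0("sigma.", seq_len(state$d)), drop = FALSE]),
       heights = h$height, times = h$time)
}

hills_bias_at <- function(state, s) {
  s <- matrix(s, ncol = state$d)
  if (!nrow(state$hills)) return(numeric(nrow(s)))
  p <- hill_parts(state)
  eval_bias_series_cpp(p$times, p$centers, p$sigmas, p$heights,
                       rep(Inf, nrow(s)), s)
}

#' Bias potential and force at a CV point
#'
#' Exact analytic sum of all deposited Gaussians plus wall terms, and the
#' exact negative gradient.
#'
#' @param state a [bias_state].
#' @param s CV point (length-d numeric).
#' @return list with `value` (kJ/mol) and `force` (-dV/ds per CV).
#' @export
bias_value_and_force <- function(state, s) {
  s <- as.numeric(s)
  stopifnot(length(s) == state$d, all(is.finite(s)))
  V <- 0; force <- numeric(state$d)
  if (nrow(state$hills)) {
    p <- hill_parts(state)
    z <- sweep(p$centers, 2, s)                 # c - s per hill
    ex <- p$heights * exp(-rowSums((z / p$sigmas)^2) / 2)
    V <- sum(ex)
    for (k in seq_len(state$d))
      force[k] <- sum(ex * (-z[, k] / p$sigmas[, k]^2)) # -dV/ds_k
  }
  for (w in state$walls) {
    V <- V + wall_energy(w, s[w$cv])
    force[w$cv] <- force[w$cv] - wall_gradient(w, s[w$cv])
  }
  list(value = V, force = force)
}

#' Height of the next well-tempered hill
#'
#' `h = h0 * exp(-V(s, t) / (kB dT))` with `V` the instantaneous hill bias
#' at the deposition point.
#'
#' @param state a [bias_state].
#' @param s CV point.
#' @return height in kJ/mol.
#' @export
next_hill_height <- function(state, s) {
  V <- hills_bias_at(state, s)
  state$params$initial_height * exp(-V / (kB * state$params$delta_T))
}

#' Regular bias/free-energy grid axes
#' @param min,max per-axis bounds (recycled).
#' @param n nodes per axis (default 501).
#' @return list of axis node vectors, usable wherever `axes` is expected.
#' @export
fes_grid <- function(min, max, n = 501L) {
  mapply(function(lo, hi, nn) seq(lo, hi, length.out = nn),
         min, max, rep(n, length.out = max(length(min), length(max))),
         SIMPLIFY = FALSE)
}

#' Free-energy surface from the accumulated bias
#'
#' In the well-tempered scheme the bias converges to `-dT/(T+dT) F`, so the
#' free energy is recovered as `F(s) = -(T+dT)/dT V(s, t_end)`, shifted so
#' its minimum is zero. The bias is replayed on the grid by summing the
#' hills in deposition order with the same node-accumulation arithmetic as
#' the runner, making the replay bit-identical to the in-run bias.
#'
#' @param state a [bias_state] with at least one hill.
#' @param axes list of grid-axis node vectors (see [fes_grid()]).
#' @return a `surface_grid` (values in kJ/mol; for 1D a vector, for 2D a
#'   matrix with the first axis on rows).
#' @export
free_energy_from_bias <- function(state, axes) {
  if (!nrow(state$hills)) stop("no hills deposited: free energy undefined")
  p <- hill_parts(state)
  V <- accumulate_hills_grid_cpp(p$centers, p$sigmas, p$heights, axes)
  gamma <- state$params$bias_factor
  Fv <- -(gamma / (gamma - 1)) * V
  Fv <- Fv - min(Fv)
  dims <- vapply(axes, length, 1L)
  vals <- if (length(axes) == 1L) as.vector(Fv) else array(Fv, dim = dims)
  structure(list(axes = axes, mids = axes, values = vals, kind = "kJ/mol",
                 bias_grid = V, low_information = FALSE),
            class = "surface_grid")
}

#' Time-dependent bias offset c(t)
#'
#' The offset relating the biased and unbiased ensembles,
#' `c(t) = (1/beta) ln( int exp(beta gamma/(gamma-1) V) ds /
#' int exp(beta/(gamma-1) V) ds )`, evaluated incrementally after each hill
#' on the supplied grid. Before the first hill c = 0.
#'
#' @param state a [bias_state] with hills.
#' @param axes grid axes covering the sampled CV range.
#' @return data.frame with columns `time` and `c` (kJ/mol), one row per
#'   hill.
#' @export
bias_offset_c_of_t <- function(state, axes) {
  if (!nrow(state$hills)) stop("no hills deposited")
  p <- hill_parts(state)
  beta <- 1 / (kB * state$params$temperature)
  cc <- bias_offset_cpp(p$centers, p$sigmas, p$heights, axes, beta,
                        state$params$bias_factor)
  # narrow-grid diagnostic: final bias should have decayed at the edges
  Vg <- accumulate_hills_grid_cpp(p$centers, p$sigmas, p$heights, axes)
  dims <- vapply(axes, length, 1L)
  Va <- if (length(dims) == 1L) Vg else array(Vg, dims)
  edge <- if (length(dims) == 1L) c(Va[1], Va[length(Va)])
          else c(Va[1, ], Va[dims[1], ], Va[, 1], Va[, dims[2]])
  if (max(edge) - min(Vg) > kB * state$params$temperature)
    warning("bias at the grid boundary exceeds the minimum by > 1 kT; ",
            "the c(t) grid may be too narrow")
  data.frame(time = p$times, c = cc)
}

#' Reweighting factors for frames of a biased run
#'
#' Computes per-frame statistical weights `w_t propto
#' exp(beta [V(s_t, t) - c(t)])` that map the well-tempered ensemble back to
#' the unbiased Boltzmann ensemble, and optionally the reweighted
#' negative-log-probability surface of an unbiased observable.
#'
#' @param state a [bias_state].
#' @param cv_series data.frame with a `time` column (ps) and d CV columns
#'   (the biased CVs, in hill order).
#' @param axes grid axes for the c(t) evaluation.
#' @param observables optional vector/matrix (1 or 2 columns) of unbiased
#'   observable values per frame; when given, a weighted surface is
#'   returned.
#' @param bins histogram bins for the observable surface.
#' @return list with `weights` (normalized to mean 1), `log_weights`,
#'   `c_of_t`, and `surface` (if observables were supplied).
#' @export
reweight_frames <- function(state, cv_series, axes, observables = NULL,
                            bins = 50) {
  scols <- setdiff(names(cv_series), "time")
  if (length(scols) != state$d)
    stop("cv_series must have exactly d CV columns besides time")
  S <- as.matrix(cv_series[, scols, drop = FALSE])
  times <- cv_series$time
  if (nrow(state$hills)) {
    ht <- state$hills$time
    if (min(ht) > max(times) || max(ht) < min(times))
      stop("hill deposition times do not align with the CV series times")
    p <- hill_parts(state)
    Vt <- eval_bias_series_cpp(p$times, p$centers, p$sigmas, p$heights,
                               times, S)
    coft <- bias_offset_c_of_t(state, axes)
    idx <- findInterval(times, coft$time)
    ct <- c(0, coft$c)[idx + 1L]
  } else {
    Vt <- numeric(nrow(S)); ct <- numeric(nrow(S))
    coft <- data.frame(time = numeric(0), c = numeric(0))
  }
  beta <- 1 / (kB * state$params$temperature)
  logw <- beta * (Vt - ct)
  w <- exp(logw - max(logw))
  w <- w / mean(w)
  out <- list(weights = w, log_weights = logw, c_of_t = coft)
  if (!is.null(observables))
    out$surface <- neg_log_probability_surface(observables, bins = bins,
                                               weights = w)
  out
}

#' Toy potential-energy system
#'
#' Built-in analytic potentials for the Langevin/metadynamics engine:
#' `"double_well"`, `U = sum_d a (x_d^2 - 1)^2` (barrier `a` kJ/mol between
#' minima at -1 and +1 on each axis), and `"harmonic"`, `U = sum_d k x_d^2 / 2`.
#'
#' @param kind `"double_well"` or `"harmonic"`.
#' @param a double-well barrier parameter in kJ/mol (default 5).
#' @param k harmonic force constant in kJ/mol per unit length squared.
#' @param dim dimensionality (1-4).
#' @param mass particle mass in kJ/mol ps^2 per unit length squared.
#' @return object of class `toy_system`.
#' @export
toy_system <- function(kind = c("double_well", "harmonic"), a = 5, k = 1,
                       dim = 1L, mass = 1) {
  kind <- match.arg(kind)
  structure(list(kind = kind, kind_code = match(kind, c("double_well", "harmonic")),
                 pars = if (kind == "double_well") a else k,
                 dim = as.integer(dim), mass = mass),
            class = "toy_system")
}

#' Potential energy of a toy system
#' @param system a [toy_system].
#' @param x numeric vector (one point, length = dim) or a matrix of points.
#' @return energy in kJ/mol.
#' @export
toy_energy <- function(system, x) {
  x <- matrix(x, ncol = system$dim)
  if (system$kind == "double_well") rowSums(system$pars * (x^2 - 1)^2)
  else rowSums(0.5 * system$pars * x^2)
}

empty_hills <- function(d) {
  cols <- c("time", paste0("center.", seq_len(d)), paste0("sigma.", seq_len(d)),
            "height")
  as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
}

walls_matrix <- function(walls, d) {
  if (!length(walls)) return(matrix(0, 0, 6))
  do.call(rbind, lapply(walls, function(w) {
    stopifnot(w$cv <= d)
    c(w$cv, w$at, if (w$side == "upper") 1 else -1, w$kappa, w$rescale,
      w$exponent)
  }))
}

#' Langevin propagation of a toy system
#'
#' BAOAB discretization of underdamped Langevin dynamics; with the bias
#' disabled it samples the Boltzmann distribution of the potential.
#' Reproducible under a fixed seed. The documented stability check
#' `dt * friction < 0.1` is enforced.
#'
#' @param system a [toy_system].
#' @param x0 start point (length = dim).
#' @param dt time step in ps.
#' @param friction friction in 1/ps.
#' @param temperature temperature in K.
#' @param n_steps number of steps.
#' @param seed integer seed.
#' @param bias optional frozen [bias_state] applied as a static potential
#'   (its hills are accumulated once; none are added).
#' @param axes bias grid axes (required when `bias` is given).
#' @param record_stride record every this many steps.
#' @param xbound divergence bound on |x| (error if exceeded).
#' @return data.frame `time`, CV columns, `bias` (kJ/mol).
#' @export
langevin_propagate <- function(system, x0, dt, friction, temperature,
                               n_steps, seed = NULL, bias = NULL,
                               axes = NULL, record_stride = 10L,
                               xbound = 50) {
  if (dt * friction >= 0.1)
    stop("unstable settings: require dt * friction < 0.1")
  if (!is.null(seed)) set.seed(seed)
  d <- system$dim
  if (is.null(axes)) axes <- fes_grid(rep(-xbound, d), rep(xbound, d), 3L)
  if (!is.null(bias) && nrow(bias$hills)) {
    p <- hill_parts(bias)
    ic <- p$centers; is_ <- p$sigmas; ih <- p$heights
  } else {
    ic <- matrix(0, 0, d); is_ <- matrix(0, 0, d); ih <- numeric(0)
  }
  res <- metad_run_cpp(system$kind_code, system$pars, as.numeric(x0),
                       system$mass, dt, friction, temperature,
                       as.integer(n_steps), 0L, 0, rep(1, d), 2,
                       walls_matrix(if (is.null(bias)) list() else bias$walls, d),
                       axes, as.integer(record_stride), xbound,
                       ic, is_, ih)
  cv <- as.data.frame(res$colvar)
  names(cv) <- c("time", paste0("x", seq_len(d)), "bias")
  cv
}

#' Run well-tempered metadynamics on a toy system
#'
#' Deposits Gaussian hills every `pace` ps with well-tempered height
#' rescaling, walls active throughout, and returns the accumulated
#' [bias_state] together with COLVAR-style and HILLS-style records. The
#' bias is held on a regular grid on which every hill is accumulated
#' exactly; replaying the emitted hills with [free_energy_from_bias()]
#' reproduces the in-run bias grid bit-for-bit.
#'
#' @param system a [toy_system] (1-4 CVs = coordinates of the toy system).
#' @param params a [wtmetad_params].
#' @param walls list of [wall_spec].
#' @param x0 start point.
#' @param n_steps steps to run.
#' @param dt time step in ps.
#' @param friction friction in 1/ps.
#' @param seed integer seed (single stream for initialization and
#'   thermostat noise).
#' @param axes bias-grid axes; must cover the wall-confined CV range.
#' @param record_stride COLVAR record stride in steps.
#' @param xbound divergence bound.
#' @return list with `state` (a [bias_state]), `colvar` (data.frame),
#'   `grid_values` (in-run final bias on the grid) and `axes`.
#' @export
run_well_tempered_metadynamics <- function(system, params, walls = list(),
                                           x0, n_steps, dt = 0.01,
                                           friction = 2, seed = 1,
                                           axes, record_stride = 20L,
                                           xbound = 50) {
  d <- system$dim
  stopifnot(d >= 1, d <= 4, length(params$widths) == d)
  if (dt * friction >= 0.1)
    stop("unstable settings: require dt * friction < 0.1")
  pace_steps <- round(params$pace / dt)
  if (pace_steps < 1) stop("pace shorter than one time step")
  set.seed(seed)
  res <- metad_run_cpp(system$kind_code, system$pars, as.numeric(x0),
                       system$mass, dt, friction, params$temperature,
                       as.integer(n_steps), as.integer(pace_steps),
                       params$initial_height, params$widths,
                       params$bias_factor, walls_matrix(walls, d), axes,
                       as.integer(record_stride), xbound,
                       matrix(0, 0, d), matrix(0, 0, d), numeric(0))
  nh <- res$n_hills
  hills <- if (nh > 0) {
    h <- as.data.frame(res$hills[seq_len(nh), , drop = FALSE])
    names(h) <- c("time", paste0("center.", seq_len(d)),
                  paste0("sigma.", seq_len(d)), "height")
    h
  } else empty_hills(d)
  cv <- as.data.frame(res$colvar)
  names(cv) <- c("time", paste0("x", seq_len(d)), "bias")
  list(state = bias_state(hills, params, walls), colvar = cv,
       grid_values = res$grid_values, axes = axes)
}
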