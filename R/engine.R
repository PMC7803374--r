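#' Simulation configuration
#'
#' Collects and validates every parameter of the lattice model.
#'
#' The two model classes differ in how the removed cell is chosen: in the
#' `"coupled"` class it is drawn from the sector of radius `m` and angle
#' `alpha` facing the tissue centre around the dividing cell
#' (`bias = 1 - alpha/(2*pi)`); in the `"uncoupled"` class it is drawn from a
#' central disk of radius `rho`, independently of the dividing cell (`rho = R`
#' means no bias). Progenitors carry a lineage division count and become
#' post-mitotic once it reaches `rls`. Under the `"equipotent"` stem model
#' every limbal site is a stem cell dividing symmetrically (limbal neutral
#' drift) with probability `1 - a` or asymmetrically into the cornea with
#' probability `a`; under the `"hierarchical"` model a fixed fraction
#' `stem_fraction` of limbal sites are irreplaceable stem cells that seed
#' limbal progenitors, which in turn divide only toward the cornea.
#'
#' Default rates: equipotent runs use `lambda_s = lambda_p = 1` (limbal cells
#' are abundant, frequently dividing equipotent stem cells); hierarchical runs
#' default to `lambda_s = 0.1` (rare, slow-dividing stem cells).
#'
#' @param model_class `"coupled"` or `"uncoupled"`.
#' @param bias convenience parameter in `[0, 1)`: for the coupled class sets
#'   `alpha = 2*pi*(1 - bias)`; for the uncoupled class sets
#'   `rho = max(1, (1 - bias) * R)`. Ignored when `alpha`/`rho` given.
#' @param alpha coupled-class sector angle in radians, `0 < alpha <= 2*pi`.
#' @param rho uncoupled-class central-disk radius, `1 <= rho <= R`.
#' @param m local interaction radius in cell units (`>= 1`).
#' @param rls replicative lifespan: maximal number of divisions along a
#'   progenitor lineage (integer `>= 0`, or `Inf`).
#' @param lambda_s stem-cell division rate (divisions per unit time).
#' @param lambda_p progenitor division rate; `t * lambda_p` is normalized time.
#' @param a fraction of stem divisions that are asymmetric, in `[0, 1]`.
#' @param stem_model `"equipotent"` or `"hierarchical"`.
#' @param stem_fraction fraction of limbal sites that are stem cells
#'   (hierarchical only; forced to 1 for equipotent).
#' @param R_total,limbal_width tissue geometry, as in [build_tissue()].
#' @param displacement_sigma length scale (cells) of the displacement kernel
#'   `exp(-d^2 / (2 * sigma^2))`, `d` the distance to the replication-removal
#'   vector.
#' @param seed default random seed for runs with this configuration.
#' @return An object of class `model_config` (a validated named list).
#' @examples
#' cfg <- model_config(model_class = "coupled", bias = 0.95, rls = 60)
#' cfg$alpha
#' @export
model_config <- function(model_class = c("coupled", "uncoupled"),
                         bias = NULL,
                         alpha = NULL,
                         rho = NULL,
                         m = 5,
                         rls = 60,
                         lambda_s = NULL,
                         lambda_p = 1,
                         a = 0.85,
                         stem_model = c("equipotent", "hierarchical"),
                         stem_fraction = NULL,
                         R_total = 101,
                         limbal_width = 1,
                         displacement_sigma = 1,
                         seed = 1L) {
  model_class <- match.arg(model_class)
  stem_model <- match.arg(stem_model)
  R <- R_total - limbal_width

  if (model_class == "coupled") {
    if (!is.null(rho))
      stop("rho is an uncoupled-model parameter; use alpha (or bias) for the coupled class",
           call. = FALSE)
    if (is.null(alpha))
      alpha <- if (is.null(bias)) 2 * pi else 2 * pi * (1 - bias)
    rho <- R
  } else {
    if (!is.null(alpha))
      stop("alpha is a coupled-model parameter; use rho (or bias) for the uncoupled class",
           call. = FALSE)
    if (is.null(rho))
      rho <- if (is.null(bias)) R else max(1, (1 - bias) * R)
    alpha <- 2 * pi
  }
  if (is.null(lambda_s))
    lambda_s <- if (stem_model == "equipotent") lambda_p else 0.1 * lambda_p
  if (stem_model == "equipotent") {
    stem_fraction <- 1
  } else if (is.null(stem_fraction)) {
    stem_fraction <- 0.1
  }

  cfg <- list(
    model_class = model_class, alpha = alpha, rho = rho, m = m, rls = rls,
    lambda_s = lambda_s, lambda_p = lambda_p, a = a,
    stem_model = stem_model, stem_fraction = stem_fraction,
    R_total = R_total, limbal_width = limbal_width,
    displacement_sigma = displacement_sigma, seed = as.integer(seed)
  )
  class(cfg) <- "model_config"
  validate_config(cfg)
}

#' Validate a model configuration
#'
#' Checks every invariant of the parameter set and returns the configuration
#' unchanged; all violations are reported at once.
#'
#' @param cfg a `model_config` (or plain named list with the same fields).
#' @return The validated `model_config`.
#' @export
validate_config <- function(cfg) {
  R <- cfg$R_total - cfg$limbal_width
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)

  chk(cfg$model_class %in% c("coupled", "uncoupled"),
      "model_class must be 'coupled' or 'uncoupled'")
  chk(cfg$stem_model %in% c("equipotent", "hierarchical"),
      "stem_model must be 'equipotent' or 'hierarchical'")
  chk(is.numeric(cfg$R_total) && cfg$R_total >= 2, "R_total must be >= 2")
  chk(is.numeric(cfg$limbal_width) && cfg$limbal_width >= 1 &&
        cfg$limbal_width < cfg$R_total,
      "limbal_width must satisfy 1 <= limbal_width < R_total")
  chk(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha <= 2 * pi + 1e-12,
      "alpha must lie in (0, 2*pi]")
  chk(is.numeric(cfg$rho) && cfg$rho >= 1 && cfg$rho <= R + 1e-9,
      "rho must satisfy 1 <= rho <= R")
  chk(is.numeric(cfg$m) && cfg$m >= 1, "m must be >= 1")
  chk(is.numeric(cfg$rls) && cfg$rls >= 0, "rls must be >= 0 (or Inf)")
  chk(is.numeric(cfg$lambda_s) && cfg$lambda_s > 0, "lambda_s must be > 0")
  chk(is.numeric(cfg$lambda_p) && cfg$lambda_p > 0, "lambda_p must be > 0")
  chk(is.numeric(cfg$a) && cfg$a >= 0 && cfg$a <= 1, "a must lie in [0, 1]")
  chk(is.numeric(cfg$stem_fraction) && cfg$stem_fraction > 0 &&
        cfg$stem_fraction <= 1,
      "stem_fraction must lie in (0, 1]")
  chk(cfg$stem_model != "equipotent" || cfg$stem_fraction == 1,
      "equipotent model forces stem_fraction = 1")
  chk(is.numeric(cfg$displacement_sigma) && cfg$displacement_sigma > 0,
      "displacement_sigma must be > 0")
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  cfg
}

#' @export
print.model_config <- function(x, ...) {
  cat("model_config:\n")
  cat(sprintf("  class: %s (%s)\n", x$model_class,
              if (x$model_class == "coupled")
                sprintf("alpha = %.4g rad, bias = %.3g", x$alpha,
                        1 - x$alpha / (2 * pi))
              else sprintf("rho = %.4g", x$rho)))
  cat(sprintf("  m = %g, RLS = %g, lambda_s = %g, lambda_p = %g, a = %g\n",
              x$m, x$rls, x$lambda_s, x$lambda_p, x$a))
  cat(sprintf("  stem model: %s (fraction %.3g)\n", x$stem_model, x$stem_fraction))
  cat(sprintf("  R_total = %g, limbal width = %g, seed = %d\n",
              x$R_total, x$limbal_width, x$seed))
  invisible(x)
}

#' Initial tissue state
#'
#' Populates the lattice at `t = 0`: every limbal cell is labeled with a
#' unique clone id (all are stem cells in the equipotent model; in the
#' hierarchical model a random `stem_fraction` subset are stem cells and the
#' rest are limbal progenitors), and every corneal site holds an unlabeled
#' progenitor with zero divisions, so the renewed fraction starts at 0.
#'
#' @param config a [model_config()].
#' @param grid optional pre-built [build_tissue()] grid matching the config.
#' @param seed seed for the stem-site subset draw (hierarchical model).
#' @return An object of class `tissue_state`: list with `grid`, `type`
#'   (character: `"S"`, `"PL"`, `"PC"`), `clone` (integer, `NA` = unlabeled),
#'   `divisions`, `t`, `event_count`.
#' @export
init_state <- function(config, grid = NULL, seed = config$seed) {
  stopifnot(inherits(config, "model_config"))
  if (is.null(grid)) grid <- build_tissue(config$R_total, config$limbal_width)
  n <- nrow(grid$sites)
  type <- rep("PC", n)
  clone <- rep(NA_integer_, n)
  divisions <- rep(0L, n)

  limb <- grid$limbus_ids
  clone[limb] <- seq_along(limb)
  if (config$stem_model == "equipotent") {
    type[limb] <- "S"
  } else {
    n_stem <- max(1L, round(config$stem_fraction * length(limb)))
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    stem <- sample(limb, n_stem)
    type[limb] <- "PL"
    type[stem] <- "S"
  }
  structure(
    list(grid = grid, type = type, clone = clone, divisions = divisions,
         t = 0, event_count = 0),
    class = "tissue_state")
}

#' @export
print.tissue_state <- function(x, ...) {
  cat(sprintf("tissue_state at t = %.4g (%d events)\n", x$t, x$event_count))
  cat(sprintf("  %d sites; renewed fraction %.3f\n",
              length(x$type), renewed_fraction(x)))
  invisible(x)
}

type_codes <- c(S = 0L, PL = 1L, PC = 2L)

state_for_cpp <- function(state) {
  list(type = unname(type_codes[state$type]),
       clone = as.integer(state$clone),
       divisions = as.integer(state$divisions),
       t = as.numeric(state$t))
}

state_from_cpp <- function(res, grid) {
  structure(
    list(grid = grid,
         type = names(type_codes)[res$type + 1L],
         clone = res$clone,
         divisions = res$divisions,
         t = res$t,
         event_count = res$event_count),
    class = "tissue_state")
}

#' Run the stochastic simulation
#'
#' Executes the event loop from an initial (or supplied) state until full
#' renewal, a stalled front, a normalized-time limit, or an event-count limit.
#' Observables are checkpointed on a regular grid of normalized time
#' (`t * lambda_p`, i.e. corneal replication times).
#'
#' @param config a [model_config()].
#' @param seed integer seed; the run is fully reproducible given
#'   `(config, seed)`.
#' @param max_tnorm stop after this many normalized replication times.
#' @param checkpoint_dt checkpoint spacing in normalized time.
#' @param record_snapshots if `TRUE`, store the full clone-label snapshot at
#'   every checkpoint (needed for [clone_size_stats()] and
#'   [time_average_map()]).
#' @param stop_when_renewed stop at the first full renewal (default).
#' @param stall_window declare a steady state (front stall) when the renewed
#'   cell count has not improved for this many normalized replication times.
#' @param max_events optional hard cap on event count.
#' @param init optional starting `tissue_state` (default [init_state()]).
#' @return An object of class `trajectory`: list with `config`, `seed`,
#'   `checkpoints` (data.frame: `t`, `tnorm`, `renewed_fraction`,
#'   `n_clones_limbus`, `n_clones_cornea`), `snapshots` (list of clone
#'   vectors or `NULL`), `state` (final `tissue_state`), `stop_reason` (one
#'   of `"renewed"`, `"stalled"`, `"max_time"`, `"max_events"`,
#'   `"no_competent"`), `renewal_tnorm` (`NA` if renewal was not reached),
#'   `n_events`, `fallbacks`.
#' @examples
#' cfg <- model_config(R_total = 16, m = 3, rls = 20, bias = 0.9)
#' tr <- run_simulation(cfg, seed = 1)
#' tr$stop_reason
#' @export
run_simulation <- function(config, seed = config$seed,
                           max_tnorm = 500, checkpoint_dt = 1,
                           record_snapshots = FALSE,
                           stop_when_renewed = TRUE,
                           stall_window = 20,
                           max_events = Inf,
                           init = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (is.null(init)) init <- init_state(config, seed = seed)
  grid <- init$grid
  control <- list(max_tnorm = as.numeric(max_tnorm),
                  checkpoint_dt = as.numeric(checkpoint_dt),
                  stall_window = as.numeric(stall_window),
                  stop_when_renewed = isTRUE(stop_when_renewed),
                  max_events = as.numeric(max_events),
                  record_snapshots = isTRUE(record_snapshots))
  res <- cpp_simulate(grid_for_cpp(grid), unclass(config),
                      state_for_cpp(init), as.integer(seed), control)
  cps <- as.data.frame(res$checkpoints)
  structure(
    list(config = config, seed = as.integer(seed),
         checkpoints = cps,
         snapshots = if (length(res$snapshots)) res$snapshots else NULL,
         state = state_from_cpp(res, grid),
         stop_reason = res$stop_reason,
         renewal_tnorm = res$renewal_tnorm,
         n_events = res$event_count,
         fallbacks = res$fallbacks),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %s model, seed %d, %d checkpoints\n",
              x$config$model_class, x$seed, nrow(x$checkpoints)))
  cat(sprintf("  stop reason: %s; final renewed fraction %.3f\n",
              x$stop_reason, utils::tail(x$checkpoints$renewed_fraction, 1)))
  if (!is.na(x$renewal_tnorm))
    cat(sprintf("  full renewal at %.2f replication times\n", x$renewal_tnorm))
  invisible(x)
}

#' Normalized simulation time
#'
#' Time in units of the corneal progenitor doubling time: `t * lambda_p`.
#'
#' @param x a `tissue_state` or `trajectory`.
#' @param config configuration supplying `lambda_p` (taken from a trajectory
#'   automatically).
#' @return Normalized time (scalar for a state, vector of checkpoint times
#'   for a trajectory).
#' @export
normalized_time <- function(x, config = NULL) {
  if (inherits(x, "trajectory")) return(x$checkpoints$tnorm)
  if (is.null(config)) stop("config required for a tissue_state", call. = FALSE)
  x$t * config$lambda_p
}

#' Sample division sites
#'
#' Draws `n` dividing-cell sites from the current state without applying any
#' event: each mitotically competent cell is selected with probability
#' proportional to its rate (`lambda_s` for stem cells, `lambda_p` for
#' progenitors below the lifespan); post-mitotic progenitors are never drawn.
#'
#' @param state a `tissue_state`.
#' @param config a [model_config()].
#' @param n number of independent draws.
#' @param seed integer seed.
#' @return Integer vector of site ids.
#' @export
select_division <- function(state, config, n = 1, seed = 1) {
  cpp_sample_division(grid_for_cpp(state$grid), unclass(config),
                      state_for_cpp(state), as.integer(seed), as.integer(n))
}

#' Sample removal sites for a given dividing cell
#'
#' Draws `n` removal sites per the model class: uniform over the inward
#' sector of the dividing cell (coupled) or over the central disk,
#' independent of the dividing cell (uncoupled). Falls back to the unbiased
#' local disk / whole cornea when the biased candidate set is empty.
#'
#' @inheritParams select_division
#' @param div_site site id of the dividing cell.
#' @return Integer vector of corneal site ids.
#' @export
select_removal <- function(state, div_site, config, n = 1, seed = 1) {
  cpp_sample_removal(grid_for_cpp(state$grid), unclass(config),
                     state_for_cpp(state), as.integer(div_site),
                     as.integer(seed), as.integer(n))
}

#' Apply a single division-removal event
#'
#' Deletes the cell at `rem_site`, pulls cells into the vacancy along the
#' `div_site -> rem_site` vector (hole-pulling kernel, weight
#' `exp(-d^2/(2*sigma^2))` in the distance `d` to the segment, restricted to
#' neighbours that progress toward the dividing cell), and places the
#' daughter next to the parent. A stem parent produces a progenitor daughter
#' carrying its clone with a fresh lineage (`divisions = 0`); a progenitor
#' parent and its daughter both advance to `divisions + 1`. Cell number is
#' conserved.
#'
#' @inheritParams select_removal
#' @param rem_site corneal site id of the removed cell (`!= div_site`).
#' @return A list with the updated `state` and the `chain` of hole positions
#'   (from `rem_site` to the final daughter position).
#' @export
apply_division <- function(state, div_site, rem_site, config, seed = 1) {
  res <- cpp_apply_event(grid_for_cpp(state$grid), unclass(config),
                         state_for_cpp(state), as.integer(div_site),
                         as.integer(rem_site), as.integer(seed))
  list(state = state_from_cpp(res, state$grid), chain = res$chain)
}
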