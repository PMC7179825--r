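#' Architectural and schedule configuration of the encoder layer
#'
#' Assembles and validates every architectural, dynamical and training-schedule
#' parameter of the encoder layer (EL). The defaults reproduce the reference
#' architecture: a 15 x 15 grid of cortical columns of 15 x 15 units each
#' (50,625 units), afferent receptive fields of 9 x 29 components over a
#' 10 x 30 embedding grid with 31 sampled inputs per column, 72 lateral and
#' 108 apical linked columns (90% of the 9 x 9 and 11 x 11 windows), six
#' potential synapses per dendritic branch, two winners per column in an SDR
#' event and a 10% afferently excited cluster.
#'
#' @param grid_rows,grid_cols column-grid dimensions.
#' @param units_rows,units_cols per-column unit-lattice dimensions.
#' @param input_rows,input_cols embedding-grid dimensions; their product is
#'   the embedding dimensionality (component `k`, 0-based, maps row-major to
#'   cell `(k %/% input_cols, k %% input_cols)`).
#' @param afferent_rf_rows,afferent_rf_cols afferent window, in components.
#' @param afferent_inputs number of components sampled (without replacement)
#'   from the afferent window; shared by every unit of the column.
#' @param wraparound logical; treat the input grid and the column grid as
#'   toroidal when placing windows.
#' @param lateral_rf_rows,lateral_rf_cols lateral window, in columns.
#' @param lateral_linked linked columns per lateral field (the column itself
#'   is excluded from its own candidate set).
#' @param apical_rf_rows,apical_rf_cols apical window over the foreign
#'   category layer, which shares the EL's column geometry.
#' @param apical_linked linked foreign columns per apical field.
#' @param synapses_per_branch potential synapses per dendritic branch.
#' @param winners_per_cc active units per column in an SDR event (upper
#'   bound; fewer fire when fewer units are predicted).
#' @param excited_fraction fraction of a column's units afferently excited;
#'   the excited-cluster size is `floor(excited_fraction * units)`.
#' @param branch_threshold active established synapses needed on a single
#'   branch for a dendritic spike.
#' @param sdr_min_predicted predicted-and-excited units needed to avoid a
#'   massive firing event (MFE).
#' @param established_threshold weight at or above which a potential synapse
#'   counts as established.
#' @param prune_period learning steps between homeostatic pruning sweeps.
#' @param prune_floor weights strictly below this are zeroed at pruning.
#' @param excitation_beta temperature of stochastic excited-cluster
#'   selection; by default the smallest integer for which the top decile of
#'   units carries at least 90% of the total sampling weight on
#'   unit-variance excitation profiles at the configured lattice size
#'   (3 for 15 x 15 units, 4 for 7 x 7).
#' @param stochastic logical; draw the excited cluster stochastically
#'   (default) or take the top-k deterministically.
#' @param apical_timing `"current"` (default): the coarse-category SDR of the
#'   current word drives apical predictions and plasticity; `"previous"`
#'   uses the previous word's category instead.
#' @param schedule training schedule, see [el_schedule()].
#' @return an object of class `el_config` (a validated named list).
#' @seealso [el_config_scaled()] for the proportionally scaled-down variant
#'   used in tests and desk-scale experiments.
#' @export
el_config <- function(grid_rows = 15L, grid_cols = 15L,
                      units_rows = 15L, units_cols = 15L,
                      input_rows = 10L, input_cols = 30L,
                      afferent_rf_rows = 9L, afferent_rf_cols = 29L,
                      afferent_inputs = 31L,
                      wraparound = TRUE,
                      lateral_rf_rows = 9L, lateral_rf_cols = 9L,
                      lateral_linked = 72L,
                      apical_rf_rows = 11L, apical_rf_cols = 11L,
                      apical_linked = 108L,
                      synapses_per_branch = 6L,
                      winners_per_cc = 2L,
                      excited_fraction = 0.10,
                      branch_threshold = 1L,
                      sdr_min_predicted = 1L,
                      established_threshold = 0.5,
                      prune_period = 1000L,
                      prune_floor = 0.1,
                      excitation_beta = NULL,
                      stochastic = TRUE,
                      apical_timing = c("current", "previous"),
                      schedule = NULL) {
  cfg <- list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    units_rows = as.integer(units_rows), units_cols = as.integer(units_cols),
    input_rows = as.integer(input_rows), input_cols = as.integer(input_cols),
    afferent_rf_rows = as.integer(afferent_rf_rows),
    afferent_rf_cols = as.integer(afferent_rf_cols),
    afferent_inputs = as.integer(afferent_inputs),
    wraparound = isTRUE(wraparound),
    lateral_rf_rows = as.integer(lateral_rf_rows),
    lateral_rf_cols = as.integer(lateral_rf_cols),
    lateral_linked = as.integer(lateral_linked),
    apical_rf_rows = as.integer(apical_rf_rows),
    apical_rf_cols = as.integer(apical_rf_cols),
    apical_linked = as.integer(apical_linked),
    synapses_per_branch = as.integer(synapses_per_branch),
    winners_per_cc = as.integer(winners_per_cc),
    excited_fraction = as.numeric(excited_fraction),
    branch_threshold = as.integer(branch_threshold),
    sdr_min_predicted = as.integer(sdr_min_predicted),
    established_threshold = as.numeric(established_threshold),
    prune_period = as.integer(prune_period),
    prune_floor = as.numeric(prune_floor),
    excitation_beta = as.numeric(excitation_beta %||%
                                   calibrate_beta(as.integer(units_rows) *
                                                    as.integer(units_cols))),
    stochastic = isTRUE(stochastic),
    apical_timing = match.arg(apical_timing)
  )
  cfg$schedule <- schedule %||% el_schedule(cfg)
  class(cfg) <- "el_config"
  validate_config(cfg)
  cfg
}

#' Default three-stage training schedule
#'
#' Stage 1 (two passes): SOM learning rate 0.1 -> 0.01, neighborhood radius
#' half the unit-lattice width -> 1.0, distal learning rate 0.3 -> 0.15.
#' Stage 2 (two passes): 0.05 -> 0.005, 2.0 -> 0.5, 0.15 -> 0.05.
#' Stage 3 (one pass): all parameters fixed at the stage-2 final values.
#' Within a stage each parameter decays exponentially (geometrically) from
#' its initial to its final value across the stage's word events.
#'
#' @param config an `el_config` (only the unit-lattice size is consulted).
#' @return a list of stages, each with `passes`, `alpha`, `sigma` and
#'   `distal_lr` (two-element initial/final vectors).
#' @export
el_schedule <- function(config) {
  half <- max(config$units_rows, config$units_cols) / 2
  list(
    list(passes = 2L, alpha = c(0.1, 0.01), sigma = c(half, 1.0),
         distal_lr = c(0.3, 0.15)),
    list(passes = 2L, alpha = c(0.05, 0.005), sigma = c(2.0, 0.5),
         distal_lr = c(0.15, 0.05)),
    list(passes = 1L, alpha = c(0.005, 0.005), sigma = c(0.5, 0.5),
         distal_lr = c(0.05, 0.05))
  )
}

#' Proportionally scaled-down configuration
#'
#' A 5 x 5 grid of columns with 7 x 7 units, 30-dimensional embeddings on a
#' 5 x 6 grid, and receptive fields scaled in proportion (4 x 5 afferent
#' window with 7 sampled inputs; 3 x 3 lateral and apical windows linked to
#' ~90% of their candidates). All mechanics of the full model are preserved
#' at roughly 1/100 the unit count; this is the configuration used for
#' desk-scale experiments and the test suite.
#'
#' @param ... overrides forwarded to [el_config()].
#' @return an `el_config`.
#' @export
el_config_scaled <- function(...) {
  args <- list(
    grid_rows = 5L, grid_cols = 5L, units_rows = 7L, units_cols = 7L,
    input_rows = 5L, input_cols = 6L,
    afferent_rf_rows = 4L, afferent_rf_cols = 5L, afferent_inputs = 7L,
    lateral_rf_rows = 3L, lateral_rf_cols = 3L, lateral_linked = 7L,
    apical_rf_rows = 3L, apical_rf_cols = 3L, apical_linked = 8L
  )
  do.call(el_config, modifyList(args, list(...)))
}

# Smallest integer temperature at which the top decile of units carries at
# least 90% of the total selection weight on unit-variance excitation
# profiles of `upc` units (deterministic Monte-Carlo calibration).
calibrate_beta <- function(upc, target = 0.9, reps = 400L) {
  with_seed(20260901L, {
    e <- matrix(rnorm(reps * upc), reps, upc)
    k <- max(1L, floor(upc / 10))
    for (beta in 1:20) {
      shares <- vapply(seq_len(reps), function(i) {
        w <- exp(beta * (e[i, ] - max(e[i, ])))
        sum(sort(w, decreasing = TRUE)[seq_len(k)]) / sum(w)
      }, 1.0)
      if (mean(shares) >= target) return(beta)
    }
    20L
  })
}

n_columns <- function(config) config$grid_rows * config$grid_cols
units_per_column <- function(config) config$units_rows * config$units_cols
n_units <- function(config) n_columns(config) * units_per_column(config)
input_size <- function(config) config$input_rows * config$input_cols
excited_size <- function(config)
  as.integer(floor(config$excited_fraction * units_per_column(config)))

validate_config <- function(cfg) {
  dims <- c("grid_rows", "grid_cols", "units_rows", "units_cols",
            "input_rows", "input_cols", "afferent_rf_rows",
            "afferent_rf_cols", "afferent_inputs", "synapses_per_branch",
            "winners_per_cc", "branch_threshold", "sdr_min_predicted")
  for (d in dims)
    if (!is.finite(cfg[[d]]) || cfg[[d]] < 1)
      stop("configuration error: `", d, "` must be a positive integer",
           call. = FALSE)
  if (cfg$lateral_linked < 0 || cfg$apical_linked < 0)
    stop("configuration error: linked-column counts must be non-negative",
         call. = FALSE)
  lat_area <- cfg$lateral_rf_rows * cfg$lateral_rf_cols
  api_area <- cfg$apical_rf_rows * cfg$apical_rf_cols
  aff_area <- cfg$afferent_rf_rows * cfg$afferent_rf_cols
  if (cfg$lateral_linked > lat_area - 1L)
    stop("configuration error: lateral_linked exceeds the lateral window ",
         "candidate count (window area minus the column itself)",
         call. = FALSE)
  if (cfg$apical_linked > api_area)
    stop("configuration error: apical_linked exceeds the apical window area",
         call. = FALSE)
  if (cfg$afferent_inputs > aff_area)
    stop("configuration error: afferent_inputs exceeds the afferent window ",
         "area", call. = FALSE)
  if (cfg$synapses_per_branch > units_per_column(cfg))
    stop("configuration error: synapses_per_branch exceeds the units per ",
         "column", call. = FALSE)
  if (excited_size(cfg) < cfg$winners_per_cc)
    stop("configuration error: floor(excited_fraction * units) must be >= ",
         "winners_per_cc", call. = FALSE)
  if (cfg$excited_fraction <= 0 || cfg$excited_fraction > 1)
    stop("configuration error: excited_fraction must lie in (0, 1]",
         call. = FALSE)
  if (cfg$established_threshold <= 0 || cfg$established_threshold > 1)
    stop("configuration error: established_threshold must lie in (0, 1]",
         call. = FALSE)
  if (cfg$prune_floor < 0 || cfg$prune_floor >= cfg$established_threshold)
    stop("configuration error: prune_floor must lie in [0, ",
         "established_threshold)", call. = FALSE)
  invisible(cfg)
}

#' @export
print.el_config <- function(x, ...) {
  cat("Encoder-layer configuration\n")
  cat(sprintf("  column grid  : %d x %d (%d columns)\n",
              x$grid_rows, x$grid_cols, n_columns(x)))
  cat(sprintf("  unit lattice : %d x %d (%d units/column, %d total)\n",
              x$units_rows, x$units_cols, units_per_column(x), n_units(x)))
  cat(sprintf("  input grid   : %d x %d (%d components), afferent window %d x %d, %d sampled\n",
              x$input_rows, x$input_cols, input_size(x),
              x$afferent_rf_rows, x$afferent_rf_cols, x$afferent_inputs))
  cat(sprintf("  lateral      : %d x %d window, %d linked columns\n",
              x$lateral_rf_rows, x$lateral_rf_cols, x$lateral_linked))
  cat(sprintf("  apical       : %d x %d window, %d linked columns\n",
              x$apical_rf_rows, x$apical_rf_cols, x$apical_linked))
  cat(sprintf("  branches     : %d synapses each, spike threshold %d\n",
              x$synapses_per_branch, x$branch_threshold))
  cat(sprintf("  activation   : %d winners/column, excited cluster %d (%.0f%%), %s\n",
              x$winners_per_cc, excited_size(x), 100 * x$excited_fraction,
              if (x$stochastic) "stochastic" else "deterministic"))
  cat(sprintf("  plasticity   : established >= %.2f, prune < %.2f every %d steps\n",
              x$established_threshold, x$prune_floor, x$prune_period))
  invisible(x)
}

# Read a configuration from a YAML (or JSON) file whose keys mirror the
# el_config() arguments field for field.
config_from_file <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- setdiff(names(formals(el_config)), c("schedule", "..."))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    stop("configuration error: unknown config keys: ",
         paste(extra, collapse = ", "), call. = FALSE)
  do.call(el_config, vals)
}

config_to_file <- function(config, path) {
  vals <- unclass(config)
  vals$schedule <- NULL
  yaml::write_yaml(vals, path)
  invisible(path)
}
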