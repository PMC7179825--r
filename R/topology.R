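# sample() without the scalar-x surprise
resample <- function(x, size) x[sample.int(length(x), size)]

#' Build the encoder layer's geometry
#'
#' Places the column grid over the input (embedding) grid, samples each
#' column's afferent input components, and draws the lateral and apical
#' linked-column sets. Column centers are uniformly spaced row-major over
#' the input grid (`center = floor((i + 0.5) * input_extent / grid_extent)`);
#' linked sets are seeded random samples from the rectangular window centered
#' at each column, with toroidal wraparound when enabled. A column is
#' excluded from its own lateral candidate set; the apical window is centered
#' on the same grid coordinate of the foreign category layer, which shares
#' the EL's column geometry.
#'
#' @param config an [el_config()].
#' @param seed integer seed; the topology is deterministic given
#'   `config` and `seed`.
#' @return an object of class `el_topology`: a list with `centers`
#'   (columns x 2, 1-based input-grid coordinates), `afferent`
#'   (`afferent_inputs` x columns matrix of flat 1-based input component
#'   indices), `lateral_links` and `apical_links` (columns x linked matrices
#'   of 1-based column ids), and the `config`.
#' @export
build_topology <- function(config, seed = 1L) {
  stopifnot(inherits(config, "el_config"))
  nc <- n_columns(config)
  centers <- matrix(0L, nc, 2L)
  for (i in seq_len(config$grid_rows)) {
    for (j in seq_len(config$grid_cols)) {
      cc <- (i - 1L) * config$grid_cols + j
      centers[cc, 1L] <- as.integer(
        floor((i - 0.5) * config$input_rows / config$grid_rows)) + 1L
      centers[cc, 2L] <- as.integer(
        floor((j - 0.5) * config$input_cols / config$grid_cols)) + 1L
    }
  }
  with_seed(derive_seed(seed, "wiring"), {
    aff <- matrix(0L, config$afferent_inputs, nc)
    for (cc in seq_len(nc))
      aff[, cc] <- sample_afferent_inputs(config, centers[cc, ])
    lat <- matrix(0L, nc, config$lateral_linked)
    api <- matrix(0L, nc, config$apical_linked)
    for (i in seq_len(config$grid_rows)) {
      for (j in seq_len(config$grid_cols)) {
        cc <- (i - 1L) * config$grid_cols + j
        cand <- window_columns(config, i, j,
                               config$lateral_rf_rows, config$lateral_rf_cols)
        cand <- setdiff(cand, cc)
        if (config$lateral_linked > length(cand))
          stop("configuration error: lateral_linked exceeds available ",
               "window candidates", call. = FALSE)
        if (config$lateral_linked > 0L)
          lat[cc, ] <- sort(resample(cand, config$lateral_linked))
        cand_a <- window_columns(config, i, j,
                                 config$apical_rf_rows, config$apical_rf_cols)
        if (config$apical_linked > length(cand_a))
          stop("configuration error: apical_linked exceeds available ",
               "window candidates", call. = FALSE)
        if (config$apical_linked > 0L)
          api[cc, ] <- sort(resample(cand_a, config$apical_linked))
      }
    }
    structure(list(config = config, centers = centers, afferent = aff,
                   lateral_links = lat, apical_links = api, seed = seed),
              class = "el_topology")
  })
}

# 1-based positions of a length-`rf` window centered at `center` on an axis
# of extent `n`; toroidal when wrap is TRUE, otherwise errors if the window
# leaves the axis. For even rf the window extends one step further towards
# lower coordinates.
window_axis <- function(center, rf, n, wrap) {
  offs <- seq_len(rf) - 1L - (rf %/% 2L)
  pos <- center + offs
  if (wrap) return(((pos - 1L) %% n) + 1L)
  if (any(pos < 1L | pos > n))
    stop("configuration error: receptive-field window exceeds the grid and ",
         "wraparound is disabled", call. = FALSE)
  pos
}

window_columns <- function(config, i, j, rf_rows, rf_cols) {
  # a window larger than the (toroidal) grid wraps onto itself: duplicate
  # positions collapse to one candidate
  rows <- unique(window_axis(i, rf_rows, config$grid_rows, config$wraparound))
  cols <- unique(window_axis(j, rf_cols, config$grid_cols, config$wraparound))
  as.integer(outer((rows - 1L) * config$grid_cols, cols, "+"))
}

#' Sample a column's afferent input components
#'
#' Draws `afferent_inputs` distinct flat component indices, without
#' replacement, from the afferent window centered at the column's input-grid
#' location. The same index list is shared by every unit of the column. Uses
#' the current RNG state; [build_topology()] seeds it once for all columns.
#'
#' @param config an [el_config()].
#' @param column_center length-2 integer vector, 1-based (row, col) center
#'   on the input grid.
#' @return an integer vector of `afferent_inputs` distinct flat (row-major,
#'   1-based) component indices.
#' @export
sample_afferent_inputs <- function(config, column_center) {
  rows <- unique(window_axis(column_center[1L], config$afferent_rf_rows,
                             config$input_rows, config$wraparound))
  cols <- unique(window_axis(column_center[2L], config$afferent_rf_cols,
                             config$input_cols, config$wraparound))
  window <- as.integer(outer((rows - 1L) * config$input_cols, cols, "+"))
  if (config$afferent_inputs > length(window))
    stop("configuration error: afferent_inputs exceeds the window area",
         call. = FALSE)
  resample(window, config$afferent_inputs)
}

#' Wire the distal potential synapses
#'
#' For every post-synaptic unit and each pathway, creates one dendritic
#' branch per linked source column, each holding `synapses_per_branch`
#' distinct presynaptic units drawn uniformly from that column. Wiring is
#' deterministic given the topology and seed.
#'
#' @param config an [el_config()].
#' @param topology an [build_topology()] result.
#' @param seed integer seed.
#' @return an object of class `el_wiring`: a list with `lateral` and
#'   `apical` integer matrices of global presynaptic unit ids
#'   (`n_units` x `linked * synapses_per_branch`; branch `b` occupies slot
#'   columns `(b-1)*spb + 1 ... b*spb`), plus `spb`.
#' @export
wire_distal <- function(config, topology, seed = 1L) {
  stopifnot(inherits(topology, "el_topology"))
  upc <- units_per_column(config)
  if (config$synapses_per_branch > upc)
    stop("configuration error: synapses_per_branch exceeds units per ",
         "source column", call. = FALSE)
  with_seed(derive_seed(seed, "distal"), {
    lat <- cpp_wire_branches(topology$lateral_links, upc,
                             config$synapses_per_branch)
    api <- cpp_wire_branches(topology$apical_links, upc,
                             config$synapses_per_branch)
    structure(list(lateral = lat, apical = api,
                   spb = config$synapses_per_branch, seed = seed),
              class = "el_wiring")
  })
}

#' Synapse census by enumeration
#'
#' Counts units and proximal/distal potential synapses by enumerating the
#' built structures (never by closed-form multiplication), so the census
#' audits the wiring. For the default configuration this yields 50,625 units,
#' 1,569,375 proximal synapses and 54,675,000 distal potential synapses
#' (432 lateral + 648 apical = 1,080 per unit).
#'
#' @param x an `el_config` (topology and wiring are then built with `seed`)
#'   or a trained/untrained [el_encoder()].
#' @param ... passed on (`seed` for the config method).
#' @return an object of class `el_census` with fields `total_units`,
#'   `proximal_synapses`, `distal_potential_synapses_total`,
#'   `distal_per_unit`, `lateral_per_unit`, `apical_per_unit`.
#' @export
synapse_census <- function(x, ...) UseMethod("synapse_census")

#' @rdname synapse_census
#' @param seed seed used to build topology and wiring.
#' @export
synapse_census.el_config <- function(x, seed = 1L, ...) {
  topo <- build_topology(x, seed)
  wiring <- wire_distal(x, topo, seed)
  census_from_parts(x, topo, wiring)
}

#' @rdname synapse_census
#' @export
synapse_census.el_encoder <- function(x, ...) {
  census_from_parts(x$config, x$topology, x$wiring)
}

census_from_parts <- function(config, topology, wiring) {
  upc <- units_per_column(config)
  # per-column afferent index counts, replicated over that column's units
  aff_per_col <- apply(topology$afferent, 2L, function(ix) sum(ix > 0L))
  proximal <- sum(rep(aff_per_col, each = upc))
  lat <- wiring$lateral
  api <- wiring$apical
  n_post <- if (!is.null(lat)) nrow(lat) else nrow(api)
  lat_counts <- if (is.null(lat) || ncol(lat) == 0L) integer(n_post)
                else rowSums(lat > 0L)
  api_counts <- if (is.null(api) || ncol(api) == 0L) integer(n_post)
                else rowSums(api > 0L)
  per_unit_l <- unique(lat_counts)
  per_unit_a <- unique(api_counts)
  if (length(per_unit_l) != 1L || length(per_unit_a) != 1L)
    stop("structural error: wiring is not uniform across units",
         call. = FALSE)
  out <- list(
    total_units = as.integer(n_post),
    proximal_synapses = proximal,
    distal_potential_synapses_total = sum(lat_counts) + sum(api_counts),
    distal_per_unit = as.integer(per_unit_l + per_unit_a),
    lateral_per_unit = as.integer(per_unit_l),
    apical_per_unit = as.integer(per_unit_a)
  )
  class(out) <- "el_census"
  out
}

#' @export
print.el_census <- function(x, ...) {
  vals <- unclass(x)
  cat("quantity\tcount\n")
  for (nm in names(vals))
    cat(nm, "\t", format(vals[[nm]], scientific = FALSE), "\n", sep = "")
  invisible(x)
}
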