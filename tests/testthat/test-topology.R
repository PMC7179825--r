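test_that("default topology links 225 columns with 72 lateral and 108 apical columns", {
  cfg <- el_config()
  topo <- build_topology(cfg, seed = 1)
  expect_equal(nrow(topo$centers), 225L)
  expect_equal(dim(topo$lateral_links), c(225L, 72L))
  expect_equal(dim(topo$apical_links), c(225L, 108L))
  # no column is linked laterally to itself
  for (cc in c(1L, 113L, 225L))
    expect_false(cc %in% topo$lateral_links[cc, ])
})

test_that("column centers stride the input grid uniformly and deterministically", {
  cfg <- el_config()
  topo <- build_topology(cfg, seed = 7)
  expect_equal(topo$centers[1, ], c(1L, 2L))
  # row-major: column index 15 is grid position (1, 15)
  expect_equal(topo$centers[15, 2], floor(14.5 * 30 / 15) + 1L)
  expect_identical(topo$centers, build_topology(cfg, seed = 99)$centers)
})

test_that("degenerate single-column grid has no lateral links", {
  cfg <- el_config(grid_rows = 1, grid_cols = 1, units_rows = 3,
                   units_cols = 3, input_rows = 2, input_cols = 2,
                   afferent_rf_rows = 1, afferent_rf_cols = 1,
                   afferent_inputs = 1, lateral_rf_rows = 1,
                   lateral_rf_cols = 1, lateral_linked = 0,
                   apical_rf_rows = 1, apical_rf_cols = 1,
                   apical_linked = 1, synapses_per_branch = 2,
                   winners_per_cc = 1, excited_fraction = 0.4)
  topo <- build_topology(cfg, 1)
  expect_equal(ncol(topo$lateral_links), 0L)
  wiring <- wire_distal(cfg, topo, 1)
  expect_equal(ncol(wiring$lateral), 0L)
})

test_that("toroidal lateral candidate sets match brute-force enumeration on a 5x5 grid", {
  cfg <- el_config(grid_rows = 5, grid_cols = 5, units_rows = 3,
                   units_cols = 3, input_rows = 5, input_cols = 5,
                   afferent_rf_rows = 3, afferent_rf_cols = 3,
                   afferent_inputs = 4, lateral_rf_rows = 3,
                   lateral_rf_cols = 3, lateral_linked = 8,
                   apical_rf_rows = 3, apical_rf_cols = 3,
                   apical_linked = 9, synapses_per_branch = 2,
                   winners_per_cc = 1, excited_fraction = 0.34)
  topo <- build_topology(cfg, 3)
  for (i in 1:5) for (j in 1:5) {
    cc <- (i - 1L) * 5L + j
    cand <- as.integer(outer((oracle_window(i, 3, 5) - 1L) * 5L,
                             oracle_window(j, 3, 5), "+"))
    expect_setequal(topo$lateral_links[cc, ], setdiff(cand, cc))
  }
})

test_that("afferent samples are distinct and lie in the brute-force toroidal window", {
  cfg <- el_config()
  topo <- build_topology(cfg, seed = 11)
  for (cc in c(1L, 100L, 225L)) {
    ix <- topo$afferent[, cc]
    expect_equal(length(unique(ix)), 31L)
    rows <- oracle_window(topo$centers[cc, 1], 9, 10)
    cols <- oracle_window(topo$centers[cc, 2], 29, 30)
    window <- as.integer(outer((rows - 1L) * 30L, cols, "+"))
    expect_true(all(ix %in% window))
  }
  # wraparound: a corner column's sampled rows use both grid edges
  rows_used <- (topo$afferent[, 1] - 1L) %/% 30L + 1L
  expect_true(all(rows_used %in% oracle_window(topo$centers[1, 1], 9, 10)))
})

test_that("afferent samples cover the brute-force window across random small configs", {
  set.seed(42)
  for (rep in 1:100) {
    ir <- sample(3:8, 1); ic <- sample(3:10, 1)
    rr <- sample(seq(1, ir, 2), 1); rc <- sample(seq(1, ic, 2), 1)
    k <- sample(rr * rc, 1)
    cfg <- el_config(grid_rows = 2, grid_cols = 2, units_rows = 2,
                     units_cols = 2, input_rows = ir, input_cols = ic,
                     afferent_rf_rows = rr, afferent_rf_cols = rc,
                     afferent_inputs = k, lateral_rf_rows = 3,
                     lateral_rf_cols = 3, lateral_linked = 3,
                     apical_rf_rows = 3, apical_rf_cols = 3,
                     apical_linked = 4, synapses_per_branch = 2,
                     winners_per_cc = 1, excited_fraction = 0.5)
    center <- c(sample(ir, 1), sample(ic, 1))
    ix <- sample_afferent_inputs(cfg, center)
    window <- as.integer(outer((oracle_window(center[1], rr, ir) - 1L) * ic,
                               oracle_window(center[2], rc, ic), "+"))
    expect_true(all(ix %in% window))
    expect_equal(anyDuplicated(ix), 0L)
  }
})

test_that("window placement without wraparound errors when it exceeds the grid", {
  cfg <- tiny_config()
  cfg$wraparound <- FALSE
  expect_error(build_topology(cfg, 1), "wraparound")
})

test_that("whole-grid window with full sampling returns the complete index set", {
  cfg <- el_config(grid_rows = 1, grid_cols = 1, units_rows = 2,
                   units_cols = 2, input_rows = 3, input_cols = 3,
                   afferent_rf_rows = 3, afferent_rf_cols = 3,
                   afferent_inputs = 9, lateral_rf_rows = 1,
                   lateral_rf_cols = 1, lateral_linked = 0,
                   apical_rf_rows = 1, apical_rf_cols = 1,
                   apical_linked = 1, synapses_per_branch = 2,
                   winners_per_cc = 1, excited_fraction = 0.5)
  topo <- build_topology(cfg, 1)
  expect_setequal(topo$afferent[, 1], 1:9)
})

test_that("distal wiring has valid distinct presynaptic ids per branch", {
  cfg <- tiny_config()
  topo <- build_topology(cfg, 5)
  wiring <- wire_distal(cfg, topo, 5)
  upc <- 6L
  spb <- cfg$synapses_per_branch
  for (r in seq_len(nrow(wiring$lateral))) {
    pc <- (r - 1L) %/% upc + 1L
    for (b in seq_len(cfg$lateral_linked)) {
      ids <- wiring$lateral[r, ((b - 1L) * spb + 1L):(b * spb)]
      expect_equal(anyDuplicated(ids), 0L)
      src <- topo$lateral_links[pc, b]
      expect_true(all((ids - 1L) %/% upc + 1L == src))
    }
  }
})

test_that("wiring is reproducible per seed and differs across seeds", {
  cfg <- tiny_config()
  topo <- build_topology(cfg, 5)
  w1 <- wire_distal(cfg, topo, 5)
  w2 <- wire_distal(cfg, topo, 5)
  w3 <- wire_distal(cfg, topo, 6)
  expect_identical(w1$lateral, w2$lateral)
  expect_false(identical(w1$lateral, w3$lateral))
})

test_that("census by enumeration matches the reference architecture exactly", {
  cen <- cached("full_census", synapse_census(el_config(), seed = 1))
  expect_equal(cen$total_units, 50625L)
  expect_equal(cen$proximal_synapses, 1569375)
  expect_equal(cen$distal_potential_synapses_total, 54675000)
  expect_equal(cen$distal_per_unit, 1080L)
  expect_equal(cen$lateral_per_unit, 432L)
  expect_equal(cen$apical_per_unit, 648L)
})

test_that("census totals equal per-unit counts times unit count on toy configs", {
  for (seed in 1:3) {
    cfg <- tiny_config()
    cen <- synapse_census(cfg, seed = seed)
    expect_equal(cen$distal_potential_synapses_total,
                 cen$distal_per_unit * cen$total_units)
    expect_equal(cen$distal_per_unit,
                 cen$lateral_per_unit + cen$apical_per_unit)
    # hand count: 2 lateral links x 2 synapses + 2 apical links x 2
    expect_equal(cen$lateral_per_unit, 4L)
    expect_equal(cen$apical_per_unit, 4L)
    expect_equal(cen$total_units, 24L)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(el_config(lateral_linked = 81), "lateral_linked")
  expect_error(el_config(apical_linked = 122), "apical_linked")
  expect_error(el_config(afferent_inputs = 262), "afferent_inputs")
  expect_error(el_config(excited_fraction = 0.004), "winners_per_cc")
  expect_error(el_config(grid_rows = 0), "positive")
  expect_error(el_config(synapses_per_branch = 226), "synapses_per_branch")
})
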