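# Nearest-neighbor and count-within-radius statistics against geometry
# examples and the O(n^2) brute-force oracle.

test_that("nearest-neighbor mean matches hand geometry", {
  les <- make_lesion(x = c(0, 30, 10), y = c(0, 0, 0),
                     markers = list(CK = c(1, 1, 0), CD8 = c(0, 0, 1)),
                     nests = list())
  expect_equal(as.numeric(nn_mean_distance(les, "tumor", "CTL")), 15)
  # coincident single ref and query
  les2 <- make_lesion(x = c(5, 5), y = c(5, 5),
                      markers = list(CK = c(1, 0), CD8 = c(0, 1)), nests = list())
  expect_equal(as.numeric(nn_mean_distance(les2, "tumor", "CTL")), 0)
  # no reference cells -> missing
  expect_true(is.na(nn_mean_distance(les2, "Treg", "CTL")))
})

test_that("count-within is boundary inclusive and counts references", {
  les <- make_lesion(x = c(0, 50, 10), y = c(0, 0, 0),
                     markers = list(CK = c(1, 1, 0), CD8 = c(0, 0, 1)),
                     nests = list())
  expect_equal(as.numeric(pct_within_radius(les, "tumor", "CTL", 20)), 50)
  # query at exactly the radius counts (closed ball)
  les2 <- make_lesion(x = c(0, 20), y = c(0, 0),
                      markers = list(CK = c(1, 0), CD8 = c(0, 1)), nests = list())
  expect_equal(as.numeric(pct_within_radius(les2, "tumor", "CTL", 20)), 100)
  expect_equal(attr(pct_within_radius(les2, "tumor", "CTL", 20), "n_reference"), 1L)
  expect_true(is.na(pct_within_radius(les2, "Treg", "CTL", 20)))
})

test_that("implementation equals the brute-force oracle on random instances", {
  set.seed(99)
  seeds <- sample.int(1e6, 30)
  for (s in seeds) {
    les <- random_lesion(sample(50:250, 1), n_fields = sample(1:3, 1), seed = s)
    expect_identical(as.numeric(nn_mean_distance(les, "tumor", "CTL")),
                     oracle_nn_mean(les, "tumor", "CTL"), info = s)
    expect_identical(as.numeric(pct_within_radius(les, "tumor", "CTL", 20)),
                     oracle_pct_within(les, "tumor", "CTL", 20), info = s)
    # overlapping reference/query labels (TRM is a subset of CTL)
    expect_identical(as.numeric(nn_mean_distance(les, "CTL", "TRM")),
                     oracle_nn_mean(les, "CTL", "TRM"), info = s)
    expect_identical(as.numeric(pct_within_radius(les, "CTL", "CTL", 25)),
                     oracle_pct_within(les, "CTL", "CTL", 25), info = s)
  }
})

test_that("cells in different fields are never neighbors and exclusions count", {
  # query cell only in field 2; references in field 1 must be excluded
  panel <- marker_panel("9-color")
  cells <- data.frame(cell_id = c("a", "b", "c"), field_id = c("F01", "F01", "F02"),
                      x = c(0, 10, 0), y = c(0, 0, 0),
                      compartment = "stroma", check.names = FALSE)
  calls <- matrix(0L, 3, 8, dimnames = list(NULL, panel$markers))
  calls[1:2, "CK"] <- 1L
  calls[3, "CD8"] <- 1L
  cells <- assign_phenotypes(cell_table(cbind(cells, as.data.frame(calls, check.names = FALSE)), panel))
  fields <- list(field_geometry("F01", 650, 500, list()),
                 field_geometry("F02", 650, 500, list()))
  les <- lesion_sample("S", "P", "primary", fields, cells)
  nn <- nn_mean_distance(les, "tumor", "CTL")
  expect_true(is.na(as.numeric(nn)))
  expect_equal(attr(nn, "n_excluded"), 2L)
  expect_equal(as.numeric(pct_within_radius(les, "tumor", "CTL", 1e6)), 0)
})

test_that("proximity statistics obey monotonicity and invariance properties", {
  les <- random_lesion(300, n_fields = 2, seed = 55)
  # non-decreasing in radius
  radii <- c(5, 10, 20, 40, 80)
  v <- vapply(radii, function(r) as.numeric(pct_within_radius(les, "tumor", "CTL", r)),
              numeric(1))
  expect_true(all(diff(v) >= 0))
  # adding a query cell: nn mean never increases, pct never decreases
  cells <- as.data.frame(les$cells, check.names = FALSE)
  extra <- cells[1, ]
  extra$cell_id <- "extra"; extra$CD8 <- 1L; extra$CK <- 0L; extra$CD103 <- 0L
  extra$x <- 325; extra$y <- 250
  les2 <- lesion_sample("S", "P", "primary", les$fields,
                        assign_phenotypes(cell_table(rbind(cells, extra),
                                                     attr(les$cells, "panel"))))
  expect_lte(as.numeric(nn_mean_distance(les2, "tumor", "CTL")),
             as.numeric(nn_mean_distance(les, "tumor", "CTL")))
  expect_gte(as.numeric(pct_within_radius(les2, "tumor", "CTL", 20)),
             as.numeric(pct_within_radius(les, "tumor", "CTL", 20)))
  # translation invariance within a field
  cells3 <- as.data.frame(les$cells, check.names = FALSE)
  cells3$x <- cells3$x + 40; cells3$y <- cells3$y + 30
  fields3 <- lapply(les$fields, function(f) field_geometry(f$field_id, 1000, 1000, list()))
  les3 <- lesion_sample("S", "P", "primary", fields3,
                        assign_phenotypes(cell_table(cells3, attr(les$cells, "panel"))))
  expect_equal(as.numeric(nn_mean_distance(les3, "tumor", "CTL")),
               as.numeric(nn_mean_distance(les, "tumor", "CTL")))
  expect_equal(as.numeric(pct_within_radius(les3, "tumor", "CTL", 20)),
               as.numeric(pct_within_radius(les, "tumor", "CTL", 20)))
})

test_that("proximity panel is tidy, asymmetric, and validates labels", {
  les <- random_lesion(300, n_fields = 2, seed = 77)
  pan <- suppressWarnings(proximity_panel(les))
  expect_equal(nrow(pan), 2L * nrow(default_proximity_pairs()))
  expect_setequal(unique(pan$statistic), c("nn_mean_distance_um", "pct_within_radius"))
  # swapping reference and query changes the result in general: construct a
  # counterexample with 1 tumor cell near a cluster of CTLs
  ctr <- make_lesion(x = c(0, 1, 2, 600), y = c(0, 0, 0, 0),
                     markers = list(CK = c(1, 0, 0, 0), CD8 = c(0, 1, 1, 1)),
                     nests = list())
  fwd <- as.numeric(pct_within_radius(ctr, "tumor", "CTL", 20))
  rev <- as.numeric(pct_within_radius(ctr, "CTL", "tumor", 20))
  expect_false(isTRUE(all.equal(fwd, rev)))
  bad_pairs <- data.frame(reference = "nonexistent", query = "CTL",
                          compartment = "both")
  expect_error(proximity_panel(les, bad_pairs), "unknown phenotype")
})

test_that("attraction enrichment raises count-within relative to CSR", {
  base <- default_calibration()
  enriched <- spatial_params(base$intensity,
                             attraction = data.frame(attracted = "mac_m2",
                                                     anchor = "cd8",
                                                     rho = 0.5, r_attr = 15))
  diffs <- vapply(1:8, function(i) {
    l0 <- generate_lesion(base, "negative", "primary", "a", n_fields = 4, seed = 1000 + i)
    l1 <- generate_lesion(enriched, "negative", "primary", "b", n_fields = 4, seed = 1000 + i)
    l0$cells <- assign_phenotypes(l0$cells)
    l1$cells <- assign_phenotypes(l1$cells)
    as.numeric(pct_within_radius(l1, "M2-TAM", "CTL", 20)) -
      as.numeric(pct_within_radius(l0, "M2-TAM", "CTL", 20))
  }, numeric(1))
  expect_true(all(diffs > 0))
})
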