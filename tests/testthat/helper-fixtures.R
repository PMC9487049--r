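# Fixture builders and independent oracles used across the suite.

# -- toy lesion with a single rectangular-ish field --------------------------

# Build a lesion from explicit cell coordinates/markers; default geometry is
# one 650x500 field with a single centered disc nest.
make_lesion <- function(x, y, markers = list(), field_id = "F01",
                        width = 650, height = 500,
                        nests = list(disc_polygon(200, 200, 120)),
                        compartment = NULL, sample_id = "S1",
                        lesion_type = "primary", assign = TRUE) {
  panel <- marker_panel("9-color")
  n <- length(x)
  calls <- matrix(0L, n, length(panel$markers),
                  dimnames = list(NULL, panel$markers))
  for (m in names(markers)) calls[, m] <- as.integer(markers[[m]])
  geom <- field_geometry(field_id, width, height, nests)
  if (is.null(compartment)) {
    compartment <- if (n) ifelse(point_in_nests(geom, x, y), "tumor", "stroma") else character(0)
  }
  cells <- data.frame(cell_id = sprintf("c%03d", seq_len(n)),
                      field_id = rep(field_id, n), x = x, y = y,
                      compartment = compartment, check.names = FALSE)
  cells <- cbind(cells, as.data.frame(calls, check.names = FALSE))
  cells <- cell_table(cells, panel)
  if (assign) cells <- assign_phenotypes(cells)
  lesion_sample(sample_id, "P1", lesion_type, list(geom), cells)
}

# random cell table over several fields for oracle-equivalence checks
random_lesion <- function(n_cells, n_fields = 3, seed, width = 650, height = 500,
                          p_cd8 = 0.3, p_ck = 0.4) {
  set.seed(seed)
  panel <- marker_panel("9-color")
  fid <- sprintf("F%02d", sample.int(n_fields, n_cells, replace = TRUE))
  calls <- matrix(0L, n_cells, length(panel$markers),
                  dimnames = list(NULL, panel$markers))
  calls[, "CD8"] <- rbinom(n_cells, 1, p_cd8)
  calls[, "CK"] <- ifelse(calls[, "CD8"] == 1L, 0L, rbinom(n_cells, 1, p_ck))
  calls[, "CD103"] <- ifelse(calls[, "CD8"] == 1L, rbinom(n_cells, 1, 0.5), 0L)
  cells <- data.frame(cell_id = sprintf("c%05d", seq_len(n_cells)),
                      field_id = fid,
                      x = runif(n_cells, 0, width), y = runif(n_cells, 0, height),
                      compartment = sample(c("tumor", "stroma"), n_cells, TRUE),
                      check.names = FALSE)
  cells <- cbind(cells, as.data.frame(calls, check.names = FALSE))
  cells <- assign_phenotypes(cell_table(cells, panel))
  fields <- lapply(sprintf("F%02d", seq_len(n_fields)), function(f)
    field_geometry(f, width, height, nests = list()))
  lesion_sample("R1", "P1", "primary", fields, cells)
}

# -- brute-force proximity oracles (plain O(n^2) double loops) ----------------

oracle_nn_mean <- function(sample, reference, query, compartment = "both") {
  cells <- sample$cells
  ref <- which(cells[[reference]] &
                 (compartment == "both" | cells$compartment == compartment))
  qry <- which(cells[[query]])
  dists <- c()
  for (i in ref) {
    best <- Inf
    for (j in qry) {
      if (j == i) next
      if (cells$field_id[j] != cells$field_id[i]) next
      d <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2)
      if (d < best) best <- d
    }
    if (is.finite(best)) dists <- c(dists, best)
  }
  if (length(dists)) mean(dists) else NA_real_
}

oracle_pct_within <- function(sample, reference, query, radius = 20,
                              compartment = "both") {
  cells <- sample$cells
  ref <- which(cells[[reference]] &
                 (compartment == "both" | cells$compartment == compartment))
  if (!length(ref)) return(NA_real_)
  qry <- which(cells[[query]])
  hits <- 0L
  for (i in ref) {
    for (j in qry) {
      if (j == i) next
      if (cells$field_id[j] != cells$field_id[i]) next
      d <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2)
      if (d <= radius) { hits <- hits + 1L; break }
    }
  }
  100 * hits / length(ref)
}

# Brute-force variants with a vectorized inner loop (still O(n^2)); used for
# the larger oracle-equivalence instances where the pure double loop is slow.
oracle_nn_mean_vec <- function(sample, reference, query, compartment = "both") {
  cells <- sample$cells
  ref <- which(cells[[reference]] &
                 (compartment == "both" | cells$compartment == compartment))
  qry <- which(cells[[query]])
  dists <- c()
  for (i in ref) {
    q <- qry[qry != i & cells$field_id[qry] == cells$field_id[i]]
    if (!length(q)) next
    dists <- c(dists, min(sqrt((cells$x[i] - cells$x[q])^2 +
                                 (cells$y[i] - cells$y[q])^2)))
  }
  if (length(dists)) mean(dists) else NA_real_
}

oracle_pct_within_vec <- function(sample, reference, query, radius = 20,
                                  compartment = "both") {
  cells <- sample$cells
  ref <- which(cells[[reference]] &
                 (compartment == "both" | cells$compartment == compartment))
  if (!length(ref)) return(NA_real_)
  qry <- which(cells[[query]])
  hits <- 0L
  for (i in ref) {
    q <- qry[qry != i & cells$field_id[qry] == cells$field_id[i]]
    if (!length(q)) next
    d <- sqrt((cells$x[i] - cells$x[q])^2 + (cells$y[i] - cells$y[q])^2)
    if (any(d <= radius)) hits <- hits + 1L
  }
  100 * hits / length(ref)
}

# -- statistical oracles ------------------------------------------------------

# two-sided Fisher p for a 2x2 table by full hypergeometric enumeration
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(support, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# BH step-up by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}
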