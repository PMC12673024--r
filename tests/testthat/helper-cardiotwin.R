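# Shared fixtures, built once per session and cached. All geometry is
# generated in code at test time; nothing is read from disk.

.fix <- new.env(parent = emptyenv())

# small desk-scale biventricular twin shared by anatomy/personalization tests
test_twin <- function() {
  if (is.null(.fix$twin)) {
    mesh <- build_idealized_biventricle(lv_radius = 15, lv_length = 30,
                                        lv_wall = 7, rv_wall = 3, rv_gap = 4,
                                        edge_length = 2.2)
    .fix$twin <- build_twin(mesh)
  }
  .fix$twin
}
test_mesh <- function() test_twin()$mesh
test_coords <- function() test_twin()$coords

# structured cube of Kuhn tetrahedra with fibers along +x
cube_mesh <- function(nx, h) {
  key <- sprintf("cube|%d|%g", nx, h)
  if (!is.null(.fix[[key]])) return(.fix[[key]])
  g <- expand.grid(x = 0:(nx - 1), y = 0:(nx - 1), z = 0:(nx - 1))
  nodes <- as.matrix(g) * h
  idx <- function(i, j, k) 1L + i + nx * (j + nx * k)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  cell <- expand.grid(i = 0:(nx - 2), j = 0:(nx - 2), k = 0:(nx - 2))
  tl <- vector("list", 6)
  for (p in 1:6) {
    pp <- perms[p, ]
    v <- matrix(0L, nrow(cell), 12)
    v[, 1:3] <- as.matrix(cell)
    for (q in 1:3) {
      v[, 3 * q + 1:3] <- v[, 3 * (q - 1) + 1:3]
      v[, 3 * q + pp[q]] <- v[, 3 * q + pp[q]] + 1L
    }
    tl[[p]] <- cbind(idx(v[, 1], v[, 2], v[, 3]), idx(v[, 4], v[, 5], v[, 6]),
                     idx(v[, 7], v[, 8], v[, 9]), idx(v[, 10], v[, 11], v[, 12]))
  }
  tets <- do.call(rbind, tl)
  out <- list(nodes = nodes, elems = tets,
              fibers = matrix(rep(c(1, 0, 0), nrow(tets)), ncol = 3,
                              byrow = TRUE))
  .fix[[key]] <- out
  out
}

ref_baseline <- function() {
  if (is.null(.fix$baseline)) .fix$baseline <- baseline_conductivities()
  .fix$baseline
}

# noise-free synthetic cohort shared by the personalization/acceptance tests
recovery_cohort <- function(n = 20, seed = 7) {
  key <- sprintf("cohort|%d|%d", n, seed)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- generate_cohort(cohort_spec(n = n), seed = seed)
  .fix[[key]]
}

personalize_patient <- function(coh, i, settings = fit_settings()) {
  rec <- coh$records
  personalize_pair(as.list(rec[rec$patient_id == i & rec$timepoint == "pre", ]),
                   as.list(rec[rec$patient_id == i & rec$timepoint == "post", ]),
                   coh$models[[paste0("p", i, "_pre")]],
                   coh$models[[paste0("p", i, "_post")]], settings)
}
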