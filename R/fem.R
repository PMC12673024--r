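# Linear (P1) finite elements on tetrahedra: element volumes, shape-function
# gradients, anisotropic stiffness assembly and lumped mass. Shared by the
# Laplace solves behind the ventricular coordinates and by the monodomain
# diffusion operator.

# volumes (mm^3, signed) and per-vertex gradients of barycentric functions
tet_geometry <- function(nodes, elems) {
  p1 <- nodes[elems[, 1], , drop = FALSE]
  p2 <- nodes[elems[, 2], , drop = FALSE]
  p3 <- nodes[elems[, 3], , drop = FALSE]
  p4 <- nodes[elems[, 4], , drop = FALSE]
  a <- p2 - p1; b <- p3 - p1; c <- p4 - p1
  cx <- cbind(b[, 2] * c[, 3] - b[, 3] * c[, 2],
              b[, 3] * c[, 1] - b[, 1] * c[, 3],
              b[, 1] * c[, 2] - b[, 2] * c[, 1])
  vol6 <- rowSums(a * cx)
  # gradient of barycentric coordinate of vertex i = (opposite face normal)/6V
  crossm <- function(u, v)
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  g2 <- crossm(b, c) / vol6
  g3 <- crossm(c, a) / vol6
  g4 <- crossm(a, b) / vol6
  g1 <- -(g2 + g3 + g4)
  list(volume_mm3 = vol6 / 6, grads = list(g1, g2, g3, g4))
}

# Stiffness matrix K[a,b] = sum_e V_e grad_a' D_e grad_b.
# tensor: NULL (identity), or an n_elem x 6 matrix (xx,yy,zz,xy,xz,yz).
assemble_stiffness <- function(nodes, elems, tensor = NULL, geom = NULL) {
  if (is.null(geom)) geom <- tet_geometry(nodes, elems)
  vol <- abs(geom$volume_mm3)
  g <- geom$grads
  n <- nrow(nodes); m <- nrow(elems)
  apply_tensor <- function(v) {
    if (is.null(tensor)) return(v)
    cbind(tensor[, 1] * v[, 1] + tensor[, 4] * v[, 2] + tensor[, 5] * v[, 3],
          tensor[, 4] * v[, 1] + tensor[, 2] * v[, 2] + tensor[, 6] * v[, 3],
          tensor[, 5] * v[, 1] + tensor[, 6] * v[, 2] + tensor[, 3] * v[, 3])
  }
  ii <- integer(16L * m); jj <- integer(16L * m); xx <- numeric(16L * m)
  k <- 0L
  for (a in 1:4) {
    dg <- apply_tensor(g[[a]])
    for (b in 1:4) {
      val <- vol * rowSums(dg * g[[b]])
      idx <- k + seq_len(m)
      ii[idx] <- elems[, a]; jj[idx] <- elems[, b]; xx[idx] <- val
      k <- k + m
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

# lumped mass vector (mm^3)
lumped_mass <- function(nodes, elems, geom = NULL) {
  if (is.null(geom)) geom <- tet_geometry(nodes, elems)
  vol <- abs(geom$volume_mm3)
  mass <- numeric(nrow(nodes))
  for (a in 1:4) {
    acc <- tapply(vol / 4, elems[, a], sum)
    idx <- as.integer(names(acc))
    mass[idx] <- mass[idx] + as.numeric(acc)
  }
  mass
}

# Solve K u = 0 with Dirichlet values; returns full nodal vector.
solve_laplace <- function(K, dirichlet_idx, dirichlet_val) {
  n <- nrow(K)
  stopifnot(length(dirichlet_idx) == length(dirichlet_val),
            length(dirichlet_idx) > 0)
  fixed <- logical(n); fixed[dirichlet_idx] <- TRUE
  u <- numeric(n); u[dirichlet_idx] <- dirichlet_val
  free <- which(!fixed)
  if (!length(free)) return(u)
  rhs <- -K[free, dirichlet_idx, drop = FALSE] %*% dirichlet_val
  u[free] <- as.numeric(Matrix::solve(K[free, free], rhs))
  u
}

# per-element gradient of a nodal field (n_elem x 3, units field/mm)
field_gradient <- function(field, elems, geom) {
  g <- geom$grads
  out <- matrix(0, nrow(elems), 3)
  for (a in 1:4) out <- out + field[elems[, a]] * g[[a]]
  out
}
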