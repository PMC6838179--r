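# Shared fixtures and independent oracles.

# small hand-built dataset on a 100-residue protein
toy_dataset <- function(z = c(0.1, 0.4, 0.8, 0.3, 0.6),
                        positions = c(10, 30, 50, 70, 90),
                        y = c(0.2, 0.5, 0.9, 0.4, 0.7)) {
  variant_dataset(
    tibble::tibble(label = paste0("t", seq_along(z)),
                   position = positions, y = y, z = z),
    protein_length = 100)
}

# Independent ordinary-Kriging oracle in the semivariogram formulation:
# [G 1; 1' 0] [l; m] = [g_u; 1], z* = l'z, s2 = l'g_u + m, solved through a
# full matrix inverse. Different linear system and code path from the
# package's covariance-form solver.
dense_ok_oracle <- function(u, x, y, z, model) {
  k <- length(x)
  G <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) {
        hij <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
        G[i, j] <- model_gamma(model, hij)
      }
    }
  }
  gu <- vapply(seq_len(k), function(i) {
    model_gamma(model, sqrt((x[i] - u[1])^2 + (y[i] - u[2])^2))
  }, 0)
  A <- rbind(cbind(G, 1), c(rep(1, k), 0))
  sol <- solve(A) %*% c(gu, 1)
  l <- sol[seq_len(k)]; m <- sol[k + 1]
  list(weights = l, z_hat = sum(l * z), sigma2 = sum(l * gu) + m)
}

# minimal valid 3-residue PDB (one CA atom per residue), written to a file
write_toy_pdb <- function(path, residues = 1:3) {
  lines <- c(
    "HEADER    TOY PROTEIN",
    sprintf(
      "ATOM  %5d  CA  ALA A%4d      %8.3f%8.3f%8.3f  1.00 20.00           C",
      seq_along(residues), residues,
      seq_along(residues) * 1.5, 0, 0),
    "TER",
    "END")
  writeLines(lines, path)
  path
}

# hand-constructed landscape object with explicit grid attributes
# (column-major: y varies fastest, matching tidyr::expand_grid(x, y))
manual_landscape <- function(gx, gy, z_hat, sigma2) {
  grid <- tidyr::expand_grid(x = gx, y = gy)
  grid$z_hat <- z_hat
  grid$sigma2 <- sigma2
  structure(grid, grid_x = gx, grid_y = gy,
            class = c("phenotype_landscape", class(grid)))
}
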