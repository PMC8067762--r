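## Reference single-branch relaxation models for the NF-L sidearm at the two
## nominal pulling rates (moduli GPa, relaxation times ps). Used throughout
## as ground truth for generation/recovery round trips.
model_rate1e8 <- function() prony_model(0.103, 0.827, 87.866)
model_rate1e9 <- function() prony_model(0, 2, 100)

## atm -> GPa conversion used by the extraction stage.
ATM_GPA <- 1.01325e-4

## A cubic frame with atoms at the centers of a simple-cubic sublattice:
## every Voronoi cell is an identical cube.
sc_lattice_frame <- function(edge = 20, stress_pv = NULL) {
  g <- as.matrix(expand.grid(c(edge / 4, 3 * edge / 4),
                             c(edge / 4, 3 * edge / 4),
                             c(edge / 4, 3 * edge / 4)))
  if (is.null(stress_pv)) stress_pv <- matrix(0, 8, 6)
  atom_frame(0L, cbind(rep(0, 3), rep(edge, 3)), 1:8, g, stress_pv)
}

## Random frame with uniform positions and standard-normal stress*volume.
random_frame <- function(n = 10, edge = 15, seed = 1, timestep = 0L) {
  set.seed(seed)
  atom_frame(timestep, cbind(rep(0, 3), rep(edge, 3)), seq_len(n),
             matrix(runif(3 * n, 0, edge), ncol = 3),
             matrix(rnorm(6 * n), ncol = 6))
}

## Frames whose pulled group translates linearly along x by `step` per frame.
ramp_frames <- function(n_frames, step, n_atoms = 4, edge = 50) {
  X0 <- matrix(runif(3 * n_atoms, 5, 15), ncol = 3)
  lapply(seq_len(n_frames) - 1L, function(k) {
    X <- X0
    X[, 1] <- X[, 1] + k * step
    atom_frame(k, cbind(rep(0, 3), rep(edge, 3)), seq_len(n_atoms), X,
               matrix(0, n_atoms, 6))
  })
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <=
                    tol * pmax(abs(expected), .Machine$double.eps)),
              label = sprintf("max rel err %.3g vs tol %.3g",
                              max(abs(actual - expected) /
                                    pmax(abs(expected), .Machine$double.eps)),
                              tol))
}
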