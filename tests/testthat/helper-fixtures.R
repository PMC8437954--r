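# Shared helpers for building small in-code fixtures.

# A random proper rigid transform (rotation angle in (0, 180), translation
# up to ~20 A), reproducible from the current RNG state.
randomRigidTransform <- function() {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 1, 179)
  th <- ang * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  RigidTransform(R, rnorm(3, sd = 10))
}

# Ten CA atoms on a line-free 3D scatter written as a PDB fixture file.
writeTinyPdb <- function(path, n = 10, seed = 42) {
  set.seed(seed)
  st <- AtomicStructure(data.frame(
    chain = "A", resno = seq_len(n), insert = "", resid = "ALA",
    elety = "CA", elesy = "C",
    x = round(rnorm(n, sd = 8), 3), y = round(rnorm(n, sd = 8), 3),
    z = round(rnorm(n, sd = 8), 3)))
  writeStructure(st, path)
  st
}
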