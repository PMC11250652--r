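# Seeded fixtures built in code; no stored data.

rand_tensor <- function(shape, seed = 1) {
  set.seed(seed)
  array(rnorm(prod(shape)), shape)
}

rand_matrix <- function(nr, nc, seed = 1) {
  set.seed(seed)
  matrix(rnorm(nr * nc), nr, nc)
}

# random matrix with orthonormal columns (deterministic given seed)
rand_orthonormal <- function(nr, nc, seed = 1) {
  orthonormalize_qr(rand_matrix(nr, nc, seed))
}

# small solver problem used across solver tests
small_problem <- function(shape = c(12, 10, 8), rank = c(2, 2, 2),
                          mr = 0.3, seed = 42) {
  truth <- random_tucker_tensor(shape, rank, seed = seed)
  mask <- sample_mask(shape, mr, seed = seed + 1)
  list(truth = truth, mask = mask,
       config = solver_config(rank = rank, seed = seed))
}
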