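test_that("gradient: flat field, linear ramp, and loop oracle", {
  expect_equal(gradient4d(array(3, c(3, 3, 3, 4))),
               structure(matrix(0, 108, 4), grid = c(3L, 3L, 3L, 4L)),
               ignore_attr = TRUE)
  ramp <- array(slice.index(array(0, c(5, 4, 3, 2)), 1), c(5, 4, 3, 2))
  g <- gradient4d(ramp)
  gx <- array(g[, 1], c(5, 4, 3, 2))
  expect_true(all(gx[1:4, , , ] == 1))
  expect_true(all(gx[5, , , ] == 0))
  expect_true(all(g[, 2:4] == 0))

  a <- small_image(c(4, 4, 4, 5), seed = 3)
  sp <- c(1, 2, 0.5, 1.5)
  g2 <- gradient4d(a, sp)
  oracle <- gradient_loop(a, sp)
  expect_equal(array(g2, c(4, 4, 4, 5, 4)), oracle, tolerance = 1e-14)
})

test_that("divergence: zero flux, Laplacian identity, adjointness", {
  z <- structure(matrix(0, 60, 4), grid = c(3L, 4L, 5L, 1L))
  expect_equal(divergence4d(z), array(0, c(3, 4, 5, 1)))

  # div(grad(I)) equals the 4D Neumann Laplacian stencil, exactly on integers
  set.seed(11)
  ai <- array(sample(-5:5, 4 * 3 * 3 * 4, replace = TRUE), c(4, 3, 3, 4))
  expect_identical(divergence4d(gradient4d(ai)), laplacian_stencil(ai))
  af <- small_image(c(4, 4, 3, 5), seed = 12)
  expect_equal(divergence4d(gradient4d(af)), laplacian_stencil(af),
               tolerance = 1e-12)

  # -div is the numerical adjoint of grad
  set.seed(13)
  for (i in 1:50) {
    I <- array(rnorm(120), c(2, 3, 4, 5))
    P <- matrix(rnorm(480), 120, 4)
    attr(P, "grid") <- c(2L, 3L, 4L, 5L)
    lhs <- sum(gradient4d(I) * P)
    rhs <- -sum(I * divergence4d(P))
    expect_equal(lhs, rhs, tolerance = 1e-10 * max(1, abs(lhs)))
  }
  expect_error(divergence4d(matrix(0, 10, 4)), "grid")
})

test_that("structure tensor matches the outer-product definition", {
  # single voxel with gradient (2,0,0,0), no guard, no smoothing:
  # outer product 4 divided by norm 2 gives diag(2,0,0,0)
  g <- matrix(0, 27, 4)
  g[14, 1] <- 2
  attr(g, "grid") <- c(3L, 3L, 3L, 1L)
  st <- structure_tensor(g, sigma_g = 0, epsilon = 0)
  expect_equal(unpack10(unclass(st)[14, ]), diag(c(2, 0, 0, 0)))
  expect_true(all(unclass(st)[-14, ] == 0))

  # zero gradient everywhere gives a zero tensor
  g0 <- structure(matrix(0, 27, 4), grid = c(3L, 3L, 3L, 1L))
  expect_true(all(unclass(structure_tensor(g0, sigma_g = 1)) == 0))

  # sigma_g = 0 path is the limit of vanishing smoothing
  set.seed(5)
  a <- small_image(c(4, 4, 4, 4), seed = 5)
  g1 <- gradient4d(a)
  st0 <- structure_tensor(g1, sigma_g = 0)
  st_eps <- structure_tensor(g1, sigma_g = 1e-4)
  expect_equal(unclass(st0), unclass(st_eps), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(structure_tensor(g1, sigma_g = -1), ">= 0")
})

test_that("unsmoothed tensor is equivariant under axis permutation", {
  a <- small_image(c(3, 4, 5, 6), seed = 21)
  perm <- c(2L, 3L, 4L, 1L)
  ap <- aperm(a, perm)
  full_tensor <- function(img) {
    comp <- unclass(structure_tensor(gradient4d(img), sigma_g = 0))
    array(apply(comp, 1, unpack10), c(4, 4, prod(dim(img))))
  }
  Torig <- full_tensor(a)
  Tperm <- full_tensor(ap)
  # voxel v of the permuted image is voxel map[v] of the original
  vmap <- as.numeric(aperm(array(seq_len(prod(dim(a))), dim(a)), perm))
  for (v in c(1, 17, 100, 300)) {
    expect_equal(Tperm[, , v], Torig[perm, perm, vmap[v]], tolerance = 1e-12)
  }
})

test_that("eigendecomposition: diagonal, identity, reconstruction oracle", {
  grid <- c(1L, 1L, 1L, 1L)
  fld <- uniform_field(diag(c(1, 3, 2, 0)), grid)
  e <- tensor_eigen(fld)
  expect_equal(as.numeric(e$values), c(3, 2, 1, 0))
  Q <- matrix(e$vectors[1, ], 4, 4)
  expect_equal(abs(Q), diag(4)[, c(2, 3, 1, 4)], tolerance = 1e-12)

  e_id <- tensor_eigen(uniform_field(diag(4), grid))
  expect_equal(as.numeric(e_id$values), rep(1, 4))
  Qi <- matrix(e_id$vectors[1, ], 4, 4)
  expect_equal(crossprod(Qi), diag(4), tolerance = 1e-12)

  set.seed(31)
  mats <- replicate(100, random_psd4(), simplify = FALSE)
  comp <- structure(t(vapply(mats, pack10, numeric(10))),
                    grid = c(100L, 1L, 1L, 1L), class = "tensor_field4d")
  e2 <- tensor_eigen(comp)
  for (v in seq_len(100)) {
    Q <- matrix(e2$vectors[v, ], 4, 4)
    rec <- Q %*% diag(e2$values[v, ]) %*% t(Q)
    expect_lt(norm(rec - mats[[v]], "F"), 1e-10)
    expect_lt(norm(crossprod(Q) - diag(4), "F"), 1e-8)
    expect_true(all(diff(e2$values[v, ]) <= 0))
  }
  # genuinely indefinite tensors are rejected
  bad <- uniform_field(diag(c(1, 1, 1, -1)), grid)
  expect_error(tensor_eigen(bad), "corrupted")
})

test_that("eigenvalue remap follows the exponential law", {
  grid <- c(3L, 1L, 1L, 1L)
  comp <- structure(rbind(pack10(diag(c(4, 0.5, 0.2, 0))),
                          pack10(diag(c(2, 1, 0.5, 0.1))),
                          pack10(matrix(0, 4, 4))),
                    grid = grid, class = "tensor_field4d")
  e <- tensor_eigen(comp)
  rm <- remap_eigenvalues(e, sigma_d = 0.2)
  # ratio 1 at sigma_d = 0.2 gives exp(-12.5)
  expect_equal(rm[1, 1], exp(-12.5))
  expect_equal(rm[2, 1], exp(-(2 / 4)^2 / (2 * 0.04)))
  # zero leading eigenvalue is fully isotropic
  expect_equal(rm[3, 1], 1)
  # the other eigenvalues are 1 for every voxel
  expect_true(all(rm[, 2:4] == 1))
  expect_true(all(rm > 0 & rm <= 1))

  # strictly decreasing in the ratio lambda1 / global_max
  lam <- seq(0, 1, by = 0.05)
  vals <- exp(-lam^2 / (2 * 0.2^2))
  expect_true(all(diff(vals) < 0))
  e_zero <- tensor_eigen(uniform_field(matrix(0, 4, 4), c(1L, 1L, 1L, 1L)))
  expect_equal(remap_eigenvalues(e_zero, sigma_d = 0.2)[1, 1], 1)
  expect_error(remap_eigenvalues(e, global_max = 1, sigma_d = 0.2),
               "dominate")
})

test_that("rebuilt steering tensor is SPD with the remapped spectrum", {
  grid <- c(1L, 1L, 1L, 1L)
  # isotropic limit: all remapped eigenvalues 1 gives the identity tensor
  e <- tensor_eigen(uniform_field(random_psd4(), grid))
  id <- rebuild_tensor(e, matrix(1, 1, 4))
  expect_equal(unpack10(unclass(id)[1, ]), diag(4), tolerance = 1e-12)

  # axis-aligned case: diag(exp(-12.5), 1, 1, 1)
  e_ax <- tensor_eigen(uniform_field(diag(c(5, 0.3, 0.2, 0.1)), grid))
  reb <- rebuild_tensor(e_ax, matrix(c(exp(-12.5), 1, 1, 1), 1))
  expect_equal(unpack10(unclass(reb)[1, ]), diag(c(exp(-12.5), 1, 1, 1)),
               tolerance = 1e-12)

  # spectral round trip over random fields
  set.seed(41)
  mats <- replicate(50, random_psd4(), simplify = FALSE)
  comp <- structure(t(vapply(mats, pack10, numeric(10))),
                    grid = c(50L, 1L, 1L, 1L), class = "tensor_field4d")
  eigs <- tensor_eigen(comp)
  rm <- remap_eigenvalues(eigs, sigma_d = 0.2)
  reb2 <- rebuild_tensor(eigs, rm)
  e_back <- tensor_eigen(reb2)
  for (v in seq_len(50)) {
    expect_equal(e_back$values[v, ], sort(rm[v, ], decreasing = TRUE),
                 tolerance = 1e-8)
    tr <- sum(unclass(reb2)[v, c(1, 5, 8, 10)])
    expect_gt(tr, 3)
    expect_lte(tr, 4 + 1e-12)
  }
})

test_that("steering_tensor pipeline produces unit-trace-bounded SPD tensors", {
  a <- small_image(c(5, 5, 5, 6), seed = 51)
  st <- steering_tensor(a)
  e <- tensor_eigen(st$field)
  expect_true(all(e$values > 0))
  expect_true(all(e$values <= 1 + 1e-10))
  expect_gt(st$lambda1_max, 0)
  expect_true(all(st$lambda1_new > 0 & st$lambda1_new <= 1))
})
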