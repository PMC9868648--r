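test_that("a constant connected grid has one essential component and nothing else", {
  d <- cubical_persistence(array(5, c(3, 3, 3)))
  expect_equal(nrow(d), 1L)
  expect_equal(d$dimension, 0L)
  expect_equal(d$birth, 5)
  expect_equal(d$death, Inf)
})

test_that("two basins merging into a plateau give the expected dim-0 pairs", {
  g <- array(5, c(5, 1, 1)); g[1] <- 1; g[5] <- 2
  d <- cubical_persistence(g)
  expect_same_diagrams(d, tibble::tibble(dimension = c(0L, 0L),
                                         birth = c(1, 2), death = c(Inf, 5)))
})

test_that("a hollow voxel shell yields exactly one dim-2 pair (shell, cavity fill)", {
  g <- array(Inf, c(5, 5, 5))
  g[2:4, 2:4, 2:4] <- 1   # shell at low value
  g[3, 3, 3] <- 10        # cavity interior filled at high value
  d <- cubical_persistence(g)
  d2 <- d[d$dimension == 2, ]
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$birth, 1)
  expect_equal(d2$death, 10)
  # and the binary mask's beta_2 from the independent labeler agrees
  m <- array(0L, c(5, 5, 5)); m[2:4, 2:4, 2:4] <- 1L; m[3, 3, 3] <- 0L
  expect_equal(unname(betti_numbers(m)["b2"]), 1L)
})

test_that("the unit square's Rips diagram is exact", {
  sq <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 1, 1, 0), ncol = 3, byrow = TRUE)
  d <- rips_persistence(sq, threshold = 2)
  expect_same_diagrams(d, tibble::tibble(
    dimension = c(0L, 0L, 0L, 0L, 1L),
    birth = c(0, 0, 0, 0, 1),
    death = c(1, 1, 1, Inf, sqrt(2))))
})

test_that("a regular 12-gon's loop is born at the side length", {
  th <- 2 * pi * (0:11) / 12
  d <- rips_persistence(cbind(cos(th), sin(th), 0))
  d1 <- d[d$dimension == 1, ]
  expect_equal(nrow(d1), 1L)
  expect_equal(d1$birth, 2 * sin(pi / 12), tolerance = 1e-12)
})

test_that("Rips dim-0 classes are born at 0 with one essential class at full threshold", {
  withr::with_seed(9, {
    for (i in 1:5) {
      pts <- random_small_cloud(7)
      d <- rips_persistence(pts, threshold = max(stats::dist(pts)) + 0.1)
      d0 <- d[d$dimension == 0, ]
      expect_true(all(d0$birth == 0))
      expect_equal(sum(is.infinite(d0$death)), 1L)
    }
  })
})

test_that("optimized cubical diagrams equal the naive reduction on random small grids", {
  withr::with_seed(31, {
    for (i in 1:25) {
      g <- random_small_grid(4)
      expect_same_diagrams(cubical_persistence(g), naive_cubical_persistence(g))
    }
  })
})

test_that("optimized Rips diagrams equal the naive reduction on small clouds", {
  withr::with_seed(32, {
    for (i in 1:10) {
      pts <- random_small_cloud()
      expect_same_diagrams(rips_persistence(pts),
                           naive_rips_persistence(pts))
    }
  })
})

test_that("pairs alive at a threshold reproduce the Betti numbers of the binary complex", {
  withr::with_seed(33, {
    for (i in 1:10) {
      # random blobby mask built from union of small balls, valued 0/Inf
      m <- array(FALSE, c(6, 6, 6))
      for (b in 1:3) {
        c0 <- runif(3, 2, 5); r0 <- runif(1, 1, 2.2)
        idx <- which(!m)
        co <- which(array(TRUE, dim(m)), arr.ind = TRUE)
        d2 <- (co[, 1] - c0[1])^2 + (co[, 2] - c0[2])^2 + (co[, 3] - c0[3])^2
        m <- m | array(d2 <= r0^2, dim(m))
      }
      if (!any(m)) next
      g <- ifelse(m, 0, Inf)
      d <- cubical_persistence(g)
      alive <- function(k) sum(d$dimension == k & d$birth <= 0 & d$death > 0)
      expect_equal(c(alive(0), alive(1), alive(2)),
                   as.integer(betti_numbers(m)))
    }
  })
})

test_that("small perturbations move matched pairs by at most the perturbation", {
  # values on a coarse 0.5 lattice: surviving pairs have persistence >= 0.5,
  # while tie-broken pairs of the perturbed grid stay within 2*eps of the
  # diagonal. After dropping near-diagonal pairs on both sides the sorted
  # per-dimension matching is the optimal (bottleneck) one.
  withr::with_seed(34, {
    for (i in 1:8) {
      g <- array(sample(seq(0, 3, by = 0.5), 4 * 4 * 3, replace = TRUE),
                 c(4, 4, 3))
      eps <- 0.005
      g2 <- g + array(runif(length(g), -eps, eps), dim(g))
      a <- cubical_persistence(g)
      b <- cubical_persistence(g2)
      drop_diag <- function(d) d[d$death - d$birth > 0.25, , drop = FALSE]
      a <- drop_diag(a); b <- drop_diag(b)
      for (k in 0:2) {
        ak <- a[a$dimension == k, ]; bk <- b[b$dimension == k, ]
        expect_equal(nrow(ak), nrow(bk))
        if (nrow(ak) && nrow(ak) == nrow(bk)) {
          expect_true(all(abs(sort(ak$birth) - sort(bk$birth)) <= eps + 1e-12))
          fa <- sort(ak$death[is.finite(ak$death)])
          fb <- sort(bk$death[is.finite(bk$death)])
          expect_true(all(abs(fa - fb) <= eps + 1e-12))
        }
      }
    }
  })
})

test_that("reduce_boundary_matrix pairs the filtered triangle by hand", {
  expect_equal(reduce_boundary_matrix(list())$pairs,
               tibble::tibble(birth = integer(0), death = integer(0)))
  # cells in filtration order: v1 v2 v3, e12 e13 e23, t123
  cols <- list(integer(0), integer(0), integer(0),
               c(1L, 2L), c(1L, 3L), c(2L, 3L), c(4L, 5L, 6L))
  red <- reduce_boundary_matrix(cols)
  expect_equal(red$pairs, tibble::tibble(birth = c(2L, 3L, 6L),
                                         death = c(4L, 5L, 7L)))
  expect_equal(red$essential, 1L)
  expect_error(reduce_boundary_matrix(list(c(2L), integer(0))), "non-nested")
})

test_that("farthest-point subsampling is deterministic and honored", {
  withr::with_seed(5, {
    pts <- matrix(runif(300), ncol = 3)
  })
  d1 <- rips_persistence(pts, max_points = 20, seed = 3)
  d2 <- rips_persistence(pts, max_points = 20, seed = 3)
  expect_identical(tibble::as_tibble(d1), tibble::as_tibble(d2))
  expect_equal(attr(d1, "n_points"), 20L)
})

test_that("degenerate grids and clouds are rejected", {
  expect_error(cubical_persistence(array(Inf, c(2, 2, 2))), "finite")
  expect_error(rips_persistence(matrix(runif(9), 3, 3)), "4 distinct")
  sq <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 1, 1, 0), ncol = 3, byrow = TRUE)
  expect_error(rips_persistence(sq, threshold = 0), "positive")
})
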