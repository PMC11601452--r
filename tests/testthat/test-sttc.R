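# STTC, matrix clustering with optimal leaf ordering, eigen gradients.

test_that("STTC matches closed-form cases and symmetry", {
  expect_equal(sttc(c(1, 2, 3), c(1, 2, 3), dt_ms = 20, duration = 10), 1.0)
  # single distant spikes: T = 0.002, P = 0 -> -0.002
  expect_equal(as.numeric(sttc(1.0, 10.0, dt_ms = 20, duration = 20)), -0.002)
  z <- sttc(numeric(), c(1), dt_ms = 20, duration = 10)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "empty"))

  set.seed(17)
  for (k in 1:10) {
    a <- poisson_train(3, 20)
    b <- poisson_train(3, 20)
    expect_equal(sttc(a, b, 15, 20), sttc(b, a, 15, 20))
    # joint time translation leaves the coefficient unchanged
    expect_equal(sttc(a + 2, b + 2, 15, 30), sttc(a, b, 15, 30) ,
                 tolerance = 0.02)
  }
})

test_that("STTC equals the brute-force window-merge oracle", {
  set.seed(23)
  for (k in 1:100) {
    dur <- runif(1, 5, 30)
    a <- poisson_train(runif(1, 0.5, 8), dur)
    b <- poisson_train(runif(1, 0.5, 8), dur)
    if (length(a) == 0 || length(b) == 0) next
    dt <- sample(c(5, 10, 20, 50), 1) / 1000
    expect_lt(abs(as.numeric(sttc(a, b, dt * 1000, dur)) -
                    brute_sttc(a, b, dt, dur)), 1e-12)
  }
})

test_that("independent Poisson trains give near-zero STTC", {
  set.seed(29)
  vals <- replicate(100, {
    sttc(poisson_train(5, 100), poisson_train(5, 100), 20, 100)
  })
  expect_gte(mean(abs(vals) < 0.05), 0.95)
})

test_that("hierarchical clustering recovers planted blocks with optimal leaves", {
  n <- 12
  m <- matrix(0, n, n)
  m[1:6, 1:6] <- 0.25
  m[7:12, 7:12] <- 0.25
  diag(m) <- 1
  dimnames(m) <- list(paste0("u", 1:n), paste0("u", 1:n))
  sm <- structure(list(values = m, dt_ms = 20, duration = 100),
                  class = "sttc_matrix")
  cl <- hierarchical_clusters(sm, k = 2)
  expect_equal(group_agreement(cl$cluster, rep(1:2, each = 6)), 1)
  # optimal leaf order keeps blocks contiguous
  ord <- match(attr(cl, "leaf_order"), rownames(m))
  expect_true(all(diff(sort(which(ord <= 6))) == 1))

  # all-equal off-diagonal: flagged degenerate
  m2 <- matrix(0.1, n, n)
  diag(m2) <- 1
  dimnames(m2) <- dimnames(m)
  sm2 <- structure(list(values = m2, dt_ms = 20, duration = 100),
                   class = "sttc_matrix")
  expect_warning(cl2 <- hierarchical_clusters(sm2, k = 2), "arbitrary")
  expect_true(attr(cl2, "degenerate"))
  expect_error(hierarchical_clusters(sm, k = 20), "clusters")
})

test_that("the leaf-ordering dynamic program is exactly optimal (brute force)", {
  set.seed(37)
  for (rep in 1:4) {
    nl <- 8
    d <- dist(matrix(rnorm(nl * 3), nl))
    hc <- hclust(d, "average")
    ord <- meacircuit:::optimal_leaf_order(hc, d)
    dm <- as.matrix(d)
    cost <- function(o) sum(dm[cbind(o[-nl], o[-1])])
    all_orders <- function(node) {
      if (node < 0) return(list(-node))
      L <- all_orders(hc$merge[node, 1])
      R <- all_orders(hc$merge[node, 2])
      out <- list()
      for (l in L) for (r in R) {
        out[[length(out) + 1]] <- c(l, r)
        out[[length(out) + 1]] <- c(r, l)
      }
      out
    }
    best <- min(vapply(all_orders(nrow(hc$merge)), cost, numeric(1)))
    expect_setequal(ord, 1:nl)
    expect_equal(cost(ord), best)
  }
})

test_that("eigendecomposition flags degeneracy and separates planted blocks", {
  eye <- diag(6)
  dimnames(eye) <- list(paste0("u", 1:6), paste0("u", 1:6))
  eg <- eigen_gradient(eye)
  expect_true(attr(eg, "degenerate"))
  expect_equal(eg$eigenvalues, rep(1, 6))

  m <- matrix(0.05, 6, 6)
  m[1:3, 1:3] <- 0.3
  m[4:6, 4:6] <- 0.3
  diag(m) <- 1
  dimnames(m) <- list(paste0("u", 1:6), paste0("u", 1:6))
  eg2 <- eigen_gradient(m)
  expect_false(attr(eg2, "degenerate"))
  # direct eigensolve oracle: block-separating vector sign pattern
  ev <- eigen(m, symmetric = TRUE)$vectors[, 2]
  expect_true(all(sign(ev[1:3]) == sign(ev[1])) &&
                all(sign(ev[4:6]) == -sign(ev[1])))
  expect_true(all(sign(eg2$scores$ev2[1:3]) != sign(eg2$scores$ev2[4:6])))
  # sign fix: largest-magnitude entry positive
  expect_gt(eg2$scores$ev2[which.max(abs(eg2$scores$ev2))], 0)

  # rank-k reconstruction error decreases with rank
  e <- eigen(m, symmetric = TRUE)
  errs <- vapply(1:4, function(k) {
    rec <- e$vectors[, 1:k, drop = FALSE] %*%
      diag(e$values[1:k], k) %*% t(e$vectors[, 1:k, drop = FALSE])
    norm(m - rec, "F")
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))

  expect_error(eigen_gradient(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("bipolar recordings cluster into the planted groups", {
  gen <- bipolar_fixture()
  m <- sttc_matrix(gen$spikes)
  expect_true(isSymmetric(m$values))
  expect_true(all(diag(m$values) == 1))
  expect_true(all(m$values >= -1 & m$values <= 1))
  cl <- hierarchical_clusters(m)
  grp <- ifelse(gen$truth$units$group == "A", 1L, 2L)
  expect_gte(group_agreement(cl$cluster, grp), 0.9)
  eg <- eigen_gradient(m)
  cor2 <- max(abs(cor(eg$scores$ev1, gen$truth$units$arc_pos)),
              abs(cor(eg$scores$ev2, gen$truth$units$arc_pos)))
  expect_gt(cor2, 0.8)
})
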