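# relationship matrices, mixed-model equations, REML, weight projection

test_that("A matrix matches hand-derived values", {
  trio <- data.frame(animal = c("S", "D", "O"), sire = c("0", "0", "S"),
                     dam = c("0", "0", "D"))
  A <- build_A(trio)
  expect_equal(A["S", "O"], 0.5)
  expect_equal(A["O", "O"], 1.0)

  sibs <- data.frame(animal = c("S", "D", "O1", "O2"),
                     sire = c("0", "0", "S", "S"),
                     dam = c("0", "0", "D", "D"))
  expect_equal(build_A(sibs)["O1", "O2"], 0.5)

  # offspring of half-sib parents (parents a = 0.25): diagonal 1.125
  hs <- data.frame(animal = c("F", "D1", "D2", "H1", "H2", "C"),
                   sire = c("0", "0", "0", "F", "F", "H1"),
                   dam = c("0", "0", "0", "D1", "D2", "H2"))
  A3 <- build_A(hs)
  expect_equal(A3["H1", "H2"], 0.25)
  expect_equal(A3["C", "C"], 1.125)
})

test_that("A equals the coancestry-recursion oracle on random pedigrees", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 40
    sire <- dam <- rep("0", n)
    for (i in 11:n) {
      sire[i] <- as.character(sample(i - 1, 1))
      dam[i] <- as.character(sample(i - 1, 1))
      if (dam[i] == sire[i]) dam[i] <- "0"
    }
    ped <- data.frame(animal = as.character(1:n), sire = sire, dam = dam)
    expect_lt(max(abs(build_A(ped) - lpeval:::.kinship_A(ped))), 1e-12)
  }
})

test_that("pedigree order is recovered and cycles are named", {
  shuffled <- data.frame(animal = c("O", "S", "D"), sire = c("S", "0", "0"),
                         dam = c("D", "0", "0"))
  A <- build_A(shuffled)
  expect_equal(A["S", "O"], 0.5)
  cyc <- data.frame(animal = c("X", "Y"), sire = c("Y", "X"),
                    dam = c("0", "0"))
  expect_error(build_A(cyc), "cycle.*X.*Y")
})

test_that("G matches the hand cross-product and VanRaden expectation", {
  G <- build_G(matrix(c(0, 1, 2), 3, 1), freqs = 0.5)
  expect_equal(diag(G), c(2, 0, 2))
  expect_equal(G[1, 3], -2)

  Gid <- build_G(rbind(c(0, 1, 2, 1), c(0, 1, 2, 1)))
  expect_true(max(Gid) - min(Gid) < 1e-12)   # identical animals: constant G

  set.seed(10)
  p <- runif(5000, 0.1, 0.9)
  Mh <- matrix(rbinom(200 * 5000, 2, rep(p, each = 200)), 200, 5000)
  Gh <- build_G(Mh, freqs = p)
  expect_gt(mean(diag(Gh)), 0.9); expect_lt(mean(diag(Gh)), 1.1)

  expect_error(build_G(matrix(2, 4, 3)), "monomorphic")
})

test_that("G handles missingness by 2p imputation with a 5% cap", {
  set.seed(11)
  M <- matrix(rbinom(40 * 100, 2, 0.4), 40, 100)
  M[1, 2] <- NA
  expect_message(G <- build_G(M), "imputed 1 missing")
  expect_true(isSymmetric(G))
  M[2, 1:10] <- NA
  expect_error(build_G(M), "missing more than 5%")
})

test_that("stabilize_G is the exact 0.99/0.01 blend and fixes singularity", {
  expect_equal(stabilize_G(diag(3)), diag(3), ignore_attr = TRUE)
  G <- matrix(2, 2, 2)          # singular (duplicate animals)
  Gs <- stabilize_G(G)
  expect_gt(min(eigen(Gs, symmetric = TRUE)$values), 1e-6)
  expect_equal(Gs[1, 1], 0.99 * 2 + 0.01)
  expect_equal(stabilize_G(diag(c(2, 2)))[1, 1], 1.99)
})

test_that("fit_blup solves the 2-animal example and the GLS oracle", {
  f <- fit_blup(c(10, 12), matrix(1, 2, 1), diag(2), diag(2), 1, 1)
  expect_equal(unname(f$beta), 11)
  expect_equal(unname(f$u), c(-0.5, 0.5))

  set.seed(14)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    K <- crossprod(matrix(rnorm(n * n), n)) / n + 0.3 * diag(n)
    X <- cbind(1, rnorm(n))
    y <- rnorm(n, 2)
    sg <- runif(1, 0.5, 2); se <- runif(1, 0.5, 2)
    fb <- fit_blup(y, X, diag(n), K, sg, se)
    V <- sg * K + se * diag(n)
    Vi <- solve(V)
    bg <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    ug <- drop(sg * K %*% Vi %*% (y - X %*% bg))
    expect_lt(max(abs(fb$beta - bg)), 1e-8)
    expect_lt(max(abs(fb$u - ug)), 1e-8)
  }

  # shrinkage limit: sigma_g2 -> 0 sends u to 0
  fz <- fit_blup(c(10, 12), matrix(1, 2, 1), diag(2), diag(2), 1e-9, 1)
  expect_lt(max(abs(fz$u)), 1e-6)

  # singular K advice
  expect_error(fit_blup(c(1, 2), matrix(1, 2, 1), diag(2),
                        matrix(1, 2, 2), 1, 1), "stabilize_G")
})

test_that("animals without records are predicted through relationships", {
  ped <- data.frame(animal = c("S", "D", "O", "U"),
                    sire = c("0", "0", "S", "0"),
                    dam = c("0", "0", "D", "0"))
  A <- build_A(ped)
  # records only on O (high) and the unrelated founder U (low)
  Z <- matrix(c(0, 0, 1, 0,
                0, 0, 0, 1), 2, 4, byrow = TRUE)
  f <- fit_blup(c(5, -5), matrix(1, 2, 1), Z, A, 1, 1)
  expect_gt(f$u["S"], 0)                     # parent of O pulled up
  expect_equal(unname(f$u["S"]), unname(f$u["D"]))
  expect_lt(abs(f$u["S"]), abs(f$u["O"]))
})

test_that("REML recovers a null and tracks a monotone likelihood", {
  set.seed(19)
  n <- 500
  y <- rnorm(n)
  K <- crossprod(matrix(rnorm(n * n), n)) / n
  vc <- reml(y, matrix(1, n, 1), diag(n), K)
  expect_lt(vc$h2, 0.1)
  expect_true(all(diff(vc$loglik) >= -1e-8))
  expect_true(vc$converged)
})

test_that("postweaning gain projection is exact on polynomials", {
  ages <- c(200, 260, 320, 380, 440)
  expect_equal(project_pwg(ages, 100 + 1.0 * ages, wean_age = 205), 1.0)
  a <- 50; b <- 0.8; cc <- 0.001
  w <- a + b * ages + cc * ages^2
  expect_equal(project_pwg(ages, w, wean_age = 205),
               b + cc * (2 * 205 + 160), tolerance = 1e-10)
  # noise: stays within 3 SE-equivalents of the noiseless value
  set.seed(3)
  ages10 <- seq(210, 520, length.out = 10)
  w10 <- a + b * ages10 + cc * ages10^2
  adgs <- replicate(50, project_pwg(ages10, w10 + rnorm(10, 0, 2), 205))
  true_adg <- b + cc * (2 * 205 + 160)
  expect_lt(abs(mean(adgs) - true_adg), 3 * sd(adgs) / sqrt(50))

  expect_error(project_pwg(c(1, 2), c(1, 2)), "at least 3")
  expect_error(project_pwg(c(200, 200, 200), c(1, 2, 3)), "degenerate")
})
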