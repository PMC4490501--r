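# Atom typing, grid rasterization, PLS fitting, LOO cross-validation and
# model statistics.

test_that("atom typing follows the N > P > D > W > H > X precedence", {
  ket <- smilesMol("CC(=O)C", "acetone")
  ty <- assignAtomTypes(ket)
  expect_equal(ty$types[atomTable(ket)$element == "O"], "W")
  carb <- smilesMol("CC([O-])=O", "acetate")
  tyC <- assignAtomTypes(carb)
  expect_true(all(tyC$types[atomTable(carb)$element == "O"] == "N"))
  am <- smilesMol("CC(N)=O", "acetamide")
  tyA <- assignAtomTypes(am)
  expect_equal(tyA$types[atomTable(am)$element == "N"], "D")
  expect_equal(tyA$types[1], "H")  # methyl carbon
  expect_equal(unname(ty$radii[atomTable(ket)$element == "O"]), 1.52)
})

test_that("sphere rasterization matches a dense-sampling oracle", {
  grid <- new("GridSpec", origin = c(-6, -6, -6), spacing = 1,
              extents = c(12L, 12L, 12L))
  denseOracle <- function(center, radius, grid) {
    hits <- character(0)
    for (ix in 0:(grid@extents[1] - 1))
      for (iy in 0:(grid@extents[2] - 1))
        for (iz in 0:(grid@extents[3] - 1)) {
          lo <- grid@origin + c(ix, iy, iz) * grid@spacing
          gx <- seq(lo[1], lo[1] + 1, by = 0.1)
          gy <- seq(lo[2], lo[2] + 1, by = 0.1)
          gz <- seq(lo[3], lo[3] + 1, by = 0.1)
          pts <- as.matrix(expand.grid(gx, gy, gz))
          d2 <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
            (pts[, 3] - center[3])^2
          if (any(d2 <= radius^2))
            hits <- c(hits, paste0(ix, ":", iy, ":", iz))
        }
    sort(hits)
  }
  set.seed(5)
  for (rep in 1:3) {
    ctr <- runif(3, -2, 2)
    cubes <- combiphore:::sphereCubes(ctr, 1.7, grid)
    got <- sort(paste0(cubes[, 1], ":", cubes[, 2], ":", cubes[, 3]))
    expect_identical(got, denseOracle(ctr, 1.7, grid))
  }
})

test_that("occupancy translation symmetry and empty input", {
  m <- smilesMol("CC", "ethane")
  grid <- new("GridSpec", origin = c(-10, -10, -10), spacing = 1,
              extents = c(40L, 40L, 40L))
  b0 <- computeOccupancy(m, conformer(m), grid)
  b1 <- computeOccupancy(m, sweep(conformer(m), 2, c(1, 0, 0), `+`),
                         grid)
  shift <- vapply(strsplit(b0, ":"), function(p)
    paste(as.integer(p[1]) + 1L, p[2], p[3], p[4], sep = ":"),
    character(1))
  expect_setequal(b1, shift)
  expect_identical(
    computeOccupancy(m, conformer(m), grid, atomSubset = integer(0)),
    character(0))
})

test_that("occupancy bit count is invariant under axis-aligned 90-degree
           rotations of grid-aligned coordinates", {
  m <- smilesMol("CCO", "eth")
  conf <- round(conformer(m))   # snap to the lattice
  grid <- new("GridSpec", origin = c(-20, -20, -20), spacing = 1,
              extents = c(40L, 40L, 40L))
  n0 <- length(computeOccupancy(m, conf, grid))
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  expect_equal(length(computeOccupancy(m, conf %*% Rz, grid)), n0)
})

test_that("PLS fits exact low-rank data and refits its own predictions
           exactly", {
  set.seed(4)
  n <- 24; p <- 40
  X <- matrix(rbinom(n * p, 1, 0.4), n, p)
  # activities exactly linear in two latent directions of the bit
  # matrix, no noise: the PLS Krylov space stays in their span, so the
  # fit interpolates
  sv <- svd(sweep(X, 2, colMeans(X)))
  y <- 6 + 0.7 * sv$u[, 1] * sv$d[1] - 0.4 * sv$u[, 2] * sv$d[2]
  fit <- combiphore:::plsFit(X, y, 3)
  pred <- as.numeric(X %*% fit$coefficients) + fit$intercept
  expect_gte(cor(pred, y)^2, 0.99)
  expect_lt(max(abs(pred - y)), 1e-6)
})

test_that("prediction equals a dense matrix-product oracle and the
           all-zero vector returns the intercept", {
  ds <- refDataset()
  grp <- ds$molecules[1:10]
  gt <- ds$truth
  grid <- gt$groups[[1]]$grid
  bitList <- lapply(grp, function(m)
    computeOccupancy(m, gt$members[[molId(m)]]$genConformer, grid))
  acts <- vapply(grp, activity, numeric(1))
  model <- fitQsar(bitList, acts, grid)
  expect_equal(predictQsar(model, character(0)), model@intercept)
  # dense oracle on random bit vectors
  set.seed(8)
  for (i in 1:20) {
    bits <- sample(model@bits, sample(5:40, 1))
    dense <- as.numeric(as.integer(model@bits %in% bits) %*%
                          model@coefficients) + model@intercept
    expect_equal(predictQsar(model, bits), dense, tolerance = 1e-10)
  }
  # unseen bits contribute nothing
  expect_equal(predictQsar(model, c(model@bits[1], "99:99:99:X")),
               predictQsar(model, model@bits[1]))
})

test_that("degenerate responses raise typed errors", {
  grid <- new("GridSpec", origin = c(0, 0, 0), spacing = 1,
              extents = c(4L, 4L, 4L))
  bits <- lapply(1:8, function(i) paste0(i %% 3, ":0:0:H"))
  expect_error(fitQsar(bits, rep(5, 8), grid), "degenerate response")
  expect_error(computeStats(rep(5, 8), rnorm(8)), "zero variance")
})

test_that("training fit never worsens when factors are added", {
  set.seed(12)
  n <- 20; p <- 30
  X <- matrix(rbinom(n * p, 1, 0.3), n, p)
  y <- as.numeric(X %*% rnorm(p)) + rnorm(n, 0, 0.3)
  r2of <- function(nf) {
    fit <- combiphore:::plsFit(X, y, nf)
    cor(as.numeric(X %*% fit$coefficients) + fit$intercept, y)^2
  }
  expect_gte(r2of(3) + 1e-12, r2of(1))
})

test_that("PLS coefficients agree with an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(3)
  n <- 18; p <- 25
  X <- matrix(rbinom(n * p, 1, 0.4), n, p)
  keep <- apply(X, 2, sd) > 0
  X <- X[, keep]
  colnames(X) <- paste0("b", seq_len(ncol(X)))
  y <- as.numeric(X %*% rnorm(ncol(X))) + rnorm(n, 0, 0.2)
  fit <- combiphore:::plsFit(X, y, 3)
  mo <- mixOmics::pls(X, y, ncomp = 3, mode = "regression",
                      scale = FALSE)
  pred <- predict(mo, X)$predict[, 1, 3]
  mine <- as.numeric(X %*% fit$coefficients) + fit$intercept
  expect_equal(unname(mine), unname(pred), tolerance = 1e-8)
})

test_that("LOO Q2 equals an independently coded refit loop", {
  ds <- refDataset()
  grp <- ds$molecules[1:20]
  gt <- ds$truth
  grid <- gt$groups[[1]]$grid
  X <- NULL
  bitList <- lapply(grp, function(m)
    computeOccupancy(m, gt$members[[molId(m)]]$genConformer, grid))
  universe <- sort(unique(unlist(bitList)))
  X <- t(vapply(bitList, function(b) as.numeric(universe %in% b),
                numeric(length(universe))))
  y <- vapply(grp, activity, numeric(1))
  internal <- looQ2(X, y, 3)
  # oracle: explicit per-compound refit, PRESS assembled independently
  press <- vapply(seq_len(nrow(X)), function(i) {
    f <- combiphore:::plsFit(X[-i, , drop = FALSE], y[-i], 3)
    (y[i] - (sum(X[i, ] * f$coefficients) + f$intercept))^2
  }, numeric(1))
  oracle <- 1 - sum(press) / sum((y - mean(y))^2)
  expect_equal(internal, oracle, tolerance = 1e-8)
})

test_that("classical statistics match hand-computed formulas on a
           10-point fixture", {
  obs <- c(5.1, 6.3, 7.2, 4.9, 5.8, 6.6, 7.9, 5.3, 6.1, 7.4)
  pred <- c(5.0, 6.1, 7.5, 5.2, 5.6, 6.8, 7.6, 5.5, 6.0, 7.1)
  st <- computeStats(obs, pred, nPredictorsEffective = 3)
  n <- 10; k <- 3
  sse <- sum((obs - pred)^2)
  ssr <- sum((pred - mean(obs))^2)
  expect_equal(st$r2, cor(obs, pred)^2)
  expect_equal(st$sd, sqrt(sse / (n - k - 1)))
  expect_equal(st$f, (ssr / k) / (sse / (n - k - 1)))
  expect_equal(st$p, pf(st$f, k, n - k - 1, lower.tail = FALSE))
  # perfect fit
  stp <- computeStats(obs, obs)
  expect_equal(stp$r2, 1)
  expect_equal(stp$sd, 0)
  # identical resampled predictions give stability 1
  str_ <- computeStats(obs, pred, resamplePredictions = list(pred, pred))
  expect_equal(str_$stability, 1)
})

test_that("coefficient map exports nonzero coefficients at cube centres", {
  grid <- new("GridSpec", origin = c(-1, -1, -1), spacing = 1,
              extents = c(4L, 4L, 4L))
  model <- new("QsarModel", grid = grid,
               bits = c("0:0:0:H", "1:2:3:W", "2:2:2:D"),
               coefficients = c(0.5, -0.2, 0),
               intercept = 6, nFactors = 3L,
               stats = c(r2 = 1, sd = 0, f = 1, p = 0.5, stability = 1,
                         q2_loo = 1),
               hypothesisRef = "x")
  cm <- coefficientMap(model)
  expect_equal(nrow(cm), 2)   # zeros suppressed
  expect_equal(cm$x[cm$channel == "W"], -1 + 1 + 0.5)
  expect_equal(cm$coefficient[cm$channel == "H"], 0.5)
  model@coefficients <- c(0, 0, 0)
  expect_equal(nrow(coefficientMap(model)), 0)
})

test_that("planted coefficient signs and locations are recovered", {
  ds <- refDataset()
  grp <- ds$molecules[1:20]
  gt <- ds$truth$groups[[1]]
  bitList <- lapply(grp, function(m)
    computeOccupancy(m, ds$truth$members[[molId(m)]]$genConformer,
                     gt$grid))
  acts <- vapply(grp, activity, numeric(1))
  model <- fitQsar(bitList, acts, gt$grid)
  cm <- coefficientMap(model)
  w <- gt$weights
  # per planted slot: the summed fitted coefficient over the slot's
  # support cubes carries the planted sign
  for (s in seq_along(gt$slots)) {
    ii <- match(gt$slotSupports[[s]], model@bits)
    signedSum <- sum(model@coefficients[ii[!is.na(ii)]])
    expect_equal(sign(signedSum), sign(gt$slots[[s]]$weight))
  }
  idx <- match(names(w), model@bits)
  ok <- !is.na(idx)
  expect_gt(cor(model@coefficients[idx[ok]], as.numeric(w)[ok]), 0.5)
  # top-|coefficient| cubes lie within 2 A of planted weighted cubes
  cmTop <- cm[order(-abs(cm$coefficient)), ][1:10, ]
  wxyz <- do.call(rbind, lapply(strsplit(names(w), ":"), function(p)
    as.numeric(p[1:3]) + 0.5 + gt$grid@origin))
  for (i in seq_len(nrow(cmTop))) {
    d <- sqrt(rowSums(sweep(wxyz, 2,
                            as.numeric(cmTop[i, c("x", "y", "z")]))^2))
    expect_lte(min(d), 2.0)
  }
})
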