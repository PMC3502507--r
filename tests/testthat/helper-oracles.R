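# Independent oracles. None of these touch the package's Kabsch path.

# Brute-force minimum RMSD over rigid motions: for a fixed rotation the
# optimal translation aligns centroids, so scan ZYZ Euler angles on a
# 15-degree grid and polish the best start with Nelder-Mead.
gridCrms <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  rotZ <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                               0, 0, 1), 3, 3)
  rotY <- function(b) matrix(c(cos(b), 0, -sin(b), 0, 1, 0,
                               sin(b), 0, cos(b)), 3, 3)
  f <- function(ang) {
    R <- rotZ(ang[1]) %*% rotY(ang[2]) %*% rotZ(ang[3])
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  step <- pi / 12
  best <- c(0, 0, 0); bestv <- Inf
  for (a in seq(0, 2 * pi - step, by = step))
    for (b in seq(0, pi, by = step))
      for (cc in seq(0, 2 * pi - step, by = step)) {
        v <- f(c(a, b, cc))
        if (v < bestv) { bestv <- v; best <- c(a, b, cc) }
      }
  o <- stats::optim(best, f, method = "Nelder-Mead",
                    control = list(reltol = 1e-15, maxit = 10000))
  min(bestv, o$value)
}

# a random proper rotation (via QR, reflection corrected)
randomRotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

applyRigid <- function(xyz, R, t) sweep(xyz %*% t(R), 2, t, "+")

# one-pass average: superpose all members onto member 1, average once
onePassAverage <- function(ensemble) {
  ms <- lapply(models(ensemble), caCoords)
  ref <- ms[[1]]
  fitted <- lapply(ms, function(P) {
    sp <- superpose(P, ref)
    applyRigid(P, sp@rotation, sp@translation)
  })
  Reduce(`+`, fitted) / length(fitted)
}

# scale sigma so the ensemble's mean cRMS to its average model hits
# `target` Angstrom; with a fixed seed rnorm scales exactly with sigma, so
# proportional correction converges in a few steps
tuneSigma <- function(target, base, nModels, seed, tol = 0.002,
                      maxSteps = 12) {
  sigma <- target
  for (i in seq_len(maxSteps)) {
    ens <- perturbEnsemble(base, nModels, sigma, seed = seed)
    r <- as.numeric(meanEnsembleCrms(ens))
    if (abs(r - target) <= tol) break
    sigma <- sigma * target / r
  }
  sigma
}
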