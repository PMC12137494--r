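# Brute-force minimum-box oracle: exhaustive 2-degree ZYZ rotation grid over a
# covering orientation domain (alpha in [0, 90) by the box's quarter-turn
# symmetry, beta in [0, 180], gamma in [0, 360)). Written from the rotation
# algebra directly, independent of the package's search; the gamma sweep is
# vectorised so the grid stays exhaustive but affordable.
brute_box_volume <- function(coords, radii, step_deg = 2) {
  ctr <- colMeans(coords)
  X <- sweep(coords, 2, ctr)
  step <- step_deg * pi / 180
  g <- seq(0, 2 * pi - 1e-9, by = step)
  cg <- cos(g); sg <- sin(g)
  n <- nrow(X)
  best <- Inf
  for (a in seq(0, pi / 2 - 1e-9, by = step)) {
    Rza <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    for (b in seq(0, pi, by = step)) {
      M <- Rza %*% matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)),
                          3, byrow = TRUE)
      vols <- rep(1, length(g))
      for (k in 1:3) {
        # projection of atom i on box axis k as a function of gamma:
        # c(g)*A_i + s(g)*B_i + C_i
        A <- M[k, 1] * X[, 1] + M[k, 2] * X[, 2]
        B <- M[k, 2] * X[, 1] - M[k, 1] * X[, 2]
        C <- M[k, 3] * X[, 3]
        P <- outer(A, cg) + outer(B, sg) + C
        hi <- do.call(pmax, lapply(seq_len(n), function(i) P[i, ] + radii[i]))
        lo <- do.call(pmin, lapply(seq_len(n), function(i) P[i, ] - radii[i]))
        vols <- vols * (hi - lo)
      }
      best <- min(best, vols)
    }
  }
  best
}
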