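# Rigid-body least-squares superposition (Kabsch, via SVD).

# Optimal rotation (optionally improper) and translation mapping X onto Y.
# X, Y: n x 3 matrices of paired coordinates. Returns list(rmsd, rot, trans,
# proper). rot is applied as Y_hat = X %*% t(rot) + trans.
kabsch <- function(X, Y, allow_inversion = FALSE) {
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2, cx); Y0 <- sweep(Y, 2, cy)
  H <- crossprod(X0, Y0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  fit <- function(D) {
    R <- sv$v %*% diag(D) %*% t(sv$u)
    res <- Y0 - X0 %*% t(R)
    list(rot = R, rmsd = sqrt(mean(rowSums(res^2))))
  }
  proper <- fit(c(1, 1, d))
  best <- list(rot = proper$rot, rmsd = proper$rmsd, proper = TRUE)
  if (allow_inversion) {
    improper <- fit(c(1, 1, -d))
    if (improper$rmsd < best$rmsd)
      best <- list(rot = improper$rot, rmsd = improper$rmsd, proper = FALSE)
  }
  best$trans <- cy - as.numeric(best$rot %*% cx)
  best
}

# angle in degrees between two 3-vectors
vec_angle <- function(u, v) {
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cs))) * 180 / pi
}
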