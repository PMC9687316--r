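# Geometry primitives shared across modules.

# Optimal (least-squares) superposition of mobile onto target (Kabsch).
# Both are n x 3 matrices over the same atoms. Returns the transformed
# mobile coordinates.
kabsch_superpose <- function(mobile, target) {
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(target, 2, ct)
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(P %*% t(R), 2, ct, FUN = "+")
}

# Rigid transform derived from a fit selection, applied to all atoms:
# superpose mobile[fit_idx, ] onto target[fit_idx, ], move everything.
kabsch_apply <- function(mobile, target, fit_idx) {
  cm <- colMeans(mobile[fit_idx, , drop = FALSE])
  ct <- colMeans(target[fit_idx, , drop = FALSE])
  P <- sweep(mobile[fit_idx, , drop = FALSE], 2, cm)
  Q <- sweep(target[fit_idx, , drop = FALSE], 2, ct)
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(mobile, 2, cm) %*% t(R), 2, ct, FUN = "+")
}

# Plain coordinate RMSD in Angstrom between two n x 3 matrices.
coord_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# Place atom D given positions A, B, C, the bond length |C-D|, the bond
# angle B-C-D (degrees) and the torsion A-B-C-D (degrees). Standard
# internal-coordinate (NeRF) construction.
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- pracma_cross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  M <- cbind(bc, m, n)
  as.numeric(M %*% d2 + c)
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Deterministic, nearly uniform points on the unit sphere (golden-section
# spiral), used by the Shrake-Rupley quadrature.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Resolve an atom selection into a logical index over an atom table.
# Accepts NULL (all atoms), a logical/integer vector, a character vector of
# chain ids, or a predicate function(atom_table) -> logical.
resolve_selection <- function(sel, atom_table, what = "selection") {
  n <- nrow(atom_table)
  idx <- if (is.null(sel)) {
    rep(TRUE, n)
  } else if (is.function(sel)) {
    sel(atom_table)
  } else if (is.logical(sel)) {
    if (length(sel) != n) stop(what, " logical vector has wrong length")
    sel
  } else if (is.numeric(sel)) {
    out <- rep(FALSE, n)
    out[as.integer(sel)] <- TRUE
    out
  } else if (is.character(sel)) {
    atom_table$chain %in% sel
  } else stop("cannot interpret ", what)
  idx <- as.logical(idx)
  if (length(idx) != n || anyNA(idx))
    stop(what, " must resolve to one logical per atom")
  if (!any(idx)) stop(what, " selects no atoms")
  idx
}

read_config_json <- function(name) {
  path <- system.file("extdata", "config", name, package = "boomdock")
  if (!nzchar(path)) stop("missing bundled config file: ", name)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
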