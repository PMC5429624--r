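# Solvent accessibility (Shrake-Rupley) and side-chain burial, used as
# structure-derived scalar features for protein residues.

# Near-uniform points on the unit sphere (Fibonacci spiral).
.sphere_points <- function(n = 92) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by sphere-point sampling: each atom's solvent sphere
#' (van der Waals radius + probe) is covered with `n_points` test points and
#' the exposed fraction scaled to the sphere area.
#'
#' @param coords n x 3 matrix of heavy-atom coordinates (Angstrom).
#' @param elements Character vector of element symbols (C, N, O, S, P, ...).
#' @param probe Probe radius, default 1.4 (water).
#' @param n_points Test points per atom, default 92.
#' @return Numeric vector of per-atom SASA (Angstrom^2).
#' @export
shrake_rupley <- function(coords, elements, probe = 1.4, n_points = 92) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(length(elements) == n)
  radii <- vdw_radius(elements) + probe
  pts <- .sphere_points(n_points)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ri <- radii[i]
    # neighbours whose solvent spheres can intersect atom i's
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    nb <- which(d < ri + radii & seq_len(n) != i)
    test <- pts * ri + matrix(coords[i, ], n_points, 3, byrow = TRUE)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      inside <- rowSums((test - matrix(coords[j, ], n_points, 3,
                                       byrow = TRUE))^2) < radii[j]^2
      exposed <- exposed & !inside
      if (!any(exposed)) break
    }
    out[i] <- 4 * pi * ri^2 * mean(exposed)
  }
  out
}

#' Relative solvent accessibility per residue
#'
#' Sums per-atom SASA of the protein chain (computed on the unbound protein,
#' i.e. without the RNA) and normalises by the Gly-X-Gly theoretical maximum
#' for the residue type (mean of the table for nonstandard `X`). Values are
#' clamped to \[0, 1\].
#'
#' @param protein Protein chain of an [rpi_complex()].
#' @inheritParams shrake_rupley
#' @return Numeric vector, one relative accessibility per residue.
#' @export
relative_sasa <- function(protein, probe = 1.4, n_points = 92) {
  n <- length(protein$index)
  if (n == 0) return(numeric(0))
  coords <- do.call(rbind, protein$atoms)
  elements <- unlist(lapply(protein$atoms, attr, "element"))
  ridx <- rep(seq_len(n), vapply(protein$atoms, nrow, integer(1)))
  asa <- shrake_rupley(coords, elements, probe, n_points)
  per_res <- vapply(split(asa, ridx), sum, numeric(1))
  mx <- max_asa_table()
  denom <- ifelse(protein$seq %in% names(mx), mx[protein$seq], mean(mx))
  pmin(pmax(unname(per_res / denom), 0), 1)
}

#' Side-chain burial proxy
#'
#' Fraction of a residue's heavy side-chain atoms (non N/CA/C/O/OXT) lying
#' within `radius` of atoms of any *other* residue of the protein. Residues
#' without side-chain atoms (glycine) use CA as proxy.
#'
#' @param protein Protein chain of an [rpi_complex()].
#' @param radius Neighbourhood radius in Angstrom, default 8.
#' @return Numeric vector in \[0, 1\], one value per residue.
#' @export
sidechain_environment <- function(protein, radius = 8) {
  n <- length(protein$index)
  if (n == 0) return(numeric(0))
  backbone <- c("N", "CA", "C", "O", "OXT")
  all_coords <- do.call(rbind, protein$atoms)
  all_res <- rep(seq_len(n), vapply(protein$atoms, nrow, integer(1)))
  vapply(seq_len(n), function(k) {
    m <- protein$atoms[[k]]
    sc <- m[!(rownames(m) %in% backbone), , drop = FALSE]
    if (nrow(sc) == 0) sc <- m[rownames(m) == "CA", , drop = FALSE]
    if (nrow(sc) == 0) return(0)
    other <- all_coords[all_res != k, , drop = FALSE]
    if (nrow(other) == 0) return(0)
    near <- vapply(seq_len(nrow(sc)), function(a) {
      any(colSums((t(other) - sc[a, ])^2) <= radius^2)
    }, logical(1))
    mean(near)
  }, numeric(1))
}
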