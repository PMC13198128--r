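# Residue graph construction for the structure encoder.
#
# Node scalar features are sin/cos of the backbone dihedrals (phi, psi, omega);
# node vector features are the forward and backward CA->CA unit vectors and an
# imputed side-chain direction; edges connect each residue to its k nearest
# neighbours by CA distance, carrying 16 Gaussian radial-basis features of the
# distance and the unit displacement vector. All features are built from
# displacements, so the graph is exactly translation-invariant, scalars are
# rotation-invariant, and vector features rotate with the coordinates.

RBF_N <- 16L
RBF_MAX <- 20

rbf_expand <- function(d, n = RBF_N, d_max = RBF_MAX) {
  centers <- seq(0, d_max, length.out = n)
  sigma <- centers[2] - centers[1]
  outer(d, centers, function(x, mu) exp(-(x - mu)^2 / (2 * sigma^2)))
}

unit_rows <- function(m, eps = 1e-8) {
  n <- sqrt(rowSums(m^2))
  out <- m / pmax(n, eps)
  out[n < eps, ] <- 0
  out
}

# Dihedral angle (radians) for rows of four point matrices.
dihedral_rows <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross_rows(b1, b2)
  n2 <- cross_rows(b2, b3)
  m1 <- cross_rows(n1, unit_rows(b2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  atan2(y, x)
}

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Build the k-nearest-neighbour residue graph of a backbone
#'
#' Only unmasked residues enter the graph. Each node receives edges from its
#' `min(k, n - 1)` nearest neighbours by CA distance. Edge scalar `j` of an
#' edge at distance `d` is `exp(-(d - mu_j)^2 / (2 sigma^2))` with 16 centers
#' `mu` evenly spanning 0-20 Angstrom and `sigma` equal to the center spacing.
#' Chain termini lacking a forward or backward neighbour get zero vectors for
#' the undefined directions and zeroed dihedral features.
#'
#' @param structure a [backbone_structure()]
#' @param k number of neighbours (default 30, capped at `n - 1`)
#' @return an object of class `residue_graph` with fields `n`, `node_s`
#'   (n x 6 dihedral sin/cos), `node_v` (3n x 3 unit direction channels),
#'   `edge_src`, `edge_dst`, `edge_s` (E x 16 RBF), `edge_v` (3E x 1 unit
#'   displacement) and `residue_index` (positions in the full chain)
#' @export
build_residue_graph <- function(structure, k = 30L) {
  stopifnot(inherits(structure, "backbone_structure"))
  keep <- which(structure$mask)
  n <- length(keep)
  if (n == 0L) stop("no unmasked residues: cannot build a residue graph")
  N <- matrix(structure$coords[keep, "N", ], n, 3L)
  CA <- matrix(structure$coords[keep, "CA", ], n, 3L)
  C <- matrix(structure$coords[keep, "C", ], n, 3L)

  # dihedrals (zeroed where a flanking residue is missing)
  phi <- psi <- omg <- rep(0, n)
  def_phi <- def_psi <- def_omg <- rep(FALSE, n)
  if (n >= 2L) {
    i <- 2:n
    phi[i] <- dihedral_rows(C[i - 1L, , drop = FALSE], N[i, , drop = FALSE],
                            CA[i, , drop = FALSE], C[i, , drop = FALSE])
    omg[i] <- dihedral_rows(CA[i - 1L, , drop = FALSE], C[i - 1L, , drop = FALSE],
                            N[i, , drop = FALSE], CA[i, , drop = FALSE])
    def_phi[i] <- def_omg[i] <- TRUE
    j <- 1:(n - 1L)
    psi[j] <- dihedral_rows(N[j, , drop = FALSE], CA[j, , drop = FALSE],
                            C[j, , drop = FALSE], N[j + 1L, , drop = FALSE])
    def_psi[j] <- TRUE
  }
  node_s <- cbind(sin(phi) * def_phi, cos(phi) * def_phi,
                  sin(psi) * def_psi, cos(psi) * def_psi,
                  sin(omg) * def_omg, cos(omg) * def_omg)

  # node vectors: forward / backward CA->CA and imputed side-chain direction
  fwd <- matrix(0, n, 3L); bwd <- matrix(0, n, 3L)
  if (n >= 2L) {
    d <- CA[-1L, , drop = FALSE] - CA[-n, , drop = FALSE]
    fwd[1:(n - 1L), ] <- unit_rows(d)
    bwd[2:n, ] <- unit_rows(-d)
  }
  nv <- unit_rows(N - CA)
  cv <- unit_rows(C - CA)
  bis <- unit_rows(nv + cv)
  perp <- unit_rows(cross_rows(nv, cv))
  side <- -bis * sqrt(1 / 3) - perp * sqrt(2 / 3)
  node_v <- matrix(0, 3L * n, 3L)
  node_v[, 1] <- as.vector(t(fwd))
  node_v[, 2] <- as.vector(t(bwd))
  node_v[, 3] <- as.vector(t(side))

  # k nearest neighbours by CA distance
  if (n >= 2L) {
    kk <- min(as.integer(k), n - 1L)
    D <- as.matrix(stats::dist(CA))
    src <- integer(n * kk); dst <- integer(n * kk)
    for (i in seq_len(n)) {
      ord <- order(D[i, ])
      nb <- ord[ord != i][seq_len(kk)]
      at <- ((i - 1L) * kk + 1L):(i * kk)
      src[at] <- nb
      dst[at] <- i
    }
    disp <- CA[dst, , drop = FALSE] - CA[src, , drop = FALSE]
    dd <- sqrt(rowSums(disp^2))
    edge_s <- rbf_expand(dd)
    ev <- unit_rows(disp)
    edge_v <- matrix(as.vector(t(ev)), ncol = 1L)
  } else {
    src <- dst <- integer(0)
    edge_s <- matrix(0, 0L, RBF_N)
    edge_v <- matrix(0, 0L, 1L)
    dd <- numeric(0)
  }

  structure(list(n = n, node_s = node_s, node_v = node_v,
                 edge_src = src, edge_dst = dst,
                 edge_s = edge_s, edge_v = edge_v, edge_dist = dd,
                 residue_index = keep),
            class = "residue_graph")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf("<residue_graph> %d residues, %d edges\n", x$n, length(x$edge_src)))
  invisible(x)
}
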