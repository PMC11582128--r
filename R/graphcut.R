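# Field-map estimation as discrete MRF optimization:
#   E(l) = sum_v D_v(l_v) + lambda * sum_(v,w) |f(l_v) - f(l_w)|
# over a uniform off-resonance label grid f. The total-variation pairwise
# cost is convex in the label difference, so every binary "jump move"
# (all voxels may shift their label by a common offset k, or stay) is
# submodular and solved exactly by one min-cut; iterating moves of different
# sizes monotonically decreases the energy. For small instances an exact
# global minimizer (single min-cut over a layered Ishikawa-style graph) is
# provided as an independent reference.

# neighbor pairs of in-mask voxels on an nx x ny grid; returns a 2-column
# index matrix (indices into the mask-ordered voxel list) and edge weights
# (1 for axial, 1/sqrt(2) for diagonal when neighborhood = 8)
grid_neighbor_pairs <- function(dims, mask = NULL, neighborhood = 4) {
  nx <- dims[1]; ny <- dims[2]
  if (is.null(mask)) mask <- matrix(TRUE, nx, ny)
  id <- matrix(0L, nx, ny)
  id[mask] <- seq_len(sum(mask))
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (neighborhood == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  pairs <- NULL; wts <- NULL
  for (o in offs) {
    dx <- o[1]; dy <- o[2]
    x <- seq_len(nx); y <- seq_len(ny)
    xv <- x[x + dx >= 1 & x + dx <= nx]
    yv <- y[y + dy >= 1 & y + dy <= ny]
    if (!length(xv) || !length(yv)) next
    X <- rep(xv, times = length(yv)); Y <- rep(yv, each = length(xv))
    a <- id[cbind(X, Y)]; b <- id[cbind(X + dx, Y + dy)]
    ok <- a > 0L & b > 0L
    if (any(ok)) {
      pairs <- rbind(pairs, cbind(a[ok], b[ok]))
      wts <- c(wts, rep(if (all(o %in% c(0L, 1L)) || dy == 0) 1 else
        1 / sqrt(2), sum(ok)))
    }
  }
  if (is.null(pairs)) pairs <- matrix(integer(0), 0, 2)
  list(pairs = pairs, weights = if (is.null(wts)) numeric(0) else wts)
}

# total MRF energy for a labeling
mrf_energy <- function(D, labels, pairs, pw, step_hz) {
  sum(D[cbind(seq_len(nrow(D)), labels)]) +
    sum(pw * step_hz * abs(labels[pairs[, 1]] - labels[pairs[, 2]]))
}

# Exact minimizer of a submodular binary energy via one s-t min-cut.
# theta0/theta1: unary costs for x = 0 / 1 (length V); pairs: P x 2 indices;
# A,B,C,D: pairwise costs for (0,0),(0,1),(1,0),(1,1), must satisfy
# B + C - A - D >= 0. Returns the optimal binary vector.
solve_binary_submodular <- function(theta0, theta1, pairs, A, B, C, D) {
  V <- length(theta0)
  # reparametrization: x_v = 1 <=> v on sink side
  add1_v <- C - A          # added to theta1 of pairs[,1]
  add1_w <- D - C          # added to theta1 of pairs[,2]
  cap_vw <- B + C - A - D
  t1 <- theta1
  if (nrow(pairs)) {
    acc <- numeric(V)
    idx <- c(pairs[, 1], pairs[, 2])
    val <- c(add1_v, add1_w)
    acc_tab <- rowsum(val, idx)
    acc[as.integer(rownames(acc_tab))] <- acc_tab[, 1]
    t1 <- t1 + acc
  }
  c_net <- t1 - theta0
  s <- V + 1L; t <- V + 2L
  from <- integer(0); to <- integer(0); cap <- numeric(0)
  pos <- which(c_net > 0)
  if (length(pos)) {                       # cost when x = 1: edge s -> v
    from <- c(from, rep(s, length(pos))); to <- c(to, pos)
    cap <- c(cap, c_net[pos])
  }
  neg <- which(c_net < 0)
  if (length(neg)) {                       # cost when x = 0: edge v -> t
    from <- c(from, neg); to <- c(to, rep(t, length(neg)))
    cap <- c(cap, -c_net[neg])
  }
  if (nrow(pairs)) {
    keep <- cap_vw > 1e-12
    if (any(keep)) {
      from <- c(from, pairs[keep, 1]); to <- c(to, pairs[keep, 2])
      cap <- c(cap, cap_vw[keep])
    }
  }
  if (!length(from)) return(as.integer(c_net < 0))
  g <- igraph::make_graph(rbind(from, to), n = V + 2L, directed = TRUE)
  mc <- igraph::min_cut(g, source = s, target = t, capacity = cap,
                        value.only = FALSE)
  x <- integer(V)
  p2 <- as.integer(mc$partition2)
  x[p2[p2 <= V]] <- 1L
  x
}

#' Graph-cut field-map estimation
#'
#' Minimizes the sum of per-voxel VARPRO residual costs and a
#' total-variation smoothness penalty on the off-resonance map by iterated
#' binary jump moves, each solved exactly by min-cut/max-flow. The energy is
#' non-increasing; iteration stops after `n_iterations` moves or when a full
#' cycle through the move schedule yields no improvement.
#'
#' @param residuals Voxels x labels matrix of unary costs (e.g. squared
#'   VARPRO residuals from [residual_lattice()]).
#' @param offres_grid Off-resonance values (Hz) of the label axis (uniform).
#' @param regularization_weight Smoothness weight `lambda` (unary units per
#'   Hz); `NULL` selects `lambda_default()`.
#' @param neighborhood 4 or 8 (ignored when `pairs` is given).
#' @param n_iterations Maximum number of binary moves (default 50).
#' @param dims,mask Spatial grid dimensions and optional logical mask; the
#'   rows of `residuals` correspond to in-mask voxels in column-major order.
#' @param pairs Optional explicit 2-column neighbor index matrix (overrides
#'   `dims`/`mask`).
#' @param move_steps Jump sizes in label units; frequency-domain jumps
#'   derived from `beat_hz`/`alias_hz` are appended when supplied.
#' @param beat_hz Fat-water beat frequency in Hz; adds swap-resolving jumps
#'   of the beat period and of the swap displacement folded into the
#'   residual's alias period (`NULL` to omit).
#' @param alias_hz Alias period of the residual along the off-resonance
#'   axis, `1 / dTE` for equidistant echoes; adds the alias jump and the
#'   folded swap jumps (`NULL` to omit).
#' @param init Optional initial label vector (default: voxelwise argmin).
#' @return List with `labels` (indices into `offres_grid`), `field`
#'   (Hz values), `energy_trace` (energy after each move, starting with the
#'   initial energy), and `lambda`.
#' @export
fieldmap_graphcut <- function(residuals, offres_grid,
                              regularization_weight = NULL,
                              neighborhood = 4, n_iterations = 50,
                              dims = NULL, mask = NULL, pairs = NULL,
                              move_steps = c(1, 2, 5, 10), beat_hz = NULL,
                              alias_hz = NULL, init = NULL) {
  stopifnot(is.matrix(residuals), ncol(residuals) == length(offres_grid),
            all(is.finite(residuals)))
  V <- nrow(residuals)
  L <- length(offres_grid)
  step_hz <- if (L > 1) offres_grid[2] - offres_grid[1] else 1
  pw_weights <- NULL
  if (is.null(pairs)) {
    if (is.null(dims)) stop("either `pairs` or `dims` must be given")
    gp <- grid_neighbor_pairs(dims, mask, neighborhood)
    pairs <- gp$pairs; pw_weights <- gp$weights
  }
  if (is.null(pw_weights)) pw_weights <- rep(1, nrow(pairs))
  lambda <- regularization_weight
  if (is.null(lambda)) lambda <- lambda_default(residuals, step_hz)
  jump_hz <- c(beat_hz, alias_hz)
  if (!is.null(beat_hz) && !is.null(alias_hz)) {
    # swap displacement folded into the alias period: where the swapped
    # branch of the residual reappears inside the search grid
    d <- beat_hz %% alias_hz
    jump_hz <- c(jump_hz, d, alias_hz - d)
  }
  if (length(jump_hz)) {
    js <- pmax(1L, as.integer(round(jump_hz / step_hz)))
    move_steps <- unique(c(move_steps, js[js <= L - 1L]))
  }
  schedule <- as.vector(rbind(move_steps, -move_steps))
  labels <- if (is.null(init)) max.col(-residuals, ties.method = "first")
            else as.integer(init)
  pw <- lambda * pw_weights
  energy <- mrf_energy(residuals, labels, pairs, pw, step_hz)
  trace <- energy
  stale <- 0L
  for (it in seq_len(n_iterations)) {
    k <- schedule[(it - 1L) %% length(schedule) + 1L]
    prop <- labels + k
    movable <- prop >= 1L & prop <= L
    theta0 <- residuals[cbind(seq_len(V), labels)]
    theta1 <- theta0
    theta1[movable] <- residuals[cbind(which(movable), prop[movable])]
    big <- sum(abs(theta0)) + sum(pw) * step_hz * L + 1
    theta1[!movable] <- big                  # forbid out-of-grid moves
    dl <- abs(labels[pairs[, 1]] - labels[pairs[, 2]]) * step_hz
    A <- pw * dl
    B <- pw * abs(labels[pairs[, 1]] - labels[pairs[, 2]] - k) * step_hz
    C <- pw * abs(labels[pairs[, 1]] + k - labels[pairs[, 2]]) * step_hz
    x <- solve_binary_submodular(theta0, theta1, pairs, A, B, C, A)
    new_labels <- labels
    new_labels[x == 1L & movable] <- prop[x == 1L & movable]
    new_energy <- mrf_energy(residuals, new_labels, pairs, pw, step_hz)
    if (new_energy < energy - 1e-12 * max(1, abs(energy))) {
      labels <- new_labels; energy <- new_energy; stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= length(schedule)) { trace <- c(trace, energy); break }
    }
    trace <- c(trace, energy)
  }
  list(labels = labels, field = offres_grid[labels], energy_trace = trace,
       lambda = lambda)
}

#' Default field-map smoothness weight
#'
#' Proportional to the mean curvature of the unary cost at the per-voxel
#' minimum: `lambda = 0.02 mean(second difference at argmin) / step_hz`.
#' The factor is calibrated so the smoothness prior is strong enough to keep
#' neighboring voxels on the same residual branch (resolving the fat-water
#' label ambiguity across noisy voxels) while remaining far too weak to
#' flatten genuine field excursions of hundreds of Hz.
#'
#' @param residuals Voxels x labels unary cost matrix.
#' @param step_hz Label grid spacing in Hz.
#' @return Scalar weight (unary units per Hz).
#' @export
lambda_default <- function(residuals, step_hz) {
  L <- ncol(residuals)
  if (L < 3) return(0)
  am <- max.col(-residuals, ties.method = "first")
  am <- pmin(pmax(am, 2L), L - 1L)
  i <- seq_len(nrow(residuals))
  d2 <- residuals[cbind(i, am - 1L)] + residuals[cbind(i, am + 1L)] -
    2 * residuals[cbind(i, am)]
  0.02 * mean(pmax(d2, 0)) / step_hz
}

#' Exact field-map optimum for small instances
#'
#' Global minimizer of the same unary + total-variation energy as
#' [fieldmap_graphcut()], computed with a single min-cut over a layered
#' (Ishikawa-style) graph in which each voxel contributes a chain of label
#' edges. Exact for convex pairwise costs, but the graph has
#' `voxels x labels` nodes, so this is a reference implementation for
#' small problems (tests, oracle comparisons), not for full images.
#'
#' @inheritParams fieldmap_graphcut
#' @return List with `labels`, `field`, and the optimal `energy`.
#' @export
fieldmap_exact <- function(residuals, offres_grid, regularization_weight,
                           neighborhood = 4, dims = NULL, mask = NULL,
                           pairs = NULL) {
  stopifnot(is.matrix(residuals), ncol(residuals) == length(offres_grid))
  V <- nrow(residuals); L <- length(offres_grid)
  step_hz <- if (L > 1) offres_grid[2] - offres_grid[1] else 1
  pw_weights <- NULL
  if (is.null(pairs)) {
    if (is.null(dims)) stop("either `pairs` or `dims` must be given")
    gp <- grid_neighbor_pairs(dims, mask, neighborhood)
    pairs <- gp$pairs; pw_weights <- gp$weights
  }
  if (is.null(pw_weights)) pw_weights <- rep(1, nrow(pairs))
  lambda <- regularization_weight
  if (L == 1) {
    return(list(labels = rep(1L, V), field = rep(offres_grid, V),
                energy = sum(residuals[, 1])))
  }
  # shift unaries to be strictly positive (min-cut needs >= 0 capacities);
  # adding a per-voxel constant shifts the energy by a known amount
  shift <- min(residuals)
  Dm <- residuals - shift
  node <- function(v, i) (i - 1L) * V + v + 2L   # i in 1..L-1; 1 = s, 2 = t
  s <- 1L; t <- 2L
  INF <- sum(Dm) + lambda * sum(pw_weights) * step_hz * L * 2 + 1
  from <- integer(0); to <- integer(0); cap <- numeric(0)
  vs <- seq_len(V)
  # unary chains: cutting the i-th chain edge of voxel v assigns label i
  from <- c(from, rep(s, V)); to <- c(to, node(vs, 1L)); cap <- c(cap, Dm[, 1])
  if (L > 2) {
    for (i in seq_len(L - 2L)) {
      from <- c(from, node(vs, i)); to <- c(to, node(vs, i + 1L))
      cap <- c(cap, Dm[, i + 1L])
    }
  }
  from <- c(from, node(vs, L - 1L)); to <- c(to, rep(t, V))
  cap <- c(cap, Dm[, L])
  # monotonicity: infinite reverse edges along each chain
  if (L > 2) {
    for (i in seq_len(L - 2L)) {
      from <- c(from, node(vs, i + 1L)); to <- c(to, node(vs, i))
      cap <- c(cap, rep(INF, V))
    }
  }
  # pairwise TV: linking edges at every layer, both directions
  if (nrow(pairs)) {
    for (i in seq_len(L - 1L)) {
      w <- lambda * pw_weights * step_hz
      from <- c(from, node(pairs[, 1], i), node(pairs[, 2], i))
      to <- c(to, node(pairs[, 2], i), node(pairs[, 1], i))
      cap <- c(cap, w, w)
    }
  }
  g <- igraph::make_graph(rbind(from, to), n = (L - 1L) * V + 2L,
                          directed = TRUE)
  mc <- igraph::min_cut(g, source = s, target = t, capacity = cap,
                        value.only = FALSE)
  in_src <- rep(FALSE, (L - 1L) * V + 2L)
  in_src[as.integer(mc$partition1)] <- TRUE
  labels <- integer(V)
  for (v in vs) labels[v] <- 1L + sum(in_src[node(v, seq_len(L - 1L))])
  list(labels = labels, field = offres_grid[labels],
       energy = mrf_energy(residuals, labels, pairs,
                           lambda * pw_weights, step_hz))
}
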