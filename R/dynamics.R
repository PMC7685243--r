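## Potential-surface analysis of the trained dynamics: a mesh in the 2-D
## sequence-subspace latent plane is lifted back to unit space through the
## dPCA encoder, each lifted point is set as the network's firing-rate
## state, the network is stepped once with a frozen input and no noise, and
## the magnitude of the state change is the "potential" at that point.
## Troughs that stay put over the length of the fixation period are fixed
## points; minimal paths between two sequences' fixed points are measured
## with Dijkstra's algorithm on the joint (point-wise minimum) surface.

#' Reconstruct the frozen input context at a chosen trial time point
#'
#' The potential surface is computed "at a moment in time": the network
#' input is frozen at its value at a chosen point of an (error-free) trial.
#' The default context is the middle of the fixation period preceding the
#' first movement. Striatal context is the action/reward input; prefrontal
#' context is the mean striatal value readout of the chosen (sequence,
#' certainty) cell joined with the instruction channels.
#'
#' @param cfg A \code{\link{coding_config}}.
#' @param sequence_id Sequence id 1-8.
#' @param tpoint List with \code{stage} (1-3: which movement's replay
#'   segment) and \code{frac} (position within the segment, 0-1).
#' @return List with \code{u_s} (15-vector), \code{u_ins} (10-vector) and
#'   the time index \code{row} into the 3-segment trial axis.
#' @export
context_inputs <- function(cfg, sequence_id, tpoint = list(stage = 1, frac = NULL)) {
  L <- cfg$seg_len
  stage <- tpoint$stage
  stopifnot(stage >= 1, stage <= 3)
  ## default: middle of the fixation gap
  pos <- if (is.null(tpoint$frac)) max(1L, round(cfg$gap / 2))
         else max(1L, min(L, round(tpoint$frac * L)))
  row <- (stage - 1L) * L + pos
  moves <- seq_moves(sequence_id)
  hemi <- task_sequences()$hemifield[task_sequences()$id == sequence_id]
  u_s <- numeric(15)
  u_ins <- numeric(10)
  in_fix <- pos <= cfg$gap
  in_act <- pos > cfg$gap && pos <= cfg$gap + cfg$action_pulse_len
  in_rew <- pos > cfg$gap + cfg$action_pulse_len
  if (in_act) u_s[moves[stage]] <- 1
  if (in_rew) u_s[10L + decision_point_of(stage - 1L, moves[stage])] <- 1
  ## instructions shown during this segment belong to the *next* decision
  next_stage <- if (stage < 3L) stage else 0L   # stage index 0-2 of upcoming
  pts <- instruction_points(next_stage, hemi)
  if (in_fix) u_ins[2L * pts - 1L] <- 1
  if (in_act) u_ins[2L * pts] <- 1
  list(u_s = u_s, u_ins = u_ins, row = row)
}

## one noise-free Euler step of a single network over a matrix of states
## (columns): returns the change in synaptic currents.
.area_mats <- function(net, area) {
  if (area == "prefrontal") {
    list(W_rr = net$W_rr_p, W_ir = net$W_ir_p)
  } else {
    list(W_rr = net$W_rr_s, W_ir = net$W_ir_s)
  }
}

.step_delta <- function(net, area, X0, u) {
  M <- .area_mats(net, area)
  a <- net$dt / net$tau
  drive <- M$W_rr %*% tanh(X0) + matrix(M$W_ir %*% u, nrow(X0), ncol(X0))
  a * (-X0 + drive)
}

#' Potential surface over a latent mesh
#'
#' Builds a G x G mesh over a rectangle in the top-two sequence-subspace
#' latent dimensions, lifts every mesh point to unit space through the dPCA
#' encoder (adding back the unit means), converts the rates to synaptic
#' currents (clipping into the open interval (-1, 1) before the inverse
#' tanh), steps the chosen network once with the frozen input and no noise,
#' and records the Euclidean magnitude of the current change.
#'
#' @param net A \code{corticostriatal_net}.
#' @param model A \code{\link{fit_dpca}} model for the same area.
#' @param area \code{"prefrontal"} or \code{"striatal"}.
#' @param input Frozen input vector: 15-D action/reward input for the
#'   striatal network, or 20-D \code{c(u_v, u_ins)} for the prefrontal one.
#' @param xlim,ylim Mesh extent in the two latent dimensions.
#' @param G Mesh resolution per side.
#' @param phi Marginalization whose encoder lifts the mesh.
#' @param baseline Optional unit-space rate vector the sequence-subspace
#'   offsets are added to when lifting mesh points (default: the model's
#'   per-unit mean). Passing the condition-mean state at the frozen trial
#'   moment anchors the mesh on the network's operating manifold, so that
#'   surface values reflect the dynamics around the actual trajectories
#'   rather than the restoring drift towards the manifold.
#' @return An object of class \code{potential_surface}: mesh axes \code{x},
#'   \code{y}, the G x G \code{values} matrix, and the context.
#' @export
potential_surface <- function(net, model, area = c("prefrontal", "striatal"),
                              input, xlim, ylim, G = 60L, phi = "s",
                              baseline = NULL) {
  area <- match.arg(area)
  stopifnot(inherits(model, "dpca_model"))
  Fm <- model$F[[phi]]
  if (ncol(Fm) < 2L) stop("need at least 2 encoder components")
  Fm <- Fm[, 1:2, drop = FALSE]
  expected <- if (area == "prefrontal") 20L else 15L
  if (length(input) != expected) {
    stop(area, " surface needs a ", expected, "-D frozen input")
  }
  if (is.null(baseline)) baseline <- model$mean
  gx <- seq(xlim[1], xlim[2], length.out = G)
  gy <- seq(ylim[1], ylim[2], length.out = G)
  mesh <- as.matrix(expand.grid(x = gx, y = gy))
  R0 <- Fm %*% t(mesh) + baseline            # units x G^2, rate space
  R0 <- pmin(pmax(R0, -1 + 1e-6), 1 - 1e-6)
  X0 <- atanh(R0)
  dX <- .step_delta(net, area, X0, input)
  vals <- matrix(sqrt(colSums(dX^2)), G, G)  # x indexes rows
  structure(list(x = gx, y = gy, values = vals, area = area, phi = phi,
                 input = input, G = G, baseline = baseline),
            class = "potential_surface")
}

#' @export
print.potential_surface <- function(x, ...) {
  cat(sprintf("<potential_surface> %s, %dx%d mesh over [%.3g, %.3g] x [%.3g, %.3g]\n",
              x$area, x$G, x$G, min(x$x), max(x$x), min(x$y), max(x$y)))
  cat(sprintf("  gradient magnitude: min %.4g, max %.4g\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.potential_surface <- function(x, ...) {
  graphics::image(x$x, x$y, x$values, xlab = "latent 1", ylab = "latent 2",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Verify a candidate fixed point by iteration
#'
#' Starting from a unit-space state, iterates the network the length of the
#' fixation period (10 steps by default) with the input frozen and no
#' noise, and checks that the state's projection into the latent plane
#' moves less than \code{eps} in total.
#'
#' @param net A \code{corticostriatal_net}.
#' @param model The \code{\link{fit_dpca}} model providing the projection.
#' @param area Which network.
#' @param x0 Unit-space synaptic-current vector.
#' @param input Frozen input (as in \code{\link{potential_surface}}).
#' @param n_iter Number of iterations (the fixation period).
#' @param eps Tolerance on total latent displacement.
#' @param phi Marginalization of the projection.
#' @return Logical; attribute \code{"displacement"} carries the measured
#'   latent displacement.
#' @export
verify_fixed_point <- function(net, model, area, x0, input, n_iter = 10L,
                               eps = 1e-2, phi = "s") {
  D <- model$D[[phi]][1:2, , drop = FALSE]
  x <- matrix(x0, ncol = 1)
  z0 <- D %*% (tanh(x) - model$mean)
  for (i in seq_len(n_iter)) {
    x <- x + .step_delta(net, area, x, input)
  }
  z1 <- D %*% (tanh(x) - model$mean)
  disp <- sqrt(sum((z1 - z0)^2))
  structure(disp < eps, displacement = disp)
}

#' Point-wise minimum of two potential surfaces
#'
#' The joint surface of two sequences' manifolds: the element-wise minimum
#' of their gradient magnitudes over a shared mesh.
#'
#' @param A,B \code{potential_surface} objects on identical meshes.
#' @return A \code{potential_surface}.
#' @export
joint_surface <- function(A, B) {
  stopifnot(inherits(A, "potential_surface"), inherits(B, "potential_surface"))
  if (!isTRUE(all.equal(A$x, B$x)) || !isTRUE(all.equal(A$y, B$y))) {
    stop("surfaces live on different meshes")
  }
  out <- A
  out$values <- pmin(A$values, B$values)
  out$input <- NULL
  out
}

#' Mesh argmin near a reference trajectory
#'
#' Finds the mesh point with the smallest gradient magnitude among points
#' whose nearest trajectory is \code{traj} (a Voronoi split between the two
#' trajectories on the joint mesh), i.e. the trough of this sequence's
#' basin.
#'
#' @param surface A \code{potential_surface}.
#' @param traj Time x 2 latent trajectory of the sequence of interest.
#' @param other Optional competing trajectory; when given, only mesh points
#'   closer to \code{traj} than to \code{other} are searched.
#' @return Integer vector \code{c(i, j)} of mesh indices.
#' @export
surface_argmin <- function(surface, traj, other = NULL) {
  G <- surface$G
  mesh <- as.matrix(expand.grid(x = surface$x, y = surface$y))
  d_self <- .min_dist_to(mesh, traj)
  keep <- if (is.null(other)) rep(TRUE, nrow(mesh)) else
    d_self <= .min_dist_to(mesh, other)
  v <- as.vector(surface$values)
  v[!keep] <- Inf
  k <- which.min(v)
  c((k - 1L) %% G + 1L, (k - 1L) %/% G + 1L)
}

.min_dist_to <- function(mesh, traj) {
  ## nearest squared distance from each mesh point to a polyline's vertices
  best <- rep(Inf, nrow(mesh))
  for (t in seq_len(nrow(traj))) {
    d <- (mesh[, 1] - traj[t, 1])^2 + (mesh[, 2] - traj[t, 2])^2
    best <- pmin(best, d)
  }
  best
}

#' Minimal path length between two points on a potential surface
#'
#' Shortest path by Dijkstra's algorithm on the 8-connected mesh graph.
#' Each edge weighs the Euclidean length of the step in (latent1, latent2,
#' value) space, so climbing the ridge between two basins lengthens the
#' path; with \code{mode = "cost"} the edge weight is instead the mean of
#' the endpoint values times the planar step length.
#'
#' @param surface A \code{potential_surface} (typically a joint surface).
#' @param p,q Mesh index pairs \code{c(i, j)} (as from
#'   \code{\link{surface_argmin}}).
#' @param mode \code{"euclidean"} (default) or \code{"cost"}.
#' @return Scalar path length.
#' @export
min_path_length <- function(surface, p, q, mode = c("euclidean", "cost")) {
  mode <- match.arg(mode)
  G <- surface$G
  chk <- function(pt) {
    if (any(pt < 1L) || any(pt > G)) stop("endpoint off the mesh")
    as.integer(pt)
  }
  p <- chk(p); q <- chk(q)
  if (all(p == q)) return(0)
  id <- function(i, j) (j - 1L) * G + i
  dx <- surface$x[2] - surface$x[1]
  dy <- surface$y[2] - surface$y[1]
  v <- surface$values
  from <- integer(0); to <- integer(0); w <- numeric(0)
  steps <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  for (s in seq_len(nrow(steps))) {
    di <- steps[s, 1]; dj <- steps[s, 2]
    i1 <- if (di >= 0L) seq_len(G - di) else seq_len(G + di) - di
    j1 <- if (dj >= 0L) seq_len(G - dj) else seq_len(G + dj) - dj
    A <- as.matrix(expand.grid(i = i1, j = j1))
    B <- cbind(A[, 1] + di, A[, 2] + dj)
    planar <- sqrt((di * dx)^2 + (dj * dy)^2)
    va <- v[A]; vb <- v[B]
    wgt <- if (mode == "euclidean") sqrt(planar^2 + (vb - va)^2)
           else (va + vb) / 2 * planar
    from <- c(from, id(A[, 1], A[, 2]))
    to <- c(to, id(B[, 1], B[, 2]))
    w <- c(w, wgt)
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  d <- igraph::distances(g, v = id(p[1], p[2]), to = id(q[1], q[2]),
                         weights = w, algorithm = "dijkstra")
  as.numeric(d)
}

#' Minimal path lengths between sequence attractors across certainty levels
#'
#' For every certainty level and every requested sequence pair, builds the
#' two sequences' potential surfaces over a shared mesh (the bounding box
#' of their latent trajectories, padded 25\%), takes the joint surface,
#' locates each sequence's basin trough, verifies it over the fixation
#' period, and measures the Dijkstra path between the troughs. Pairs whose
#' trough fails verification are skipped with a warning.
#'
#' @param net A trained \code{corticostriatal_net}.
#' @param model A \code{\link{fit_dpca}} model for this area's tensor.
#' @param pop The \code{\link{population_tensor}} the model was fit to.
#' @param area Which network.
#' @param pairs Matrix of sequence-id pairs (rows); default all
#'   within-hemifield pairs for prefrontal, all pairs for striatal.
#' @param G Mesh resolution.
#' @param tpoint Trial time point of the frozen context (see
#'   \code{\link{context_inputs}}).
#' @param sigma Smoothing for the latent trajectories.
#' @param verify_eps Tolerance of the fixed-point verification, as a
#'   fraction of the mesh diagonal. The candidate trough state is first
#'   given \code{n_settle} noise-free iterations to shed the transient
#'   induced by the rank-2 mesh lift, then must move less than this over
#'   the fixation period; a displacement below half the landscape scale
#'   means the state stays within its own basin rather than crossing the
#'   inter-sequence ridge.
#' @param n_settle Settling iterations before verification.
#' @return List: \code{curve} (data.frame certainty x mean path length),
#'   \code{pairs} (pairs x certainty matrix of path lengths).
#' @export
path_length_by_certainty <- function(net, model, pop,
                                     area = c("prefrontal", "striatal"),
                                     pairs = NULL, G = 40L,
                                     tpoint = list(stage = 1, frac = NULL),
                                     sigma = 2, verify_eps = 0.5,
                                     n_settle = 10L) {
  area <- match.arg(area)
  X <- pop$X
  C <- dim(X)[3]
  hemi <- pop$hemifield
  if (is.null(pairs)) {
    pairs <- if (area == "prefrontal") {
      rbind(t(utils::combn(which(hemi == "upper"), 2L)),
            t(utils::combn(which(hemi == "lower"), 2L)))
    } else {
      t(utils::combn(1:8, 2L))
    }
  }
  res <- matrix(NA_real_, nrow(pairs), C)
  rownames(res) <- apply(pairs, 1, paste, collapse = "-")
  for (c_i in seq_len(C)) {
    for (pr in seq_len(nrow(pairs))) {
      s1 <- pairs[pr, 1]; s2 <- pairs[pr, 2]
      z1 <- dpca_project(X[, s1, c_i, ], model, phi = "s", d = 2L,
                         sigma = sigma)
      z2 <- dpca_project(X[, s2, c_i, ], model, phi = "s", d = 2L,
                         sigma = sigma)
      zz <- rbind(z1, z2)
      pad <- 0.25
      xr <- range(zz[, 1]); yr <- range(zz[, 2])
      xr <- xr + c(-1, 1) * pad * max(diff(xr), 1e-8)
      yr <- yr + c(-1, 1) * pad * max(diff(yr), 1e-8)
      surf_of <- function(sid) {
        ctx <- context_inputs(pop$cfg, sid, tpoint)
        input <- if (area == "striatal") ctx$u_s else
          c(pop$u_v[, sid, c_i, ctx$row], ctx$u_ins)
        potential_surface(net, model, area = area, input = input,
                          xlim = xr, ylim = yr, G = G,
                          baseline = baseline)
      }
      ## anchor the mesh on the mean state at the frozen trial moment
      ctx0 <- context_inputs(pop$cfg, s1, tpoint)
      baseline <- rowMeans(pop$X[, , c_i, ctx0$row])
      A <- surf_of(s1); B <- surf_of(s2)
      J <- joint_surface(A, B)
      p1 <- surface_argmin(A, z1, z2)
      p2 <- surface_argmin(B, z2, z1)
      eps_abs <- verify_eps * sqrt(diff(xr)^2 + diff(yr)^2)
      ok <- TRUE
      for (side in list(list(s = A, pt = p1, sid = s1),
                        list(s = B, pt = p2, sid = s2))) {
        Fm <- model$F[["s"]][, 1:2, drop = FALSE]
        z <- c(side$s$x[side$pt[1]], side$s$y[side$pt[2]])
        r0 <- pmin(pmax(Fm %*% z + baseline, -1 + 1e-6), 1 - 1e-6)
        x0 <- atanh(r0)
        for (i in seq_len(n_settle)) {
          x0 <- x0 + .step_delta(net, area, x0, side$s$input)
        }
        if (!verify_fixed_point(net, model, area, x0, side$s$input,
                                eps = eps_abs)) ok <- FALSE
      }
      if (!ok) {
        warning(sprintf("pair %d-%d, certainty %d: trough not fixed; skipped",
                        s1, s2, c_i))
        next
      }
      res[pr, c_i] <- min_path_length(J, p1, p2)
    }
  }
  list(curve = data.frame(certainty = seq_len(C),
                          path_length = colMeans(res, na.rm = TRUE)),
       pairs = res)
}
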