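# Dynamics oracles: analytic fixed points of linear systems, constructed
# oscillators, flat-surface Dijkstra closed forms, ridge monotonicity.

# a "striatal" network with zero recurrence whose drive is a constant c:
# x' = -x + c has its unique fixed point at x = c
linear_net <- function(cvec) {
  net <- manual_net(n_s = length(cvec))
  net$W_ir_s <- cbind(cvec, matrix(0, length(cvec), 14))
  net
}

test_that("the potential surface of a linear system bottoms out at the analytic fixed point", {
  cvec <- c(0.10, -0.05)
  net <- linear_net(cvec)
  model <- identity_dpca(2)
  input <- c(1, rep(0, 14))             # selects the first input column
  # odd mesh centered on the fixed point, so one grid node sits exactly on it
  xlim <- tanh(cvec[1]) + c(-0.3, 0.3); ylim <- tanh(cvec[2]) + c(-0.3, 0.3)
  surf <- potential_surface(net, model, "striatal", input,
                            xlim = xlim, ylim = ylim, G = 41)
  k <- which(surf$values == min(surf$values), arr.ind = TRUE)
  found <- c(surf$x[k[1, 1]], surf$y[k[1, 2]])
  cell <- c(diff(surf$x[1:2]), diff(surf$y[1:2]))
  expect_true(all(abs(found - tanh(cvec)) <= cell))
  # at the fixed point itself the gradient magnitude is (numerically) zero
  expect_lt(min(surf$values), 1e-3 * sqrt(sum(cvec^2)) + 1e-6)
  # grid refinement: the minimum stays within the old cell size
  surf2 <- potential_surface(net, model, "striatal", input,
                             xlim = xlim, ylim = ylim, G = 81)
  k2 <- which(surf2$values == min(surf2$values), arr.ind = TRUE)
  found2 <- c(surf2$x[k2[1, 1]], surf2$y[k2[1, 2]])
  expect_true(all(abs(found2 - found) <= cell))
  expect_error(potential_surface(net, model, "striatal", rep(0, 20)),
               "15-D")
})

test_that("fixed-point verification accepts stable points and rejects a limit cycle", {
  model <- identity_dpca(2)
  # stable origin: zero-input, zero-recurrence network
  net0 <- manual_net(n_s = 2)
  expect_true(verify_fixed_point(net0, model, "striatal", c(0, 0),
                                 rep(0, 15)))
  # and the analytic fixed point of the linear system passes
  cvec <- c(0.1, -0.05)
  netl <- linear_net(cvec)
  expect_true(verify_fixed_point(netl, model, "striatal", cvec,
                                 c(1, rep(0, 14)), eps = 1e-2))
  # a rotational 2-unit system keeps moving: not a fixed point
  th <- 0.9
  W <- 3 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  netr <- manual_net(n_s = 2, W_rr_s = W)
  x0 <- c(0.8, 0)
  v <- verify_fixed_point(netr, model, "striatal", x0, rep(0, 15),
                          n_iter = 10, eps = 1e-3)
  expect_false(v)
  expect_gt(attr(v, "displacement"), 1e-3)
  # eps = Inf accepts anything
  expect_true(verify_fixed_point(netr, model, "striatal", x0, rep(0, 15),
                                 eps = Inf))
})

flat_surface <- function(G = 21, h = 1, val = 0) {
  structure(list(x = seq(0, (G - 1) * h, by = h),
                 y = seq(0, (G - 1) * h, by = h),
                 values = matrix(val, G, G), area = "striatal", phi = "s",
                 input = NULL, G = G),
            class = "potential_surface")
}

test_that("joint surfaces are the point-wise minimum, commutative and idempotent", {
  set.seed(43)
  A <- flat_surface(); B <- flat_surface()
  A$values <- matrix(runif(21 * 21), 21)
  B$values <- matrix(runif(21 * 21), 21)
  J <- joint_surface(A, B)
  expect_equal(J$values, pmin(A$values, B$values))
  expect_equal(joint_surface(B, A)$values, J$values)
  expect_equal(joint_surface(A, A)$values, A$values)
  expect_true(all(J$values <= A$values) && all(J$values <= B$values))
  C <- flat_surface(G = 11)
  expect_error(joint_surface(A, C), "mesh")
})

test_that("Dijkstra on a flat surface equals the analytic 8-connected distance", {
  s <- flat_surface(G = 25, h = 0.5)
  p <- c(3, 4); q <- c(18, 11)
  di <- abs(q[1] - p[1]); dj <- abs(q[2] - p[2])
  analytic <- (min(di, dj) * sqrt(2) + abs(di - dj)) * 0.5
  expect_equal(min_path_length(s, p, q), analytic, tolerance = 1e-10)
  expect_equal(min_path_length(s, p, p), 0)
  # symmetry and the lower bound by straight-line distance
  expect_equal(min_path_length(s, q, p), min_path_length(s, p, q))
  expect_gte(min_path_length(s, p, q) + 1e-12,
             0.5 * sqrt(di^2 + dj^2))
  expect_error(min_path_length(s, c(0, 1), q), "off the mesh")
})

test_that("an inserted ridge lengthens the minimal path monotonically", {
  lengths <- vapply(c(0, 0.5, 1, 2, 4), function(h) {
    s <- flat_surface(G = 21, h = 1)
    s$values[11, ] <- h          # wall between column 1 and column 21
    min_path_length(s, c(3, 11), c(19, 11))
  }, numeric(1))
  expect_true(all(diff(lengths) > 0))
})

test_that("surface_argmin picks each basin's trough under a Voronoi split", {
  s <- flat_surface(G = 21, h = 1)
  s$values[,] <- 1
  s$values[5, 5] <- 0.1     # trough A
  s$values[17, 17] <- 0.05  # trough B (globally deeper)
  trajA <- matrix(c(4, 4), 1); trajB <- matrix(c(16, 16), 1)
  expect_equal(surface_argmin(s, trajA, trajB), c(5L, 5L))
  expect_equal(surface_argmin(s, trajB, trajA), c(17L, 17L))
  expect_equal(surface_argmin(s, trajB), c(17L, 17L))  # global, no split
})

test_that("context inputs reconstruct the frozen trial state", {
  cfg <- coding_config(action_pulse_len = 10, gap = 4)
  # default: mid-fixation of the first movement -> all input channels off,
  # upcoming instructions mark the second movement's Fixate channels
  ctx <- context_inputs(cfg, 5L)
  expect_equal(sum(ctx$u_s), 0)
  expect_equal(which(ctx$u_ins == 1), c(2 * 2 - 1, 2 * 3 - 1))
  # mid-action of the first movement: the action channel of move 1 is on
  ctx2 <- context_inputs(cfg, 5L, list(stage = 1, frac = 0.5))
  expect_equal(which(ctx2$u_s[1:10] == 1), seq_moves(5L)[1])
})
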