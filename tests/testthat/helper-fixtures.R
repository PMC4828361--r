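# Shared fixtures and independent oracles, built in code at test time.

# small two-segment model: a 4-marker base with a 3-marker arm hanging from
# a hinge 200 mm above the base origin
toy_model <- function() {
  segs <- list(
    base = list(name = "base", parent = NA_character_,
                joint_offset = c(0, 0, 0), sequence = "YXZ",
                markers = rbind(B1 = c(100, 0, 0), B2 = c(-100, 0, 0),
                                B3 = c(0, 100, 0), B4 = c(0, 0, 50)),
                owns = c("B1", "B2", "B3", "B4")),
    arm = list(name = "arm", parent = "base",
               joint_offset = c(0, 0, 200), sequence = "YXZ",
               markers = rbind(A1 = c(0, 0, 0), A2 = c(150, 0, 0),
                               A3 = c(0, 80, 40)),
               owns = c("A1", "A2", "A3")))
  skeleton_model(segs)
}

# a small random marker series (no missing samples unless asked)
random_series <- function(n_frames = 10, n_markers = 3, seed = 42,
                          frame_rate = 200) {
  set.seed(seed)
  pos <- array(runif(n_frames * 3 * n_markers, -500, 1500),
               dim = c(n_frames, 3, n_markers))
  marker_series(pos, sprintf("M%02d", seq_len(n_markers)), frame_rate)
}

# independent exact-alignment oracle: the unique rigid transform mapping
# three non-collinear points onto their images, built from orthonormal
# frames (no SVD involved)
rigid_from_three_points <- function(P, Q) {
  frame_of <- function(X) {
    u1 <- X[2, ] - X[1, ]; u1 <- u1 / sqrt(sum(u1^2))
    v <- X[3, ] - X[1, ]
    u2 <- v - sum(v * u1) * u1; u2 <- u2 / sqrt(sum(u2^2))
    u3 <- c(u1[2] * u2[3] - u1[3] * u2[2],
            u1[3] * u2[1] - u1[1] * u2[3],
            u1[1] * u2[2] - u1[2] * u2[1])
    cbind(u1, u2, u3)
  }
  R <- frame_of(Q) %*% t(frame_of(P))
  list(R = R, t = as.numeric(Q[1, ] - R %*% P[1, ]))
}

# random proper rotation away from gimbal lock
random_rotation <- function() {
  cardan_compose(c(runif(1, -170, 170), runif(1, -80, 80),
                   runif(1, -170, 170)), "YXZ")
}

expect_rotation <- function(R, tol = 1e-9) {
  expect_equal(det(R), 1, tolerance = tol)
  expect_equal(t(R) %*% R, diag(3), tolerance = tol, ignore_attr = TRUE)
}

# hinge fixture: two-point muscle spanning a single revolute joint; the
# planar two-link closed form (law of cosines on the attachment triangle)
# is the independent oracle
hinge_poses <- function(theta_deg, nf = length(theta_deg)) {
  base_R <- array(diag(3), c(3, 3, nf))
  arm_R <- array(NA_real_, c(3, 3, nf))
  arm_t <- matrix(NA_real_, nf, 3)
  for (f in seq_len(nf)) {
    arm_R[, , f] <- rot_axis("Y", theta_deg[f])
    arm_t[f, ] <- c(0, 0, 200)           # joint centre fixed on the base
  }
  mk <- function(seg, R, t) structure(
    list(segment = seg, R = R, t = t, residual = rep(0, nf),
         valid = rep(TRUE, nf), frame_rate = 200, n_frames = nf),
    class = "pose_series")
  list(base = mk("base", base_R, matrix(0, nf, 3)),
       arm = mk("arm", arm_R, arm_t))
}

hinge_muscle <- muscle_path("hinge_m", c("base", "arm"),
                            rbind(c(0, 0, 100), c(80, 0, 0)))

# closed form: origin at global (0,0,100), joint centre at (0,0,200),
# insertion 80 mm from the joint along the arm's rotated X direction
hinge_length_closed_form <- function(theta_deg) {
  th <- theta_deg * pi / 180
  ins <- cbind(80 * cos(th), 0, 200 - 80 * sin(th))
  org <- matrix(rep(c(0, 0, 100), each = length(th)), ncol = 3)
  sqrt(rowSums((ins - org)^2))
}
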