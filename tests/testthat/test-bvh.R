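test_that("minimal BVH fixture parses with correct counts", {
  path <- write_tmp_bvh(minimal_bvh_text())
  b <- read_bvh(path)
  expect_equal(length(b$hierarchy$nodes), 3L)  # 2 joints + 1 end site
  expect_equal(joint_names <- vapply(b$hierarchy$nodes, `[[`, character(1), "name"),
               c("Hips", "Child", "Child_end"))
  expect_equal(dim(b$motion$channel_values), c(2L, 9L))
  expect_equal(b$motion$frame_time, 0.0083333)
  expect_equal(b$hierarchy$root, "Hips")
})

test_that("frame-count mismatch and unknown channels give parse errors", {
  short <- write_tmp_bvh(minimal_bvh_text(n_frames = 10))
  expect_error(read_bvh(short), class = "ehecco_parse_error")
  expect_error(read_bvh(short), "10 frames")
  bad <- write_tmp_bvh(minimal_bvh_text(child_channels = "Zrotation Wrotation Yrotation"))
  expect_error(read_bvh(bad), "unknown channel")
  nomotion <- write_tmp_bvh(minimal_bvh_text()[1:15])
  expect_error(read_bvh(nomotion), "MOTION")
})

test_that("write/read round trip preserves structure and values", {
  cfg <- generator_config(duration_range = c(0.5, 0.7), frame_rate = 60, seed = 4)
  rec <- generate_record(2, 1, cfg, record_seed = 9)
  path <- tempfile(fileext = ".bvh")
  write_bvh(rec$hierarchy, rec$motion, path)
  back <- read_bvh(path)
  expect_equal(back$motion$channel_values, rec$motion$channel_values,
               tolerance = 1e-7)
  expect_equal(back$motion$frame_time, rec$motion$frame_time)
  expect_equal(vapply(back$hierarchy$nodes, `[[`, character(1), "name"),
               vapply(rec$hierarchy$nodes, `[[`, character(1), "name"))
  expect_error(write_bvh(rec$hierarchy,
                         new_motion <- list(channel_values = rec$motion$channel_values[, 1:3],
                                            frame_time = 1 / 60),
                         tempfile()), class = "ehecco_dim_error")
})

test_that("forward kinematics matches analytic cases", {
  # zero rotations: positions are cumulative offsets
  path <- write_tmp_bvh(minimal_bvh_text(frames = c("0 0 0 0 0 0 0 0 0")))
  b <- read_bvh(path)
  p <- forward_kinematics(b$hierarchy, b$motion)
  expect_equal(p$positions[1, 1, ], c(0, 0, 0))
  expect_equal(p$positions[1, 2, ], c(1, 0, 0))
  # 90 degree root Z rotation sends the (1,0,0) bone to (0,1,0)
  path <- write_tmp_bvh(minimal_bvh_text(frames = c("0 0 0 90 0 0 0 0 0")))
  b <- read_bvh(path)
  p <- forward_kinematics(b$hierarchy, b$motion)
  expect_equal(p$positions[1, 2, ], c(0, 1, 0), tolerance = 1e-9)
  # root translation shifts every joint rigidly
  path <- write_tmp_bvh(minimal_bvh_text(frames = c("5 0 0 90 0 0 0 0 0")))
  b <- read_bvh(path)
  p2 <- forward_kinematics(b$hierarchy, b$motion)
  expect_equal(p2$positions[1, , ], p$positions[1, , ] + rep(c(5, 0, 0), each = 2))
})

test_that("declared channel order is respected", {
  # Z-first then X 90/90 differs from X-first then Z 90/90 on the child bone
  zfirst <- read_bvh(write_tmp_bvh(minimal_bvh_text(
    child_channels = "Zrotation Xrotation Yrotation",
    frames = "0 0 0 0 0 0 90 90 0")))
  xfirst <- read_bvh(write_tmp_bvh(minimal_bvh_text(
    child_channels = "Xrotation Zrotation Yrotation",
    frames = "0 0 0 0 0 0 90 90 0")))
  # end-site world position: child at (1,0,0); end-site offset (0,2,0)
  # Rz(90)Rx(90): (0,2,0) -> Rx: (0,0,2) -> Rz: (0,0,2)
  # Rx(90)Rz(90): (0,2,0) -> Rz: (-2,0,0) -> Rx: (-2,0,0)
  fk_end <- function(b) {
    nodes <- b$hierarchy$nodes
    # recompute via full FK on a hierarchy where the end site is a joint
    nodes[[3]]$end_site <- FALSE
    h2 <- ehecco:::new_skeleton(nodes, b$hierarchy$root)
    forward_kinematics(h2, b$motion)$positions[1, 3, ]
  }
  expect_equal(fk_end(zfirst), c(1, 0, 2), tolerance = 1e-9)
  expect_equal(fk_end(xfirst), c(-1, 0, 0), tolerance = 1e-9)
})

test_that("extra root rotation rotates all world positions rigidly", {
  cfg <- generator_config(duration_range = c(0.3, 0.4), frame_rate = 60,
                          noise_sd = 0, seed = 2)
  rec <- generate_record(1, 1, cfg, record_seed = 5)
  # zero out root translation and the root X/Y rotations so the root rotation
  # is a pure Z rotation we can increment analytically
  m <- rec$motion
  m$channel_values[, c(1:3, 5, 6)] <- 0
  p0 <- forward_kinematics(rec$hierarchy, m)
  m2 <- m
  m2$channel_values[, 4] <- m$channel_values[, 4] + 90
  p1 <- forward_kinematics(rec$hierarchy, m2)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
  for (f in c(1, nrow(m$channel_values))) {
    rotated <- t(Rz %*% t(p0$positions[f, , ]))
    expect_equal(p1$positions[f, , ], rotated, tolerance = 1e-9)
  }
})

test_that("hip normalization centers the root and preserves shape", {
  cfg <- generator_config(duration_range = c(0.3, 0.4), frame_rate = 60, seed = 3)
  rec <- generate_record(1, 1, cfg, record_seed = 6)
  p <- forward_kinematics(rec$hierarchy, rec$motion)
  hn <- hip_normalize(p)
  expect_equal(max(abs(hn$positions[, 1, ])), 0)
  # inter-joint difference vectors unchanged frame-wise
  expect_equal(hn$positions[, 5, ] - hn$positions[, 2, ],
               p$positions[, 5, ] - p$positions[, 2, ], tolerance = 1e-12)
  # idempotent
  expect_equal(hip_normalize(hn)$positions, hn$positions)
  expect_error(hip_normalize(p, "NoSuchJoint"), class = "ehecco_validation_error")
})

test_that("hip normalization removes injected constant root translation", {
  cfg <- generator_config(duration_range = c(0.3, 0.4), frame_rate = 60,
                          noise_sd = 0, seed = 8)
  rec <- generate_record(1, 1, cfg, record_seed = 11)
  shifted <- rec$motion
  shifted$channel_values[, 1:3] <- sweep(shifted$channel_values[, 1:3], 2,
                                         c(250, -80, 31), "+")
  a <- flatten_poses(hip_normalize(forward_kinematics(rec$hierarchy, rec$motion)))
  b <- flatten_poses(hip_normalize(forward_kinematics(rec$hierarchy, shifted)))
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("flatten and unflatten are exact inverses with the documented layout", {
  pos <- array(0, c(1, 2, 3))
  pos[1, 1, ] <- c(1, 2, 3); pos[1, 2, ] <- c(4, 5, 6)
  p <- ehecco:::new_pose_sequence(pos, c("A", "B"), 1 / 60)
  M <- flatten_poses(p)
  expect_equal(dim(M), c(1L, 6L))
  expect_equal(unname(M[1, ]), 1:6 + 0)
  back <- unflatten_poses(M, p$joint_names, p$frame_time)
  expect_equal(back$positions, p$positions)
})

test_that("pose CSV export is tidy", {
  pos <- array(rnorm(12), c(2, 2, 3))
  p <- ehecco:::new_pose_sequence(pos, c("A", "B"), 1 / 60)
  path <- tempfile(fileext = ".csv")
  write_pose_csv(p, path)
  df <- read.csv(path)
  expect_equal(names(df), c("frame", "joint", "x", "y", "z"))
  expect_equal(nrow(df), 4L)
  expect_equal(df$x[df$frame == 1 & df$joint == "B"], pos[1, 2, 1])
})
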