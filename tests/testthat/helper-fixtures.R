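# Shared fixture builders for the test suite. Everything is generated in
# code; nothing is read from disk except files the tests themselves write.

# Random weighted sample set with optional non-uniform weights.
random_wss <- function(n, V, Q, uniform = TRUE) {
  w <- if (uniform) NULL else {
    raw <- stats::runif(n) + 0.05
    raw / sum(raw)
  }
  weighted_sample_set(matrix(stats::rnorm(n * V), n),
                      matrix(stats::rnorm(n * Q), n), w)
}

# Minimal two-joint BVH file text (root with 6 channels, one child with 3,
# an End Site, 2 frames). Channel order of the child is configurable.
minimal_bvh_text <- function(child_channels = "Zrotation Xrotation Yrotation",
                             frames = c("0 0 0 0 0 0 0 0 0",
                                        "1 2 3 10 20 30 5 15 25"),
                             n_frames = length(frames)) {
  c("HIERARCHY",
    "ROOT Hips",
    "{",
    "  OFFSET 0 0 0",
    "  CHANNELS 6 Xposition Yposition Zposition Zrotation Xrotation Yrotation",
    "  JOINT Child",
    "  {",
    "    OFFSET 1 0 0",
    paste0("    CHANNELS 3 ", child_channels),
    "    End Site",
    "    {",
    "      OFFSET 0 2 0",
    "    }",
    "  }",
    "}",
    "MOTION",
    paste("Frames:", n_frames),
    "Frame Time: 0.0083333",
    frames)
}

write_tmp_bvh <- function(lines) {
  path <- tempfile(fileext = ".bvh")
  writeLines(lines, path)
  path
}

# Small synthetic dataset shared by pipeline tests (kept tiny for speed).
tiny_dataset <- function(seed = 7, n_classes = 3, n_subjects = 2, reps = 4,
                         class_separation = 1) {
  generate_dataset(generator_config(
    n_classes = n_classes, n_subjects = n_subjects, reps_per_cell = reps,
    duration_range = c(1, 1.5), frame_rate = 60,
    class_separation = class_separation, seed = seed))
}
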