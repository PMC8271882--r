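# Synthetic articulated-skeleton motion generator: labeled, multi-class,
# multi-subject records with controllable class separation, subject style,
# per-frame jitter, and subject covariates linked to the hidden style
# parameter. Kinematics are sinusoidal so every channel has a closed-form
# ground truth for oracle tests, and the cyclic structure mimics repeated
# actions (a subject performing the same movement several times).

#' Generator configuration
#'
#' Bundles the knobs of the synthetic motion-capture generator.
#'
#' @param n_classes number of action classes.
#' @param n_subjects number of subjects.
#' @param reps_per_cell records per (class, subject) cell.
#' @param n_joints articulated joint count of the skeleton (template needs
#'   >= 13; smaller values fall back to a simple chain).
#' @param frame_rate frames per second.
#' @param duration_range (min, max) record duration in seconds; each record's
#'   duration is drawn uniformly from this range, so records differ in length.
#' @param class_separation scale (>= 0) of the between-class differences of
#'   the per-channel motion parameters; 0 removes all class signal.
#' @param style_scale scale (>= 0) of the subject-level posture offsets; each
#'   subject carries a hidden scalar style drawn once, shifting rotation
#'   offsets in a fixed channel direction — the same subject "performs every
#'   action their own way".
#' @param noise_sd per-frame, per-channel Gaussian jitter (degrees).
#' @param seed master seed; all record-level seeds derive from it, so
#'   subsetting a dataset never changes the surviving records.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_classes = 5L, n_subjects = 4L, reps_per_cell = 5L,
                             n_joints = 15L, frame_rate = 120,
                             duration_range = c(2, 4),
                             class_separation = 1, style_scale = 1,
                             noise_sd = 2, seed = 0L) {
  stopifnot(n_classes >= 1L, n_subjects >= 1L, reps_per_cell >= 1L,
            n_joints >= 2L, frame_rate > 0,
            length(duration_range) == 2L, duration_range[1] > 0,
            duration_range[2] >= duration_range[1],
            class_separation >= 0, style_scale >= 0, noise_sd >= 0)
  structure(list(n_classes = as.integer(n_classes),
                 n_subjects = as.integer(n_subjects),
                 reps_per_cell = as.integer(reps_per_cell),
                 n_joints = as.integer(n_joints), frame_rate = frame_rate,
                 duration_range = duration_range,
                 class_separation = class_separation,
                 style_scale = style_scale, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Deterministic humanoid-like skeleton
#'
#' Builds a fixed joint tree: hip root, two three-joint legs, a spine chain
#' (absorbing any joints beyond the 13 the template requires), a head, and
#' two two-joint arms, with End Sites on the head, elbows, and feet. The root
#' carries six channels (3 positions + 3 rotations); every other joint
#' carries three rotation channels. Offsets are in centimeters.
#'
#' @param n_joints articulated joint count; values below 13 fall back to a
#'   simple kinematic chain with a warning.
#' @return a `skeleton_hierarchy`.
#' @export
make_skeleton <- function(n_joints = 15L) {
  n_joints <- as.integer(n_joints)
  if (n_joints < 2L) stop_validation("a skeleton needs at least 2 joints")
  rot3 <- c("Zrotation", "Xrotation", "Yrotation")
  root6 <- c("Xposition", "Yposition", "Zposition", rot3)
  nodes <- list()
  add <- function(name, parent, offset, channels, end_site = FALSE)
    nodes[[length(nodes) + 1L]] <<- list(name = name, parent = parent,
                                         offset = offset, channels = channels,
                                         end_site = end_site)
  if (n_joints < 13L) {
    warning(sprintf("n_joints = %d too small for the humanoid template; using a chain",
                    n_joints))
    add("Hips", NA_character_, c(0, 0, 0), root6)
    for (k in 2:n_joints)
      add(sprintf("Joint%d", k), if (k == 2L) "Hips" else sprintf("Joint%d", k - 1L),
          c(0, 10, 0), rot3)
    add(sprintf("Joint%d_end", n_joints), sprintf("Joint%d", n_joints),
        c(0, 10, 0), character(0), end_site = TRUE)
    return(new_skeleton(nodes, "Hips"))
  }
  n_spine <- n_joints - 13L        # segments between hips and chest (>= 0)
  add("Hips", NA_character_, c(0, 0, 0), root6)
  for (side in c("L", "R")) {
    sgn <- if (side == "L") 1 else -1
    add(paste0(side, "UpLeg"), "Hips", c(sgn * 9, -2, 0), rot3)
    add(paste0(side, "LowLeg"), paste0(side, "UpLeg"), c(0, -40, 0), rot3)
    add(paste0(side, "Foot"), paste0(side, "LowLeg"), c(0, -40, 0), rot3)
    add(paste0(side, "Foot_end"), paste0(side, "Foot"), c(0, -6, 13),
        character(0), end_site = TRUE)
  }
  prev <- "Hips"
  for (k in seq_len(n_spine)) {
    nm <- if (n_spine == 1L) "Spine" else sprintf("Spine%d", k)
    add(nm, prev, c(0, 44 / max(n_spine, 1L), 0), rot3)
    prev <- nm
  }
  add("Chest", prev, c(0, 16, 0), rot3)
  add("Head", "Chest", c(0, 14, 0), rot3)
  add("Head_end", "Head", c(0, 12, 0), character(0), end_site = TRUE)
  for (side in c("L", "R")) {
    sgn <- if (side == "L") 1 else -1
    add(paste0(side, "Shoulder"), "Chest", c(sgn * 17, 4, 0), rot3)
    add(paste0(side, "Elbow"), paste0(side, "Shoulder"), c(sgn * 27, 0, 0), rot3)
    add(paste0(side, "Elbow_end"), paste0(side, "Elbow"), c(sgn * 25, 0, 0),
        character(0), end_site = TRUE)
  }
  new_skeleton(nodes, "Hips")
}

# Channel metadata for a skeleton: name, kind (position/rotation), in motion
# column order.
channel_table <- function(hierarchy) {
  rows <- do.call(rbind, lapply(hierarchy$nodes, function(n) {
    if (length(n$channels) == 0L) return(NULL)
    data.frame(joint = n$name, channel = n$channels,
               kind = ifelse(endsWith(n$channels, "position"), "position", "rotation"),
               stringsAsFactors = FALSE)
  }))
  rows
}

# Fixed per-channel baseline sinusoid parameters (amplitude deg or cm,
# frequency Hz, phase rad, offset). Deterministic given the channel count;
# independent of class, subject and the dataset seed.
base_channel_params <- function(ct) {
  nc <- nrow(ct)
  with_seed(123451L, {
    rot <- ct$kind == "rotation"
    data.frame(
      amp    = ifelse(rot, stats::runif(nc, 8, 25), stats::runif(nc, 2, 8)),
      freq   = ifelse(rot, stats::runif(nc, 0.5, 1.5), stats::runif(nc, 0.05, 0.25)),
      phase  = stats::runif(nc, 0, 2 * pi),
      offset = ifelse(rot, stats::runif(nc, -10, 10), stats::runif(nc, -15, 15)) +
        ifelse(ct$channel == "Yposition", 95, 0))
  })
}

# Per-class parameter deviations, scaled by class_separation downstream.
class_channel_deltas <- function(class_id, n_channels) {
  with_seed(derive_seed(987654L, class_id), data.frame(
    amp    = stats::runif(n_channels, -7, 7),
    freq   = stats::runif(n_channels, -0.35, 0.35),
    phase  = stats::runif(n_channels, -pi / 2, pi / 2),
    offset = stats::runif(n_channels, -8, 8)))
}

# Fixed unit-scale direction along which a subject's style shifts the
# rotation-channel offsets (position channels are untouched so global
# placement carries no style signal).
style_direction <- function(ct) {
  u <- with_seed(424242L, stats::rnorm(nrow(ct)))
  u[ct$kind == "position"] <- 0
  u
}

# Hidden per-subject style scalar, deterministic given (config seed, subject).
subject_style <- function(config, subject_id) {
  with_seed(derive_seed(config$seed, 500000L + subject_id), stats::rnorm(1))
}

#' Generate one synthetic motion record
#'
#' Every rotation channel follows \eqn{A \sin(2\pi f t + \varphi) + c} where
#' the parameters combine a fixed per-channel baseline, a per-class deviation
#' scaled by `class_separation`, and a subject-style posture shift of the
#' offsets scaled by `style_scale`, plus independent per-frame Gaussian
#' jitter of `noise_sd` degrees. Root translation channels follow a slow
#' class-independent sinusoidal drift so that hip-based normalization is
#' exercised. Record duration is drawn uniformly from `duration_range`.
#'
#' @param class_id class index in 1..n_classes.
#' @param subject_id subject index in 1..n_subjects.
#' @param config a [generator_config()].
#' @param record_seed integer seed for this record's duration and jitter.
#' @param hierarchy optionally a pre-built skeleton (must match
#'   `config$n_joints`); avoids rebuilding it per record.
#' @return list with `hierarchy` and `motion`.
#' @export
generate_record <- function(class_id, subject_id, config, record_seed,
                            hierarchy = NULL) {
  stopifnot(inherits(config, "generator_config"),
            class_id >= 1L, class_id <= config$n_classes,
            subject_id >= 1L, subject_id <= config$n_subjects)
  if (is.null(hierarchy)) hierarchy <- make_skeleton(config$n_joints)
  ct <- channel_table(hierarchy)
  base <- base_channel_params(ct)
  delta <- class_channel_deltas(class_id, nrow(ct))
  u <- style_direction(ct)
  style <- subject_style(config, subject_id)

  amp   <- base$amp   + config$class_separation * delta$amp
  freq  <- pmax(base$freq + config$class_separation * delta$freq, 0.05)
  phase <- base$phase + config$class_separation * delta$phase
  off   <- base$offset + config$class_separation * delta$offset +
    config$style_scale * style * 8 * u

  with_seed(record_seed, {
    duration <- stats::runif(1, config$duration_range[1], config$duration_range[2])
    T_ <- max(2L, as.integer(round(duration * config$frame_rate)))
    t <- (seq_len(T_) - 1L) / config$frame_rate
    vals <- vapply(seq_len(nrow(ct)), function(ch)
      amp[ch] * sin(2 * pi * freq[ch] * t + phase[ch]) + off[ch], numeric(T_))
    if (config$noise_sd > 0)
      vals <- vals + matrix(stats::rnorm(length(vals), 0, config$noise_sd),
                            nrow = T_)
    list(hierarchy = hierarchy,
         motion = new_motion(vals, 1 / config$frame_rate))
  })
}

#' Generate a full labeled synthetic dataset
#'
#' Produces the complete factorial design classes x subjects x repetitions,
#' together with a per-subject covariate table holding one "size-like" column
#' with a known linear dependence on the hidden subject style
#' (wingspan_cm = 12 * style + 180 + N(0, 1)) and three independent Gaussian
#' distractor columns. Record seeds are derived hierarchically from the
#' master seed, so regenerating with the same config is byte-identical and
#' subsetting never changes surviving records.
#'
#' @param config a [generator_config()].
#' @param dir optional directory; when given, records are written as BVH
#'   files together with `labels.csv` (record, class, subject) and
#'   `covariates.csv` (subject plus covariate columns).
#' @return list of class `synthetic_mocap_dataset`: `records` (each a
#'   hierarchy/motion pair), `labels`, `subject_ids`, `covariates`
#'   (data.frame), `styles` (the hidden per-subject style scalars, exposed
#'   for validation), `config`.
#' @export
generate_dataset <- function(config = generator_config(), dir = NULL) {
  hierarchy <- make_skeleton(config$n_joints)
  grid <- expand.grid(rep = seq_len(config$reps_per_cell),
                      subject = seq_len(config$n_subjects),
                      class = seq_len(config$n_classes))
  records <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    records[[i]] <- generate_record(grid$class[i], grid$subject[i], config,
                                    record_seed = derive_seed(config$seed, i),
                                    hierarchy = hierarchy)
  }
  styles <- vapply(seq_len(config$n_subjects),
                   function(s) subject_style(config, s), numeric(1))
  covariates <- with_seed(derive_seed(config$seed, 900001L), data.frame(
    subject = paste0("subject_", seq_len(config$n_subjects)),
    wingspan_cm = 12 * styles + 180 + stats::rnorm(config$n_subjects, 0, 1),
    age_yr = stats::rnorm(config$n_subjects, 25, 5),
    mass_kg = stats::rnorm(config$n_subjects, 70, 10),
    cephalic_cm = stats::rnorm(config$n_subjects, 56, 2)))
  out <- structure(list(records = records,
                        labels = paste0("class_", grid$class),
                        subject_ids = paste0("subject_", grid$subject),
                        covariates = covariates,
                        styles = styles,
                        config = config),
                   class = "synthetic_mocap_dataset")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(records))
      write_bvh(records[[i]]$hierarchy, records[[i]]$motion,
                file.path(dir, sprintf("record_%03d.bvh", i)))
    utils::write.csv(data.frame(record = sprintf("record_%03d.bvh", seq_along(records)),
                                class = out$labels, subject = out$subject_ids),
                     file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(covariates, file.path(dir, "covariates.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  out
}

#' @export
print.synthetic_mocap_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_mocap_dataset> %d records: %d classes x %d subjects x %d reps\n",
              length(x$records), x$config$n_classes, x$config$n_subjects,
              x$config$reps_per_cell))
  invisible(x)
}

#' Paired records with identical marginals but opposite limb coupling
#'
#' Emits two classes of records whose per-channel marginal distributions
#' match while their inter-limb dependence differs: arm rotation channels on
#' both sides share amplitudes and frequencies, but in the `in_phase` class
#' the right-arm channels move in phase with the left, and in the
#' `anti_phase` class they are shifted by half a cycle. Because a sinusoid's
#' value distribution over whole cycles is invariant to its phase, each
#' single channel looks the same in both classes; only the joint structure
#' across channels distinguishes them. This is the motion-domain analogue of
#' comparing the joint laws of (X, +X) and (X, -X).
#'
#' @param n_per_class records per class.
#' @param n_joints skeleton size (>= 13 for the humanoid template).
#' @param frame_rate frames per second.
#' @param n_cycles whole movement cycles per record (duration = n_cycles / f).
#' @param noise_sd per-frame jitter in degrees.
#' @param seed master seed.
#' @return list with `records` and `labels` (`"in_phase"` / `"anti_phase"`).
#' @export
generate_coupled_records <- function(n_per_class = 10L, n_joints = 15L,
                                     frame_rate = 60, n_cycles = 3L,
                                     noise_sd = 0.5, seed = 0L) {
  hierarchy <- make_skeleton(n_joints)
  ct <- channel_table(hierarchy)
  base <- base_channel_params(ct)
  right_arm <- grepl("^R(Shoulder|Elbow)", ct$joint)
  f0 <- 1.0
  records <- list(); labels <- character(0)
  idx <- 0L
  for (cls in c("in_phase", "anti_phase")) {
    for (r in seq_len(n_per_class)) {
      idx <- idx + 1L
      records[[idx]] <- with_seed(derive_seed(seed, idx), {
        T_ <- as.integer(round(n_cycles / f0 * frame_rate))
        t <- (seq_len(T_) - 1L) / frame_rate
        phase0 <- stats::runif(1, 0, 2 * pi)   # random global phase per record
        phase <- rep(phase0, nrow(ct))
        if (cls == "anti_phase") phase[right_arm] <- phase0 + pi
        vals <- vapply(seq_len(nrow(ct)), function(ch)
          base$amp[ch] * sin(2 * pi * f0 * t + phase[ch]) + base$offset[ch],
          numeric(T_))
        if (noise_sd > 0)
          vals <- vals + matrix(stats::rnorm(length(vals), 0, noise_sd), nrow = T_)
        list(hierarchy = hierarchy, motion = new_motion(vals, 1 / frame_rate))
      })
      labels <- c(labels, cls)
    }
  }
  list(records = records, labels = labels)
}
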