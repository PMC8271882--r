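# BVH (Biovision Hierarchy) motion-capture I/O, forward kinematics, and the
# hip-based pose normalization applied before any distance computation.

ALLOWED_CHANNELS <- c("Xposition", "Yposition", "Zposition",
                      "Xrotation", "Yrotation", "Zrotation")

new_skeleton <- function(nodes, root) {
  structure(list(nodes = nodes, root = root), class = "skeleton_hierarchy")
}

#' @export
print.skeleton_hierarchy <- function(x, ...) {
  art <- !vapply(x$nodes, `[[`, logical(1), "end_site")
  cat(sprintf("<skeleton_hierarchy> root '%s', %d joints (+%d end sites), %d channels\n",
              x$root, sum(art), sum(!art), total_channels(x)))
  invisible(x)
}

total_channels <- function(hierarchy) {
  sum(vapply(hierarchy$nodes, function(n) length(n$channels), integer(1)))
}

joint_names <- function(hierarchy, include_end_sites = FALSE) {
  keep <- vapply(hierarchy$nodes,
                 function(n) include_end_sites || !n$end_site, logical(1))
  vapply(hierarchy$nodes[keep], `[[`, character(1), "name")
}

new_motion <- function(channel_values, frame_time) {
  if (!is.matrix(channel_values) || nrow(channel_values) < 1L)
    stop_validation("motion must have at least one frame")
  if (!is.numeric(frame_time) || frame_time <= 0)
    stop_validation("frame_time must be positive")
  structure(list(channel_values = channel_values, frame_time = frame_time),
            class = "motion_sequence")
}

new_pose_sequence <- function(positions, joint_names, frame_time) {
  structure(list(positions = positions, joint_names = joint_names,
                 frame_time = frame_time),
            class = "pose_sequence")
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence> %d frames x %d joints (%.1f fps)\n",
              dim(x$positions)[1], dim(x$positions)[2], 1 / x$frame_time))
  invisible(x)
}

parse_error <- function(line, msg) {
  stop(errorCondition(sprintf("BVH parse error at line %d: %s", line, msg),
                      class = c("ehecco_parse_error", "ehecco_error")))
}

#' Read a BVH motion-capture file
#'
#' Parses the text BVH dialect: a `HIERARCHY` section describing the joint
#' tree (per-joint `OFFSET` and `CHANNELS`, `End Site` leaves) followed by a
#' `MOTION` section with one row of channel values per frame. Rotations are
#' stored in degrees and any declared channel order (e.g. Zrotation-first or
#' Xrotation-first) is respected. End Site nodes are retained in the
#' hierarchy as zero-channel leaves.
#'
#' @param path path to a BVH file.
#' @return list with components `hierarchy` (class `skeleton_hierarchy`) and
#'   `motion` (class `motion_sequence`, with `channel_values` a T x C matrix
#'   and `frame_time` in seconds).
#' @seealso [write_bvh()], [forward_kinematics()]
#' @export
read_bvh <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  pos <- new.env(parent = emptyenv())
  pos$i <- 1L

  next_tokens <- function() {
    while (pos$i <= length(lines)) {
      tok <- strsplit(trimws(lines[[pos$i]]), "\\s+")[[1]]
      if (length(tok) > 0L && nzchar(tok[1])) return(tok)
      pos$i <- pos$i + 1L
    }
    NULL
  }
  advance <- function() pos$i <- pos$i + 1L
  expect <- function(word) {
    tok <- next_tokens()
    if (is.null(tok) || toupper(tok[1]) != toupper(word))
      parse_error(min(pos$i, length(lines)), sprintf("expected '%s'", word))
    advance()
    tok
  }

  nodes <- list()
  seen <- character(0)

  parse_node <- function(kind, parent) {
    tok <- next_tokens()
    line0 <- pos$i
    if (kind == "End Site") {
      name <- paste0(parent, "_end")
      k <- 1L
      while (name %in% seen) { name <- paste0(parent, "_end", k); k <- k + 1L }
      advance()  # 'End Site' line
      expect("{")
    } else {
      if (length(tok) < 2L) parse_error(line0, sprintf("%s requires a name", kind))
      name <- tok[2]
      if (name %in% seen) parse_error(line0, sprintf("duplicate joint name '%s'", name))
      advance()
      expect("{")
    }
    seen <<- c(seen, name)
    tok <- expect("OFFSET")
    if (length(tok) != 4L) parse_error(line0, "OFFSET requires 3 values")
    offset <- as.numeric(tok[2:4])
    if (any(!is.finite(offset))) parse_error(line0, "non-finite OFFSET")
    channels <- character(0)
    tok <- next_tokens()
    if (!is.null(tok) && toupper(tok[1]) == "CHANNELS") {
      nch <- suppressWarnings(as.integer(tok[2]))
      if (is.na(nch) || length(tok) != 2L + nch)
        parse_error(pos$i, "CHANNELS count does not match listed names")
      channels <- tok[3:(2 + nch)]
      bad <- setdiff(channels, ALLOWED_CHANNELS)
      if (length(bad) > 0L)
        parse_error(pos$i, sprintf("unknown channel name(s): %s", paste(bad, collapse = ", ")))
      advance()
    }
    nodes[[length(nodes) + 1L]] <<- list(name = name, parent = parent,
                                         offset = offset, channels = channels,
                                         end_site = kind == "End Site")
    repeat {
      tok <- next_tokens()
      if (is.null(tok)) parse_error(length(lines), "unexpected end of file in hierarchy")
      key <- toupper(tok[1])
      if (key == "JOINT") {
        parse_node("JOINT", name)
      } else if (key == "END") {
        parse_node("End Site", name)
      } else if (tok[1] == "}") {
        advance()
        break
      } else parse_error(pos$i, sprintf("unexpected token '%s'", tok[1]))
    }
    name
  }

  expect("HIERARCHY")
  tok <- next_tokens()
  if (is.null(tok) || toupper(tok[1]) != "ROOT")
    parse_error(pos$i, "expected ROOT")
  root <- parse_node("ROOT", NA_character_)
  hierarchy <- new_skeleton(nodes, root)

  tok <- next_tokens()
  if (is.null(tok) || toupper(tok[1]) != "MOTION")
    parse_error(min(pos$i, length(lines)), "missing MOTION section")
  advance()
  tok <- expect("Frames:")
  n_frames <- suppressWarnings(as.integer(tok[2]))
  if (is.na(n_frames) || n_frames < 1L) parse_error(pos$i - 1L, "invalid Frames count")
  tok <- next_tokens()
  if (is.null(tok) || toupper(tok[1]) != "FRAME" || toupper(tok[2]) != "TIME:")
    parse_error(pos$i, "expected 'Frame Time:'")
  frame_time <- as.numeric(tok[3])
  if (!is.finite(frame_time) || frame_time <= 0)
    parse_error(pos$i, "invalid Frame Time")
  advance()

  C <- total_channels(hierarchy)
  rows <- matrix(NA_real_, n_frames, C)
  for (f in seq_len(n_frames)) {
    tok <- next_tokens()
    if (is.null(tok))
      parse_error(length(lines),
                  sprintf("header declares %d frames but only %d data rows found",
                          n_frames, f - 1L))
    vals <- suppressWarnings(as.numeric(tok))
    if (length(vals) != C || any(is.na(vals)))
      parse_error(pos$i, sprintf("frame row has %d values, expected %d channels",
                                 length(tok), C))
    rows[f, ] <- vals
    advance()
  }
  list(hierarchy = hierarchy, motion = new_motion(rows, frame_time))
}

#' Write a BVH motion-capture file
#'
#' Serializes a hierarchy/motion pair to standard BVH text. Numeric fields are
#' written with 10 significant digits so that a write/read round trip
#' reproduces channel values well within 1e-6.
#'
#' @param hierarchy `skeleton_hierarchy`.
#' @param motion `motion_sequence` whose channel count matches the hierarchy.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bvh <- function(hierarchy, motion, path) {
  C <- total_channels(hierarchy)
  if (ncol(motion$channel_values) != C)
    stop_dim(sprintf("motion has %d channels but hierarchy requires %d",
                     ncol(motion$channel_values), C))
  num <- function(x) sprintf("%.10g", x)
  out <- c("HIERARCHY")
  children_of <- function(parent)
    Filter(function(n) identical(n$parent, parent), hierarchy$nodes)
  emit <- function(node, depth) {
    ind <- strrep("  ", depth)
    if (node$end_site) {
      out <<- c(out, paste0(ind, "End Site"), paste0(ind, "{"),
                paste0(ind, "  OFFSET ", paste(num(node$offset), collapse = " ")),
                paste0(ind, "}"))
      return(invisible(NULL))
    }
    kind <- if (is.na(node$parent)) "ROOT" else "JOINT"
    out <<- c(out, paste0(ind, kind, " ", node$name), paste0(ind, "{"),
              paste0(ind, "  OFFSET ", paste(num(node$offset), collapse = " ")))
    if (length(node$channels) > 0L)
      out <<- c(out, paste0(ind, "  CHANNELS ", length(node$channels), " ",
                            paste(node$channels, collapse = " ")))
    for (child in children_of(node$name)) emit(child, depth + 1L)
    out <<- c(out, paste0(ind, "}"))
  }
  rootnode <- Filter(function(n) is.na(n$parent), hierarchy$nodes)[[1]]
  emit(rootnode, 0L)
  out <- c(out, "MOTION",
           sprintf("Frames: %d", nrow(motion$channel_values)),
           sprintf("Frame Time: %.10g", motion$frame_time),
           apply(motion$channel_values, 1L,
                 function(r) paste(num(r), collapse = " ")))
  writeLines(out, path)
  invisible(path)
}

rot_mat <- function(axis, deg) {
  a <- deg * pi / 180
  c <- cos(a); s <- sin(a)
  switch(axis,
         X = matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3),
         Y = matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3),
         Z = matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3))
}

#' World-space joint positions by forward kinematics
#'
#' Composes each joint's local transform (fixed offset translation, then the
#' file's position channels, then its rotation channels interpreted as
#' intrinsic rotations applied in the declared channel order, in degrees) down
#' the skeleton tree to obtain per-frame world coordinates of every
#' articulated joint. End Sites carry no motion channels and are excluded
#' from the returned pose sequence.
#'
#' @param hierarchy `skeleton_hierarchy`.
#' @param motion matching `motion_sequence`.
#' @return a `pose_sequence`: `positions` is a T x J x 3 array in the file's
#'   length units, `joint_names` the J articulated joint names.
#' @export
forward_kinematics <- function(hierarchy, motion) {
  C <- total_channels(hierarchy)
  if (ncol(motion$channel_values) != C)
    stop_dim(sprintf("motion has %d channels but hierarchy requires %d",
                     ncol(motion$channel_values), C))
  nodes <- hierarchy$nodes
  n_nodes <- length(nodes)
  ch_offset <- cumsum(c(0L, vapply(nodes, function(n) length(n$channels),
                                   integer(1))))[seq_len(n_nodes)]
  parent_idx <- match(vapply(nodes, `[[`, character(1), "parent"),
                      vapply(nodes, `[[`, character(1), "name"))
  art <- which(!vapply(nodes, `[[`, logical(1), "end_site"))
  T_ <- nrow(motion$channel_values)
  positions <- array(NA_real_, c(T_, length(art), 3L))

  for (f in seq_len(T_)) {
    row <- motion$channel_values[f, ]
    world_R <- vector("list", n_nodes)
    world_p <- vector("list", n_nodes)
    for (k in seq_len(n_nodes)) {
      node <- nodes[[k]]
      trans <- node$offset
      R <- diag(3)
      for (ci in seq_along(node$channels)) {
        ch <- node$channels[ci]
        val <- row[ch_offset[k] + ci]
        ax <- substr(ch, 1L, 1L)
        if (endsWith(ch, "position")) {
          trans[match(ax, c("X", "Y", "Z"))] <- trans[match(ax, c("X", "Y", "Z"))] + val
        } else {
          R <- R %*% rot_mat(ax, val)
        }
      }
      if (is.na(parent_idx[k])) {
        world_p[[k]] <- trans
        world_R[[k]] <- R
      } else {
        p <- parent_idx[k]
        world_p[[k]] <- world_p[[p]] + drop(world_R[[p]] %*% trans)
        world_R[[k]] <- world_R[[p]] %*% R
      }
    }
    for (jj in seq_along(art)) positions[f, jj, ] <- world_p[[art[jj]]]
  }
  new_pose_sequence(positions, joint_names(hierarchy), motion$frame_time)
}

#' Hip-based pose normalization
#'
#' Subtracts the root (hip) joint's position from every joint in every frame,
#' removing global translation so that records are compared by posture and
#' movement rather than by where in the capture volume they were performed.
#' Only translation is removed — orientation and body size are deliberately
#' preserved, since anthropometric analysis relies on size information.
#' The operation is idempotent.
#'
#' @param poses a `pose_sequence`.
#' @param root_joint name of the reference joint; defaults to the first joint
#'   (the BVH root, the hip/pelvis in common skeletons).
#' @return normalized `pose_sequence` with the root at the origin everywhere.
#' @export
hip_normalize <- function(poses, root_joint = NULL) {
  if (is.null(root_joint)) root_joint <- poses$joint_names[1]
  j <- match(root_joint, poses$joint_names)
  if (is.na(j))
    stop_validation(sprintf("unknown joint '%s'; available: %s", root_joint,
                            paste(poses$joint_names, collapse = ", ")))
  pos <- poses$positions
  for (d in 1:3) pos[, , d] <- pos[, , d] - pos[, j, d]
  new_pose_sequence(pos, poses$joint_names, poses$frame_time)
}

#' Flatten a pose sequence to a frame matrix
#'
#' Row t of the result is the concatenation (x1, y1, z1, ..., xJ, yJ, zJ) of
#' frame t's joint coordinates, giving the V = 3J dimensional vectors on
#' which codebooks, the latent basis, and the primary-space kernel operate.
#' `unflatten_poses()` is the exact inverse.
#'
#' @param poses a `pose_sequence`.
#' @return T x 3J numeric matrix.
#' @export
flatten_poses <- function(poses) {
  pos <- poses$positions
  T_ <- dim(pos)[1]; J <- dim(pos)[2]
  out <- matrix(NA_real_, T_, 3L * J)
  for (j in seq_len(J)) out[, (3L * j - 2L):(3L * j)] <- pos[, j, ]
  colnames(out) <- paste0(rep(poses$joint_names, each = 3L), "_", c("x", "y", "z"))
  out
}

#' @rdname flatten_poses
#' @param mat T x 3J matrix as produced by `flatten_poses()`.
#' @param joint_names J joint names.
#' @param frame_time seconds per frame.
#' @export
unflatten_poses <- function(mat, joint_names, frame_time) {
  J <- length(joint_names)
  if (ncol(mat) != 3L * J)
    stop_dim(sprintf("matrix has %d columns, expected 3 x %d joints", ncol(mat), J))
  pos <- array(NA_real_, c(nrow(mat), J, 3L))
  for (j in seq_len(J)) pos[, j, ] <- mat[, (3L * j - 2L):(3L * j)]
  new_pose_sequence(pos, joint_names, frame_time)
}

#' Export a pose sequence as tidy CSV
#'
#' Writes one row per frame/joint with columns frame, joint, x, y, z.
#'
#' @param poses a `pose_sequence`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(poses, path) {
  T_ <- dim(poses$positions)[1]; J <- dim(poses$positions)[2]
  df <- data.frame(
    frame = rep(seq_len(T_), times = J),
    joint = rep(poses$joint_names, each = T_),
    x = as.vector(poses$positions[, , 1]),
    y = as.vector(poses$positions[, , 2]),
    z = as.vector(poses$positions[, , 3]))
  df <- df[order(df$frame), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
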