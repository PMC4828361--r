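#' Load a skeleton + muscle model configuration
#'
#' The configuration is a YAML (or JSON) tree describing the rigid-segment
#' model: for each segment its parent, the location of its proximal joint
#' centre in the parent's local frame (`joint_offset`, mm), the Cardan
#' `sequence` used to report its joint angles, and its template markers in
#' segment-local coordinates (mm). Each segment's local frame has its origin
#' at the proximal joint centre and is axis-aligned with the global frame
#' (X anterior, Y left, Z up) in the neutral standing posture, so the neutral
#' pose of every segment is the identity rotation.
#'
#' A template may include markers physically generated by a neighbouring
#' segment (e.g. a marker at a joint centre, rigid in both frames); the
#' `owns` list names the markers whose trajectories belong to this segment.
#' Muscles are ordered polylines of attachment points, each point expressed
#' in one segment's local frame.
#'
#' @param path path to a YAML/JSON model file.
#' @return a list with components `model` (a `skeleton_model`) and `muscles`
#'   (named list of `muscle_path` objects).
#' @examples
#' cfg <- load_model_config(default_model_path())
#' cfg$model
#' names(cfg$muscles)
#' @export
load_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$segments)) stop("model config has no 'segments' section")
  conv <- cfg$convention
  if (!is.null(conv)) {
    if (!is.null(conv$units) && conv$units != "mm")
      stop("model config units must be mm, got: ", conv$units)
    if (!is.null(conv$up_axis) && tolower(conv$up_axis) != "z")
      stop("model config up axis must be z, got: ", conv$up_axis)
  }
  segs <- lapply(names(cfg$segments), function(nm) {
    s <- cfg$segments[[nm]]
    mk <- s$markers
    if (is.null(mk) || length(mk) < 3)
      stop("segment '", nm, "' defines ", length(mk),
           " template markers; at least 3 are required")
    mkm <- do.call(rbind, lapply(mk, function(v) as.numeric(v)))
    rownames(mkm) <- names(mk)
    if (ncol(mkm) != 3) stop("segment '", nm, "': marker coordinates must be 3-vectors")
    owns <- if (is.null(s$owns)) names(mk) else as.character(s$owns)
    if (!all(owns %in% names(mk)))
      stop("segment '", nm, "' owns markers absent from its template: ",
           paste(setdiff(owns, names(mk)), collapse = ", "))
    list(name = nm,
         parent = if (is.null(s$parent)) NA_character_ else s$parent,
         joint_offset = as.numeric(if (is.null(s$joint_offset)) s$origin else s$joint_offset),
         sequence = if (is.null(s$sequence)) "YXZ" else toupper(s$sequence),
         markers = mkm, owns = owns)
  })
  names(segs) <- names(cfg$segments)
  model <- skeleton_model(segs, stature_mm = cfg$stature_mm)

  muscles <- list()
  for (nm in names(cfg$muscles)) {
    pts <- cfg$muscles[[nm]]$points
    muscles[[nm]] <- muscle_path(
      name = nm,
      segments = vapply(pts, function(p) p$segment, character(1)),
      points = do.call(rbind, lapply(pts, function(p) as.numeric(p$xyz))))
  }
  for (m in muscles) {
    unknown <- setdiff(m$segments, names(model$segments))
    if (length(unknown) > 0)
      stop("muscle '", m$name, "' references unknown segment(s): ",
           paste(unknown, collapse = ", "))
  }
  list(model = model, muscles = muscles)
}

#' Construct and validate a skeleton model
#'
#' @param segments named list of segment definitions (see
#'   [load_model_config()] for the fields).
#' @param stature_mm reference stature of the template body (mm); used for
#'   reporting only.
#' @return object of class `skeleton_model`.
#' @export
skeleton_model <- function(segments, stature_mm = NULL) {
  nms <- names(segments)
  roots <- nms[vapply(segments, function(s) is.na(s$parent), logical(1))]
  if (length(roots) != 1)
    stop("skeleton must have exactly one root segment, found: ",
         paste(roots, collapse = ", "))
  for (s in segments) {
    if (!is.na(s$parent) && !s$parent %in% nms)
      stop("segment '", s$name, "' has unknown parent '", s$parent, "'")
    if (length(s$joint_offset) != 3)
      stop("segment '", s$name, "': joint_offset must be a 3-vector")
    if (!s$sequence %in% c("XYZ", "XZY", "YXZ", "YZX", "ZXY", "ZYX"))
      stop("segment '", s$name, "': unsupported Cardan sequence '", s$sequence, "'")
    if (nrow(s$markers) < 3)
      stop("segment '", s$name, "' has fewer than 3 template markers")
    ctr <- scale(s$markers, scale = FALSE)
    if (qr(ctr)$rank < 2)
      stop("segment '", s$name, "': template markers are collinear")
  }
  # topological order; cycle detection
  order <- roots
  remaining <- setdiff(nms, roots)
  while (length(remaining) > 0) {
    ready <- remaining[vapply(segments[remaining],
                              function(s) s$parent %in% order, logical(1))]
    if (length(ready) == 0)
      stop("cyclic joint tree involving: ", paste(remaining, collapse = ", "))
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  owners <- unlist(lapply(segments, function(s) s$owns))
  if (anyDuplicated(owners))
    stop("markers owned by more than one segment: ",
         paste(unique(owners[duplicated(owners)]), collapse = ", "))
  structure(list(segments = segments, root = roots, order = order,
                 marker_labels = unique(owners),
                 stature_mm = stature_mm),
            class = "skeleton_model")
}

#' @export
print.skeleton_model <- function(x, ...) {
  cat(sprintf("skeleton_model: %d segments, root '%s', %d markers\n",
              length(x$segments), x$root, length(x$marker_labels)))
  invisible(x)
}

#' Define a muscle path
#'
#' An ordered polyline of attachment points (origin, optional via points,
#' insertion), each fixed in one segment's local frame.
#'
#' @param name muscle name.
#' @param segments character vector: the segment carrying each point.
#' @param points numeric `n x 3` matrix of local coordinates (mm).
#' @return object of class `muscle_path`.
#' @export
muscle_path <- function(name, segments, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 2 || length(segments) != nrow(points))
    stop("muscle '", name, "' needs >= 2 attachment points, one segment each")
  structure(list(name = name, segments = as.character(segments),
                 points = points), class = "muscle_path")
}

#' @export
print.muscle_path <- function(x, ...) {
  cat(sprintf("muscle_path '%s': %d points through %s\n", x$name,
              nrow(x$points), paste(unique(x$segments), collapse = " -> ")))
  invisible(x)
}

#' Path to the bundled default full-body model
#'
#' A 15-segment full-body skeleton (head, upper and lower trunk, and paired
#' upper arms, forearms, hands, thighs, shanks, feet) with 42 marker labels
#' and 9 muscle paths (rectus femoris, vastus lateralis, biceps femoris,
#' adductor magnus, gracilis, gluteus medius, semimembranosus on the right
#' leg; pectoralis major and latissimus dorsi on the right arm/trunk). The
#' attachment coordinates are plausible fixtures for a 1.70 m reference
#' body, not anatomical ground truth.
#'
#' @return path to the bundled YAML file.
#' @export
default_model_path <- function() {
  system.file("extdata", "default_model.yaml", package = "kinerisk",
              mustWork = TRUE)
}

#' Load the bundled default model
#' @return list with `model` and `muscles`, as [load_model_config()].
#' @export
default_model <- function() load_model_config(default_model_path())
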