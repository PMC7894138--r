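#' Bundle the unisensory populations of a network variant
#'
#' The lower layer of the network concatenates the unisensory populations'
#' activity into one vector. This constructor records the layouts and the
#' index slice each population occupies, for a given model variant.
#'
#' @param variant one of `"constrained"`, `"unconstrained"` (identical
#'   architecture, different training statistics), `"handvision"` (adds a
#'   visual population coding hand position), `"joint"` (proprioception as
#'   joint angles), `"gaze"` (joint angles plus a 1D gaze population).
#' @param visual_grid visual grid size (the full-scale model uses 50x50; a
#'   reduced 30x30 grid is used for fast runs).
#' @param n_tactile number of tactile units.
#' @return An object of class `pps_populations`: `$layouts` (named list of
#'   [pps_layout()]s plus the tactile size), `$slices` (named list of
#'   column index ranges into the lower-layer vector), `$n_low`,
#'   `$variant`.
#' @export
pps_populations <- function(variant = c("constrained", "unconstrained",
                                        "handvision", "joint", "gaze"),
                            visual_grid = c(50, 50), n_tactile = 30) {
  variant <- match.arg(variant)
  vis <- layout_visual(visual_grid)
  prop <- if (variant %in% c("joint", "gaze")) layout_joint()
          else layout_proprioceptive()
  layouts <- list(visual = vis, proprioceptive = prop)
  if (variant == "handvision") layouts$hand_visual <- layout_visual(visual_grid)
  if (variant == "gaze") layouts$gaze <- layout_gaze()
  n_units <- vapply(layouts, function(l) prod(l$n), numeric(1))
  n_units <- c(n_units, tactile = n_tactile)
  ends <- cumsum(n_units)
  starts <- c(1, head(ends, -1) + 1)
  slices <- Map(function(s, e) seq.int(s, e), starts, ends)
  names(slices) <- names(n_units)
  structure(
    list(layouts = layouts, n_tactile = n_tactile, slices = slices,
         n_low = sum(n_units), variant = variant),
    class = "pps_populations"
  )
}

#' @export
print.pps_populations <- function(x, ...) {
  cat(sprintf("<pps_populations '%s'> %d lower-layer units: %s\n",
              x$variant, x$n_low,
              paste(sprintf("%s[%d]", names(x$slices),
                            lengths(x$slices)), collapse = " ")))
  invisible(x)
}

#' Encode a stream of world samples into lower-layer activity
#'
#' Maps each trial of a generated stream (see [sample_constrained()] and
#' friends) through the populations' tuning curves into one activity
#' vector per trial. Occluded hand-visual positions (`NA`) encode as
#' silence.
#'
#' @param pops a [pps_populations()].
#' @param world a world tibble from the matching generator variant.
#' @param sample draw Poisson counts (`TRUE`, used in training) or return
#'   the deterministic means.
#' @return Numeric matrix, trials x `pops$n_low`.
#' @export
encode_world <- function(pops, world, sample = TRUE) {
  stopifnot(inherits(pops, "pps_populations"))
  n <- nrow(world)
  parts <- list()
  vis_pos <- cbind(world$vis_x, world$vis_y)
  parts$visual <- encode_position(pops$layouts$visual, vis_pos,
                                  world$gain_v, sample)
  prop_pos <- if (pops$variant %in% c("joint", "gaze")) {
    cbind(world$theta1, world$theta2)
  } else {
    cbind(world$hand_x, world$hand_y)
  }
  parts$proprioceptive <- encode_position(pops$layouts$proprioceptive,
                                          prop_pos, world$gain_p, sample)
  if (pops$variant == "handvision") {
    hv <- cbind(world$hv_x, world$hv_y)
    occ <- !stats::complete.cases(hv)
    hv[occ, ] <- 0   # placeholder position; activity zeroed below
    hv_act <- encode_position(pops$layouts$hand_visual, hv,
                              world$gain_hv, sample)
    hv_act[occ, ] <- 0
    parts$hand_visual <- hv_act
  }
  if (pops$variant == "gaze") {
    parts$gaze <- encode_position(pops$layouts$gaze, world$gaze,
                                  world$gain_g, sample)
  }
  parts$tactile <- encode_tactile(world$touch, world$gain_t,
                                  pops$n_tactile, sample)
  do.call(cbind, parts[names(pops$slices)])
}
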