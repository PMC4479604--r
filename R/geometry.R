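#' Build the box-synapse geometry for one configuration
#'
#' The world is a rectangular perisynaptic box enclosing two box-shaped
#' synaptic elements (pre- and postsynaptic), separated by a 20-nm cleft.
#' The elements span the full height of the perisynaptic box, so the gap
#' between the elements and the perisynaptic membrane (`peri_gap`) is
#' lateral. The AZ (presynaptic) and PSD (postsynaptic) are congruent
#' squares of side `Ls` centred on the apposed faces; the release point is
#' the AZ centre and the coordinate origin (cleft axis = z, cleft occupying
#' z in \[-Hc, 0\]).
#'
#' `peri_gap` is solved analytically so that the extracellular space (ECS:
#' perisynaptic interior minus the two elements) is `ecs_target` of the
#' total volume, then clipped into \[38, 65\] nm; the achieved fraction is
#' recorded (with a warning when clipping moved it by more than 0.02).
#'
#' @param cfg one row of a `synapse_population` (or any list with `Ls`,
#'   `La`), in nm.
#' @param ecs_target target extracellular volume fraction (0 < f < 1),
#'   default 0.20.
#' @param element_height depth of the pre/post boxes in nm; default `La`.
#' @param Hc cleft height in nm (default 20).
#' @param gap_range admissible `peri_gap` interval in nm (default 38--65).
#' @return An object of class `synapse_geometry`: list with `Ls`, `La`,
#'   `Hc`, `element_height`, `peri_gap`, `ecs_fraction`, `ecs_target`,
#'   `release_point`, bounding boxes `peri`, `pre`, `post` (each
#'   `c(xlo, xhi, ylo, yhi, zlo, zhi)`), and tagged `surfaces`.
#' @export
build_geometry <- function(cfg, ecs_target = 0.20, element_height = NULL,
                           Hc = 20, gap_range = c(38, 65)) {
  Ls <- cfg$Ls; La <- cfg$La
  if (is.null(Ls) || is.null(La) || Ls <= 0 || La < Ls || La > 2 * Ls + 1e-9)
    stop("cfg must satisfy 0 < Ls <= La <= 2 Ls")
  if (!is.numeric(ecs_target) || ecs_target <= 0 || ecs_target >= 1)
    stop("ecs_target must lie in (0, 1)")
  eh <- if (is.null(element_height)) La else element_height
  if (eh <= 0) stop("element_height must be positive")

  ## ecs(g) = 1 - 2 La^2 eh / ((La + 2g)^2 (2 eh + Hc))  => closed form for g
  ecs_of <- function(g) 1 - 2 * La^2 * eh / ((La + 2 * g)^2 * (2 * eh + Hc))
  side <- sqrt(2 * La^2 * eh / ((1 - ecs_target) * (2 * eh + Hc)))
  g <- (side - La) / 2
  g_clip <- min(max(g, gap_range[1]), gap_range[2])
  achieved <- ecs_of(g_clip)
  if (abs(achieved - ecs_target) > 0.02)
    warning(sprintf(
      "ECS balance unsolvable within peri_gap bounds: target %.3f, achieved %.3f at gap %.1f nm",
      ecs_target, achieved, g_clip))

  half_a <- La / 2; half_s <- Ls / 2; half_p <- half_a + g_clip
  peri <- c(-half_p, half_p, -half_p, half_p, -Hc - eh, eh)
  pre  <- c(-half_a, half_a, -half_a, half_a, 0, eh)
  post <- c(-half_a, half_a, -half_a, half_a, -Hc - eh, -Hc)

  ## tagged faces: every ECS boundary is either synaptic (AZ/PSD) or
  ## transporter-bearing membrane
  ann <- function(z) list(z = z, inner = Ls, outer = La)   # apposed annulus
  surfaces <- list(
    psd = list(z = -Hc, half = half_s),
    az  = list(z = 0,   half = half_s),
    post_annulus = ann(-Hc),
    pre_annulus  = ann(0),
    pre_walls  = list(zlo = 0, zhi = eh, half = half_a),
    post_walls = list(zlo = -Hc - eh, zhi = -Hc, half = half_a),
    peri_walls = list(zlo = -Hc - eh, zhi = eh, half = half_p),
    peri_top_annulus    = list(z = eh,        inner = La, outer = 2 * half_p),
    peri_bottom_annulus = list(z = -Hc - eh,  inner = La, outer = 2 * half_p)
  )
  structure(list(
    Ls = Ls, La = La, Hc = Hc, element_height = eh,
    peri_gap = g_clip, peri_gap_unclipped = g,
    ecs_target = ecs_target, ecs_fraction = achieved,
    release_point = c(0, 0, 0),
    peri = peri, pre = pre, post = post,
    psd_area = Ls^2, az_area = Ls^2,
    surfaces = surfaces
  ), class = "synapse_geometry")
}

in_box <- function(b, p) {
  p[1] > b[1] & p[1] < b[2] & p[2] > b[3] & p[2] < b[4] & p[3] > b[5] & p[3] < b[6]
}

#' Test whether a point lies in the extracellular space
#'
#' @param geom a `synapse_geometry`.
#' @param p numeric length-3 coordinate (nm), or an n x 3 matrix.
#' @return Logical (vector for a matrix input): inside the perisynaptic box
#'   and outside both synaptic elements. Boundary points count as outside
#'   the ECS.
#' @export
point_in_ecs <- function(geom, p) {
  if (is.matrix(p))
    return(unname(apply(p, 1, function(r) point_in_ecs(geom, r))))
  in_box(geom$peri, p) && !in_box(geom$pre, p) && !in_box(geom$post, p)
}

#' Extracellular and element volumes of a geometry (nm^3)
#' @param geom a `synapse_geometry`.
#' @return List with `total`, `elements`, `ecs`, `ecs_fraction`.
#' @export
geometry_volumes <- function(geom) {
  vol <- function(b) (b[2] - b[1]) * (b[4] - b[3]) * (b[6] - b[5])
  total <- vol(geom$peri); el <- vol(geom$pre) + vol(geom$post)
  list(total = total, elements = el, ecs = total - el,
       ecs_fraction = 1 - el / total)
}

#' Serialize a geometry to JSON
#' @param geom a `synapse_geometry`.
#' @param path optional file path; if missing the JSON string is returned.
#' @export
geometry_as_json <- function(geom, path = NULL) {
  x <- unclass(geom)
  x$volumes <- geometry_volumes(geom)
  if (is.null(path)) return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

## ---- reactive rectangle construction (engine input) ----
## Each reactive face is an axis-aligned rectangle tiled with an nu x nv grid;
## each tile holds at most one surface molecule. Returns a list of rects:
## axis (0=x,1=y,2=z: the constant axis), pos (plane coordinate), u0,v0,du,dv,
## nu,nv and the u/v axes indices.
plane_axes <- function(axis) switch(axis + 1L, c(1L, 2L), c(0L, 2L), c(0L, 1L))

make_rect <- function(axis, pos, u0, u1, v0, v1) {
  list(axis = axis, pos = pos, u0 = u0, u1 = u1, v0 = v0, v1 = v1,
       area = (u1 - u0) * (v1 - v0))
}

annulus_rects <- function(axis, pos, inner, outer) {
  hi <- inner / 2; ho <- outer / 2
  if (ho - hi < 1e-9) return(list())
  list(make_rect(axis, pos, -ho, -hi, -ho, ho),
       make_rect(axis, pos,  hi,  ho, -ho, ho),
       make_rect(axis, pos, -hi,  hi, -ho, -hi),
       make_rect(axis, pos, -hi,  hi,  hi,  ho))
}

walls_rects <- function(half, zlo, zhi) {
  ## four vertical walls of a square prism |x|,|y| <= half, z in [zlo, zhi]
  list(make_rect(0L, -half, -half, half, zlo, zhi),
       make_rect(0L,  half, -half, half, zlo, zhi),
       make_rect(1L, -half, -half, half, zlo, zhi),
       make_rect(1L,  half, -half, half, zlo, zhi))
}

#' Transporter-bearing rectangles of a geometry
#'
#' @param geom a `synapse_geometry`.
#' @param placement character vector choosing which membranes carry
#'   transporters: any of `"apposed"` (extrasynaptic pre/post annuli),
#'   `"element_walls"`, `"peri"` (perisynaptic box inner faces). Default all.
#' @return List of rectangles.
#' @export
glut_rects <- function(geom,
                       placement = c("apposed", "element_walls", "peri")) {
  s <- geom$surfaces
  out <- list()
  if ("apposed" %in% placement)
    out <- c(out,
             annulus_rects(2L, s$post_annulus$z, geom$Ls, geom$La),
             annulus_rects(2L, s$pre_annulus$z, geom$Ls, geom$La))
  if ("element_walls" %in% placement)
    out <- c(out,
             walls_rects(geom$La / 2, s$pre_walls$zlo, s$pre_walls$zhi),
             walls_rects(geom$La / 2, s$post_walls$zlo, s$post_walls$zhi))
  if ("peri" %in% placement)
    out <- c(out,
             walls_rects(geom$peri[2], geom$peri[5], geom$peri[6]),
             annulus_rects(2L, s$peri_top_annulus$z, geom$La, 2 * geom$peri[2]),
             annulus_rects(2L, s$peri_bottom_annulus$z, geom$La, 2 * geom$peri[2]))
  out
}

psd_rect <- function(geom) {
  h <- geom$Ls / 2
  make_rect(2L, -geom$Hc, -h, h, -h, h)
}
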