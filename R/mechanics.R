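#' Minimum distance between two capsule cells
#'
#' Computes the shortest distance between the two axis segments, subtracts
#' both radii, and reports the witness points and the unit normal from the
#' first to the second cell. Negative gaps mean the capsules overlap. Exact
#' for parallel and degenerate (point) segments; the witness pair of a
#' parallel overlap is the midpoint of the overlap interval.
#'
#' @param a,b Cells: lists with `center` (length-2 or 3 numeric), `axis`
#'   (unit vector, in-plane) and `seg_length`.
#' @param radius Capsule radius shared by both cells (µm).
#' @return A list of class `t6_contact` with `d` (signed gap, µm), `point_a`,
#'   `point_b` (closest surface-axis witness points) and `normal`.
#' @examples
#' a <- list(center = c(0, 0), axis = c(1, 0), seg_length = 2)
#' b <- list(center = c(0, 1.2), axis = c(1, 0), seg_length = 2)
#' capsule_capsule_distance(a, b, radius = 0.5)$d   # 0.2
#' @export
capsule_capsule_distance <- function(a, b, radius) {
  stopifnot(radius > 0, a$seg_length >= 0, b$seg_length >= 0)
  ca <- a$center[1:2]; cb <- b$center[1:2]
  ha <- a$seg_length / 2; hb <- b$seg_length / 2
  axa <- a$axis[1:2] / sqrt(sum(a$axis[1:2]^2))
  axb <- b$axis[1:2] / sqrt(sum(b$axis[1:2]^2))
  res <- seg_seg_closest_cpp(ca - axa * ha, ca + axa * ha,
                             cb - axb * hb, cb + axb * hb)
  nrm <- res$c2 - res$c1
  nl <- sqrt(sum(nrm^2))
  if (nl > 1e-12) nrm <- nrm / nl
  else {
    nrm <- cb - ca
    nl2 <- sqrt(sum(nrm^2))
    nrm <- if (nl2 > 1e-12) nrm / nl2 else c(1, 0)
  }
  structure(list(d = res$dist - 2 * radius,
                 point_a = res$c1, point_b = res$c2, normal = nrm),
            class = "t6_contact")
}

#' Find all overlapping or near-contact cell pairs
#'
#' Returns every pair whose surface gap is below `cutoff`, using a uniform
#' spatial bin as broad phase (near-linear cost) followed by exact
#' segment-segment narrow phase; the result is identical to an all-pairs
#' check.
#'
#' @param patch A `t6_patch`.
#' @param cutoff Gap threshold (µm); pairs with `d < cutoff` are reported.
#' @return A data frame with columns `i`, `j` (cell indices), `d` (signed
#'   gap), witness points `wix, wiy, wjx, wjy` and the contact normal
#'   `nx, ny`.
#' @export
find_contacts <- function(patch, cutoff = 0) {
  stopifnot(inherits(patch, "t6_patch"), cutoff >= 0 || cutoff < 0) # numeric
  if (cutoff < 0) stop("cutoff must be non-negative")
  cs <- patch$cells
  m <- find_contacts_cpp(cs$x, cs$y, cs$ax, cs$ay, half_lengths(patch),
                         patch$params$R_cell, cutoff)
  out <- as.data.frame(m)
  names(out) <- c("i", "j", "d", "wix", "wiy", "wjx", "wjy", "nx", "ny")
  out
}

#' Relax a patch to mechanical quasi-equilibrium
#'
#' Resolves capsule overlaps by the regularized impulse method: each
#' iteration finds the overlapping contacts, builds the contact Jacobian `A`
#' (planar rigid-body degrees of freedom x, y, rotation), and solves the
#' regularized normal equations
#' \deqn{(A^T A + \alpha M)\,p = -A^T d}
#' for impulses `p` (M is the diagonal drag matrix), which are applied as
#' rigid displacements and rotations. Contacts are re-found each iteration
#' until the worst residual overlap is below `relax_tol` or the iteration cap
#' is reached. Deterministic: no random draws.
#'
#' @param patch A `t6_patch`.
#' @return The patch with updated poses; relaxation diagnostics are attached
#'   as attribute `"relax"` (iterations, initial/final worst overlap,
#'   regularization actually used).
#' @export
relax <- function(patch) {
  stopifnot(inherits(patch, "t6_patch"))
  relax_impl(patch)
}

relax_impl <- function(patch) {
  cs <- patch$cells
  if (length(cs$id) == 0) return(patch)
  dr <- cell_drags(patch)
  res <- relax_cpp(cs$x, cs$y, cs$ax, cs$ay, half_lengths(patch),
                   patch$params$R_cell, dr$t, dr$r,
                   patch$params$alpha, patch$params$relax_tol,
                   patch$params$relax_max_iter)
  if (isTRUE(res$warned))
    warning("relaxation escalated its regularization weight to ",
            format(res$alpha_used), call. = FALSE)
  patch$cells$x <- res$x
  patch$cells$y <- res$y
  patch$cells$ax <- res$ax
  patch$cells$ay <- res$ay
  attr(patch, "relax") <- list(iterations = res$iterations,
                               max_overlap_initial = res$max_overlap_initial,
                               max_overlap_final = res$max_overlap_final,
                               alpha_used = res$alpha_used)
  patch
}
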