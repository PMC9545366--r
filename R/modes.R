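# Hand-designed deformation fields over the 85-point template, orthogonalised
# by Gram-Schmidt so the synthetic generative model has an identifiable,
# exactly orthonormal mode basis.

mode_field_builders <- function() {
  list(
    # isotropic inflation of the femoral head about its centre
    head_size = function(tpl, schema, m) {
      idx <- attr(tpl, "head_arc_idx")
      f <- matrix(0, nrow(m), 2)
      r <- m[idx, , drop = FALSE]
      len <- sqrt(rowSums(r^2))
      f[idx, ] <- r / len
      f
    },
    # femoral neck widening via displacement of the superior border away from
    # the neck axis (the narrowest-width mechanism described for moderate OA)
    neck_width = function(tpl, schema, m) {
      idx <- schema$superior_neck_idx
      p <- attr(tpl, "params")
      th <- deg2rad(180 - p$nsa)
      v <- c(-sin(th), cos(th))
      f <- matrix(0, nrow(m), 2)
      f[idx, 1] <- v[1]
      f[idx, 2] <- v[2]
      f
    },
    # cam-type radial bump centred on the superior head-neck junction; kept
    # clear of the head-circle-fit points so cam scores do not perturb the
    # fitted head centre (and hence the centre-edge angle)
    cam_bump = function(tpl, schema, m) {
      idx <- 29:37
      w <- exp(-((idx - 33)^2) / (2 * 1.8^2))
      f <- matrix(0, nrow(m), 2)
      r <- m[idx, , drop = FALSE]
      len <- sqrt(rowSums(r^2))
      f[idx, ] <- (r / len) * w
      f
    },
    # rigid rotation of the acetabular arc about the head centre; positive
    # scores extend the arc laterally (greater coverage, higher LCEA)
    acetab_coverage = function(tpl, schema, m) {
      idx <- attr(tpl, "acetab_arc_idx")
      f <- matrix(0, nrow(m), 2)
      r_ac <- sqrt(rowSums(m[idx, , drop = FALSE]^2))
      f[idx, 1] <- -m[idx, 2] / mean(r_ac)
      f[idx, 2] <- m[idx, 1] / mean(r_ac)
      f
    },
    # combined enlargement of greater and lesser trochanters, each lobe
    # inflated away from its own centroid
    troch_size = function(tpl, schema, m) {
      f <- matrix(0, nrow(m), 2)
      for (idx in list(schema$greater_troch_idx, schema$lesser_troch_idx)) {
        cen <- colMeans(m[idx, , drop = FALSE])
        r <- sweep(m[idx, , drop = FALSE], 2, cen)
        len <- sqrt(rowSums(r^2))
        len[len == 0] <- 1
        f[idx, ] <- r / len
      }
      f
    },
    # head + neck region translated along the neck axis (neck elongation)
    neck_length = function(tpl, schema, m) {
      p <- attr(tpl, "params")
      th <- deg2rad(180 - p$nsa)
      u <- c(cos(th), sin(th))
      idx <- c(schema$inferior_neck_idx, attr(tpl, "head_arc_idx"),
               schema$superior_neck_idx)
      f <- matrix(0, nrow(m), 2)
      f[idx, 1] <- u[1]
      f[idx, 2] <- u[2]
      f
    }
  )
}

# Orthonormal basis of the similarity-transform tangent space at a centred
# template: x/y translation, infinitesimal rotation, scaling. Generated mode
# fields are projected off this space so the synthetic variation is pure
# shape -- Procrustes alignment removes exactly these components, so only
# similarity-free fields are recoverable by alignment + PCA.
similarity_tangent_basis <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  p <- nrow(m)
  tx <- xy_to_vec(cbind(rep(1, p), rep(0, p)))
  ty <- xy_to_vec(cbind(rep(0, p), rep(1, p)))
  rot <- xy_to_vec(cbind(-m[, 2], m[, 1]))
  scl <- xy_to_vec(m)
  gram_schmidt(cbind(tx, ty, rot, scl))
}

gram_schmidt <- function(M, tol = 1e-12) {
  Q <- M
  for (j in seq_len(ncol(M))) {
    vj <- Q[, j]
    if (j > 1) {
      proj <- Q[, seq_len(j - 1), drop = FALSE]
      vj <- vj - proj %*% crossprod(proj, vj)
    }
    nrm <- sqrt(sum(vj^2))
    if (nrm < tol) abort("Deformation fields are linearly dependent.")
    Q[, j] <- vj / nrm
  }
  Q
}

#' Generative shape specification for the synthetic cohort
#'
#' Couples the template outline with a set of unit-norm, mutually orthogonal
#' deformation fields and per-mode score standard deviations. Fields are
#' projected off the similarity-transform tangent space (translation,
#' rotation, scaling) at the template, so generated variation is pure shape
#' and the generating subspace is identifiable after Procrustes alignment. Named modes
#' include `cam_bump` (radial widening of the superior head-neck junction) and
#' `acetab_coverage` (rotation of the acetabular arc about the head centre),
#' the two morphologies whose measured proxies (alpha angle and lateral
#' centre-edge angle) drive the adjustment analyses downstream.
#'
#' Score SDs are in mm of the unit-norm field and were chosen once to give
#' realistic dispersions of the geometric measures at the default template;
#' the isotropic per-point landmark noise default (0.5 mm) is of the order of
#' manual point-correction distances on DXA annotations.
#'
#' @param template Template landmark tibble from [hip_template()].
#' @param score_sd Named numeric vector of per-mode score SDs (mm); names must
#'   match the built-in field names.
#' @param point_noise_sd Isotropic Gaussian landmark noise SD, mm.
#' @param schema A [hip_schema()].
#' @return An object of class `hip_shape_spec` with elements `template`,
#'   `modes` (170 x K orthonormal matrix), `mode_names`, `score_sd`,
#'   `point_noise_sd`, `schema`.
#' @export
generative_shape_spec <- function(template = hip_template(),
                                  score_sd = c(head_size = 4, neck_width = 3,
                                               cam_bump = 3, acetab_coverage = 5,
                                               troch_size = 2.5, neck_length = 2),
                                  point_noise_sd = 0.5,
                                  schema = hip_schema()) {
  # the all-defaults spec is requested constantly (it defines the study
  # conditions); cache it, since the feature reference stats cost a moment
  default_args <- missing(template) && missing(score_sd) &&
    missing(point_noise_sd) && missing(schema)
  if (default_args && exists("default_shape_spec", envir = .hipshapes_cache)) {
    return(get("default_shape_spec", envir = .hipshapes_cache))
  }
  builders <- mode_field_builders()
  miss <- setdiff(names(score_sd), names(builders))
  if (length(miss)) {
    abort(paste0("Unknown mode name(s): ", paste(miss, collapse = ", ")))
  }
  if (any(score_sd <= 0)) abort("All mode score SDs must be positive.")
  m <- config_matrix(template)
  fields <- vapply(names(score_sd),
                   function(nm) xy_to_vec(builders[[nm]](template, schema, m)),
                   numeric(2 * nrow(m)))
  tang <- similarity_tangent_basis(m)
  fields <- fields - tang %*% crossprod(tang, fields)
  # orthogonalize the two localized morphologic fields first: their
  # similarity-projection residue is (infinitesimally) rigid and invisible
  # to the angle measures, while later fields absorb any spillover -- this
  # keeps "coverage" free of junction deformation and vice versa
  precedence <- c(intersect(c("acetab_coverage", "cam_bump"), names(score_sd)),
                  setdiff(names(score_sd), c("acetab_coverage", "cam_bump")))
  modes <- gram_schmidt(fields[, precedence, drop = FALSE])
  modes <- modes[, match(names(score_sd), precedence), drop = FALSE]
  check_mode_orthogonality(modes)
  spec <- structure(
    list(template = template, modes = modes, mode_names = names(score_sd),
         score_sd = score_sd, point_noise_sd = point_noise_sd, schema = schema),
    class = "hip_shape_spec"
  )
  spec$feature_stats <- feature_reference_stats(spec)
  if (default_args) assign("default_shape_spec", spec, envir = .hipshapes_cache)
  spec
}

.hipshapes_cache <- new.env(parent = emptyenv())

check_mode_orthogonality <- function(modes, tol = 1e-8) {
  g <- crossprod(modes)
  off <- abs(g - diag(ncol(modes)))
  if (max(off) >= tol) {
    abort("Deformation modes are not orthonormal (Gram off-diagonal >= 1e-8).")
  }
  invisible(TRUE)
}

#' @export
print.hip_shape_spec <- function(x, ...) {
  cat("<hip_shape_spec> ", length(x$mode_names), " orthonormal modes over ",
      x$schema$n_points, " points\n", sep = "")
  cat("  modes:      ", paste(x$mode_names, collapse = ", "), "\n", sep = "")
  cat("  score SDs:  ", paste(format(x$score_sd), collapse = ", "), " mm\n", sep = "")
  cat("  point noise:", format(x$point_noise_sd), "mm\n")
  invisible(x)
}
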