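#' Reaction-coordinate rotation axes
#'
#' An ordered list of rotatable bonds. Each axis is a list with fields
#' `pivot` and `axis` (atom labels `"<resi> <atom>"` defining the bond
#' line) and `moving` (labels of the downstream atoms carried by the
#' rotation). Rotating an axis moves only its declared atoms.
#'
#' @param ... Axis definitions created with [rotation_axis()].
#' @return Object of class `rotation_axes`.
#' @export
rotation_axes <- function(...) {
  axes <- list(...)
  if (length(axes) == 1 && is.list(axes[[1]]) && is.null(axes[[1]]$pivot))
    axes <- axes[[1]]
  for (ax in axes)
    stopifnot(!is.null(ax$pivot), !is.null(ax$axis), length(ax$moving) >= 1)
  structure(axes, class = "rotation_axes")
}

#' @rdname rotation_axes
#' @param pivot,axis Atom labels (`"<resi> <atom>"`) defining the bond.
#' @param moving Character vector of downstream atom labels.
#' @param span Search half-width in degrees for this axis (default 60;
#'   use small spans, e.g. 10, for declared main-chain axes).
#' @export
rotation_axis <- function(pivot, axis, moving, span = 60) {
  list(pivot = pivot, axis = axis, moving = moving, span = span)
}

#' Side-chain chi1/chi2 axis template for an Asn-like residue
#'
#' chi1 rotates about CA-CB (carrying CG, OD1, ND2); chi2 rotates about
#' CB-CG (carrying OD1, ND2).
#'
#' @param resi Residue number.
#' @return A [rotation_axes()] object.
#' @export
asn_chi_axes <- function(resi) {
  r <- function(a) paste(resi, a)
  rotation_axes(
    rotation_axis(r("CA"), r("CB"), c(r("CG"), r("OD1"), r("ND2"))),
    rotation_axis(r("CB"), r("CG"), c(r("OD1"), r("ND2"))))
}

# Rodrigues rotation of selected atoms about the pivot->axis line
.rotate_atoms <- function(model, axis, angle_deg) {
  if (angle_deg == 0) return(model)
  labs <- atom_labels(model)
  ip <- match(axis$pivot, labs); ia <- match(axis$axis, labs)
  im <- match(axis$moving, labs)
  if (anyNA(c(ip, ia, im)))
    stop("axis atoms missing from model: axis ", axis$pivot, " -> ", axis$axis)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  p <- xyz[ip, ]
  u <- xyz[ia, ] - p
  u <- u / sqrt(sum(u^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  v <- sweep(xyz[im, , drop = FALSE], 2, p)
  xyz[im, ] <- sweep(v %*% t(R), 2, p, `+`)
  model$atoms[, c("x", "y", "z")] <- xyz
  model
}

#' Apply dihedral-angle offsets along declared axes
#'
#' @param model An [atom_model()].
#' @param axes A [rotation_axes()] set.
#' @param offsets Numeric vector of angle offsets in degrees (one per
#'   axis), applied in axis order.
#' @return The rotated `atom_model`.
#' @export
apply_axis_offsets <- function(model, axes, offsets) {
  stopifnot(length(offsets) == length(axes))
  for (i in seq_along(axes))
    model <- .rotate_atoms(model, axes[[i]], offsets[i])
  model
}

#' A candidate light-state conformer
#'
#' @param base Base (dark) [atom_model()].
#' @param axes [rotation_axes()] describing the reaction coordinates.
#' @param offsets Angle offsets in degrees per axis.
#' @return Object of class `conformer` with fields `base`, `axes`,
#'   `offsets`, `model` (derived coordinates) and `cc` (`NA` until
#'   scored).
#' @export
conformer <- function(base, axes, offsets) {
  structure(list(base = base, axes = axes, offsets = offsets,
                 model = apply_axis_offsets(base, axes, offsets),
                 cc = NA_real_),
            class = "conformer")
}

#' Generate a library of conformers on per-axis angle grids
#'
#' Coordinate-descent neighborhood: for each axis in turn, offsets are
#' sampled on `center + seq(-span, span, by = step)` while the other
#' axes keep their current offsets. (A full Cartesian product over axes
#' explodes combinatorially; on toy systems the coordinate-wise library
#' searched iteratively reproduces the brute-force optimum.)
#'
#' @param model Base [atom_model()].
#' @param axes A [rotation_axes()] set.
#' @param step_deg Grid step in degrees (> 0).
#' @param span_deg Half-width of the grid in degrees (>= step).
#' @param center Current offsets (default all zero).
#' @return List of [conformer()]s.
#' @export
generate_conformers <- function(model, axes, step_deg, span_deg,
                                center = rep(0, length(axes))) {
  stopifnot(step_deg > 0, span_deg >= step_deg)
  out <- list()
  for (i in seq_along(axes)) {
    for (dth in seq(-span_deg, span_deg, by = step_deg)) {
      off <- center
      off[i] <- off[i] + dth
      out[[length(out) + 1]] <- conformer(model, axes, off)
    }
  }
  out
}

# --- fast DED_c scoring --------------------------------------------------
# Context object precomputing everything that does not change between
# candidate conformers: hkl list, complex dark SF, moving-atom dark
# contribution, dark phases, grid, mask voxel indices, observed values.
.dfocc_context <- function(dark_model, axes, ded_o, mask, d_min,
                           mode = "cromer_mann") {
  grid <- dim(ded_o$values)
  hkl <- unique_hkl(dark_model$cell, d_min)
  f_dark <- .complex_sf(dark_model, hkl, mode)
  moving <- unique(unlist(lapply(axes, `[[`, "moving")))
  imov <- match(moving, atom_labels(dark_model))
  sub <- dark_model; sub$atoms <- dark_model$atoms[imov, , drop = FALSE]
  f_mov_dark <- .complex_sf(sub, hkl, mode)
  list(hkl = hkl, grid = grid, cell = dark_model$cell, mode = mode,
       f_dark = f_dark, f_mov_dark = f_mov_dark, imov = imov,
       ph_dark = Arg(f_dark), obs = ded_o$values[mask$voxels],
       mask = mask, d_min = d_min)
}

# DED_c synthesized from |F_c,l| - |F_c,dark| with dark phases, given the
# candidate's moving-atom coordinates; returns masked voxel values, or
# NULL when the candidate leaves the amplitudes (numerically) unchanged
.dfocc_calc_ded <- function(ctx, cand_model) {
  sub <- cand_model
  sub$atoms <- cand_model$atoms[ctx$imov, , drop = FALSE]
  f_mov <- .complex_sf(sub, ctx$hkl, ctx$mode)
  f_l <- ctx$f_dark - ctx$f_mov_dark + f_mov
  dF <- Mod(f_l) - Mod(ctx$f_dark)
  if (max(abs(dF)) < 1e-9 * max(Mod(ctx$f_dark))) return(NULL)
  rs <- reflection_set(ctx$hkl, f = abs(dF), phase = ctx$ph_dark * 180 / pi,
                       cell = ctx$cell, role = "difference")
  rs$data$f <- dF
  m <- synthesize_map(rs, grid = ctx$grid, provenance = "calculated-DED")
  m$values[ctx$mask$voxels]
}

#' Score a conformer against an observed DED map
#'
#' Computes calculated light structure factors for the conformer, forms
#' the calculated DED map `|F_c,l| - |F_c,dark|` (dark phases) on the
#' observed map's grid, and returns the Pearson correlation with the
#' observed DED over the masked voxels.
#'
#' @param conf A [conformer()].
#' @param dark_model Dark [atom_model()].
#' @param ded_o Observed DED `density_map`.
#' @param mask A [region_mask()] covering the moving atoms.
#' @param d_min Resolution for the calculated sets (default: the Nyquist
#'   limit implied by `ded_o`'s grid, conservatively `3 * spacing`).
#' @param mode Form-factor mode.
#' @return The correlation coefficient; also stored on the conformer
#'   when the return value is reassigned (see [dfocc_refine()] for the
#'   iterative driver).
#' @export
score_conformer <- function(conf, dark_model, ded_o, mask, d_min = NULL,
                            mode = "cromer_mann") {
  if (is.null(d_min)) {
    sp <- min(dark_model$cell$a / dim(ded_o$values)[1],
              dark_model$cell$b / dim(ded_o$values)[2],
              dark_model$cell$c / dim(ded_o$values)[3])
    d_min <- 3 * sp
  }
  ctx <- .dfocc_context(dark_model, conf$axes, ded_o, mask, d_min, mode)
  calc <- .dfocc_calc_ded(ctx, conf$model)
  if (is.null(calc) || stats::sd(calc) == 0)
    stop("calculated DED has zero variance within the mask (no atoms moved?)")
  stats::cor(calc, ctx$obs)
}

#' dFoCC refinement of reaction coordinates
#'
#' Iteratively maximizes the correlation between calculated and observed
#' DED maps by coordinate descent over the declared rotation axes:
#' each round sweeps every axis on a 1-D angle grid around the current
#' offsets, re-centers on the best conformer, and halves the step once a
#' sweep no longer improves. The search terminates when the step drops
#' below `min_step_deg` (default 0.1 degrees, the conformational
#' resolution limit) or, when enabled, when the implied atomic
#' displacement of one step falls below `min_step_ang` Angstrom, or when
#' the correlation gain falls below `tol_cc`.
#'
#' The voxel mask is fixed for the whole search: the union of
#' `mask_radius` spheres around the moving atoms in the dark position and
#' at the +/- span extremes of every axis, so both departing and arriving
#' density are covered for all candidates. Ties on equal CC are broken
#' toward the smaller total |offset|, then earlier axis order; the search
#' is fully deterministic.
#'
#' @param dark_model Dark [atom_model()].
#' @param axes [rotation_axes()].
#' @param ded_o Observed DED `density_map`.
#' @param mask Optional [region_mask()]; built automatically when `NULL`.
#' @param config List of tuning parameters: `step0` (initial step, deg,
#'   default 10), `span` (half-width, deg, default 60; per-axis `span`
#'   fields override), `shrink` (step factor per stall, default 0.5),
#'   `min_step_deg` (default 0.1), `min_step_ang` (default 0 = disabled),
#'   `tol_cc` (default 1e-6), `d_min` (calculated-set resolution),
#'   `mask_radius` (default 2.5), `max_iter` (default 60).
#' @return The best [conformer()] with `cc` set and attribute `"trace"`:
#'   a data.frame of per-iteration best CC and step size.
#' @export
dfocc_refine <- function(dark_model, axes, ded_o, mask = NULL,
                         config = list()) {
  cfg <- utils::modifyList(list(step0 = 10, span = 60, shrink = 0.5,
                                min_step_deg = 0.1, min_step_ang = 0,
                                tol_cc = 1e-6, d_min = NULL,
                                mask_radius = 2.5, max_iter = 60,
                                mode = "cromer_mann"), config)
  if (is.null(cfg$d_min)) {
    sp <- min(dark_model$cell$a / dim(ded_o$values)[1],
              dark_model$cell$b / dim(ded_o$values)[2],
              dark_model$cell$c / dim(ded_o$values)[3])
    cfg$d_min <- 3 * sp
  }
  spans <- vapply(axes, function(a) if (is.null(a$span)) cfg$span else a$span,
                  numeric(1))
  moving <- unique(unlist(lapply(axes, `[[`, "moving")))
  if (is.null(mask)) {
    extras <- list()
    for (i in seq_along(axes)) for (sgn in c(-1, 1)) {
      off <- rep(0, length(axes)); off[i] <- sgn * spans[i]
      mm <- apply_axis_offsets(dark_model, axes, off)
      extras[[length(extras) + 1]] <-
        as.matrix(mm$atoms[match(moving, atom_labels(mm)), c("x", "y", "z")])
    }
    mask <- region_mask(dark_model, moving, grid = dim(ded_o$values),
                        radius = cfg$mask_radius,
                        extra_xyz = do.call(rbind, extras))
  }
  ctx <- .dfocc_context(dark_model, axes, ded_o, mask, cfg$d_min, cfg$mode)
  if (stats::sd(ctx$obs) == 0) {
    # null signal: no move can be justified, return the base offsets
    warning("observed DED is flat within the mask; returning base offsets")
    out <- conformer(dark_model, axes, rep(0, length(axes)))
    attr(out, "trace") <- data.frame(iter = 0, cc = NA_real_, step = NA_real_)
    attr(out, "mask") <- mask
    return(out)
  }

  score_at <- function(off) {
    m <- apply_axis_offsets(dark_model, axes, off)
    calc <- .dfocc_calc_ded(ctx, m)
    if (is.null(calc) || stats::sd(calc) == 0) return(NA_real_)
    stats::cor(calc, ctx$obs)
  }

  cur <- rep(0, length(axes))
  cur_cc <- score_at(cur)
  if (is.na(cur_cc)) cur_cc <- -Inf   # zero offsets move nothing: score later
  step <- cfg$step0
  trace <- data.frame(iter = 0, cc = cur_cc, step = NA_real_)
  iter <- 0
  # largest moving-atom distance from any axis, for the displacement rule
  max_r <- 0
  xyz <- as.matrix(dark_model$atoms[, c("x", "y", "z")])
  labs <- atom_labels(dark_model)
  for (ax in axes) {
    p <- xyz[match(ax$pivot, labs), ]
    u <- xyz[match(ax$axis, labs), ] - p; u <- u / sqrt(sum(u^2))
    for (ml in ax$moving) {
      v <- xyz[match(ml, labs), ] - p
      r <- sqrt(sum(v^2) - sum(v * u)^2)
      max_r <- max(max_r, r)
    }
  }
  spans_cur <- spans
  repeat {
    iter <- iter + 1
    improved <- FALSE
    for (i in seq_along(axes)) {
      grid_th <- cur[i] + seq(-spans_cur[i], spans_cur[i], by = step)
      best_i <- cur[i]; best_cc <- cur_cc
      best_tot <- sum(abs(cur))
      for (th in grid_th) {
        off <- cur; off[i] <- th
        cc <- score_at(off)
        if (is.na(cc)) next
        tot <- sum(abs(off))
        if (cc > best_cc + 1e-12 ||
            (abs(cc - best_cc) <= 1e-12 && tot < best_tot - 1e-9)) {
          best_i <- th; best_cc <- cc; best_tot <- tot
        }
      }
      if (best_cc > cur_cc + cfg$tol_cc) improved <- TRUE
      if (best_cc >= cur_cc) { cur[i] <- best_i; cur_cc <- best_cc }
    }
    trace <- rbind(trace, data.frame(iter = iter, cc = cur_cc, step = step))
    if (iter == 1 && !improved && all(cur == 0)) {
      if (cur_cc < 0.99)
        warning("first sweep found no improving conformer; returning base offsets")
    }
    if (!improved) {
      step <- step * cfg$shrink
      # narrow the search window with the step so sweeps stay cheap
      spans_cur <- pmax(spans_cur * cfg$shrink, 3 * step)
      disp <- step * pi / 180 * max_r
      if (step < cfg$min_step_deg) break
      if (cfg$min_step_ang > 0 && disp < cfg$min_step_ang) break
    }
    if (iter >= cfg$max_iter) break
  }
  out <- conformer(dark_model, axes, cur)
  out$cc <- cur_cc
  attr(out, "trace") <- trace
  attr(out, "mask") <- mask
  out
}
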