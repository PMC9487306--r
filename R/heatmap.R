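#' MCI heatmap over control point and collimator angle
#'
#' For every control point of the arc, the target union is projected into the
#' BEV; for every collimator angle a conformal MLC aperture is fitted in the
#' rotated frame, and the MLC conformity index is recorded. The default grid
#' is 180 control points (2 degrees/CP over a 358-degree arc) by 180
#' collimator angles (1-degree steps over \[0, 180)), 180 degrees being
#' redundant with 0 for a symmetric leaf bank.
#'
#' Implementation note: the silhouette area is invariant under collimator
#' rotation, so per collimator angle only the silhouette's boundary pixels
#' are rotated and reduced to per-leaf-band extents (boundary pixels carry
#' both band occupancy and extreme u extents). This is algebraically the
#' same fit as [rotate_bev()] + [fit_aperture()] up to raster resampling; a
#' regression test keeps the two routes in agreement.
#'
#' @param x Target structures: a `contour_tbl` (slice polygons projected
#'   directly, the highest-fidelity route), a `vox_mask`, or an n x 3 point
#'   matrix (union of all targets).
#' @param arc An [arc_spec()].
#' @param geom A [linac_geometry()].
#' @param mlc An [mlc_model()].
#' @param thetas Collimator angles, degrees (default `0:179`).
#' @param pixel BEV pixel size, mm.
#' @param voxel Rasterization voxel, mm (unused for contour input).
#' @param mode Projection mode, `"divergent"` or `"parallel"`.
#' @return An object of class `mci_heatmap`: list with `values`
#'   (n_cp x n_theta matrix of MCI in (0, 1\]), `gantry`, `thetas`, plus the
#'   cached per-CP silhouettes used by [subarc_field_sizes()].
#' @export
mci_heatmap <- function(x, arc = arc_spec(), geom = linac_geometry(),
                        mlc = mlc_model(), thetas = 0:179, pixel = 0.5,
                        voxel = 1, mode = c("divergent", "parallel")) {
  mode <- match.arg(mode)
  stopifnot(inherits(arc, "arc_spec"), length(thetas) >= 1)
  use_contours <- is.data.frame(x)
  if (use_contours) x <- validate_contour_tbl(x)
  pts <- if (!use_contours) structure_points(x, voxel)
  gantry <- control_points(arc)
  nT <- length(thetas)
  ct <- cos(thetas * pi / 180); st <- sin(thetas * pi / 180)
  nb <- mlc$n_pairs
  values <- matrix(NA_real_, length(gantry), nT)
  a_tp <- numeric(length(gantry))
  sil <- vector("list", length(gantry))
  for (i in seq_along(gantry)) {
    if (use_contours) {
      # continuous slab geometry: extents come straight from the silhouette
      # envelopes (no raster quantization in A_MLC); the raster only
      # supplies the silhouette area
      sl <- contour_slab_samples(x, gantry[i], geom, pixel, mode)
      bev <- contour_slab_bev(x, gantry[i], geom, pixel, mode, sl = sl)
      bpts <- contour_boundary_points(sl, pixel)
    } else {
      pr <- project_points(pts, gantry[i], geom, mode)
      bev <- points_to_bev(pr$u, pr$v, pixel)
      bpts <- bev_boundary_points(bev)
    }
    a_tp[i] <- bev_area_cm2(bev)
    if (a_tp[i] <= 0) {
      abort(sprintf("empty silhouette at control point %d (gantry %g)", i, gantry[i]),
            class = "subarcvmat_geometry_error")
    }
    sil[[i]] <- bpts
    values[i, ] <- mci_over_thetas(bpts, a_tp[i], ct, st, mlc, pixel,
                                   inflate = TRUE)
  }
  structure(list(values = values, gantry = gantry, thetas = as.numeric(thetas),
                 arc = arc, pixel = pixel, mode = mode, a_tp_cm2 = a_tp,
                 silhouettes = sil, inflate = TRUE,
                 mlc = mlc, geom = geom),
            class = "mci_heatmap")
}

# MCI for one silhouette across all collimator angles (vectors ct, st).
# bpts: boundary points (u, v); a_tp: silhouette area (cm^2). `inflate`
# adds the corner support of a half-pixel square around each point (needed
# when the points are pixel centers; continuous boundary points need none).
mci_over_thetas <- function(bpts, a_tp, ct, st, mlc, pixel, inflate = TRUE) {
  nT <- length(ct); nb <- mlc$n_pairs
  bu <- bpts[, 1L]; bv <- bpts[, 2L]
  U <- outer(bu, ct) + outer(bv, st)     # rotate points by -theta
  V <- -outer(bu, st) + outer(bv, ct)
  band <- findInterval(as.vector(V), mlc$edges)
  if (any(band < 1L) || any(band > nb)) {
    abort("silhouette exceeds the MLC bank height",
          class = "subarcvmat_aperture_error")
  }
  theta_id <- rep(seq_len(nT), each = length(bu))
  dt <- data.table::data.table(gid = band + nb * (theta_id - 1L),
                               u = as.vector(U))
  ext <- dt[, list(umin = min(u), umax = max(u)), by = "gid"]
  b <- (ext$gid - 1L) %% nb + 1L
  tid <- (ext$gid - 1L) %/% nb + 1L
  # corner (l1) support inflation: a boundary pixel's extreme corner lies
  # px/2*(|cos|+|sin|) beyond its center along the rotated u axis. Equals
  # plain half-pixel-per-side inflation for unrotated masks and varies
  # smoothly with theta, unlike grid snapping of rotated centers.
  infl <- if (inflate) (abs(ct) + abs(st))[tid] * pixel / 2 else 0
  opening <- (ext$umax - ext$umin + 2 * infl) * mlc$leaf_widths[b] / 100
  a_mlc <- as.numeric(rowsum(opening, tid, reorder = TRUE))
  pmin(a_tp / a_mlc, 1)
}

#' Construct an MCI heatmap from a matrix
#'
#' Mainly for tests, segmentation studies and reading heatmaps back from CSV.
#' @param values n_cp x n_theta matrix of MCI values in (0, 1\].
#' @param gantry Gantry angle per row, degrees (ordered along the arc).
#' @param thetas Collimator angle per column, degrees.
#' @param terminal_cp Is the last CP the terminal arc boundary (endpoint
#'   inclusive, the default for partial arcs)?
#' @export
as_mci_heatmap <- function(values, gantry, thetas, terminal_cp = TRUE) {
  stopifnot(is.matrix(values), nrow(values) == length(gantry),
            ncol(values) == length(thetas))
  if (any(!is.finite(values)) || any(values <= 0) || any(values > 1 + 1e-9)) {
    abort("heatmap values must be finite and in (0, 1]",
          class = "subarcvmat_config_error")
  }
  structure(list(values = values, gantry = as.numeric(gantry),
                 thetas = as.numeric(thetas), arc = NULL,
                 terminal_cp = terminal_cp),
            class = "mci_heatmap")
}

heatmap_cp_spacing <- function(h) {
  if (!is.null(h$arc)) return(h$arc$cp_spacing)
  d <- (h$gantry[2L] - h$gantry[1L]) %% 360
  min(d, 360 - d)
}

heatmap_terminal <- function(h) {
  if (!is.null(h$arc)) return(h$arc$total_span < 360)
  isTRUE(h$terminal_cp %||% TRUE)
}

#' Optimal collimator angle for a set of control points
#'
#' Sums MCI over the given control points for every collimator angle and
#' returns the angle with the highest sum (ties broken toward the lowest
#' angle).
#'
#' @param h An `mci_heatmap`.
#' @param cps Integer CP (row) indices; default all rows.
#' @return A one-row tibble: `theta`, `score`.
#' @export
select_collimator <- function(h, cps = NULL) {
  stopifnot(inherits(h, "mci_heatmap"))
  cps <- cps %||% seq_len(nrow(h$values))
  if (length(cps) == 0L) abort("empty control-point range",
                               class = "subarcvmat_config_error")
  s <- colSums(h$values[cps, , drop = FALSE])
  j <- which.max(s)  # first maximum = lowest theta
  tibble(theta = h$thetas[j], score = s[[j]])
}

# -- segmentation ------------------------------------------------------------

# S[a, b] = max over theta of sum(values[a:b, theta]); th[a, b] = argmax
# (lowest theta on ties). Computed from column cumsums.
segment_score_table <- function(values) {
  n <- nrow(values)
  C <- rbind(0, apply(values, 2L, cumsum))
  S <- matrix(-Inf, n, n)
  TH <- matrix(NA_integer_, n, n)
  for (b in seq_len(n)) {
    D <- C[rep.int(b + 1L, b), , drop = FALSE] - C[seq_len(b), , drop = FALSE]
    wm <- max.col(D, ties.method = "first")
    S[seq_len(b), b] <- D[cbind(seq_len(b), wm)]
    TH[seq_len(b), b] <- wm
  }
  list(S = S, TH = TH)
}

# minimum CP count of a segment ending at e (the terminal segment of an
# endpoint-inclusive arc needs one extra CP because its span is (len-1)*sp)
seg_min_len <- function(e, n, lmin, terminal) {
  if (terminal && e == n) lmin + 1L else lmin
}

#' Segment an arc into sub-arcs and pick each sub-arc's collimator
#'
#' Finds the contiguous partition of the arc's control points that maximizes
#' the total of each segment's best summed MCI, by exact dynamic programming,
#' subject to a minimum sub-arc span and a maximum sub-arc count. The
#' objective never decreases under splitting, so among partitions whose score
#' is within a relative tolerance `delta` of the best achievable over all
#' admissible counts, the one with the fewest sub-arcs is returned (low-MCI
#' heatmap regions are avoided because any segment forced to cross them
#' scores poorly at every collimator angle).
#'
#' @param h An `mci_heatmap`.
#' @param min_span Minimum sub-arc gantry span, degrees (default 30).
#' @param max_subarcs Maximum number of sub-arcs (default 9).
#' @param delta Relative score tolerance used to prefer fewer sub-arcs
#'   (default 0.01).
#' @return A tibble of class `subarc_plan`: one row per sub-arc with
#'   `cp_start`, `cp_end`, `gantry_start`, `gantry_end`, `span`,
#'   `collimator`, `score`; attributes `total_score` and `scores_by_k`.
#' @export
segment_subarcs <- function(h, min_span = 30, max_subarcs = 9, delta = 0.01) {
  stopifnot(inherits(h, "mci_heatmap"))
  sp <- heatmap_cp_spacing(h)
  terminal <- heatmap_terminal(h)
  if (min_span < sp) abort("min_span must be at least cp_spacing",
                           class = "subarcvmat_config_error")
  if (max_subarcs < 1L) abort("max_subarcs must be >= 1",
                              class = "subarcvmat_config_error")
  n <- nrow(h$values)
  lmin <- as.integer(ceiling(min_span / sp - 1e-9))
  if (n < lmin + as.integer(terminal)) {
    abort("infeasible constraints: arc shorter than the minimum sub-arc span",
          class = "subarcvmat_config_error")
  }
  st <- segment_score_table(h$values)
  kmax <- min(as.integer(max_subarcs),
              (n - as.integer(terminal)) %/% lmin)
  # g[k, i]: best score partitioning CPs i..n into exactly k segments
  g <- matrix(-Inf, kmax, n + 1L)
  for (i in n:1) {
    if (n - i + 1L >= seg_min_len(n, n, lmin, terminal)) g[1L, i] <- st$S[i, n]
  }
  if (kmax >= 2L) {
    for (k in 2:kmax) {
      hi <- n + 1L - k * lmin - as.integer(terminal)
      if (hi < 1L) next
      for (i in hi:1) {
        es <- (i + lmin - 1L):(n - 1L)
        cand <- st$S[i, es] + g[k - 1L, es + 1L]
        m <- max(cand)
        if (is.finite(m)) g[k, i] <- m
      }
    }
  }
  scores_k <- g[, 1L]
  if (!any(is.finite(scores_k))) {
    abort("infeasible constraints: no admissible segmentation",
          class = "subarcvmat_config_error")
  }
  best <- max(scores_k[is.finite(scores_k)])
  kstar <- which(is.finite(scores_k) & scores_k >= (1 - delta) * best)[1L]
  ends <- backtrack_ends(st$S, g, kstar, n, lmin, terminal)
  build_subarc_plan(h, ends, st, min_span, max_subarcs, delta,
                    scores_by_k = scores_k)
}

# lexicographically smallest end sequence achieving g[k, 1]
backtrack_ends <- function(S, g, k, n, lmin, terminal) {
  ends <- integer(k)
  i <- 1L
  for (r in k:1) {
    target <- g[r, i]
    tol <- 1e-9 * max(1, abs(target))
    if (r == 1L) {
      ends[k - r + 1L] <- n
      break
    }
    es <- (i + lmin - 1L):(n - 1L)
    cand <- S[i, es] + g[r - 1L, es + 1L]
    e <- es[which(cand >= target - tol)[1L]]
    ends[k - r + 1L] <- e
    i <- e + 1L
  }
  ends
}

build_subarc_plan <- function(h, ends, st, min_span, max_subarcs, delta,
                              scores_by_k = NULL) {
  sp <- heatmap_cp_spacing(h)
  terminal <- heatmap_terminal(h)
  n <- nrow(h$values)
  starts <- c(1L, head(ends, -1L) + 1L)
  k <- length(ends)
  rows <- lapply(seq_len(k), function(s) {
    i <- starts[s]; e <- ends[s]
    len <- e - i + 1L
    is_last <- e == n
    g_end <- if (is_last) {
      if (terminal) h$gantry[n] else h$gantry[1L]
    } else h$gantry[e + 1L]
    span <- if (is_last && terminal) (len - 1L) * sp else len * sp
    tibble(subarc = s, cp_start = i, cp_end = e,
           gantry_start = h$gantry[i], gantry_end = g_end, span = span,
           collimator = h$thetas[st$TH[i, e]], score = st$S[i, e])
  })
  out <- bind_rows(rows)
  class(out) <- c("subarc_plan", class(out))
  attr(out, "total_score") <- sum(out$score)
  attr(out, "n_subarcs") <- k
  attr(out, "cp_spacing") <- sp
  attr(out, "terminal_cp") <- terminal
  attr(out, "constraints") <- list(min_span = min_span,
                                   max_subarcs = max_subarcs, delta = delta)
  if (!is.null(scores_by_k)) {
    attr(out, "scores_by_k") <- tibble(k = seq_along(scores_by_k),
                                       score = scores_by_k)
  }
  out
}

#' Exhaustive-enumeration segmentation (test oracle)
#'
#' Enumerates every admissible contiguous partition (lexicographic order of
#' segment ends, strict-improvement updates) under the same objective,
#' constraints and tie-breaks as [segment_subarcs()]. Refuses instances with
#' more than 40 control points.
#'
#' @inheritParams segment_subarcs
#' @export
brute_force_segment <- function(h, min_span = 30, max_subarcs = 9,
                                delta = 0.01) {
  stopifnot(inherits(h, "mci_heatmap"))
  n <- nrow(h$values)
  if (n > 40L) abort("brute force refused for n_cp > 40",
                     class = "subarcvmat_config_error")
  sp <- heatmap_cp_spacing(h)
  terminal <- heatmap_terminal(h)
  if (min_span < sp) abort("min_span must be at least cp_spacing",
                           class = "subarcvmat_config_error")
  lmin <- as.integer(ceiling(min_span / sp - 1e-9))
  if (n < lmin + as.integer(terminal)) {
    abort("infeasible constraints: arc shorter than the minimum sub-arc span",
          class = "subarcvmat_config_error")
  }
  st <- segment_score_table(h$values)
  kmax <- min(as.integer(max_subarcs), (n - as.integer(terminal)) %/% lmin)
  best_score <- rep(-Inf, kmax)
  best_ends <- vector("list", kmax)
  rec <- function(i, ends, acc) {
    k_used <- length(ends)
    if (k_used >= kmax && i <= n) return(invisible())
    first_e <- i + lmin - 1L
    if (first_e > n) return(invisible())
    for (e in first_e:n) {
      len <- e - i + 1L
      if (e == n) {
        if (len < seg_min_len(n, n, lmin, terminal)) next
        tot <- acc + st$S[i, n]
        k <- k_used + 1L
        if (tot > best_score[k] + 1e-12 * max(1, abs(tot))) {
          best_score[k] <<- tot
          best_ends[[k]] <<- c(ends, n)
        }
      } else {
        rec(e + 1L, c(ends, e), acc + st$S[i, e])
      }
    }
  }
  rec(1L, integer(0), 0)
  if (!any(is.finite(best_score))) {
    abort("infeasible constraints: no admissible segmentation",
          class = "subarcvmat_config_error")
  }
  best <- max(best_score[is.finite(best_score)])
  kstar <- which(is.finite(best_score) & best_score >= (1 - delta) * best)[1L]
  build_subarc_plan(h, best_ends[[kstar]], st, min_span, max_subarcs, delta,
                    scores_by_k = best_score)
}

#' Jaw field size per sub-arc
#'
#' For each sub-arc, rotates every member control point's silhouette into the
#' sub-arc's collimator frame, fits the leaf extents, and takes the jaw
#' rectangle bounding all of them; the field size is that rectangle's area.
#' Requires a heatmap built by [mci_heatmap()] (which caches the per-CP
#' silhouettes).
#'
#' @param h An `mci_heatmap` with cached silhouettes.
#' @param plan A [segment_subarcs()] result for `h`.
#' @return `plan` with an `fs_cm2` column added.
#' @export
subarc_field_sizes <- function(h, plan) {
  stopifnot(inherits(h, "mci_heatmap"), inherits(plan, "subarc_plan"))
  if (is.null(h$silhouettes)) {
    abort("heatmap has no cached silhouettes; rebuild it with mci_heatmap()",
          class = "subarcvmat_config_error")
  }
  mlc <- h$mlc; px <- h$pixel
  half <- if (isTRUE(h$inflate)) px / 2 else 0
  fs <- map_dbl(seq_len(nrow(plan)), function(s) {
    th <- plan$collimator[s] * pi / 180
    uL <- Inf; uR <- -Inf; bmin <- Inf; bmax <- -Inf
    for (i in plan$cp_start[s]:plan$cp_end[s]) {
      b <- h$silhouettes[[i]]
      u <- b[, 1L] * cos(th) + b[, 2L] * sin(th)
      v <- -b[, 1L] * sin(th) + b[, 2L] * cos(th)
      band <- findInterval(v, mlc$edges)
      uL <- min(uL, min(u) - half)
      uR <- max(uR, max(u) + half)
      bmin <- min(bmin, min(band)); bmax <- max(bmax, max(band))
    }
    (uR - uL) * (mlc$edges[bmax + 1L] - mlc$edges[bmin]) / 100
  })
  plan$fs_cm2 <- fs
  plan
}

#' Format a sub-arc plan in gantry-range notation
#'
#' One token per sub-arc, `"<gantry_start>-<gantry_end>/<collimator>"`
#' (degrees mod 360, in arc direction), e.g. `"179-71/91, 71-293/95,
#' 293-181/91"`.
#' @param plan A `subarc_plan`.
#' @export
plan_string <- function(plan) {
  stopifnot(inherits(plan, "subarc_plan"))
  paste(sprintf("%s-%s/%s",
                formatC(plan$gantry_start %% 360, format = "g"),
                formatC(plan$gantry_end %% 360, format = "g"),
                formatC(plan$collimator, format = "g")),
        collapse = ", ")
}

#' @rdname plan_string
#' @param s A plan string as produced by [plan_string()].
#' @export
parse_plan_string <- function(s) {
  toks <- strsplit(trimws(strsplit(s, ",")[[1]]), "[-/]")
  bind_rows(lapply(seq_along(toks), function(i) {
    v <- as.numeric(toks[[i]])
    tibble(subarc = i, gantry_start = v[1], gantry_end = v[2], collimator = v[3])
  }))
}
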