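#' Tidy an MCI heatmap into long form
#'
#' @param x An `mci_heatmap`.
#' @param ... Unused.
#' @return A tibble: `cp`, `gantry`, `theta`, `mci`.
#' @export
tidy.mci_heatmap <- function(x, ...) {
  tibble(cp = rep(seq_along(x$gantry), times = length(x$thetas)),
         gantry = rep(x$gantry, times = length(x$thetas)),
         theta = rep(x$thetas, each = length(x$gantry)),
         mci = as.vector(x$values))
}

#' @rdname tidy.mci_heatmap
#' @export
glance.mci_heatmap <- function(x, ...) {
  tibble(n_cp = nrow(x$values), n_theta = ncol(x$values),
         mci_min = min(x$values), mci_mean = mean(x$values),
         mci_max = max(x$values))
}

#' Tidy / summarize a sub-arc plan
#'
#' @param x A `subarc_plan`.
#' @param ... Unused.
#' @export
tidy.subarc_plan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "subarc_plan")
  as_tibble(out)
}

#' @rdname tidy.subarc_plan
#' @export
glance.subarc_plan <- function(x, ...) {
  tibble(n_subarcs = nrow(x), total_score = attr(x, "total_score"),
         min_span = min(x$span), mean_span = mean(x$span),
         mean_mci = attr(x, "total_score") /
           sum(x$cp_end - x$cp_start + 1L))
}

#' Tidy / summarize a phantom
#'
#' @param x A `phantom`.
#' @param ... Unused.
#' @export
tidy.phantom <- function(x, ...) x$lesions

#' @rdname tidy.phantom
#' @export
glance.phantom <- function(x, ...) {
  rmax <- if (nrow(x$lesions) >= 2L) phantom_rmax(x) else NULL
  out <- tibble(n_lesions = nrow(x$lesions),
                total_volume_cc = sum(x$lesions$volume_cc),
                head_radius_mm = x$head_radius)
  if (!is.null(rmax)) {
    out$rmax_x_cm <- rmax$r_max_cm[rmax$axis == "x"]
    out$rmax_y_cm <- rmax$r_max_cm[rmax$axis == "y"]
    out$rmax_z_cm <- rmax$r_max_cm[rmax$axis == "z"]
  }
  out
}

#' @export
print.mci_heatmap <- function(x, ...) {
  cat(sprintf("<mci_heatmap> %d control points x %d collimator angles\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  gantry %g..%g, MCI in [%.3f, %.3f]\n",
              x$gantry[1], x$gantry[length(x$gantry)],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d lesion(s), %.1f cc total, head radius %g mm\n",
              nrow(x$lesions), sum(x$lesions$volume_cc), x$head_radius))
  print(x$lesions)
  invisible(x)
}
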