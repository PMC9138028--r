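#' Piecewise-linear stress-strain curve
#'
#' A stress-strain law represented as an ordered list of linear
#' segments.  Each segment has a label (`unfold`,
#' `stretch_pre_hyper`, `stretch_post_hyper`, `plateau`, `drop`), a
#' strain window `[eps_start, eps_end)`, the stress at its left edge
#' (`sigma_start`, Pa) and a slope (`modulus`, Pa).  Segments tile
#' `[0, Inf)`; stress is continuous across boundaries except at
#' designed drops (crosslink rupture, bond rupture), where it may only
#' decrease and evaluation returns the right limit.
#'
#' @param segments A data.frame with columns `label`, `eps_start`,
#'   `eps_end`, `sigma_start`, `modulus`.
#' @param metadata Named list of provenance labels (model variant,
#'   fibril diameter, crosslink density, ...).
#' @return An object of class `stress_strain_curve`.
#' @export
stress_strain_curve <- function(segments, metadata = list()) {
  need <- c("label", "eps_start", "eps_end", "sigma_start", "modulus")
  stopifnot(is.data.frame(segments), all(need %in% names(segments)))
  segments <- segments[, need]
  n <- nrow(segments)
  stopifnot(n >= 1)
  if (segments$eps_start[1] != 0)
    stop("first segment must start at zero strain", call. = FALSE)
  if (is.finite(segments$eps_end[n]))
    stop("last segment must be open-ended (eps_end = Inf)", call. = FALSE)
  if (any(segments$eps_start >= segments$eps_end))
    stop("each segment needs eps_start < eps_end", call. = FALSE)
  drops <- numeric(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      if (abs(segments$eps_end[i] - segments$eps_start[i + 1]) > 1e-12)
        stop("segments must be contiguous in strain", call. = FALSE)
      s_end <- segments$sigma_start[i] +
        segments$modulus[i] * (segments$eps_end[i] - segments$eps_start[i])
      gap <- segments$sigma_start[i + 1] - s_end
      if (gap > 1e-6 * max(1, abs(s_end)))
        stop("stress may not jump upward between segments", call. = FALSE)
      if (gap < -1e-6 * max(1, abs(s_end)))
        drops <- c(drops, segments$eps_end[i])
    }
  }
  structure(list(segments = segments, metadata = metadata, drops = drops),
            class = "stress_strain_curve")
}

#' Segment table of a curve
#'
#' @param curve A [stress_strain_curve()].
#' @return The segment data.frame.
#' @export
curve_segments <- function(curve) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  curve$segments
}

#' Evaluate a stress-strain curve
#'
#' Piecewise-linear evaluation.  At a boundary shared by two continuous
#' segments both sides agree; at a drop the right limit (post-drop
#' stress) is returned.
#'
#' @param curve A [stress_strain_curve()].
#' @param eps Strain value(s), dimensionless, >= 0.
#' @return Stress in Pa (vectorised over `eps`).
#' @export
evaluate_curve <- function(curve, eps) {
  stopifnot(inherits(curve, "stress_strain_curve"), is.numeric(eps))
  if (any(eps < 0)) stop("strain must be non-negative", call. = FALSE)
  seg <- curve$segments
  i <- findInterval(eps, seg$eps_start)  # right-continuous by construction
  seg$sigma_start[i] + seg$modulus[i] * (eps - seg$eps_start[i])
}

# Stress at segment right edges (finite ones), used for maxima.
.segment_end_stress <- function(curve) {
  seg <- curve$segments
  fin <- is.finite(seg$eps_end)
  ends <- seg$sigma_start[fin] +
    seg$modulus[fin] * (seg$eps_end[fin] - seg$eps_start[fin])
  c(seg$sigma_start, ends)
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  md <- x$metadata
  tag <- if (length(md)) {
    paste0(" (", paste(names(md), unlist(md), sep = " = ", collapse = ", "), ")")
  } else ""
  cat("Piecewise-linear stress-strain curve", tag, "\n", sep = "")
  seg <- x$segments
  for (i in seq_len(nrow(seg))) {
    cat(sprintf("  %-18s strain %7.3f%% -> %8s  stress %8.1f MPa + %8.2f GPa x d-eps\n",
                seg$label[i], 100 * seg$eps_start[i],
                ifelse(is.finite(seg$eps_end[i]),
                       sprintf("%.3f%%", 100 * seg$eps_end[i]), "Inf"),
                seg$sigma_start[i] / 1e6, seg$modulus[i] / 1e9))
  }
  if (length(x$drops))
    cat(sprintf("  stress drop(s) at strain %s\n",
                paste(sprintf("%.2f%%", 100 * x$drops), collapse = ", ")))
  invisible(x)
}

#' @export
plot.stress_strain_curve <- function(x, eps_max = NULL, n = 400,
                                     xlab = "strain", ylab = "stress (GPa)",
                                     ...) {
  seg <- x$segments
  if (is.null(eps_max)) {
    last_fin <- max(seg$eps_start)
    eps_max <- 1.15 * max(last_fin, 0.01)
  }
  eps <- sort(unique(c(seq(0, eps_max, length.out = n),
                       seg$eps_start, x$drops,
                       pmin(x$drops - 1e-9, eps_max))))
  eps <- eps[eps >= 0 & eps <= eps_max]
  plot(eps, evaluate_curve(x, eps) / 1e9, type = "l",
       xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Export a curve as CSV or JSON
#'
#' `write_curve_csv()` samples the curve on a strain grid and writes
#' columns `strain`, `stress_Pa`.  `write_curve_json()` dumps the
#' segment table (labels, endpoints, slopes) plus metadata.
#'
#' @param curve A [stress_strain_curve()].
#' @param path Output file path.
#' @param eps_max Largest strain sampled (default: 15% past the last
#'   breakpoint).
#' @param n Number of grid points.
#' @return The path, invisibly.
#' @export
write_curve_csv <- function(curve, path, eps_max = NULL, n = 500) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  seg <- curve$segments
  if (is.null(eps_max)) eps_max <- 1.15 * max(seg$eps_start, 0.01)
  eps <- sort(unique(c(seq(0, eps_max, length.out = n), seg$eps_start)))
  eps <- eps[eps <= eps_max]
  utils::write.csv(data.frame(strain = eps,
                              stress_Pa = evaluate_curve(curve, eps)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
write_curve_json <- function(curve, path) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  jsonlite::write_json(list(metadata = curve$metadata,
                            segments = curve$segments,
                            drops = curve$drops),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
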