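#' Temporal expression archetypes
#'
#' The eight qualitative trajectories used to describe gene expression over
#' the osteoclast differentiation time course: early / mid / late peaking and
#' transient trajectories, each in an up- and down-regulated flavour. A ninth
#' label, `"null"`, denotes flat (non differentially expressed) genes in the
#' synthetic generator.
#'
#' @format Character vector of the eight signal archetype names.
#' @export
ARCHETYPES <- c(
  "early_up", "mid_up", "late_up", "transient_up",
  "early_down", "mid_down", "late_down", "transient_down"
)

#' Evaluate an archetype profile at the study timepoints
#'
#' Profiles are piecewise linear in log2 space, anchored at the first
#' timepoint (baseline 0), the peak timepoint, and the last timepoint:
#' early profiles peak at the second timepoint and partially decline,
#' mid profiles peak at the middle interior timepoint, late profiles ramp
#' monotonically to the last timepoint, and transient profiles return to
#' baseline by the last timepoint. Down archetypes are mirror images.
#'
#' @param archetype One of [ARCHETYPES] or `"null"`.
#' @param timepoints Strictly increasing numeric vector of days (>= 3 values).
#' @param amplitude Peak absolute log2 fold change.
#' @return Numeric vector of log2 fold changes relative to baseline, one per
#'   timepoint.
#' @examples
#' archetype_profile("transient_up", c(0, 2, 5, 9), amplitude = 2)
#' @export
archetype_profile <- function(archetype, timepoints, amplitude = 1) {
  stopifnot(length(timepoints) >= 3, !is.unsorted(timepoints, strictly = TRUE))
  if (archetype == "null") return(rep(0, length(timepoints)))
  if (!archetype %in% ARCHETYPES) stop("unknown archetype: ", archetype)
  parts <- strsplit(archetype, "_", fixed = TRUE)[[1]]
  kind <- parts[1]
  sign <- if (parts[2] == "up") 1 else -1
  t1 <- timepoints[1]
  t2 <- timepoints[2]
  tl <- timepoints[length(timepoints)]
  tm <- timepoints[ceiling((length(timepoints) + 1) / 2)]
  shape <- switch(kind,
    early     = stats::approx(c(t1, t2, tl), c(0, 1, 0.7), xout = timepoints)$y,
    mid       = stats::approx(c(t1, tm, tl), c(0, 1, 0.8), xout = timepoints)$y,
    late      = stats::approx(c(t1, tl), c(0, 1), xout = timepoints)$y,
    transient = stats::approx(c(t1, t2, tl), c(0, 1, 0), xout = timepoints)$y
  )
  sign * amplitude * shape
}

# label a single z-scored centroid profile; see label_archetypes()
.label_profile <- function(z, timepoints) {
  tn <- length(z)
  up_amp <- max(z) - z[1]
  down_amp <- z[1] - min(z)
  if (up_amp == 0 && down_amp == 0) return("flat")
  if (up_amp >= down_amp) {
    p <- which.max(z)
    if (p == tn) return("late_up")
    # interior peak: transient if the profile has returned at least half-way
    # from the peak back toward the starting value by the last timepoint
    if (z[tn] <= (max(z) + z[1]) / 2) return("transient_up")
    if (p == 2) return("early_up") else return("mid_up")
  } else {
    p <- which.min(z)
    if (p == tn) return("late_down")
    if (z[tn] >= (min(z) + z[1]) / 2) return("transient_down")
    if (p == 2) return("early_down") else return("mid_down")
  }
}

#' Label cluster centroids with temporal archetypes
#'
#' Assigns each z-scored centroid one of the eight archetype labels from the
#' position of its extremum and its endpoint behaviour: an extremum at the
#' last timepoint gives `late_*`; an interior extremum whose profile returns
#' at least half-way back toward the starting value by the last timepoint
#' gives `transient_*`; otherwise `early_*` (extremum at the second
#' timepoint) or `mid_*` (later interior extremum). Direction (up vs down)
#' is decided by whether the rise above or the dip below the starting value
#' is larger.
#'
#' @param centroids Numeric matrix, clusters x timepoints (z-scored profiles),
#'   or a `cluster_assignment` object from [kmeans_cluster()].
#' @param timepoints Numeric vector of days (taken from the object when a
#'   `cluster_assignment` is supplied).
#' @return For a matrix, a character vector of labels; for a
#'   `cluster_assignment`, the object with `$labels` set and an `archetype`
#'   column merged into `$assignment`.
#' @export
label_archetypes <- function(centroids, timepoints = NULL) {
  if (inherits(centroids, "cluster_assignment")) {
    ca <- centroids
    labs <- label_archetypes(ca$centroids, ca$timepoints)
    ca$labels <- labs
    ca$assignment$archetype <- labs[ca$assignment$cluster]
    return(ca)
  }
  stopifnot(is.matrix(centroids))
  timepoints <- timepoints %||% seq_len(ncol(centroids))
  apply(centroids, 1, .label_profile, timepoints = timepoints)
}
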