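#' Single-particle trajectory
#'
#' A trajectory is an ordered sequence of 2D positions (in micrometres)
#' recorded at a fixed frame interval. Positions are stored as an
#' \eqn{(N+1) \times 2} matrix, where \eqn{N} is the number of displacements.
#'
#' @param id Track identifier (coerced to character).
#' @param pos Numeric matrix with two columns (x, y positions in um) and at
#'   least two rows, or a data.frame with columns \code{x} and \code{y}.
#'
#' @return Object of class \code{"trajectory"}.
#' @export
trajectory <- function(id, pos) {
  if (is.data.frame(pos)) pos <- as.matrix(pos[, c("x", "y")])
  if (!is.matrix(pos) || ncol(pos) != 2L)
    stop("'pos' must be a two-column matrix of x, y positions")
  storage.mode(pos) <- "double"
  if (nrow(pos) < 2L)
    stop("a trajectory needs at least 2 positions (1 displacement)")
  if (!all(is.finite(pos)))
    stop("positions must be finite")
  colnames(pos) <- c("x", "y")
  structure(list(id = as.character(id)[1L], pos = pos), class = "trajectory")
}

#' Number of displacements of a trajectory
#' @param traj A \code{"trajectory"}.
#' @return Integer, \code{nrow(traj$pos) - 1}.
#' @export
n_steps <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  nrow(traj$pos) - 1L
}

#' Frame-to-frame displacements of a trajectory
#'
#' @param traj A \code{"trajectory"}.
#' @param dim Spatial dimension: 1 (x) or 2 (y), or \code{NULL} for both.
#' @return If \code{dim} is given, a numeric vector of length
#'   \code{n_steps(traj)} with entries \code{pos[n+1] - pos[n]}; otherwise the
#'   \code{n_steps x 2} displacement matrix.
#' @examples
#' tr <- trajectory("a", cbind(c(0, 0.1, 0.3), c(0, 0, 0)))
#' displacements(tr, 1)  # 0.1 0.2
#' @export
displacements <- function(traj, dim = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  d <- diff(traj$pos)
  if (is.null(dim)) return(d)
  if (!dim %in% c(1L, 2L)) stop("'dim' must be 1 or 2")
  d[, dim]
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory '%s': %d positions (%d displacements)\n",
              x$id, nrow(x$pos), nrow(x$pos) - 1L))
  invisible(x)
}

#' Collection of trajectories sharing acquisition settings
#'
#' @param tracks List of \code{"trajectory"} objects.
#' @param acquisition An \code{\link{acquisition_params}} object shared by all
#'   tracks.
#' @return Object of class \code{"track_set"}.
#' @export
track_set <- function(tracks, acquisition) {
  stopifnot_acq(acquisition)
  if (!is.list(tracks) || length(tracks) == 0L)
    stop("'tracks' must be a non-empty list of trajectories")
  ok <- vapply(tracks, inherits, logical(1), "trajectory")
  if (!all(ok)) stop("all elements of 'tracks' must be trajectory objects")
  structure(list(tracks = tracks, acquisition = acquisition),
            class = "track_set")
}

#' @export
length.track_set <- function(x) length(x$tracks)

#' @export
`[.track_set` <- function(x, i) {
  track_set(x$tracks[i], x$acquisition)
}

#' @export
print.track_set <- function(x, ...) {
  ns <- vapply(x$tracks, function(t) nrow(t$pos) - 1L, integer(1))
  cat(sprintf("Track set: %d trajectories, %d-%d displacements (median %g)\n",
              length(x$tracks), min(ns), max(ns), stats::median(ns)))
  print(x$acquisition)
  invisible(x)
}

#' @export
as.data.frame.track_set <- function(x, ...) {
  do.call(rbind, lapply(x$tracks, function(t) {
    data.frame(track_id = t$id, frame = seq_len(nrow(t$pos)),
               x = t$pos[, 1L], y = t$pos[, 2L], row.names = NULL)
  }))
}

#' Read trajectories from a delimited table
#'
#' Reads a CSV table with columns \code{track_id}, \code{frame}, \code{x},
#' \code{y} (positions in um), groups rows into tracks, and applies the
#' minimum-length filter. Frames within a track must be strictly increasing;
#' tracks with frame gaps are dropped by default (a gap would make the time
#' between consecutive rows non-uniform and corrupt the displacement
#' covariance) or split into contiguous segments when \code{split_gaps = TRUE}.
#'
#' @param path Path to a CSV file with header \code{track_id,frame,x,y}.
#' @param acquisition \code{\link{acquisition_params}} for this dataset.
#' @param min_length Minimum number of displacements a track must have to be
#'   retained. Default 15, the usual sptPALM minimum-track-length cutoff.
#' @param split_gaps If \code{TRUE}, tracks with gaps in \code{frame} are
#'   split at each gap into contiguous segments (segments re-filtered by
#'   \code{min_length}); if \code{FALSE} (default) such tracks are dropped
#'   with a warning.
#' @return A \code{\link{track_set}}.
#' @export
read_tracks <- function(path, acquisition, min_length = 15L,
                        split_gaps = FALSE) {
  stopifnot_acq(acquisition)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "x", "y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("trajectory table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tracks_from_table(df, acquisition, min_length, split_gaps)
}

# Shared grouping/filtering core for read_tracks and in-memory tables.
tracks_from_table <- function(df, acquisition, min_length, split_gaps) {
  pieces <- split(df, factor(df$track_id, levels = unique(df$track_id)))
  out <- list()
  dropped <- 0L
  for (p in pieces) {
    p <- p[order(p$frame), , drop = FALSE]
    dfr <- diff(p$frame)
    segs <- if (all(dfr == 1L)) {
      list(p)
    } else if (split_gaps) {
      idx <- cumsum(c(1L, as.integer(dfr != 1L)))
      split(p, idx)
    } else {
      dropped <- dropped + 1L
      list()
    }
    for (s in segs) {
      if (nrow(s) - 1L >= min_length) {
        id <- as.character(s$track_id[1L])
        if (length(segs) > 1L)
          id <- paste0(id, ".", s$frame[1L])
        out[[length(out) + 1L]] <- trajectory(id, cbind(x = s$x, y = s$y))
      }
    }
  }
  if (dropped > 0L)
    warning(sprintf("dropped %d track(s) with non-contiguous frames", dropped))
  if (length(out) == 0L)
    stop("no tracks with >= ", min_length, " displacements")
  track_set(out, acquisition)
}

#' Write trajectories to a delimited table
#'
#' Emits the same CSV schema that \code{\link{read_tracks}} reads
#' (\code{track_id,frame,x,y}, positions in um), so write-then-read is the
#' identity on the retained tracks.
#'
#' @param tracks A \code{\link{track_set}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"))
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
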