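#' Trajectory containers
#'
#' A trajectory is a `d x T` (latent) or `n x T` (lifted) numeric matrix whose
#' columns are states ordered by time; step labels are 0-based, so column
#' `t + 1` holds the state at step `t`. `latent_trajectory()` wraps a
#' low-dimensional ground-truth state sequence, `lifted_trajectory()` a
#' high-dimensional observed sequence together with the provenance (source
#' trajectory, lifting map, noise) that produced it.
#'
#' @param values numeric matrix, one column per time step.
#' @param provenance optional list recording how a lifted trajectory was made.
#' @return An object of class `latent_trajectory` or `lifted_trajectory`
#'   (both inherit `ekatp_trajectory`) with fields `values`, `d`/`n`, `T`,
#'   and `time` (0-based step labels).
#' @export
latent_trajectory <- function(values) {
  values <- as.matrix(values)
  check_finite(values, "latent trajectory")
  structure(
    list(values = values, d = nrow(values), T = ncol(values),
         time = seq_len(ncol(values)) - 1L),
    class = c("latent_trajectory", "ekatp_trajectory")
  )
}

#' @rdname latent_trajectory
#' @export
lifted_trajectory <- function(values, provenance = list()) {
  values <- as.matrix(values)
  check_finite(values, "lifted trajectory")
  structure(
    list(values = values, n = nrow(values), T = ncol(values),
         time = seq_len(ncol(values)) - 1L, provenance = provenance),
    class = c("lifted_trajectory", "ekatp_trajectory")
  )
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    bad <- which(!apply(is.finite(x), 2, all))[1]
    stop(sprintf("%s contains non-finite values (first bad step: %d)",
                 what, bad - 1L), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.ekatp_trajectory <- function(x, ...) {
  kind <- if (inherits(x, "latent_trajectory")) "latent" else "lifted"
  cat(sprintf("<%s trajectory: %d states x %d steps>\n",
              kind, nrow(x$values), x$T))
  invisible(x)
}

#' @export
dim.ekatp_trajectory <- function(x) dim(x$values)

#' Read and write trajectories as TSV
#'
#' Plain-text interchange format: a header row `t, s1, ..., sd`, one row per
#' time step, a 0-based step column, values at full double precision.
#'
#' @param traj an `ekatp_trajectory` (or bare matrix, columns = steps).
#' @param path file path.
#' @export
write_trajectory_tsv <- function(traj, path) {
  values <- if (inherits(traj, "ekatp_trajectory")) traj$values else as.matrix(traj)
  d <- nrow(values)
  df <- data.frame(t = seq_len(ncol(values)) - 1L, t(values))
  names(df) <- c("t", paste0("s", seq_len(d)))
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_tsv
#' @param lifted return a `lifted_trajectory` instead of a `latent_trajectory`.
#' @export
read_trajectory_tsv <- function(path, lifted = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (names(df)[1] != "t")
    stop("trajectory TSV must have a leading 't' step column")
  values <- t(as.matrix(df[, -1, drop = FALSE]))
  dimnames(values) <- NULL
  if (lifted) lifted_trajectory(values) else latent_trajectory(values)
}
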