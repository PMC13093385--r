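#' Build the detection vector of a sampled pedigree
#'
#' The detection vector `y` holds, for each unique parent detected in the
#' sample, the number of sampled offspring naming that parent. Every
#' offspring contributes one count to its mother and one to its father, so
#' `sum(y) == 2 * n_obs` always. An offspring with no sibling matches adds
#' two 1's; a triad of maternal half-siblings adds a single 3 and three 1's.
#'
#' @param x An `"offspring_sample"`, or a numeric vector of per-parent counts
#'   (for externally reconstructed pedigrees), in which case `n_obs` must be
#'   supplied.
#' @param n_obs Number of sampled offspring; only used when `x` is a bare
#'   count vector.
#' @return An object of class `"detection_vector"`: list with `y` (integer
#'   counts, one per detected parent), `n_det`, `n_obs` and `freq` (named
#'   counts `a1`..`a4` of parents detected exactly 1--4 times).
#' @examples
#' # a triad of half-siblings: one shared mother, three distinct fathers
#' detection_vector(c(3, 1, 1, 1), n_obs = 3)
#' @export
detection_vector <- function(x, n_obs = NULL) {
  if (inherits(x, "offspring_sample")) {
    if (x$n_obs == 0L) stop("empty sample: detection vector undefined")
    y <- as.integer(tabulate(factor(c(x$records$mother_id, x$records$father_id))))
    n_obs <- x$n_obs
  } else {
    y <- as.integer(x)
    if (is.null(n_obs)) stop("n_obs is required when supplying raw counts")
    n_obs <- as.integer(n_obs)
    if (length(y) == 0L) stop("empty detection vector")
    if (any(y < 1L)) stop("detection counts must be >= 1")
    if (sum(y) != 2L * n_obs)
      warning("sum(y) != 2 * n_obs: expected when both parents of every ",
              "offspring are assigned; proceeding anyway")
  }
  freq <- vapply(1:4, function(k) sum(y == k), integer(1L))
  names(freq) <- paste0("a", 1:4)
  structure(list(y = y, n_det = length(y), n_obs = n_obs, freq = freq),
            class = "detection_vector")
}

#' @export
print.detection_vector <- function(x, ...) {
  cat("Detection vector: n_det =", x$n_det, ", n_obs =", x$n_obs, "\n")
  cat("  ", paste(names(x$freq), x$freq, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a detection vector as plain text
#'
#' One count per line, with a JSON sidecar (`<path>.json`) recording `n_obs`
#' and `n_det`. This is also the entry point for users bringing per-parent
#' offspring counts from a real reconstructed pedigree.
#'
#' @param d A `"detection_vector"`.
#' @param path File path for the counts; sidecar written to `<path>.json`.
#' @export
write_detection_vector <- function(d, path) {
  stopifnot(inherits(d, "detection_vector"))
  writeLines(as.character(d$y), path)
  jsonlite::write_json(list(n_obs = d$n_obs, n_det = d$n_det),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_detection_vector
#' @param n_obs Overrides the sidecar's `n_obs` (required if no sidecar).
#' @export
read_detection_vector <- function(path, n_obs = NULL) {
  y <- as.integer(readLines(path))
  if (is.null(n_obs)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("no n_obs given and no sidecar found at ", sidecar)
    n_obs <- jsonlite::read_json(sidecar)$n_obs
  }
  detection_vector(y, n_obs = n_obs)
}
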