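# Pedigree-reconstruction error injectors.
#
# Both operate on an offspring_sample and return a modified copy; eligibility
# is evaluated once on the input sample before any flips, and each parent slot
# (maternal, paternal) of an eligible offspring flips independently with the
# given rate.

# offspring with at least one sampled sibling (shared mother or father)
has_sibling <- function(records) {
  dm <- duplicated(records$mother_id) | duplicated(records$mother_id, fromLast = TRUE)
  df <- duplicated(records$father_id) | duplicated(records$father_id, fromLast = TRUE)
  dm | df
}

#' Inject Type I (false-positive sibship) pedigree errors
#'
#' A Type I reconstruction error infers a sibling relationship between two
#' offspring that share no parent, merging two distinct parents into one and
#' so reducing the number of detected parents. Only offspring with no
#' detected sibling in the sample ("true negatives") are eligible; for each,
#' the maternal and paternal assignments each flip with probability `rate`,
#' and a flipped parent is replaced by a uniformly chosen *different* parent
#' of the same sex drawn from the unique parents of the original sample. If
#' no alternative same-sex parent exists the slot is left unchanged with a
#' warning.
#'
#' @param sample An `"offspring_sample"`.
#' @param rate Per-parent-slot flip probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @return A new `"offspring_sample"`; the input is unchanged.
#' @seealso [inject_type2()]
#' @export
inject_type1 <- function(sample, rate, seed = NULL) {
  stopifnot(inherits(sample, "offspring_sample"))
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate > 1)
    stop("rate must be a probability in [0, 1]")
  if (rate == 0 || sample$n_obs == 0L) return(sample)
  if (!is.null(seed)) set.seed(seed)

  rec <- sample$records
  eligible <- which(!has_sibling(rec))
  if (length(eligible) == 0L) return(sample)

  pool_m <- unique(rec$mother_id)
  pool_f <- unique(rec$father_id)
  flip_m <- stats::runif(length(eligible)) < rate
  flip_f <- stats::runif(length(eligible)) < rate

  warn_noalt <- FALSE
  for (k in seq_along(eligible)) {
    i <- eligible[k]
    if (flip_m[k]) {
      alt <- pool_m[pool_m != rec$mother_id[i]]
      if (length(alt) == 0L) warn_noalt <- TRUE
      else rec$mother_id[i] <- alt[sample.int(length(alt), 1L)]
    }
    if (flip_f[k]) {
      alt <- pool_f[pool_f != rec$father_id[i]]
      if (length(alt) == 0L) warn_noalt <- TRUE
      else rec$father_id[i] <- alt[sample.int(length(alt), 1L)]
    }
  }
  if (warn_noalt)
    warning("some flips skipped: no alternative same-sex parent in the sample")

  out <- sample
  out$records <- rec
  out
}

#' Inject Type II (false-negative sibship) pedigree errors
#'
#' A Type II reconstruction error fails to detect a true sibling
#' relationship, splitting one true parent into several apparent parents and
#' so inflating the number of detected parents. Only offspring with at least
#' one detected sibling are eligible; for each, the maternal and paternal
#' assignments each flip with probability `rate`, and a flipped parent is
#' replaced by a brand-new same-sex parent identifier unique to that
#' offspring (not found elsewhere in the sample).
#'
#' @inheritParams inject_type1
#' @return A new `"offspring_sample"`; novel parent ids extend beyond the
#'   original population and their sexes are recorded in `$novel_sex`.
#' @export
inject_type2 <- function(sample, rate, seed = NULL) {
  stopifnot(inherits(sample, "offspring_sample"))
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate > 1)
    stop("rate must be a probability in [0, 1]")
  if (rate == 0 || sample$n_obs == 0L) return(sample)
  if (!is.null(seed)) set.seed(seed)

  rec <- sample$records
  eligible <- which(has_sibling(rec))
  if (length(eligible) == 0L) return(sample)

  flip_m <- stats::runif(length(eligible)) < rate
  flip_f <- stats::runif(length(eligible)) < rate
  n_new <- sum(flip_m) + sum(flip_f)
  if (n_new == 0L) {
    out <- sample
    out$records <- rec
    return(out)
  }
  new_ids <- sample$max_parent_id + seq_len(n_new)
  new_sex <- character(n_new)
  nxt <- 1L
  for (k in seq_along(eligible)) {
    i <- eligible[k]
    if (flip_m[k]) {
      rec$mother_id[i] <- new_ids[nxt]
      new_sex[nxt] <- "female"
      nxt <- nxt + 1L
    }
    if (flip_f[k]) {
      rec$father_id[i] <- new_ids[nxt]
      new_sex[nxt] <- "male"
      nxt <- nxt + 1L
    }
  }

  out <- sample
  out$records <- rec
  out$max_parent_id <- sample$max_parent_id + n_new
  out$novel_sex <- c(sample$novel_sex,
                     stats::setNames(new_sex, as.character(new_ids)))
  out
}
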