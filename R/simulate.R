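#' Define a breeding scenario
#'
#' A breeding scenario fixes the composition of the spawning population and
#' the mating-system parameters used by [simulate_breeding()]. The defaults
#' emulate typical salmonid reproductive ecology: each individual takes a
#' Poisson (lambda = 4) number of mates and each female produces a total
#' number of offspring drawn uniformly from 2500--6500.
#'
#' The true parental abundance of the scenario is `n_females + n_males`; the
#' simulator guarantees that every configured adult parents at least one
#' offspring, so this total is exactly the estimand recovered by the
#' estimators in this package.
#'
#' @param n_females,n_males Number of breeding females and males (each >= 1).
#' @param mate_lambda Mean of the (zero-truncated) Poisson number of mates per
#'   female. Must be positive.
#' @param fecundity Length-2 integer vector, the inclusive range of the
#'   discrete-uniform total offspring count per female.
#'
#' @return An object of class `"breeding_scenario"`.
#' @seealso [simulate_breeding()], [sample_offspring()]
#' @examples
#' breeding_scenario(12, 13)
#' @export
breeding_scenario <- function(n_females, n_males, mate_lambda = 4,
                              fecundity = c(2500L, 6500L)) {
  n_females <- as.integer(n_females)
  n_males <- as.integer(n_males)
  if (is.na(n_females) || n_females < 1L) stop("n_females must be >= 1")
  if (is.na(n_males) || n_males < 1L) stop("n_males must be >= 1")
  if (!is.numeric(mate_lambda) || length(mate_lambda) != 1L || mate_lambda <= 0)
    stop("mate_lambda must be a positive scalar")
  fecundity <- as.integer(fecundity)
  if (length(fecundity) != 2L || anyNA(fecundity) || fecundity[1L] > fecundity[2L] ||
      fecundity[1L] < 1L)
    stop("fecundity must be an increasing positive range c(min, max)")
  structure(
    list(n_females = n_females, n_males = n_males, mate_lambda = mate_lambda,
         fecundity_min = fecundity[1L], fecundity_max = fecundity[2L],
         true_n_p = n_females + n_males),
    class = "breeding_scenario"
  )
}

#' @export
print.breeding_scenario <- function(x, ...) {
  cat("Breeding scenario:", x$n_females, "females +", x$n_males,
      "males (N_P =", x$true_n_p, ")\n")
  cat("  mates per female ~ zero-truncated Poisson(", x$mate_lambda, ")\n", sep = "")
  cat("  female fecundity ~ Uniform{", x$fecundity_min, "..", x$fecundity_max,
      "}\n", sep = "")
  invisible(x)
}

# Exact zero-truncated Poisson draws by inverse CDF restricted to x >= 1.
rztpois <- function(n, lambda) {
  u <- stats::runif(n, stats::dpois(0L, lambda), 1)
  stats::qpois(u, lambda)
}

#' Split a total abundance between the sexes
#'
#' Integer split of a total parental abundance `n_p` at a given female
#' proportion; the rounding remainder is assigned to the males, so a 1:1
#' ratio with odd `n_p` yields one more male than female.
#'
#' @param n_p Total number of parents.
#' @param prop_female Proportion of females, in (0, 1).
#' @return Integer vector `c(n_females, n_males)`.
#' @examples
#' split_sexes(25)   # 12 females, 13 males
#' @export
split_sexes <- function(n_p, prop_female = 0.5) {
  n_p <- as.integer(n_p)
  if (n_p < 2L) stop("n_p must be >= 2 (at least one parent per sex)")
  nf <- max(1L, min(n_p - 1L, as.integer(floor(n_p * prop_female))))
  c(n_females = nf, n_males = n_p - nf)
}

#' Simulate a breeding cohort with known parentage
#'
#' Generates the full offspring cohort of one breeding event. Each female
#' draws a zero-truncated Poisson number of mates (capped at the number of
#' available males and at her fecundity) and selects that many distinct males
#' uniformly; any male left unmated is then assigned one uniformly chosen
#' female so that every configured adult becomes a true parent. Each female's
#' total offspring count is drawn uniformly from the scenario's fecundity
#' range and divided among her mates: one offspring per mate guaranteed, the
#' remainder multinomial with equal probabilities.
#'
#' Parent identifiers are integers: mothers `1..n_females`, fathers
#' `n_females + (1..n_males)`.
#'
#' @param scenario A [breeding_scenario()].
#' @param seed Optional integer seed; when supplied the simulation is
#'   reproducible.
#' @return An object of class `"cohort_pedigree"`: a list with `offspring`
#'   (data.frame of `offspring_id`, `mother_id`, `father_id`), `n_females`,
#'   `n_males` and `true_n_p`.
#' @examples
#' ped <- simulate_breeding(breeding_scenario(3, 4, fecundity = c(20, 40)), seed = 1)
#' nrow(ped$offspring)
#' @export
simulate_breeding <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "breeding_scenario"))
  if (!is.null(seed)) set.seed(seed)
  nf <- scenario$n_females
  nm <- scenario$n_males

  fec <- sample.int(scenario$fecundity_max - scenario$fecundity_min + 1L, nf,
                    replace = TRUE) + scenario$fecundity_min - 1L
  n_mates <- pmin(rztpois(nf, scenario$mate_lambda), nm, fec)
  mates <- lapply(seq_len(nf), function(i) {
    sample.int(nm, n_mates[i]) + nf
  })

  # Guarantee every male is a parent: unmated males each join one female.
  mated <- unique(unlist(mates, use.names = FALSE))
  unmated <- setdiff(seq_len(nm) + nf, mated)
  for (m in unmated) {
    # only attach where fecundity can still cover one offspring per mate
    open <- which(fec > lengths(mates))
    if (length(open) == 0L)
      stop("cannot guarantee every male a mating: female fecundity exhausted; ",
           "increase fecundity or reduce n_males")
    f <- open[sample.int(length(open), 1L)]
    mates[[f]] <- c(mates[[f]], m)
  }

  per_female <- vector("list", nf)
  for (i in seq_len(nf)) {
    k <- length(mates[[i]])
    counts <- rep(1L, k)
    extra <- fec[i] - k
    if (extra > 0L)
      counts <- counts + as.integer(stats::rmultinom(1L, extra, rep(1 / k, k)))
    per_female[[i]] <- rep(mates[[i]], counts)
  }
  father <- unlist(per_female, use.names = FALSE)
  mother <- rep.int(seq_len(nf), fec)
  n_off <- length(father)

  structure(
    list(
      offspring = data.frame(offspring_id = seq_len(n_off),
                             mother_id = mother, father_id = father),
      n_females = nf, n_males = nm, true_n_p = scenario$true_n_p
    ),
    class = "cohort_pedigree"
  )
}

#' @export
print.cohort_pedigree <- function(x, ...) {
  cat("Cohort pedigree:", nrow(x$offspring), "offspring from", x$n_females,
      "females and", x$n_males, "males (N_P =", x$true_n_p, ")\n")
  invisible(x)
}

#' Sex of a parent identifier
#'
#' @param x A `"cohort_pedigree"` or `"offspring_sample"`.
#' @param id Integer parent id(s).
#' @return Character vector, `"female"` or `"male"`. Novel parents introduced
#'   by [inject_type2()] carry their sex in the sample's `novel_sex` table.
#' @export
parent_sex <- function(x, id) {
  nf <- x$n_females
  nm <- x$n_males
  out <- ifelse(id <= nf, "female", ifelse(id <= nf + nm, "male", NA_character_))
  if (anyNA(out) && !is.null(x$novel_sex)) {
    idx <- which(is.na(out))
    out[idx] <- unname(x$novel_sex[as.character(id[idx])])
  }
  out
}

#' Sample offspring from a simulated cohort
#'
#' Uniform sampling without replacement of `n_obs` offspring, carrying their
#' true parent identifiers. This is the "perfectly reconstructed pedigree"
#' sample; reconstruction errors can then be layered on with
#' [inject_type1()] / [inject_type2()].
#'
#' @param pedigree A `"cohort_pedigree"`.
#' @param n_obs Number of offspring to sample (0 <= n_obs <= cohort size).
#' @param seed Optional integer seed.
#' @return An object of class `"offspring_sample"`: list with `records`
#'   (data.frame `offspring_id`, `mother_id`, `father_id`), `n_obs`,
#'   `n_females`, `n_males`, `true_n_p` and `max_parent_id`.
#' @export
sample_offspring <- function(pedigree, n_obs, seed = NULL) {
  stopifnot(inherits(pedigree, "cohort_pedigree"))
  n_obs <- as.integer(n_obs)
  total <- nrow(pedigree$offspring)
  if (is.na(n_obs) || n_obs < 0L) stop("n_obs must be a nonnegative integer")
  if (n_obs > total)
    stop("n_obs (", n_obs, ") exceeds cohort size (", total, ")")
  if (!is.null(seed)) set.seed(seed)
  idx <- if (n_obs == total) seq_len(total) else sort(sample.int(total, n_obs))
  structure(
    list(records = pedigree$offspring[idx, , drop = FALSE],
         n_obs = n_obs,
         n_females = pedigree$n_females, n_males = pedigree$n_males,
         true_n_p = pedigree$true_n_p,
         max_parent_id = pedigree$n_females + pedigree$n_males,
         novel_sex = NULL),
    class = "offspring_sample"
  )
}

#' @export
print.offspring_sample <- function(x, ...) {
  nd <- length(unique(c(x$records$mother_id, x$records$father_id)))
  cat("Offspring sample: n_obs =", x$n_obs, "; detected parents =", nd, "\n")
  invisible(x)
}

#' Write / read an offspring sample as delimited text
#'
#' Three tab-separated columns (`offspring_id`, `mother_id`, `father_id`)
#' with a mandatory header row.
#'
#' @param sample An `"offspring_sample"`.
#' @param path File path.
#' @export
write_offspring_sample <- function(sample, path) {
  stopifnot(inherits(sample, "offspring_sample"))
  utils::write.table(sample$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_offspring_sample
#' @param n_females,n_males Population composition of the file being read,
#'   used to recover parent sexes from integer ids; if omitted they are
#'   inferred from the largest mother and father ids in the file (mothers
#'   are `1..n_females`, fathers `n_females + (1..n_males)`).
#' @export
read_offspring_sample <- function(path, n_females = NULL, n_males = NULL) {
  rec <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "integer")
  need <- c("offspring_id", "mother_id", "father_id")
  if (!all(need %in% names(rec)))
    stop("offspring sample file must have columns: ",
         paste(need, collapse = ", "))
  if (is.null(n_females)) n_females <- max(rec$mother_id)
  if (is.null(n_males)) n_males <- max(rec$father_id) - n_females
  structure(
    list(records = rec[, need], n_obs = nrow(rec),
         n_females = as.integer(n_females), n_males = as.integer(n_males),
         true_n_p = as.integer(n_females) + as.integer(n_males),
         max_parent_id = max(as.integer(n_females) + as.integer(n_males),
                             rec$mother_id, rec$father_id),
         novel_sex = NULL),
    class = "offspring_sample"
  )
}
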