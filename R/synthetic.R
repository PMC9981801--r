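#' Seeded synthetic cohorts, pedigrees and glucose traces
#'
#' The generators in this module produce data with the statistical
#' structure the pipeline assumes — timestamped multivariate indicator
#' records with a class-dependent mean shift, loop-free multi-generation
#' pedigrees with affected members, and smooth noisy glucose traces — so
#' every downstream module is exercisable without external data. All
#' generators are deterministic given their seed and leave the caller's
#' RNG state untouched.
#'
#' @name synthetic_data
NULL

#' Specification of a synthetic cohort
#'
#' @param n_patients positive number of patients.
#' @param n_features positive number of indicator columns `d`.
#' @param records_per_patient_range inclusive integer interval (length-2)
#'   from which each patient's record count is drawn; lower bound >= 1.
#' @param positive_fraction probability in `[0,1]` that a patient is in the
#'   positive (diabetic) class.
#' @param effect_size non-negative mean shift of the positive class, in
#'   units of the feature standard deviation `noise_sd`.
#' @param noise_sd positive per-record feature standard deviation.
#' @param seed integer RNG seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients, n_features = 5L,
                        records_per_patient_range = c(3L, 8L),
                        positive_fraction = 0.3, effect_size = 3,
                        noise_sd = 1, seed = 1L) {
  spec <- list(
    n_patients = check_count(n_patients, "n_patients"),
    n_features = check_count(n_features, "n_features"),
    records_per_patient_range = records_per_patient_range,
    positive_fraction = check_scalar(positive_fraction, "positive_fraction",
                                     min = 0, max = 1),
    effect_size = check_scalar(effect_size, "effect_size", min = 0),
    noise_sd = check_scalar(noise_sd, "noise_sd"),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  )
  r <- spec$records_per_patient_range
  if (!is.numeric(r) || length(r) != 2L || any(r != floor(r)) ||
      r[1] < 1L || r[2] < r[1]) {
    stop_param("records_per_patient_range",
               "must be an inclusive integer interval with lower bound >= 1")
  }
  if (spec$noise_sd <= 0) stop_param("noise_sd", "must be > 0")
  spec$records_per_patient_range <- as.integer(r)
  class(spec) <- "cohort_spec"
  spec
}

#' Generate a labeled synthetic cohort
#'
#' Each patient receives a label in \{-1, +1\} drawn Bernoulli
#' (`positive_fraction`), a record count drawn uniformly from
#' `records_per_patient_range`, strictly increasing integer-day
#' timestamps (gaps uniform on 1..7 days), and per-record features drawn
#' i.i.d. Gaussian around the class mean: 0 for negatives,
#' `effect_size * noise_sd` for positives, with standard deviation
#' `noise_sd` in every coordinate.
#'
#' @param spec a [cohort_spec].
#' @return an object of class `glycorisk_cohort`: list with `histories`
#'   (list of [patient_history]), `labels` (-1/+1 integer vector) and
#'   `n_features`.
#' @examples
#' co <- generate_cohort(cohort_spec(20, seed = 42))
#' table(co$labels)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  with_seed(spec$seed, {
    labels <- ifelse(stats::runif(spec$n_patients) < spec$positive_fraction,
                     1L, -1L)
    shift <- spec$effect_size * spec$noise_sd
    r <- spec$records_per_patient_range
    histories <- lapply(seq_len(spec$n_patients), function(i) {
      l <- if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
      gaps <- sample(1:7, l, replace = TRUE)
      ts <- cumsum(gaps) - gaps[1]  # start at day 0, strictly increasing
      mu <- if (labels[i] > 0) shift else 0
      f <- matrix(stats::rnorm(l * spec$n_features, mean = mu,
                               sd = spec$noise_sd),
                  nrow = l, ncol = spec$n_features)
      patient_history(sprintf("P%04d", i), ts, f)
    })
    structure(list(histories = histories, labels = labels,
                   n_features = spec$n_features, spec = spec),
              class = "glycorisk_cohort")
  })
}

#' @export
print.glycorisk_cohort <- function(x, ...) {
  cat(sprintf("<glycorisk_cohort: %d patients, %d features, %d positive>\n",
              length(x$histories), x$n_features, sum(x$labels > 0)))
  invisible(x)
}

#' Generate a loop-free multi-generation pedigree
#'
#' Founders form generation 1 as `n_founder_couples` mating pairs. Each
#' couple produces 2–3 children; children of the current generation are
#' paired greedily into next-generation couples, allowing only mates that
#' share no common ancestor, so the pedigree is non-inbred by
#' construction. Unpaired children remain as leaves. Affected status is
#' drawn Bernoulli(`affected_fraction`) for every member.
#'
#' @param generations positive integer number of generations.
#' @param affected_fraction proportion in `[0,1]`.
#' @param seed integer RNG seed.
#' @param n_founder_couples number of founder couples; defaults to
#'   `max(4, 2^(generations - 1))` so deep pedigrees keep enough
#'   unrelated lines to pair from.
#' @return a [pedigree] object; members carry a `generation` column.
#' @examples
#' ped <- generate_pedigree(3, affected_fraction = 0.3, seed = 7)
#' nrow(ped$members)
#' @export
generate_pedigree <- function(generations, affected_fraction = 0.25,
                              seed = 1L, n_founder_couples = NULL) {
  generations <- check_count(generations, "generations")
  affected_fraction <- check_scalar(affected_fraction, "affected_fraction",
                                    min = 0, max = 1)
  if (is.null(n_founder_couples)) {
    # deeper pedigrees need more unrelated founder lines to pair from
    n_founder_couples <- max(4L, 2L^(generations - 1L))
  }
  n_founder_couples <- check_count(n_founder_couples, "n_founder_couples")
  with_seed(seed, {
    next_id <- 0L
    new_id <- function() {
      next_id <<- next_id + 1L
      sprintf("I%03d", next_id)
    }
    rows <- list()
    add_member <- function(father, mother, gen) {
      id <- new_id()
      rows[[id]] <<- data.frame(id = id, father = father, mother = mother,
                                generation = gen,
                                stringsAsFactors = FALSE)
      id
    }
    # ancestor sets (including self) maintained incrementally
    anc <- list()
    record_anc <- function(id, father, mother) {
      up <- character(0)
      if (father != "0") up <- anc[[father]]
      if (mother != "0") up <- c(up, anc[[mother]])
      anc[[id]] <<- c(id, up)
    }
    couples <- lapply(seq_len(n_founder_couples), function(i) {
      f <- add_member("0", "0", 1L); record_anc(f, "0", "0")
      m <- add_member("0", "0", 1L); record_anc(m, "0", "0")
      c(f, m)
    })
    if (generations > 1L) {
      for (gen in 2L:generations) {
        children <- character(0)
        for (cp in couples) {
          for (k in seq_len(sample(2:3, 1L))) {
            id <- add_member(cp[1], cp[2], gen)
            record_anc(id, cp[1], cp[2])
            children <- c(children, id)
          }
        }
        if (gen == generations) break
        pool <- sample(children)
        couples <- list()
        while (length(pool) >= 2L) {
          mate <- NA_character_
          a <- NA_character_
          for (ii in seq_len(length(pool) - 1L)) {
            for (b in pool[-seq_len(ii)]) {
              if (length(intersect(anc[[pool[ii]]], anc[[b]])) == 0L) {
                a <- pool[ii]
                mate <- b
                break
              }
            }
            if (!is.na(mate)) break
          }
          if (is.na(mate)) break  # no unrelated pair left; rest are leaves
          couples <- c(couples, list(c(a, mate)))
          pool <- setdiff(pool, c(a, mate))
        }
        if (length(couples) == 0L) {
          stop("pedigree generation stalled: no unrelated mates available; ",
               "increase n_founder_couples", call. = FALSE)
        }
      }
    }
    members <- do.call(rbind, rows)
    members$affected <- as.integer(stats::runif(nrow(members)) <
                                     affected_fraction)
    rownames(members) <- NULL
    pedigree(members)
  })
}

#' Specification of a synthetic glucose trace
#'
#' @param length number of samples (>= 2).
#' @param baseline positive baseline glucose in mmol/L.
#' @param amplitude non-negative sinusoid amplitude in mmol/L.
#' @param period positive oscillation period in samples.
#' @param noise_sd non-negative Gaussian noise standard deviation.
#' @param seed integer RNG seed.
#' @param interval_minutes sampling interval metadata (default 5-minute
#'   ambulatory sampling).
#' @return a `trace_spec` list.
#' @export
trace_spec <- function(length = 288L, baseline = 8, amplitude = 3,
                       period = 48L, noise_sd = 0.3, seed = 1L,
                       interval_minutes = 5) {
  spec <- list(
    length = check_count(length, "length", min = 2L),
    baseline = check_scalar(baseline, "baseline"),
    amplitude = check_scalar(amplitude, "amplitude", min = 0),
    period = check_count(period, "period"),
    noise_sd = check_scalar(noise_sd, "noise_sd", min = 0),
    seed = check_count(seed, "seed", min = -.Machine$integer.max),
    interval_minutes = check_scalar(interval_minutes, "interval_minutes")
  )
  if (spec$baseline <= 0) stop_param("baseline", "must be > 0")
  class(spec) <- "trace_spec"
  spec
}

#' Generate a synthetic ambulatory glucose trace
#'
#' Produces `baseline + amplitude * sin(2*pi*t/period) + N(0, noise_sd)`
#' for `t = 0..length-1`, truncated below at 0 mmol/L.
#'
#' @param spec a [trace_spec].
#' @return a `glucose_series` object: list with `values` (mmol/L) and
#'   `interval_minutes`.
#' @examples
#' tr <- generate_trace(trace_spec(length = 48, noise_sd = 0, seed = 3))
#' range(tr$values)
#' @export
generate_trace <- function(spec) {
  if (!inherits(spec, "trace_spec")) spec <- do.call(trace_spec, spec)
  with_seed(spec$seed, {
    t <- seq_len(spec$length) - 1
    v <- spec$baseline +
      spec$amplitude * sin(2 * pi * t / spec$period) +
      stats::rnorm(spec$length, sd = spec$noise_sd)
    glucose_series(pmax(v, 0), interval_minutes = spec$interval_minutes)
  })
}

#' Construct a glucose series
#'
#' @param values numeric vector of glucose values in mmol/L, all finite
#'   and non-negative, length >= 2.
#' @param interval_minutes sampling interval metadata.
#' @return object of class `glucose_series`.
#' @export
glucose_series <- function(values, interval_minutes = 5) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop_param("values", "series length must be >= 2")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop_param("values", "glucose values must be finite and >= 0")
  }
  structure(list(values = values, interval_minutes = interval_minutes),
            class = "glucose_series")
}

#' @export
print.glucose_series <- function(x, ...) {
  cat(sprintf("<glucose_series: %d samples @ %g min, %.1f-%.1f mmol/L>\n",
              length(x$values), x$interval_minutes,
              min(x$values), max(x$values)))
  invisible(x)
}
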