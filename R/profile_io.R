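#' One replicate's extraction-time profile
#'
#' Container for a single SPME extraction-time series: GC peak area of
#' one compound, in one matrix/temperature condition, recorded at an
#' ascending set of extraction times for one replicate run.
#'
#' @param compound compound label.
#' @param condition condition label (e.g. matrix plus temperature).
#' @param replicate replicate identifier (1..3).
#' @param times extraction times in minutes, strictly increasing.
#' @param areas nonnegative peak areas aligned with `times`.
#' @param normalized has the profile been divided by its final-time area
#'   (so the last area is exactly 1)?
#' @return An object of class `extraction_profile`. Fields `holdout`
#'   (a `list(time, area)` withheld from fitting, see
#'   [select_validation_point()]) and `norm_divisor` (the area the run
#'   was normalized by) start out `NULL`.
#' @export
extraction_profile <- function(compound, condition, replicate, times, areas,
                               normalized = FALSE) {
  times <- as.numeric(times)
  areas <- as.numeric(areas)
  if (length(times) != length(areas)) {
    stop("times and areas must have equal length")
  }
  if (length(times) < 2) {
    stop("a profile needs at least two samples")
  }
  if (any(!is.finite(times)) || any(!is.finite(areas))) {
    stop("times and areas must be finite")
  }
  if (any(diff(times) <= 0)) {
    stop(sprintf(
      "duplicate or non-increasing times in %s / %s replicate %s",
      compound, condition, replicate
    ))
  }
  if (any(areas < 0)) {
    stop("peak areas must be nonnegative")
  }
  if (normalized && areas[length(areas)] != 1) {
    stop("a normalized profile must end at area exactly 1")
  }
  structure(
    list(
      compound = as.character(compound),
      condition = as.character(condition),
      replicate = replicate,
      times = times,
      areas = areas,
      normalized = isTRUE(normalized),
      holdout = NULL,
      norm_divisor = NULL
    ),
    class = "extraction_profile"
  )
}

#' @export
print.extraction_profile <- function(x, ...) {
  cat(sprintf(
    "extraction_profile: %s / %s, replicate %s, %d points over [%g, %g] min%s%s\n",
    x$compound, x$condition, x$replicate, length(x$times),
    min(x$times), max(x$times),
    if (x$normalized) ", normalized" else "",
    if (!is.null(x$holdout)) {
      sprintf(", holdout at t = %g", x$holdout$time)
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Triplicate set of extraction profiles
#'
#' Groups exactly three [extraction_profile()]s of the same compound and
#' condition; the triplicate is fitted jointly under one shared
#' weighting factor.
#'
#' @param profiles list of exactly three `extraction_profile`s.
#' @return An object of class `replicate_set` with elements `compound`,
#'   `condition` and `profiles`.
#' @export
replicate_set <- function(profiles) {
  if (length(profiles) != 3) {
    stop(sprintf(
      "a replicate set requires exactly 3 profiles (triplicate design), got %d%s",
      length(profiles),
      if (length(profiles) > 0) {
        sprintf(" for %s / %s", profiles[[1]]$compound, profiles[[1]]$condition)
      } else {
        ""
      }
    ))
  }
  compounds <- unique(vapply(profiles, `[[`, "", "compound"))
  conditions <- unique(vapply(profiles, `[[`, "", "condition"))
  if (length(compounds) != 1 || length(conditions) != 1) {
    stop("all profiles in a replicate set must share compound and condition")
  }
  structure(
    list(compound = compounds, condition = conditions, profiles = profiles),
    class = "replicate_set"
  )
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf(
    "replicate_set: %s / %s, 3 replicates\n", x$compound, x$condition
  ))
  for (p in x$profiles) print(p)
  invisible(x)
}

profile_columns <- c("compound", "condition", "replicate", "time_min", "peak_area")

#' Read replicate extraction profiles from CSV
#'
#' Reads a long-format CSV with columns `compound`, `condition`,
#' `replicate`, `time_min`, `peak_area`, groups rows into triplicate
#' [replicate_set()]s, and validates each group. Rows with non-finite
#' peak areas are dropped with a message; unsorted times are sorted with
#' a message; groups with other than three replicates, or duplicate
#' times within a replicate, raise an error naming the group.
#'
#' @param path path to a CSV file with a header row.
#' @return Named list of `replicate_set`s, keyed `compound | condition`.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(profile_columns, names(df))
  if (length(missing) > 0) {
    stop("missing required columns: ", paste(missing, collapse = ", "))
  }
  bad <- !is.finite(df$peak_area) | !is.finite(df$time_min)
  if (any(bad)) {
    message(sprintf(
      "dropping %d row(s) with non-finite time or peak area", sum(bad)
    ))
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0) {
    stop("no usable rows in ", path)
  }
  key <- paste(df$compound, df$condition, sep = " | ")
  sets <- lapply(split(df, key), function(grp) {
    reps <- split(grp, grp$replicate)
    if (length(reps) != 3) {
      stop(sprintf(
        "%s / %s has %d replicate(s); the triplicate design requires 3",
        grp$compound[1], grp$condition[1], length(reps)
      ))
    }
    profiles <- lapply(reps, function(r) {
      if (is.unsorted(r$time_min, strictly = TRUE)) {
        message(sprintf(
          "sorting times for %s / %s replicate %s",
          r$compound[1], r$condition[1], r$replicate[1]
        ))
        ord <- order(r$time_min)
        r <- r[ord, , drop = FALSE]
      }
      extraction_profile(
        compound = r$compound[1], condition = r$condition[1],
        replicate = r$replicate[1], times = r$time_min, areas = r$peak_area
      )
    })
    replicate_set(unname(profiles))
  })
  sets
}

#' Write replicate sets back to the long CSV schema
#'
#' Inverse of [read_profiles()] on valid data: emits one row per sample
#' with columns `compound`, `condition`, `replicate`, `time_min`,
#' `peak_area` (holdout points, if any, are written back in place).
#'
#' @param sets a `replicate_set` or list of them.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_profiles <- function(sets, path) {
  if (inherits(sets, "replicate_set")) sets <- list(sets)
  rows <- do.call(rbind, lapply(sets, function(s) {
    do.call(rbind, lapply(s$profiles, function(p) {
      times <- p$times
      areas <- p$areas
      if (!is.null(p$holdout)) {
        times <- c(times, p$holdout$time)
        areas <- c(areas, p$holdout$area)
        ord <- order(times)
        times <- times[ord]
        areas <- areas[ord]
      }
      data.frame(
        compound = p$compound, condition = p$condition,
        replicate = p$replicate, time_min = times, peak_area = areas,
        stringsAsFactors = FALSE
      )
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize a profile by its final-time area
#'
#' Divides every peak area of one run by the area at that run's final
#' sampling time, which the model takes as the run's equilibrium level;
#' the last normalized area is exactly 1. Idempotent. The divisor is
#' retained in `norm_divisor` so fitted amplitudes can be mapped back to
#' the raw scale.
#'
#' @param profile an [extraction_profile()] with positive final area.
#' @return The normalized profile.
#' @export
normalize_profile <- function(profile) {
  n <- length(profile$areas)
  divisor <- profile$areas[n]
  if (divisor <= 0) {
    stop("cannot normalize: final-time area is not positive")
  }
  profile$areas <- profile$areas / divisor
  profile$areas[n] <- 1 # guard rounding: last point defines the scale
  profile$normalized <- TRUE
  profile$norm_divisor <- if (is.null(profile$norm_divisor)) {
    divisor
  } else {
    profile$norm_divisor * divisor
  }
  profile
}

#' Normalize every profile of a replicate set
#'
#' @param set a [replicate_set()].
#' @return The set with each run normalized by its own final-time area.
#' @export
normalize_set <- function(set) {
  set$profiles <- lapply(set$profiles, normalize_profile)
  set
}

#' Sample with the largest observed peak area
#'
#' Returns the profile sample of maximal area; ties are broken to the
#' earliest time. A profile whose maximum sits at the last sample has no
#' interior peak and is flagged accordingly.
#'
#' @param profile an [extraction_profile()].
#' @return `list(time, area, interior)` where `interior` is `FALSE` for
#'   a monotone (no-interior-peak) profile.
#' @export
observed_peak <- function(profile) {
  i <- which.max(profile$areas) # first max = earliest time (times ascending)
  list(
    time = profile$times[i],
    area = profile$areas[i],
    interior = i < length(profile$areas)
  )
}

#' Withhold one validation point per replicate
#'
#' Marks the sample at `default_time` of every replicate as the hold-out
#' validation point and removes it from the fitting view. If that sample
#' is the replicate's observed peak, the latest non-peak sample is
#' withheld instead, so the characteristic peak point always remains
#' available to the fit.
#'
#' @param set a [replicate_set()].
#' @param default_time the nominal validation time in minutes (must be
#'   on every replicate's grid), e.g. 300 for beverage profiles or 20
#'   for chewing-gum profiles.
#' @return The set with each profile's `holdout` populated and the point
#'   removed from `times`/`areas`.
#' @export
select_validation_point <- function(set, default_time) {
  set$profiles <- lapply(set$profiles, function(p) {
    idx <- match(default_time, p$times)
    if (is.na(idx)) {
      stop(sprintf(
        "validation time %g not on the grid of %s / %s replicate %s (available: %s)",
        default_time, p$compound, p$condition, p$replicate,
        paste(p$times, collapse = ", ")
      ))
    }
    pk <- observed_peak(p)
    if (p$times[idx] == pk$time) {
      # default point is the observed peak: fall back to the latest
      # non-peak sample
      candidates <- setdiff(seq_along(p$times), idx)
      idx <- max(candidates)
    }
    p$holdout <- list(time = p$times[idx], area = p$areas[idx])
    p$times <- p$times[-idx]
    p$areas <- p$areas[-idx]
    p
  })
  set
}
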