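#' Assign birth years to half-open cohort bins
#'
#' Bins are contiguous half-open intervals `[start, start + width)` of birth
#' years, anchored at `origin_year` (default: the earliest birth year rounded
#' down to a multiple of the bin width). Every birth year maps to exactly one
#' cohort.
#'
#' @param birth_years integer vector (non-empty).
#' @param bin_width_years bin width in birth years (>= 1; width 1 puts each
#'   birth year in its own cohort).
#' @param origin_year optional anchor year for the bin grid.
#'
#' @return an object of class `cohort_assignment`: a list with `cohort`
#'   (factor aligned with `birth_years`, labelled `"start-end"`), `starts`,
#'   `bin_width_years`, `origin_year`, and `counts` (a tibble).
#' @export
#' @examples
#' a <- assign_cohorts(c(1950, 1954, 1955), 5)
#' table(a$cohort)
assign_cohorts <- function(birth_years, bin_width_years = 5,
                           origin_year = NULL) {
  if (length(birth_years) == 0) stop_config("birth_years is empty")
  if (any(is.na(birth_years))) stop_config("birth_years contains NA")
  if (bin_width_years < 1) stop_config("bin_width_years must be >= 1")
  w <- as.integer(bin_width_years)
  if (is.null(origin_year)) {
    origin_year <- floor(min(birth_years) / w) * w
  }
  origin_year <- as.integer(origin_year)
  starts <- origin_year + (floor((birth_years - origin_year) / w)) * w
  all_starts <- sort(unique(starts))
  labels <- sprintf("%d-%d", all_starts, all_starts + w - 1L)
  cohort <- factor(sprintf("%d-%d", starts, starts + w - 1L), levels = labels)
  n_per_bin <- as.integer(table(cohort)[labels])
  counts <- tibble::tibble(
    cohort = labels,
    birth_start = as.integer(all_starts),
    n = n_per_bin
  )
  structure(
    list(cohort = cohort, starts = as.integer(starts),
         bin_width_years = w, origin_year = origin_year, counts = counts),
    class = "cohort_assignment"
  )
}

#' @export
print.cohort_assignment <- function(x, ...) {
  cat(sprintf("<cohort_assignment: %d observations, %d cohorts, width %d>\n",
              length(x$cohort), nlevels(x$cohort), x$bin_width_years))
  print(x$counts)
  invisible(x)
}

# Merge cohorts with fewer than min_n observations into their nearest
# neighbouring cohort (by bin start). Prevents rank deficiency in the
# cohort-by-year interaction fit. Returns the factor of (possibly merged)
# cohort labels; warns once with the number of merges.
merge_sparse_cohorts <- function(cohort, min_n = 5) {
  cohort <- droplevels(as.factor(cohort))
  n_merged <- 0L
  repeat {
    tab <- table(cohort)
    if (nlevels(cohort) <= 1 || all(tab >= min_n)) break
    small <- names(tab)[which.min(tab)]
    lv <- levels(cohort)
    pos <- match(small, lv)
    neighbour <- if (pos == 1) lv[2] else if (pos == nlevels(cohort)) {
      lv[pos - 1]
    } else {
      # nearer neighbour by bin start; ties go to the older bin
      if (tab[lv[pos - 1]] <= tab[lv[pos + 1]]) lv[pos - 1] else lv[pos + 1]
    }
    merged_label <- paste(sort(c(small, neighbour)), collapse = "+")
    lv[lv %in% c(small, neighbour)] <- merged_label
    levels(cohort) <- lv
    n_merged <- n_merged + 1L
  }
  if (n_merged > 0) {
    warning(sprintf("merged %d sparse cohort(s) (< %d observations) into neighbours",
                    n_merged, min_n), call. = FALSE)
  }
  cohort
}
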