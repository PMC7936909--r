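# ADME screening of compound libraries.

#' Screen compounds by oral bioavailability and drug-likeness
#'
#' A compound passes the screen iff it satisfies `ob >= ob_min` and
#' `dl >= dl_min` (both thresholds inclusive), or it is whitelisted
#' (literature-added despite failing the thresholds), or it is an
#' animal-medicine entry (`source == "animal_db"`) with absent ADME values
#' -- such compounds come from a separate collection route that provides no
#' OB/DL and are retained unconditionally. Rejected compounds carry a
#' reason: `ob_fail`, `dl_fail` or `both_fail`.
#'
#' @param library data.frame as returned by [read_compound_library()].
#' @param config a [pipeline_config()]; supplies `ob_min` and `dl_min`.
#' @param use_whitelist set to `FALSE` to ignore the whitelist column and
#'   screen purely on thresholds.
#' @return list of class `screen_result` with elements `passed`, `rejected`
#'   (with `reason` column), `per_herb_counts` (named integer vector,
#'   compounds shared between herbs counted once per herb), and
#'   `pass_route` (factor over passed rows: `threshold`, `whitelist`,
#'   `animal_db`).
#' @export
screen_compounds <- function(library, config = pipeline_config(),
                             use_whitelist = TRUE) {
  stopifnot(nrow(library) > 0)
  has_ob <- !is.na(library$ob)
  has_dl <- !is.na(library$dl)
  animal_na <- library$source == "animal_db" & !has_ob & !has_dl
  inconsistent <- xor(has_ob, has_dl) & !library$whitelisted
  if (any(inconsistent)) {
    stop("compound(s) with exactly one of OB/DL present and not whitelisted: ",
         paste(library$name[inconsistent], collapse = ", "), call. = FALSE)
  }
  ob_ok <- has_ob & library$ob >= config$ob_min
  dl_ok <- has_dl & library$dl >= config$dl_min
  threshold_pass <- ob_ok & dl_ok
  whitelist_pass <- use_whitelist & library$whitelisted & !threshold_pass & !animal_na
  pass <- threshold_pass | whitelist_pass | animal_na

  reason <- rep(NA_character_, nrow(library))
  reason[!pass & !ob_ok & dl_ok] <- "ob_fail"
  reason[!pass & ob_ok & !dl_ok] <- "dl_fail"
  reason[!pass & !ob_ok & !dl_ok] <- "both_fail"

  passed <- library[pass, , drop = FALSE]
  rejected <- library[!pass, , drop = FALSE]
  if (nrow(rejected) > 0) rejected$reason <- reason[!pass]

  route <- character(nrow(passed))
  route[threshold_pass[pass]] <- "threshold"
  route[whitelist_pass[pass]] <- "whitelist"
  route[animal_na[pass]] <- "animal_db"

  counts <- table(unlist(split_herbs(passed$herbs)))
  per_herb <- stats::setNames(as.integer(counts), names(counts))
  per_herb <- sort(per_herb, decreasing = TRUE)

  structure(
    list(passed = passed, rejected = rejected, per_herb_counts = per_herb,
         pass_route = factor(route, levels = c("threshold", "whitelist",
                                               "animal_db"))),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("ADME screen: %d passed (%d threshold, %d whitelist, %d animal-db), %d rejected\n",
              nrow(x$passed), sum(x$pass_route == "threshold"),
              sum(x$pass_route == "whitelist"),
              sum(x$pass_route == "animal_db"), nrow(x$rejected)))
  cat("per-herb counts:\n")
  print(x$per_herb_counts)
  invisible(x)
}

#' Attribute screened compounds to herbs
#'
#' A compound attributed to several herbs appears in the set of every one of
#' them, so herb totals from this mapping match `per_herb_counts` of the
#' screen result.
#'
#' @param result a `screen_result` from [screen_compounds()].
#' @return named list mapping herb code to character vector of compound
#'   names.
#' @export
attribute_to_herbs <- function(result) {
  stopifnot(inherits(result, "screen_result"))
  if (nrow(result$passed) == 0) return(stats::setNames(list(), character()))
  pairs <- data.frame(
    herb = unlist(split_herbs(result$passed$herbs)),
    compound = rep(result$passed$name,
                   lengths(split_herbs(result$passed$herbs))),
    stringsAsFactors = FALSE
  )
  split(pairs$compound, pairs$herb)
}
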