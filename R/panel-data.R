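#' Panel data for an interval-censored illness-death process
#'
#' A panel dataset bundles, per subject, the visit grid at which the binary
#' disease marker was observed and the survival outcome. Disease is
#' irreversible, so the marker per subject is a block of 0s followed
#' (possibly) by a block of 1s; disease onset is only known to lie in the
#' half-open interval `(L, R]` between the last negative and the first
#' positive visit. Death time is observed exactly; if the last screen
#' before death or censoring was negative, the terminal disease status is
#' unknown.
#'
#' @param visits data.frame with columns `id`, `time` (months, ascending
#'   within subject, starting at 0), `marker` (0/1, non-decreasing within
#'   subject).
#' @param outcomes data.frame with columns `id`, `tstar` (end of follow-up
#'   in months), `delta` (1 = died at `tstar`, 0 = censored alive).
#' @return an object of class `idm_panel`: a list with validated `visits`
#'   and `outcomes` data.frames.
#' @examples
#' visits <- data.frame(id = "s1", time = c(0, 3, 6, 9),
#'                      marker = c(0, 0, 1, 1))
#' outcomes <- data.frame(id = "s1", tstar = 14, delta = 1)
#' pd <- idm_panel(visits, outcomes)
#' summarize_intervals(pd)
#' @export
idm_panel <- function(visits, outcomes) {
  need_v <- c("id", "time", "marker")
  need_o <- c("id", "tstar", "delta")
  if (!all(need_v %in% names(visits))) {
    stop("`visits` needs columns ", paste(need_v, collapse = ", "))
  }
  if (!all(need_o %in% names(outcomes))) {
    stop("`outcomes` needs columns ", paste(need_o, collapse = ", "))
  }
  visits$id <- as.character(visits$id)
  outcomes$id <- as.character(outcomes$id)
  if (anyDuplicated(outcomes$id)) stop("duplicated subject ids in `outcomes`")
  if (!setequal(unique(visits$id), outcomes$id)) {
    stop("`visits` and `outcomes` must cover the same subjects")
  }
  if (!all(outcomes$delta %in% c(0, 1))) stop("`delta` must be 0/1")
  if (!all(visits$marker %in% c(0, 1))) stop("`marker` must be 0/1")

  visits <- visits[order(visits$id, visits$time), , drop = FALSE]
  tstar <- setNames(outcomes$tstar, outcomes$id)
  for (sid in split(seq_len(nrow(visits)), visits$id)) {
    tm <- visits$time[sid]; mk <- visits$marker[sid]
    id1 <- visits$id[sid[1]]
    if (tm[1] != 0) stop("subject ", id1, ": first visit must be at time 0")
    if (any(diff(tm) <= 0)) {
      stop("subject ", id1, ": visit times must be strictly increasing")
    }
    if (any(diff(mk) < 0)) {
      stop("subject ", id1, ": marker must be non-decreasing (irreversible disease)")
    }
    if (tm[length(tm)] > tstar[[id1]] + 1e-9) {
      stop("subject ", id1, ": last visit exceeds end of follow-up")
    }
  }
  structure(list(visits = visits, outcomes = outcomes), class = "idm_panel")
}

#' @export
print.idm_panel <- function(x, ...) {
  n <- nrow(x$outcomes)
  cat(sprintf("Illness-death panel: %d subjects, %d visit records, %d deaths\n",
              n, nrow(x$visits), sum(x$outcomes$delta)))
  invisible(x)
}

#' Interval-censoring summary of a panel dataset
#'
#' Reduces each subject's visit history to the quadruple used by the
#' interval-censored likelihoods: `L`, the last disease-free visit; `R`,
#' the first positive visit (`NA` if disease was never observed); `tstar`
#' the end of follow-up; `delta` the death indicator. Onset lies in
#' `(L, R]` when `R` is observed.
#'
#' @param panel an [idm_panel()].
#' @return data.frame with columns `id`, `L`, `R`, `tstar`, `delta`, one
#'   row per subject, in `outcomes` order.
#' @export
summarize_intervals <- function(panel) {
  stopifnot(inherits(panel, "idm_panel"))
  v <- panel$visits
  idx <- split(seq_len(nrow(v)), v$id)
  LR <- vapply(idx, function(i) {
    tm <- v$time[i]; mk <- v$marker[i]
    if (any(mk == 1)) {
      r <- tm[match(1, mk)]
      l <- if (match(1, mk) > 1) tm[match(1, mk) - 1] else 0
      c(l, r)
    } else {
      c(tm[length(tm)], NA_real_)
    }
  }, numeric(2))
  out <- data.frame(id = colnames(LR), L = LR[1, ], R = LR[2, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- merge(out, panel$outcomes, by = "id", sort = FALSE)
  out[match(panel$outcomes$id, out$id), , drop = FALSE]
}

#' Read and write panel data as CSV
#'
#' The on-disk form is two long-format UTF-8 CSV files with header rows:
#' visits (`id,time,marker`) and outcomes (`id,tstar,delta`). Derived
#' interval summaries are written as `id,L,R,tstar,delta` with an empty
#' field for an absent `R`.
#'
#' @param panel an [idm_panel()].
#' @param visits_file,outcomes_file CSV paths.
#' @return `read_idm_panel` returns an [idm_panel()];
#'   `write_idm_panel` returns `panel` invisibly.
#' @export
write_idm_panel <- function(panel, visits_file, outcomes_file) {
  stopifnot(inherits(panel, "idm_panel"))
  write.csv(panel$visits, visits_file, row.names = FALSE, quote = FALSE)
  write.csv(panel$outcomes, outcomes_file, row.names = FALSE, quote = FALSE)
  invisible(panel)
}

#' @rdname write_idm_panel
#' @export
read_idm_panel <- function(visits_file, outcomes_file) {
  idm_panel(read.csv(visits_file, stringsAsFactors = FALSE),
            read.csv(outcomes_file, stringsAsFactors = FALSE))
}

#' @rdname write_idm_panel
#' @param intervals data.frame as returned by [summarize_intervals()].
#' @param file CSV path for the interval summary.
#' @export
write_intervals <- function(intervals, file) {
  write.csv(intervals, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(intervals)
}
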