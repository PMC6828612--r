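#' Classify trials relative to isolated errors
#'
#' Labels every trial of one subject with its position relative to isolated
#' commission errors. An error is *isolated* when at least three correct
#' trials immediately precede and follow it within the same block; its six
#' correct neighbours are labelled `ER_M3`..`ER_M1` (before) and
#' `ER_P1`..`ER_P3` (after). A correct trial is `ERROR_FREE` when no
#' non-correct trial (commission error or miss) lies within distance 3 inside
#' the block. Everything else - non-isolated errors, misses, corrects near
#' errors that are not neighbours of an isolated error - is `EXCLUDED`.
#'
#' Classification windows never cross block boundaries: blocks were recorded
#' separately, so context outside a block is treated as error-free for the
#' `ERROR_FREE` rule, while an error closer than four trials to a block edge
#' can never be isolated (its required neighbours do not all exist).
#'
#' Ambiguity rule: with exactly three correct trials between two isolated
#' errors a correct trial would be a neighbour of both; such trials are
#' `EXCLUDED` rather than given two labels, so the labels always partition
#' the trials.
#'
#' Misses (non-responses) count as non-correct: they break correct runs and
#' disqualify adjacent errors from isolation, but are never themselves
#' `ERROR_ISOLATED` (only commission errors are).
#'
#' Classification depends only on the correctness/miss sequence and the block
#' structure, never on reaction times.
#'
#' @param correct logical (or 0/1) vector, one element per trial, in
#'   chronological order within subject.
#' @param block integer vector of block indices (1-based), non-decreasing.
#' @param miss logical vector flagging missed responses (default: none).
#'   A missed trial must also have `correct = FALSE`.
#' @return factor of length `length(correct)` with levels
#'   `r paste(PERI_LABELS, collapse = ", ")`.
#' @examples
#' classify_trials(c(1, 1, 1, 0, 1, 1, 1), rep(1, 7))
#' @export
classify_trials <- function(correct, block, miss = NULL) {
  n <- length(correct)
  correct <- as.logical(correct)
  if (length(block) != n) stop("`block` must have one entry per trial")
  if (any(is.na(correct))) stop("`correct` must not contain NA")
  if (is.unsorted(block)) {
    stop("trials must be ordered by (block, index); `block` is not non-decreasing")
  }
  if (is.null(miss)) miss <- rep(FALSE, n)
  miss <- as.logical(miss)
  if (any(miss & correct)) stop("a missed trial cannot be correct")

  labels <- rep("EXCLUDED", n)
  noncorrect <- !correct
  commission <- !correct & !miss

  for (b in unique(block)) {
    idx <- which(block == b)
    nb <- length(idx)
    corr_b <- correct[idx]
    nonc_b <- noncorrect[idx]
    comm_b <- commission[idx]
    lab_b <- rep("EXCLUDED", nb)

    iso <- logical(nb)
    for (i in which(comm_b)) {
      if (i >= 4L && i <= nb - 3L &&
          all(corr_b[(i - 3L):(i - 1L)]) && all(corr_b[(i + 1L):(i + 3L)])) {
        iso[i] <- TRUE
      }
    }
    lab_b[iso] <- "ERROR_ISOLATED"

    iso_idx <- which(iso)
    for (j in which(corr_b)) {
      d <- j - iso_idx
      near <- d[abs(d) <= 3L]
      if (length(near) == 1L) {
        k <- near[1L]
        lab_b[j] <- if (k > 0) paste0("ER_P", k) else paste0("ER_M", -k)
      } else if (length(near) == 0L) {
        lo <- max(1L, j - 3L); hi <- min(nb, j + 3L)
        if (!any(nonc_b[lo:hi])) lab_b[j] <- "ERROR_FREE"
      } # >= 2 neighbours of isolated errors: stays EXCLUDED (ambiguous)
    }
    labels[idx] <- lab_b
  }
  factor(labels, levels = PERI_LABELS)
}

#' Signed peri-error position of a classification label
#'
#' Maps peri-error labels to the trial-position covariate used by the mixed
#' models: -3..-1 for pre-error trials, 0 for the isolated error itself,
#' +1..+3 for post-error trials, `NA` for error-free and excluded trials.
#'
#' @param label factor or character vector of peri-error labels.
#' @return integer vector of positions.
#' @export
peri_position <- function(label) {
  map <- c(ER_M3 = -3L, ER_M2 = -2L, ER_M1 = -1L, ERROR_ISOLATED = 0L,
           ER_P1 = 1L, ER_P2 = 2L, ER_P3 = 3L,
           ERROR_FREE = NA_integer_, EXCLUDED = NA_integer_)
  unname(map[as.character(label)])
}
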