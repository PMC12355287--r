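#' Score a numeric vector into empirical quantile bins
#'
#' Assigns score \eqn{k \in \{0, \dots, q-1\}} when a value falls in the
#' k-th empirical q-quantile bin.  Bins are right-closed on the
#' empirical quantile cut points, so ties at a cut point go to the lower
#' bin; scores depend only on ranks, so any strictly increasing
#' transform of the data leaves them unchanged.  Cut points may be
#' supplied (e.g. computed on a reference sample) so that scores mean
#' the same thing across data splits.
#'
#' @param x numeric vector, finite.
#' @param q number of quantile groups (10 = deciles).
#' @param cuts optional numeric vector of q+1 cut points; computed from
#'   \code{x} when \code{NULL}.
#' @return integer vector of scores in 0..q-1 with the cut points in
#'   attribute \code{"cuts"}.  A column with no variation gets all-zero
#'   scores and a warning.
#' @examples
#' quantile_scores(seq(10, 100, by = 10))  # 0 1 2 ... 9
#' @export
quantile_scores <- function(x, q = 10L, cuts = NULL) {
  stopifnot(is.numeric(x))
  if (any(!is.finite(x))) stop("non-finite exposure values")
  if (is.null(cuts)) {
    if (length(x) < q)
      stop("need at least q = ", q, " observations to form quantile bins")
    cuts <- quantile(x, probs = seq(0, 1, length.out = q + 1L),
                     names = FALSE, type = 7)
  }
  br <- unique(cuts)
  if (length(br) < 2L) {
    warning("degenerate constituent: no variation, all scores set to 0")
    out <- rep.int(0L, length(x))
    attr(out, "cuts") <- cuts
    return(out)
  }
  if (is.unsorted(cuts)) stop("cut points must be non-decreasing")
  # right-closed bins (br[b], br[b+1]]; values at/below the lowest cut
  # point and above the highest collapse into the extreme bins
  b <- findInterval(x, br, left.open = TRUE)
  b[b < 1L] <- 1L
  b[b > length(br) - 1L] <- length(br) - 1L
  # a bin's score is the 0-based index of its left cut's LAST occurrence
  # among the original cut points, so scores stay on the 0..q-1 scale
  # when empirical quantiles tie
  score_of_bin <- findInterval(br, cuts) - 1L
  out <- as.integer(score_of_bin[b])
  attr(out, "cuts") <- cuts
  out
}

#' Decile-transform an exposure table
#'
#' Applies \code{\link{quantile_scores}} to each constituent column of a
#' linked exposure table.  Cut points are computed once on the full
#' analysis sample (or taken from \code{cuts}) so training and
#' validation halves share the same decile meaning.
#'
#' @param exposures data frame with \code{id} plus one numeric column
#'   per constituent (the output of \code{\link{link_exposures}}).
#' @param q number of quantile groups.
#' @param cuts optional list of per-constituent cut-point vectors.
#' @return data frame of integer scores with \code{id}; attribute
#'   \code{"cuts"} holds the list of per-constituent cut points.
#' @export
quantile_transform <- function(exposures, q = 10L, cuts = NULL) {
  stopifnot(is.data.frame(exposures), "id" %in% names(exposures))
  cons <- setdiff(names(exposures), "id")
  out <- exposures["id"]
  cutlist <- vector("list", length(cons))
  names(cutlist) <- cons
  for (cc in cons) {
    s <- quantile_scores(exposures[[cc]], q = q,
                         cuts = if (is.null(cuts)) NULL else cuts[[cc]])
    cutlist[[cc]] <- attr(s, "cuts")
    out[[cc]] <- as.integer(s)
  }
  attr(out, "cuts") <- cutlist
  attr(out, "q") <- as.integer(q)
  out
}

#' Weighted quantile sum mixture index
#'
#' Computes \eqn{wqs = \sum_i w_i d_i}, the weighted sum of per-
#' constituent quantile scores.  With weights on the simplex and decile
#' scores in 0..9 the index lies in [0, 9] and moves by exactly
#' \eqn{w_i} when constituent i's score moves by one decile.
#'
#' @param deciles matrix or data frame of quantile scores (constituent
#'   columns only, or a \code{quantile_transform} result with its
#'   \code{id} column).
#' @param w named or positional weight vector matching the constituent
#'   columns.
#' @return numeric vector, one index value per row.
#' @export
mixture_index <- function(deciles, w) {
  D <- deciles
  if (is.data.frame(D)) {
    if ("id" %in% names(D)) D <- D[setdiff(names(D), "id")]
    D <- as.matrix(D)
  }
  if (!is.null(names(w)) && !is.null(colnames(D))) {
    if (!setequal(names(w), colnames(D)))
      stop("weight names do not match decile columns")
    w <- w[colnames(D)]
  }
  if (length(w) != ncol(D))
    stop("dimension mismatch: ", length(w), " weights vs ",
         ncol(D), " constituents")
  drop(D %*% as.numeric(w))
}

#' Reproducible train/validation split
#'
#' Simple random partition of recipients into a training set (used only
#' for bootstrap weight estimation) and a validation set (used only for
#' the stage-2 regression).  The same seed always yields the same
#' assignment.
#'
#' @param ids vector of recipient identifiers.
#' @param train_fraction fraction assigned to training, in (0, 1).
#' @param seed integer seed for the split stream.
#' @return list with \code{train} and \code{validation} id vectors and
#'   an \code{assignment} factor aligned with \code{ids}.
#' @export
split_cohort <- function(ids, train_fraction = 0.4, seed = 1L) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  n <- length(ids)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, "split"))
  n_train <- round(n * train_fraction)
  idx <- sample.int(n, n_train)
  assignment <- factor(rep("validation", n), levels = c("train", "validation"))
  assignment[idx] <- "train"
  list(train = ids[idx], validation = ids[-idx], assignment = assignment,
       train_fraction = train_fraction, seed = seed)
}
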